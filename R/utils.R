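#' Count local maxima of a sampled profile
#'
#' Plateau-aware peak counting for sampled cross-sections: a maximum is a
#' (possibly flat) run of samples strictly above its neighbours on both
#' sides. Peaks below `threshold` times the global maximum are ignored, so
#' numerical ripple far below the image peaks does not count. Endpoints are
#' not peaks.
#'
#' @param values Numeric vector of profile samples.
#' @param threshold Minimum peak height as a fraction of the maximum.
#' @return Integer count of local maxima.
#' @export
count_local_maxima <- function(values, threshold = 0.01) {
  v <- as.numeric(values)
  if (length(v) < 3 || max(v) <= 0) return(0L)
  s <- sign(diff(v))
  pos <- which(s != 0)
  if (length(pos) < 2) return(0L)
  sn <- s[pos]                        # nonzero slope signs, in order
  peak_at <- which(sn[-length(sn)] == 1 & sn[-1] == -1)
  if (!length(peak_at)) return(0L)
  heights <- v[pos[peak_at] + 1]      # sample at the top of the rise
  sum(heights >= threshold * max(v))
}
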