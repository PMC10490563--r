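# Bessel helpers valid on the whole real line (base besselJ/besselY require
# x >= 0). J0 is even, J1 is odd; the Hankel kernels only ever see positive
# arguments.

bessel_j0 <- function(x) besselJ(abs(x), 0)

bessel_j1 <- function(x) sign(x) * besselJ(abs(x), 1)

# Zeroth/first order Hankel functions of the first kind, x > 0.
hankel1_0 <- function(x) complex(real = besselJ(x, 0), imaginary = besselY(x, 0))

hankel1_1 <- function(x) complex(real = besselJ(x, 1), imaginary = besselY(x, 1))

# d/du J0(u)^2 = -2 J0(u) J1(u)
d_j0sq <- function(u) -2 * bessel_j0(u) * bessel_j1(u)

# d^2/du^2 J0(u)^2 = -2 [J0^2 - J1^2 - J0 J1 / u], with limit 2*(-1/2) ... at
# u = 0 the bracket tends to 1 - 0 - 1/2 = 1/2, so the value tends to -1.
dd_j0sq <- function(u) {
  u <- as.numeric(u)
  out <- numeric(length(u))
  small <- abs(u) < 1e-8
  if (any(!small)) {
    us <- u[!small]
    out[!small] <- -2 * (bessel_j0(us)^2 - bessel_j1(us)^2 -
                           bessel_j0(us) * bessel_j1(us) / us)
  }
  if (any(small)) out[small] <- -1
  out
}
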