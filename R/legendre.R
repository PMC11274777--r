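# Legendre polynomials P_n(x) and derivatives P_n'(x) for n = 1..nmax,
# evaluated by upward recursion (stable on [-1, 1], defined at the poles).
legendre_table <- function(nmax, x) {
  x <- as.numeric(x)
  m <- length(x)
  P <- matrix(0, nrow = nmax, ncol = m)
  dP <- matrix(0, nrow = nmax, ncol = m)
  Pm1 <- rep(1, m)        # P_0
  P[1, ] <- x             # P_1
  dP[1, ] <- 1
  if (nmax >= 2) {
    for (n in 2:nmax) {
      P[n, ] <- ((2 * n - 1) * x * P[n - 1, ] - (n - 1) *
                   (if (n == 2) Pm1 else P[n - 2, ])) / n
      # P_n' = P_{n-2}' + (2n-1) P_{n-1}
      dP[n, ] <- (if (n == 2) 0 else dP[n - 2, ]) + (2 * n - 1) * P[n - 1, ]
    }
  }
  list(P = P, dP = dP)
}
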