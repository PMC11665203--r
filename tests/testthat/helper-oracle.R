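# Independent brute-force oracles used by the vesselness tests: explicit
# per-pixel 2x2 eigendecomposition (base eigen()) of finite-difference
# second derivatives of the smoothed image, and the vesselness formula
# evaluated scalar-by-scalar on top of it.

oracle_hessian_eig <- function(m, sigma) {
  s <- gaussian_smooth(m, sigma)
  nr <- nrow(s); nc <- ncol(s)
  l1 <- matrix(0, nr, nc); l2 <- matrix(0, nr, nc)
  cl <- function(i, n) min(max(i, 1L), n)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      hyy <- s[cl(i - 1, nr), j] + s[cl(i + 1, nr), j] - 2 * s[i, j]
      hxx <- s[i, cl(j - 1, nc)] + s[i, cl(j + 1, nc)] - 2 * s[i, j]
      hxy <- (s[cl(i + 1, nr), cl(j + 1, nc)] +
              s[cl(i - 1, nr), cl(j - 1, nc)] -
              s[cl(i + 1, nr), cl(j - 1, nc)] -
              s[cl(i - 1, nr), cl(j + 1, nc)]) / 4
      H <- sigma^2 * matrix(c(hxx, hxy, hxy, hyy), 2L)
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      o <- order(abs(ev))
      l1[i, j] <- ev[o[1]]; l2[i, j] <- ev[o[2]]
    }
  }
  list(l1 = l1, l2 = l2)
}

oracle_frangi <- function(m, params) {
  sigma <- params$kernel_px / 2
  eig <- oracle_hessian_eig(m, sigma)
  S <- sqrt(eig$l1^2 + eig$l2^2)
  border <- ceiling(2 * sigma)
  nr <- nrow(S); nc <- ncol(S)
  Si <- if (nr > 2 * border + 2 && nc > 2 * border + 2)
    S[(border + 1):(nr - border), (border + 1):(nc - border)] else S
  cc <- if (params$c_mode == "adaptive") max(Si) / 2 else params$c_value
  v <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      lam1 <- eig$l1[i, j]; lam2 <- eig$l2[i, j]
      if (lam2 >= 0) next
      rb2 <- (lam1 / lam2)^2
      s2 <- lam1^2 + lam2^2
      v[i, j] <- exp(-rb2 / (2 * params$beta^2)) *
        (1 - exp(-s2 / (2 * cc^2)))
    }
  }
  v
}
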