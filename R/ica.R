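# Fixed-point (FastICA-style) independent component analysis with the
# logcosh contrast, symmetric decorrelation, and PCA whitening.
#
# x: mixtures x observations matrix (here: samples x genes). Returns the
# estimated sources (n_comp x observations), i.e. component loading vectors
# over genes. No package on the system provides this primitive, so it is
# implemented here.

fastica_logcosh <- function(x, n_comp, seed = 1, maxit = 200, tol = 1e-6,
                            alpha = 1) {
  x <- as.matrix(x)
  m <- nrow(x)
  g <- ncol(x)
  if (n_comp > m) stop("n_comp exceeds the number of mixtures")
  xc <- x - rowMeans(x)

  cv <- tcrossprod(xc) / (g - 1)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12
  if (sum(pos) < n_comp)
    stop("requested ", n_comp, " components but data rank is ", sum(pos))
  d <- eg$values[seq_len(n_comp)]
  k <- sweep(t(eg$vectors[, seq_len(n_comp), drop = FALSE]), 1, sqrt(d), "/")
  z <- k %*% xc  # whitened: rows approx uncorrelated, unit variance

  w <- with_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(n_comp * n_comp), n_comp, n_comp)))
  })
  sym_decorrelate <- function(w) {
    s <- svd(w)
    s$u %*% t(s$v)
  }
  w <- sym_decorrelate(w)
  for (it in seq_len(maxit)) {
    u <- w %*% z
    gu <- tanh(alpha * u)
    w1 <- gu %*% t(z) / g - diag(alpha * rowMeans(1 - gu^2), n_comp) %*% w
    w1 <- sym_decorrelate(w1)
    conv <- max(abs(abs(diag(w1 %*% t(w))) - 1))
    w <- w1
    if (conv < tol) break
  }
  s <- w %*% z
  rownames(s) <- paste0("IC", seq_len(n_comp))
  colnames(s) <- colnames(x)
  s
}

# Unit-normalize rows and orient each so its loading distribution has
# positive skew (ICA signs are arbitrary; the 3-SD module rule is
# one-directional, so the heavier tail is made positive).
orient_components <- function(s) {
  nrm <- sqrt(rowSums(s^2))
  nrm[nrm == 0] <- 1
  s <- s / nrm
  ctr <- s - rowMeans(s)
  skew <- rowMeans(ctr^3) / (rowMeans(ctr^2)^1.5 + 1e-300)
  flip <- skew < 0
  s[flip, ] <- -s[flip, , drop = FALSE]
  s
}
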