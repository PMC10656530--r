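# Fixed-point ICA with a logcosh contrast and symmetric decorrelation.
# Written against the standard whitened FastICA iteration; kept internal —
# trait extraction is the supported surface.

# Symmetric decorrelation: W <- (W W^T)^{-1/2} W
.sym_decorrelate <- function(w) {
  e <- eigen(w %*% t(w), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% (t(e$vectors) / sqrt(vals)) %*% w
}

# Fixed-point ICA on an n x p data matrix (rows = observations).
# Returns NULL on non-convergence. Sources come back as n x n.comp columns
# with unit variance; the caller handles scaling conventions.
.fastica <- function(x, n.comp, seed = NULL, alpha = 1,
                     tol = 1e-6, maxit = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  p <- ncol(x)
  if (n.comp > p) stop("n.comp exceeds the number of variables")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)

  # whiten via the p x p covariance (p = M rows of the group matrix, small)
  cv <- crossprod(xc) / n
  e <- eigen(cv, symmetric = TRUE)
  if (e$values[n.comp] < 1e-12) stop("data rank below n.comp; reduce n.comp")
  k_mat <- e$vectors[, seq_len(n.comp), drop = FALSE] %*%
    diag(1 / sqrt(e$values[seq_len(n.comp)]), n.comp)
  z <- xc %*% k_mat  # n x n.comp, identity covariance

  w <- matrix(stats::rnorm(n.comp * n.comp), n.comp, n.comp)
  w <- .sym_decorrelate(w)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    wx <- z %*% t(w)                       # n x n.comp
    g <- tanh(alpha * wx)
    g_prime <- alpha * colMeans(1 - g^2)
    w1 <- crossprod(g, z) / n - g_prime * w
    w1 <- .sym_decorrelate(w1)
    delta <- max(abs(abs(diag(w1 %*% t(w))) - 1))
    w <- w1
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) return(NULL)
  s <- z %*% t(w)  # n x n.comp independent sources, unit variance
  list(sources = s, unmixing = w, whitening = k_mat, center = mu)
}
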