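# Subject identifiability: test-retest similarity of edge vectors, the
# differential-identifiability score, and the PCA-reconstruction sweep that
# selects the number of components K maximizing it.

#' Test-retest identifiability matrix
#'
#' Entry (i, j) is the Pearson correlation between subject i's monoband edge
#' vector (test) and subject j's multiband edge vector (retest). The diagonal
#' therefore holds within-subject FC similarity, the off-diagonal
#' between-subject similarity.
#'
#' @param group A `group_fc` object with exactly one monoband and one
#'   multiband row per subject.
#' @return An S x S numeric matrix, S = number of subjects, with subject ids
#'   on both dimnames.
#' @export
identifiability_matrix <- function(group) {
  idx <- group$index
  subjects <- unique(idx$subject)
  mono <- match(paste(subjects, "monoband"), paste(idx$subject, idx$session))
  multi <- match(paste(subjects, "multiband"), paste(idx$subject, idx$session))
  if (anyNA(mono) || anyNA(multi)) {
    bad <- subjects[is.na(mono) | is.na(multi)]
    stop("missing session row for subject(s): ", paste(bad, collapse = ", "))
  }
  im <- stats::cor(t(group$matrix[mono, , drop = FALSE]),
                   t(group$matrix[multi, , drop = FALSE]))
  dimnames(im) <- list(subjects, subjects)
  im
}

#' Differential identifiability of an identifiability matrix
#'
#' I_diff = (mean within-subject similarity - mean between-subject
#' similarity) x 100, i.e. the diagonal mean minus the off-diagonal mean of
#' the identifiability matrix, on a percent-like scale.
#'
#' @param ident An S x S identifiability matrix (S >= 2).
#' @return A list with `i_self`, `i_others` and `i_diff`.
#' @export
compute_idiff <- function(ident) {
  s <- nrow(ident)
  if (is.null(s) || s < 2 || ncol(ident) != s) {
    stop("ident must be a square matrix with at least 2 subjects")
  }
  i_self <- mean(diag(ident))
  off <- ident[row(ident) != col(ident)]
  i_others <- mean(off)
  list(i_self = i_self, i_others = i_others,
       i_diff = (i_self - i_others) * 100)
}

#' PCA reconstruction of a group FC matrix at rank k
#'
#' Columns (edges) are mean-centered across the M rows, decomposed by SVD,
#' reconstructed from the top-k components, and the column means added back.
#' No variance scaling is applied: all edges already live on a common
#' correlation scale.
#'
#' @param group A `group_fc` object.
#' @param k Number of principal components to retain, `1 <= k <= min(M, E)`.
#' @return A `group_fc` object with the reconstructed matrix and the same
#'   row index.
#' @export
pca_reconstruct <- function(group, k) {
  x <- group$matrix
  if (k < 1 || k > min(dim(x))) stop("k out of range [1, min(M, E)]")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = k, nv = k)
  recon <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
  recon <- sweep(recon, 2, mu, `+`)
  dimnames(recon) <- dimnames(x)
  group_fc(recon, group$index)
}

#' Differential-identifiability sweep over PCA reconstructions
#'
#' For each K in `k_range`, reconstructs the group FC matrix from its top-K
#' principal components and computes the differential identifiability of the
#' reconstruction. The optimal K attains the maximum I_diff; ties are broken
#' toward the smallest K (parsimony). The unreconstructed data's own I_diff
#' is reported alongside for reference.
#'
#' @param group A `group_fc` object.
#' @param k_range Integer vector of K values to evaluate; default every
#'   integer from 2 to M (the row rank bounds the useful range).
#' @param stride Optional stride applied to the default range for speed.
#' @return A list of class `idiff_sweep` with `curve` (data.frame: k,
#'   i_self, i_others, i_diff), `optimal_k`, `optimal` (the
#'   [compute_idiff()] result at the optimum), `original` (I_diff of the
#'   input data) and `reconstructed` (a `group_fc` at the optimal K).
#' @export
sweep_identifiability <- function(group, k_range = NULL, stride = 1L) {
  x <- group$matrix
  m <- nrow(x)
  if (is.null(k_range)) k_range <- seq(2L, m, by = as.integer(stride))
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) stop("k_range is empty")
  if (min(k_range) < 2 || max(k_range) > min(dim(x))) {
    stop("k_range must lie within [2, min(M, E)]")
  }

  idx <- group$index
  subjects <- unique(idx$subject)
  mono <- match(paste(subjects, "monoband"), paste(idx$subject, idx$session))
  multi <- match(paste(subjects, "multiband"), paste(idx$subject, idx$session))
  if (anyNA(mono) || anyNA(multi)) stop("every subject needs both sessions")

  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))  # M x r

  idiff_of <- function(recon) {
    im <- stats::cor(t(recon[mono, , drop = FALSE]),
                     t(recon[multi, , drop = FALSE]))
    compute_idiff(im)
  }

  curve <- data.frame(k = k_range, i_self = NA_real_, i_others = NA_real_,
                      i_diff = NA_real_)
  for (ii in seq_along(k_range)) {
    k <- k_range[ii]
    recon <- scores[, seq_len(k), drop = FALSE] %*%
      t(sv$v[, seq_len(k), drop = FALSE])
    recon <- sweep(recon, 2, mu, `+`)
    res <- idiff_of(recon)
    curve$i_self[ii] <- res$i_self
    curve$i_others[ii] <- res$i_others
    curve$i_diff[ii] <- res$i_diff
  }

  best <- which.max(curve$i_diff)  # first maximum = smallest K on ties
  optimal_k <- curve$k[best]
  reconstructed <- pca_reconstruct(group, optimal_k)
  structure(list(
    curve = curve,
    optimal_k = optimal_k,
    optimal = list(i_self = curve$i_self[best],
                   i_others = curve$i_others[best],
                   i_diff = curve$i_diff[best]),
    original = idiff_of(x),
    reconstructed = reconstructed
  ), class = "idiff_sweep")
}

#' @export
print.idiff_sweep <- function(x, ...) {
  cat(sprintf(
    "identifiability sweep over %d values of K\n  original I_diff: %.2f\n  optimal K = %d with I_diff = %.2f\n",
    nrow(x$curve), x$original$i_diff, x$optimal_k, x$optimal$i_diff))
  invisible(x)
}

#' Write an identifiability curve as TSV
#'
#' @param sweep An `idiff_sweep` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_idiff_curve <- function(sweep, path) {
  utils::write.table(sweep$curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
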