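# FC-trait extraction: ICA decomposition of the PCA-reconstructed group FC
# matrix into independent edge patterns with subject-session weights,
# robustness assessment across repeated randomly-initialized runs, sign
# canonicalization and trait matching.

.skewness <- function(x) {
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) return(0)
  mean(xc^3) / m2^1.5
}

#' Construct an FC-trait
#'
#' An FC-trait pairs an edge-level connectivity pattern (unit L2 norm) with
#' a weight per subject-session row quantifying how strongly the pattern is
#' expressed in that row's FC matrix.
#'
#' @param pattern Numeric edge vector (length E).
#' @param weights Numeric vector (length M) aligned with `index`.
#' @param index Data.frame with columns `subject` and `session` describing
#'   the weight rows.
#' @param trait_id Integer identifier.
#' @param robustness Fraction of ICA runs in which a matching component
#'   appeared, in `[0, 1]`.
#' @return An object of class `fc_trait`.
#' @export
fc_trait <- function(pattern, weights, index, trait_id = 1L,
                     robustness = 1.0) {
  if (length(weights) != nrow(index)) stop("weights do not match index")
  structure(list(pattern = as.numeric(pattern),
                 weights = as.numeric(weights),
                 index = index,
                 trait_id = as.integer(trait_id),
                 robustness = robustness),
            class = "fc_trait")
}

#' @export
print.fc_trait <- function(x, ...) {
  cat(sprintf("FC-trait %d: %d edges, %d weight rows, robustness %.2f\n",
              x$trait_id, length(x$pattern), length(x$weights),
              x$robustness))
  invisible(x)
}

#' Canonicalize the sign of an FC-trait
#'
#' ICA leaves a joint sign indeterminacy between a pattern and its weights.
#' The canonical orientation makes the pattern's skewness positive (with the
#' largest-|loading| edge made positive on an exact tie); the weights are
#' flipped jointly so the rank-one product pattern x weights is unchanged.
#'
#' @param trait An `fc_trait`.
#' @return The trait in canonical orientation.
#' @export
canonicalize_sign <- function(trait) {
  p <- trait$pattern
  if (all(p == 0)) stop("cannot canonicalize an all-zero pattern")
  sk <- .skewness(p)
  flip <- if (sk != 0) sk < 0 else p[which.max(abs(p))] < 0
  if (flip) {
    trait$pattern <- -trait$pattern
    trait$weights <- -trait$weights
  }
  trait
}

# Orient a raw pattern vector the same way (helper for run matching).
.canonical_pattern_sign <- function(p) {
  sk <- .skewness(p)
  if (sk != 0) {
    if (sk < 0) -1 else 1
  } else if (p[which.max(abs(p))] < 0) -1 else 1
}

#' Greedy maximum-correlation pairing between two trait sets
#'
#' Pairs traits across two sets by absolute Pearson correlation of their
#' edge patterns, greedily: the globally most-correlated pair is fixed
#' first, then the next among the remainder, and so on. Patterns may also be
#' given directly as matrices (rows = traits).
#'
#' @param set_a,set_b Lists of `fc_trait` objects, or numeric matrices with
#'   one pattern per row.
#' @return A data.frame with columns `a`, `b`, `r` (signed correlation) and
#'   `abs_r`, one row per pair (as many pairs as the smaller set).
#' @export
match_traits <- function(set_a, set_b) {
  pat <- function(s) {
    if (is.matrix(s)) s else do.call(rbind, lapply(s, `[[`, "pattern"))
  }
  a <- pat(set_a)
  b <- pat(set_b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty trait set")
  cc <- stats::cor(t(a), t(b))  # nA x nB
  n_pairs <- min(nrow(a), nrow(b))
  avail_a <- rep(TRUE, nrow(a))
  avail_b <- rep(TRUE, nrow(b))
  out <- data.frame(a = integer(n_pairs), b = integer(n_pairs),
                    r = numeric(n_pairs), abs_r = numeric(n_pairs))
  for (k in seq_len(n_pairs)) {
    sub <- abs(cc)
    sub[!avail_a, ] <- -Inf
    sub[, !avail_b] <- -Inf
    best <- arrayInd(which.max(sub), dim(sub))
    ia <- best[1, 1]; ib <- best[1, 2]
    out$a[k] <- ia; out$b[k] <- ib
    out$r[k] <- cc[ia, ib]; out$abs_r[k] <- abs(cc[ia, ib])
    avail_a[ia] <- FALSE; avail_b[ib] <- FALSE
  }
  out[order(out$a), , drop = FALSE]
}

#' Extract robust FC-traits from a reconstructed group FC matrix
#'
#' Models the M x E group matrix as A S, with S the n_components x E matrix
#' of independent edge patterns and A the M x n_components weights. ICA is
#' run `n_runs` times from random initializations; components are matched
#' across runs to a reference run by absolute pattern correlation at or
#' above `match_threshold`, and components recurring in at least
#' `min_frequency` of converged runs are retained, each represented by the
#' unit-normalized centroid of its matched, sign-aligned patterns. Weights
#' are then recomputed in one least-squares step of the group matrix on the
#' retained patterns, so the returned traits jointly minimize Frobenius
#' reconstruction error given the patterns.
#'
#' @param reconstructed A `group_fc` object (typically the optimal PCA
#'   reconstruction from [sweep_identifiability()]).
#' @param n_components Number of ICA components, at most `min(M, E)`.
#' @param n_runs Number of randomly initialized ICA runs.
#' @param match_threshold Minimum absolute pattern correlation to count as
#'   the same component across runs.
#' @param min_frequency Minimum fraction of converged runs in which a
#'   component must recur to be retained.
#' @param seed Base seed; run r uses `seed + r`.
#' @param tol,maxit Fixed-point convergence tolerance and iteration cap per
#'   run; non-converged runs are dropped but still count in the robustness
#'   denominator.
#' @return A list of `fc_trait` objects in canonical sign orientation,
#'   ordered by decreasing robustness.
#' @export
extract_traits <- function(reconstructed, n_components, n_runs = 100L,
                           match_threshold = 0.75, min_frequency = 0.75,
                           seed = 1L, tol = 1e-6, maxit = 1000L) {
  x <- reconstructed$matrix
  if (n_components > min(dim(x))) stop("n_components exceeds min(M, E)")
  if (n_runs < 1) stop("n_runs must be >= 1")
  xt <- t(x)  # E x M: observations = edges, variables = subject-session rows

  runs <- vector("list", n_runs)
  n_converged <- 0L
  for (r in seq_len(n_runs)) {
    fit <- .fastica(xt, n_components, seed = seed + r,
                    tol = tol, maxit = maxit)
    if (is.null(fit)) next
    n_converged <- n_converged + 1L
    pats <- t(fit$sources)  # n_components x E
    pats <- pats / sqrt(rowSums(pats^2))
    signs <- apply(pats, 1, .canonical_pattern_sign)
    runs[[n_converged]] <- pats * signs
  }
  if (n_converged == 0L) stop("ICA failed to converge in all ", n_runs,
                              " runs")
  runs <- runs[seq_len(n_converged)]

  ref <- runs[[1]]
  n_ref <- nrow(ref)
  freq <- rep(1L, n_ref)
  sums <- ref
  if (n_converged > 1) {
    for (r in 2:n_converged) {
      pairing <- match_traits(ref, runs[[r]])
      hit <- pairing[pairing$abs_r >= match_threshold, , drop = FALSE]
      for (k in seq_len(nrow(hit))) {
        ia <- hit$a[k]
        p <- runs[[r]][hit$b[k], ]
        if (hit$r[k] < 0) p <- -p
        sums[ia, ] <- sums[ia, ] + p
        freq[ia] <- freq[ia] + 1L
      }
    }
  }
  robustness <- freq / n_converged
  keep <- which(robustness >= min_frequency)
  if (length(keep) == 0) stop("no component recurred in at least ",
                              min_frequency, " of the converged runs")

  centroids <- sums[keep, , drop = FALSE] / freq[keep]
  centroids <- centroids / sqrt(rowSums(centroids^2))

  # least-squares weights of the group matrix on the retained patterns
  a_mat <- x %*% t(centroids) %*% solve(tcrossprod(centroids))

  ord <- order(-robustness[keep])
  traits <- lapply(seq_along(ord), function(i) {
    k <- ord[i]
    canonicalize_sign(fc_trait(centroids[k, ], a_mat[, k],
                               reconstructed$index, trait_id = i,
                               robustness = robustness[keep][k]))
  })
  traits
}

#' Collect trait weights into an M x n_traits matrix
#'
#' @param traits List of `fc_trait` objects sharing a row index.
#' @return A list with `weights` (M x n_traits matrix, columns named by
#'   trait id) and `index`.
#' @export
trait_weight_matrix <- function(traits) {
  w <- do.call(cbind, lapply(traits, `[[`, "weights"))
  colnames(w) <- vapply(traits, function(t) paste0("trait_", t$trait_id),
                        character(1))
  list(weights = w, index = traits[[1]]$index)
}

#' Write extracted traits to disk
#'
#' Patterns go to a traits x edges TSV, weights to a rows x traits TSV with
#' the (subject, session) index as leading columns, and robustness to JSON.
#'
#' @param traits List of `fc_trait` objects.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_traits <- function(traits, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pat <- do.call(rbind, lapply(traits, `[[`, "pattern"))
  rownames(pat) <- vapply(traits, function(t) paste0("trait_", t$trait_id),
                          character(1))
  pat_path <- file.path(dir, "trait_patterns.tsv")
  utils::write.table(pat, pat_path, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  wm <- trait_weight_matrix(traits)
  w_path <- file.path(dir, "trait_weights.tsv")
  utils::write.table(cbind(wm$index, as.data.frame(wm$weights)), w_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rob <- lapply(traits, function(t) t$robustness)
  names(rob) <- rownames(pat)
  rob_path <- file.path(dir, "trait_robustness.json")
  jsonlite::write_json(rob, rob_path, auto_unbox = TRUE, digits = NA)
  invisible(c(patterns = pat_path, weights = w_path, robustness = rob_path))
}
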