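# Functional connectivity construction: motion-based frame censoring,
# Pearson FC matrices from ROI time series, edge vectorization with a fixed
# upper-triangle ordering, and assembly of the group FC matrix.

#' Number of edges for an R-ROI connectome
#'
#' @param n_roi Number of ROIs.
#' @return `n_roi * (n_roi - 1) / 2`.
#' @examples
#' n_edges(408)  # 83028
#' @export
n_edges <- function(n_roi) {
  as.integer(n_roi * (n_roi - 1) / 2)
}

#' Recover the number of ROIs from an edge count
#'
#' Inverse of [n_edges()]; errors when `n_edge` is not of the form
#' R(R-1)/2 for an integer R.
#'
#' @param n_edge Length of an edge vector.
#' @return Integer number of ROIs.
#' @export
n_roi_from_edges <- function(n_edge) {
  r <- (1 + sqrt(1 + 8 * n_edge)) / 2
  if (abs(r - round(r)) > 1e-9) {
    stop("edge-vector length ", n_edge, " is not of the form R(R-1)/2")
  }
  as.integer(round(r))
}

#' Edge index table for the fixed vectorization order
#'
#' Edges are ordered row-major along the upper triangle excluding the
#' diagonal: (1,2), (1,3), ..., (1,R), (2,3), ...; this single convention
#' makes every vectorized artifact interchangeable.
#'
#' @param n_roi Number of ROIs.
#' @return A data.frame with columns `edge_index`, `i`, `j` (`i < j`).
#' @export
edge_pairs <- function(n_roi) {
  lt <- which(lower.tri(matrix(0, n_roi, n_roi)), arr.ind = TRUE)
  # column-major lower triangle of the transpose enumerates the upper
  # triangle row-major: (1,2),(1,3),...,(1,R),(2,3),...
  data.frame(edge_index = seq_len(nrow(lt)),
             i = as.integer(lt[, "col"]),
             j = as.integer(lt[, "row"]))
}

#' Vectorize the upper triangle of an FC matrix
#'
#' @param fc A symmetric R x R matrix.
#' @return Numeric vector of length R(R-1)/2 in the [edge_pairs()] order.
#' @export
vectorize_fc <- function(fc) {
  if (!is.matrix(fc) || nrow(fc) != ncol(fc)) stop("fc must be square")
  tm <- t(fc)
  tm[lower.tri(tm)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_fc()]: restores a symmetric matrix with unit
#' diagonal from a fixed-order edge vector.
#'
#' @param v Edge vector of length R(R-1)/2.
#' @param diag_value Value placed on the diagonal (default 1).
#' @return A symmetric R x R matrix.
#' @export
devectorize_fc <- function(v, diag_value = 1) {
  r <- n_roi_from_edges(length(v))
  m <- matrix(0, r, r)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Euclidean norm of the temporal derivative of realignment parameters
#'
#' The frame-wise head-motion index ENORM: for each frame t, the Euclidean
#' norm of the first difference of the six rigid-body realignment parameters
#' (3 translations, 3 rotations, assumed already commensurate in mm-equivalent
#' units). The first frame has no predecessor and is 0 by convention.
#'
#' @param params A T x 6 numeric matrix of realignment parameters.
#' @return Numeric vector of length T, non-negative, first element 0.
#' @export
compute_enorm <- function(params) {
  params <- as.matrix(params)
  if (ncol(params) != 6) stop("params must have 6 columns")
  if (!all(is.finite(params))) stop("params must be finite")
  if (nrow(params) == 1) return(0)
  c(0, sqrt(rowSums(diff(params)^2)))
}

#' Frame censoring from motion and despiking metrics
#'
#' A frame is kept iff its ENORM does not exceed `enorm_limit` AND its
#' despiked-voxel fraction does not exceed `despike_limit`; both rules are
#' strict on the "larger than" side, so values exactly at the limit are kept.
#' Defaults are the standard 0.4 mm ENORM and 10% despiking thresholds.
#'
#' @param enorm Per-frame ENORM values (see [compute_enorm()]).
#' @param despike_fraction Per-frame fraction of despiked voxels in `[0, 1]`;
#'   defaults to all zero when the metric is unavailable.
#' @param enorm_limit Censor frames with ENORM strictly above this (mm).
#' @param despike_limit Censor frames with despike fraction strictly above
#'   this.
#' @return Logical keep mask of length T.
#' @export
censor_frames <- function(enorm, despike_fraction = NULL,
                          enorm_limit = 0.4, despike_limit = 0.10) {
  if (enorm_limit < 0 || despike_limit < 0) stop("limits must be >= 0")
  if (is.null(despike_fraction)) despike_fraction <- rep(0, length(enorm))
  if (length(despike_fraction) != length(enorm)) {
    stop("enorm and despike_fraction must have the same length")
  }
  enorm <= enorm_limit & despike_fraction <= despike_limit
}

#' Subject exclusion by censored-volume fraction
#'
#' A subject is excluded when strictly more than `max_censored_fraction` of
#' volumes were censored in either of the two sessions; a fraction exactly at
#' the limit is retained.
#'
#' @param masks Named list: for each subject, a named list of logical keep
#'   masks with entries `monoband` and `multiband`.
#' @param max_censored_fraction Exclusion threshold on the censored fraction.
#' @return A list with `included` (character vector of subject ids) and
#'   `report` (data.frame: subject, session, censored_fraction, excluded).
#' @export
exclude_subjects <- function(masks, max_censored_fraction = 0.20) {
  sessions <- c("monoband", "multiband")
  rows <- lapply(names(masks), function(s) {
    m <- masks[[s]]
    if (!all(sessions %in% names(m))) {
      stop("subject ", s, " is missing a session mask")
    }
    frac <- vapply(sessions, function(sess) mean(!m[[sess]]), numeric(1))
    data.frame(subject = s, session = sessions,
               censored_fraction = frac,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  excl_subj <- unique(report$subject[
    report$censored_fraction > max_censored_fraction])
  report$excluded <- report$subject %in% excl_subj
  list(included = setdiff(names(masks), excl_subj), report = report)
}

#' Pearson functional connectivity matrix from a ROI time-series table
#'
#' Computes all pairwise Pearson correlations between ROI time series over
#' the retained frames only; censored frames are removed before correlating,
#' so they cannot leak into the estimate. The diagonal is set to exactly 1.
#'
#' @param ts A T x R numeric matrix (rows = frames, columns = ROIs).
#' @param keep_mask Optional logical vector of length T; frames with `FALSE`
#'   are dropped before correlating.
#' @return A symmetric R x R correlation matrix with unit diagonal.
#' @export
compute_fc <- function(ts, keep_mask = NULL) {
  ts <- as.matrix(ts)
  if (!is.null(keep_mask)) {
    if (length(keep_mask) != nrow(ts)) {
      stop("keep_mask length must match the number of frames")
    }
    ts <- ts[keep_mask, , drop = FALSE]
  }
  if (nrow(ts) < 3) stop("need at least 3 retained frames to correlate")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop("constant time series for ROI(s): ", paste(bad, collapse = ", "))
  }
  fc <- stats::cor(ts)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  fc
}

#' Assemble the group FC matrix
#'
#' Stacks the vectorized upper triangles of a set of subject-session FC
#' matrices into an M x E matrix (M = 2 x number of subjects), with rows
#' ordered subject-major and monoband before multiband within each subject.
#'
#' @param fcs A list whose elements are lists with fields `values` (the R x R
#'   FC matrix), `subject` and `session` (`"monoband"` or `"multiband"`).
#' @return An object of class `group_fc`: list with `matrix` (M x E) and
#'   `index` (data.frame with columns `subject`, `session`).
#' @export
assemble_group_matrix <- function(fcs) {
  if (length(fcs) == 0) stop("no FC matrices supplied")
  subj <- vapply(fcs, function(x) as.character(x$subject), character(1))
  sess <- vapply(fcs, function(x) as.character(x$session), character(1))
  if (!all(sess %in% c("monoband", "multiband"))) {
    stop("session must be 'monoband' or 'multiband'")
  }
  key <- paste(subj, sess, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (subject, session): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  dims <- vapply(fcs, function(x) nrow(x$values), integer(1))
  if (length(unique(dims)) != 1) stop("FC matrices have mixed sizes")
  ord <- order(match(subj, unique(subj)),
               match(sess, c("monoband", "multiband")))
  mat <- do.call(rbind, lapply(fcs[ord], function(x) vectorize_fc(x$values)))
  index <- data.frame(subject = subj[ord], session = sess[ord],
                      stringsAsFactors = FALSE)
  rownames(mat) <- paste(index$subject, index$session, sep = "|")
  group_fc(mat, index)
}

#' Construct a group_fc object from a matrix and a row index
#'
#' @param matrix An M x E numeric matrix of edge vectors.
#' @param index A data.frame with columns `subject` and `session` describing
#'   the rows, in order.
#' @return An object of class `group_fc`.
#' @export
group_fc <- function(matrix, index) {
  if (nrow(matrix) != nrow(index)) stop("index does not match matrix rows")
  if (anyDuplicated(paste(index$subject, index$session))) {
    stop("duplicate (subject, session) in index")
  }
  rownames(matrix) <- paste(index$subject, index$session, sep = "|")
  structure(list(matrix = matrix, index = index), class = "group_fc")
}

#' @export
print.group_fc <- function(x, ...) {
  cat(sprintf("group FC matrix: %d rows (%d subjects x 2 sessions), %d edges\n",
              nrow(x$matrix), length(unique(x$index$subject)),
              ncol(x$matrix)))
  invisible(x)
}

#' Read a ROI time-series TSV
#'
#' @param path Tab-separated file, T rows x R columns, header = ROI ids.
#' @return Numeric matrix T x R.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  as.matrix(utils::read.delim(path, check.names = FALSE))
}

#' Write a ROI time-series TSV
#'
#' @param ts T x R matrix.
#' @param path Output path; column header is the 1-based ROI id.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  colnames(ts) <- seq_len(ncol(ts))
  utils::write.table(ts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a group FC matrix and its row index
#'
#' The matrix is written as a headerless TSV of M rows x E columns and the
#' (subject, session) row index as a sidecar TSV.
#'
#' @param group A `group_fc` object.
#' @param path Output TSV path for the matrix; the index is written next to
#'   it with suffix `"_index.tsv"`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_group_matrix <- function(group, path) {
  utils::write.table(group$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  idx_path <- sub("\\.tsv$", "", path)
  idx_path <- paste0(idx_path, "_index.tsv")
  utils::write.table(group$index, idx_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, idx_path))
}

#' Read a group FC matrix written by [write_group_matrix()]
#'
#' @param path Path to the matrix TSV.
#' @return A `group_fc` object.
#' @export
read_group_matrix <- function(path) {
  idx_path <- paste0(sub("\\.tsv$", "", path), "_index.tsv")
  mat <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(mat) <- NULL
  index <- utils::read.delim(idx_path, stringsAsFactors = FALSE)
  rownames(mat) <- paste(index$subject, index$session, sep = "|")
  group_fc(mat, index)
}
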