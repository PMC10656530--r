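# Parcellation lookup tables: ROI id / name / hemisphere / resting-state
# network. The scheme mirrors a Schaefer-style cortical atlas labelled with
# the seven canonical resting-state networks, plus a small set of bilateral
# subcortical regions grouped under a single "subcortical" label.

RSN_NETWORKS <- c("VN", "SMN", "DAN", "VAN", "LN", "FPN", "DMN")

SUBCORTICAL_NAMES <- c("Thalamus", "Caudate", "Putamen", "Pallidum",
                       "Hippocampus", "Amygdala", "Accumbens", "VentralDC")

#' Build a parcellation lookup table
#'
#' Constructs a Schaefer-style lookup table with `n_roi - n_subcortical`
#' cortical parcels split as evenly as possible across the seven canonical
#' resting-state networks (visual VN, sensorimotor SMN, dorsal attention DAN,
#' ventral attention VAN, limbic LN, frontoparietal FPN, default mode DMN),
#' alternating left/right hemisphere within each network, followed by
#' `n_subcortical` bilateral subcortical regions labelled `"subcortical"`.
#'
#' The full-scale scheme used on real data is 400 cortical parcels plus 8
#' subcortical regions (`n_roi = 408`); smaller tables are convenient for
#' simulation and testing.
#'
#' @param n_roi Total number of ROIs (cortical + subcortical).
#' @param n_subcortical Number of bilateral subcortical regions; default 8,
#'   shrunk automatically for very small parcellations so that every
#'   cortical network keeps at least two parcels.
#' @param networks Character vector of cortical network labels.
#' @return A data.frame with columns `roi_id` (1-based, contiguous),
#'   `roi_name`, `hemisphere` (`"L"`, `"R"` or `"bilateral"`) and `network`.
#' @examples
#' parc <- make_parcellation(100)
#' table(parc$network)
#' @export
make_parcellation <- function(n_roi = 408, n_subcortical = NULL,
                              networks = RSN_NETWORKS) {
  if (is.null(n_subcortical)) {
    n_subcortical <- max(0L, min(8L, n_roi - 2L * length(networks)))
  }
  if (n_subcortical < 0) stop("n_subcortical must be >= 0")
  n_cortical <- n_roi - n_subcortical
  if (n_cortical < 2 * length(networks)) {
    stop("need at least two cortical parcels per network")
  }
  net <- sort(factor(rep(networks, length.out = n_cortical),
                     levels = networks))
  per_net <- split(seq_len(n_cortical), net)
  hemi <- unlist(lapply(per_net, function(ix) {
    rep(c("L", "R"), length.out = length(ix))
  }), use.names = FALSE)
  net <- as.character(net)
  within_idx <- unlist(lapply(per_net, seq_along), use.names = FALSE)
  cortical <- data.frame(
    roi_id = seq_len(n_cortical),
    roi_name = sprintf("%s_%s_%d", net, hemi, within_idx),
    hemisphere = hemi,
    network = net,
    stringsAsFactors = FALSE
  )
  if (n_subcortical == 0) return(cortical)
  sc_names <- rep(SUBCORTICAL_NAMES, length.out = n_subcortical)
  if (n_subcortical > length(SUBCORTICAL_NAMES)) {
    sc_names <- make.unique(sc_names, sep = "_")
  }
  subcortical <- data.frame(
    roi_id = n_cortical + seq_len(n_subcortical),
    roi_name = sc_names,
    hemisphere = "bilateral",
    network = "subcortical",
    stringsAsFactors = FALSE
  )
  rbind(cortical, subcortical)
}

#' Validate a parcellation lookup table
#'
#' Checks the structural invariants every downstream stage relies on:
#' required columns, unique contiguous 1-based ROI ids, and exactly one
#' network label per ROI.
#'
#' @param parc A parcellation data.frame.
#' @return The parcellation, invisibly, if valid; otherwise an error.
#' @export
validate_parcellation <- function(parc) {
  required <- c("roi_id", "roi_name", "hemisphere", "network")
  missing <- setdiff(required, names(parc))
  if (length(missing) > 0) {
    stop("parcellation is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyNA(parc$network) || any(!nzchar(parc$network))) {
    stop("every ROI must carry a network label")
  }
  ids <- parc$roi_id
  if (anyDuplicated(ids) || !identical(as.integer(sort(ids)),
                                       seq_len(nrow(parc)))) {
    stop("roi_id must be unique and contiguous from 1")
  }
  invisible(parc)
}

#' Read a parcellation lookup table from TSV
#'
#' @param path Path to a tab-separated file with columns `roi_id`,
#'   `roi_name`, `hemisphere`, `network`.
#' @return A validated parcellation data.frame ordered by `roi_id`.
#' @export
read_parcellation <- function(path) {
  if (!file.exists(path)) stop("parcellation file not found: ", path)
  parc <- utils::read.delim(path, stringsAsFactors = FALSE)
  parc <- parc[order(parc$roi_id), , drop = FALSE]
  rownames(parc) <- NULL
  validate_parcellation(parc)
  parc
}

#' Write a parcellation lookup table to TSV
#'
#' @param parc A parcellation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(parc, path) {
  validate_parcellation(parc)
  utils::write.table(parc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
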