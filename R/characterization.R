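# Characterization of significant FC-traits: strongest-edge selection,
# nodal strength on normalized loadings, per-network contribution labels,
# and plot-ready exports. All steps work on absolute loadings, so a global
# sign flip of a trait leaves the characterization unchanged.

#' Strongest edges of an FC-trait
#'
#' Selects the top `round(pct/100 * E)` edges by absolute loading (at least
#' one edge; for the full-scale 408-ROI connectome with E = 83,028 edges the
#' default 1% keeps 830), with ties broken by edge index for determinism,
#' and resolves ROI pairs through the parcellation.
#'
#' @param trait An `fc_trait`.
#' @param parcellation Parcellation lookup table matching the trait's edge
#'   length.
#' @param pct Percentage of edges to keep, in (0, 100]; default 1 (the "1%
#'   strongest connections").
#' @return Data.frame sorted by decreasing |loading| with columns
#'   `edge_index`, `roi_i`, `roi_j`, `name_i`, `name_j`, `hemisphere_i`,
#'   `hemisphere_j`, `network_i`, `network_j`, `loading`.
#' @export
top_percent_edges <- function(trait, parcellation, pct = 1.0) {
  if (pct <= 0 || pct > 100) stop("pct must lie in (0, 100]")
  p <- trait$pattern
  if (all(p == 0)) stop("trait pattern is all zero")
  e_count <- length(p)
  r <- n_roi_from_edges(e_count)
  validate_parcellation(parcellation)
  if (nrow(parcellation) != r) {
    stop("parcellation size does not match the trait's edge count")
  }
  n_keep <- max(1L, round(pct / 100 * e_count))
  ord <- order(-abs(p), seq_along(p))[seq_len(n_keep)]
  pairs <- edge_pairs(r)[ord, , drop = FALSE]
  data.frame(
    edge_index = pairs$edge_index,
    roi_i = pairs$i, roi_j = pairs$j,
    name_i = parcellation$roi_name[pairs$i],
    name_j = parcellation$roi_name[pairs$j],
    hemisphere_i = parcellation$hemisphere[pairs$i],
    hemisphere_j = parcellation$hemisphere[pairs$j],
    network_i = parcellation$network[pairs$i],
    network_j = parcellation$network[pairs$j],
    loading = p[ord],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# Normalize a full pattern under the chosen scheme.
.normalize_loadings <- function(p, normalization) {
  switch(normalization,
         zscore = (p - mean(p)) / stats::sd(p),
         maxabs = p / max(abs(p)),
         none = p,
         stop("unknown normalization: ", normalization))
}

#' Nodal strength of a trait's selected edges
#'
#' Loadings are normalized over the whole pattern under the chosen scheme,
#' then each ROI's strength is the sum of absolute normalized loadings of
#' the selected edges incident to it; ROIs touching no selected edge get 0.
#' The strengths obey the handshake identity: they sum to twice the total
#' absolute normalized loading of the selected edges.
#'
#' @param trait An `fc_trait`.
#' @param edges Edge data.frame from [top_percent_edges()] for this trait.
#' @param normalization One of `"zscore"` (default), `"maxabs"`, `"none"`.
#' @return Named numeric vector of length R (names = ROI ids).
#' @export
nodal_strength <- function(trait, edges, normalization = "zscore") {
  r <- n_roi_from_edges(length(trait$pattern))
  norm_p <- .normalize_loadings(trait$pattern, normalization)
  strength <- numeric(r)
  vals <- abs(norm_p[edges$edge_index])
  for (k in seq_len(nrow(edges))) {
    strength[edges$roi_i[k]] <- strength[edges$roi_i[k]] + vals[k]
    strength[edges$roi_j[k]] <- strength[edges$roi_j[k]] + vals[k]
  }
  names(strength) <- seq_len(r)
  strength
}

#' Per-network contribution scores and presence labels
#'
#' A network's score is the mean absolute loading over all edges with at
#' least one endpoint in the network, normalized by the trait's overall mean
#' absolute loading, so a uniform pattern scores exactly 1 everywhere.
#' Labels follow a documented threshold rule: score < `t_low` is "-"
#' (absent), `t_low` <= score < `t_high` is "+" (medium; the lower boundary
#' is inclusive), and score >= `t_high` is "++" (high).
#'
#' @param trait An `fc_trait`.
#' @param parcellation Parcellation lookup table.
#' @param t_low,t_high Label thresholds (defaults 1.0 and 1.5, placing a
#'   uniformly loaded pattern at "+").
#' @return A list with `scores` (named numeric) and `labels` (named
#'   character in `-`/`+`/`++`).
#' @export
network_contribution <- function(trait, parcellation,
                                 t_low = 1.0, t_high = 1.5) {
  validate_parcellation(parcellation)
  p <- abs(trait$pattern)
  r <- n_roi_from_edges(length(p))
  if (nrow(parcellation) != r) stop("parcellation does not match trait")
  overall <- mean(p)
  if (overall == 0) stop("trait pattern is all zero")
  pairs <- edge_pairs(r)
  net_i <- parcellation$network[pairs$i]
  net_j <- parcellation$network[pairs$j]
  networks <- unique(parcellation$network)
  scores <- vapply(networks, function(nw) {
    touch <- net_i == nw | net_j == nw
    mean(p[touch]) / overall
  }, numeric(1))
  labels <- ifelse(scores < t_low, "-", ifelse(scores < t_high, "+", "++"))
  names(labels) <- networks
  list(scores = scores, labels = labels)
}

#' Full characterization summary of one FC-trait
#'
#' Bundles the strongest-edge list, nodal strengths and network labels into
#' one object ready for export.
#'
#' @inheritParams top_percent_edges
#' @inheritParams nodal_strength
#' @inheritParams network_contribution
#' @return A list of class `trait_summary`.
#' @export
summarize_trait <- function(trait, parcellation, pct = 1.0,
                            normalization = "zscore",
                            t_low = 1.0, t_high = 1.5) {
  edges <- top_percent_edges(trait, parcellation, pct = pct)
  structure(list(
    trait_id = trait$trait_id,
    top_edges = edges,
    nodal_strength = nodal_strength(trait, edges, normalization),
    networks = network_contribution(trait, parcellation, t_low, t_high),
    pct = pct,
    normalization = normalization,
    thresholds = c(t_low = t_low, t_high = t_high)
  ), class = "trait_summary")
}

#' @export
print.trait_summary <- function(x, ...) {
  lab <- paste(names(x$networks$labels), x$networks$labels, collapse = "  ")
  cat(sprintf("FC-trait %d: %d strongest edges (%.3g%%)\n  networks: %s\n",
              x$trait_id, nrow(x$top_edges), x$pct, lab))
  invisible(x)
}

#' Export plot-ready characterization files
#'
#' Writes (i) the strongest-edge list as TSV ordered by network then
#' hemisphere (ready for circular plotting), (ii) nodal strengths keyed by
#' ROI id as TSV, and (iii) the network scores/labels plus the label rule as
#' JSON.
#'
#' @param summary A `trait_summary`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_plot_data <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- sprintf("trait_%d", summary$trait_id)

  edges <- summary$top_edges
  ord <- order(edges$network_i, edges$hemisphere_i,
               edges$network_j, edges$hemisphere_j, edges$edge_index)
  edge_path <- file.path(dir, paste0(tag, "_edges.tsv"))
  utils::write.table(edges[ord, , drop = FALSE], edge_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ns_path <- file.path(dir, paste0(tag, "_nodal_strength.tsv"))
  utils::write.table(
    data.frame(roi_id = as.integer(names(summary$nodal_strength)),
               strength = unname(summary$nodal_strength)),
    ns_path, sep = "\t", quote = FALSE, row.names = FALSE)

  net_path <- file.path(dir, paste0(tag, "_networks.json"))
  jsonlite::write_json(list(
    scores = as.list(summary$networks$scores),
    labels = as.list(summary$networks$labels),
    rule = list(t_low = unname(summary$thresholds["t_low"]),
                t_high = unname(summary$thresholds["t_high"]),
                description = paste(
                  "score < t_low: '-'; t_low <= score < t_high: '+';",
                  "score >= t_high: '++'; lower boundary inclusive"))),
    net_path, auto_unbox = TRUE, digits = NA)

  invisible(c(edges = edge_path, nodal_strength = ns_path,
              networks = net_path))
}
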