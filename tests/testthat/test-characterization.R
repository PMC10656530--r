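make_test_trait <- function(pattern, n_sessions = 4) {
  idx <- data.frame(
    subject = rep(sprintf("s%d", seq_len(n_sessions / 2)), each = 2),
    session = rep(c("monoband", "multiband"), n_sessions / 2))
  fc_trait(pattern, seq_len(n_sessions), idx)
}

test_that("top-percent edge selection counts, resolves and sorts correctly", {
  # E = 1000 does not come from a triangular number; use R = 46 (E = 1035)
  parc <- make_parcellation(46)
  set.seed(1)
  tr <- make_test_trait(rnorm(n_edges(46)))
  edges <- top_percent_edges(tr, parc, pct = 1)
  expect_equal(nrow(edges), round(0.01 * 1035))

  # selection equals a full-sort brute force
  brute <- order(-abs(tr$pattern), seq_along(tr$pattern))[1:10]
  expect_equal(edges$edge_index, brute)
  expect_true(all(diff(abs(edges$loading)) <= 0))

  # single dominant edge survives a tiny percentage
  p <- numeric(n_edges(46)); p[17] <- 1
  one <- top_percent_edges(make_test_trait(p), parc, pct = 1e-4)
  expect_equal(one$edge_index, 17)
  pairs <- edge_pairs(46)
  expect_equal(c(one$roi_i, one$roi_j),
               c(pairs$i[17], pairs$j[17]))

  expect_error(top_percent_edges(make_test_trait(p), parc, pct = 0),
               "\\(0, 100\\]")
  expect_error(top_percent_edges(
    make_test_trait(numeric(n_edges(46))), parc), "all zero")
})

test_that("the full-scale 1% rule keeps 830 of 83,028 edges", {
  # R = 408 connectome; verify the count rule without allocating patterns
  expect_equal(max(1L, round(1 / 100 * n_edges(408))), 830)
  # and at a modest scale through the real code path
  parc <- make_parcellation(60)
  set.seed(2)
  tr <- make_test_trait(rnorm(n_edges(60)))
  expect_equal(nrow(top_percent_edges(tr, parc, pct = 1)),
               round(0.01 * n_edges(60)))
})

test_that("nodal strength accumulates |normalized loading| per endpoint", {
  parc <- make_parcellation(20)
  e <- n_edges(20)
  pairs <- edge_pairs(20)

  # single selected edge: its normalized |loading| lands on both endpoints
  set.seed(3)
  p <- rnorm(e)
  tr <- make_test_trait(p)
  edges <- top_percent_edges(tr, parc, pct = 100 / e)  # exactly 2 edges
  ns <- nodal_strength(tr, edges[1, ], normalization = "maxabs")
  v <- abs(p[edges$edge_index[1]]) / max(abs(p))
  expect_equal(sum(ns > 0), 2)
  expect_equal(unname(ns[edges$roi_i[1]]), v)
  expect_equal(unname(ns[edges$roi_j[1]]), v)

  # handshake identity and brute-force accumulation on random traits
  for (s in 1:5) {
    set.seed(s)
    tr <- make_test_trait(rnorm(e))
    edges <- top_percent_edges(tr, parc, pct = 10)
    ns <- nodal_strength(tr, edges, normalization = "zscore")
    znorm <- (tr$pattern - mean(tr$pattern)) / sd(tr$pattern)
    expect_equal(sum(ns), 2 * sum(abs(znorm[edges$edge_index])),
                 tolerance = 1e-12)
    brute <- numeric(20)
    for (roi in 1:20) {
      touch <- edges$roi_i == roi | edges$roi_j == roi
      brute[roi] <- sum(abs(znorm[edges$edge_index[touch]]))
    }
    expect_equal(unname(ns), brute, tolerance = 1e-12)
  }
  expect_error(nodal_strength(tr, edges, normalization = "weird"),
               "unknown normalization")
})

test_that("network contribution scores and labels behave as documented", {
  parc <- make_parcellation(30)
  e <- n_edges(30)
  pairs <- edge_pairs(30)
  net_i <- parc$network[pairs$i]
  net_j <- parc$network[pairs$j]

  # support only on SMN-SMN edges: SMN "++", every other network "-"
  p <- numeric(e)
  p[net_i == "SMN" & net_j == "SMN"] <- 1
  nc <- network_contribution(make_test_trait(p), parc)
  expect_equal(unname(nc$labels["SMN"]), "++")
  expect_true(all(nc$labels[names(nc$labels) != "SMN"] == "-"))

  # uniform pattern: all scores exactly 1, inclusive boundary labels "+"
  nc_u <- network_contribution(make_test_trait(rep(0.2, e)), parc)
  expect_equal(unname(nc_u$scores), rep(1, length(nc_u$scores)))
  expect_true(all(nc_u$labels == "+"))

  # brute-force edge-membership oracle on a random trait
  set.seed(4)
  p <- rnorm(e)
  nc_r <- network_contribution(make_test_trait(p), parc)
  for (nw in names(nc_r$scores)) {
    touch <- net_i == nw | net_j == nw
    expect_equal(unname(nc_r$scores[nw]),
                 mean(abs(p[touch])) / mean(abs(p)), tolerance = 1e-12)
  }
})

test_that("characterization is invariant to a global sign flip", {
  parc <- make_parcellation(24)
  set.seed(5)
  tr <- make_test_trait(rnorm(n_edges(24)))
  neg <- tr; neg$pattern <- -neg$pattern; neg$weights <- -neg$weights
  s1 <- summarize_trait(tr, parc)
  s2 <- summarize_trait(neg, parc)
  expect_equal(s1$top_edges$edge_index, s2$top_edges$edge_index)
  expect_equal(s1$nodal_strength, s2$nodal_strength)
  expect_equal(s1$networks$labels, s2$networks$labels)
})

test_that("raising an edge loading never demotes its networks' labels", {
  parc <- make_parcellation(24)
  rank_of <- c("-" = 1, "+" = 2, "++" = 3)
  pairs <- edge_pairs(24)
  set.seed(6)
  for (i in 1:10) {
    p <- rnorm(n_edges(24))
    k <- sample(length(p), 1)
    before <- network_contribution(make_test_trait(p), parc)$labels
    p2 <- p; p2[k] <- p2[k] * 5
    after <- network_contribution(make_test_trait(p2), parc)$labels
    for (nw in unique(c(parc$network[pairs$i[k]],
                        parc$network[pairs$j[k]]))) {
      expect_gte(rank_of[after[nw]], rank_of[before[nw]])
    }
  }
})

test_that("plot-data export round-trips a hand-checkable toy trait", {
  # 16-ROI toy: small enough to verify by hand, valid for the 7 networks
  parc <- make_parcellation(16)
  e <- n_edges(16)
  p <- numeric(e)
  p[c(1, 5, 9)] <- c(0.9, -0.8, 0.7)
  tr <- make_test_trait(p)
  summ <- summarize_trait(tr, parc, pct = 100 * 3 / e)
  expect_equal(nrow(summ$top_edges), 3)

  dir <- withr::local_tempdir()
  paths <- export_plot_data(summ, dir)
  expect_true(all(file.exists(paths)))

  back <- utils::read.delim(paths[["edges"]])
  expect_equal(nrow(back), 3)
  expect_setequal(back$edge_index, c(1, 5, 9))
  expect_equal(sort(back$loading), sort(summ$top_edges$loading))

  ns <- utils::read.delim(paths[["nodal_strength"]])
  expect_equal(ns$strength, unname(summ$nodal_strength))

  js <- jsonlite::read_json(paths[["networks"]])
  expect_equal(unlist(js$labels), summ$networks$labels)
})
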