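# Shared fixture builders and independent oracles.

# Random group FC matrix (edge vectors only; no planted structure).
random_group <- function(n_subj = 6, n_roi = 12, seed = 1) {
  set.seed(seed)
  e <- n_edges(n_roi)
  mat <- matrix(stats::runif(2 * n_subj * e, -0.8, 0.8), 2 * n_subj, e)
  index <- data.frame(
    subject = rep(sprintf("s%02d", seq_len(n_subj)), each = 2),
    session = rep(c("monoband", "multiband"), n_subj),
    stringsAsFactors = FALSE
  )
  group_fc(mat, index)
}

# Small planted cohort for recovery-style tests.
small_cohort <- function(seed = 1, n_roi = 40, n_traits = 3,
                         group_sizes = c("PD-MCI" = 6, "PD-CN" = 5,
                                         "HC" = 5), ...) {
  simulate_cohort(group_sizes = group_sizes, n_roi = n_roi,
                  n_traits = n_traits, seed = seed, ...)
}

# Independently coded Benjamini-Hochberg step-up adjustment.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Partial F from first principles: residual sums of squares of two nested
# OLS fits solved by QR, F = ((RSS0 - RSS1)/q) / (RSS1/(n - p1)).
oracle_partial_f <- function(y, x0, x1) {
  rss <- function(x) {
    beta <- qr.solve(x, y)
    sum((y - x %*% beta)^2)
  }
  rss0 <- rss(x0)
  rss1 <- rss(x1)
  q <- ncol(x1) - ncol(x0)
  df2 <- length(y) - ncol(x1)
  f <- ((rss0 - rss1) / q) / (rss1 / df2)
  list(f = f, p = stats::pf(f, q, df2, lower.tail = FALSE))
}

# Subject-level design frame used by the rmANOVA oracles.
make_subject_table <- function(index, seed = 1) {
  set.seed(seed)
  subj <- unique(index$subject)
  groups <- unique(index$group)
  data.frame(
    subject_id = subj,
    group = index$group[!duplicated(index$subject)],
    age = stats::rnorm(length(subj), 70, 6),
    gender = sample(c("male", "female"), length(subj), replace = TRUE),
    tgm = stats::rnorm(length(subj), 620, 50),
    etiv = stats::rnorm(length(subj), 1500, 120),
    avg_enorm = abs(stats::rnorm(length(subj), 0.1, 0.04)),
    stringsAsFactors = FALSE
  )
}
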