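# Shared fixtures and independent oracles. Oracles are deliberately naive
# (straight loops, textbook formulas) and never call the package paths
# they check.

tiny_expr <- function(genes = c("G1", "G2", "G3"), samples = c("S1", "S2"),
                      seed = 42) {
  set.seed(seed)
  m <- matrix(round(rnorm(length(genes) * length(samples), 6, 1), 4),
              nrow = length(genes), dimnames = list(genes, samples))
  m
}

write_tsv_fixture <- function(mat, path = tempfile(fileext = ".tsv")) {
  write_expression(mat, path)
  path
}

small_config <- function(seed = 1, ...) {
  # reduced study for fast unit tests; acceptance tests use the defaults
  cohort_config(n_case = 20, n_control = 20, n_driver = 30, n_suppressor = 30,
                n_marker = 10, n_background = 100, seed = seed, ...)
}

# --- independent oracles -------------------------------------------------

# AUC by exhaustive pairwise Mann-Whitney comparison
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}

# BH step-up by sort and cumulative minimum
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# classical two-sample pooled t (textbook formula)
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(abs(t), df = n1 + n2 - 2, lower.tail = FALSE))
}

# Welch t (textbook formula)
oracle_welch <- function(a, b) {
  se2 <- var(a) / length(a) + var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                   (var(b) / length(b))^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(abs(t), df = df, lower.tail = FALSE))
}

# two-group log-rank by explicit risk-table summation over event times
oracle_logrank <- function(times, events, groups) {
  g <- as.integer(factor(groups))
  ts <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (tt in ts) {
    at_risk <- times >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O1 - E1)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# consensus tallies by straight loops over a given resample stream,
# re-clustering each subsample independently
oracle_consensus <- function(x, resamples, k) {
  n <- ncol(x)
  cooc <- cos <- matrix(0, n, n)
  for (idx in resamples) {
    sub <- x[, idx, drop = FALSE]
    cc <- suppressWarnings(cor(sub)); cc[!is.finite(cc)] <- 0; diag(cc) <- 1
    lab <- cutree(hclust(as.dist(1 - cc), method = "average"), k = k)
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      i <- idx[a]; j <- idx[b]
      cos[i, j] <- cos[i, j] + 1
      if (lab[a] == lab[b]) cooc[i, j] <- cooc[i, j] + 1
    }
  }
  cm <- ifelse(cos > 0, cooc / cos, 0)
  diag(cm) <- 1
  cm
}

# adjusted Rand index (hand-rolled, for label-recovery checks)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
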