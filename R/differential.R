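# Two-group moderated differential expression. The empirical-Bayes engine
# shrinks per-gene pooled variances toward a common prior (d0, s0^2)
# estimated by moment matching on log-variances (digamma/trigamma
# inversion), giving a moderated t on d0 + dg degrees of freedom.

# Invert trigamma by Newton iteration (monotone decreasing, convex).
trigamma_inverse <- function(x) {
  if (!is.finite(x)) return(if (x > 0) Inf else NaN)
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

# Moment-match a scaled F prior to the observed log pooled variances:
# returns list(d0, s0_sq). d0 = Inf when the observed spread is no larger
# than the sampling spread (complete shrinkage).
estimate_variance_prior <- function(s2, dg) {
  ok <- is.finite(s2) & s2 > 0 & dg > 0
  s2 <- s2[ok]; dg <- dg[ok]
  if (length(s2) < 2) stop("too few positive variances to fit prior")
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(dg / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # observed spread no larger than sampling noise: complete shrinkage to
    # the pooled variance
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-group t-test per gene
#'
#' For each gene the pooled within-group variance `s2_g` (on
#' `dg = n1 + n2 - 2` df) is shrunk toward an empirical-Bayes prior
#' `(d0, s0^2)` fitted by moment matching on `log(s2_g)`; the moderated t
#' is `log_fc / (s_tilde * sqrt(1/n1 + 1/n2))` with two-sided p-values on
#' `d0 + dg` df. With fewer than 10 genes the prior cannot be estimated
#' reliably and the ordinary two-sample pooled t is used (`d0 = 0`).
#'
#' @param x expression matrix (genes x samples).
#' @param labels factor/character of length ncol(x) with exactly two levels.
#' @param case the level treated as the case group; `log_fc` is
#'   mean(case) - mean(other). Defaults to the second sorted level.
#' @param d0 override the prior df (0 forces the ordinary t).
#' @return data.frame (gene, log_fc, t_mod, p, p_adj, s2_g) with attributes
#'   `d0` and `s0_sq`; class `ferro_de`.
#' @export
moderated_t_test <- function(x, labels, case = NULL, d0 = NULL) {
  labels <- as.character(labels)
  if (length(labels) != ncol(x)) stop("labels must match columns of x")
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("exactly two groups required")
  if (is.null(case)) case <- lev[2]
  if (!case %in% lev) stop("'case' is not one of the group labels")
  ctrl <- setdiff(lev, case)
  i1 <- labels == ctrl; i2 <- labels == case
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")

  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- apply(x[, i1, drop = FALSE], 1, var)
  v2 <- apply(x[, i2, drop = FALSE], 1, var)
  dg <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
  log_fc <- m2 - m1

  if (is.null(d0)) {
    if (sum(is.finite(s2) & s2 > 0) >= 10) {
      prior <- estimate_variance_prior(s2, rep(dg, length(s2)))
      d0 <- prior$d0; s0_sq <- prior$s0_sq
    } else {
      d0 <- 0; s0_sq <- NA_real_
    }
  } else if (d0 == 0) {
    s0_sq <- NA_real_
  } else {
    s0_sq <- exp(mean(log(s2[s2 > 0])))
  }

  if (is.infinite(d0)) {
    s_tilde_sq <- rep(s0_sq, length(s2))
    # complete shrinkage: cap the df at the total pooled residual df
    df_total <- dg * length(s2)
  } else if (d0 == 0) {
    s_tilde_sq <- s2
    df_total <- dg
  } else {
    s_tilde_sq <- (d0 * s0_sq + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
  }
  se <- sqrt(s_tilde_sq * (1 / n1 + 1 / n2))
  t_mod <- log_fc / se
  # zero pooled + prior variance: no evidence either way when means agree
  degen <- se == 0
  t_mod[degen & log_fc == 0] <- 0
  t_mod[degen & log_fc != 0] <- sign(log_fc[degen & log_fc != 0]) * Inf
  p <- 2 * pt(abs(t_mod), df = df_total, lower.tail = FALSE)

  out <- data.frame(gene = rownames(x), log_fc = log_fc, t_mod = t_mod,
                    p = p, p_adj = bh_adjust(p), s2_g = s2,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "df_residual") <- dg
  attr(out, "case") <- case
  attr(out, "control") <- ctrl
  class(out) <- c("ferro_de", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Derive up/down signatures from a differential result
#'
#' Signature A holds genes up in the case group (`log_fc > lfc_threshold`),
#' signature B genes down (`log_fc < -lfc_threshold`), both at
#' `p_adj < fdr_threshold`; all inequalities strict.
#'
#' @param result a `ferro_de` table oriented so positive `log_fc` means
#'   higher in the case cluster.
#' @param lfc_threshold absolute log2 fold-change threshold (default 0.5).
#' @param fdr_threshold adjusted-p threshold (default 0.05).
#' @return list of class `signature_pair`: `signature_A`, `signature_B`,
#'   `thresholds`.
#' @export
derive_signatures <- function(result, lfc_threshold = 0.5,
                              fdr_threshold = 0.05) {
  if (lfc_threshold <= 0) stop("lfc_threshold must be positive")
  sig_a <- result$gene[result$log_fc > lfc_threshold &
                         result$p_adj < fdr_threshold]
  sig_b <- result$gene[result$log_fc < -lfc_threshold &
                         result$p_adj < fdr_threshold]
  if (length(sig_a) == 0 || length(sig_b) == 0) {
    stop("empty signature at |logFC| > ", lfc_threshold, ", FDR < ",
         fdr_threshold, "; relax the thresholds")
  }
  structure(list(signature_A = sig_a, signature_B = sig_b,
                 thresholds = c(lfc = lfc_threshold, fdr = fdr_threshold)),
            class = "signature_pair")
}

#' @export
print.signature_pair <- function(x, ...) {
  cat(sprintf("Signature pair (|logFC| > %g, FDR < %g)\n",
              x$thresholds["lfc"], x$thresholds["fdr"]))
  cat(sprintf("  A (up in case cluster):   %d genes\n", length(x$signature_A)))
  cat(sprintf("  B (down in case cluster): %d genes\n", length(x$signature_B)))
  invisible(x)
}
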