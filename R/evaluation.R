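# Diagnostic and prognostic evaluation: ROC/AUC with the Youden cutoff,
# Welch group comparison, Kaplan-Meier curves, the two-group log-rank
# test, and a fixed-horizon survival ROC. The AUC equals the normalized
# Mann-Whitney U (ties counted 1/2) exactly; the threshold sweep uses the
# ">= cutoff means predicted positive" convention.

#' ROC curve and AUC
#'
#' @param scores numeric vector.
#' @param labels binary labels (logical, 0/1, or values matched against
#'   `positive`).
#' @param positive value of `labels` treated as positive (default
#'   auto-detects logical/0-1, otherwise `"TCMR"`).
#' @return object of class `ferro_roc`: `auc`, a `thresholds` data.frame
#'   (cutoff, sensitivity, specificity), the Youden cutoff with its
#'   sensitivity/specificity, and class counts.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  pos <- binarize_labels(labels, positive)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be non-empty")
  if (any(!is.finite(scores))) stop("scores must be finite")

  # exact Mann-Whitney AUC via midranks (ties count 1/2)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  if (length(unique(scores)) == 1) {
    warning("constant scores; AUC = 0.5", call. = FALSE)
  }

  cuts <- c(sort(unique(scores)), Inf)   # ">= cutoff" => predicted positive
  sens <- vapply(cuts, function(cc) mean(scores[pos] >= cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(scores[!pos] < cc), numeric(1))
  thr <- data.frame(cutoff = cuts, sensitivity = sens, specificity = spec)

  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]  # ties toward higher specificity
  structure(list(auc = auc, thresholds = thr,
                 youden_cutoff = cuts[best],
                 sens_at_cutoff = sens[best], spec_at_cutoff = spec[best],
                 youden_j = j[best], n_pos = n_pos, n_neg = n_neg),
            class = "ferro_roc")
}

binarize_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.null(positive)) {
    u <- unique(labels)
    if (all(u %in% c(0, 1))) return(labels == 1)
    positive <- "TCMR"
  }
  if (!positive %in% labels) stop("positive label '", positive, "' absent")
  labels == positive
}

#' Youden-optimal cutoff of a ROC result
#'
#' The cutoff maximizing sensitivity + specificity - 1; ties break toward
#' higher specificity.
#'
#' @param roc a `ferro_roc`.
#' @return named list (cutoff, sensitivity, specificity, j).
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "ferro_roc"))
  list(cutoff = roc$youden_cutoff, sensitivity = roc$sens_at_cutoff,
       specificity = roc$spec_at_cutoff, j = roc$youden_j)
}

#' @export
print.ferro_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (n+ = %d, n- = %d)\n", x$auc, x$n_pos, x$n_neg))
  cat(sprintf("Youden cutoff %.4g: sensitivity %.3f, specificity %.3f\n",
              x$youden_cutoff, x$sens_at_cutoff, x$spec_at_cutoff))
  invisible(x)
}

#' @export
plot.ferro_roc <- function(x, ...) {
  with(x$thresholds, {
    o <- order(1 - specificity, sensitivity)
    graphics::plot((1 - specificity)[o], sensitivity[o], type = "s",
                   xlab = "1 - specificity", ylab = "sensitivity",
                   xlim = c(0, 1), ylim = c(0, 1), ...)
  })
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Welch two-group comparison of scores
#'
#' Two-sided Welch t-test (unequal variances). Degenerate constant groups
#' with equal means return t = 0, p = 1.
#'
#' @param scores numeric vector.
#' @param labels two-group labels.
#' @return list (t_statistic, p, df, means).
#' @export
compare_groups <- function(scores, labels) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("exactly two groups required")
  a <- scores[labels == lev[1]]; b <- scores[labels == lev[2]]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t_statistic = 0, p = 1,
                                        df = NA_real_,
                                        means = c(mean(a), mean(b))))
    return(list(t_statistic = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = NA_real_, means = c(mean(a), mean(b))))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(t_statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), means = unname(tt$estimate))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator via the survival package; censored-only times
#' reduce the risk set without a step.
#'
#' @param times follow-up times (>= 0).
#' @param events event indicators (1 = failure, 0 = censored).
#' @return data.frame (time, surv, n_risk, n_event) of class `ferro_km`,
#'   starting at S(0) = 1.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  if (any(times < 0)) stop("negative times")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = c(0, fit$time), surv = c(1, fit$surv),
                    n_risk = c(length(times), fit$n.risk),
                    n_event = c(0, fit$n.event))
  class(out) <- c("ferro_km", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' @param times follow-up times.
#' @param events event indicators (0/1).
#' @param groups two-group labels.
#' @return list (chi2, p) with p from chi-square on 1 df.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) != 2) stop("exactly two groups required")
  if (sum(events) == 0) stop("no events observed; log-rank undefined")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  chi2 <- unname(sd_$chisq)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Survival report for a score: KM curves, log-rank, horizon ROC
#'
#' Samples are split into high/low score groups (median split by default,
#' or any quantile), compared by Kaplan-Meier and log-rank, and the score
#' is evaluated as a predictor of the fixed-horizon outcome.
#'
#' @param scores numeric vector.
#' @param times,events survival data aligned with `scores`.
#' @param horizon fixed horizon (days; default 1095 = 3 years).
#' @param split quantile for the high/low split (default 0.5 = median).
#' @return list of class `ferro_survival`: `km_curves` (per group),
#'   `logrank_chi2`, `logrank_p`, `grouping_rule`, `horizon_roc`.
#' @export
survival_report <- function(scores, times, events, horizon = 1095,
                            split = 0.5) {
  cut <- quantile(scores, split)
  grp <- ifelse(scores > cut, "high", "low")
  if (length(unique(grp)) != 2) stop("degenerate score split")
  lr <- logrank_test(times, events, grp)
  km <- lapply(c(high = "high", low = "low"), function(g) {
    km_curve(times[grp == g], events[grp == g])
  })
  hroc <- fixed_horizon_roc(scores, times, events, horizon)
  structure(list(km_curves = km, logrank_chi2 = lr$chi2, logrank_p = lr$p,
                 grouping_rule = sprintf("quantile %.2f split at %.4g",
                                         split, cut),
                 horizon_roc = hroc),
            class = "ferro_survival")
}

#' Fixed-horizon survival ROC
#'
#' Positive = event observed at or before the horizon; negative = followed
#' beyond the horizon (event-free at the horizon). Samples censored before
#' the horizon are excluded, with the count reported.
#'
#' @param scores numeric vector.
#' @param times,events survival data aligned with `scores`.
#' @param horizon time horizon (> 0).
#' @return a `ferro_roc` with attribute `n_excluded`.
#' @export
fixed_horizon_roc <- function(scores, times, events, horizon) {
  if (horizon <= 0) stop("horizon must be positive")
  pos <- events == 1 & times <= horizon
  neg <- times > horizon
  excluded <- !(pos | neg)
  if (sum(pos) == 0 || sum(neg) == 0) {
    stop(sprintf("no usable %s after excluding %d sample(s) censored before the horizon",
                 if (sum(pos) == 0) "positives" else "negatives",
                 sum(excluded)))
  }
  roc <- roc_auc(scores[!excluded], pos[!excluded], positive = TRUE)
  attr(roc, "n_excluded") <- sum(excluded)
  roc
}
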