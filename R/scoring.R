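# The PCA-based ferroptosis score. Per signature, genes are centered at
# their training means and the leading principal direction over genes (the
# rotation) maps a centered profile to its PC1 coordinate; the per-sample
# score is the signed difference of the two coordinates (B minus A),
# oriented so the case group scores higher. New cohorts are projected with
# the stored rotation — no refitting.

fit_signature_pca <- function(x, genes, label, scale. = FALSE) {
  present <- genes[genes %in% rownames(x)]
  missing <- setdiff(genes, present)
  if (length(missing)) {
    warning(sprintf("signature %s: %d gene(s) absent from training matrix: %s",
                    label, length(missing), paste(missing, collapse = ", ")),
            call. = FALSE)
  }
  if (length(present) < 3) {
    stop("signature ", label, ": fewer than 3 usable genes")
  }
  sub <- x[present, , drop = FALSE]
  if (all(apply(sub, 1, var) == 0)) {
    stop("signature ", label, ": zero-variance submatrix")
  }
  means <- rowMeans(sub)
  sds <- rep(1, length(present))
  if (scale.) {
    sds <- apply(sub, 1, sd)
    sds[sds == 0] <- 1
  }
  centered <- (sub - means) / sds
  pc <- prcomp(t(centered), center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, 1]
  coords <- as.numeric(crossprod(centered, rot))
  # fix the sign ambiguity: the coordinate should rise with the mean
  # expression of the signature's own genes
  anchor <- suppressWarnings(cor(coords, colMeans(sub)))
  if (is.finite(anchor) && anchor < 0) {
    rot <- -rot
    coords <- -coords
  }
  list(genes = present, means = setNames(means, present),
       sds = setNames(sds, present), rotation = setNames(rot, present),
       coords = setNames(coords, colnames(x)))
}

#' Fit the ferroptosis scoring model
#'
#' For each signature the genes x samples submatrix is centered per gene at
#' its training mean (optionally z-scored) and the unit-norm PC1 loading
#' vector over genes is stored as the rotation. The raw per-sample score is
#' `PC1_B - PC1_A`; with phenotype labels supplied, the orientation sign is
#' set so the case group's mean score exceeds the control group's (without
#' labels it defaults to +1).
#'
#' @param x training expression matrix (genes x samples, log2).
#' @param signatures a `signature_pair` (or list with `signature_A`,
#'   `signature_B`).
#' @param labels optional character/factor per sample; used with `case` to
#'   orient the score.
#' @param case label value marking the case group (default `"TCMR"`).
#' @param scale. z-score genes before PCA (default FALSE: centering only).
#' @return object of class `ferroscore_model`.
#' @seealso [project_scores()], [save_model()], [load_model()]
#' @export
fit_ferroscore <- function(x, signatures, labels = NULL, case = "TCMR",
                           scale. = FALSE) {
  validate_expression(x)
  fa <- fit_signature_pca(x, signatures$signature_A, "A", scale.)
  fb <- fit_signature_pca(x, signatures$signature_B, "B", scale.)
  raw <- fb$coords - fa$coords

  orientation <- 1
  training_summary <- NULL
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != ncol(x)) stop("labels must match columns of x")
    is_case <- labels == case
    if (any(is_case) && any(!is_case)) {
      if (mean(raw[is_case]) < mean(raw[!is_case])) orientation <- -1
      sc <- orientation * raw
      training_summary <- list(
        case_mean = mean(sc[is_case]), control_mean = mean(sc[!is_case]),
        case_label = case, n_case = sum(is_case), n_control = sum(!is_case))
    } else {
      warning("labels contain a single group; orientation defaults to +1",
              call. = FALSE)
    }
  } else {
    message("no labels supplied; orientation_sign defaults to +1")
  }

  model <- structure(list(
    signature_A = fa$genes, signature_B = fb$genes,
    gene_means_A = fa$means, gene_means_B = fb$means,
    gene_sds_A = fa$sds, gene_sds_B = fb$sds,
    rotation_A = fa$rotation, rotation_B = fb$rotation,
    orientation_sign = orientation,
    training_summary = training_summary,
    scaled = scale.), class = "ferroscore_model")
  model$training_scores <- setNames(orientation * raw, colnames(x))
  model
}

project_one <- function(model, x_new, sig) {
  genes <- model[[paste0("signature_", sig)]]
  means <- model[[paste0("gene_means_", sig)]]
  sds <- model[[paste0("gene_sds_", sig)]]
  if (is.null(sds)) sds <- setNames(rep(1, length(genes)), genes)
  rot <- model[[paste0("rotation_", sig)]]
  present <- genes[genes %in% rownames(x_new)]
  missing <- setdiff(genes, present)
  if (length(present) == 0) {
    stop("signature ", sig, ": every gene absent from new matrix")
  }
  if (length(missing) > 0.5 * length(genes)) {
    stop(sprintf("signature %s: %d of %d genes missing (> 50%%)", sig,
                 length(missing), length(genes)))
  }
  if (length(missing)) {
    warning(sprintf("signature %s: %d gene(s) missing, imputed at training mean: %s",
                    sig, length(missing), paste(missing, collapse = ", ")),
            call. = FALSE)
  }
  centered <- matrix(0, length(genes), ncol(x_new),
                     dimnames = list(genes, colnames(x_new)))
  centered[present, ] <- (x_new[present, , drop = FALSE] - means[present]) /
    sds[present]
  as.numeric(crossprod(centered, rot))
}

#' Project the ferroptosis score onto a new cohort
#'
#' Each sample is centered with the stored training means and mapped
#' through the stored rotations; missing signature genes are imputed at
#' the training mean (centered value 0), with an error if over half of a
#' signature is absent.
#'
#' @param model a fitted `ferroscore_model`.
#' @param x_new expression matrix sharing the model's gene symbol space.
#' @return data.frame (sample_id, ferroptosis_score).
#' @export
project_scores <- function(model, x_new) {
  stopifnot(inherits(model, "ferroscore_model"))
  ca <- project_one(model, x_new, "A")
  cb <- project_one(model, x_new, "B")
  data.frame(sample_id = colnames(x_new),
             ferroptosis_score = model$orientation_sign * (cb - ca),
             stringsAsFactors = FALSE)
}

#' @export
predict.ferroscore_model <- function(object, newdata, ...) {
  project_scores(object, newdata)
}

#' @export
coef.ferroscore_model <- function(object, ...) {
  list(rotation_A = object$rotation_A, rotation_B = object$rotation_B)
}

#' @export
print.ferroscore_model <- function(x, ...) {
  cat("Ferroptosis scoring model (PC1_B - PC1_A, oriented)\n")
  cat(sprintf("  signature A: %d genes   signature B: %d genes\n",
              length(x$signature_A), length(x$signature_B)))
  cat(sprintf("  orientation sign: %+d\n", as.integer(x$orientation_sign)))
  if (!is.null(x$training_summary)) {
    ts <- x$training_summary
    cat(sprintf("  training means: %s %.3f vs control %.3f (n = %d/%d)\n",
                ts$case_label, ts$case_mean, ts$control_mean,
                ts$n_case, ts$n_control))
  }
  invisible(x)
}

#' @export
summary.ferroscore_model <- function(object, ...) {
  print(object)
  top <- function(rot) head(rot[order(-abs(rot))], 5)
  cat("  top |loading| signature A:\n")
  print(round(top(object$rotation_A), 3))
  cat("  top |loading| signature B:\n")
  print(round(top(object$rotation_B), 3))
  invisible(object)
}
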