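# Resampling consensus clustering over the ferroptosis-panel subspace.
# For each resample a fraction of samples is drawn without replacement and
# clustered; the consensus matrix is the ratio of co-clustering to
# co-sampling counts. k is selected quantitatively by PAC (proportion of
# ambiguous clustering) or by the relative increase in area under the
# consensus CDF, replacing visual CDF inspection.

#' Restrict an expression matrix to a gene panel
#'
#' Rows are restricted to panel symbols present in the matrix, in panel
#' order. Panel genes absent from the matrix are reported with a warning;
#' zero-variance rows are dropped (they carry no clustering information
#' and break correlation distances).
#'
#' @param x expression matrix (genes x samples).
#' @param panel a `ferro_gene_set`.
#' @return the restricted matrix, with attributes `missing_genes` and
#'   `dropped_constant`.
#' @export
subset_to_panel <- function(x, panel) {
  present <- panel$symbol[panel$symbol %in% rownames(x)]
  missing <- setdiff(panel$symbol, present)
  if (length(present) == 0) {
    stop("no overlap between panel and expression matrix genes")
  }
  if (length(missing)) {
    warning(sprintf("%d panel gene(s) absent from expression matrix: %s",
                    length(missing), paste(missing, collapse = ", ")),
            call. = FALSE)
  }
  out <- x[present, , drop = FALSE]
  v <- apply(out, 1, var)
  const <- v == 0
  if (any(const)) {
    warning(sprintf("dropped %d zero-variance panel row(s): %s",
                    sum(const), paste(rownames(out)[const], collapse = ", ")),
            call. = FALSE)
    out <- out[!const, , drop = FALSE]
  }
  attr(out, "missing_genes") <- missing
  attr(out, "dropped_constant") <- present[const]
  out
}

# Dissimilarity between samples (columns): 1 - Pearson correlation across
# genes, or Euclidean. Columns with zero variance get correlation 0 with
# everything (maximally dissimilar but defined).
sample_dissimilarity <- function(x, distance = c("pearson", "euclidean")) {
  distance <- match.arg(distance)
  if (distance == "euclidean") return(dist(t(x)))
  cc <- suppressWarnings(cor(x))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  as.dist(1 - cc)
}

# Cluster one subsample at every k in k_range. For the hierarchical base
# method a single tree is cut at each k; for kmeans each k is fit
# separately with a deterministic multi-start.
cluster_at_ks <- function(x, k_range, base = c("hclust", "kmeans"),
                          distance = "pearson") {
  base <- match.arg(base)
  if (base == "hclust") {
    d <- sample_dissimilarity(x, distance)
    tree <- hclust(d, method = "average")
    lab <- lapply(k_range, function(k) cutree(tree, k = k))
  } else {
    lab <- lapply(k_range, function(k) {
      kmeans(t(x), centers = k, nstart = 10, iter.max = 50)$cluster
    })
  }
  names(lab) <- as.character(k_range)
  lab
}

#' Consensus clustering with subsampling
#'
#' For each of `n_resamples` draws, `ceiling(subsample_fraction * n)`
#' samples are taken without replacement and clustered into each `k` in
#' `k_range` (average-linkage agglomerative clustering on 1 - Pearson
#' correlation by default). The consensus entry for a sample pair is the
#' fraction of their co-sampled draws in which they shared a cluster.
#' Pairs never co-sampled get consensus 0 with a warning.
#'
#' @param x expression matrix (genes x samples), typically panel-restricted.
#' @param k_range integer vector of cluster numbers (default 2:9).
#' @param n_resamples number of subsampling draws (>= 2; default 200).
#' @param subsample_fraction fraction of samples per draw (default 0.8).
#' @param seed RNG seed; fixed seed gives identical output.
#' @param base base clusterer, `"hclust"` (default) or `"kmeans"`.
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param k_select method for [select_k()], applied to fill `chosen_k`.
#' @return object of class `consensus_result`: per-k consensus matrices,
#'   co-occurrence/co-sampling counts, CDFs, delta-area, PAC, `chosen_k`,
#'   final `labels`, and the resample index stream.
#' @export
consensus_cluster <- function(x, k_range = 2:9, n_resamples = 200,
                              subsample_fraction = 0.8, seed = 1L,
                              base = c("hclust", "kmeans"),
                              distance = c("pearson", "euclidean"),
                              k_select = c("pac", "delta_area")) {
  base <- match.arg(base)
  distance <- match.arg(distance)
  k_select <- match.arg(k_select)
  n <- ncol(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (n_resamples < 2) stop("n_resamples must be >= 2")
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop("subsample_fraction must lie in (0, 1]")
  }
  if (n < max(k_range) + 1) {
    stop("need at least max(k_range) + 1 samples")
  }
  m <- ceiling(subsample_fraction * n)

  set.seed(seed)
  # draw the full resample stream up front: it is shared across k and is
  # what the tally oracle replays
  resamples <- vector("list", n_resamples)
  for (b in seq_len(n_resamples)) {
    for (try in seq_len(100)) {
      idx <- sort(sample.int(n, m))
      n_distinct <- nrow(unique(t(x[, idx, drop = FALSE])))
      if (n_distinct >= max(k_range)) break
      idx <- NULL
    }
    if (is.null(idx)) {
      stop("could not draw a resample with at least max(k_range) distinct samples")
    }
    resamples[[b]] <- idx
  }

  cosample <- matrix(0L, n, n, dimnames = list(colnames(x), colnames(x)))
  cooccur <- lapply(k_range, function(k) cosample)
  names(cooccur) <- as.character(k_range)
  for (b in seq_len(n_resamples)) {
    idx <- resamples[[b]]
    cosample[idx, idx] <- cosample[idx, idx] + 1L
    labs <- cluster_at_ks(x[, idx, drop = FALSE], k_range, base, distance)
    for (kk in names(labs)) {
      same <- outer(labs[[kk]], labs[[kk]], "==")
      cooccur[[kk]][idx, idx] <- cooccur[[kk]][idx, idx] + (same * 1L)
    }
  }

  never <- cosample == 0 & !diag(TRUE, n)
  if (any(never)) {
    warning(sprintf("%d sample pair(s) never co-sampled; consensus set to 0",
                    sum(never) / 2), call. = FALSE)
  }
  consensus <- lapply(cooccur, function(co) {
    cm <- ifelse(cosample > 0, co / cosample, 0)
    diag(cm) <- 1
    dimnames(cm) <- dimnames(cosample)
    cm
  })

  ut <- upper.tri(cosample)
  cdf <- lapply(consensus, function(cm) ecdf(cm[ut]))
  area <- vapply(consensus, function(cm) cdf_area(cm[ut]), numeric(1))
  delta_area <- area
  if (length(k_range) > 1) {
    delta_area[-1] <- diff(area) / area[-length(area)]
  }
  pac <- vapply(consensus, function(cm) {
    v <- cm[ut]
    mean(v > 0.1 & v < 0.9)
  }, numeric(1))

  res <- structure(list(
    k_range = k_range, consensus = consensus,
    cooccurrence_counts = cooccur, cosample_counts = cosample,
    cdf = cdf, area = area, delta_area = delta_area, pac = pac,
    resamples = resamples, n_resamples = n_resamples,
    subsample_fraction = subsample_fraction, base = base,
    distance = distance, seed = seed), class = "consensus_result")
  res$chosen_k <- select_k(res, method = k_select)
  res$labels <- final_labels(res, res$chosen_k)
  res
}

# area under the empirical CDF of consensus values over [0, 1]
cdf_area <- function(v) {
  s <- sort(v)
  f <- seq_along(s) / length(s)
  sum(diff(c(s, 1)) * f)
}

#' Select the number of clusters from a consensus result
#'
#' `pac`: the k minimizing the proportion of ambiguous consensus values
#' (entries strictly inside `window`); `delta_area`: the largest k whose
#' relative increase in area under the consensus CDF exceeds `threshold`.
#' Ties break toward smaller k.
#'
#' @param result a `consensus_result`.
#' @param method `"pac"` or `"delta_area"`.
#' @param window PAC ambiguity window (default c(0.1, 0.9)).
#' @param threshold delta-area threshold (default 0.05).
#' @return chosen k (integer).
#' @export
select_k <- function(result, method = c("pac", "delta_area"),
                     window = c(0.1, 0.9), threshold = 0.05) {
  method <- match.arg(method)
  ks <- result$k_range
  if (method == "pac") {
    ut <- upper.tri(result$cosample_counts)
    pac <- vapply(result$consensus, function(cm) {
      v <- cm[ut]
      mean(v > window[1] & v < window[2])
    }, numeric(1))
    if (all(!is.finite(pac))) {
      warning("PAC undefined for every k; falling back to delta_area",
              call. = FALSE)
      return(select_k(result, "delta_area", threshold = threshold))
    }
    return(ks[which.min(pac)])  # which.min takes the first (smallest k) on ties
  }
  ok <- which(result$delta_area > threshold)
  if (length(ok) == 0) return(ks[1])
  ks[max(ok)]
}

#' Final cluster labels at a given k
#'
#' Average-linkage hierarchical clustering of the dissimilarity
#' 1 - consensus, cut at k; cluster ids are relabelled 1..k by decreasing
#' cluster size (ties by first occurrence).
#'
#' @param result a `consensus_result`.
#' @param k number of clusters (must be in `result$k_range`).
#' @return named integer vector, sample -> cluster id.
#' @export
final_labels <- function(result, k) {
  if (!k %in% result$k_range) stop("k not in evaluated k_range")
  cm <- result$consensus[[as.character(k)]]
  tree <- hclust(as.dist(1 - cm), method = "average")
  raw <- cutree(tree, k = k)
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  remap <- setNames(seq_along(ord), names(sizes)[ord])
  out <- remap[as.character(raw)]
  setNames(as.integer(out), names(raw))
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering result\n")
  cat(sprintf("  samples: %d  resamples: %d  fraction: %.2f  base: %s/%s\n",
              ncol(x$cosample_counts), x$n_resamples, x$subsample_fraction,
              x$base, x$distance))
  cat(sprintf("  k range: %s\n", paste(x$k_range, collapse = ", ")))
  cat(sprintf("  PAC: %s\n",
              paste(sprintf("k=%d %.3f", x$k_range, x$pac), collapse = "  ")))
  cat(sprintf("  chosen k: %d  (cluster sizes: %s)\n", x$chosen_k,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}
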