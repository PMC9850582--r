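# Readers/writers for the on-disk artifacts: expression matrices (TSV/GCT),
# phenotype tables (CSV), ferroptosis gene panels (TSV) and scoring models
# (JSON). All readers validate; all writers round-trip.

MODEL_SCHEMA_VERSION <- "1.0"

#' Validate an expression matrix
#'
#' An expression matrix is a numeric genes x samples matrix with unique,
#' non-empty rownames (gene symbols) and colnames (sample identifiers), all
#' values finite, on log2 scale.
#'
#' @param x numeric matrix to validate.
#' @return `x` invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression must be a numeric matrix")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate sample identifiers")
  if (!all(is.finite(x))) stop("expression matrix contains non-finite values")
  invisible(x)
}

# Collapse duplicate gene symbols: keep the row with maximal variance across
# samples (standard probe-to-gene practice; deterministic — first maximum on
# ties in file order).
collapse_duplicates <- function(mat) {
  genes <- rownames(mat)
  if (!anyDuplicated(genes)) return(mat)
  dup_syms <- unique(genes[duplicated(genes)])
  keep <- rep(TRUE, nrow(mat))
  for (g in dup_syms) {
    idx <- which(genes == g)
    v <- apply(mat[idx, , drop = FALSE], 1, var)
    keep[idx] <- FALSE
    keep[idx[which.max(v)]] <- TRUE
  }
  warning(sprintf("collapsed %d duplicate gene symbol(s) by max-variance rule",
                  length(dup_syms)), call. = FALSE)
  mat[keep, , drop = FALSE]
}

# Missing-value policy: row-mean imputation if < 20% of the row is missing,
# otherwise drop the row with a warning.
impute_missing <- function(mat, max_missing_frac = 0.2) {
  miss <- is.na(mat)
  if (!any(miss)) return(mat)
  frac <- rowMeans(miss)
  drop <- frac >= max_missing_frac
  if (any(drop)) {
    warning(sprintf("dropped %d gene row(s) with >= %d%% missing values",
                    sum(drop), round(100 * max_missing_frac)), call. = FALSE)
    mat <- mat[!drop, , drop = FALSE]
    miss <- miss[!drop, , drop = FALSE]
  }
  if (any(miss)) {
    rm <- rowMeans(mat, na.rm = TRUE)
    idx <- which(miss, arr.ind = TRUE)
    mat[idx] <- rm[idx[, 1]]
  }
  mat
}

#' Read a gene x sample expression matrix
#'
#' Supported dialects: `"tsv"` — tab-separated with first column header
#' `gene` and one column per sample; `"gct"` — GCT v1.2 with its two-line
#' preamble and a Description column that is discarded. Values are assumed
#' to be log2-scale already; set `log2 = TRUE` to apply `log2(x + 1)`.
#' Duplicate gene symbols are collapsed to the row with maximal variance;
#' missing cells (token `NA`) are row-mean imputed when under 20% of the
#' row, otherwise the row is dropped.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"gct"`.
#' @param log2 apply `log2(x + 1)` after reading (for linear-scale input).
#' @return validated numeric matrix (genes x samples).
#' @export
read_expression <- function(path, dialect = c("tsv", "gct"), log2 = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "gct") {
    l1 <- readLines(path, n = 1)
    if (!startsWith(l1, "#1.2")) {
      stop("malformed GCT header: expected '#1.2' on line 1")
    }
    df <- read.delim(path, skip = 2, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 3 || tolower(names(df)[1]) != "name") {
      stop("malformed GCT header: expected Name/Description columns")
    }
    genes <- as.character(df[[1]])
    df <- df[, -c(1, 2), drop = FALSE]
  } else {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2 || tolower(names(df)[1]) != "gene") {
      stop("malformed header: first column of an expression TSV must be 'gene'")
    }
    genes <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  # read.delim silently uniquifies duplicate header names; check the raw line
  hdr_line <- readLines(path, n = if (dialect == "gct") 3 else 1)
  raw_hdr <- strsplit(hdr_line[length(hdr_line)], "\t", fixed = TRUE)[[1]]
  raw_samples <- raw_hdr[-seq_len(if (dialect == "gct") 2 else 1)]
  if (anyDuplicated(raw_samples)) {
    stop("duplicate sample IDs in header: ",
         paste(unique(raw_samples[duplicated(raw_samples)]), collapse = ", "))
  }
  samples <- names(df)
  if (anyDuplicated(samples)) {
    stop("duplicate sample IDs in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & toupper(trimws(col)) != "NA")
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                     col[bad[1]], genes[bad[1]], samples[j]))
      }
      df[[j]] <- num
    }
  }
  mat <- as.matrix(df)
  rownames(mat) <- genes
  mat <- impute_missing(mat)
  mat <- collapse_duplicates(mat)
  if (log2) mat <- log2(mat + 1)
  validate_expression(mat)
  mat
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()] for the `tsv` dialect; full precision so
#' the round-trip reproduces values to within 1e-12.
#'
#' @param x validated expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  num <- apply(x, 2, function(col) sprintf("%.17g", col))
  if (nrow(x) == 1) num <- matrix(num, nrow = 1, dimnames = dimnames(x))
  df <- data.frame(gene = rownames(x), num, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("gene", colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample phenotype table
#'
#' CSV with required columns `sample_id` and `diagnosis`, optional `time`
#' (follow-up days) and `event` (graft loss, 0/1). Diagnosis labels are
#' mapped case-insensitively onto the closed vocabulary `TCMR`,
#' `non_rejection`, `other`; extra aliases (e.g. `STA`, `NR`) can be
#' supplied via `aliases`. Unknown labels map to `other`.
#'
#' @param path CSV path.
#' @param aliases named character vector mapping extra labels (lowercased)
#'   to vocabulary terms, e.g. `c(nr = "non_rejection", sta = "non_rejection")`.
#' @return data.frame with columns sample_id, diagnosis, time, event.
#' @export
read_phenotypes <- function(path, aliases = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "diagnosis")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id values")
  vocab <- c(tcmr = "TCMR", non_rejection = "non_rejection",
             "non-rejection" = "non_rejection", other = "other")
  if (!is.null(aliases)) {
    names(aliases) <- tolower(names(aliases))
    bad <- setdiff(aliases, c("TCMR", "non_rejection", "other"))
    if (length(bad)) stop("alias targets outside vocabulary: ",
                          paste(bad, collapse = ", "))
    vocab <- c(vocab, aliases)
  }
  key <- tolower(trimws(df$diagnosis))
  diag <- unname(vocab[key])
  diag[is.na(diag)] <- "other"
  out <- data.frame(sample_id = as.character(df$sample_id),
                    diagnosis = diag, stringsAsFactors = FALSE)
  has_time <- "time" %in% names(df)
  has_event <- "event" %in% names(df)
  if (has_time != has_event) {
    stop("columns 'time' and 'event' must be supplied together")
  }
  if (has_time) {
    tm <- as.numeric(df$time)
    ev <- as.numeric(df$event)
    present <- !is.na(tm) | !is.na(ev)
    if (any(is.na(tm) != is.na(ev))) {
      stop("'event' must be present exactly where 'time' is")
    }
    if (any(tm[present] < 0, na.rm = TRUE)) stop("negative follow-up time")
    if (!all(ev[present] %in% c(0, 1))) stop("'event' must be 0 or 1")
    out$time <- tm
    out$event <- ev
  }
  out
}

#' Read a ferroptosis gene panel
#'
#' TSV with columns `symbol` and `category`; categories are the closed
#' vocabulary `driver`, `suppressor`, `marker`.
#'
#' @param path TSV path.
#' @return data.frame (symbol, category) with class `ferro_gene_set`; the
#'   per-category counts are available via [panel_counts()].
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("symbol", "category")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("empty gene panel")
  if (anyDuplicated(df$symbol)) {
    stop("duplicate panel symbols: ",
         paste(unique(df$symbol[duplicated(df$symbol)]), collapse = ", "))
  }
  ok <- df$category %in% c("driver", "suppressor", "marker")
  if (!all(ok)) {
    stop("unknown category token(s) at row(s) ",
         paste(which(!ok), collapse = ", "), ": ",
         paste(unique(df$category[!ok]), collapse = ", "))
  }
  out <- df[, req]
  class(out) <- c("ferro_gene_set", "data.frame")
  out
}

#' Per-category counts of a gene panel
#'
#' @param panel a `ferro_gene_set`.
#' @return named integer vector (driver, suppressor, marker, total).
#' @export
panel_counts <- function(panel) {
  n <- c(driver = sum(panel$category == "driver"),
         suppressor = sum(panel$category == "suppressor"),
         marker = sum(panel$category == "marker"))
  c(n, total = sum(n))
}

#' Write a gene panel as TSV
#' @param panel a `ferro_gene_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(panel, path) {
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Save a fitted scoring model as JSON
#'
#' The JSON schema stores the signature gene lists, training gene means,
#' unit-norm PC1 rotations, the orientation sign and a training summary,
#' plus a schema version that is checked on load.
#'
#' @param model a `ferroscore_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ferroscore_model"))
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    signature_A = model$signature_A,
    signature_B = model$signature_B,
    gene_means_A = as.list(model$gene_means_A),
    gene_means_B = as.list(model$gene_means_B),
    gene_sds_A = as.list(model$gene_sds_A),
    gene_sds_B = as.list(model$gene_sds_B),
    rotation_A = as.list(model$rotation_A),
    rotation_B = as.list(model$rotation_B),
    orientation_sign = model$orientation_sign,
    training_summary = model$training_summary
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a scoring model saved by [save_model()]
#'
#' @param path JSON path.
#' @return a `ferroscore_model`; projecting with the loaded model matches
#'   the original to within 1e-10.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("model schema error: not valid JSON (", conditionMessage(e), ")",
                         call. = FALSE)
                  })
  if (is.null(obj$schema_version)) stop("model schema error: missing schema_version")
  if (!identical(as.character(obj$schema_version), MODEL_SCHEMA_VERSION)) {
    stop(sprintf("model schema version mismatch: file has '%s', expected '%s'",
                 obj$schema_version, MODEL_SCHEMA_VERSION))
  }
  unl <- function(x) unlist(x, use.names = TRUE)
  model <- list(
    signature_A = as.character(unl(obj$signature_A)),
    signature_B = as.character(unl(obj$signature_B)),
    gene_means_A = unl(obj$gene_means_A),
    gene_means_B = unl(obj$gene_means_B),
    gene_sds_A = unl(obj$gene_sds_A),
    gene_sds_B = unl(obj$gene_sds_B),
    rotation_A = unl(obj$rotation_A),
    rotation_B = unl(obj$rotation_B),
    orientation_sign = as.numeric(obj$orientation_sign),
    training_summary = lapply(obj$training_summary, unl)
  )
  class(model) <- "ferroscore_model"
  check_model(model)
  model
}

check_model <- function(model) {
  for (s in c("A", "B")) {
    rot <- model[[paste0("rotation_", s)]]
    sig <- model[[paste0("signature_", s)]]
    if (!identical(names(rot), sig)) {
      stop("model schema error: rotation_", s, " not indexed by signature_", s)
    }
    if (abs(sqrt(sum(rot^2)) - 1) > 1e-8) {
      stop("model schema error: rotation_", s, " is not unit norm")
    }
    if (!identical(names(model[[paste0("gene_means_", s)]]), sig)) {
      stop("model schema error: gene_means_", s, " not indexed by signature_", s)
    }
  }
  if (!model$orientation_sign %in% c(-1, 1)) {
    stop("model schema error: orientation_sign must be +1 or -1")
  }
  invisible(model)
}
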