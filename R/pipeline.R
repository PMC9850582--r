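# End-to-end orchestration from one configuration: simulate or ingest a
# training cohort, consensus-cluster it on the ferroptosis panel, derive
# signatures between the clusters, fit the scoring model, project every
# cohort and evaluate. All stage seeds derive from the global seed by
# fixed offsets so reruns are reproducible.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    simulate = NULL,      # cohort_config fields, or NULL when paths given
    training = NULL,      # list(expression=, phenotypes=)
    validation = list(),  # named list of list(expression=, phenotypes=)
    panel = NULL,         # panel TSV path (defaults to simulated panel)
    clustering = list(k_min = 2L, k_max = 9L, resamples = 200L,
                      fraction = 0.8, base = "hclust", distance = "pearson"),
    de = list(lfc = 0.5, fdr = 0.05),
    scoring = list(scale = FALSE),
    evaluation = list(positive_label = "TCMR", horizon = 1095, split = 0.5)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML path or a list; unknown keys are rejected by name,
#' defaults are filled in, and thresholds are range-checked. Errors are
#' aggregated into one message.
#'
#' @param config list or path to a YAML file.
#' @return the normalized configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path")
  defaults <- pipeline_defaults()
  errs <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  for (sect in c("clustering", "de", "scoring", "evaluation")) {
    if (!is.null(config[[sect]])) {
      bad <- setdiff(names(config[[sect]]), names(defaults[[sect]]))
      if (length(bad)) {
        errs <- c(errs, paste0("unknown key(s) in ", sect, ": ",
                               paste(bad, collapse = ", ")))
      }
      defaults[[sect]] <- modifyList(defaults[[sect]], config[[sect]])
    }
  }
  for (key in setdiff(names(defaults),
                      c("clustering", "de", "scoring", "evaluation"))) {
    if (!is.null(config[[key]])) defaults[[key]] <- config[[key]]
  }
  cfg <- defaults
  if (is.null(cfg$simulate) && is.null(cfg$training)) {
    errs <- c(errs, "either 'simulate' or 'training' must be given")
  }
  if (!is.null(cfg$training)) {
    for (p in unlist(cfg$training)) {
      if (!file.exists(p)) errs <- c(errs, paste0("missing file: ", p))
    }
    if (is.null(cfg$panel)) errs <- c(errs, "'panel' required with 'training'")
  }
  if (!is.null(cfg$panel) && !file.exists(cfg$panel)) {
    errs <- c(errs, paste0("missing file: ", cfg$panel))
  }
  for (nm in names(cfg$validation)) {
    for (p in unlist(cfg$validation[[nm]])) {
      if (!file.exists(p)) errs <- c(errs, paste0("missing file: ", p))
    }
  }
  if (cfg$de$lfc <= 0) errs <- c(errs, "de.lfc must be > 0")
  if (cfg$de$fdr <= 0 || cfg$de$fdr >= 1) errs <- c(errs, "de.fdr must be in (0,1)")
  if (cfg$clustering$k_min < 2) errs <- c(errs, "clustering.k_min must be >= 2")
  if (cfg$clustering$k_max < cfg$clustering$k_min) {
    errs <- c(errs, "clustering.k_max must be >= k_min")
  }
  if (!is.null(cfg$simulate)) {
    cfg$simulate <- tryCatch(
      do.call(cohort_config,
              modifyList(cfg$simulate, list(seed = cfg$seed + 11L))),
      error = function(e) {
        errs <<- c(errs, paste0("simulate: ", conditionMessage(e)))
        NULL
      })
  }
  if (length(errs)) stop("invalid configuration:\n  - ",
                         paste(errs, collapse = "\n  - "), call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full scoring pipeline
#'
#' Stages: cohort acquisition (simulation or files), panel restriction,
#' consensus clustering, cluster-vs-cluster differential expression,
#' signature derivation, model fitting, projection of training and
#' validation cohorts, diagnostic and (when survival data are present)
#' prognostic evaluation. Artifacts are written under `config$out_dir`
#' when set, together with a provenance manifest.
#'
#' @param config a configuration list or YAML path (see [validate_config()]).
#' @return list with the consensus result, DE table, signatures, fitted
#'   model, per-cohort score tables and evaluation reports.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  out_dir <- cfg$out_dir
  persist <- !is.null(out_dir)
  if (persist) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- stage("ingest", {
    if (!is.null(cfg$simulate)) {
      ch <- generate_cohort(cfg$simulate)
      ch$phenotypes <- attach_survival(ch$phenotypes,
                                       ch$truth$latent_scores, cfg$simulate)
      ch
    } else {
      list(expression = read_expression(cfg$training$expression),
           phenotypes = read_phenotypes(cfg$training$phenotypes),
           panel = read_gene_set(cfg$panel))
    }
  })
  x <- cohort$expression
  pheno <- cohort$phenotypes
  panel <- if (!is.null(cfg$panel) && is.null(cfg$simulate)) {
    read_gene_set(cfg$panel)
  } else cohort$panel

  xp <- stage("panel_subset", subset_to_panel(x, panel))

  cons <- stage("consensus_clustering", consensus_cluster(
    xp, k_range = cfg$clustering$k_min:cfg$clustering$k_max,
    n_resamples = cfg$clustering$resamples,
    subsample_fraction = cfg$clustering$fraction,
    seed = cfg$seed + 101L, base = cfg$clustering$base,
    distance = cfg$clustering$distance))

  labels <- cons$labels[colnames(x)]
  # case-enriched cluster: the one with the highest positive-label fraction
  pos <- cfg$evaluation$positive_label
  case_cluster <- stage("case_cluster", {
    frac <- tapply(pheno$diagnosis[match(names(labels), pheno$sample_id)] == pos,
                   labels, mean)
    as.integer(names(frac)[which.max(frac)])
  })

  de <- stage("differential_expression", moderated_t_test(
    x, labels = ifelse(labels == case_cluster, "case_cluster", "other"),
    case = "case_cluster"))

  sigs <- stage("signatures", derive_signatures(de, cfg$de$lfc, cfg$de$fdr))

  model <- stage("fit", fit_ferroscore(
    x, sigs, labels = pheno$diagnosis[match(colnames(x), pheno$sample_id)],
    case = pos, scale. = cfg$scoring$scale))

  scores <- list(training = project_scores(model, x))
  reports <- list()
  diag_train <- pheno$diagnosis[match(scores$training$sample_id,
                                      pheno$sample_id)]
  reports$training <- stage("evaluate_training", {
    r <- list(roc = roc_auc(scores$training$ferroptosis_score, diag_train,
                            positive = pos))
    r$t_test <- compare_groups(scores$training$ferroptosis_score,
                               ifelse(diag_train == pos, pos, "other"))
    if (!is.null(pheno$time)) {
      idx <- match(scores$training$sample_id, pheno$sample_id)
      r$survival <- survival_report(scores$training$ferroptosis_score,
                                    pheno$time[idx], pheno$event[idx],
                                    horizon = cfg$evaluation$horizon,
                                    split = cfg$evaluation$split)
    }
    r
  })

  for (nm in names(cfg$validation)) {
    vc <- cfg$validation[[nm]]
    vx <- stage(paste0("project_", nm), read_expression(vc$expression))
    scores[[nm]] <- project_scores(model, vx)
    if (!is.null(vc$phenotypes)) {
      vp <- read_phenotypes(vc$phenotypes)
      vd <- vp$diagnosis[match(scores[[nm]]$sample_id, vp$sample_id)]
      reports[[nm]] <- stage(paste0("evaluate_", nm), list(
        roc = roc_auc(scores[[nm]]$ferroptosis_score, vd, positive = pos)))
    }
  }

  result <- list(consensus = cons, de = de, signatures = sigs,
                 model = model, case_cluster = case_cluster,
                 scores = scores, reports = reports, config = cfg)

  if (persist) {
    jsonlite::write_json(
      list(labels = as.list(cons$labels), chosen_k = cons$chosen_k,
           pac = as.list(cons$pac), delta_area = as.list(cons$delta_area)),
      file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
    write.table(as.data.frame(de), file.path(out_dir, "de_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(signature_A = sigs$signature_A, signature_B = sigs$signature_B,
           thresholds = as.list(sigs$thresholds)),
      file.path(out_dir, "signatures.json"), auto_unbox = TRUE, digits = NA)
    save_model(model, file.path(out_dir, "model.json"))
    for (nm in names(scores)) {
      write.table(scores[[nm]], file.path(out_dir, paste0("scores_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("ferroscore")),
      seed = cfg$seed,
      parameters = cfg[c("clustering", "de", "scoring", "evaluation")],
      chosen_k = cons$chosen_k, case_cluster = case_cluster,
      n_signature_A = length(sigs$signature_A),
      n_signature_B = length(sigs$signature_B),
      training_auc = reports$training$roc$auc)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
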