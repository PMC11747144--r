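#' Preprocess a cohort beta matrix
#'
#' Runs the QC chain downstream of normalization: probe filters (sex
#' chromosomes, SNP overlap, missingness), sample filters (missingness),
#' and empirical-Bayes batch correction using the sample-sheet batch
#' column. The input is assumed to be already normalized; functional
#' normalization needs raw control-probe intensities and is outside this
#' package's boundary. Correction is applied on the M scale by default
#' and back-transformed to beta values.
#'
#' @param bm Beta matrix (probes x samples).
#' @param ann Probe annotations.
#' @param sheet Sample sheet covering the matrix columns (batch column
#'   used for correction; correction is skipped when all batches agree
#'   or batch is absent).
#' @param qc [qc_params()].
#' @param correction_scale `"m"` (default) or `"beta"`.
#' @return A list: `beta` (filtered, corrected matrix), `probe_report`,
#'   `sample_report`.
#' @export
preprocess_cohort <- function(bm, ann, sheet, qc = qc_params(),
                              correction_scale = c("m", "beta")) {
  correction_scale <- match.arg(correction_scale)
  fp <- filter_probes(bm, ann, qc)
  fs <- filter_samples(fp$matrix, qc)
  bm2 <- fs$matrix
  batches <- sheet$batch[match(colnames(bm2), sheet$sample_id)]
  if (anyNA(batches)) {
    stop("sample sheet does not cover all matrix columns", call. = FALSE)
  }
  if (length(unique(batches)) > 1) {
    if (correction_scale == "m") {
      m <- beta_to_m(bm2, qc$mvalue_epsilon)
      bm2 <- m_to_beta(combat_adjust(m, batches))
    } else {
      adj <- combat_adjust(bm2, batches)
      bm2 <- pmin(pmax(adj, 0), 1)
      dimnames(bm2) <- dimnames(adj)
    }
  }
  list(beta = bm2, probe_report = fp$report, sample_report = fs$report)
}

#' Run the full pipeline on one cohort
#'
#' QC -> batch correction -> mQTL restriction -> top-k variance
#' selection -> stratified k-fold cross-validation.
#'
#' @inheritParams preprocess_cohort
#' @param catalog [mqtl_catalog()].
#' @param fs_cfg [feature_selection_config()].
#' @param net_cfg [network_config()].
#' @param k Number of CV folds.
#' @param seed Integer seed.
#' @return A list: `cv` (a `cv_report`), `preprocess` (filter reports).
#' @export
run_cohort_pipeline <- function(bm, sheet, ann, catalog, qc = qc_params(),
                                fs_cfg = feature_selection_config(),
                                net_cfg = network_config(), k = 10L,
                                seed = 1L,
                                correction_scale = c("m", "beta")) {
  pre <- preprocess_cohort(bm, ann, sheet, qc, correction_scale)
  cv <- cross_validate(pre$beta, sheet, fs_cfg = fs_cfg, net_cfg = net_cfg,
                       catalog = catalog, k = k, seed = seed)
  list(cv = cv, preprocess = pre[c("probe_report", "sample_report")])
}

#' Default pipeline configuration
#'
#' The nested configuration consumed by [run_pipeline()] and the
#' `cupclf` command-line script; a YAML config file overrides any subset
#' of these keys.
#'
#' @return A nested named list (blocks: `seed`, `paths`, `qc`,
#'   `correction_scale`, `features`, `model`, `evaluation`, `simulate`).
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    correction_scale = "m",
    paths = list(
      out_dir = ".",
      beta = "beta.tsv",
      samples = "samples.csv",
      manifest = "manifest.csv",
      catalog = "catalog.csv",
      model_dir = "model"
    ),
    qc = list(max_probe_missing_frac = 0.10, max_sample_missing_frac = 0.10,
              drop_sex_chromosomes = TRUE, drop_snp_probes = TRUE,
              mvalue_epsilon = 1e-6),
    features = list(organs = blockt_classes(), top_k = 20000L,
                    variance_scope = "training_only"),
    model = list(layer_dims = c(20000L, 1024L, 512L, 6L), dropout_rate = 0.5,
                 batch_size = 16L, epochs = 50L, learning_rate = 1e-3,
                 class_weighting = "none"),
    evaluation = list(k = 10L, fractions = c(0.70, 0.15, 0.15),
                      inner_val_frac = 0.15),
    simulate = list(n_probes = 2000L, mqtl_per_class = 100L,
                    effect_delta = 1.5, n_batches = 2L, batch_shift_sd = 0.5,
                    missing_rate = 0.01, frac_sex_probes = 0.05,
                    frac_snp_probes = 0.02)
  )
}

#' @noRd
merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      stop("unknown configuration key: ", full, call. = FALSE)
    }
    if (is.list(base[[key]]) && is.list(override[[key]]) &&
        !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' Loads a YAML file, validates its keys against
#' [default_pipeline_config()], and applies dotted-path overrides (e.g.
#' `"evaluation.k=5"`). Values in overrides are parsed as YAML, so
#' numbers and booleans keep their types.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @param overrides Character vector of `key.sub=value` strings.
#' @return The merged configuration list.
#' @export
read_pipeline_config <- function(path = NULL, overrides = character()) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (length(user)) cfg <- merge_config(cfg, user)
  }
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("override must be key=value: ", ov,
                              call. = FALSE)
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    wrap <- yaml::yaml.load(kv[2])
    for (i in rev(seq_along(keys))) wrap <- stats::setNames(list(wrap),
                                                            keys[i])
    cfg <- merge_config(cfg, wrap)
  }
  cfg
}

#' @noRd
write_provenance <- function(cfg, command, config_path, input_paths,
                             out_dir) {
  existing <- input_paths[file.exists(input_paths)]
  prov <- list(
    command = command,
    seed = cfg$seed,
    config_hash = if (!is.null(config_path) && file.exists(config_path)) {
      unname(tools::md5sum(config_path))
    } else {
      NA_character_
    },
    config = cfg,
    input_checksums = as.list(tools::md5sum(existing)),
    package_version = as.character(utils::packageVersion("cupclf")),
    r_version = R.version.string
  )
  jsonlite::write_json(prov, file.path(out_dir,
                                       sprintf("provenance_%s.json", command)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @noRd
cv_report_to_list <- function(cv) {
  list(
    k = cv$k, seed = cv$seed,
    mean_accuracy = cv$mean_accuracy,
    mean_top2_accuracy = cv$mean_top2_accuracy,
    mean_macro_f1 = cv$mean_macro_f1,
    pooled_accuracy = cv$pooled_accuracy,
    best_fold = cv$best_fold,
    per_fold = cv$per_fold,
    confusion = as.data.frame.matrix(cv$confusion),
    class_order = cv$class_order,
    warnings = cv$warnings
  )
}

#' Run one pipeline command
#'
#' The programmatic backend of the `cupclf` command-line script. Each
#' command reads/writes the documented file formats under
#' `cfg$paths$out_dir` and records a provenance JSON (config hash, seed,
#' versions, input checksums).
#'
#' Commands: `simulate` writes a synthetic cohort (beta matrix, sample
#' sheet, manifest, catalog, truth.json); `preprocess` writes the
#' QC-filtered, batch-corrected matrix and filter reports; `train`
#' trains on a stratified train/validation split, evaluates on the held
#' -out test split, and saves the model; `crossvalidate` runs the full
#' k-fold evaluation and writes `cv_report.json`, `confusion.csv`,
#' `folds.csv`; `predict` loads a saved model and writes a prediction
#' report; `report` writes the cohort composition.
#'
#' @param command One of `simulate`, `preprocess`, `train`,
#'   `crossvalidate`, `predict`, `report`.
#' @param config_path Optional YAML configuration path.
#' @param overrides Character vector of dotted-path `key=value` strings.
#' @return Invisibly, the command's main result object.
#' @export
run_pipeline <- function(command = c("simulate", "preprocess", "train",
                                     "crossvalidate", "predict", "report"),
                         config_path = NULL, overrides = character()) {
  command <- match.arg(command)
  cfg <- read_pipeline_config(config_path, overrides)
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  in_dir <- function(p) {
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(out_dir, p)
  }
  paths <- lapply(cfg$paths[c("beta", "samples", "manifest", "catalog")],
                  in_dir)
  qc <- do.call(qc_params, cfg$qc)
  fs_cfg <- do.call(feature_selection_config, cfg$features)
  net_cfg <- do.call(network_config, c(cfg$model, list(seed = cfg$seed)))

  result <- switch(command,
    simulate = {
      sim_args <- c(cfg$simulate, list(seed = cfg$seed))
      sim <- simulate_cohort(do.call(sim_config, sim_args))
      write_beta_matrix(sim$beta, paths$beta)
      write_cohort_metadata(sim$sheet, paths$samples)
      write_probe_annotations(sim$annotations, paths$manifest)
      write_mqtl_catalog(sim$catalog, paths$catalog)
      jsonlite::write_json(
        list(blocks = sim$truth$blocks,
             batch_shift = sim$truth$batch_shift,
             n_missing = sim$truth$n_missing),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
      sim
    },
    preprocess = {
      bm <- load_beta_matrix(paths$beta)
      sheet <- load_cohort_metadata(paths$samples)
      ann <- load_probe_annotations(paths$manifest, paths$catalog)$annotations
      pre <- preprocess_cohort(bm, ann, sheet, qc, cfg$correction_scale)
      write_beta_matrix(pre$beta, file.path(out_dir, "beta_preprocessed.tsv"))
      jsonlite::write_json(
        list(probes = unclass(pre$probe_report),
             samples = unclass(pre$sample_report)),
        file.path(out_dir, "filter_report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      pre
    },
    train = {
      bm <- load_beta_matrix(paths$beta)
      sheet <- load_cohort_metadata(paths$samples)
      loaded <- load_probe_annotations(paths$manifest, paths$catalog)
      pre <- preprocess_cohort(bm, loaded$annotations, sheet, qc,
                               cfg$correction_scale)
      bm2 <- restrict_to_mqtl(pre$beta, loaded$catalog,
                              intersect(fs_cfg$organs,
                                        names(loaded$catalog)))
      sheet2 <- sheet[sheet$sample_id %in% colnames(bm2), , drop = FALSE]
      split <- split_cohort(sheet2, split_spec(cfg$evaluation$fractions,
                                               seed = cfg$seed))
      sel <- select_top_variable(
        bm2[, if (fs_cfg$variance_scope == "training_only") split$train
            else colnames(bm2), drop = FALSE],
        fs_cfg$top_k)
      X <- t(bm2[sel, , drop = FALSE])
      mu <- colMeans(X[split$train, , drop = FALSE], na.rm = TRUE)
      mu[is.nan(mu)] <- 0.5
      dims <- net_cfg$layer_dims
      dims[1] <- length(sel)
      cfg_t <- network_config(layer_dims = dims,
                              dropout_rate = net_cfg$dropout_rate,
                              batch_size = net_cfg$batch_size,
                              epochs = net_cfg$epochs,
                              learning_rate = net_cfg$learning_rate,
                              seed = cfg$seed,
                              class_weighting = net_cfg$class_weighting)
      lab <- function(ids) sheet2$label[match(ids, sheet2$sample_id)]
      fit <- train_network(
        build_network(cfg_t),
        impute_with_means(X[split$train, , drop = FALSE], mu),
        lab(split$train), cfg_t, class_order = blockt_classes(),
        X_val = impute_with_means(X[split$validation, , drop = FALSE], mu),
        y_val = lab(split$validation))
      save_model(fit$model, in_dir(cfg$paths$model_dir))
      utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                       row.names = FALSE)
      test_report <- predict_probabilities(fit$model,
                                           bm2[sel, split$test, drop = FALSE])
      test_metrics <- compute_metrics(test_report, lab(split$test))
      jsonlite::write_json(
        list(accuracy = test_metrics$accuracy,
             top2_accuracy = test_metrics$top2_accuracy,
             macro_f1 = test_metrics$macro_f1,
             n_test = test_metrics$n,
             split_sizes = lapply(split, length)),
        file.path(out_dir, "test_metrics.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      list(model = fit$model, history = fit$history,
           test_metrics = test_metrics)
    },
    crossvalidate = {
      bm <- load_beta_matrix(paths$beta)
      sheet <- load_cohort_metadata(paths$samples)
      loaded <- load_probe_annotations(paths$manifest, paths$catalog)
      res <- run_cohort_pipeline(bm, sheet, loaded$annotations,
                                 loaded$catalog, qc, fs_cfg, net_cfg,
                                 k = cfg$evaluation$k, seed = cfg$seed,
                                 correction_scale = cfg$correction_scale)
      jsonlite::write_json(cv_report_to_list(res$cv),
                           file.path(out_dir, "cv_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "columns")
      utils::write.csv(as.data.frame.matrix(res$cv$confusion),
                       file.path(out_dir, "confusion.csv"))
      utils::write.csv(res$cv$fold_assignments,
                       file.path(out_dir, "folds.csv"), row.names = FALSE)
      res$cv
    },
    predict = {
      bm <- load_beta_matrix(paths$beta)
      model <- load_model(in_dir(cfg$paths$model_dir))
      report <- predict_probabilities(model, bm)
      write_prediction_report(report, file.path(out_dir, "predictions.csv"))
      report
    },
    report = {
      sheet <- load_cohort_metadata(paths$samples)
      rep <- cohort_report(sheet)
      jsonlite::write_json(
        list(by_class = rep$by_class, total = rep$total,
             n_metastasis = rep$n_metastasis,
             pct_metastasis = rep$pct_metastasis),
        file.path(out_dir, "cohort_report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE,
        dataframe = "columns")
      rep
    })

  write_provenance(cfg, command, config_path,
                   unlist(paths, use.names = FALSE), out_dir)
  invisible(result)
}
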