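#' @noRd
sep_for_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a beta-value matrix from TSV/CSV
#'
#' The canonical on-disk layout is probes x samples: row 1 holds sample
#' ids, column 1 holds probe ids. Files stored samples x probes can be
#' read with `orientation = "samples_by_probes"`; orientation is never
#' guessed from the data, because probe and sample counts can both be
#' large and a silent transposition is a classic failure mode. Empty
#' cells and the token `NA` are read as missing.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file.
#' @param orientation `"probes_by_samples"` (default) or
#'   `"samples_by_probes"`.
#' @return A validated beta matrix (see [beta_matrix()]), probes x samples.
#' @export
load_beta_matrix <- function(path,
                             orientation = c("probes_by_samples",
                                             "samples_by_probes")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = sep_for_path(path), header = TRUE,
                          row.names = 1, check.names = FALSE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  values <- as.matrix(df)
  storage.mode(values) <- "double"
  if (orientation == "samples_by_probes") values <- t(values)
  beta_matrix(values)
}

#' Write a beta-value matrix to TSV/CSV
#'
#' Missing entries are written as the token `NA`.
#'
#' @param bm Beta matrix (probes x samples, with dimnames).
#' @param path Output path; `.csv` writes comma-separated, anything else tab.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(bm, path) {
  df <- data.frame(probe_id = rownames(bm), bm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep_for_path(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a cohort sample sheet
#'
#' Expects a CSV with header columns `sample_id`, `batch`,
#' `is_metastasis`, and optionally `label`. A sheet without a `label`
#' column parses as inference-only (all labels `NA`).
#'
#' @param path Path to the CSV file.
#' @return A validated sample sheet (see [sample_sheet()]); attribute
#'   `inference_only` is `TRUE` when the label column was absent.
#' @export
load_cohort_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  required <- c("sample_id", "batch", "is_metastasis")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  inference_only <- !("label" %in% names(df))
  sheet <- sample_sheet(df$sample_id,
                        label = if (inference_only) NULL else df$label,
                        batch = df$batch,
                        is_metastasis = df$is_metastasis)
  attr(sheet, "inference_only") <- inference_only
  sheet
}

#' Write a cohort sample sheet to CSV
#'
#' @param sheet Sample sheet data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_metadata <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read probe annotations and an mQTL catalog
#'
#' The manifest CSV has columns `probe_id,chromosome,position,snp_overlap`;
#' the catalog CSV is long-format with columns `organ,probe_id`. Catalog
#' rows naming organs outside the six-class vocabulary are dropped with a
#' message (public catalogs describe more organs than this classifier
#' uses). Catalog probes absent from the manifest raise a warning with a
#' count, not an error, because catalogs may exceed array content.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param catalog_path Path to the long-format catalog CSV.
#' @return A list with elements `annotations` (see [probe_annotations()])
#'   and `catalog` (see [mqtl_catalog()]).
#' @export
load_probe_annotations <- function(manifest_path, catalog_path) {
  for (p in c(manifest_path, catalog_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  miss <- setdiff(c("probe_id", "chromosome", "position", "snp_overlap"),
                  names(man))
  if (length(miss)) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ann <- probe_annotations(man$probe_id, man$chromosome, man$position,
                           man$snp_overlap)

  cat_df <- utils::read.csv(catalog_path, stringsAsFactors = FALSE)
  miss <- setdiff(c("organ", "probe_id"), names(cat_df))
  if (length(miss)) {
    stop("catalog is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rejected <- setdiff(unique(cat_df$organ), blockt_classes())
  if (length(rejected)) {
    message("dropping catalog organ(s) outside the six-class vocabulary: ",
            paste(rejected, collapse = ", "))
    cat_df <- cat_df[cat_df$organ %in% blockt_classes(), , drop = FALSE]
  }
  if (!nrow(cat_df)) stop("catalog contains no usable organs", call. = FALSE)
  catalog <- mqtl_catalog(split(cat_df$probe_id, cat_df$organ))
  unknown <- setdiff(attr(catalog, "union_probes"), ann$probe_id)
  if (length(unknown)) {
    warning(length(unknown),
            " catalog probe(s) absent from the manifest (catalog may exceed",
            " array content)", call. = FALSE)
  }
  list(annotations = ann, catalog = catalog)
}

#' Write probe annotations / an mQTL catalog to CSV
#'
#' @param ann Probe annotation data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_probe_annotations <- function(ann, path) {
  utils::write.csv(ann, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_probe_annotations
#' @param catalog An [mqtl_catalog()].
#' @export
write_mqtl_catalog <- function(catalog, path) {
  df <- data.frame(
    organ = rep(names(catalog), lengths(catalog)),
    probe_id = unlist(catalog, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist a trained classifier to a directory
#'
#' Writes a portable, framework-free representation: `model.json` holds
#' the configuration (layer dimensions, dropout, class order, selected
#' probes, frozen preprocessing state) and each weight array is stored as
#' a raw little-endian float64 binary file named in the manifest. Doubles
#' are stored at full precision so that a load/save round trip reproduces
#' bit-identical predictions.
#'
#' @param model A trained classifier from [train_network()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "trained_classifier"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format_version = 1L,
    layer_dims = model$layer_dims,
    dropout_rate = model$dropout_rate,
    class_order = model$class_order,
    selected_probes = model$selected_probes,
    preprocessing_state = list(
      impute_means = as.list(model$preprocessing_state$impute_means),
      input_scale = model$preprocessing_state$input_scale
    ),
    weights = lapply(seq_along(model$weights), function(i) {
      list(name = sprintf("layer%02d", i),
           w_file = sprintf("layer%02d_W.bin", i),
           b_file = sprintf("layer%02d_b.bin", i),
           w_dim = dim(model$weights[[i]]$W),
           b_len = length(model$weights[[i]]$b))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(model$weights)) {
    wcon <- file(file.path(dir, sprintf("layer%02d_W.bin", i)), "wb")
    writeBin(as.numeric(model$weights[[i]]$W), wcon, size = 8,
             endian = "little")
    close(wcon)
    bcon <- file(file.path(dir, sprintf("layer%02d_b.bin", i)), "wb")
    writeBin(as.numeric(model$weights[[i]]$b), bcon, size = 8,
             endian = "little")
    close(bcon)
  }
  writeLines(model$selected_probes, file.path(dir, "selected_probes.txt"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  manifest_path <- file.path(dir, "model.json")
  if (!file.exists(manifest_path)) {
    stop("missing model manifest: ", manifest_path, call. = FALSE)
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  layer_dims <- as.integer(man$layer_dims)
  class_order <- as.character(man$class_order)
  if (layer_dims[length(layer_dims)] != length(class_order)) {
    stop("corrupt model manifest: output dimension (",
         layer_dims[length(layer_dims)], ") does not match class_order length (",
         length(class_order), ")", call. = FALSE)
  }
  selected <- as.character(man$selected_probes)
  if (length(selected) != layer_dims[1]) {
    stop("corrupt model manifest: selected_probes length does not match",
         " input dimension", call. = FALSE)
  }
  weights <- vector("list", nrow(man$weights))
  for (i in seq_len(nrow(man$weights))) {
    w_path <- file.path(dir, man$weights$w_file[i])
    b_path <- file.path(dir, man$weights$b_file[i])
    for (p in c(w_path, b_path)) {
      if (!file.exists(p)) stop("missing weight file: ", p, call. = FALSE)
    }
    w_dim <- as.integer(man$weights$w_dim[[i]])
    wcon <- file(w_path, "rb")
    w <- readBin(wcon, "double", n = prod(w_dim), size = 8, endian = "little")
    close(wcon)
    if (length(w) != prod(w_dim)) {
      stop("corrupt weight file (unexpected length): ", w_path, call. = FALSE)
    }
    bcon <- file(b_path, "rb")
    b <- readBin(bcon, "double", n = man$weights$b_len[i], size = 8,
                 endian = "little")
    close(bcon)
    if (length(b) != man$weights$b_len[i]) {
      stop("corrupt weight file (unexpected length): ", b_path, call. = FALSE)
    }
    weights[[i]] <- list(W = matrix(w, nrow = w_dim[1], ncol = w_dim[2]), b = b)
  }
  impute_means <- unlist(man$preprocessing_state$impute_means)
  new_trained_classifier(
    layer_dims = layer_dims,
    dropout_rate = man$dropout_rate,
    weights = weights,
    class_order = class_order,
    selected_probes = selected,
    preprocessing_state = list(
      impute_means = impute_means,
      input_scale = man$preprocessing_state$input_scale
    )
  )
}

#' Write a prediction report to CSV
#'
#' Columns: `sample_id`, one probability column per class
#' (`p_breast`, ..., `p_testis`), `predicted_label`, `second_label`,
#' `confidence` (the maximum probability).
#'
#' @param report Prediction report from [predict_probabilities()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prediction_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
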