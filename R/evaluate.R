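#' Cohort split specification
#'
#' Fractions for non-overlapping training/validation/test sets. Sizes
#' follow a fixed rounding convention: train = floor(f_train * n),
#' test = ceil(f_test * n), validation = the remainder. With n = 509 and
#' fractions (0.70, 0.15, 0.15) this yields 356 / 76 / 77.
#'
#' @param fractions Numeric length-3 vector (train, validation, test)
#'   summing to 1 within 1e-9.
#' @param seed Integer seed for the shuffle.
#' @param stratify_by_label Keep per-class proportions within +/- 1
#'   sample per class per set (default `TRUE`).
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(fractions = c(0.70, 0.15, 0.15), seed = 1L,
                       stratify_by_label = TRUE) {
  stopifnot(length(fractions) == 3, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  structure(list(fractions = fractions, seed = as.integer(seed),
                 stratify_by_label = isTRUE(stratify_by_label)),
            class = "split_spec")
}

#' @noRd
split_sizes <- function(n, fractions) {
  n_train <- floor(fractions[1] * n)
  n_test <- ceiling(fractions[3] * n)
  c(train = n_train, validation = n - n_train - n_test, test = n_test)
}

#' Split a cohort into train/validation/test sets
#'
#' Global set sizes follow the [split_spec()] rounding convention
#' exactly. Under stratification, each class is first allocated
#' floor(f_set * n_class) samples per set and the per-class leftovers are
#' assigned greedily to the sets furthest below their global quota, so
#' per-class counts stay within one sample of proportional while global
#' sizes are exact.
#'
#' @param sheet Sample sheet with labels (required when stratifying).
#' @param spec A [split_spec()].
#' @return A list of class `cohort_split` with character-vector elements
#'   `train`, `validation`, `test` (sample ids).
#' @export
split_cohort <- function(sheet, spec = split_spec()) {
  n <- nrow(sheet)
  if (n < 3) stop("cohort must have at least 3 samples", call. = FALSE)
  sizes <- split_sizes(n, spec$fractions)
  set_names <- c("train", "validation", "test")
  assigned <- stats::setNames(vector("list", 3), set_names)

  withr::with_seed(spec$seed, {
    if (spec$stratify_by_label) {
      if (anyNA(sheet$label)) {
        stop("stratified split requires labels for all samples", call. = FALSE)
      }
      classes <- intersect(blockt_classes(), unique(sheet$label))
      if (!length(classes)) classes <- sort(unique(sheet$label))
      class_n <- vapply(classes, function(cl) sum(sheet$label == cl), 0L)
      # pass 1: floor quotas per class per set
      quota <- vapply(class_n, function(nc) floor(spec$fractions * nc),
                      numeric(3))  # 3 x n_classes
      remaining <- sizes - rowSums(quota)
      # rounding can leave a set oversubscribed by its floors; release one
      # quota unit from the largest class of that set
      for (s in 1:3) {
        while (remaining[s] < 0) {
          donor <- which.max(quota[s, ])
          quota[s, donor] <- quota[s, donor] - 1L
          remaining[s] <- remaining[s] + 1L
        }
      }
      # pass 2: distribute per-class leftovers to the sets with the
      # largest residual demand, distinct sets within a class when possible
      leftover <- class_n - colSums(quota)
      for (ci in order(-leftover, classes)) {
        used <- logical(3)
        for (extra in seq_len(leftover[ci])) {
          cand <- order(-(remaining * ifelse(used, 0, 1)))[1]
          if (remaining[cand] == 0 || used[cand]) {
            cand <- which.max(remaining)
          }
          quota[cand, ci] <- quota[cand, ci] + 1L
          remaining[cand] <- remaining[cand] - 1L
          used[cand] <- TRUE
        }
      }
      for (ci in seq_along(classes)) {
        ids <- sample(sheet$sample_id[sheet$label == classes[ci]])
        offset <- 0L
        for (s in 1:3) {
          if (quota[s, ci] > 0) {
            assigned[[s]] <- c(assigned[[s]],
                               ids[offset + seq_len(quota[s, ci])])
          }
          offset <- offset + quota[s, ci]
        }
      }
    } else {
      ids <- sample(sheet$sample_id)
      assigned$train <- ids[seq_len(sizes[1])]
      assigned$validation <- ids[sizes[1] + seq_len(sizes[2])]
      assigned$test <- ids[sizes[1] + sizes[2] + seq_len(sizes[3])]
    }
  })
  stopifnot(lengths(assigned) == sizes,
            !anyDuplicated(unlist(assigned)))
  structure(assigned, class = "cohort_split")
}

#' Stratified k-fold assignment
#'
#' Partitions samples into k folds with per-fold class counts within one
#' of balanced allocation. Within each class the (seeded) shuffled
#' members are dealt round-robin across folds, with the starting fold
#' rotated between classes to keep overall fold sizes even. A class with
#' fewer than k samples triggers a warning and its samples land in
#' distinct folds.
#'
#' @param labels Character/factor class labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
make_stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  if (k > n) stop("`k` exceeds the number of samples", call. = FALSE)
  classes <- intersect(blockt_classes(), unique(labels))
  if (!length(classes)) classes <- sort(unique(labels))
  folds <- integer(n)
  withr::with_seed(seed, {
    offset <- 0L
    for (cl in classes) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        warning("class '", cl, "' has fewer samples (", length(idx),
                ") than folds (", k, "); spreading across distinct folds",
                call. = FALSE)
      }
      idx <- if (length(idx) > 1) sample(idx) else idx
      folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  folds
}

#' Multiclass metrics from predicted probabilities
#'
#' @param probs A `prediction_report` or a numeric probability matrix
#'   (samples x classes, columns in class order).
#' @param truth True labels, same sample order.
#' @param class_order Class labels in column order (taken from the
#'   report when omitted).
#' @return A list: `accuracy` (trace of confusion / n), `top2_accuracy`
#'   (true class among the two largest probabilities; rank-2 ties broken
#'   by class-order position), `macro_f1` (unweighted mean of per-class
#'   F1, with F1 = 0 when precision + recall = 0), `confusion` (rows =
#'   true classes, columns = predicted), `per_class_f1`, `n`.
#' @export
compute_metrics <- function(probs, truth, class_order = NULL) {
  if (inherits(probs, "prediction_report")) {
    if (is.null(class_order)) class_order <- attr(probs, "class_order")
    probs <- report_probabilities(probs)
  }
  stopifnot(is.matrix(probs))
  if (is.null(class_order)) class_order <- colnames(probs)
  truth <- as.character(truth)
  if (length(truth) != nrow(probs)) {
    stop("length(truth) must equal the number of prediction rows",
         call. = FALSE)
  }
  bad <- setdiff(unique(truth), class_order)
  if (length(bad)) {
    stop("truth labels outside class_order: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  k <- length(class_order)
  n <- nrow(probs)
  pred_idx <- max.col(probs, ties.method = "first")
  truth_idx <- match(truth, class_order)
  confusion <- matrix(0L, k, k, dimnames = list(true = class_order,
                                                predicted = class_order))
  for (i in seq_len(n)) {
    confusion[truth_idx[i], pred_idx[i]] <- confusion[truth_idx[i],
                                                      pred_idx[i]] + 1L
  }
  accuracy <- sum(diag(confusion)) / n
  top2_hit <- vapply(seq_len(n), function(i) {
    truth_idx[i] %in% order(-probs[i, ], seq_len(k))[1:2]
  }, logical(1))
  tp <- diag(confusion)
  precision <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  recall <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(accuracy = accuracy,
       top2_accuracy = mean(top2_hit),
       macro_f1 = mean(f1),
       per_class_f1 = stats::setNames(f1, class_order),
       confusion = confusion,
       n = n)
}

#' @noRd
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 1000003) * 1013 + stream) %% 2147483647L
}

#' Stratified k-fold cross-validation of the full classifier
#'
#' For each fold: feature selection (per the configured variance scope;
#' with `variance_scope = "training_only"` the top-k list is recomputed
#' from the in-fold training samples, so held-out values never influence
#' selection), an inner stratified train/validation split for the
#' per-epoch history, network training, and metrics on the held-out
#' fold. The "best fold" is the one with the lowest final validation
#' loss.
#'
#' @param bm Preprocessed beta matrix (probes x samples).
#' @param sheet Sample sheet with labels for every column of `bm`.
#' @param fs_cfg [feature_selection_config()].
#' @param net_cfg [network_config()]; the input-layer width is adapted to
#'   the number of selected probes.
#' @param catalog Optional [mqtl_catalog()]; when supplied the matrix is
#'   restricted to mQTL probes before selection.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment, inner splits,
#'   and per-fold training.
#' @param inner_val_frac Fraction of in-fold training samples held out as
#'   the per-epoch validation set (default 0.15).
#' @return A list of class `cv_report`: `per_fold` (data frame with
#'   accuracy, top-2 accuracy, macro F1, final losses), `mean_accuracy`,
#'   `mean_top2_accuracy`, `mean_macro_f1` (arithmetic fold averages),
#'   `pooled_accuracy` (all held-out predictions pooled), `confusion`
#'   (summed over folds), `best_fold`, `fold_assignments`, `histories`,
#'   `warnings`.
#' @export
cross_validate <- function(bm, sheet, fs_cfg = feature_selection_config(),
                           net_cfg = network_config(), catalog = NULL,
                           k = 10L, seed = 1L, inner_val_frac = 0.15) {
  stopifnot(is.matrix(bm))
  idx <- match(colnames(bm), sheet$sample_id)
  if (anyNA(idx)) {
    stop("sample sheet does not cover all matrix columns", call. = FALSE)
  }
  sheet <- sheet[idx, , drop = FALSE]
  if (anyNA(sheet$label)) {
    stop("cross-validation requires labels for all samples", call. = FALSE)
  }
  if (!is.null(catalog)) {
    organs <- intersect(fs_cfg$organs, names(catalog))
    if (!length(organs)) {
      stop("catalog covers none of the configured organs", call. = FALSE)
    }
    bm <- restrict_to_mqtl(bm, catalog, organs)
  }
  class_order <- blockt_classes()
  labels <- sheet$label
  folds <- withCallingHandlers(
    make_stratified_folds(labels, k, seed = derive_seed(seed, 0L)),
    warning = function(w) invokeRestart("muffleWarning"))
  warn_log <- character(0)
  small <- names(which(table(labels) < k))
  if (length(small)) {
    warn_log <- c(warn_log, paste0("class(es) with fewer samples than folds: ",
                                   paste(small, collapse = ", ")))
  }
  sel_full <- NULL
  if (fs_cfg$variance_scope == "full_cohort") {
    sel_full <- select_top_variable(bm, fs_cfg$top_k)
  }

  per_fold <- data.frame(fold = seq_len(k), n_test = NA_integer_,
                         accuracy = NA_real_, top2_accuracy = NA_real_,
                         macro_f1 = NA_real_, final_train_loss = NA_real_,
                         final_val_loss = NA_real_)
  histories <- vector("list", k)
  confusion <- matrix(0L, length(class_order), length(class_order),
                      dimnames = list(true = class_order,
                                      predicted = class_order))
  pooled_hits <- 0L

  for (f in seq_len(k)) {
    train_mask <- folds != f
    test_ids <- sheet$sample_id[!train_mask]
    train_sheet <- sheet[train_mask, , drop = FALSE]
    miss_cls <- setdiff(unique(labels), unique(train_sheet$label))
    if (length(miss_cls)) {
      warn_log <- c(warn_log,
                    paste0("fold ", f, " training data lacks class(es): ",
                           paste(miss_cls, collapse = ", ")))
    }
    sel <- if (is.null(sel_full)) {
      select_top_variable(bm[, train_mask, drop = FALSE], fs_cfg$top_k)
    } else {
      sel_full
    }
    fold_seed <- derive_seed(seed, f)
    inner <- split_cohort(train_sheet,
                          split_spec(c(1 - inner_val_frac, inner_val_frac, 0),
                                     seed = fold_seed))
    Xsub <- t(bm[sel, , drop = FALSE])
    tr_rows <- inner$train
    va_rows <- inner$validation
    X_tr <- Xsub[tr_rows, , drop = FALSE]
    # frozen training means impute both the training and downstream data
    mu <- colMeans(X_tr, na.rm = TRUE)
    mu[is.nan(mu)] <- 0.5
    X_tr <- impute_with_means(X_tr, mu)
    X_va <- impute_with_means(Xsub[va_rows, , drop = FALSE], mu)
    y_tr <- sheet$label[match(tr_rows, sheet$sample_id)]
    y_va <- sheet$label[match(va_rows, sheet$sample_id)]

    dims <- net_cfg$layer_dims
    dims[1] <- length(sel)
    dims[length(dims)] <- length(class_order)
    cfg_f <- network_config(layer_dims = dims,
                            dropout_rate = net_cfg$dropout_rate,
                            batch_size = net_cfg$batch_size,
                            epochs = net_cfg$epochs,
                            learning_rate = net_cfg$learning_rate,
                            seed = fold_seed,
                            class_weighting = net_cfg$class_weighting)
    fit <- train_network(build_network(cfg_f), X_tr, y_tr, cfg_f,
                         class_order = class_order,
                         X_val = X_va, y_val = y_va)
    histories[[f]] <- fit$history

    report <- predict_probabilities(fit$model,
                                    bm[sel, test_ids, drop = FALSE])
    y_te <- sheet$label[match(test_ids, sheet$sample_id)]
    m <- compute_metrics(report, y_te, class_order)
    per_fold$n_test[f] <- m$n
    per_fold$accuracy[f] <- m$accuracy
    per_fold$top2_accuracy[f] <- m$top2_accuracy
    per_fold$macro_f1[f] <- m$macro_f1
    per_fold$final_train_loss[f] <-
      fit$history$train_loss[nrow(fit$history)]
    per_fold$final_val_loss[f] <- fit$history$val_loss[nrow(fit$history)]
    confusion <- confusion + m$confusion
    pooled_hits <- pooled_hits + round(m$accuracy * m$n)
  }

  structure(list(
    per_fold = per_fold,
    mean_accuracy = mean(per_fold$accuracy),
    mean_top2_accuracy = mean(per_fold$top2_accuracy),
    mean_macro_f1 = mean(per_fold$macro_f1),
    pooled_accuracy = pooled_hits / nrow(sheet),
    confusion = confusion,
    best_fold = per_fold$fold[which.min(per_fold$final_val_loss)],
    fold_assignments = data.frame(sample_id = sheet$sample_id, fold = folds,
                                  stringsAsFactors = FALSE),
    histories = histories,
    class_order = class_order,
    k = k, seed = seed,
    warnings = warn_log
  ), class = "cv_report")
}

#' @noRd
impute_with_means <- function(X, mu) {
  if (anyNA(X)) {
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2L]]
  }
  X
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  cat(sprintf("  mean accuracy:       %.4f\n", x$mean_accuracy))
  cat(sprintf("  mean top-2 accuracy: %.4f\n", x$mean_top2_accuracy))
  cat(sprintf("  mean macro F1:       %.4f\n", x$mean_macro_f1))
  cat(sprintf("  best fold (lowest final validation loss): %d\n",
              x$best_fold))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Cohort composition report
#'
#' Per-class counts with integer percentages (rounded half-up), the
#' total, and the metastasis count/percentage.
#'
#' @param sheet Sample sheet with labels.
#' @return A list: `by_class` (data frame label, n, pct), `total`,
#'   `n_metastasis`, `pct_metastasis`.
#' @export
cohort_report <- function(sheet) {
  if (!nrow(sheet)) stop("empty sample sheet", call. = FALSE)
  if (anyNA(sheet$label)) {
    stop("cohort report requires labels for all samples", call. = FALSE)
  }
  total <- nrow(sheet)
  classes <- intersect(blockt_classes(), unique(sheet$label))
  n_by <- vapply(classes, function(cl) sum(sheet$label == cl), 0L)
  ord <- order(-n_by, classes)
  by_class <- data.frame(label = classes[ord], n = n_by[ord],
                         pct = round_half_up(100 * n_by[ord] / total),
                         stringsAsFactors = FALSE, row.names = NULL)
  n_met <- sum(sheet$is_metastasis, na.rm = TRUE)
  list(by_class = by_class, total = total, n_metastasis = n_met,
       pct_metastasis = round_half_up(100 * n_met / total))
}

#' @noRd
round_half_up <- function(x) floor(x + 0.5)
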