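#' Network configuration
#'
#' Hyperparameters of the fully connected classifier. The default
#' architecture is 20000 input nodes narrowing to 1024, 512, and finally
#' 6 output nodes, with ReLU activations and 0.5 dropout after each
#' hidden layer, trained with mini-batches of 16 for 50 epochs. The
#' optimizer is Adam with learning rate 1e-3 (declared default; exposed
#' here) minimizing multiclass cross-entropy.
#'
#' @param layer_dims Integer vector of layer widths, input first, output
#'   (number of classes) last.
#' @param dropout_rate Dropout probability after each hidden ReLU, in
#'   \[0, 1).
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of full passes over the training data.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling weight initialization, shuffling,
#'   and dropout draws; identical seeds give bit-identical runs on the
#'   same platform.
#' @param class_weighting `"none"` (default) or `"inverse_frequency"`
#'   (weights each sample by n / (K * n_class)).
#' @return A list of class `network_config`.
#' @export
network_config <- function(layer_dims = c(20000L, 1024L, 512L, 6L),
                           dropout_rate = 0.5,
                           batch_size = 16L,
                           epochs = 50L,
                           learning_rate = 1e-3,
                           seed = 1L,
                           class_weighting = c("none", "inverse_frequency")) {
  class_weighting <- match.arg(class_weighting)
  layer_dims <- as.integer(layer_dims)
  if (length(layer_dims) < 2) {
    stop("`layer_dims` needs at least an input and an output layer",
         call. = FALSE)
  }
  stopifnot(all(layer_dims >= 1), dropout_rate >= 0, dropout_rate < 1,
            batch_size >= 1, epochs >= 1, learning_rate >= 0)
  structure(list(layer_dims = layer_dims, dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 class_weighting = class_weighting),
            class = "network_config")
}

#' Build a classifier specification
#'
#' Validates the configuration and reports the layer structure: fully
#' connected layers per `layer_dims`, ReLU + dropout between consecutive
#' fully connected layers (never after the output layer), and a softmax
#' over the output. The trainable parameter count is
#' sum over layers of (d_in + 1) * d_out.
#'
#' @param cfg [network_config()].
#' @return A list of class `classifier_spec` with elements `layer_dims`,
#'   `dropout_rate`, `n_parameters`.
#' @export
#' @examples
#' build_network(network_config(layer_dims = c(4, 3, 2)))$n_parameters # 23
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  dims <- cfg$layer_dims
  n_par <- sum((as.numeric(dims[-length(dims)]) + 1) * dims[-1])
  if (n_par <= .Machine$integer.max) n_par <- as.integer(n_par)
  structure(list(layer_dims = dims, dropout_rate = cfg$dropout_rate,
                 n_parameters = n_par),
            class = "classifier_spec")
}

#' @noRd
new_trained_classifier <- function(layer_dims, dropout_rate, weights,
                                   class_order, selected_probes,
                                   preprocessing_state, seed = NA_integer_) {
  stopifnot(length(selected_probes) == layer_dims[1],
            layer_dims[length(layer_dims)] == length(class_order))
  structure(list(layer_dims = as.integer(layer_dims),
                 dropout_rate = dropout_rate, weights = weights,
                 class_order = as.character(class_order),
                 selected_probes = as.character(selected_probes),
                 preprocessing_state = preprocessing_state,
                 seed = seed),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat("Trained classifier:", paste(x$layer_dims, collapse = " -> "),
      "\n  classes:", paste(x$class_order, collapse = ", "),
      "\n  input probes:", length(x$selected_probes), "\n")
  invisible(x)
}

# He-style uniform initialization: W ~ U(-sqrt(6/fan_in), sqrt(6/fan_in)),
# biases zero. Draws come from the current RNG stream.
#' @noRd
init_weights <- function(layer_dims) {
  lapply(seq_len(length(layer_dims) - 1L), function(l) {
    d_in <- layer_dims[l]
    d_out <- layer_dims[l + 1L]
    lim <- sqrt(6 / d_in)
    list(W = matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out),
         b = numeric(d_out))
  })
}

#' @noRd
softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. `training` enables inverted dropout (masks drawn from the
# current RNG stream). Returns probabilities plus the per-layer caches
# needed by the backward pass.
#' @noRd
mlp_forward <- function(weights, X, dropout_rate, training = FALSE) {
  n_layers <- length(weights)
  a <- X
  caches <- vector("list", n_layers)
  for (l in seq_len(n_layers - 1L)) {
    z <- sweep(a %*% weights[[l]]$W, 2L, weights[[l]]$b, "+")
    act <- pmax(z, 0)
    mask <- NULL
    if (training && dropout_rate > 0) {
      keep <- 1 - dropout_rate
      mask <- matrix(
        (stats::runif(length(act)) < keep) / keep,
        nrow(act), ncol(act))
      act <- act * mask
    }
    caches[[l]] <- list(a_prev = a, z = z, mask = mask)
    a <- act
  }
  logits <- sweep(a %*% weights[[n_layers]]$W, 2L, weights[[n_layers]]$b, "+")
  caches[[n_layers]] <- list(a_prev = a)
  list(probs = softmax_rows(logits), caches = caches)
}

# Backward pass for softmax + cross-entropy. `y_onehot` is n x K;
# `sample_w` are per-sample loss weights (mean 1 under no weighting).
#' @noRd
mlp_backward <- function(weights, caches, probs, y_onehot, sample_w) {
  n_layers <- length(weights)
  n <- nrow(probs)
  grads <- vector("list", n_layers)
  delta <- (probs - y_onehot) * (sample_w / n)
  for (l in seq(n_layers, 1L)) {
    grads[[l]] <- list(W = unname(crossprod(caches[[l]]$a_prev, delta)),
                       b = unname(colSums(delta)))
    if (l > 1L) {
      d_act <- delta %*% t(weights[[l]]$W)
      if (!is.null(caches[[l - 1L]]$mask)) {
        d_act <- d_act * caches[[l - 1L]]$mask
      }
      delta <- d_act * (caches[[l - 1L]]$z > 0)
    }
  }
  grads
}

#' @noRd
cross_entropy <- function(probs, y_idx, sample_w = NULL) {
  p <- probs[cbind(seq_len(nrow(probs)), y_idx)]
  nll <- -log(pmax(p, 1e-15))
  if (is.null(sample_w)) mean(nll) else mean(sample_w * nll)
}

#' Train the fully connected classifier
#'
#' Minimizes multiclass cross-entropy with mini-batch Adam for a fixed
#' number of epochs (no early stopping). All randomness -- weight
#' initialization, per-epoch shuffling, dropout masks -- derives from
#' `cfg$seed`, so two runs with identical inputs produce identical loss
#' histories. Per-epoch losses and accuracies are evaluated with dropout
#' disabled on the full training set (and validation set, if given).
#'
#' @param spec [build_network()] output; `layer_dims[1]` must equal
#'   `ncol(X)` and the last entry the number of classes.
#' @param X Numeric matrix, samples x features, no missing values;
#'   `colnames(X)` are the frozen selected-probe ids.
#' @param y Character/factor labels drawn from `class_order`.
#' @param cfg [network_config()].
#' @param class_order Class labels in output-column order (default: the
#'   BLOCKT classes present in `y`, in canonical order, if all labels are
#'   BLOCKT; otherwise sorted unique labels).
#' @param X_val,y_val Optional validation split evaluated each epoch.
#' @return A list with `model` (a `trained_classifier`) and `history`
#'   (data frame: epoch, train_loss, val_loss, train_acc, val_acc).
#' @export
train_network <- function(spec, X, y, cfg, class_order = NULL,
                          X_val = NULL, y_val = NULL) {
  stopifnot(inherits(spec, "classifier_spec"), is.matrix(X))
  y <- as.character(y)
  if (ncol(X) != spec$layer_dims[1]) {
    stop("X has ", ncol(X), " features but the network input layer has ",
         spec$layer_dims[1], " nodes", call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (anyNA(X)) stop("X contains missing values; impute upstream", call. = FALSE)
  if (is.null(class_order)) {
    u <- unique(y)
    class_order <- if (all(u %in% blockt_classes())) {
      intersect(blockt_classes(), u)
    } else {
      sort(u)
    }
  }
  k <- length(class_order)
  if (k != spec$layer_dims[length(spec$layer_dims)]) {
    stop("number of classes (", k, ") does not match the output layer (",
         spec$layer_dims[length(spec$layer_dims)], ")", call. = FALSE)
  }
  bad <- setdiff(unique(y), class_order)
  if (length(bad)) {
    stop("labels outside class_order: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  y_idx <- match(y, class_order)
  if (cfg$class_weighting == "inverse_frequency") {
    cnt <- tabulate(y_idx, nbins = k)
    if (any(cnt == 0)) {
      stop("class absent from y with inverse-frequency weighting: ",
           paste(class_order[cnt == 0], collapse = ", "), call. = FALSE)
    }
    class_w <- length(y) / (k * cnt)
  } else {
    class_w <- rep(1, k)
  }
  sample_w <- class_w[y_idx]

  has_val <- !is.null(X_val)
  if (has_val) {
    stopifnot(is.matrix(X_val), ncol(X_val) == ncol(X),
              nrow(X_val) == length(y_val))
    yv_idx <- match(as.character(y_val), class_order)
    if (anyNA(yv_idx)) stop("validation labels outside class_order",
                            call. = FALSE)
  }

  n <- nrow(X)
  y_onehot <- matrix(0, n, k)
  y_onehot[cbind(seq_len(n), y_idx)] <- 1

  history <- data.frame(epoch = seq_len(cfg$epochs),
                        train_loss = NA_real_, val_loss = NA_real_,
                        train_acc = NA_real_, val_acc = NA_real_)

  weights <- NULL
  withr::with_seed(cfg$seed, {
    weights <- init_weights(spec$layer_dims)
    adam_m <- lapply(weights, function(w) list(W = w$W * 0, b = w$b * 0))
    adam_v <- adam_m
    step <- 0L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      for (s in starts) {
        ii <- perm[s:min(s + cfg$batch_size - 1L, n)]
        fw <- mlp_forward(weights, X[ii, , drop = FALSE], spec$dropout_rate,
                          training = TRUE)
        grads <- mlp_backward(weights, fw$caches, fw$probs,
                              y_onehot[ii, , drop = FALSE], sample_w[ii])
        step <- step + 1L
        bc1 <- 1 - b1^step
        bc2 <- 1 - b2^step
        for (l in seq_along(weights)) {
          for (p in c("W", "b")) {
            g <- grads[[l]][[p]]
            adam_m[[l]][[p]] <- b1 * adam_m[[l]][[p]] + (1 - b1) * g
            adam_v[[l]][[p]] <- b2 * adam_v[[l]][[p]] + (1 - b2) * g * g
            weights[[l]][[p]] <- weights[[l]][[p]] -
              cfg$learning_rate * (adam_m[[l]][[p]] / bc1) /
              (sqrt(adam_v[[l]][[p]] / bc2) + eps)
          }
        }
      }
      tr <- mlp_forward(weights, X, spec$dropout_rate, training = FALSE)
      history$train_loss[epoch] <- cross_entropy(tr$probs, y_idx, sample_w)
      history$train_acc[epoch] <-
        mean(max.col(tr$probs, ties.method = "first") == y_idx)
      if (has_val) {
        va <- mlp_forward(weights, X_val, spec$dropout_rate, training = FALSE)
        history$val_loss[epoch] <- cross_entropy(va$probs, yv_idx)
        history$val_acc[epoch] <-
          mean(max.col(va$probs, ties.method = "first") == yv_idx)
      }
    }
  })

  probe_ids <- colnames(X)
  if (is.null(probe_ids)) probe_ids <- sprintf("f%05d", seq_len(ncol(X)))
  model <- new_trained_classifier(
    layer_dims = spec$layer_dims, dropout_rate = spec$dropout_rate,
    weights = weights, class_order = class_order,
    selected_probes = probe_ids,
    preprocessing_state = list(impute_means = stats::setNames(colMeans(X),
                                                              probe_ids),
                               input_scale = "beta"),
    seed = cfg$seed)
  list(model = model, history = history)
}

#' Predict class probabilities for new samples
#'
#' Extracts the model's frozen probe list from the beta matrix, imputes
#' missing *values* with the frozen training means, and runs a
#' deterministic forward pass (dropout disabled). Probes entirely absent
#' from the matrix are an error unless `impute_missing_probes = TRUE`,
#' in which case the frozen training means stand in (with a warning).
#'
#' @param model A `trained_classifier`.
#' @param bm Beta matrix (probes x samples) containing the model's
#'   selected probes.
#' @param impute_missing_probes Substitute frozen training means for
#'   probes absent from `bm` (default `FALSE`).
#' @return A `prediction_report` data frame: `sample_id`, one `p_<class>`
#'   column per class, `predicted_label`, `second_label`, `confidence`.
#'   Probability rows sum to 1 within 1e-6.
#' @export
predict_probabilities <- function(model, bm, impute_missing_probes = FALSE) {
  stopifnot(inherits(model, "trained_classifier"), is.matrix(bm))
  sel <- model$selected_probes
  absent <- setdiff(sel, rownames(bm))
  if (length(absent) && !impute_missing_probes) {
    stop(length(absent), " required probe(s) missing from input",
         " (use impute_missing_probes = TRUE to substitute training means): ",
         paste(utils::head(absent, 20), collapse = ", "), call. = FALSE)
  }
  n_samp <- ncol(bm)
  X <- matrix(NA_real_, n_samp, length(sel),
              dimnames = list(colnames(bm), sel))
  present <- intersect(sel, rownames(bm))
  X[, present] <- t(bm[present, , drop = FALSE])
  if (length(absent)) {
    warning("imputing ", length(absent),
            " absent probe(s) with frozen training means", call. = FALSE)
  }
  if (anyNA(X)) {
    mu <- model$preprocessing_state$impute_means[sel]
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2L]]
  }
  probs <- mlp_forward(model$weights, X, model$dropout_rate,
                       training = FALSE)$probs
  as_prediction_report(probs, colnames(bm), model$class_order)
}

#' @noRd
as_prediction_report <- function(probs, sample_ids, class_order) {
  top <- max.col(probs, ties.method = "first")
  second <- vapply(seq_len(nrow(probs)), function(i) {
    order(-probs[i, ], seq_along(class_order))[2L]
  }, integer(1))
  out <- data.frame(sample_id = sample_ids, probs,
                    predicted_label = class_order[top],
                    second_label = class_order[second],
                    confidence = probs[cbind(seq_len(nrow(probs)), top)],
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[1L + seq_along(class_order)] <- paste0("p_", class_order)
  structure(out, class = c("prediction_report", "data.frame"),
            class_order = class_order)
}

#' Extract the probability matrix from a prediction report
#'
#' @param report A `prediction_report`.
#' @return Numeric matrix, samples x classes, columns in class order.
#' @export
report_probabilities <- function(report) {
  co <- attr(report, "class_order")
  m <- as.matrix(report[, paste0("p_", co), drop = FALSE])
  dimnames(m) <- list(report$sample_id, co)
  m
}
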