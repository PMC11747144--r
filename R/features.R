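#' Feature-selection configuration
#'
#' @param organs Organ subset whose mQTL probe sets are used (default:
#'   all six classes).
#' @param top_k Number of most-variable probes to keep (default 20000).
#' @param variance_scope `"training_only"` (default; variance computed on
#'   training samples per fold, no leakage) or `"full_cohort"`
#'   (variance on all samples; mirrors selection before splitting and is
#'   optimistic for held-out estimates).
#' @return A list of class `feature_selection_config`.
#' @export
feature_selection_config <- function(organs = blockt_classes(),
                                     top_k = 20000L,
                                     variance_scope = c("training_only",
                                                        "full_cohort")) {
  variance_scope <- match.arg(variance_scope)
  organs <- as.character(organs)
  stopifnot(length(organs) >= 1, all(organs %in% blockt_classes()),
            top_k >= 1)
  structure(list(organs = organs, top_k = as.integer(top_k),
                 variance_scope = variance_scope),
            class = "feature_selection_config")
}

#' Restrict a beta matrix to mQTL probes
#'
#' Keeps only probes contained in the union of the catalog's probe sets
#' for the requested organs, preserving the original probe order.
#' Catalog probes absent from the matrix are reported in a message (the
#' catalog may exceed array content).
#'
#' @param bm Beta matrix.
#' @param catalog [mqtl_catalog()].
#' @param organs Organ subset (default: all organs in the catalog).
#' @return The restricted beta matrix.
#' @export
restrict_to_mqtl <- function(bm, catalog, organs = names(catalog)) {
  wanted <- catalog_union(catalog, organs)
  keep <- rownames(bm) %in% wanted
  if (!any(keep)) stop("no mQTL probes present on array", call. = FALSE)
  absent <- setdiff(wanted, rownames(bm))
  if (length(absent)) {
    message(length(absent), " catalog probe(s) not present in the matrix")
  }
  bm[keep, , drop = FALSE]
}

#' Select the most variable probes
#'
#' Ranks probes by the sample variance of their beta values (unbiased
#' estimator, denominator n - 1, computed on non-missing entries; probes
#' with fewer than 2 non-missing values get variance 0) and returns the
#' top `k` probe ids. Ties are broken lexicographically by probe id so
#' the result is deterministic and independent of input row order.
#'
#' @param bm Beta matrix.
#' @param k Number of probes to select; if `k >= nrow(bm)` all probes are
#'   returned, ordered by decreasing variance then id.
#' @return Character vector of probe ids, highest variance first.
#' @export
select_top_variable <- function(bm, k) {
  if (!nrow(bm)) stop("beta matrix has no probes", call. = FALSE)
  if (k < 1) stop("`k` must be at least 1", call. = FALSE)
  # variances are compared after rounding to 12 significant digits so that
  # mathematically equal variances tie (and break lexicographically)
  # regardless of floating-point summation order
  v <- signif(probe_variances(bm), 12)
  ord <- order(-v, rownames(bm), method = "radix")
  rownames(bm)[ord][seq_len(min(k, nrow(bm)))]
}

#' @noRd
probe_variances <- function(bm) {
  n_obs <- rowSums(!is.na(bm))
  mu <- rowMeans(bm, na.rm = TRUE)
  ss <- rowSums((bm - mu)^2, na.rm = TRUE)
  v <- ifelse(n_obs >= 2, ss / pmax(n_obs - 1, 1), 0)
  v[n_obs < 2] <- 0
  v
}
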