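#' The six BLOCKT organ classes
#'
#' Fixed vocabulary of organ-of-origin labels the classifier predicts:
#' breast, lung, ovarian/gynecologic ("gyn"), colon, kidney, and testis.
#' The order is the canonical class order used for probability columns,
#' confusion matrices, and deterministic tie-breaking.
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' blockt_classes()
blockt_classes <- function() {
  c("breast", "lung", "gyn", "colon", "kidney", "testis")
}

#' Chromosome vocabulary for probe manifests
#' @noRd
allowed_chromosomes <- function() {
  c(paste0("chr", 1:22), "chrX", "chrY")
}

#' Construct and validate a beta-value matrix
#'
#' A beta matrix is a numeric matrix of methylation fractions with probes
#' as rows and samples as columns; `rownames` hold probe ids and
#' `colnames` hold sample ids. Missing values (`NA`) are permitted; every
#' non-missing value must lie in \[0, 1\].
#'
#' @param values Numeric matrix, probes x samples, with dimnames.
#' @param probe_ids,sample_ids Optional identifier vectors overriding the
#'   dimnames of `values`.
#' @return The validated matrix (probes x samples) with dimnames set.
#' @export
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.5, 0.4), nrow = 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' bm <- beta_matrix(m)
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (probes x samples)", call. = FALSE)
  }
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("probe and sample identifiers are required (dimnames or arguments)",
         call. = FALSE)
  }
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  dup_p <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup_p)) {
    stop("duplicate probe ids: ", paste(utils::head(dup_p, 10), collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicate sample ids: ", paste(utils::head(dup_s, 10), collapse = ", "),
         call. = FALSE)
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  check_beta_range(values)
  values
}

#' @noRd
check_beta_range <- function(values) {
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    coords <- apply(utils::head(bad, 5), 1L, function(ij) {
      sprintf("[probe %s, sample %s] = %g",
              rownames(values)[ij[1]], colnames(values)[ij[2]],
              values[ij[1], ij[2]])
    })
    stop("beta values outside [0, 1]: ", paste(coords, collapse = "; "),
         if (nrow(bad) > 5) sprintf(" (and %d more)", nrow(bad) - 5),
         call. = FALSE)
  }
  invisible(values)
}

#' Construct and validate a sample sheet
#'
#' Per-sample metadata for a methylation cohort: unique sample id, organ
#' label (one of [blockt_classes()], or `NA` for inference-only cohorts),
#' processing batch (e.g. processing year), and a metastasis flag.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param label Organ labels, or `NULL`/`NA` when unknown.
#' @param batch Batch identifiers (coerced to character).
#' @param is_metastasis Logical vector.
#' @return A `data.frame` with columns `sample_id`, `label`, `batch`,
#'   `is_metastasis`.
#' @export
sample_sheet <- function(sample_id, label = NULL, batch = NULL,
                         is_metastasis = NULL) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  dup <- unique(sample_id[duplicated(sample_id)])
  if (length(dup)) {
    stop("duplicate sample ids: ", paste(utils::head(dup, 10), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(label)) label <- rep(NA_character_, n)
  label <- as.character(label)
  bad <- setdiff(unique(label[!is.na(label)]), blockt_classes())
  if (length(bad)) {
    stop("unknown organ label(s): ", paste(bad, collapse = ", "),
         "; allowed labels are: ", paste(blockt_classes(), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(batch)) batch <- rep(NA_character_, n)
  if (is.null(is_metastasis)) is_metastasis <- rep(NA, n)
  if (length(batch) == 1L) batch <- rep(batch, n)
  if (length(is_metastasis) == 1L) is_metastasis <- rep(is_metastasis, n)
  stopifnot(length(label) == n, length(batch) == n, length(is_metastasis) == n)
  data.frame(sample_id = sample_id, label = label,
             batch = as.character(batch),
             is_metastasis = as.logical(is_metastasis),
             stringsAsFactors = FALSE)
}

#' Construct and validate probe annotations
#'
#' Array manifest information used by the QC filters: chromosome
#' (chr1..chr22, chrX, chrY), base-pair position, and whether the probe
#' overlaps a common SNP.
#'
#' @param probe_id Character vector of unique probe ids.
#' @param chromosome Chromosome per probe.
#' @param position Non-negative integer position (bp).
#' @param snp_overlap Logical SNP-overlap flag.
#' @return A `data.frame` with the four columns above.
#' @export
probe_annotations <- function(probe_id, chromosome, position, snp_overlap) {
  probe_id <- as.character(probe_id)
  dup <- unique(probe_id[duplicated(probe_id)])
  if (length(dup)) {
    stop("duplicate probe ids in manifest: ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  }
  chromosome <- as.character(chromosome)
  bad <- setdiff(unique(chromosome), allowed_chromosomes())
  if (length(bad)) {
    stop("chromosome values outside chr1..chr22/chrX/chrY: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 0)) {
    stop("positions must be non-negative integers", call. = FALSE)
  }
  data.frame(probe_id = probe_id, chromosome = chromosome,
             position = position, snp_overlap = as.logical(snp_overlap),
             stringsAsFactors = FALSE)
}

#' Construct an mQTL catalog
#'
#' Maps each organ class to the set of probes whose methylation level is
#' an organ-specific methylation quantitative trait locus (mQTL). Organs
#' outside the six-class vocabulary are rejected.
#'
#' @param mapping Named list: organ label -> character vector of probe ids.
#' @return An object of class `mqtl_catalog`: the named list with an
#'   attribute `union_probes` holding the union over organs.
#' @export
mqtl_catalog <- function(mapping) {
  if (!is.list(mapping) || is.null(names(mapping)) || any(names(mapping) == "")) {
    stop("`mapping` must be a named list organ -> probe ids", call. = FALSE)
  }
  bad <- setdiff(names(mapping), blockt_classes())
  if (length(bad)) {
    stop("organ label(s) outside the six-class vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mapping <- lapply(mapping, function(p) unique(as.character(p)))
  empty <- names(mapping)[lengths(mapping) == 0]
  if (length(empty)) {
    stop("empty probe set for organ(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  structure(mapping, class = "mqtl_catalog",
            union_probes = unique(unlist(mapping, use.names = FALSE)))
}

#' @export
print.mqtl_catalog <- function(x, ...) {
  cat("mQTL catalog:", length(x), "organ(s),",
      length(attr(x, "union_probes")), "probes in union\n")
  for (o in names(x)) cat("  ", o, ": ", length(x[[o]]), " probes\n", sep = "")
  invisible(x)
}

#' Union of catalog probe sets
#'
#' @param catalog An [mqtl_catalog()].
#' @param organs Organ subset (default: all organs in the catalog).
#' @return Character vector of probe ids.
#' @export
catalog_union <- function(catalog, organs = names(catalog)) {
  missing_org <- setdiff(organs, names(catalog))
  if (length(missing_org)) {
    stop("catalog does not cover organ(s): ",
         paste(missing_org, collapse = ", "), call. = FALSE)
  }
  unique(unlist(catalog[organs], use.names = FALSE))
}
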