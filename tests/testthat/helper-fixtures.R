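# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# small beta matrix with known values
toy_beta <- function(n_probes = 5, n_samples = 3, seed = 11) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n_probes * n_samples), n_probes, n_samples,
                dimnames = list(sprintf("cg%07d", seq_len(n_probes)),
                                sprintf("s%03d", seq_len(n_samples))))
    beta_matrix(m)
  })
}

# manifest covering the probes of a matrix: all autosomal, no SNPs
clean_annotations <- function(probe_ids) {
  probe_annotations(probe_ids,
                    chromosome = rep("chr1", length(probe_ids)),
                    position = seq_along(probe_ids),
                    snp_overlap = rep(FALSE, length(probe_ids)))
}

# the QC fixture: 10 probes; 2 on chrX, 1 SNP-flagged autosomal,
# 1 clean probe with 20% missing, 6 clean
qc_fixture <- function() {
  probes <- sprintf("cg%07d", 1:10)
  samples <- sprintf("s%02d", 1:10)
  vals <- matrix(0.5, 10, 10, dimnames = list(probes, samples))
  vals[4, 1:2] <- NA  # 20% missing
  ann <- probe_annotations(
    probes,
    chromosome = c("chrX", "chrX", "chr5", "chr7", rep("chr1", 6)),
    position = 1:10,
    snp_overlap = c(FALSE, FALSE, TRUE, rep(FALSE, 7)))
  list(beta = beta_matrix(vals), ann = ann)
}

# variance-ranking fixture with hand-computed variances
# A: 0.04, B: 0.00, C: 0.09, D: 0.04, E: 0.01
variance_fixture <- function() {
  vals <- rbind(A = c(0.3, 0.5, 0.7),
                B = c(0.5, 0.5, 0.5),
                C = c(0.2, 0.5, 0.8),
                D = c(0.1, 0.3, 0.5),
                E = c(0.4, 0.5, 0.6))
  colnames(vals) <- c("s1", "s2", "s3")
  beta_matrix(vals)
}

# a sheet with the published cohort's class counts, labels only
table1_sheet <- function() {
  counts <- c(breast = 143L, gyn = 91L, testis = 86L, lung = 85L,
              kidney = 84L, colon = 20L)
  n <- sum(counts)
  sample_sheet(sprintf("s%04d", seq_len(n)),
               label = rep(names(counts), counts),
               batch = rep("b1", n),
               is_metastasis = c(rep(TRUE, 82L), rep(FALSE, n - 82L)))
}

# well-separated two-class gaussian problem
separable_xy <- function(n = 100, p = 20, sep = 5, seed = 42) {
  withr::with_seed(seed, {
    y <- rep(c("breast", "lung"), length.out = n)
    mu <- ifelse(y == "breast", 0, sep)
    X <- matrix(stats::rnorm(n * p, mean = rep(mu, p)), n, p)
    colnames(X) <- sprintf("f%03d", seq_len(p))
    list(X = X, y = y)
  })
}

# memoized heavy pipeline runs shared between acceptance blocks
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}
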