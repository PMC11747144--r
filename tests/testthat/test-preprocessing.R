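test_that("probe filters remove sex/SNP/missing probes with first-rule attribution", {
  fx <- qc_fixture()
  res <- filter_probes(fx$beta, fx$ann)
  expect_identical(nrow(res$matrix), 6L)
  expect_identical(res$report$removed$sex, 2L)
  expect_identical(res$report$removed$snp, 1L)
  expect_identical(res$report$removed$missingness, 1L)
  expect_identical(res$report$removed$unannotated, 0L)
  expect_identical(sum(unlist(res$report$removed)) + res$report$retained,
                   res$report$total)
})

test_that("clean matrices pass the probe filter unchanged", {
  bm <- toy_beta(8, 4)
  res <- filter_probes(bm, clean_annotations(rownames(bm)))
  expect_equal(res$matrix, bm)
  expect_true(all(unlist(res$report$removed) == 0))
})

test_that("a chrX probe that is also SNP-flagged counts under the sex rule only", {
  probes <- c("cgA", "cgB")
  vals <- matrix(0.5, 2, 4, dimnames = list(probes, paste0("s", 1:4)))
  ann <- probe_annotations(probes, c("chrX", "chr2"), 1:2, c(TRUE, FALSE))
  res <- filter_probes(beta_matrix(vals), ann)
  expect_identical(res$report$removed$sex, 1L)
  expect_identical(res$report$removed$snp, 0L)
})

test_that("unannotated probes fail QC and all-removed input errors", {
  bm <- toy_beta(4, 3)
  ann <- clean_annotations(rownames(bm)[1:2])
  res <- filter_probes(bm, ann)
  expect_identical(res$report$removed$unannotated, 2L)
  sexed <- probe_annotations(rownames(bm), rep("chrY", 4), 1:4, rep(FALSE, 4))
  expect_error(filter_probes(bm, sexed), "empty matrix after QC")
})

test_that("sample filter drops high-missingness samples only", {
  bm <- toy_beta(10, 5)
  bm[1:5, 2] <- NA  # 50% missing in sample 2
  res <- filter_samples(bm, qc_params(max_sample_missing_frac = 0.10))
  expect_identical(ncol(res$matrix), 4L)
  expect_false("s002" %in% colnames(res$matrix))
  expect_identical(res$report$removed$missingness, 1L)

  # degenerate threshold keeps everything
  res2 <- filter_samples(bm, qc_params(max_sample_missing_frac = 1.0))
  expect_identical(ncol(res2$matrix), 5L)
  # no missing values: identity
  res3 <- filter_samples(toy_beta(10, 5))
  expect_identical(ncol(res3$matrix), 5L)
})

test_that("beta/M transforms match hand-computed values and invert exactly", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(m_to_beta(0), 0.5)
  expect_equal(m_to_beta(2), 0.8)
  # frozen: log2(1e-6 / (1 - 1e-6))
  expect_equal(beta_to_m(0, epsilon = 1e-6), -19.931567126628412)

  withr::with_seed(9, {
    b <- matrix(stats::runif(600, 0.01, 0.99), 30, 20,
                dimnames = list(sprintf("cg%03d", 1:30),
                                sprintf("s%03d", 1:20)))
    expect_lt(max(abs(m_to_beta(beta_to_m(b)) - b)), 1e-9)
    # strictly increasing and antisymmetric
    x <- sort(stats::runif(100, 0.001, 0.999))
    expect_true(all(diff(beta_to_m(x)) > 0))
    expect_equal(beta_to_m(x), -beta_to_m(1 - x))
  })
  # missing stays missing
  expect_true(is.na(beta_to_m(NA_real_)))
})

test_that("single-batch input passes through batch correction unchanged", {
  m <- beta_to_m(toy_beta(20, 8))
  expect_lt(max(abs(combat_adjust(m, rep("b1", 8)) - m)), 1e-8)
})

test_that("batch correction removes an injected shift from nearly all probes", {
  withr::with_seed(31, {
    n_p <- 200L; n_b <- 50L
    mu <- stats::rnorm(n_p, 0, 2)
    m <- matrix(stats::rnorm(n_p * 2 * n_b, mu, 0.25), n_p, 2 * n_b,
                dimnames = list(sprintf("cg%04d", 1:n_p),
                                sprintf("s%04d", 1:(2 * n_b))))
    batch <- rep(c("y2019", "y2020"), each = n_b)
    m[, batch == "y2020"] <- m[, batch == "y2020"] + 1.0
    adj <- combat_adjust(m, batch)
    gap <- abs(rowMeans(adj[, batch == "y2019"]) -
                 rowMeans(adj[, batch == "y2020"]))
    expect_gte(mean(gap < 0.1), 0.95)
    # shape, missingness mask, and per-probe grand mean preserved
    expect_identical(dim(adj), dim(m))
    expect_lt(max(abs(rowMeans(adj) - rowMeans(m))), 1e-6)
  })
})

test_that("batch correction is equivariant under joint column permutation", {
  withr::with_seed(13, {
    m <- matrix(stats::rnorm(50 * 12), 50, 12,
                dimnames = list(sprintf("cg%03d", 1:50),
                                sprintf("s%03d", 1:12)))
    batch <- rep(c("a", "b", "c"), 4)
    perm <- sample(12)
    expect_equal(combat_adjust(m, batch)[, perm],
                 combat_adjust(m[, perm], batch[perm]))
  })
})

test_that("batch correction preserves the missingness mask and handles NAs", {
  withr::with_seed(17, {
    m <- matrix(stats::rnorm(40 * 10), 40, 10,
                dimnames = list(sprintf("cg%03d", 1:40),
                                sprintf("s%03d", 1:10)))
    m[sample(length(m), 30)] <- NA
    adj <- combat_adjust(m, rep(c("a", "b"), each = 5))
    expect_identical(is.na(adj), is.na(m))
  })
})

test_that("a batch with fewer than two samples is rejected by name", {
  m <- matrix(stats::rnorm(30), 10, 3,
              dimnames = list(sprintf("cg%03d", 1:10), c("s1", "s2", "s3")))
  expect_error(combat_adjust(m, c("a", "a", "lonely")), "lonely")
})

test_that("adjustment matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  withr::with_seed(7, {
    n_p <- 150L; n <- 60L
    m <- matrix(stats::rnorm(n_p * n, rep(stats::rnorm(n_p, 0, 2), n), 1),
                n_p, n, dimnames = list(sprintf("cg%04d", 1:n_p),
                                        sprintf("s%03d", 1:n)))
    batch <- rep(c("a", "b", "c"), each = 20)
    m[, batch == "b"] <- m[, batch == "b"] + 0.8
    m[, batch == "c"] <- m[, batch == "c"] * 1.3
    mine <- combat_adjust(m, batch)
    ref <- suppressMessages(sva::ComBat(m, batch = batch))
    # identical up to the exact per-probe grand-mean restoration step
    diff <- mine - ref
    expect_lt(max(abs(diff - rowMeans(diff))), 1e-9)
  })
})
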