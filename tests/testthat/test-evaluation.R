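test_that("split sizes follow the floor/ceil/remainder convention", {
  sheet <- table1_sheet()
  split <- split_cohort(sheet, split_spec(c(0.70, 0.15, 0.15), seed = 1))
  expect_identical(lengths(split),
                   c(train = 356L, validation = 76L, test = 77L))
  expect_identical(sort(unname(unlist(split))), sort(sheet$sample_id))

  small <- sample_sheet(paste0("s", 1:10), label = rep("breast", 10),
                        batch = "b", is_metastasis = FALSE)
  split2 <- split_cohort(small, split_spec(c(0.8, 0.1, 0.1), seed = 1))
  expect_identical(lengths(split2),
                   c(train = 8L, validation = 1L, test = 1L))

  expect_error(split_spec(c(0.5, 0.3, 0.3)), "sum to 1")
})

test_that("stratified splits keep class proportions within one sample", {
  sheet <- table1_sheet()
  split <- split_cohort(sheet, split_spec(c(0.70, 0.15, 0.15), seed = 5))
  lab <- function(ids) sheet$label[match(ids, sheet$sample_id)]
  for (cl in blockt_classes()) {
    n_cl <- sum(sheet$label == cl)
    for (s in seq_along(split)) {
      expected <- c(0.70, 0.15, 0.15)[s] * n_cl
      expect_lte(abs(sum(lab(split[[s]]) == cl) - expected), 1)
    }
  }
})

test_that("splits with identical seeds are identical; seeds matter", {
  sheet <- table1_sheet()
  s1 <- split_cohort(sheet, split_spec(seed = 3))
  s2 <- split_cohort(sheet, split_spec(seed = 3))
  s3 <- split_cohort(sheet, split_spec(seed = 4))
  expect_identical(s1, s2)
  expect_false(identical(s1$train, s3$train))
})

test_that("stratified folds balance classes and partition the cohort", {
  labels <- rep(c("breast", "lung"), each = 5)
  folds <- make_stratified_folds(labels, 5, seed = 2)
  for (f in 1:5) {
    expect_identical(sum(labels[folds == f] == "breast"), 1L)
    expect_identical(sum(labels[folds == f] == "lung"), 1L)
  }
  # leave-one-out: every fold size 1
  lab2 <- rep("breast", 8)
  folds2 <- make_stratified_folds(lab2, 8, seed = 1)
  expect_identical(sort(folds2), 1:8)
  # partition property on an imbalanced cohort
  sheet <- table1_sheet()
  folds3 <- make_stratified_folds(sheet$label, 10, seed = 7)
  expect_identical(length(folds3), nrow(sheet))
  expect_true(all(folds3 %in% 1:10))
  tab <- table(sheet$label, folds3)
  expect_true(all(apply(tab, 1, function(r) max(r) - min(r)) <= 1))
  # a class smaller than k warns and lands in distinct folds
  expect_warning(folds4 <- make_stratified_folds(
    c(rep("breast", 20), rep("colon", 3)), 10, seed = 1), "colon")
  expect_identical(anyDuplicated(folds4[21:23]), 0L)
})

test_that("metrics reproduce the hand-computed toy table", {
  co <- c("A", "B", "C")
  # predictions: A, B, B, B for truth A, A, B, C
  probs <- rbind(c(0.8, 0.1, 0.1),
                 c(0.2, 0.7, 0.1),
                 c(0.1, 0.8, 0.1),
                 c(0.3, 0.5, 0.2))
  colnames(probs) <- co
  m <- compute_metrics(probs, c("A", "A", "B", "C"), co)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$macro_f1, 7 / 18)
  expect_identical(as.vector(m$confusion["A", ]), c(1L, 1L, 0L))
  expect_identical(sum(m$confusion), 4L)

  # perfect predictions
  perfect <- diag(3)[c(1, 2, 3), ]
  colnames(perfect) <- co
  mp <- compute_metrics(perfect, co, co)
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$top2_accuracy, 1)
  expect_equal(mp$macro_f1, 1)
  expect_true(all(mp$confusion[upper.tri(mp$confusion)] == 0))

  expect_error(compute_metrics(probs, c("A", "B")), "length")
  expect_error(compute_metrics(probs, c("A", "A", "B", "D"), co), "D")
})

test_that("confusion rows sum to true class counts and top2 >= top1", {
  withr::with_seed(19, {
    for (i in 1:20) {
      n <- sample(3:40, 1)
      k <- 6
      probs <- matrix(stats::rexp(n * k), n, k)
      probs <- probs / rowSums(probs)
      colnames(probs) <- blockt_classes()
      truth <- sample(blockt_classes(), n, replace = TRUE)
      m <- compute_metrics(probs, truth)
      expect_equal(as.vector(rowSums(m$confusion)),
                   as.vector(table(factor(truth, blockt_classes()))),
                   ignore_attr = TRUE)
      expect_equal(sum(m$confusion), n, ignore_attr = TRUE)
      expect_equal(m$accuracy, sum(diag(m$confusion)) / n)
      expect_gte(m$top2_accuracy, m$accuracy)
    }
  })
})

test_that("rank-2 ties in top-2 accuracy break by class-order position", {
  co <- c("A", "B", "C")
  probs <- matrix(c(0.5, 0.25, 0.25), 1, dimnames = list(NULL, co))
  # tie between B and C at rank 2: B (earlier in class order) wins
  expect_equal(compute_metrics(probs, "B", co)$top2_accuracy, 1)
  expect_equal(compute_metrics(probs, "C", co)$top2_accuracy, 0)
})

test_that("cohort report reproduces the published cohort arithmetic", {
  rep <- cohort_report(table1_sheet())
  expect_identical(rep$total, 509L)
  pct <- stats::setNames(rep$by_class$pct, rep$by_class$label)
  n <- stats::setNames(rep$by_class$n, rep$by_class$label)
  expect_identical(n[["breast"]], 143L)
  expect_identical(pct[["breast"]], 28)
  expect_identical(pct[["gyn"]], 18)
  expect_identical(pct[["testis"]], 17)
  expect_identical(pct[["lung"]], 17)
  expect_identical(pct[["colon"]], 4)
  expect_identical(rep$n_metastasis, 82L)
  expect_identical(rep$pct_metastasis, 16)

  single <- sample_sheet("s1", label = "lung", batch = "b",
                         is_metastasis = FALSE)
  expect_identical(cohort_report(single)$by_class$pct, 100)
  expect_error(cohort_report(single[0, ]), "empty")
})

test_that("cross-validation on a small separable cohort recovers labels", {
  sim <- simulate_cohort(sim_config(
    n_per_class = c(breast = 12L, lung = 12L, colon = 12L),
    n_probes = 300L, mqtl_per_class = 30L, n_batches = 1L,
    missing_rate = 0, seed = 2))
  cv <- cross_validate(sim$beta, sim$sheet,
                       fs_cfg = feature_selection_config(top_k = 90),
                       net_cfg = network_config(layer_dims = c(90, 128, 6),
                                                epochs = 20),
                       catalog = sim$catalog, k = 3, seed = 2)
  expect_gte(cv$mean_accuracy, 0.9)
  expect_equal(cv$mean_accuracy, mean(cv$per_fold$accuracy))
  expect_equal(cv$mean_macro_f1, mean(cv$per_fold$macro_f1))
  expect_identical(sort(cv$fold_assignments$sample_id),
                   sort(sim$sheet$sample_id))
  expect_identical(cv$best_fold,
                   cv$per_fold$fold[which.min(cv$per_fold$final_val_loss)])
  expect_identical(sum(cv$confusion), nrow(sim$sheet))
})
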