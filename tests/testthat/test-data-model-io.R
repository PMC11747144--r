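test_that("beta matrix round-trips through TSV and CSV including NA cells", {
  bm <- toy_beta()
  bm[2, 3] <- NA
  for (ext in c("tsv", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_beta_matrix(bm, path)
    back <- load_beta_matrix(path)
    expect_identical(rownames(back), rownames(bm))
    expect_identical(colnames(back), colnames(bm))
    expect_equal(back, bm)
    expect_identical(is.na(back), is.na(bm))
  }
})

test_that("samples-by-probes orientation is transposed on load, never guessed", {
  bm <- toy_beta()
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(sample_id = colnames(bm), t(bm), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  back <- load_beta_matrix(path, orientation = "samples_by_probes")
  expect_equal(back, bm)
})

test_that("out-of-range values are rejected with probe/sample coordinates", {
  bm <- toy_beta()
  bm[3, 2] <- 1.2
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(probe_id = rownames(bm), bm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_beta_matrix(path), "cg0000003.*s002")
  expect_error(beta_matrix(bm), "outside \\[0, 1\\]")
})

test_that("duplicate identifiers are rejected by name", {
  m <- matrix(0.5, 2, 2, dimnames = list(c("cgA", "cgA"), c("s1", "s2")))
  expect_error(beta_matrix(m), "duplicate probe ids.*cgA")
  m2 <- matrix(0.5, 2, 2, dimnames = list(c("cgA", "cgB"), c("s1", "s1")))
  expect_error(beta_matrix(m2), "duplicate sample ids.*s1")
})

test_that("simulated cohort file reloads with the injected missing count", {
  cfg <- sim_config(n_per_class = c(breast = 20L, lung = 20L, colon = 20L),
                    n_probes = 200L, mqtl_per_class = 30L,
                    missing_rate = 0.02, seed = 5)
  sim <- simulate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(sim$beta, path)
  # independent count of NA tokens in the raw file
  lines <- readLines(path)[-1]
  n_na_file <- sum(vapply(strsplit(lines, "\t"),
                          function(x) sum(x == "NA"), 0L))
  back <- load_beta_matrix(path)
  expect_identical(dim(back), c(200L, 60L))
  expect_identical(sum(is.na(back)), n_na_file)
  expect_identical(sum(is.na(back)), sim$truth$n_missing)
})

test_that("sample sheets parse, reject unknown labels, allow label-free files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,label,batch,is_metastasis",
               "s1,breast,2019,TRUE",
               "s2,lung,2020,FALSE"), path)
  sheet <- load_cohort_metadata(path)
  expect_identical(sheet$label, c("breast", "lung"))
  expect_false(attr(sheet, "inference_only"))

  writeLines(c("sample_id,label,batch,is_metastasis",
               "s1,liver,2019,TRUE"), path)
  expect_error(load_cohort_metadata(path), "liver.*allowed labels")

  writeLines(c("sample_id,batch,is_metastasis",
               "s1,2019,TRUE", "s2,2019,FALSE"), path)
  sheet <- load_cohort_metadata(path)
  expect_true(attr(sheet, "inference_only"))
  expect_true(all(is.na(sheet$label)))

  writeLines(c("sample_id,label,batch,is_metastasis",
               "s1,breast,2019,TRUE", "s1,lung,2020,FALSE"), path)
  expect_error(load_cohort_metadata(path), "duplicate sample ids")
})

test_that("manifest/catalog loading restricts organs and warns on unknown probes", {
  man_path <- withr::local_tempfile(fileext = ".csv")
  cat_path <- withr::local_tempfile(fileext = ".csv")
  probes <- sprintf("cg%07d", 1:100)
  write_probe_annotations(clean_annotations(probes), man_path)

  cat_df <- data.frame(
    organ = c(rep("breast", 5), rep("lung", 5), rep("colon", 5),
              rep("liver", 3)),
    probe_id = c(probes[1:15], paste0("cgX", 1:3)))
  utils::write.csv(cat_df, cat_path, row.names = FALSE, quote = FALSE)
  expect_message(res <- load_probe_annotations(man_path, cat_path), "liver")
  expect_setequal(names(res$catalog), c("breast", "lung", "colon"))
  expect_setequal(attr(res$catalog, "union_probes"), probes[1:15])

  cat_df2 <- data.frame(organ = "breast",
                        probe_id = c(probes[1:5], paste0("cgU", 1:10)))
  utils::write.csv(cat_df2, cat_path, row.names = FALSE, quote = FALSE)
  expect_warning(res2 <- load_probe_annotations(man_path, cat_path),
                 "10 catalog probe")
})

test_that("catalog constructor enforces the class vocabulary and non-empty sets", {
  expect_error(mqtl_catalog(list(liver = "cg1")), "liver")
  expect_error(mqtl_catalog(list(breast = character(0))), "empty probe set")
  cat3 <- mqtl_catalog(list(breast = c("a", "b"), lung = c("b", "c")))
  expect_setequal(attr(cat3, "union_probes"), c("a", "b", "c"))
})

test_that("model save/load round trip reproduces predictions bit for bit", {
  d <- separable_xy(n = 40, p = 10)
  cfg <- network_config(layer_dims = c(10, 8, 2), epochs = 5, seed = 3)
  fit <- train_network(build_network(cfg), d$X, d$y, cfg)
  bm <- t(d$X)
  colnames(bm) <- sprintf("s%03d", seq_len(ncol(bm)))
  before <- predict_probabilities(fit$model, bm[, 1:10])

  dir <- withr::local_tempdir()
  save_model(fit$model, dir)
  loaded <- load_model(dir)
  after <- predict_probabilities(loaded, bm[, 1:10])
  expect_identical(report_probabilities(before), report_probabilities(after))
  expect_identical(loaded$selected_probes, fit$model$selected_probes)

  # tampered class_order must be caught at load
  man <- jsonlite::read_json(file.path(dir, "model.json"),
                             simplifyVector = TRUE)
  man$class_order <- man$class_order[1]
  jsonlite::write_json(man, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  expect_error(load_model(dir), "class_order")

  # missing weight file named in the error
  dir2 <- withr::local_tempdir()
  save_model(fit$model, dir2)
  unlink(file.path(dir2, "layer01_W.bin"))
  expect_error(load_model(dir2), "layer01_W.bin")
})
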