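# Train/validate on planted-rule synthetic data; the generator is the
# ground-truth oracle.
prep_benchmark <- function(n, seed) {
  lib <- generate_library(n, seed = seed)
  rec <- plant_bioassay(lib, sar_truth(seed = seed))
  ds <- label_records(rec) |> resolve_duplicates() |>
    stratified_split(0.75, seed = seed) |>
    fingerprint_compounds()
  train <- with_fp_config(dplyr::filter(ds, split == "train"), ds)
  valid <- with_fp_config(dplyr::filter(ds, split == "validation"), ds)
  list(train = train, valid = valid)
}

test_that("training learns the planted substructure rule (AUC >= 0.9)", {
  b <- prep_benchmark(2000, seed = 7)
  m <- train_activity_model(b$train, seed = 7)
  pv <- predict_index(m, b$valid)
  expect_true(all(pv$pred_index >= 0 & pv$pred_index <= 1))
  expect_gte(roc_auc(pv$label, pv$pred_index), 0.90)
})

test_that("the benchmark operates in the high-specificity regime", {
  # over the seed-set benchmark, mean validation AUC >= 0.9 and, at the 0.7
  # threshold, mean specificity at least mean sensitivity (screening is
  # tuned to produce few false positives)
  aucs <- ses <- sps <- numeric(5)
  for (s in 1:5) {
    b <- prep_benchmark(2000, seed = s)
    m <- train_activity_model(b$train, seed = s)
    pv <- predict_index(m, b$valid)
    aucs[s] <- roc_auc(pv$label, pv$pred_index)
    mm <- screen_metrics(confusion_counts(pv$label, pv$pred_index, 0.7))
    ses[s] <- mm$se; sps[s] <- mm$sp
  }
  expect_gte(mean(aucs), 0.90)
  expect_gte(mean(sps), mean(ses))
})

test_that("training and prediction are deterministic under a fixed seed", {
  b <- prep_benchmark(400, seed = 3)
  m1 <- train_activity_model(b$train, seed = 3)
  m2 <- train_activity_model(b$train, seed = 3)
  p1 <- predict_index(m1, b$valid)$pred_index
  p2 <- predict_index(m2, b$valid)$pred_index
  expect_identical(p1, p2)
  # repeated prediction from one model is identical too
  expect_identical(p1, predict_index(m1, b$valid)$pred_index)
})

test_that("planted actives outrank planted decoys in sampled pairs", {
  b <- prep_benchmark(1200, seed = 13)
  m <- train_activity_model(b$train, seed = 13)
  pv <- predict_index(m, b$valid)
  act <- pv$pred_index[pv$true_active]
  dec <- pv$pred_index[!pv$true_active]
  set.seed(13)
  wins <- mean(sample(act, 100, replace = TRUE) >
                 sample(dec, 100, replace = TRUE))
  expect_gte(wins, 0.95)
})

test_that("single-class input refuses to train", {
  b <- prep_benchmark(300, seed = 5)
  allact <- with_fp_config(dplyr::filter(b$train, label == "active"), b$train)
  expect_error(train_activity_model(allact), class = "cyp_train_error")
})

test_that("the nnet engine trains, predicts in range, and is seeded", {
  # exercised on the compact MACCS key set; a dense network on the 4096-bit
  # hashed space is far beyond what this optimiser is sized for
  lib <- generate_library(300, seed = 9)
  rec <- plant_bioassay(lib, sar_truth(seed = 9))
  ds <- label_records(rec) |> resolve_duplicates() |>
    stratified_split(0.75, seed = 9) |>
    fingerprint_compounds(fp = fp_config("MACCS"))
  train <- with_fp_config(dplyr::filter(ds, split == "train"), ds)
  valid <- with_fp_config(dplyr::filter(ds, split == "validation"), ds)
  m1 <- train_activity_model(train, engine = "nnet", seed = 9, hidden = 4,
                             epochs = 50)
  m2 <- train_activity_model(train, engine = "nnet", seed = 9, hidden = 4,
                             epochs = 50)
  p1 <- predict_index(m1, valid)$pred_index
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, predict_index(m2, valid)$pred_index)
})

test_that("classification threshold is inclusive and monotone", {
  expect_equal(as.character(classify_index(c(0.93, 0.70, 0.69))),
               c("active", "active", "inactive"))
  idx <- seq(0, 1, by = 0.01)
  hits_low <- which(classify_index(idx, 0.6) == "active")
  hits_high <- which(classify_index(idx, 0.8) == "active")
  expect_true(all(hits_high %in% hits_low))
  expect_error(classify_index(0.5, threshold = 0), class = "cyp_threshold_error")
})

test_that("fingerprint-configuration mismatch is caught at prediction", {
  b <- prep_benchmark(200, seed = 21)
  m <- train_activity_model(b$train, seed = 21)
  other <- generate_library(20, seed = 22) |>
    parse_smiles() |> desalt() |>
    dplyr::filter(!is.na(smiles_canonical)) |>
    fingerprint_compounds(fp = fp_config("FP2"))
  expect_error(predict_index(m, other), class = "cyp_screen_error")
})

test_that("tidy and glance expose coefficients and training metadata", {
  b <- prep_benchmark(300, seed = 2)
  m <- train_activity_model(b$train, seed = 2)
  td <- tidy(m)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_gt(nrow(td), 1)
  g <- glance(m)
  expect_equal(g$engine, "glmnet")
  expect_equal(g$n_train, nrow(b$train))
})
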