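test_that("balanced undersampling yields equal class counts per dataset", {
  tb <- synth_feature_table(table_spec(n = 300, shb_fraction = 1 / 3,
                                       mode = "exact", seed = 1))
  ds <- make_balanced_datasets(tb, k = 5, seed = 2)
  expect_length(ds, 5)
  for (d in ds) {
    expect_equal(sum(d$label == "SHB"), 100)
    expect_equal(sum(d$label == "NHB"), 100)
  }
  # determinism
  ds2 <- make_balanced_datasets(tb, k = 5, seed = 2)
  expect_identical(ds, ds2)
  # equal classes in, k = 1 -> same records up to order
  bal <- ds[[1]]
  d1 <- make_balanced_datasets(bal, k = 1, seed = 9)[[1]]
  expect_equal(nrow(d1), nrow(bal))
  expect_equal(sum(d1$label == "SHB"), sum(bal$label == "SHB"))
  # single-class input is a contract error
  expect_error(make_balanced_datasets(bal[bal$label == "SHB", ], 2),
               "both")
})

test_that("depth selection returns the single candidate immediately", {
  x <- matrix(rnorm(60), 30); y <- rbinom(30, 1, 0.5)
  cfg <- shb_config(depth_candidates = 3)
  expect_equal(select_interaction_depth(x, y, cfg), 3L)
  expect_error(select_interaction_depth(x[1:5, ], y[1:5],
                                        shb_config(depth_candidates = 1:2,
                                                   cv_folds = 10)),
               "smaller")
})

test_that("depth selection tracks the interaction order of the signal", {
  cfg <- shb_config(n_trees = 150, shrinkage = 0.1, depth_candidates = 1:3,
                    cv_folds = 3)
  add_d1 <- 0
  xor_ge2 <- 0
  for (sd in 1:5) {
    set.seed(sd)
    n <- 400
    x <- cbind(f1 = rbinom(n, 1, 0.5), f2 = rbinom(n, 1, 0.5),
               f3 = rnorm(n))
    y_add <- as.integer(runif(n) < plogis(-1 + 2 * x[, 1]))
    y_xor <- as.integer(xor(x[, 1], x[, 2]))
    add_d1 <- add_d1 + (select_interaction_depth(x, y_add, cfg, sd) == 1)
    xor_ge2 <- xor_ge2 + (select_interaction_depth(x, y_xor, cfg, sd) >= 2)
  }
  expect_gte(add_d1, 4)   # additive signal: depth 1 in almost all repeats
  expect_equal(xor_ge2, 5)  # XOR is not learnable at depth 1
})

test_that("prediction is the arithmetic mean of member probabilities", {
  tb <- synth_feature_table(table_spec(
    n = 250, odds_ratios = list(lig_functional_group = 6), seed = 3))
  m <- train_ensemble(tb, small_config(n_members = 3, rng_seed = 5))
  expect_length(m$members, 3)
  p <- predict_proba(m, tb[1:40, ], per_member = TRUE)
  pm <- attr(p, "members")
  expect_equal(dim(pm), c(40, 3))
  expect_equal(as.numeric(p), rowMeans(pm), tolerance = 1e-12)
  expect_true(all(p >= apply(pm, 1, min) - 1e-12 &
                    p <= apply(pm, 1, max) + 1e-12))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("training is reproducible bit-for-bit under a fixed seed", {
  tb <- synth_feature_table(table_spec(
    n = 200, odds_ratios = list(lig_logP = 5), seed = 8))
  m1 <- train_ensemble(tb, small_config(rng_seed = 42))
  m2 <- train_ensemble(tb, small_config(rng_seed = 42))
  expect_identical(predict_proba(m1, tb), predict_proba(m2, tb))
  m3 <- train_ensemble(tb, small_config(rng_seed = 43))
  expect_false(identical(predict_proba(m1, tb), predict_proba(m3, tb)))
})

test_that("classification applies the >= threshold rule", {
  expect_equal(classify(0.870, 0.870), "SHB")
  expect_equal(classify(0.8699999, 0.870), "NHB")
  expect_equal(classify(0.5), "NHB")
  expect_equal(unique(classify(c(0, 0.4, 1), threshold = 0)), "SHB")
  expect_error(classify(0.5, threshold = 1.2), "threshold")
  expect_error(classify(1.4), "0, 1")
})

test_that("unknown categorical levels map to UNK with a warning", {
  tb <- synth_feature_table(table_spec(n = 200, seed = 4))
  m <- train_ensemble(tb, small_config())
  nd <- tb[1:3, ]
  nd$lig_functional_group[1] <- "hydronium"
  expect_warning(p <- predict_proba(m, nd), "UNK")
  expect_true(all(is.finite(p)))
  # all-missing physchem values still give a finite probability
  nd2 <- tb[1:3, ]
  nd2$lig_pKa <- NA_real_; nd2$lig_pKb <- NA_real_; nd2$lig_logP <- NA_real_
  expect_true(all(is.finite(predict_proba(m, nd2))))
})

test_that("model archives round-trip and validate their schema", {
  tb <- synth_feature_table(table_spec(n = 200, seed = 6))
  m <- train_ensemble(tb, small_config())
  tf <- tempfile(fileext = ".shb")
  save_model(m, tf)
  m2 <- load_model(tf)
  expect_identical(predict_proba(m2, tb), predict_proba(m, tb))
  expect_equal(m2$threshold, 0.870)
  # tampering with the frozen vocabulary must fail validation
  bad <- readRDS(tf)
  bad$vocab$aa_residue <- c(bad$vocab$aa_residue, "ZZZ")
  tf2 <- tempfile(fileext = ".shb")
  saveRDS(bad, tf2)
  expect_error(load_model(tf2), "schema")
})

test_that("the no-undersampling variant trains on the full table", {
  tb <- synth_feature_table(table_spec(n = 200, shb_fraction = 0.4,
                                       mode = "exact", seed = 9))
  m <- train_ensemble(tb, small_config(n_members = 1, undersample = FALSE))
  expect_length(m$members, 1)
  expect_equal(unname(m$class_counts["SHB"]), 80)
  expect_true(all(is.finite(predict_proba(m, tb))))
})
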