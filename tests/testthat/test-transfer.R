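# Shared fixture: reference cohort + model set, LRRK2-like arm at 0.5
# attenuation.
ref_cohort <- generate_cohort(cohort_config(
  group_sizes = c(HC = 104, sPD = 104, LRRK2_PD = 30),
  n_sites = 3L, lrrk2_attenuation = 0.5, seed = 101))
ref_ids <- ref_cohort$participants$group %in% c("HC", "sPD")
model_set <- fit_model_set(ref_cohort$participants[ref_ids, ],
                           ref_cohort$morphometry)

test_that("predictions on the training sample reproduce OLS properties", {
  train <- ref_cohort$participants[ref_ids, ]
  pred <- predict_morphometry(model_set, train)
  meas <- measured_in_model_units(
    model_set, ref_cohort$morphometry[match(train$participant_id,
                                            ref_cohort$morphometry$participant_id), ])
  expect_identical(dim(pred), dim(meas))
  # mean residual per region is 0 (OLS with intercept)
  expect_true(all(abs(colMeans(meas - pred)) < 1e-10))
  # a participant identical to a training row gets that row's fitted value
  one <- train[5, , drop = FALSE]
  expect_equal(predict_morphometry(model_set, one)[1, ], pred[5, ],
               tolerance = 1e-12)
})

test_that("prediction is linear in the stored coefficients", {
  train <- ref_cohort$participants[ref_ids, ]
  pred1 <- predict_morphometry(model_set, train)
  ms2 <- model_set
  ms2$coefficients$cortical["age", ] <- 2 * ms2$coefficients$cortical["age", ]
  pred2 <- predict_morphometry(ms2, train)
  X <- build_design(train, model_set$spec, "cortical")
  cort <- model_set$registry$name[model_set$registry$tissue == "cortical"]
  age_contrib <- outer(X[, "age"], model_set$coefficients$cortical["age", ])
  expect_equal(pred2[, cort] - pred1[, cort], age_contrib, tolerance = 1e-10)
})

test_that("transfer freezes the model set", {
  before <- serialize(model_set, NULL)
  invisible(predict_morphometry(model_set, ref_cohort$participants))
  expect_identical(serialize(model_set, NULL), before)
})

test_that("measured = predicted gives an all-zero difference object", {
  train <- ref_cohort$participants[ref_ids, ][1:20, ]
  pred <- predict_morphometry(model_set, train)
  pd <- compute_prediction_difference(pred, pred, rep(c("A", "B"), 10))
  expect_true(all(pd$differences == 0))
  expect_true(all(pd$region_means == 0))
  # misaligned ids are rejected
  bad <- pred
  rownames(bad)[1] <- "nobody"
  expect_error(compute_prediction_difference(pred, bad, rep("A", 20)),
               "misaligned")
})

test_that("an attenuated subgroup shows positive mean preservation", {
  p <- ref_cohort$participants
  sel <- p[p$group %in% c("LRRK2_PD", "sPD"), ]
  sel <- sel[order(sel$participant_id), ]
  pred <- predict_morphometry(model_set, sel)
  meas <- measured_in_model_units(
    model_set, ref_cohort$morphometry[match(sel$participant_id,
                                            ref_cohort$morphometry$participant_id), ])
  pd <- compute_prediction_difference(meas, pred, sel$group)
  # LRRK2 arm: atrophy only half of what the transferred model expects
  expect_gt(mean(pd$region_means[, "LRRK2_PD"]), 0)
  expect_gt(mean(pd$region_means[, "LRRK2_PD"]),
            mean(pd$region_means[, "sPD"]))
  # preservation concentrates where the injected atrophy was strongest
  eff <- ref_cohort$config$diagnosis_effect
  expect_gt(cor(abs(eff), pd$region_means[, "LRRK2_PD"],
                method = "spearman"), 0.2)
})

test_that("a zero-effect contrast is centred on zero", {
  cohort0 <- generate_cohort(cohort_config(
    group_sizes = c(HC = 104, sPD = 104, LRRK2_NMC = 50),
    n_sites = 3L, seed = 131))
  ids0 <- cohort0$participants$group %in% c("HC", "sPD")
  ms0 <- fit_model_set(cohort0$participants[ids0, ], cohort0$morphometry)
  tgt <- cohort0$participants[cohort0$participants$group %in%
                                c("HC", "LRRK2_NMC"), ]
  pred <- predict_morphometry(ms0, tgt)
  meas <- measured_in_model_units(
    ms0, cohort0$morphometry[match(tgt$participant_id,
                                   cohort0$morphometry$participant_id), ])
  pd <- compute_prediction_difference(meas, pred, tgt$group)
  # NMC carries no injected effect: both arms' mean deviations are near 0
  expect_lt(abs(mean(pd$region_means[, "LRRK2_NMC"])), 0.1)
  tst <- test_group_difference(pd, "LRRK2_NMC", "HC")
  expect_gt(tst$p_value, 0.001)
})

test_that("group difference test matches the Welch oracle and edge cases", {
  set.seed(140)
  n <- 82
  a <- rnorm(n); b <- rnorm(n, 0.1)
  pd <- structure(list(
    differences = rbind(a, b),
    groups = c("A", "B"),
    region_means = cbind(A = a, B = b)), class = "prediction_difference")
  pd$groups <- c(rep("A", 2), rep("B", 2))  # n >= 2 per side for the test
  pd$region_means <- cbind(A = a, B = b)
  tst <- test_group_difference(pd, "A", "B")
  oracle <- welch_oracle(a, b)
  expect_equal(tst$statistic, oracle$t, tolerance = 1e-12)
  expect_equal(tst$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(tst$estimate, mean(a) - mean(b), tolerance = 1e-12)

  # identical region means: t = 0, p = 1
  pd2 <- pd; pd2$region_means <- cbind(A = a, B = a)
  tst2 <- test_group_difference(pd2, "A", "B")
  expect_equal(tst2$statistic, 0)
  expect_equal(tst2$p_value, 1)

  # a 5-pooled-SD shift is overwhelming
  pd3 <- pd; pd3$region_means <- cbind(A = a + 5 * sd(a), B = a)
  expect_lt(test_group_difference(pd3, "A", "B")$p_value, 1e-6)

  # paired family uses the region pairing
  tstp <- test_group_difference(pd, "A", "B", family = "paired")
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(tstp$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(tstp$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("preservation maps have difference semantics and round-trip", {
  p <- ref_cohort$participants
  sel <- p[p$group %in% c("LRRK2_PD", "sPD"), ]
  pred <- predict_morphometry(model_set, sel)
  meas <- measured_in_model_units(
    model_set, ref_cohort$morphometry[match(sel$participant_id,
                                            ref_cohort$morphometry$participant_id), ])
  pd <- compute_prediction_difference(meas, pred, sel$group)
  map <- preservation_map(pd, "LRRK2_PD")
  expect_s3_class(map, "brain_map")
  expect_identical(attr(map, "semantics"), "prediction_difference")
  expect_equal(nrow(map), 82L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_brain_map(map, f)
  back <- read_brain_map(f, "prediction_difference")
  expect_equal(back$value, map$value, tolerance = 1e-12)
  expect_error(preservation_map(pd, "HC"), "not present")
})

test_that("mean preservation rises monotonically as attenuation falls", {
  levels <- c(1.0, 0.5, 0.0)
  means <- vapply(levels, function(a) {
    acc <- 0
    for (seed in 1:8) {
      cohort <- generate_cohort(cohort_config(
        group_sizes = c(HC = 80, sPD = 80, LRRK2_PD = 19),
        n_sites = 3L, lrrk2_attenuation = a, seed = 1000 * seed + a * 10))
      ids <- cohort$participants$group %in% c("HC", "sPD")
      ms <- fit_model_set(cohort$participants[ids, ], cohort$morphometry)
      tgt <- cohort$participants[cohort$participants$group == "LRRK2_PD", ]
      pred <- predict_morphometry(ms, tgt)
      meas <- measured_in_model_units(
        ms, cohort$morphometry[match(tgt$participant_id,
                                     cohort$morphometry$participant_id), ])
      pd <- compute_prediction_difference(meas, pred, tgt$group)
      acc <- acc + mean(pd$region_means[, "LRRK2_PD"])
    }
    acc / 8
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
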