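make_participants <- function(n, n_sites = 3, seed = 1) {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    pd_diagnosis = rep(c(1, 0), length.out = n),
    age = rnorm(n, 62, 9),
    sex = sample(c("male", "female"), n, replace = TRUE),
    site = sample(paste0("site", seq_len(n_sites)), n, replace = TRUE),
    tiv = rnorm(n, 1.45e6, 1.5e5),
    stringsAsFactors = FALSE)
}

test_that("design matrices have the documented structure", {
  p <- make_participants(60, n_sites = 3)
  spec <- covariate_spec(p)
  Xc <- build_design(p, spec, "cortical")
  expect_identical(colnames(Xc),
                   c("(Intercept)", "diagnosis", "age", "sex",
                     "site_site2", "site_site3"))
  Xs <- build_design(p, spec, "subcortical")
  expect_identical(colnames(Xs), c(colnames(Xc), "tiv"))
  # age centered at the training mean; sex encoded male = 0, female = 1
  expect_equal(mean(Xc[, "age"]), 0, tolerance = 1e-10)
  expect_equal(unname(Xc[, "sex"]), as.numeric(p$sex == "female"))
  # full rank on random cohorts
  for (seed in 1:5) {
    pp <- make_participants(40, n_sites = 4, seed = seed)
    X <- build_design(pp, covariate_spec(pp), "subcortical")
    expect_equal(qr(X)$rank, ncol(X))
  }
  # unseen site: error by default, mappable to reference on request
  p2 <- p; p2$site[1] <- "siteX"
  expect_error(build_design(p2, spec, "cortical"), "siteX")
  expect_warning(X2 <- build_design(p2, spec, "cortical",
                                    unseen_site = "reference"), "siteX")
  expect_equal(sum(X2[1, grepl("^site_", colnames(X2))]), 0)
})

test_that("a noiseless diagnosis effect is recovered exactly", {
  p <- make_participants(80)
  spec <- covariate_spec(p)
  X <- build_design(p, spec, "cortical")
  y <- drop(X %*% c(2.5, -0.37, 0.01, 0, 0.1, -0.1))
  fit <- fit_region_model(y, X)
  expect_equal(unname(fit$coefficients["diagnosis"]), -0.37, tolerance = 1e-10)
  expect_equal(fit$sigma, 0, tolerance = 1e-8)
})

test_that("a constant outcome gives zero slopes and zero R squared", {
  p <- make_participants(50)
  X <- build_design(p, covariate_spec(p), "cortical")
  fit <- fit_region_model(rep(2.5, 50), X)
  expect_equal(unname(fit$coefficients[-1]), rep(0, ncol(X) - 1),
               tolerance = 1e-10)
  expect_equal(fit$r_squared, 0)
})

test_that("OLS matches the pseudo-inverse oracle on random instances", {
  set.seed(90)
  for (rep in 1:20) {
    n <- 20; k <- 4
    X <- cbind(1, matrix(rnorm(n * (k - 1)), n, k - 1))
    colnames(X) <- c("(Intercept)", paste0("x", 1:(k - 1)))
    y <- rnorm(n)
    fit <- fit_region_model(y, X)
    expect_equal(unname(fit$coefficients), unname(pinv_ols(y, X)),
                 tolerance = 1e-8)
    # residuals orthogonal to every design column
    expect_true(all(abs(crossprod(X, fit$residuals)) < 1e-8))
  }
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  p <- make_participants(40)
  X <- build_design(p, covariate_spec(p), "cortical")
  X <- cbind(X, age_copy = X[, "age"])
  expect_error(fit_region_model(rnorm(40), X), "age_copy")
})

test_that("shifting age translates the intercept but never the diagnosis beta", {
  p <- make_participants(100, seed = 3)
  spec <- covariate_spec(p)
  X <- build_design(p, spec, "cortical")
  set.seed(4)
  y <- drop(X %*% c(2.5, -0.3, -0.01, 0.05, 0.1, -0.1)) + rnorm(100, 0, 0.1)
  fit1 <- fit_region_model(y, X)
  p2 <- p; p2$age <- p$age + 25
  # same spec (same centering constant) -> pure translation of the age column
  X2 <- build_design(p2, spec, "cortical")
  fit2 <- fit_region_model(y, X2)
  expect_equal(fit2$coefficients["diagnosis"], fit1$coefficients["diagnosis"],
               tolerance = 1e-8)
  expect_equal(fit2$coefficients["age"], fit1$coefficients["age"],
               tolerance = 1e-8)
  expect_equal(unname(fit2$coefficients["(Intercept)"]),
               unname(fit1$coefficients["(Intercept)"] -
                        25 * fit1$coefficients["age"]),
               tolerance = 1e-8)
})

test_that("the fitted model set covers all regions with the right designs", {
  cohort <- generate_cohort(small_config(seed = 17))
  ref <- cohort$participants[cohort$participants$group %in% c("HC", "sPD"), ]
  ms <- fit_model_set(ref, cohort$morphometry)
  expect_s3_class(ms, "atrophy_model_set")
  expect_equal(length(ms$beta1), 82L)
  expect_identical(names(ms$beta1), region_registry()$name)
  # TIV coefficient present iff subcortical
  expect_false("tiv" %in% rownames(ms$coefficients$cortical))
  expect_true("tiv" %in% rownames(ms$coefficients$subcortical))
  expect_true(all(is.finite(ms$se_beta1)))
  bm <- diagnosis_beta_map(ms)
  expect_s3_class(bm, "brain_map")
  expect_equal(nrow(bm), 82L)
  expect_identical(attr(bm, "semantics"), "beta")
  expect_equal(nrow(r_squared_map(ms)), 82L)
})

test_that("injected negative effects produce mostly negative diagnosis betas", {
  cohort <- generate_cohort(cohort_config(
    group_sizes = c(HC = 104, sPD = 104), n_sites = 3L, seed = 23))
  ref <- cohort$participants
  ms <- fit_model_set(ref, cohort$morphometry)
  expect_gt(mean(ms$beta1 < 0), 0.5)
  # betas track the injected effects across regions
  expect_gt(cor(ms$beta1, cohort$config$diagnosis_effect), 0.3)
})

test_that("z-scored diagnosis betas are invariant to the native scale", {
  cohort <- generate_cohort(small_config(seed = 29))
  ref <- cohort$participants[cohort$participants$group %in% c("HC", "sPD"), ]
  ms1 <- fit_model_set(ref, cohort$morphometry, zscore = TRUE)
  scaled <- cohort$morphometry
  scaled$lh_lingual_thickness <- scaled$lh_lingual_thickness * 1000
  ms2 <- fit_model_set(ref, scaled, zscore = TRUE)
  expect_equal(ms2$beta1[["lh_lingual_thickness"]],
               ms1$beta1[["lh_lingual_thickness"]], tolerance = 1e-10)
  # in native mode the beta scales with the outcome
  ms3 <- fit_model_set(ref, cohort$morphometry, zscore = FALSE)
  ms4 <- fit_model_set(ref, scaled, zscore = FALSE)
  expect_equal(ms4$beta1[["lh_lingual_thickness"]],
               1000 * ms3$beta1[["lh_lingual_thickness"]], tolerance = 1e-8)
})

test_that("with no injected effect the diagnosis t-test has nominal size", {
  reg <- region_registry()
  null_cfg <- function(seed) cohort_config(
    group_sizes = c(HC = 60, sPD = 60),
    diagnosis_effect = setNames(rep(0, 82), reg$name),
    saa_effect_scale = 0, n_sites = 3L, noise_sd = 1, seed = seed)
  hits <- 0L; total <- 0L
  for (seed in 1:60) {
    cohort <- generate_cohort(null_cfg(seed))
    ms <- fit_model_set(cohort$participants, cohort$morphometry)
    tstat <- ms$beta1 / ms$se_beta1
    df <- ifelse(region_registry()$tissue == "cortical",
                 ms$df_residual["cortical"], ms$df_residual["subcortical"])
    hits <- hits + sum(abs(tstat) > qt(0.975, df))
    total <- total + 82L
  }
  rate <- hits / total
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.075)
})
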