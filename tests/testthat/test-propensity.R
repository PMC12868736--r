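test_that("assignment solver matches the exhaustive oracle on small instances", {
  set.seed(10)
  for (rep in 1:40) {
    nr <- sample(1:5, 1); nc <- sample(1:5, 1)
    cost <- matrix(round(runif(nr * nc), 3), nr, nc)
    sol <- solve_assignment_lsap(cost)
    expect_equal(attr(sol, "total_cost"), brute_force_assignment_cost(cost),
                 tolerance = 1e-12)
    expect_lte(nrow(sol), min(nr, nc))
    expect_false(anyDuplicated(sol$row) > 0)
    expect_false(anyDuplicated(sol$col) > 0)
  }
  # worked 2x2 example: diagonal is optimal
  sol <- solve_assignment_lsap(matrix(c(0.1, 0.3, 0.4, 0.2), 2, 2))
  expect_equal(sol$row, c(1L, 2L))
  expect_equal(sol$col, c(1L, 2L))
  expect_equal(attr(sol, "total_cost"), 0.3)
})

test_that("identical score lists match completely at zero cost", {
  scores <- c(0.2, 0.4, 0.6)
  cost <- build_cost_matrix(scores, scores, Inf)
  sol <- solve_assignment(cost)
  expect_equal(nrow(sol), 3L)
  expect_equal(attr(sol, "total_cost"), 0)
})

test_that("uninformative covariates give prevalence scores and AUC 0.5", {
  set.seed(20)
  n <- 2000
  p <- data.frame(
    participant_id = sprintf("P%04d", 1:n),
    y = rep(c(1, 0), c(600, 1400)),
    age = rnorm(n, 60, 10),
    sex = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  m <- estimate_propensity(p, "y", c("age", "sex"))
  expect_true(all(m$scores > 0 & m$scores < 1))
  expect_equal(length(m$scores), n)
  expect_equal(mean(m$scores), 0.3, tolerance = 0.02)
  # rank-based AUC of scores for the outcome
  auc <- (mean(rank(m$scores)[p$y == 1]) - (601) / 2) / 1400
  expect_equal(auc, 0.5, tolerance = 0.05)
})

test_that("the variant-status model uses exactly the requested terms", {
  cohort <- generate_cohort(small_config(seed = 13))
  pd <- cohort$participants[cohort$participants$group %in%
                              c("sPD", "LRRK2_PD"), ]
  m <- estimate_propensity(pd, "lrrk2_carrier",
                           c("sex", "age", "disease_duration", "site"))
  nms <- names(m$coefficients)
  expect_true("(Intercept)" %in% nms)
  expect_true(all(c("sex", "age", "disease_duration") %in% nms))
  expect_true(any(grepl("^site_", nms)))
  # no morphometry leakage possible
  expect_error(estimate_propensity(pd, "lrrk2_carrier",
                                   c("age", "lh_cuneus_thickness")),
               "morphometry")
})

test_that("a separating covariate yields AUC 1 via the penalized fallback", {
  set.seed(30)
  n <- 80
  p <- data.frame(
    participant_id = sprintf("P%03d", 1:n),
    y = rep(c(1, 0), each = n / 2),
    x = c(rnorm(n / 2, 5), rnorm(n / 2, -5)),
    stringsAsFactors = FALSE)
  expect_warning(m <- estimate_propensity(p, "y", "x"), "separation")
  expect_true(m$penalized)
  expect_true(all(m$scores[p$y == 1] > max(m$scores[p$y == 0])))
})

test_that("cost matrix applies caliper and sentinel correctly", {
  expect_equal(unname(build_cost_matrix(0.2, 0.5, Inf)[1, 1]), 0.3)

  # caliper on the raw scale: all pairwise gaps beyond it become sentinel
  cm <- build_cost_matrix(c(0.1, 0.15), c(0.8, 0.9), 0.05, scale = "raw")
  expect_true(all(cm == attr(cm, "sentinel")))

  # sentinel strictly exceeds any feasible total: n * max_gap bound
  set.seed(40)
  for (rep in 1:20) {
    a <- runif(sample(2:8, 1)); b <- runif(sample(2:8, 1))
    cm <- build_cost_matrix(a, b, 0.5, scale = "raw")
    feas <- cm[cm < attr(cm, "sentinel")]
    if (length(feas) > 0) {
      expect_gt(attr(cm, "sentinel"),
                (length(a) + length(b)) * max(feas))
    }
  }

  expect_error(build_cost_matrix(numeric(0), 0.5, Inf), "non-empty")
})

test_that("SMD has its closed form, detects imbalance, and is scale invariant", {
  expect_equal(compute_smd(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(50)
  a <- as.numeric(scale(rnorm(200)))   # exactly mean 0, sd 1
  b <- a + 1                           # mean 1, sd 1
  expect_equal(compute_smd(a, b), 1.0, tolerance = 1e-12)
  expect_equal(compute_smd(10 * a, 10 * b), compute_smd(a, b),
               tolerance = 1e-12)
  # binary covariates use proportion variance p(1-p)
  x <- rep(c(0, 1), c(30, 70)); y <- rep(c(0, 1), c(70, 30))
  pooled <- sqrt((0.7 * 0.3 + 0.3 * 0.7) / 2)
  expect_equal(compute_smd(x, y), 0.4 / pooled, tolerance = 1e-12)
  # zero pooled SD with unequal means flags infinity
  expect_equal(compute_smd(c(1, 1), c(2, 2)), Inf)
})

test_that("matching two identical groups pairs everyone with zero SMD", {
  set.seed(60)
  base <- data.frame(
    age = rnorm(50, 60, 8),
    sex = sample(c("male", "female"), 50, replace = TRUE),
    site = sample(paste0("site", 1:3), 50, replace = TRUE),
    stringsAsFactors = FALSE)
  p <- rbind(cbind(participant_id = sprintf("A%02d", 1:50), y = 1, base),
             cbind(participant_id = sprintf("B%02d", 1:50), y = 0, base))
  p$y <- as.numeric(p$y)
  m <- match_subgroups(p, "y", c("age", "sex", "site"))
  expect_equal(m$n_matched, 50L)
  expect_true(all(m$balance$smd_after < 1e-8))
  expect_true(all(m$pairs$delta_ps <= 1e-8))
})

test_that("matched pairs respect the caliper and row-order invariance", {
  cohort <- generate_cohort(small_config(seed = 70))
  ref <- cohort$participants[cohort$participants$group %in% c("HC", "sPD"), ]
  m <- match_subgroups(ref, "pd_diagnosis", c("age", "sex", "site"))
  # every retained pair lies within the caliper on the logit scale
  ps <- m$model$scores
  gap <- abs(log(ps[m$pairs$id_A] / (1 - ps[m$pairs$id_A])) -
             log(ps[m$pairs$id_B] / (1 - ps[m$pairs$id_B])))
  expect_true(all(gap <= m$caliper$value + 1e-9))
  expect_true(all(m$pairs$id_A %in% ref$participant_id))
  # permuting input rows leaves the pair set unchanged
  perm <- ref[sample(nrow(ref)), ]
  m2 <- match_subgroups(perm, "pd_diagnosis", c("age", "sex", "site"))
  o1 <- m$pairs[order(m$pairs$id_A), ]
  o2 <- m2$pairs[order(m2$pairs$id_A), ]
  expect_equal(o1$id_A, o2$id_A)
  expect_equal(o1$id_B, o2$id_B)
})

test_that("matched count shrinks monotonically as the caliper tightens", {
  cohort <- generate_cohort(small_config(seed = 80))
  ref <- cohort$participants[cohort$participants$group %in% c("HC", "sPD"), ]
  mult <- c(2, 0.5, 0.1, 0.02, 0.002)
  counts <- vapply(mult, function(k) {
    suppressWarnings(
      match_subgroups(ref, "pd_diagnosis", c("age", "sex", "site"),
                      caliper = caliper_spec(k))$n_matched)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  # an absurdly tight caliper leaves (close to) nothing, with a warning if 0
  expect_lt(counts[length(counts)], counts[1])
})
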