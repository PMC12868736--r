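# Transfer of the fitted atrophy model set to data-poor subgroups.
#
# The reference model's coefficients are frozen: predictions for new
# participants use the stored encodings, centering constants and (if
# enabled) the training-sample z-scale. Deviations are measured - predicted,
# so positive values mean the structure is better preserved than the
# reference PD atrophy model predicts.

#' Predict regional morphometry from a transferred model set
#'
#' Computes the linear prediction of every region for every participant,
#' using each participant's observed diagnosis status and the frozen
#' coefficients of the model set - no parameter is re-estimated.
#'
#' @param model_set An [fit_model_set()] result.
#' @param participants Participants carrying every covariate the model set
#'   needs (`pd_diagnosis`, `age`, `sex`, `site`, `tiv`).
#' @param unseen_site Policy for site levels absent at training: `"error"`
#'   (default) or `"reference"`.
#' @return Numeric matrix (participants x 82 regions, rownames =
#'   participant ids) in model-set units (z units when the model set was
#'   fitted z-scored, native units otherwise).
#' @export
predict_morphometry <- function(model_set, participants,
                                unseen_site = c("error", "reference")) {
  assert_that(inherits(model_set, "atrophy_model_set"),
              "model_set must be an atrophy_model_set")
  unseen_site <- match.arg(unseen_site)
  registry <- model_set$registry
  pred <- matrix(NA_real_, nrow(participants), nrow(registry),
                 dimnames = list(participants$participant_id, registry$name))
  for (tis in c("cortical", "subcortical")) {
    sel <- registry$tissue == tis
    X <- build_design(participants, model_set$spec, tis,
                      unseen_site = unseen_site)
    pred[, sel] <- X %*% model_set$coefficients[[tis]]
  }
  pred
}

#' Express measured morphometry in model-set units
#'
#' Applies the training-sample z-scale stored in the model set (identity
#' when the set was fitted in native units), so measured and predicted
#' values are comparable.
#'
#' @param model_set An [fit_model_set()] result.
#' @param morphometry Morphometry table (`participant_id` + regions).
#' @return Numeric matrix (participants x 82, rownames = participant ids).
#' @export
measured_in_model_units <- function(model_set, morphometry) {
  assert_that(inherits(model_set, "atrophy_model_set"),
              "model_set must be an atrophy_model_set")
  registry <- model_set$registry
  Y <- as.matrix(morphometry[, registry$name, drop = FALSE])
  storage.mode(Y) <- "double"
  rownames(Y) <- morphometry$participant_id
  sweep(sweep(Y, 2, model_set$scale_mean, `-`), 2, model_set$scale_sd, `/`)
}

#' Per-participant and per-region prediction differences
#'
#' Differences are measured - predicted: positive values indicate structure
#' better preserved than the reference atrophy model predicts, negative
#' values indicate atrophy beyond the model's expectation. Differences are
#' averaged across participants within each subgroup to give one value per
#' region per subgroup.
#'
#' @param measured Participants x regions matrix in model-set units
#'   (from [measured_in_model_units()]).
#' @param predicted Participants x regions matrix (from
#'   [predict_morphometry()]); must have identical row and column names.
#' @param groups Character/factor vector of subgroup labels, one per row.
#' @return An object of class `prediction_difference`: list with
#'   `differences` (participant x region matrix), `groups`,
#'   `region_means` (region x subgroup matrix of mean differences).
#' @export
compute_prediction_difference <- function(measured, predicted, groups) {
  assert_that(is.matrix(measured) && is.matrix(predicted),
              "measured and predicted must be matrices")
  assert_that(identical(dim(measured), dim(predicted)),
              "measured and predicted must have identical shape")
  if (!identical(rownames(measured), rownames(predicted))) {
    if (is.null(rownames(measured)) || is.null(rownames(predicted)) ||
        !setequal(rownames(measured), rownames(predicted))) {
      stop("measured and predicted rows are misaligned (participant ids differ)",
           call. = FALSE)
    }
    predicted <- predicted[rownames(measured), , drop = FALSE]
  }
  assert_that(identical(colnames(measured), colnames(predicted)),
              "measured and predicted must share region columns")
  assert_that(length(groups) == nrow(measured),
              "groups must have one label per participant row")
  diffs <- measured - predicted
  groups <- as.character(groups)
  glev <- unique(groups)
  region_means <- vapply(glev, function(g) {
    colMeans(diffs[groups == g, , drop = FALSE])
  }, numeric(ncol(diffs)))
  structure(list(differences = diffs, groups = groups,
                 region_means = region_means),
            class = "prediction_difference")
}

#' @export
print.prediction_difference <- function(x, ...) {
  cat("<prediction_difference>", nrow(x$differences), "participants x",
      ncol(x$differences), "regions\n")
  for (g in colnames(x$region_means)) {
    cat(sprintf("  %-12s n = %3d, mean deviation %+0.4f\n", g,
                sum(x$groups == g), mean(x$region_means[, g])))
  }
  invisible(x)
}

#' Test a subgroup difference in prediction deviations
#'
#' The unit of analysis is the per-region subgroup mean difference (82
#' values per subgroup). The default is a two-sample Welch t-test between
#' the two subgroups' region-mean vectors; `family = "paired"` pairs the
#' regions across subgroups instead. Two-sided p-values.
#'
#' @param pd A [compute_prediction_difference()] result.
#' @param group_A,group_B Subgroup labels present in `pd`.
#' @param family `"two_sample"` (default) or `"paired"`.
#' @return A list of class `group_difference_test`: `statistic`, `p_value`,
#'   `family`, `n_regions`, `mean_A`, `mean_B`, `estimate`
#'   (mean_A - mean_B), `n_participants` (per side).
#' @export
test_group_difference <- function(pd, group_A, group_B,
                                  family = c("two_sample", "paired")) {
  family <- match.arg(family)
  assert_that(inherits(pd, "prediction_difference"),
              "pd must be a prediction_difference")
  for (g in c(group_A, group_B)) {
    assert_that(g %in% colnames(pd$region_means),
                paste("subgroup not present:", g))
  }
  assert_that(sum(pd$groups == group_A) >= 2 && sum(pd$groups == group_B) >= 2,
              "need at least 2 participants per side")
  a <- pd$region_means[, group_A]
  b <- pd$region_means[, group_B]
  if (isTRUE(all.equal(a, b, tolerance = 0))) {
    # degenerate: identical region means; t is 0/0 under paired testing
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(a, b, paired = (family == "paired"),
                        var.equal = FALSE)
  }
  structure(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                 family = family, n_regions = length(a),
                 mean_A = mean(a), mean_B = mean(b),
                 estimate = mean(a) - mean(b),
                 n_participants = c(A = sum(pd$groups == group_A),
                                    B = sum(pd$groups == group_B)),
                 groups = c(group_A, group_B)),
            class = "group_difference_test")
}

#' @export
print.group_difference_test <- function(x, ...) {
  cat(sprintf("<group_difference_test> %s vs %s (%s, %d regions)\n",
              x$groups[1], x$groups[2], x$family, x$n_regions))
  cat(sprintf("  mean deviation %+.4f vs %+.4f; t = %.3f, p = %.3g\n",
              x$mean_A, x$mean_B, x$statistic, x$p_value))
  invisible(x)
}

#' Preservation map of a subgroup
#'
#' The 82-entry brain map of a subgroup's mean prediction differences.
#' Positive entries mean less thinning or volume loss than the reference
#' atrophy model predicts; negative entries mean increased atrophy.
#'
#' @param pd A [compute_prediction_difference()] result.
#' @param group Subgroup label.
#' @return A [brain_map()] with `prediction_difference` semantics.
#' @export
preservation_map <- function(pd, group) {
  assert_that(inherits(pd, "prediction_difference"),
              "pd must be a prediction_difference")
  assert_that(group %in% colnames(pd$region_means),
              paste("subgroup not present:", group))
  brain_map(pd$region_means[, group], "prediction_difference")
}
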