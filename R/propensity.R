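# Propensity-score estimation, caliper-modified cost matrices, optimal
# assignment matching, and covariate balance diagnostics.
#
# The propensity score PS = P(y = 1 | C) is fitted by logistic regression of
# a binary group indicator on background covariates only (never morphometry),
# and used as a one-dimensional balancing index: participants from the two
# groups are paired by minimum-cost one-to-one assignment on |dPS|, with
# pairs further apart than the caliper excluded.

#' Caliper specification
#'
#' The caliper is the maximum allowed propensity-score distance for a pair
#' to be matchable. The default follows standard practice: 0.2 times the
#' standard deviation of the logit of the propensity score, applied on the
#' logit scale. A fixed caliper on the raw probability scale is also
#' supported.
#'
#' @param multiplier Caliper width; with `relative = TRUE` interpreted as a
#'   multiple of the SD of the (logit) PS, otherwise as an absolute
#'   distance.
#' @param scale `"logit"` (default) or `"raw"`: the scale on which the
#'   caliper distance is measured.
#' @param relative If `TRUE` (default), `multiplier` scales the SD of the
#'   PS on `scale`.
#' @return An object of class `caliper_spec`.
#' @export
#' @examples
#' caliper_spec()                      # 0.2 x SD(logit PS), the default
#' caliper_spec(0.1, "raw", FALSE)     # fixed width 0.1 on the PS scale
caliper_spec <- function(multiplier = 0.2, scale = c("logit", "raw"),
                         relative = TRUE) {
  scale <- match.arg(scale)
  assert_that(is.numeric(multiplier) && length(multiplier) == 1 &&
                (multiplier > 0 || is.infinite(multiplier)),
              "caliper multiplier must be positive (or Inf)")
  structure(list(multiplier = multiplier, scale = scale, relative = relative),
            class = "caliper_spec")
}

#' @keywords internal
resolve_caliper <- function(spec, scores) {
  if (!inherits(spec, "caliper_spec")) {
    if (is.numeric(spec) && length(spec) == 1) {
      spec <- caliper_spec(spec)
    } else {
      stop("caliper_spec must be a caliper_spec object or a single number",
           call. = FALSE)
    }
  }
  if (!spec$relative) return(list(value = spec$multiplier, scale = spec$scale))
  s <- if (spec$scale == "logit") stats::sd(logit(scores)) else stats::sd(scores)
  if (!is.finite(s) || s == 0) s <- 1e-12   # degenerate: all scores equal
  list(value = spec$multiplier * s, scale = spec$scale)
}

# Ridge-penalized logistic fit by IRLS (penalty excludes the intercept).
# Fallback when the ML fit separates; penalty 1e-4 barely perturbs
# coefficients but keeps them finite.
#' @keywords internal
ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(rep(lambda, p))
  pen[1, 1] <- 0
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- inv_logit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

#' @keywords internal
.ps_design <- function(participants, covariates) {
  n <- nrow(participants)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    v <- participants[[cv]]
    if (cv == "sex") {
      # PS convention: female = 0, male = 1
      X <- cbind(X, sex = as.numeric(v == "male"))
    } else if (cv == "site" || is.character(v) || is.factor(v)) {
      f <- factor(v)
      if (nlevels(f) > 1) {
        d <- stats::model.matrix(~ f)[, -1, drop = FALSE]
        colnames(d) <- paste0(cv, "_", levels(f)[-1])
        X <- cbind(X, d)
      }
    } else {
      Xc <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, cv))
      X <- cbind(X, Xc)
    }
  }
  X
}

#' Estimate propensity scores by logistic regression
#'
#' Fits PS = P(y = 1 | C) by maximum-likelihood logistic regression of a
#' binary outcome column on the requested covariates. Sex is encoded
#' female = 0 / male = 1 and site levels become indicator variables.
#' Participants with a missing value in any covariate are excluded from the
#' fit (and reported); morphometry columns are never admitted as
#' covariates. If the fit separates (fitted probabilities of 0/1), a
#' ridge-penalized fit (penalty 1e-4) is used instead and a warning is
#' issued.
#'
#' @param participants Participant data.frame.
#' @param outcome Name of a binary (0/1) column, e.g. `pd_diagnosis` or
#'   `lrrk2_carrier`.
#' @param covariates Character vector of covariate column names.
#' @return An object of class `propensity_model` with elements
#'   `coefficients`, `scores` (named by participant_id, in (0,1)),
#'   `outcome`, `covariates`, `dropped_ids`, `penalized`.
#' @export
estimate_propensity <- function(participants, outcome, covariates) {
  assert_that(outcome %in% names(participants),
              paste("outcome column not found:", outcome))
  bad <- grep("(_thickness|_volume)$", covariates, value = TRUE)
  if (length(bad) > 0) {
    stop("morphometry columns may not be used as propensity covariates: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  missing_cov <- setdiff(covariates, names(participants))
  if (length(missing_cov) > 0) {
    stop("covariate column(s) not found: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  y_all <- participants[[outcome]]
  assert_that(all(y_all %in% c(0, 1)), "outcome must be binary 0/1")
  complete <- stats::complete.cases(participants[, covariates, drop = FALSE]) &
    !is.na(y_all)
  dropped <- participants$participant_id[!complete]
  dat <- participants[complete, , drop = FALSE]
  y <- as.numeric(dat[[outcome]])
  assert_that(length(unique(y)) == 2,
              "outcome is constant among participants with complete covariates")

  X <- .ps_design(dat, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    X <- X[, sort(keep), drop = FALSE]
  }

  penalized <- FALSE
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())
  )
  mu <- fit$fitted.values
  eps <- 1e-8
  if (!fit$converged || any(mu < eps) || any(mu > 1 - eps) ||
      any(abs(stats::coef(fit)) > 15)) {
    warning("propensity fit shows (quasi-)separation; using ridge-penalized fit (penalty 1e-4)",
            call. = FALSE)
    beta <- ridge_logistic(X, y)
    mu <- inv_logit(drop(X %*% beta))
    penalized <- TRUE
  } else {
    beta <- stats::coef(fit)
  }
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  names(mu) <- dat$participant_id

  structure(list(coefficients = beta, scores = mu, outcome = outcome,
                 covariates = covariates, dropped_ids = dropped,
                 penalized = penalized),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("<propensity_model> outcome:", x$outcome, "\n")
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat("  n scored:", length(x$scores), " dropped:", length(x$dropped_ids),
      if (x$penalized) " [ridge-penalized]" else "", "\n")
  invisible(x)
}

#' Build the caliper-modified assignment cost matrix
#'
#' Entry (i, j) is `|PS_A[i] - PS_B[j]|` when the pair lies within the
#' caliper, and a sentinel cost otherwise. The sentinel,
#' `(n_A + n_B) * (max finite gap + 1)`, is strictly larger than any
#' feasible total cost, so the optimal assignment uses sentinel pairs only
#' when unavoidable; such pairs are discarded after solving.
#'
#' @param scores_A,scores_B Numeric PS vectors for the two sides.
#' @param caliper Caliper width (a positive number, possibly `Inf`).
#' @param scale Scale on which the caliper distance is measured: `"logit"`
#'   (default) or `"raw"`. Costs themselves are always raw `|dPS|`.
#' @return A numeric `length(scores_A) x length(scores_B)` matrix with
#'   attributes `sentinel` and `caliper`.
#' @export
build_cost_matrix <- function(scores_A, scores_B, caliper,
                              scale = c("logit", "raw")) {
  scale <- match.arg(scale)
  assert_that(length(scores_A) > 0 && length(scores_B) > 0,
              "both score vectors must be non-empty")
  assert_that(is.numeric(caliper) && length(caliper) == 1 && caliper > 0,
              "caliper must be positive (or Inf)")
  cost <- abs(outer(scores_A, scores_B, `-`))
  dist <- if (scale == "logit") {
    abs(outer(logit(scores_A), logit(scores_B), `-`))
  } else {
    cost
  }
  feasible <- dist <= caliper
  max_gap <- if (any(feasible)) max(cost[feasible]) else 1
  sentinel <- (length(scores_A) + length(scores_B)) * (max_gap + 1)
  cost[!feasible] <- sentinel
  attr(cost, "sentinel") <- sentinel
  attr(cost, "caliper") <- caliper
  attr(cost, "caliper_scale") <- scale
  cost
}

#' Solve the assignment problem on a caliper-modified cost matrix
#'
#' Runs the Hungarian algorithm on the cost matrix and discards any
#' assigned pair whose cost equals the sentinel, implementing the rule that
#' only pairs within the caliper are matched. Costs are rounded at 1e-12
#' before solving so that floating-point ties break deterministically.
#'
#' @param cost Cost matrix from [build_cost_matrix()] (or any numeric
#'   matrix; without a `sentinel` attribute no pairs are discarded).
#' @return A data.frame with columns `row`, `col`, `cost` of retained
#'   pairs; attribute `total_cost` is the total over retained pairs.
#' @export
solve_assignment <- function(cost) {
  sentinel <- attr(cost, "sentinel")
  sol <- solve_assignment_lsap(round(cost, 12))
  if (!is.null(sentinel)) {
    keep <- sol$cost < sentinel - 1e-9
    sol <- sol[keep, , drop = FALSE]
    rownames(sol) <- NULL
  }
  attr(sol, "total_cost") <- sum(sol$cost)
  sol
}

#' Standardized mean difference
#'
#' `|mean_A - mean_B| / SD_pooled` with `SD_pooled = sqrt((var_A + var_B)/2)`.
#' For binary covariates the proportion variance p(1-p) is used in place of
#' the sample variance. Returns `Inf` when the pooled SD is zero but the
#' means differ, and 0 when both are identical constants.
#'
#' @param values_A,values_B Non-empty numeric vectors (missing values are
#'   dropped).
#' @param binary Treat inputs as binary 0/1. Default: autodetect.
#' @return A non-negative scalar.
#' @export
compute_smd <- function(values_A, values_B, binary = NULL) {
  values_A <- values_A[!is.na(values_A)]
  values_B <- values_B[!is.na(values_B)]
  assert_that(length(values_A) > 0 && length(values_B) > 0,
              "both sides must contain non-missing values")
  if (is.null(binary)) {
    binary <- all(c(values_A, values_B) %in% c(0, 1))
  }
  mA <- mean(values_A); mB <- mean(values_B)
  if (binary) {
    vA <- mA * (1 - mA); vB <- mB * (1 - mB)
  } else {
    vA <- if (length(values_A) > 1) stats::var(values_A) else 0
    vB <- if (length(values_B) > 1) stats::var(values_B) else 0
  }
  pooled <- sqrt((vA + vB) / 2)
  d <- abs(mA - mB)
  if (pooled == 0) return(if (d == 0) 0 else Inf)
  d / pooled
}

#' @keywords internal
.balance_covariate_values <- function(participants, covariates) {
  out <- list()
  for (cv in covariates) {
    v <- participants[[cv]]
    if (cv == "sex") {
      out[["sex"]] <- as.numeric(v == "male")
    } else if (is.character(v) || is.factor(v)) {
      f <- factor(v)
      for (lv in levels(f)) {
        out[[paste0(cv, "_", lv)]] <- as.numeric(f == lv)
      }
    } else {
      out[[cv]] <- as.numeric(v)
    }
  }
  out
}

#' Match two subgroups on propensity scores
#'
#' End-to-end matching: estimates propensity scores for the binary
#' `outcome`, derives the caliper, builds the caliper-modified cost matrix
#' between the outcome = 1 (side A) and outcome = 0 (side B) participants,
#' solves the optimal one-to-one assignment, discards pairs beyond the
#' caliper, and reports covariate balance before and after matching.
#' Participants are sorted by id before matching so the result is invariant
#' to input row order.
#'
#' @param participants Participant data.frame containing both groups.
#' @param outcome Binary column defining the two sides.
#' @param covariates Covariates for the propensity model.
#' @param caliper A [caliper_spec()] (default 0.2 x SD of logit PS) or a
#'   single number (relative logit-scale multiplier).
#' @return An object of class `matched_pairs`: list with `pairs`
#'   (data.frame `id_A`, `id_B`, `delta_ps`), `unmatched_A`, `unmatched_B`,
#'   `caliper` (resolved value, scale and spec), `balance` (data.frame of
#'   per-covariate SMD before/after), `model` (the `propensity_model`),
#'   `n_matched`.
#' @export
match_subgroups <- function(participants, outcome, covariates,
                            caliper = caliper_spec()) {
  model <- estimate_propensity(participants, outcome, covariates)
  scores <- model$scores
  ids <- names(scores)
  dat <- participants[match(ids, participants$participant_id), , drop = FALSE]
  y <- dat[[outcome]]
  assert_that(sum(y == 1) > 0 && sum(y == 0) > 0,
              "both outcome groups must be non-empty after dropping incomplete rows")

  # deterministic order: sort each side by participant id
  idx_A <- order(dat$participant_id[y == 1])
  idx_B <- order(dat$participant_id[y == 0])
  ids_A <- dat$participant_id[y == 1][idx_A]
  ids_B <- dat$participant_id[y == 0][idx_B]
  ps_A <- scores[ids_A]
  ps_B <- scores[ids_B]

  cal <- resolve_caliper(caliper, scores)
  cost <- build_cost_matrix(ps_A, ps_B, cal$value, cal$scale)
  sol <- solve_assignment(cost)

  pairs <- data.frame(id_A = ids_A[sol$row], id_B = ids_B[sol$col],
                      delta_ps = sol$cost, stringsAsFactors = FALSE)
  matched_ids <- c(pairs$id_A, pairs$id_B)

  cov_vals <- .balance_covariate_values(dat, covariates)
  in_A <- dat$participant_id %in% ids_A
  in_B <- dat$participant_id %in% ids_B
  m_A <- dat$participant_id %in% pairs$id_A
  m_B <- dat$participant_id %in% pairs$id_B
  balance <- do.call(rbind, lapply(names(cov_vals), function(nm) {
    v <- cov_vals[[nm]]
    data.frame(covariate = nm,
               smd_before = compute_smd(v[in_A], v[in_B]),
               smd_after = if (nrow(pairs) > 0) {
                 compute_smd(v[m_A], v[m_B])
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))

  out <- structure(list(
    pairs = pairs,
    unmatched_A = setdiff(ids_A, pairs$id_A),
    unmatched_B = setdiff(ids_B, pairs$id_B),
    caliper = list(value = cal$value, scale = cal$scale,
                   spec = if (inherits(caliper, "caliper_spec")) caliper
                          else caliper_spec(caliper)),
    balance = balance, model = model,
    n_matched = nrow(pairs),
    n_A = length(ids_A), n_B = length(ids_B)
  ), class = "matched_pairs")
  if (nrow(pairs) == 0) {
    warning("no pairs within the caliper: matched set is empty", call. = FALSE)
  }
  out
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat("<matched_pairs>", x$n_matched, "pairs from",
      x$n_A, "x", x$n_B, "participants\n")
  cat(sprintf("  caliper: %.4g on the %s scale\n",
              x$caliper$value, x$caliper$scale))
  if (nrow(x$balance) > 0) {
    cat("  balance (SMD before -> after):\n")
    for (i in seq_len(nrow(x$balance))) {
      cat(sprintf("    %-16s %.3f -> %.3f\n", x$balance$covariate[i],
                  x$balance$smd_before[i], x$balance$smd_after[i]))
    }
  }
  invisible(x)
}

#' Participant ids retained by a matching
#' @param matched A `matched_pairs` object.
#' @return Character vector of matched ids (both sides).
#' @export
matched_ids <- function(matched) {
  assert_that(inherits(matched, "matched_pairs"),
              "matched must be a matched_pairs object")
  c(matched$pairs$id_A, matched$pairs$id_B)
}
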