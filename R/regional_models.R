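# Per-region linear atrophy models fitted on the matched reference sample.
#
# Each of the 82 regions gets an ordinary least-squares model
#   Y = b1*diagnosis + b2*age + b3*sex + b4*site (+ b5*TIV, subcortical only)
# with an explicit intercept and indicator-coded site against a reference
# level. The diagnosis coefficient b1 is the quantity of interest: its
# 82-vector is the transferable PD atrophy map.

#' Covariate specification for the regional models
#'
#' Captures the encodings and centering constants shared by all 82 models:
#' the site levels seen at training (first level = reference), the age
#' center, the TIV standardization constants, and the sex encoding used in
#' the linear models (male = 0, female = 1; note this is deliberately the
#' reverse of the propensity-score convention, both being fixed
#' conventions of their respective model families - the diagnosis
#' coefficient is unaffected by either choice).
#'
#' @param participants Reference-sample participant data.frame.
#' @return An object of class `covariate_spec`.
#' @export
covariate_spec <- function(participants) {
  assert_that(all(c("pd_diagnosis", "age", "sex", "site", "tiv") %in%
                    names(participants)),
              "participants must carry pd_diagnosis, age, sex, site, tiv")
  site_levels <- sort(unique(as.character(participants$site)))
  tiv_sd <- stats::sd(participants$tiv)
  structure(list(
    site_levels = site_levels,
    age_center = mean(participants$age),
    tiv_center = mean(participants$tiv),
    tiv_scale = if (is.finite(tiv_sd) && tiv_sd > 0) tiv_sd else 1,
    sex_encoding = c(male = 0, female = 1)
  ), class = "covariate_spec")
}

#' Build the design matrix for the regional models
#'
#' Columns: intercept, diagnosis, age (centered at the training mean), sex
#' (male = 0, female = 1), one indicator per non-reference site level, and,
#' for subcortical models, standardized TIV.
#'
#' @param participants Participant data.frame.
#' @param spec A [covariate_spec()].
#' @param tissue `"cortical"` or `"subcortical"` (adds the TIV column).
#' @param unseen_site Policy for site levels absent from `spec`:
#'   `"error"` (default) or `"reference"` (map to the reference level with
#'   a warning).
#' @return Numeric design matrix with named columns.
#' @export
build_design <- function(participants, spec,
                         tissue = c("cortical", "subcortical"),
                         unseen_site = c("error", "reference")) {
  tissue <- match.arg(tissue)
  unseen_site <- match.arg(unseen_site)
  assert_that(inherits(spec, "covariate_spec"),
              "spec must be a covariate_spec object")
  n <- nrow(participants)
  site <- as.character(participants$site)
  unseen <- setdiff(unique(site), spec$site_levels)
  if (length(unseen) > 0) {
    if (unseen_site == "error") {
      stop("site level(s) unseen at training: ",
           paste(unseen, collapse = ", "),
           " (set unseen_site = \"reference\" to map them to the reference level)",
           call. = FALSE)
    }
    warning("mapping unseen site level(s) to the reference level: ",
            paste(unseen, collapse = ", "), call. = FALSE)
    site[site %in% unseen] <- spec$site_levels[1]
  }
  X <- cbind(
    `(Intercept)` = rep(1, n),
    diagnosis = as.numeric(participants$pd_diagnosis),
    age = as.numeric(participants$age) - spec$age_center,
    sex = spec$sex_encoding[as.character(participants$sex)]
  )
  if (any(is.na(X[, "sex"]))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  for (lv in spec$site_levels[-1]) {
    X <- cbind(X, as.numeric(site == lv))
    colnames(X)[ncol(X)] <- paste0("site_", lv)
  }
  if (tissue == "subcortical") {
    X <- cbind(X, tiv = (as.numeric(participants$tiv) - spec$tiv_center) /
                 spec$tiv_scale)
  }
  rownames(X) <- participants$participant_id
  X
}

#' Fit a single region model by ordinary least squares
#'
#' @param y Numeric outcome vector (regional morphometry, any units).
#' @param design Design matrix (with intercept) from [build_design()] or
#'   any full-rank numeric matrix; `nrow > ncol` required.
#' @return A list of class `region_model`: `coefficients`, `se`,
#'   `sigma` (residual SD), `r_squared`, `n`, `df_residual`, `fitted`,
#'   `residuals`.
#' @export
fit_region_model <- function(y, design) {
  assert_that(is.numeric(y) && all(is.finite(y)), "y must be finite numeric")
  assert_that(is.matrix(design) && nrow(design) == length(y),
              "design must be a matrix with one row per outcome value")
  n <- nrow(design); p <- ncol(design)
  assert_that(n > p, "need more observations than model parameters")
  qrX <- qr(design)
  if (qrX$rank < p) {
    collinear <- colnames(design)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(collinear, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qrX, y)
  fitted <- drop(design %*% coef)
  res <- y - fitted
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qrX)[, order(qrX$pivot), drop = FALSE])
  se <- sqrt(pmax(sigma2 * diag(xtx_inv), 0))
  names(se) <- names(coef)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  structure(list(coefficients = coef, se = se, sigma = sqrt(sigma2),
                 r_squared = r2, n = n, df_residual = n - p,
                 fitted = fitted, residuals = res),
            class = "region_model")
}

#' Fit the full 82-region atrophy model set
#'
#' Fits one OLS model per region on the matched reference sample. Cortical
#' regions share one design (no TIV), subcortical regions share another
#' (with standardized TIV). By default each region's outcome is z-scored
#' using the reference sample's mean and SD; those constants are stored in
#' the model set so that transfer to new participants uses the training
#' scale and never peeks at target-group statistics.
#'
#' @param participants Matched reference participants (both diagnosis
#'   groups).
#' @param morphometry Morphometry table covering those participants.
#' @param registry Region registry (default [region_registry()]).
#' @param zscore Z-score each region's outcome with reference-sample
#'   mean/SD (default `TRUE`; `FALSE` fits in native units).
#' @param provenance Optional list recorded verbatim (matched ids, seed).
#' @return An object of class `atrophy_model_set`: per-tissue coefficient
#'   matrices, per-region `beta1` (diagnosis), `se_beta1`, `sigma`,
#'   `r_squared`, the `covariate_spec`, scaling metadata and provenance.
#' @export
fit_model_set <- function(participants, morphometry,
                          registry = region_registry(), zscore = TRUE,
                          provenance = list()) {
  validate_registry(registry)
  assert_that(all(participants$participant_id %in% morphometry$participant_id),
              "every participant needs a morphometry row")
  rows <- match(participants$participant_id, morphometry$participant_id)
  Y <- as.matrix(morphometry[rows, registry$name, drop = FALSE])
  storage.mode(Y) <- "double"

  scale_mean <- rep(0, nrow(registry))
  scale_sd <- rep(1, nrow(registry))
  names(scale_mean) <- names(scale_sd) <- registry$name
  if (zscore) {
    scale_mean[] <- colMeans(Y)
    scale_sd[] <- apply(Y, 2, stats::sd)
    scale_sd[scale_sd == 0 | !is.finite(scale_sd)] <- 1
    Y <- sweep(sweep(Y, 2, scale_mean, `-`), 2, scale_sd, `/`)
  }

  spec <- covariate_spec(participants)
  fits <- list()
  beta1 <- se_beta1 <- sigma <- r2 <- rep(NA_real_, nrow(registry))
  names(beta1) <- names(se_beta1) <- names(sigma) <- names(r2) <- registry$name
  coefs <- list()
  for (tis in c("cortical", "subcortical")) {
    sel <- registry$tissue == tis
    X <- build_design(participants, spec, tis)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      collinear <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop(sprintf("rank-deficient %s design; collinear column(s): %s",
                   tis, paste(collinear, collapse = ", ")), call. = FALSE)
    }
    cf <- qr.coef(qrX, Y[, sel, drop = FALSE])
    res <- Y[, sel, drop = FALSE] - X %*% cf
    dfres <- nrow(X) - ncol(X)
    assert_that(dfres > 0, "need more matched participants than parameters")
    s2 <- colSums(res^2) / dfres
    xtx_inv <- chol2inv(qr.R(qrX)[, order(qrX$pivot), drop = FALSE])
    tss <- colSums(sweep(Y[, sel, drop = FALSE], 2,
                         colMeans(Y[, sel, drop = FALSE]), `-`)^2)
    coefs[[tis]] <- cf
    beta1[sel] <- cf["diagnosis", ]
    se_beta1[sel] <- sqrt(s2 * xtx_inv[2, 2])
    sigma[sel] <- sqrt(s2)
    r2[sel] <- ifelse(tss > 0, 1 - colSums(res^2) / tss, 0)
  }

  structure(list(
    coefficients = coefs, beta1 = beta1, se_beta1 = se_beta1,
    sigma = sigma, r_squared = r2,
    spec = spec, registry = registry, zscore = zscore,
    scale_mean = scale_mean, scale_sd = scale_sd,
    n = nrow(participants),
    df_residual = c(cortical = nrow(participants) - nrow(coefs[["cortical"]]),
                    subcortical = nrow(participants) -
                      nrow(coefs[["subcortical"]])),
    provenance = provenance
  ), class = "atrophy_model_set")
}

#' @export
print.atrophy_model_set <- function(x, ...) {
  cat("<atrophy_model_set>", length(x$beta1), "region models, n =", x$n, "\n")
  cat(sprintf("  diagnosis beta: median %.3f (%.3f .. %.3f), %d%% negative\n",
              stats::median(x$beta1), min(x$beta1), max(x$beta1),
              round(100 * mean(x$beta1 < 0))))
  cat("  outcome scale:", if (x$zscore) "z-scored (training mean/SD)"
      else "native units", "\n")
  invisible(x)
}

#' Diagnosis-coefficient brain map of a model set
#' @param model_set An [fit_model_set()] result.
#' @return A [brain_map()] of the 82 diagnosis coefficients.
#' @export
diagnosis_beta_map <- function(model_set) {
  assert_that(inherits(model_set, "atrophy_model_set"),
              "model_set must be an atrophy_model_set")
  brain_map(model_set$beta1, "beta")
}

#' Explained-variance brain map of a model set
#' @param model_set An [fit_model_set()] result.
#' @return A [brain_map()] of per-region R-squared values.
#' @export
r_squared_map <- function(model_set) {
  assert_that(inherits(model_set, "atrophy_model_set"),
              "model_set must be an atrophy_model_set")
  brain_map(model_set$r_squared, "r_squared")
}
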