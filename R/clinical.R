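# Clinical and genetic associations of the transferred morphometry
# estimates: global and region-wise Pearson correlations with UPDRS III,
# MoCA and PRS, partial correlation controlling the first 10 genetic
# principal components, and Benjamini-Hochberg FDR control.

#' Pearson correlation with a two-sided p-value
#' @keywords internal
.pearson_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= 3, "need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Global correlation of a clinical score with mean predicted morphometry
#'
#' Averages each participant's predicted morphometry over all regions and
#' correlates the average with the requested clinical score (Pearson,
#' two-sided). The structural quantity defaults to the model predictions;
#' `values` can supply measured or deviation matrices instead.
#'
#' @param predictions Participants x regions matrix (rownames = ids), e.g.
#'   from [predict_morphometry()].
#' @param participants Participant data.frame carrying the score column.
#' @param score Column name: `"updrs3"`, `"moca"` or `"prs"` (any numeric
#'   column is accepted).
#' @return A data.frame of class `association_result` with one row:
#'   `variable`, `scope`, `r`, `p`, `n`.
#' @export
correlate_global <- function(predictions, participants, score) {
  assert_that(score %in% names(participants),
              paste("score column not found:", score))
  ids <- intersect(rownames(predictions), participants$participant_id)
  assert_that(length(ids) >= 3, "need at least 3 participants")
  avg <- rowMeans(predictions[ids, , drop = FALSE])
  sc <- participants[[score]][match(ids, participants$participant_id)]
  res <- .pearson_test(avg, sc)
  out <- data.frame(variable = score, scope = "global",
                    r = res$r, p = res$p, n = res$n,
                    stringsAsFactors = FALSE)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Region-wise correlations of clinical scores with predicted morphometry
#'
#' One Pearson correlation per region per score. FDR q-values are attached
#' over the whole family of `n_regions x n_scores` tests
#' (Benjamini-Hochberg).
#'
#' @param predictions Participants x regions matrix (rownames = ids).
#' @param participants Participant data.frame.
#' @param scores Character vector of score columns (default
#'   `c("updrs3", "moca", "prs")`).
#' @return A data.frame of class `association_result`: `variable`, `scope`
#'   (region name), `r`, `p`, `q`, `n`; `n_regions x n_scores` rows.
#' @export
correlate_regional <- function(predictions, participants,
                               scores = c("updrs3", "moca", "prs")) {
  ids <- intersect(rownames(predictions), participants$participant_id)
  assert_that(length(ids) >= 3, "need at least 3 participants")
  P <- predictions[ids, , drop = FALSE]
  rows <- list()
  for (score in scores) {
    assert_that(score %in% names(participants),
                paste("score column not found:", score))
    sc <- participants[[score]][match(ids, participants$participant_id)]
    for (region in colnames(P)) {
      res <- .pearson_test(P[, region], sc)
      rows[[length(rows) + 1L]] <-
        data.frame(variable = score, scope = region,
                   r = res$r, p = res$p, n = res$n,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Partial correlation controlling for covariates
#'
#' Correlation of the residuals of `x` and `y` after each is linearly
#' regressed (with intercept) on the covariates. The p-value uses the t
#' distribution with `n - 2 - k` degrees of freedom, `k` the number of
#' covariates. With an empty covariate set this reduces exactly to the
#' plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix/data.frame with `length(x)` rows, or
#'   `NULL` for none.
#' @return A list with `r`, `p`, `n`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  if (is.null(covariates) || NCOL(covariates) == 0) {
    Z <- NULL
    k <- 0L
    ok <- !is.na(x) & !is.na(y)
  } else {
    Z <- as.matrix(covariates)
    assert_that(nrow(Z) == length(x),
                "covariates must have one row per observation")
    k <- ncol(Z)
    ok <- !is.na(x) & !is.na(y) & stats::complete.cases(Z)
    Z <- Z[ok, , drop = FALSE]
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n > k + 2, "need n > n_covariates + 2 observations")
  sx0 <- stats::sd(x); sy0 <- stats::sd(y)
  if (!is.null(Z)) {
    D <- cbind(1, Z)
    if (qr(D)$rank < ncol(D)) {
      stop("rank-deficient covariate matrix", call. = FALSE)
    }
    x <- stats::lm.fit(D, x)$residuals
    y <- stats::lm.fit(D, y)$residuals
  }
  # degenerate: a residual that is numerically zero relative to the input
  # scale (e.g. y identical to a covariate) has no defined correlation
  if (stats::sd(x) <= 1e-10 * max(sx0, 1e-300) ||
      stats::sd(y) <= 1e-10 * max(sy0, 1e-300)) {
    return(list(r = NA_real_, p = NA_real_, n = n, df = n - 2L - k))
  }
  r <- stats::cor(x, y)
  df <- n - 2L - k
  tt <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df)
  list(r = r, p = p, n = n, df = df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, monotone in the p-value ranks and capped at
#' 1; `NA` p-values are passed through.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
fdr_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Run the standard clinical/genetic association battery
#'
#' Global and region-wise Pearson correlations of predicted morphometry
#' with UPDRS III and MoCA, and a partial correlation with PRS controlling
#' the first 10 genetic principal components. Global p-values are
#' FDR-adjusted as a 3-test family; regional q-values span the
#' `n_regions x 3` family.
#'
#' @param predictions Participants x regions matrix (rownames = ids).
#' @param participants Participant data.frame with `updrs3`, `moca`, `prs`
#'   and `pc1` .. `pc10` columns.
#' @param n_pcs Number of genetic PCs to control in the PRS analysis.
#' @return A list with `global` (data.frame: variable, r, p, q, n,
#'   controlled) and `regional` (the [correlate_regional()] table).
#' @export
clinical_associations <- function(predictions, participants, n_pcs = 10L) {
  ids <- intersect(rownames(predictions), participants$participant_id)
  P <- predictions[ids, , drop = FALSE]
  dat <- participants[match(ids, participants$participant_id), , drop = FALSE]
  avg <- rowMeans(P)

  res_updrs <- .pearson_test(avg, dat$updrs3)
  res_moca <- .pearson_test(avg, dat$moca)
  pc_cols <- paste0("pc", seq_len(n_pcs))
  assert_that(all(pc_cols %in% names(dat)),
              "participants must carry the genetic PC columns")
  res_prs <- partial_correlation(avg, dat$prs, dat[, pc_cols, drop = FALSE])

  global <- data.frame(
    variable = c("updrs3", "moca", "prs"),
    r = c(res_updrs$r, res_moca$r, res_prs$r),
    p = c(res_updrs$p, res_moca$p, res_prs$p),
    n = c(res_updrs$n, res_moca$n, res_prs$n),
    controlled = c("", "", paste(pc_cols, collapse = ",")),
    stringsAsFactors = FALSE
  )
  global$q <- fdr_adjust(global$p)

  regional <- correlate_regional(P, dat, scores = c("updrs3", "moca", "prs"))
  list(global = global, regional = regional)
}
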