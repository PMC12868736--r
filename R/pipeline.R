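# End-to-end orchestration: reference model extraction (matched sPD vs HC),
# transfer of the frozen model to the three data-poor contrasts, spatial
# comparison of the preservation pattern with the atrophy pattern, and the
# clinical/genetic association battery. One top-level seed fans out to
# per-stage seeds (stage k gets seed*100 + k, modulo 2^31 - 1).

#' Built-in comparison specifications
#'
#' The three transfer contrasts the pipeline runs after the reference fit:
#' LRRK2 PD vs sPD (propensity covariates sex, age, disease duration,
#' site), LRRK2 NMC vs HC (sex, age, site), and SAA-positive vs
#' SAA-negative (sex, age, disease duration, site; participants without an
#' SAA result are excluded, and requiring disease duration restricts the
#' contrast to diagnosed participants).
#'
#' @return A named list of comparison specs (name, outcome, covariates,
#'   group labels, subset function).
#' @export
comparison_specs <- function() {
  list(
    lrrk2_pd_vs_spd = list(
      name = "lrrk2_pd_vs_spd",
      outcome = "lrrk2_carrier",
      covariates = c("sex", "age", "disease_duration", "site"),
      group_A = "LRRK2_PD", group_B = "sPD",
      group_of = function(p) p$group,
      subset = function(p) p$group %in% c("LRRK2_PD", "sPD")
    ),
    nmc_vs_hc = list(
      name = "nmc_vs_hc",
      outcome = "lrrk2_carrier",
      covariates = c("sex", "age", "site"),
      group_A = "LRRK2_NMC", group_B = "HC",
      group_of = function(p) p$group,
      subset = function(p) p$group %in% c("LRRK2_NMC", "HC")
    ),
    saa_pos_vs_neg = list(
      name = "saa_pos_vs_neg",
      outcome = "saa_positive",
      covariates = c("sex", "age", "disease_duration", "site"),
      group_A = "SAA+", group_B = "SAA-",
      group_of = function(p) ifelse(p$saa_status == "positive", "SAA+", "SAA-"),
      subset = function(p) !is.na(p$saa_status)
    )
  )
}

#' Fit the reference atrophy model on matched sPD vs HC
#'
#' Restricts the cohort to the HC and sPD groups, matches them on
#' propensity scores for PD diagnosis given age, sex and site, and fits
#' the 82 per-region models on the matched sample.
#'
#' @param participants Participant data.frame.
#' @param morphometry Morphometry table.
#' @param registry Region registry.
#' @param caliper A [caliper_spec()].
#' @param zscore Z-score outcomes with the matched-sample scale (default
#'   `TRUE`).
#' @return A list of class `reference_fit`: `model_set`, `matched`,
#'   `beta_map`, `r2_map`.
#' @export
run_reference <- function(participants, morphometry,
                          registry = region_registry(),
                          caliper = caliper_spec(), zscore = TRUE) {
  ref <- participants[participants$group %in% c("HC", "sPD"), , drop = FALSE]
  assert_that(nrow(ref) > 0 && length(unique(ref$group)) == 2,
              "reference fit needs both HC and sPD participants")
  matched <- match_subgroups(ref, "pd_diagnosis",
                             c("age", "sex", "site"), caliper)
  if (matched$n_matched == 0) {
    stop("reference matching produced zero pairs; caliper too tight or groups disjoint",
         call. = FALSE)
  }
  ids <- matched_ids(matched)
  sel <- ref[match(ids, ref$participant_id), , drop = FALSE]
  model_set <- fit_model_set(sel, morphometry, registry, zscore = zscore,
                             provenance = list(
                               matched_ids = ids,
                               caliper = matched$caliper[c("value", "scale")],
                               n_pairs = matched$n_matched))
  structure(list(model_set = model_set, matched = matched,
                 beta_map = diagnosis_beta_map(model_set),
                 r2_map = r_squared_map(model_set)),
            class = "reference_fit")
}

#' Transfer the reference model to one data-poor contrast
#'
#' Matches the two sides of the comparison on propensity scores, predicts
#' morphometry for every matched participant with the frozen model set
#' (using each participant's observed diagnosis status), computes
#' measured - predicted deviations, and tests the subgroup difference on
#' the 82 per-region mean deviations.
#'
#' @param participants Participant data.frame.
#' @param morphometry Morphometry table.
#' @param model_set Fitted [fit_model_set()] result.
#' @param comparison One entry of [comparison_specs()].
#' @param caliper A [caliper_spec()].
#' @param test_family `"two_sample"` (default) or `"paired"`.
#' @param unseen_site Site policy at prediction time (`"error"` or
#'   `"reference"`).
#' @return A list of class `transfer_result`: `matched`, `pred_diff`,
#'   `test`, `maps` (preservation map per side), `comparison`.
#' @export
run_transfer <- function(participants, morphometry, model_set, comparison,
                         caliper = caliper_spec(),
                         test_family = c("two_sample", "paired"),
                         unseen_site = c("error", "reference")) {
  test_family <- match.arg(test_family)
  unseen_site <- match.arg(unseen_site)
  pool <- participants[comparison$subset(participants), , drop = FALSE]
  assert_that(nrow(pool) > 0, paste("no participants for comparison",
                                    comparison$name))
  if (comparison$outcome == "saa_positive" &&
      !"saa_positive" %in% names(pool)) {
    pool$saa_positive <- as.integer(pool$saa_status == "positive")
  }
  matched <- match_subgroups(pool, comparison$outcome,
                             comparison$covariates, caliper)
  if (matched$n_matched == 0) {
    stop(sprintf("comparison %s: zero matched pairs", comparison$name),
         call. = FALSE)
  }
  ids <- matched_ids(matched)
  sel <- pool[match(ids, pool$participant_id), , drop = FALSE]
  pred <- predict_morphometry(model_set, sel, unseen_site = unseen_site)
  meas <- measured_in_model_units(
    model_set, morphometry[match(ids, morphometry$participant_id), ,
                           drop = FALSE])
  groups <- comparison$group_of(sel)
  pd <- compute_prediction_difference(meas, pred, groups)
  test <- test_group_difference(pd, comparison$group_A, comparison$group_B,
                                family = test_family)
  maps <- list(A = preservation_map(pd, comparison$group_A),
               B = preservation_map(pd, comparison$group_B))
  names(maps) <- c(comparison$group_A, comparison$group_B)
  structure(list(matched = matched, pred_diff = pd, test = test,
                 maps = maps, comparison = comparison$name),
            class = "transfer_result")
}

#' @keywords internal
.config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  plain <- config
  plain$registry <- NULL
  jsonlite::write_json(plain, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a synthetic cohort, fits the reference atrophy
#' model on matched sPD vs HC, transfers it to the three data-poor
#' contrasts, compares the LRRK2 PD preservation map against the reference
#' atrophy map with a spin-permutation test, and runs the clinical and
#' genetic association battery on the matched PD participants. Results and
#' a manifest are optionally written to `outdir`.
#'
#' @param config A [cohort_config()]; its own seed is replaced by a
#'   stage seed derived from `seed`.
#' @param seed Top-level integer seed; fans out to stage seeds.
#' @param outdir Optional output directory for TSV/JSON artifacts.
#' @param caliper A [caliper_spec()].
#' @param n_perm Rotations for the spin test.
#' @param test_family t-test family for the transfer tests.
#' @param cohort Optionally, a ready-made list with `participants` and
#'   `morphometry` (skips generation; `config` ignored).
#' @return A list of class `pipeline_result`: `cohort`, `reference`,
#'   `transfers`, `spin`, `associations`, `manifest`.
#' @export
run_all <- function(config = cohort_config(), seed = 1L, outdir = NULL,
                    caliper = caliper_spec(), n_perm = 999L,
                    test_family = c("two_sample", "paired"),
                    cohort = NULL) {
  test_family <- match.arg(test_family)
  if (is.null(cohort)) {
    cfg <- config
    cfg$seed <- stage_seed(seed, 1L)
    if (isTRUE(config$effects_default)) {
      # redraw region effects under the stage seed so the whole run is a
      # pure function of `seed`
      cfg$diagnosis_effect <- with_seed(cfg$seed,
        stats::runif(nrow(cfg$registry), -0.4, 0))
      names(cfg$diagnosis_effect) <- cfg$registry$name
    }
    cohort <- generate_cohort(cfg)
  }
  participants <- cohort$participants
  morphometry <- cohort$morphometry
  registry <- region_registry()

  stages <- list()
  reference <- run_reference(participants, morphometry, registry, caliper)
  stages$reference <- list(
    n_pairs = reference$matched$n_matched,
    caliper = reference$matched$caliper[c("value", "scale")])

  transfers <- list()
  for (cmp in comparison_specs()) {
    if (cmp$outcome == "saa_positive" &&
        (!"saa_status" %in% names(participants) ||
         all(is.na(participants$saa_status)))) {
      warning("SAA status unavailable; skipping comparison saa_pos_vs_neg",
              call. = FALSE)
      next
    }
    tr <- run_transfer(participants, morphometry, reference$model_set, cmp,
                       caliper = caliper, test_family = test_family,
                       unseen_site = "reference")
    transfers[[cmp$name]] <- tr
    stages[[cmp$name]] <- list(
      n_pairs = tr$matched$n_matched,
      t_statistic = tr$test$statistic,
      p_value = tr$test$p_value,
      mean_preservation_A = tr$test$mean_A,
      mean_preservation_B = tr$test$mean_B)
  }

  spin <- NULL
  if (!is.null(transfers$lrrk2_pd_vs_spd)) {
    geometry <- parcel_geometry(registry)
    spin <- spin_test(transfers$lrrk2_pd_vs_spd$maps[["LRRK2_PD"]],
                      reference$beta_map, geometry,
                      n_perm = n_perm, seed = stage_seed(seed, 2L))
    stages$spin <- list(r = spin$r_obs, p_spin = spin$p_spin,
                        n_perm = spin$n_perm)
  }

  associations <- NULL
  if (!is.null(transfers$lrrk2_pd_vs_spd)) {
    ids <- matched_ids(transfers$lrrk2_pd_vs_spd$matched)
    sel <- participants[match(ids, participants$participant_id), ,
                        drop = FALSE]
    pred <- predict_morphometry(reference$model_set, sel,
                                unseen_site = "reference")
    associations <- clinical_associations(pred, sel)
    stages$associations <- list(
      r_updrs3 = associations$global$r[1],
      r_moca = associations$global$r[2],
      r_prs = associations$global$r[3],
      q_moca = associations$global$q[2])
  }

  manifest <- list(
    seed = as.integer(seed),
    stage_seeds = list(cohort = stage_seed(seed, 1L),
                       spin = stage_seed(seed, 2L)),
    config_hash = if (!is.null(cohort$config)) .config_hash(cohort$config)
                  else NA_character_,
    n_participants = nrow(participants),
    comparisons = names(transfers),
    stages = stages,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  result <- structure(list(cohort = cohort, reference = reference,
                           transfers = transfers, spin = spin,
                           associations = associations, manifest = manifest),
                      class = "pipeline_result")

  if (!is.null(outdir)) {
    artifacts <- list(
      participants = participants,
      beta_map = reference$beta_map,
      r2_map = reference$r2_map,
      matched_reference = reference$matched$pairs,
      associations_global = associations$global,
      associations_regional = associations$regional
    )
    for (nm in names(transfers)) {
      artifacts[[paste0("preservation_", nm)]] <-
        transfers[[nm]]$maps[[1]]
      artifacts[[paste0("pairs_", nm)]] <- transfers[[nm]]$matched$pairs
      artifacts[[paste0("test_", nm)]] <- unclass(transfers[[nm]]$test)
    }
    if (!is.null(spin)) {
      artifacts$spin <- list(r = spin$r_obs, p_spin = spin$p_spin,
                             n_perm = spin$n_perm, seed = spin$seed)
    }
    write_results(outdir, artifacts, meta = manifest)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$manifest$n_participants, "participants\n")
  cat("  reference pairs:", x$reference$matched$n_matched, "\n")
  for (nm in names(x$transfers)) {
    tr <- x$transfers[[nm]]
    cat(sprintf("  %-16s %3d pairs, mean dev %+0.4f vs %+0.4f, p = %.3g\n",
                nm, tr$matched$n_matched, tr$test$mean_A, tr$test$mean_B,
                tr$test$p_value))
  }
  if (!is.null(x$spin)) {
    cat(sprintf("  spin: r = %.3f, p_spin = %.4f\n",
                x$spin$r_obs, x$spin$p_spin))
  }
  invisible(x)
}
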