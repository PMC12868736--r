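# Synthetic multi-site cohort generator.
#
# Emulates the statistical structure the analysis assumes: four clinical
# groups (HC, sPD, LRRK2_PD, LRRK2_NMC) with realistic demographics, site
# offsets, per-region diagnosis effects on morphometry, an attenuation
# factor for the LRRK2 PD group, extra atrophy for SAA-positive
# participants, and clinical scores coupled to each participant's
# biological morphometry deviation.

.groups <- c("HC", "sPD", "LRRK2_PD", "LRRK2_NMC")

.default_baseline <- function(registry) {
  cort <- registry$tissue == "cortical"
  # typical adult cortical thickness, with mild deterministic variation
  # across parcels so regions are not interchangeable
  n_c <- sum(cort)
  mean_c <- 2.5 + 0.3 * sin(seq_len(n_c))
  sd_c <- rep(0.15, n_c)
  vols <- c(Thalamus = 7800, Caudate = 3600, Putamen = 4800, Pallidum = 1700,
            Hippocampus = 4000, Amygdala = 1500, Accumbens = 550)
  mean_s <- vols[registry$parcel[!cort]]
  sd_s <- 0.10 * mean_s
  out <- data.frame(name = registry$name,
                    mean = NA_real_, sd = NA_real_,
                    stringsAsFactors = FALSE)
  out$mean[cort] <- mean_c; out$sd[cort] <- sd_c
  out$mean[!cort] <- mean_s; out$sd[!cort] <- sd_s
  out
}

#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration object. Defaults reproduce the group
#' sizes and demographics of the multi-site Parkinson's disease cohort the
#' package is designed around: 293 sporadic PD (sPD), 77 LRRK2 PD, 139
#' healthy controls (HC) and 94 LRRK2 non-manifesting carriers (NMC),
#' five acquisition sites with group-dependent site usage, per-region
#' diagnosis effects drawn once from Uniform(-0.4, 0) on the z-scale, a
#' 0.5 attenuation of those effects in LRRK2 PD, and extra atrophy for
#' SAA-positive participants proportional to the diagnosis-effect profile.
#'
#' @param group_sizes Named integer vector of participants per group.
#' @param age_params Named list `group -> c(mean, sd)` in years.
#' @param male_fraction Named numeric vector of male fractions per group.
#' @param duration_params Named list `PD group -> c(mean, sd)` of disease
#'   duration in years (PD groups only).
#' @param n_sites Number of acquisition sites.
#' @param site_effect_sd SD of the per-site additive offset (z units,
#'   region-constant within site).
#' @param baseline Data.frame `name, mean, sd` of per-region native-unit
#'   baselines (mm for thickness, mm^3 for volume).
#' @param diagnosis_effect Per-region signed diagnosis effect, named by
#'   region. `NULL` (default) draws each region's effect from
#'   Uniform(-0.4, 0) using `seed`.
#' @param effect_units `"z"` (default) or `"native"`; units of
#'   `diagnosis_effect`.
#' @param lrrk2_attenuation Scalar in \[0, 1\] multiplying the diagnosis
#'   effect for LRRK2 PD participants.
#' @param saa_effect_scale Scalar >= 0; SAA-positive participants receive
#'   additional deviation `saa_effect_scale * diagnosis_effect`.
#' @param saa_positive_rate Named vector of SAA-positive rates among tested
#'   participants per group.
#' @param saa_missing_rate Fraction of participants with unavailable SAA
#'   status.
#' @param noise_sd Per-region residual SD (z units); scalar or 82-vector.
#' @param age_slope Per-region age effect (z units per year); scalar or
#'   82-vector.
#' @param age_ref Reference age (years) at which the baseline applies.
#' @param tiv_params `c(mean, sd)` of total intracranial volume in mm^3.
#' @param tiv_volume_coupling Coupling of subcortical volume (z units) to
#'   TIV (z units).
#' @param clinical_coupling List with `moca` and `updrs3`: score points per
#'   z unit of a participant's mean biological morphometry deviation.
#' @param clinical_noise_sd List with `moca` and `updrs3` residual SDs.
#' @param prs_params List with `mean`, `sd`, `carrier_shift` (added for
#'   LRRK2 carriers) and `pc_loading` (loading of PRS on the first genetic
#'   PC).
#' @param seed Integer seed; fixes every generated byte.
#' @param registry Region registry (default [region_registry()]).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(HC = 139, sPD = 293,
                                          LRRK2_PD = 77, LRRK2_NMC = 94),
                          age_params = list(HC = c(61.1, 11.7),
                                            sPD = c(63.3, 9.5),
                                            LRRK2_PD = c(65.0, 8.7),
                                            LRRK2_NMC = c(62.0, 6.9)),
                          male_fraction = c(HC = 92 / 139, sPD = 181 / 293,
                                            LRRK2_PD = 44 / 77,
                                            LRRK2_NMC = 40 / 94),
                          duration_params = list(sPD = c(2.2, 1.9),
                                                 LRRK2_PD = c(3.2, 2.2)),
                          n_sites = 5L,
                          site_effect_sd = 0.3,
                          baseline = NULL,
                          diagnosis_effect = NULL,
                          effect_units = c("z", "native"),
                          lrrk2_attenuation = 0.5,
                          saa_effect_scale = 0.5,
                          saa_positive_rate = c(HC = 0.03, sPD = 0.93,
                                                LRRK2_PD = 0.67,
                                                LRRK2_NMC = 0.08),
                          saa_missing_rate = 0.25,
                          noise_sd = 0.7,
                          age_slope = -0.03,
                          age_ref = 62,
                          tiv_params = c(mean = 1.45e6, sd = 1.5e5),
                          tiv_volume_coupling = 0.4,
                          clinical_coupling = list(moca = 3.0, updrs3 = -2.0),
                          clinical_noise_sd = list(moca = 2.5, updrs3 = 9.0),
                          prs_params = list(mean = 0, sd = 1,
                                            carrier_shift = 0.3,
                                            pc_loading = 0.1),
                          seed = 1L,
                          registry = region_registry()) {
  effect_units <- match.arg(effect_units)
  validate_registry(registry)
  n_region <- nrow(registry)

  missing_groups <- setdiff(names(group_sizes), .groups)
  if (length(missing_groups) > 0) {
    stop("invalid config field 'group_sizes': unknown group(s) ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  if (any(group_sizes < 0) || any(group_sizes != round(group_sizes))) {
    stop("invalid config field 'group_sizes': counts must be non-negative integers",
         call. = FALSE)
  }
  check_scalar(lrrk2_attenuation, "lrrk2_attenuation", 0, 1)
  check_scalar(saa_effect_scale, "saa_effect_scale", 0)
  check_scalar(site_effect_sd, "site_effect_sd", 0)
  check_scalar(saa_missing_rate, "saa_missing_rate", 0, 1)
  check_scalar(n_sites, "n_sites", 1)
  check_scalar(age_ref, "age_ref", 0)
  check_scalar(tiv_volume_coupling, "tiv_volume_coupling")
  if (any(saa_positive_rate < 0 | saa_positive_rate > 1)) {
    stop("invalid config field 'saa_positive_rate': rates must lie in [0, 1]",
         call. = FALSE)
  }
  if (any(noise_sd < 0)) {
    stop("invalid config field 'noise_sd': must be >= 0", call. = FALSE)
  }
  for (g in names(age_params)) {
    if (age_params[[g]][2] < 0) {
      stop("invalid config field 'age_params': sd must be >= 0", call. = FALSE)
    }
  }

  if (is.null(baseline)) baseline <- .default_baseline(registry)
  assert_that(all(registry$name %in% baseline$name),
              "invalid config field 'baseline': must cover every region")
  assert_that(all(baseline$mean > 0) && all(baseline$sd >= 0),
              "invalid config field 'baseline': means must be positive, sds >= 0")

  effects_default <- is.null(diagnosis_effect)
  if (effects_default) {
    diagnosis_effect <- with_seed(seed, stats::runif(n_region, -0.4, 0))
    names(diagnosis_effect) <- registry$name
  }
  assert_that(length(diagnosis_effect) == n_region,
              "invalid config field 'diagnosis_effect': needs one value per region")
  if (is.null(names(diagnosis_effect))) names(diagnosis_effect) <- registry$name

  noise_sd <- rep_len(noise_sd, n_region)
  age_slope <- rep_len(age_slope, n_region)

  structure(list(
    group_sizes = group_sizes, effects_default = effects_default,
    age_params = age_params,
    male_fraction = male_fraction, duration_params = duration_params,
    n_sites = as.integer(n_sites), site_effect_sd = site_effect_sd,
    baseline = baseline, diagnosis_effect = diagnosis_effect,
    effect_units = effect_units, lrrk2_attenuation = lrrk2_attenuation,
    saa_effect_scale = saa_effect_scale,
    saa_positive_rate = saa_positive_rate,
    saa_missing_rate = saa_missing_rate,
    noise_sd = noise_sd, age_slope = age_slope, age_ref = age_ref,
    tiv_params = tiv_params, tiv_volume_coupling = tiv_volume_coupling,
    clinical_coupling = clinical_coupling,
    clinical_noise_sd = clinical_noise_sd,
    prs_params = prs_params, seed = as.integer(seed), registry = registry
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  groups:", paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                         collapse = ", "), "\n")
  cat("  sites:", x$n_sites, " seed:", x$seed, "\n")
  cat(sprintf("  lrrk2_attenuation: %.2f  saa_effect_scale: %.2f  (%s units)\n",
              x$lrrk2_attenuation, x$saa_effect_scale, x$effect_units))
  invisible(x)
}

# group-dependent site usage: rotating a decreasing weight vector per group
# makes site composition differ across groups, so site is a real confounder
.site_probs <- function(group_index, n_sites) {
  base <- rev(seq_len(n_sites))
  w <- base[((seq_len(n_sites) - 1 + group_index) %% n_sites) + 1]
  w / sum(w)
}

#' Generate a synthetic cohort
#'
#' Draws participant metadata and a participants x 82 regions morphometry
#' table from the generative model described in the methods vignette.
#' Regional values (native units) are
#' `baseline_mean + baseline_sd * z`, where the z-scale deviation is
#' `age_slope * (age - age_ref) + site offset +
#'  diagnosis * effect * (attenuation if LRRK2 PD) +
#'  SAA+ * saa_effect_scale * effect + TIV coupling (subcortical) + noise`.
#' MoCA and UPDRS III are coupled to each participant's mean biological
#' deviation (injected effects, age trend and regional noise; site and TIV
#' terms excluded). The output is fully determined by `config$seed`.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `synthetic_cohort` with elements
#'   `participants` (data.frame, one row per participant) and
#'   `morphometry` (data.frame: `participant_id` plus 82 region columns).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   group_sizes = c(HC = 20, sPD = 20, LRRK2_PD = 5, LRRK2_NMC = 5),
#'   seed = 42))
#' nrow(cohort$participants)
generate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_config"),
              "config must be created by cohort_config()")
  registry <- config$registry
  n_region <- nrow(registry)
  sizes <- config$group_sizes[config$group_sizes > 0]
  n <- sum(sizes)
  assert_that(n > 0, "invalid config field 'group_sizes': empty cohort")

  with_seed(config$seed, {
    group <- rep(names(sizes), sizes)
    gi <- match(group, .groups)
    pd <- as.integer(group %in% c("sPD", "LRRK2_PD"))
    carrier <- as.integer(group %in% c("LRRK2_PD", "LRRK2_NMC"))

    age <- numeric(n); sex <- character(n); site <- integer(n)
    duration <- rep(NA_real_, n)
    for (g in names(sizes)) {
      idx <- which(group == g)
      ap <- config$age_params[[g]]
      age[idx] <- pmax(18, stats::rnorm(length(idx), ap[1], ap[2]))
      sex[idx] <- ifelse(stats::runif(length(idx)) < config$male_fraction[[g]],
                         "male", "female")
      site[idx] <- sample.int(config$n_sites, length(idx), replace = TRUE,
                              prob = .site_probs(match(g, .groups),
                                                 config$n_sites))
      if (g %in% names(config$duration_params)) {
        dp <- config$duration_params[[g]]
        duration[idx] <- pmax(0.1, stats::rnorm(length(idx), dp[1], dp[2]))
      }
    }

    # SAA status: per-group positivity among tested, missing fraction overall
    saa <- rep(NA_character_, n)
    tested <- stats::runif(n) >= config$saa_missing_rate
    rate <- config$saa_positive_rate[group]
    pos <- stats::runif(n) < rate
    saa[tested] <- ifelse(pos[tested], "positive", "negative")
    saa_num <- ifelse(is.na(saa), 0L, as.integer(saa == "positive"))

    tiv <- stats::rnorm(n, config$tiv_params[["mean"]],
                        config$tiv_params[["sd"]])
    z_tiv <- (tiv - config$tiv_params[["mean"]]) / config$tiv_params[["sd"]]

    # per-site additive offsets, constant across regions (z units)
    site_offset <- stats::rnorm(config$n_sites, 0, config$site_effect_sd)

    # effects on the z scale
    eff_z <- config$diagnosis_effect
    if (config$effect_units == "native") {
      sdv <- config$baseline$sd[match(names(eff_z), config$baseline$name)]
      eff_z <- eff_z / ifelse(sdv > 0, sdv, 1)
    }
    atten <- ifelse(group == "LRRK2_PD", config$lrrk2_attenuation, 1)

    injected <- outer(pd * atten, eff_z) +
      outer(saa_num * config$saa_effect_scale, eff_z)
    age_part <- outer(age - config$age_ref, config$age_slope)
    noise <- matrix(stats::rnorm(n * n_region), n, n_region) *
      rep(config$noise_sd, each = n)
    z <- injected + age_part + site_offset[site] +
      outer(z_tiv * config$tiv_volume_coupling,
            as.numeric(registry$tissue == "subcortical")) +
      noise

    bmean <- config$baseline$mean[match(registry$name, config$baseline$name)]
    bsd <- config$baseline$sd[match(registry$name, config$baseline$name)]
    values <- sweep(sweep(z, 2, bsd, `*`), 2, bmean, `+`)
    values <- pmax(values, 1e-6)
    colnames(values) <- registry$name

    # clinical scores follow the biological part of the deviation only
    bio_dev <- rowMeans(injected + age_part + noise)
    moca <- 27 + config$clinical_coupling$moca * bio_dev +
      stats::rnorm(n, 0, config$clinical_noise_sd$moca)
    moca <- round(pmin(30, pmax(0, moca)))
    updrs3 <- ifelse(pd == 1, 21, 1) +
      config$clinical_coupling$updrs3 * bio_dev +
      stats::rnorm(n, 0, config$clinical_noise_sd$updrs3)
    updrs3 <- round(pmax(0, updrs3))

    pcs <- matrix(stats::rnorm(n * 10), n, 10)
    colnames(pcs) <- paste0("pc", 1:10)
    prs <- config$prs_params$mean +
      config$prs_params$carrier_shift * carrier +
      config$prs_params$pc_loading * pcs[, 1] +
      stats::rnorm(n, 0, config$prs_params$sd)

    participants <- data.frame(
      participant_id = sprintf("P%04d", seq_len(n)),
      group = group, pd_diagnosis = pd, lrrk2_carrier = carrier,
      saa_status = saa, age = age, sex = sex,
      site = paste0("site", site), disease_duration = duration,
      tiv = tiv, moca = moca, updrs3 = updrs3, prs = prs,
      stringsAsFactors = FALSE
    )
    participants <- cbind(participants, as.data.frame(pcs))

    morphometry <- data.frame(participant_id = participants$participant_id,
                              as.data.frame(values, optional = TRUE),
                              stringsAsFactors = FALSE, check.names = FALSE)

    structure(list(participants = participants, morphometry = morphometry,
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$participants), "participants,",
      ncol(x$morphometry) - 1L, "regions\n")
  print(table(x$participants$group))
  invisible(x)
}
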