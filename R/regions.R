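# Region registry: 68 Desikan-Killiany cortical parcels (34 per hemisphere,
# cortical thickness in mm) and 14 Harvard-Oxford subcortical parcels
# (volume in mm^3, 7 per hemisphere).

.dk_parcels <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal"
)

.ho_structures <- c(
  "Thalamus", "Caudate", "Putamen", "Pallidum",
  "Hippocampus", "Amygdala", "Accumbens"
)

#' Region registry for the 82-parcel morphometry table
#'
#' Returns the ordered registry of the 68 Desikan-Killiany cortical thickness
#' parcels and the 14 Harvard-Oxford subcortical volume parcels that every
#' morphometry table in this package must carry. Cortical columns use
#' FreeSurfer-style names (`lh_<parcel>_thickness`), subcortical columns use
#' `Left-<Structure>_volume` / `Right-<Structure>_volume`.
#'
#' @return A data.frame with one row per region and columns `name` (the
#'   table column name), `atlas`, `tissue` (`"cortical"` or `"subcortical"`),
#'   `hemisphere` (`"L"` or `"R"`), and `parcel` (the bare parcel name).
#' @export
#' @examples
#' reg <- region_registry()
#' table(reg$tissue)
region_registry <- function() {
  cort <- data.frame(
    name = c(paste0("lh_", .dk_parcels, "_thickness"),
             paste0("rh_", .dk_parcels, "_thickness")),
    atlas = "Desikan-Killiany",
    tissue = "cortical",
    hemisphere = rep(c("L", "R"), each = length(.dk_parcels)),
    parcel = rep(.dk_parcels, 2L),
    stringsAsFactors = FALSE
  )
  sub <- data.frame(
    name = c(paste0("Left-", .ho_structures, "_volume"),
             paste0("Right-", .ho_structures, "_volume")),
    atlas = "Harvard-Oxford",
    tissue = "subcortical",
    hemisphere = rep(c("L", "R"), each = length(.ho_structures)),
    parcel = rep(.ho_structures, 2L),
    stringsAsFactors = FALSE
  )
  out <- rbind(cort, sub)
  rownames(out) <- NULL
  out
}

#' Validate a region registry
#' @keywords internal
validate_registry <- function(registry) {
  assert_that(is.data.frame(registry) &&
                all(c("name", "tissue", "hemisphere") %in% names(registry)),
              "registry must be a data.frame with name/tissue/hemisphere")
  assert_that(sum(registry$tissue == "cortical") == 68L,
              "registry must contain exactly 68 cortical regions")
  assert_that(sum(registry$tissue == "subcortical") == 14L,
              "registry must contain exactly 14 subcortical regions")
  assert_that(!anyDuplicated(registry$name), "region names must be unique")
  invisible(registry)
}

#' Unit-sphere centroids for the cortical parcels
#'
#' Builds reproducible parcel centroids on the unit sphere for the 68
#' Desikan-Killiany cortical parcels, for use by the spin-permutation test.
#' Following the spherical-registration convention, each hemisphere's 34
#' parcels tile their own full unit sphere: left-hemisphere centroids are
#' laid out along a Fibonacci spiral, and right-hemisphere homologues are
#' their exact mirror images across the x = 0 plane. Subcortical parcels
#' have no spherical model and are excluded.
#'
#' @param registry A region registry (default [region_registry()]).
#' @return A data.frame with columns `name`, `hemisphere`, `parcel`,
#'   `x`, `y`, `z`; one row per cortical parcel, centroids of unit norm.
#' @export
#' @examples
#' geo <- parcel_geometry()
#' range(sqrt(geo$x^2 + geo$y^2 + geo$z^2))
parcel_geometry <- function(registry = region_registry()) {
  validate_registry(registry)
  cort <- registry[registry$tissue == "cortical", , drop = FALSE]
  lh <- cort[cort$hemisphere == "L", , drop = FALSE]
  assert_that(nrow(lh) == 34L, "expected 34 left-hemisphere cortical parcels")
  n <- nrow(lh)
  k <- seq_len(n)
  # Fibonacci spiral over the full sphere (spherical-registration layout)
  zc <- -1 + 2 * (k - 0.5) / n
  golden <- (1 + sqrt(5)) / 2
  phi <- 2 * pi * ((k * golden) %% 1)
  r <- sqrt(pmax(0, 1 - zc^2))
  xl <- r * cos(phi)
  yl <- r * sin(phi)
  left <- data.frame(name = lh$name, hemisphere = "L", parcel = lh$parcel,
                     x = xl, y = yl, z = zc, stringsAsFactors = FALSE)
  rh <- cort[cort$hemisphere == "R", , drop = FALSE]
  m <- match(rh$parcel, left$parcel)
  if (anyNA(m)) {
    stop("unknown right-hemisphere parcel(s): ",
         paste(rh$parcel[is.na(m)], collapse = ", "), call. = FALSE)
  }
  right <- data.frame(name = rh$name, hemisphere = "R", parcel = rh$parcel,
                      x = -left$x[m], y = left$y[m], z = left$z[m],
                      stringsAsFactors = FALSE)
  out <- rbind(left, right)
  rownames(out) <- NULL
  out
}
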