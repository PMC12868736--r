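# Spatial comparison of parcellated brain maps: Pearson correlation with a
# spin-permutation null. The null preserves the spatial autocorrelation of
# one map by rigidly rotating its parcel centroids on the sphere and
# reassigning parcel values by nearest rotated centroid; one rotation is
# drawn per permutation and applied to the left hemisphere, with its
# x-mirrored image applied to the right (mirrored-spin convention).

#' Pearson correlation between two brain maps
#'
#' @param map_a,map_b [brain_map()] objects (or named numeric vectors) over
#'   the same region set; at least 3 regions, non-zero variance.
#' @return Pearson correlation coefficient.
#' @export
correlate_maps <- function(map_a, map_b) {
  a <- .map_values(map_a)
  b <- .map_values(map_b)
  assert_that(setequal(names(a), names(b)),
              "maps must cover the same region set")
  b <- b[names(a)]
  assert_that(length(a) >= 3, "need at least 3 regions")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: a map has zero variance", call. = FALSE)
  }
  stats::cor(a, b)
}

#' @keywords internal
.map_values <- function(map) {
  if (inherits(map, "brain_map")) {
    v <- map$value
    names(v) <- map$region
    v
  } else {
    assert_that(is.numeric(map) && !is.null(names(map)),
                "map must be a brain_map or a named numeric vector")
    map
  }
}

# Uniform random 3-D rotation via a random unit quaternion.
#' @keywords internal
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Spin-permutation indices for a parcel geometry
#'
#' Draws `n_perm` uniform random rotations and, for each, reassigns every
#' cortical parcel the value of the parcel whose rotated centroid is
#' nearest (by maximum dot product on the unit sphere), per hemisphere with
#' the mirrored rotation on the right hemisphere.
#'
#' @param geometry A [parcel_geometry()] data.frame.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Integer matrix `n_perm x n_parcel`; row k maps each parcel
#'   position to the source parcel index whose value it receives under
#'   rotation k. Attribute `n_duplicate` counts, per permutation, parcels
#'   receiving the same source (0 = the reassignment is a bijection).
#' @export
spin_permutations <- function(geometry, n_perm, seed = 1L) {
  assert_that(all(c("x", "y", "z", "hemisphere") %in% names(geometry)),
              "geometry must carry x, y, z, hemisphere")
  n <- nrow(geometry)
  C <- t(as.matrix(geometry[, c("x", "y", "z")]))   # 3 x n
  lh <- which(geometry$hemisphere == "L")
  rh <- which(geometry$hemisphere == "R")
  M <- diag(c(-1, 1, 1))
  idx <- matrix(NA_integer_, n_perm, n)
  ndup <- integer(n_perm)
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      R <- random_rotation()
      Rr <- M %*% R %*% M
      rotL <- R %*% C[, lh, drop = FALSE]
      rotR <- Rr %*% C[, rh, drop = FALSE]
      # original parcel p receives the value of the parcel whose rotated
      # centroid lands nearest to p's centroid
      simL <- crossprod(C[, lh, drop = FALSE], rotL)   # orig x rotated
      simR <- crossprod(C[, rh, drop = FALSE], rotR)
      iL <- max.col(simL, ties.method = "first")
      iR <- max.col(simR, ties.method = "first")
      idx[k, lh] <- lh[iL]
      idx[k, rh] <- rh[iR]
      ndup[k] <- sum(duplicated(iL)) + sum(duplicated(iR))
    }
  })
  attr(idx, "n_duplicate") <- ndup
  idx
}

#' Spin-permutation test for the correlation of two brain maps
#'
#' Tests the Pearson correlation between two cortical brain maps against a
#' spatial null built by random spherical rotations of `map_a`'s parcel
#' assignment (see [spin_permutations()]). Subcortical regions have no
#' spherical model and are excluded; both maps are restricted to the
#' parcels present in `geometry`. Two-sided p by |r|:
#' `p = (1 + #\{|r_null| >= |r_obs|\}) / (n_perm + 1)`.
#'
#' @param map_a,map_b [brain_map()]s or named numeric vectors.
#' @param geometry A [parcel_geometry()] covering the cortical parcels.
#' @param n_perm Number of rotations (>= 99).
#' @param seed Integer seed for the rotation schedule.
#' @return A list of class `spin_result`: `r_obs`, `p_spin`, `n_perm`,
#'   `r_null` (null distribution), `n_parcel`, `seed`, `n_duplicate`.
#' @export
spin_test <- function(map_a, map_b, geometry = parcel_geometry(),
                      n_perm = 999L, seed = 1L) {
  assert_that(is.numeric(n_perm) && n_perm >= 99,
              "n_perm must be at least 99")
  a <- .map_values(map_a)
  b <- .map_values(map_b)
  use <- intersect(geometry$name, intersect(names(a), names(b)))
  assert_that(length(use) >= 3,
              "maps and geometry share fewer than 3 cortical parcels")
  geo <- geometry[match(use, geometry$name), , drop = FALSE]
  a <- a[use]
  b <- b[use]
  r_obs <- stats::cor(a, b)

  idx <- spin_permutations(geo, n_perm, seed)
  # map idx (positions in geo) to values of a
  r_null <- vapply(seq_len(n_perm), function(k) {
    stats::cor(a[idx[k, ]], b)
  }, numeric(1))
  p <- (1 + sum(abs(r_null) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  structure(list(r_obs = r_obs, p_spin = p, n_perm = as.integer(n_perm),
                 r_null = r_null, n_parcel = length(use),
                 seed = as.integer(seed),
                 n_duplicate = attr(idx, "n_duplicate")),
            class = "spin_result")
}

#' @export
print.spin_result <- function(x, ...) {
  cat(sprintf("<spin_result> r = %.3f, p_spin = %.4f (%d rotations, %d parcels)\n",
              x$r_obs, x$p_spin, x$n_perm, x$n_parcel))
  invisible(x)
}
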