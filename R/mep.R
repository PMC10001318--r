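#' @title Microscopic-extension-probability (MEP) fields
#' @description
#' An MEP field assigns to every cell the probability that it is a tumour
#' clonogen. Infiltrating glioblastoma cells spread far beyond the imageable
#' gross tumour; the MEP is 1 inside the GTV, decays with distance from the
#' GTV surface, and vanishes beyond the microscopic-extension (ME) extent.
#' Three geometries are provided: isotropic (`mep_circular`), anisotropic by
#' elliptical coordinate scaling (`mep_elliptical`), and lobed with seeded
#' random angular harmonics (`mep_irregular`).
#'
#' The radial profile shared by all three models is
#' `MEP(r) = 1` for `r <= R_gtv`, then `exp(-decay * u)` with
#' `u = r - R_gtv`, linearly tapered to 0 over the final `taper_mm` of the
#' ME extent and exactly 0 beyond it. The default decay reaches MEP = 0.01
#' at a 2.0 cm CTV radius.
#' @name mep_models
NULL

# Shared radial profile. u_eff: distance beyond the GTV surface in
# effective (possibly anisotropically scaled) coordinates.
mep_radial_profile <- function(u_eff, me_extent_mm, decay_per_mm, taper_mm) {
  base <- exp(-decay_per_mm * pmax(u_eff, 0))
  taper <- pmin(pmax((me_extent_mm - u_eff) / taper_mm, 0), 1)
  out <- base * taper
  out[u_eff <= 0] <- 1
  out
}

new_mep_field <- function(values, grid, model, params, seed = NULL) {
  structure(list(values = values, grid = grid, model = model,
                 params = params, seed = seed),
            class = "mep_field")
}

#' @export
print.mep_field <- function(x, ...) {
  cat(sprintf("mep_field (%s): %d x %d cells, sum(MEP) = %.4g\n",
              x$model, x$grid$n_y, x$grid$n_x, sum(x$values)))
  invisible(x)
}

#' Default MEP decay constant
#'
#' Decay rate (per mm beyond the GTV surface) such that the isotropic MEP
#' falls to `target_mep` at the clinical-target-volume radius implied by
#' `at_margin_mm`. With the defaults, MEP is 0.01 at the 2.0 cm CTV margin.
#'
#' @param target_mep MEP value reached at the margin.
#' @param at_margin_mm CTV margin beyond the GTV surface, mm.
#' @return Decay constant in 1/mm.
#' @export
default_mep_decay <- function(target_mep = 0.01, at_margin_mm = 20) {
  -log(target_mep) / at_margin_mm
}

#' @describeIn mep_models Isotropic MEP field.
#' @param grid A [build_grid()] object.
#' @param gtv_radius_mm GTV disc radius (MEP = 1 inside), mm.
#' @param me_extent_mm ME extent beyond the GTV surface (MEP = 0 beyond), mm.
#' @param decay_per_mm Exponential decay rate of MEP with distance beyond the
#'   GTV surface, 1/mm.
#' @param taper_mm Width of the linear taper to zero at the outer ME edge
#'   (keeps the field continuous), mm.
#' @return An object of class `mep_field` with matrix element `values` in
#'   \[0, 1\].
#' @examples
#' g <- build_grid(101, 101, cell_size_um = 1000)
#' m <- mep_circular(g)
#' range(m$values)
#' @export
mep_circular <- function(grid, gtv_radius_mm = 0.5, me_extent_mm = 41,
                         decay_per_mm = default_mep_decay(), taper_mm = 0.5) {
  stopifnot_grid(grid)
  check_mep_geometry(gtv_radius_mm, me_extent_mm, decay_per_mm, taper_mm)
  r <- radial_distance_field(grid)
  vals <- mep_radial_profile(r - gtv_radius_mm, me_extent_mm,
                             decay_per_mm, taper_mm)
  new_mep_field(vals, grid, "circular",
                list(gtv_radius_mm = gtv_radius_mm, me_extent_mm = me_extent_mm,
                     decay_per_mm = decay_per_mm, taper_mm = taper_mm))
}

check_mep_geometry <- function(gtv_radius_mm, me_extent_mm, decay_per_mm,
                               taper_mm) {
  if (me_extent_mm <= 0)
    stop("me_extent_mm must be positive", call. = FALSE)
  if (gtv_radius_mm < 0)
    stop("gtv_radius_mm must be non-negative", call. = FALSE)
  if (decay_per_mm <= 0) stop("decay_per_mm must be > 0", call. = FALSE)
  if (taper_mm <= 0 || taper_mm > me_extent_mm)
    stop("taper_mm must be in (0, me_extent_mm]", call. = FALSE)
}

#' @describeIn mep_models Anisotropic (elliptical) MEP field. The radial
#'   profile is evaluated on the elliptical effective radius
#'   `r_eff = sqrt(x'^2 + (axis_ratio * y')^2)` in the frame rotated by
#'   `orientation_rad`, so the major semi-axis of the infiltration reaches the
#'   full ME extent and the minor semi-axis `me_extent / axis_ratio`; the
#'   field never extends beyond the ME extent in true distance. Cells inside
#'   the (circular) GTV always have MEP = 1. `axis_ratio = 1` reproduces
#'   [mep_circular()] exactly.
#' @param axis_ratio Major:minor axis ratio (> 0; > 1 elongates along the
#'   orientation axis).
#' @param orientation_rad Major-axis orientation, radians from +x.
#' @export
mep_elliptical <- function(grid, gtv_radius_mm = 0.5, me_extent_mm = 41,
                           decay_per_mm = default_mep_decay(), axis_ratio = 2,
                           orientation_rad = 0, taper_mm = 0.5) {
  stopifnot_grid(grid)
  check_mep_geometry(gtv_radius_mm, me_extent_mm, decay_per_mm, taper_mm)
  if (axis_ratio <= 0) stop("axis_ratio must be > 0", call. = FALSE)
  cc <- cell_coords(grid)
  x <- matrix(cc$x, nrow = grid$n_y, ncol = grid$n_x, byrow = TRUE)
  y <- matrix(cc$y, nrow = grid$n_y, ncol = grid$n_x)
  if (orientation_rad != 0) {
    co <- cos(orientation_rad); si <- sin(orientation_rad)
    xr <- x * co + y * si
    yr <- -x * si + y * co
  } else {
    xr <- x; yr <- y
  }
  r_eff <- sqrt(xr^2 + (axis_ratio * yr)^2)
  vals <- mep_radial_profile(r_eff - gtv_radius_mm, me_extent_mm,
                             decay_per_mm, taper_mm)
  r <- sqrt(x^2 + y^2)
  vals[r <= gtv_radius_mm] <- 1   # GTV disc stays circular
  new_mep_field(vals, grid, "elliptical",
                list(gtv_radius_mm = gtv_radius_mm, me_extent_mm = me_extent_mm,
                     decay_per_mm = decay_per_mm, axis_ratio = axis_ratio,
                     orientation_rad = orientation_rad, taper_mm = taper_mm))
}

#' @describeIn mep_models Irregular (lobed) MEP field. The angular extent is
#'   modulated by random low-order harmonics:
#'   `extent(theta) = me_extent * (1 + A * sum_k c_k cos(k theta + phi_k)) / (1 + A)`
#'   with `c_k` proportional to `1/k` (normalised so `sum |c_k| = 1`) and
#'   phases `phi_k` drawn uniformly from the seed. The normalisation keeps
#'   `extent(theta) <= me_extent` everywhere. The radial profile is then
#'   evaluated on `r * me_extent / extent(theta)`. `amplitude = 0` reproduces
#'   [mep_circular()] exactly; the field is a pure function of its arguments
#'   and `seed`.
#' @param n_lobes Number of angular harmonics (>= 1).
#' @param amplitude Modulation amplitude in \[0, 1).
#' @param seed Integer seed for the harmonic phases.
#' @export
mep_irregular <- function(grid, gtv_radius_mm = 0.5, me_extent_mm = 41,
                          decay_per_mm = default_mep_decay(), n_lobes = 5,
                          amplitude = 0.3, seed = 1, taper_mm = 0.5) {
  stopifnot_grid(grid)
  check_mep_geometry(gtv_radius_mm, me_extent_mm, decay_per_mm, taper_mm)
  if (amplitude < 0 || amplitude >= 1)
    stop("amplitude must lie in [0, 1)", call. = FALSE)
  if (n_lobes < 1) stop("n_lobes must be >= 1", call. = FALSE)
  cc <- cell_coords(grid)
  x <- matrix(cc$x, nrow = grid$n_y, ncol = grid$n_x, byrow = TRUE)
  y <- matrix(cc$y, nrow = grid$n_y, ncol = grid$n_x)
  r <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)
  scale <- irregular_extent_factor(theta, n_lobes, amplitude, seed)
  r_eff <- r / scale
  vals <- mep_radial_profile(r_eff - gtv_radius_mm, me_extent_mm,
                             decay_per_mm, taper_mm)
  vals[r <= gtv_radius_mm] <- 1
  new_mep_field(vals, grid, "irregular",
                list(gtv_radius_mm = gtv_radius_mm, me_extent_mm = me_extent_mm,
                     decay_per_mm = decay_per_mm, n_lobes = n_lobes,
                     amplitude = amplitude, taper_mm = taper_mm),
                seed = seed)
}

# Angular extent modulation factor in ((1-A)/(1+A), 1]; ==1 when A == 0.
irregular_extent_factor <- function(theta, n_lobes, amplitude, seed) {
  if (amplitude == 0) return(array(1, dim = dim(theta)))
  phases <- local_rng(seed, stats::runif(n_lobes, 0, 2 * pi))
  ck <- (1 / seq_len(n_lobes))
  ck <- ck / sum(ck)
  mod <- 0
  for (k in seq_len(n_lobes))
    mod <- mod + ck[k] * cos(k * theta + phases[k])
  (1 + amplitude * mod) / (1 + amplitude)
}

# Evaluate expr with a private RNG stream; restores global RNG state.
local_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Boron biodistribution from an MEP field
#'
#' Maps tumour-cell probability to boron-10 concentration with the linear
#' regression `B = slope * MEP + intercept`, so that pure normal brain
#' (MEP = 0) carries the baseline concentration and certain tumour (MEP = 1)
#' carries the tumour concentration. With the defaults these are 13 and
#' 45.5 ug/g — a 3.5:1 tumour-to-normal-brain uptake ratio.
#'
#' @param mep A [mep_circular()]-family `mep_field`.
#' @param slope_ug_g Regression slope, ug/g per unit MEP; default 32.5.
#' @param intercept_ug_g Normal-brain concentration, ug/g; default 13.
#' @return Numeric matrix of per-cell boron-10 concentration (ug/g).
#' @examples
#' g <- build_grid(51, 51, cell_size_um = 2000)
#' b <- boron_from_mep(mep_circular(g))
#' max(b)  # 45.5 at the tumour centre
#' @export
boron_from_mep <- function(mep, slope_ug_g = 32.5, intercept_ug_g = 13) {
  if (!inherits(mep, "mep_field")) stop("mep must be a mep_field", call. = FALSE)
  if (slope_ug_g < 0) stop("slope_ug_g must be >= 0", call. = FALSE)
  if (intercept_ug_g <= 0) stop("intercept_ug_g must be > 0", call. = FALSE)
  slope_ug_g * mep$values + intercept_ug_g
}
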