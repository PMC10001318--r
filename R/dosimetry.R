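#' @title Surrogate cell-based dosimetry
#' @description
#' Generates per-cell physical dose matrices standing in for full Monte
#' Carlo neutron transport. The BNCT surrogate is separable: a lateral
#' thermal-fluence profile (flat in the beam, error-function penumbra) times
#' the local boron concentration for the capture-product components (alpha
#' and lithium-7), plus broader boron-independent gamma and residual-neutron
#' components. Multiplicative Gaussian noise emulates run-to-run Monte Carlo
#' scoring statistics; independent seeded runs form an ensemble for
#' uncertainty estimation. Absolute magnitudes are arbitrary at this stage —
#' the prescription calibration (see [calibrate_prescription()]) sets the
#' clinical scale.
#' @name synthetic_dosimetry
NULL

#' Lateral beam fluence profile
#'
#' Noise-free relative lateral profile of the beam on the slice: ~1 on axis,
#' sigmoidal (Gaussian-error-function) falloff centred at the beam edge,
#' tending to 0 far outside. Implemented as
#' `pnorm((beam_radius - r) / penumbra_sigma)`, i.e. exactly 0.5 at the beam
#' edge and < 0.01 by 3 sigma outside it.
#'
#' @param grid A [build_grid()] object.
#' @param beam_radius_mm Beam radius, mm.
#' @param penumbra_sigma_mm Penumbra falloff scale, mm.
#' @return Numeric matrix of weights in (0, 1).
#' @export
lateral_beam_profile <- function(grid, beam_radius_mm, penumbra_sigma_mm) {
  stopifnot_grid(grid)
  if (penumbra_sigma_mm <= 0)
    stop("penumbra_sigma_mm must be > 0", call. = FALSE)
  r <- radial_distance_field(grid)
  stats::pnorm((beam_radius_mm - r) / penumbra_sigma_mm)
}

#' Surrogate dosimetry parameters
#'
#' Shape and magnitude parameters of the BNCT dose surrogate. `k_alpha` and
#' `k_li7` convert local boron concentration times fluence into alpha and
#' lithium-7 physical dose; their default ratio 1.77/1.01 follows the
#' emission-energy ratio of the two boron-capture fragments (alpha up to
#' 1.77 MeV, recoil Li-7 up to 1.01 MeV), so the alpha matrix always carries
#' that fixed multiple of the lithium matrix. Gamma and residual-neutron
#' components are boron-independent with broader lateral falloff (scatter).
#' Absolute magnitudes are nominal; the prescription calibration rescales
#' all components jointly.
#'
#' @param k_alpha,k_li7 Dose coefficients, Gy per (ug/g of boron) at unit
#'   fluence weight.
#' @param gamma_dose_gy,neutron_dose_gy On-axis physical dose of the gamma
#'   and residual (fast + thermal) neutron components, Gy.
#' @param penumbra_sigma_mm Lateral falloff scale of the thermal-fluence
#'   profile driving the boron components, mm.
#' @param gamma_sigma_mm,neutron_sigma_mm Broader falloff scales for the
#'   gamma and neutron components, mm.
#' @param noise_rel_sd Relative standard deviation of the multiplicative
#'   per-cell Gaussian noise emulating Monte Carlo scoring statistics
#'   (0 disables noise).
#' @return A list of class `bnct_dose_params`.
#' @export
bnct_dose_params <- function(k_alpha = 0.177, k_li7 = 0.101,
                             gamma_dose_gy = 5, neutron_dose_gy = 3,
                             penumbra_sigma_mm = 2, gamma_sigma_mm = 6,
                             neutron_sigma_mm = 4, noise_rel_sd = 0.02) {
  stopifnot(k_alpha >= 0, k_li7 >= 0, gamma_dose_gy >= 0, neutron_dose_gy >= 0,
            penumbra_sigma_mm > 0, gamma_sigma_mm > 0, neutron_sigma_mm > 0,
            noise_rel_sd >= 0)
  structure(list(k_alpha = k_alpha, k_li7 = k_li7,
                 gamma_dose_gy = gamma_dose_gy, neutron_dose_gy = neutron_dose_gy,
                 penumbra_sigma_mm = penumbra_sigma_mm,
                 gamma_sigma_mm = gamma_sigma_mm,
                 neutron_sigma_mm = neutron_sigma_mm,
                 noise_rel_sd = noise_rel_sd),
            class = "bnct_dose_params")
}

# Multiplicative noise factor matrix, clipped so doses stay non-negative.
noise_factor <- function(n_y, n_x, rel_sd) {
  if (rel_sd == 0) return(matrix(1, n_y, n_x))
  pmax(1 + matrix(stats::rnorm(n_y * n_x, 0, rel_sd), n_y, n_x), 0)
}

#' Generate one run of BNCT physical dose components
#'
#' Produces the four per-cell physical dose matrices of one simulated run:
#' `alpha` and `li7` (boron-capture fragments, proportional to local boron
#' concentration times the thermal-fluence profile), `gamma` (hydrogen-capture
#' photons) and `neutron_residual` (fast + thermal neutron dose, scored
#' jointly since the two share one RBE). All matrices are in Gy and
#' non-negative.
#'
#' @param grid A [build_grid()] object.
#' @param boron Boron concentration matrix from [boron_from_mep()], ug/g.
#' @param beam_radius_mm Beam radius, mm.
#' @param params A [bnct_dose_params()] list.
#' @param seed Integer seed for the per-cell noise; ignored when
#'   `noise_rel_sd = 0`.
#' @param run_id Integer label for ensemble bookkeeping.
#' @return An object of class `dose_components` with matrices `alpha`, `li7`,
#'   `gamma`, `neutron_residual` and metadata `run_id`, `seed`.
#' @export
generate_bnct_components <- function(grid, boron, beam_radius_mm,
                                     params = bnct_dose_params(),
                                     seed = 1, run_id = 1L) {
  stopifnot_grid(grid)
  check_field_dim(boron, grid, "boron map")
  if (any(boron < 0)) stop("boron concentrations must be >= 0", call. = FALSE)
  phi <- lateral_beam_profile(grid, beam_radius_mm, params$penumbra_sigma_mm)
  phi_g <- lateral_beam_profile(grid, beam_radius_mm, params$gamma_sigma_mm)
  phi_n <- lateral_beam_profile(grid, beam_radius_mm, params$neutron_sigma_mm)
  comps <- local_rng(seed, {
    list(
      alpha = params$k_alpha * boron * phi *
        noise_factor(grid$n_y, grid$n_x, params$noise_rel_sd),
      li7 = params$k_li7 * boron * phi *
        noise_factor(grid$n_y, grid$n_x, params$noise_rel_sd),
      gamma = params$gamma_dose_gy * phi_g *
        noise_factor(grid$n_y, grid$n_x, params$noise_rel_sd),
      neutron_residual = params$neutron_dose_gy * phi_n *
        noise_factor(grid$n_y, grid$n_x, params$noise_rel_sd)
    )
  })
  structure(c(comps, list(grid = grid, run_id = as.integer(run_id),
                          seed = seed, params = params)),
            class = "dose_components")
}

#' @export
print.dose_components <- function(x, ...) {
  cat(sprintf(
    "dose_components (run %d): max alpha %.3g, li7 %.3g, gamma %.3g, neutron %.3g Gy\n",
    x$run_id, max(x$alpha), max(x$li7), max(x$gamma), max(x$neutron_residual)))
  invisible(x)
}

#' Generate a fractionated X-ray (EBRT) dose field
#'
#' Builds the external-beam comparison field: a flat-in-beam per-fraction
#' dose with the same error-function penumbra shape as the BNCT surrogate,
#' delivered in `n_fractions` (default 30 x 2 Gy to the PTV), plus a boost to
#' the GTV delivered as additional fractions of the same fraction size
#' (default 10 Gy as 5 x 2 Gy).
#'
#' @param grid A [build_grid()] object.
#' @param beam_radius_mm Beam radius, mm.
#' @param gtv_mask Logical matrix of GTV membership (boost target).
#' @param fraction_dose_gy Prescribed dose per fraction, Gy; default 2.
#' @param n_fractions Number of PTV fractions; default 30.
#' @param boost_gy Total GTV boost dose, Gy; default 10, delivered in
#'   `ceiling(boost_gy / fraction_dose_gy)` extra fractions.
#' @param penumbra_sigma_mm Penumbra falloff scale, mm.
#' @param noise_rel_sd Relative SD of multiplicative per-cell noise.
#' @param seed Integer noise seed.
#' @param run_id Integer run label.
#' @return An object of class `ebrt_field` with matrices `fraction_dose`
#'   (Gy per fraction) and `boost_fraction_dose` (Gy per boost fraction, zero
#'   outside the GTV), counts `n_fractions`, `n_boost_fractions`, and
#'   metadata.
#' @export
generate_ebrt_field <- function(grid, beam_radius_mm, gtv_mask,
                                fraction_dose_gy = 2, n_fractions = 30,
                                boost_gy = 10, penumbra_sigma_mm = 2,
                                noise_rel_sd = 0.02, seed = 1, run_id = 1L) {
  stopifnot_grid(grid)
  check_field_dim(gtv_mask, grid, "gtv_mask")
  if (fraction_dose_gy <= 0) stop("fraction_dose_gy must be > 0", call. = FALSE)
  if (n_fractions < 1) stop("n_fractions must be >= 1", call. = FALSE)
  if (boost_gy < 0) stop("boost_gy must be >= 0", call. = FALSE)
  phi <- lateral_beam_profile(grid, beam_radius_mm, penumbra_sigma_mm)
  n_boost <- if (boost_gy > 0) ceiling(boost_gy / fraction_dose_gy) else 0L
  boost_fx <- if (n_boost > 0) boost_gy / n_boost else 0
  fields <- local_rng(seed, {
    fd <- fraction_dose_gy * phi * noise_factor(grid$n_y, grid$n_x, noise_rel_sd)
    bd <- matrix(0, grid$n_y, grid$n_x)
    if (n_boost > 0) {
      bd_full <- boost_fx * phi * noise_factor(grid$n_y, grid$n_x, noise_rel_sd)
      bd[gtv_mask] <- bd_full[gtv_mask]
    }
    list(fraction_dose = fd, boost_fraction_dose = bd)
  })
  structure(list(fraction_dose = fields$fraction_dose,
                 boost_fraction_dose = fields$boost_fraction_dose,
                 n_fractions = as.integer(n_fractions),
                 n_boost_fractions = as.integer(n_boost),
                 grid = grid, run_id = as.integer(run_id), seed = seed),
            class = "ebrt_field")
}

#' Build an ensemble of independent dosimetry runs
#'
#' Replays a dose generator with seeds derived deterministically from a base
#' seed, emulating independent Monte Carlo runs. At least two runs are
#' required so that run-to-run uncertainties are defined; the reference
#' analysis uses four.
#'
#' @param generator Function `(seed, run_id) -> dose object` (e.g. a closure
#'   over [generate_bnct_components()]).
#' @param n_runs Number of runs (>= 2); default 4.
#' @param base_seed Integer base seed; run `i` uses seed
#'   `base_seed + 7919 * i`.
#' @return An object of class `run_ensemble`: list with element `runs`.
#' @export
make_run_ensemble <- function(generator, n_runs = 4, base_seed = 1) {
  if (n_runs < 2)
    stop("n_runs must be >= 2 (run-to-run uncertainty undefined otherwise)",
         call. = FALSE)
  seeds <- (base_seed + 7919 * seq_len(n_runs)) %% .Machine$integer.max
  runs <- lapply(seq_len(n_runs),
                 function(i) generator(seed = seeds[i], run_id = i))
  structure(list(runs = runs, base_seed = base_seed, seeds = seeds),
            class = "run_ensemble")
}
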