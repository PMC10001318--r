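#' RBE weights for the BNCT dose components
#'
#' Relative-biological-effectiveness factors applied to the physical dose
#' components when forming the biological (RBE-weighted) dose. One weight
#' applies to the summed boron-capture fragments (alpha + Li-7), one to the
#' gamma component, and one to the combined fast + thermal residual-neutron
#' component (the two neutron components share a single RBE, which is why
#' they are scored jointly). Defaults are literature-typical surrogates for
#' the clinical weighting convention.
#'
#' @param w_boron Weight for alpha + Li-7 boron dose; default 1.35.
#' @param w_gamma Weight for the gamma component; default 1.
#' @param w_neutron Weight for the residual neutron component; default 3.2.
#' @return A list of class `rbe_weights`.
#' @export
rbe_weights <- function(w_boron = 1.35, w_gamma = 1.0, w_neutron = 3.2) {
  if (w_boron <= 0 || w_gamma <= 0 || w_neutron <= 0)
    stop("all RBE weights must be > 0", call. = FALSE)
  structure(list(w_boron = w_boron, w_gamma = w_gamma, w_neutron = w_neutron),
            class = "rbe_weights")
}

#' RBE-weight physical dose components into biological dose
#'
#' `d = w_boron * (alpha + li7) + w_gamma * gamma + w_neutron * neutron_residual`,
#' per cell, in RBE-Gy.
#'
#' @param components A [generate_bnct_components()] `dose_components` object.
#' @param weights An [rbe_weights()] list.
#' @return Numeric matrix of per-cell RBE-weighted dose (RBE-Gy).
#' @export
weight_components <- function(components, weights = rbe_weights()) {
  if (!inherits(components, "dose_components"))
    stop("components must be a dose_components object", call. = FALSE)
  if (!inherits(weights, "rbe_weights")) weights <- do.call(rbe_weights, weights)
  weights$w_boron * (components$alpha + components$li7) +
    weights$w_gamma * components$gamma +
    weights$w_neutron * components$neutron_residual
}

#' Calibrate biological dose to the single-fraction prescription
#'
#' Rescales the RBE-weighted dose so that the maximum dose over tumour cells
#' equals the prescription (default 73.4 RBE-Gy, the reported mean maximum
#' tumour dose of clinical single-fraction BNCT). When a list of run fields
#' is supplied, the scale factor is computed once from their element-wise
#' ensemble mean and applied identically to every run, so per-run noise
#' cannot change the prescription scale between runs.
#'
#' @param bio A biological-dose matrix, or a list of such matrices (one per
#'   run of an ensemble).
#' @param tumour_mask Logical matrix selecting tumour cells (typically
#'   `mep$values > 0`).
#' @param prescription_rbe_gy Target maximum tumour dose; default 73.4.
#' @return List with `scale` (the factor applied) and `bio` (the rescaled
#'   matrix or list of matrices, same shape as the input).
#' @export
calibrate_prescription <- function(bio, tumour_mask,
                                   prescription_rbe_gy = 73.4) {
  single <- is.matrix(bio)
  runs <- if (single) list(bio) else bio
  if (!length(runs)) stop("empty dose input", call. = FALSE)
  if (!any(tumour_mask)) stop("tumour_mask selects no cells", call. = FALSE)
  mean_field <- Reduce(`+`, runs) / length(runs)
  mx <- max(mean_field[tumour_mask])
  if (mx <= 0) stop("maximum tumour dose is zero; cannot calibrate",
                    call. = FALSE)
  s <- prescription_rbe_gy / mx
  scaled <- lapply(runs, function(m) m * s)
  list(scale = s, bio = if (single) scaled[[1L]] else scaled)
}

#' Sample heterogeneous per-cell radiosensitivity
#'
#' Draws independent per-cell linear-quadratic parameters from truncated
#' Gaussian cell-line distributions (alpha truncated at > 0, beta at >= 0),
#' representing genetic heterogeneity in radiosensitivity across the tumour.
#' `alpha_sd = beta_sd = 0` reduces to a homogeneous cell population. The
#' field is a pure function of `(grid, parameters, seed)`.
#'
#' @param grid A [build_grid()] object.
#' @param alpha_mean,alpha_sd Mean and SD of alpha, 1/Gy.
#' @param beta_mean,beta_sd Mean and SD of beta, 1/Gy^2.
#' @param seed Integer seed.
#' @return An object of class `rs_field` with matrices `alpha`, `beta` and
#'   the distribution parameters.
#' @export
sample_radiosensitivity <- function(grid, alpha_mean = 0.3, alpha_sd = 0.12,
                                    beta_mean = 0.03, beta_sd = 0.01,
                                    seed = 1) {
  stopifnot_grid(grid)
  if (alpha_mean <= 0 || beta_mean < 0)
    stop("alpha_mean must be > 0 and beta_mean >= 0", call. = FALSE)
  if (alpha_sd < 0 || beta_sd < 0) stop("sds must be >= 0", call. = FALSE)
  n <- grid$n_y * grid$n_x
  draws <- local_rng(seed, {
    a <- rtrunc_norm(n, alpha_mean, alpha_sd, lower = 0, strict = TRUE)
    b <- rtrunc_norm(n, beta_mean, beta_sd, lower = 0, strict = FALSE)
    list(a = a, b = b)
  })
  structure(list(alpha = matrix(draws$a, grid$n_y, grid$n_x),
                 beta = matrix(draws$b, grid$n_y, grid$n_x),
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 beta_mean = beta_mean, beta_sd = beta_sd,
                 seed = seed, grid = grid),
            class = "rs_field")
}

# Rejection-sampled truncated normal. strict: lower bound excluded.
rtrunc_norm <- function(n, mean, sd, lower = 0, strict = FALSE) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- if (strict) x <= lower else x < lower
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- if (strict) x <= lower else x < lower
  }
  x
}

#' Build an oxygen-enhancement-ratio field
#'
#' For BNCT (`mode = "bnct"`) the OER is 1 everywhere: high-LET boron-capture
#' fragments are insensitive to oxygen status. For X-ray EBRT
#' (`mode = "ebrt"`) the field models a severely hypoxic tumour core:
#' `OER(r) = 1 + (oer_max - 1) * exp(-(r / core_radius)^2)`, radially
#' monotone from `oer_max` at the tumour centre to 1 far outside the core
#' (and hence at the ME boundary).
#'
#' @param grid A [build_grid()] object.
#' @param mode `"bnct"` or `"ebrt"`.
#' @param oer_max Maximum OER at the tumour centre (>= 1); default 3.
#' @param core_radius_mm Gaussian scale of the hypoxic core, mm; default 1
#'   (hypoxia concentrated at GTV scale).
#' @return Numeric matrix of per-cell OER values in \[1, `oer_max`\].
#' @export
build_oer_field <- function(grid, mode = c("bnct", "ebrt"), oer_max = 3,
                            core_radius_mm = 1) {
  stopifnot_grid(grid)
  mode <- match.arg(mode)
  if (oer_max < 1) stop("oer_max must be >= 1", call. = FALSE)
  if (core_radius_mm <= 0) stop("core_radius_mm must be > 0", call. = FALSE)
  if (mode == "bnct" || oer_max == 1)
    return(matrix(1, grid$n_y, grid$n_x))
  r <- radial_distance_field(grid)
  1 + (oer_max - 1) * exp(-(r / core_radius_mm)^2)
}

#' Per-cell survival probability, single-fraction BNCT
#'
#' Linear-quadratic survival weighted by tumour-cell probability:
#' `SP = MEP * exp(-(alpha * d + beta * d^2))` with `d` the RBE-weighted dose
#' delivered in a single fraction. The MEP factor makes SP the probability
#' that a cell both is a tumour clonogen and survives, so
#' `0 <= SP <= MEP` always, with equality wherever `d = 0`.
#'
#' @param mep An `mep_field`.
#' @param bio Calibrated biological-dose matrix (RBE-Gy).
#' @param rs A [sample_radiosensitivity()] `rs_field`.
#' @return Numeric matrix of per-cell survival probabilities.
#' @export
survival_bnct <- function(mep, bio, rs) {
  if (!inherits(mep, "mep_field")) stop("mep must be a mep_field", call. = FALSE)
  if (!inherits(rs, "rs_field")) stop("rs must be an rs_field", call. = FALSE)
  check_field_dim(bio, mep$grid, "biological dose")
  if (any(bio < 0)) stop("negative dose encountered", call. = FALSE)
  mep$values * exp(-(rs$alpha * bio + rs$beta * bio^2))
}

#' Per-cell survival probability, fractionated EBRT
#'
#' Fractionated linear-quadratic survival with oxygen modification applied
#' as a dose divisor (the classical OER definition): the effective dose per
#' fraction is `d_eff = d_fx / OER` and
#' `SP = MEP * exp(-(n * (alpha * d_eff + beta * d_eff^2) +
#'                   n_boost * (alpha * d_b + beta * d_b^2)))`
#' where the boost term applies only inside the GTV (where the boost
#' fraction dose is non-zero). With OER = 1, one fraction and no boost this
#' reduces exactly to [survival_bnct()] on the same dose.
#'
#' @param mep An `mep_field`.
#' @param ebrt A [generate_ebrt_field()] `ebrt_field`.
#' @param rs An `rs_field`.
#' @param oer OER matrix from [build_oer_field()].
#' @return Numeric matrix of per-cell survival probabilities.
#' @export
survival_ebrt <- function(mep, ebrt, rs, oer) {
  if (!inherits(mep, "mep_field")) stop("mep must be a mep_field", call. = FALSE)
  if (!inherits(ebrt, "ebrt_field")) stop("ebrt must be an ebrt_field", call. = FALSE)
  if (!inherits(rs, "rs_field")) stop("rs must be an rs_field", call. = FALSE)
  check_field_dim(oer, mep$grid, "OER field")
  if (any(ebrt$fraction_dose < 0) || any(ebrt$boost_fraction_dose < 0))
    stop("negative dose encountered", call. = FALSE)
  if (any(oer < 1)) stop("OER values must be >= 1", call. = FALSE)
  d1 <- ebrt$fraction_dose / oer
  db <- ebrt$boost_fraction_dose / oer
  lethality <- ebrt$n_fractions * (rs$alpha * d1 + rs$beta * d1^2) +
    ebrt$n_boost_fractions * (rs$alpha * db + rs$beta * db^2)
  mep$values * exp(-lethality)
}
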