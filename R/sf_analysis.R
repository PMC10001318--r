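#' Expected number of surviving tumour cells in a region
#'
#' Sums per-cell survival probabilities over a region of interest — the
#' expected surviving clonogen count.
#'
#' @param survival Survival-probability matrix ([survival_bnct()] /
#'   [survival_ebrt()]).
#' @param roi_mask Logical matrix; `NULL` means the whole grid.
#' @return Non-negative scalar.
#' @export
count_survivors <- function(survival, roi_mask = NULL) {
  if (is.null(roi_mask)) return(sum(survival))
  if (!identical(dim(survival), dim(roi_mask)))
    stop("roi_mask does not match the survival map", call. = FALSE)
  sum(survival[roi_mask])
}

#' Expected initial tumour-cell count
#'
#' Sums the tumour-cell probabilities (MEP) over the requested support — the
#' expected number of tumour clonogens present before treatment. The default
#' support is the whole grid, which makes regional survival fractions
#' additive to the total.
#'
#' @param mep An `mep_field`.
#' @param roi_mask Logical matrix; `NULL` (default) means the whole grid.
#' @return Non-negative scalar.
#' @export
initial_tumour_cells <- function(mep, roi_mask = NULL) {
  if (!inherits(mep, "mep_field")) stop("mep must be a mep_field", call. = FALSE)
  count_survivors(mep$values, roi_mask)
}

#' Regional survival fraction
#'
#' `SF = 100 * (surviving cells in the ROI) / (initial tumour cells)`, in
#' percent. With `denominator_mode = "global"` (default) the denominator is
#' the grid-wide initial count, so the survival fractions of disjoint regions
#' covering the grid sum exactly to the total SF. `"per_region"` divides by
#' the initial count inside the ROI instead.
#'
#' @param survival Survival-probability matrix.
#' @param mep An `mep_field`.
#' @param roi_mask Logical matrix; `NULL` means the whole grid.
#' @param denominator_mode `"global"` or `"per_region"`.
#' @return SF in percent.
#' @export
region_sf <- function(survival, mep, roi_mask = NULL,
                      denominator_mode = c("global", "per_region")) {
  denominator_mode <- match.arg(denominator_mode)
  denom <- initial_tumour_cells(
    mep, if (denominator_mode == "global") NULL else roi_mask)
  if (denom <= 0)
    stop("survival fraction undefined: no tumour cells in the denominator support",
         call. = FALSE)
  100 * count_survivors(survival, roi_mask) / denom
}

#' Differential survival fraction by radial shell
#'
#' Survival fraction per concentric shell about the tumour centre:
#' `SF_s = 100 * sum(SP in shell) / sum(MEP in shell)`. Shells containing no
#' tumour cells (zero initial MEP) are reported as `NA` (undefined), not 0.
#'
#' @param survival Survival-probability matrix.
#' @param mep An `mep_field`.
#' @param shells A [shell_decomposition()] object.
#' @return Data frame with columns `shell` (0-based index), `r_mm` (shell
#'   centre radius), `n_cells`, `initial_cells`, `survivors`, `sf` (percent,
#'   `NA` where undefined).
#' @export
differential_sf <- function(survival, mep, shells) {
  if (!inherits(shells, "shell_decomposition"))
    stop("shells must be a shell_decomposition", call. = FALSE)
  if (!inherits(mep, "mep_field")) stop("mep must be a mep_field", call. = FALSE)
  idx <- factor(shells$shell_index, levels = 0:(shells$n_shells - 1L))
  init <- as.numeric(tapply(mep$values, idx, sum, default = 0))
  surv <- as.numeric(tapply(survival, idx, sum, default = 0))
  ncell <- as.integer(table(idx))
  sf <- ifelse(init > 0, 100 * (surv / init), NA_real_)
  data.frame(shell = 0:(shells$n_shells - 1L),
             r_mm = shells$shell_centre_mm,
             n_cells = ncell, initial_cells = init,
             survivors = surv, sf = sf)
}

#' Mean and standard deviation of survival fractions across runs
#'
#' Collapses per-run regional survival fractions into ensemble mean and
#' sample SD — the run-to-run uncertainty from independent dosimetry runs.
#'
#' @param per_run Data frame with one row per run and numeric SF columns
#'   (e.g. `sf_in_beam`, `sf_penumbra`, `sf_out_of_field`, `sf_total`).
#' @return List with `mean` and `sd` named vectors and `n_runs`.
#' @export
run_statistics <- function(per_run) {
  num <- per_run[vapply(per_run, is.numeric, logical(1))]
  num <- num[setdiff(names(num), "run")]
  if (nrow(num) < 2)
    stop("need >= 2 runs for run-to-run statistics", call. = FALSE)
  list(mean = vapply(num, mean, numeric(1)),
       sd = vapply(num, stats::sd, numeric(1)),
       n_runs = nrow(num))
}

#' Survival-fraction change from extending the CTV margin
#'
#' Relative SF reduction (percent) when the clinical-target-volume margin is
#' extended: `100 * (SF_small - SF_large) / SF_small`. Positive values mean
#' the larger margin kills more of the infiltrating disease; negative values
#' are possible and reported as such.
#'
#' @param sf_small_ctv SF (percent) at the smaller margin (e.g. 2.0 cm).
#' @param sf_large_ctv SF (percent) at the larger margin (e.g. 2.5 cm).
#' @return SF change in percent.
#' @export
sf_change <- function(sf_small_ctv, sf_large_ctv) {
  if (any(sf_small_ctv <= 0))
    stop("sf_change undefined for zero baseline SF", call. = FALSE)
  100 * (sf_small_ctv - sf_large_ctv) / sf_small_ctv
}

#' Monte Carlo summary of per-run SF changes
#'
#' Summarises the SF-change values observed across dosimetry runs by drawing
#' `n_samples` values uniformly within their range and reporting the sample
#' mean and SD. Deterministic given the seed; if all per-run values coincide
#' the SD is exactly 0.
#'
#' @param per_run_sfchange Numeric vector (>= 2) of per-run SF changes, percent.
#' @param n_samples Number of uniform draws; default 10.
#' @param seed Integer seed.
#' @return List with `mean`, `sd`, `samples`, `n_samples`, `seed`.
#' @export
sfchange_mc <- function(per_run_sfchange, n_samples = 10, seed = 1) {
  if (length(per_run_sfchange) < 2)
    stop("need >= 2 per-run SF-change values", call. = FALSE)
  lo <- min(per_run_sfchange); hi <- max(per_run_sfchange)
  samples <- local_rng(seed, stats::runif(n_samples, lo, hi))
  list(mean = mean(samples),
       sd = if (lo == hi) 0 else stats::sd(samples),
       samples = samples, n_samples = n_samples, seed = seed)
}

#' Compare SF-change samples between modalities
#'
#' Two-sided Welch two-sample t-test on the Monte Carlo SF-change samples of
#' two treatment modalities. Identical degenerate (zero-variance) samples
#' return p = 1 by convention.
#'
#' @param samples_a,samples_b Numeric vectors (>= 2 each).
#' @return p-value in (0, 1\].
#' @export
compare_modalities <- function(samples_a, samples_b) {
  if (length(samples_a) < 2 || length(samples_b) < 2)
    stop("need >= 2 samples per modality", call. = FALSE)
  va <- stats::var(samples_a); vb <- stats::var(samples_b)
  if (va == 0 && vb == 0) {
    if (mean(samples_a) == mean(samples_b)) return(1)
    return(.Machine$double.xmin)  # perfectly separated degenerate samples
  }
  stats::t.test(samples_a, samples_b, var.equal = FALSE)$p.value
}
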