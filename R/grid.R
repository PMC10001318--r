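#' Build the cellular scoring-slice grid
#'
#' Defines a 2-D lattice of square cells representing the dose-scoring slice
#' through the tumour centre. The tumour centre sits at the geometric centre
#' of the grid; all distances are measured from cell centres, in millimetres.
#'
#' @param n_x,n_y Number of cells along x and y (columns and rows).
#' @param cell_size_um Side length of a (square) cell in micrometres. The
#'   reference configuration is a 9 cm x 9 cm slice of 20 um cells
#'   (4500 x 4500); analyses are routinely run at reduced resolution
#'   (e.g. 200 um cells) with the same physical extent.
#' @param slice_depth_cm Depth of the slice below the phantom surface
#'   (metadata only; the model is purely 2-D).
#'
#' @return An object of class `grid_spec`: a list with elements `n_x`, `n_y`,
#'   `cell_size_um`, `cell_size_mm`, `extent_x_mm`, `extent_y_mm`,
#'   `slice_depth_cm`.
#' @examples
#' g <- build_grid(450, 450, cell_size_um = 200)
#' g$extent_x_mm  # 90 mm
#' @export
build_grid <- function(n_x, n_y, cell_size_um, slice_depth_cm = 2.0) {
  if (length(n_x) != 1L || length(n_y) != 1L || n_x < 1 || n_y < 1 ||
      n_x != round(n_x) || n_y != round(n_y))
    stop("n_x and n_y must be positive integers", call. = FALSE)
  if (length(cell_size_um) != 1L || !is.finite(cell_size_um) || cell_size_um <= 0)
    stop("cell_size_um must be a positive number", call. = FALSE)
  g <- list(
    n_x = as.integer(n_x), n_y = as.integer(n_y),
    cell_size_um = cell_size_um,
    cell_size_mm = cell_size_um / 1000,
    extent_x_mm = n_x * cell_size_um / 1000,
    extent_y_mm = n_y * cell_size_um / 1000,
    slice_depth_cm = slice_depth_cm
  )
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g um (%.1f x %.1f mm slice)\n",
              x$n_x, x$n_y, x$cell_size_um, x$extent_x_mm, x$extent_y_mm))
  invisible(x)
}

# Cell-centre coordinates (mm) relative to the tumour centre.
cell_coords <- function(grid) {
  cs <- grid$cell_size_mm
  list(
    x = (seq_len(grid$n_x) - (grid$n_x + 1) / 2) * cs,
    y = (seq_len(grid$n_y) - (grid$n_y + 1) / 2) * cs
  )
}

stopifnot_grid <- function(grid) {
  if (!inherits(grid, "grid_spec")) stop("expected a grid_spec", call. = FALSE)
}

# Check that a field matrix matches the grid dimensions.
check_field_dim <- function(mat, grid, what = "field") {
  if (!is.matrix(mat) || nrow(mat) != grid$n_y || ncol(mat) != grid$n_x)
    stop(sprintf("%s does not match grid (%d x %d expected)",
                 what, grid$n_y, grid$n_x), call. = FALSE)
  invisible(TRUE)
}

#' Radial distance field
#'
#' Euclidean distance (mm) from the tumour centre to every cell centre.
#'
#' @param grid A [build_grid()] object.
#' @return Numeric matrix (`n_y` rows, `n_x` columns) of distances in mm.
#' @export
radial_distance_field <- function(grid) {
  stopifnot_grid(grid)
  cc <- cell_coords(grid)
  sqrt(outer(cc$y^2, cc$x^2, `+`))
}

#' Region-of-interest masks
#'
#' Classifies every cell of the slice into the regions used throughout the
#' survival-fraction analysis: the gross tumour volume (GTV) disc, the
#' microscopic-extension (ME) annulus, the in-beam region (the PTV footprint),
#' the penumbra annulus just outside the beam, and the out-of-field remainder.
#' A cell belongs to a circular region iff its centre does.
#'
#' @param grid A [build_grid()] object.
#' @param beam_radius_mm Beam field radius on the slice (25 mm covers a
#'   2.0 cm CTV margin, 30 mm a 2.5 cm margin).
#' @param gtv_radius_mm GTV disc radius; default 0.5 mm (1 mm diameter
#'   gross tumour).
#' @param me_extent_mm Extent of the microscopic-extension region beyond the
#'   GTV surface; default 41 mm.
#' @param penumbra_width_mm Width of the penumbra annulus outside the beam
#'   edge; default 5 mm.
#'
#' @return An object of class `region_masks`: logical matrices `gtv`,
#'   `me_region`, `in_beam`, `penumbra`, `out_of_field` plus the defining
#'   radii. `in_beam`, `penumbra` and `out_of_field` partition the grid.
#' @export
make_roi_masks <- function(grid, beam_radius_mm, gtv_radius_mm = 0.5,
                           me_extent_mm = 41, penumbra_width_mm = 5) {
  stopifnot_grid(grid)
  if (beam_radius_mm <= 0) stop("beam_radius_mm must be > 0", call. = FALSE)
  if (penumbra_width_mm <= 0) stop("penumbra_width_mm must be > 0", call. = FALSE)
  if (gtv_radius_mm >= gtv_radius_mm + me_extent_mm || me_extent_mm <= 0)
    stop("me_extent_mm must be > 0", call. = FALSE)
  if (gtv_radius_mm > beam_radius_mm)
    stop("GTV must lie inside the beam (gtv_radius_mm <= beam_radius_mm)",
         call. = FALSE)
  r <- radial_distance_field(grid)
  half_extent <- min(grid$extent_x_mm, grid$extent_y_mm) / 2
  if (beam_radius_mm + penumbra_width_mm > half_extent)
    warning("beam + penumbra exceed the grid half-extent; ",
            "out_of_field region may be empty", call. = FALSE)
  m <- list(
    gtv = r <= gtv_radius_mm,
    me_region = r > gtv_radius_mm & r <= gtv_radius_mm + me_extent_mm,
    in_beam = r <= beam_radius_mm,
    penumbra = r > beam_radius_mm & r <= beam_radius_mm + penumbra_width_mm,
    out_of_field = r > beam_radius_mm + penumbra_width_mm,
    beam_radius_mm = beam_radius_mm,
    gtv_radius_mm = gtv_radius_mm,
    me_extent_mm = me_extent_mm,
    penumbra_width_mm = penumbra_width_mm
  )
  class(m) <- "region_masks"
  m
}

#' @export
print.region_masks <- function(x, ...) {
  cat(sprintf(
    "region_masks: beam %g mm, penumbra +%g mm | cells: beam %d, penumbra %d, out %d\n",
    x$beam_radius_mm, x$penumbra_width_mm,
    sum(x$in_beam), sum(x$penumbra), sum(x$out_of_field)))
  invisible(x)
}

#' Concentric radial shell decomposition
#'
#' Assigns every cell to a concentric annulus ("shell") about the tumour
#' centre, for differential survival-fraction analysis. Shell `k` contains
#' cells with `k*w <= r < (k+1)*w`, i.e. `shell_index = floor(r / w)`.
#'
#' @param grid A [build_grid()] object.
#' @param shell_width_mm Shell width; default 0.5 mm.
#' @return An object of class `shell_decomposition`: integer matrix
#'   `shell_index` (0-based), `shell_width_mm`, `n_shells`, vectors
#'   `shell_outer_mm` and `shell_centre_mm`.
#' @export
shell_decomposition <- function(grid, shell_width_mm = 0.5) {
  stopifnot_grid(grid)
  if (shell_width_mm <= 0) stop("shell_width_mm must be > 0", call. = FALSE)
  r <- radial_distance_field(grid)
  idx <- floor(r / shell_width_mm)
  storage.mode(idx) <- "integer"
  n_shells <- max(idx) + 1L
  s <- list(
    shell_index = idx,
    shell_width_mm = shell_width_mm,
    n_shells = n_shells,
    shell_outer_mm = seq_len(n_shells) * shell_width_mm,
    shell_centre_mm = (seq_len(n_shells) - 0.5) * shell_width_mm
  )
  class(s) <- "shell_decomposition"
  s
}
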