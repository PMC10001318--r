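#' Write a field matrix as dense CSV with a metadata header
#'
#' Row-major dense CSV, one value per cell, preceded by a single comment
#' line of `key=value` pairs separated by `;` recording grid shape, cell
#' size and any extra metadata (units, component, run id, seed).
#'
#' @param mat Numeric matrix.
#' @param path Output path.
#' @param meta Named list of additional metadata values.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(mat, path, meta = list()) {
  meta <- c(list(n_y = nrow(mat), n_x = ncol(mat)), meta)
  header <- paste0("# ", paste(names(meta), unlist(meta), sep = "=",
                               collapse = ";"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(mat, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a field matrix written by [write_field_csv()]
#'
#' @param path Input path.
#' @return Numeric matrix with attribute `meta` (named character vector).
#' @export
read_field_csv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# "))
    stop("missing metadata header line", call. = FALSE)
  pairs <- strsplit(strsplit(sub("^# ", "", header), ";")[[1]], "=")
  meta <- vapply(pairs, `[`, character(1), 2)
  names(meta) <- vapply(pairs, `[`, character(1), 1)
  mat <- as.matrix(utils::read.table(path, sep = ",", skip = 1L,
                                     colClasses = "numeric"))
  dimnames(mat) <- NULL
  attr(mat, "meta") <- meta
  mat
}

#' Write region masks as an integer-coded CSV
#'
#' Encodes the beam partition as 0 = out-of-field, 1 = in-beam,
#' 2 = penumbra, with the usual metadata header.
#'
#' @param masks A [make_roi_masks()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_masks_csv <- function(masks, path) {
  coded <- matrix(0L, nrow(masks$in_beam), ncol(masks$in_beam))
  coded[masks$in_beam] <- 1L
  coded[masks$penumbra] <- 2L
  write_field_csv(coded, path,
                  meta = list(coding = "0=out|1=beam|2=penumbra",
                              beam_radius_mm = masks$beam_radius_mm,
                              penumbra_width_mm = masks$penumbra_width_mm))
}

#' Write a survival-fraction report as JSON
#'
#' @param report An `sf_report` or `sf_change_result` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sf_report <- function(report, path) {
  out <- unclass(report)
  out$config <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
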