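# Plain-text / TIFF interfaces shared by the generators and the detector.

#' Write an smFISH object table as TSV
#'
#' Schema: `object_id`, `region`, `x`, `y`, `z`, `n_slices`,
#' `ref_intensity`, `tgt_intensity`; with `truth = TRUE` the ground-truth
#' columns `copy_number` and `detected` (present only in generated tables)
#' are appended.
#'
#' @param objects An `smfish_objects` `data.frame`.
#' @param path Output path.
#' @param truth Export ground-truth columns when available? Default
#'   `FALSE`.
#' @export
write_object_table <- function(objects, path, truth = FALSE) {
  cols <- c("object_id", "region", "x", "y", "z", "n_slices",
            "ref_intensity", "tgt_intensity")
  if (truth) {
    cols <- c(cols, intersect(c("copy_number", "detected"),
                              names(objects)))
  }
  write.table(as.data.frame(objects)[, cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an smFISH object table from TSV
#'
#' @param path Path to a TSV written by [write_object_table()] (or any
#'   table with the same header).
#' @return An `smfish_objects` `data.frame`.
#' @export
read_object_table <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("object_id", "region", "x", "y", "z", "n_slices",
            "ref_intensity", "tgt_intensity")
  missing <- setdiff(need, names(out))
  if (length(missing) > 0) {
    stop("object table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  class(out) <- c("smfish_objects", "data.frame")
  out
}

#' Write a single-channel stack as a multi-page 16-bit TIFF
#'
#' One page per z-slice; voxel values are photon counts, rounded and
#' clamped to the unsigned 16-bit range.
#'
#' @param stack Numeric array `(nx, ny, nz)`.
#' @param path Output path.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  pages <- lapply(seq_len(dim(stack)[3]), function(z) {
    # tiff stores [row, col]; keep rows = y so images view naturally
    t(pmin(pmax(round(stack[, , z]), 0), 65535)) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page 16-bit TIFF as a photon-count stack
#'
#' @param path Path to a TIFF written by [write_stack_tiff()].
#' @return Numeric array `(nx, ny, nz)` of photon counts.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  first <- pages[[1]]
  out <- array(0, dim = c(ncol(first), nrow(first), nz))
  for (z in seq_len(nz)) out[, , z] <- t(round(pages[[z]] * 65535))
  out
}
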