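#' @include AllClasses.R
NULL

#' Construct a saturation-offset table
#'
#' @param offset_ppm numeric, unique signed offsets in ppm, in on-disk
#'   frame order.
#' @param n_acq integer, acquisitions per offset (recycled if length 1).
#' @param reference_ppm offset of the registration reference frame.
#' @return an [OffsetTable].
#' @examples
#' offsetTable(c(-3.5, 3.5), n_acq = 8)
#' @export
offsetTable <- function(offset_ppm, n_acq = 1L, reference_ppm = 3.5) {
  n_acq <- as.integer(rep_len(n_acq, length(offset_ppm)))
  new("OffsetTable", offset_ppm = as.numeric(offset_ppm), n_acq = n_acq,
      reference_ppm = reference_ppm)
}

#' The default 31-offset, 61-frame clinical protocol
#'
#' Offsets 0, +/-0.25, +/-0.5, +/-0.75, +/-1 (2), +/-1.5 (2), +/-2 (2),
#' +/-2.5 (2), +/-3 (2), +/-3.25 (2), +/-3.5 (8), +/-3.75 (2), +/-4 (2),
#' +/-4.5, +/-5, +/-6 ppm, where parenthesized values are acquisition
#' counts (1 where unspecified): 31 unique offsets, 61 frames in total.
#'
#' @return an [OffsetTable] with 31 unique offsets and 61 frames.
#' @examples
#' nFrames(defaultOffsetTable())  # 61
#' @export
defaultOffsetTable <- function() {
  mag <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 3.25, 3.5, 3.75, 4, 4.5, 5, 6)
  rep2 <- c(1, 1, 1, 2, 2, 2, 2, 2, 2, 8, 2, 2, 1, 1, 1)
  offsetTable(c(0, as.vector(rbind(mag, -mag))),
              c(1L, as.vector(rbind(rep2, rep2))))
}

#' Expand an offset table to per-frame offsets
#'
#' Repeats at one offset are contiguous, in table order, matching the
#' on-disk frame layout.
#'
#' @param table an [OffsetTable].
#' @return numeric vector with one entry per frame.
#' @export
expandOffsets <- function(table) {
  stopifnot(is(table, "OffsetTable"))
  rep(table@offset_ppm, times = table@n_acq)
}

#' Read / write an offset table as CSV
#'
#' The CSV has columns `offset_ppm` and `n_acq`; the reference offset is
#' stored as an attribute column `reference_ppm` on the first row.
#'
#' @param path file path.
#' @return [readOffsetTable()] returns an [OffsetTable];
#'   [writeOffsetTable()] returns `path` invisibly.
#' @export
readOffsetTable <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("offset_ppm", "n_acq") %in% names(d)))
    stop("offset table CSV needs columns offset_ppm, n_acq")
  ref <- if ("reference_ppm" %in% names(d)) d$reference_ppm[1L] else 3.5
  offsetTable(d$offset_ppm, d$n_acq, reference_ppm = ref)
}

#' @rdname readOffsetTable
#' @param table an [OffsetTable] to write.
#' @export
writeOffsetTable <- function(table, path) {
  stopifnot(is(table, "OffsetTable"))
  d <- data.frame(offset_ppm = table@offset_ppm, n_acq = table@n_acq,
                  reference_ppm = table@reference_ppm)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
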