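#' Paired genomic anchors
#'
#' A `PairSet` is an ordered table of paired anchors (the loop/domain call
#' abstraction): columns `chrom1,start1,end1,chrom2,start2,end2`
#' (0-based half-open), an optional `source` label per pair, and any number of
#' metadata columns. Order is stable and index-addressable; all operations
#' preserve metadata bit-exactly and never reorder surviving pairs.
#'
#' @param df A data.frame with at least the six anchor columns.
#' @param chromsizes A [chrom_sizes] table; chromosomes are validated
#'   against it.
#' @param source Optional single source label recycled to all pairs.
#' @return A `PairSet` (a classed data.frame with a `chromsizes` attribute).
#' @export
pair_set <- function(df, chromsizes, source = NULL) {
  cs <- .validate_chromsizes(chromsizes)
  core <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (!all(core %in% names(df))) .stopf("missing anchor columns: %s",
                                        paste(setdiff(core, names(df)), collapse = ", "))
  df$chrom1 <- as.character(df$chrom1); df$chrom2 <- as.character(df$chrom2)
  for (cc in c(1, 2)) {
    ci <- match(df[[paste0("chrom", cc)]], cs$chrom)
    if (anyNA(ci)) {
      bad <- which(is.na(ci))[1]
      .stopf("pair %d: unknown chromosome '%s'", bad, df[[paste0("chrom", cc)]][bad])
    }
    s <- df[[paste0("start", cc)]]; e <- df[[paste0("end", cc)]]
    if (any(e <= s)) .stopf("pair %d: end <= start", which(e <= s)[1])
    if (any(s < 0) || any(e > cs$length[ci]))
      .stopf("pair %d: anchor outside chromosome",
             which(s < 0 | e > cs$length[ci])[1])
  }
  if (!is.null(source)) df$source <- as.character(source)
  df <- .orient_pairs(df)
  rownames(df) <- NULL
  structure(df, chromsizes = cs, class = c("PairSet", "data.frame"))
}

## canonical orientation: intra-chromosomal anchors sorted by (start, end)
.orient_pairs <- function(df) {
  flip <- df$chrom1 == df$chrom2 &
    (df$start2 < df$start1 | (df$start2 == df$start1 & df$end2 < df$end1))
  if (any(flip)) {
    tmp <- df[flip, c("chrom1", "start1", "end1")]
    df[flip, c("chrom1", "start1", "end1")] <- df[flip, c("chrom2", "start2", "end2")]
    df[flip, c("chrom2", "start2", "end2")] <- tmp
  }
  df
}

.pair_core_cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
.pair_reserved <- c(.pair_core_cols, "source", "bin1", "bin2",
                    "r1", "r2", "c1", "c2", ".oor")

#' @export
`[.PairSet` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "chromsizes") <- attr(x, "chromsizes")
    if (!is.null(attr(x, "binsize"))) attr(out, "binsize") <- attr(x, "binsize")
    class(out) <- class(x)
  }
  out
}

#' Metadata columns of a PairSet
#' @param x A `PairSet`.
#' @return Character vector of metadata column names.
#' @export
pair_metadata_cols <- function(x) setdiff(names(x), .pair_reserved)

#' @export
print.PairSet <- function(x, ...) {
  cat(sprintf("%s with %d pairs", class(x)[1], nrow(x)))
  bs <- attr(x, "binsize")
  if (!is.null(bs)) cat(sprintf(" | binsize %s bp", format(bs, scientific = FALSE)))
  md <- pair_metadata_cols(x)
  if (length(md)) cat(sprintf(" | metadata: %s", paste(md, collapse = ", ")))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more\n", nrow(x) - 6))
  invisible(x)
}

#' Snap anchors to a bin grid
#'
#' Each anchor collapses to the single bin containing its start, midpoint, or
#' last base (`anchor_point`), i.e. bin `k = floor(p / binsize)`. Midpoint
#' ties at half-integers resolve by floor. Intra-chromosomal pairs are
#' reoriented so `bin1 <= bin2`; metadata is carried unchanged. The result
#' carries genome-wide 0-based bin ids (`bin1`, `bin2`) on the grid defined
#' by the `chromsizes` attribute.
#'
#' @param pairs A `PairSet`.
#' @param binsize_bp Positive bin size in bp.
#' @param anchor_point `"center"` (default), `"start"`, or `"end"`.
#' @return A `BinnedPairSet`: the input with `bin1`/`bin2` columns, snapped
#'   anchor coordinates, and a `binsize` attribute.
#' @export
snap_to_bins <- function(pairs, binsize_bp,
                         anchor_point = c("center", "start", "end")) {
  stopifnot(inherits(pairs, "PairSet"))
  anchor_point <- match.arg(anchor_point)
  if (binsize_bp <= 0) .stopf("binsize_bp must be positive")
  cs <- attr(pairs, "chromsizes")
  df <- as.data.frame(pairs)
  for (cc in c(1, 2)) {
    s <- df[[paste0("start", cc)]]; e <- df[[paste0("end", cc)]]
    p <- switch(anchor_point,
                start = s, end = e - 1, center = floor((s + e) / 2))
    k <- floor(p / binsize_bp)
    ci <- match(df[[paste0("chrom", cc)]], cs$chrom)
    nb <- .bins_per_chrom(cs, binsize_bp)[ci]
    if (any(k >= nb)) .stopf("pair %d: snapped bin beyond chromosome end",
                             which(k >= nb)[1])
    df[[paste0("start", cc)]] <- k * binsize_bp
    df[[paste0("end", cc)]] <- pmin((k + 1) * binsize_bp, cs$length[ci])
    df[[paste0("bin", cc)]] <- .global_bin(cs, binsize_bp,
                                           df[[paste0("chrom", cc)]], k)
  }
  flip <- df$chrom1 == df$chrom2 & df$bin2 < df$bin1
  if (any(flip)) {
    tmp <- df[flip, c("chrom1", "start1", "end1", "bin1")]
    df[flip, c("chrom1", "start1", "end1", "bin1")] <-
      df[flip, c("chrom2", "start2", "end2", "bin2")]
    df[flip, c("chrom2", "start2", "end2", "bin2")] <- tmp
  }
  structure(df, chromsizes = cs, binsize = binsize_bp,
            class = c("BinnedPairSet", "PairSet", "data.frame"))
}

.assert_binned <- function(pairs) {
  if (!inherits(pairs, "BinnedPairSet") || is.null(attr(pairs, "binsize")))
    .stopf("pairs must first be snapped to a bin grid (see snap_to_bins)")
  invisible(pairs)
}

.has_footprints <- function(pairs) all(c("r1", "r2", "c1", "c2") %in% names(pairs))

## footprint bin intervals for either pixels or expanded squares
.footprints <- function(pairs) {
  if (.has_footprints(pairs)) {
    data.frame(r1 = pairs$r1, r2 = pairs$r2, c1 = pairs$c1, c2 = pairs$c2)
  } else {
    data.frame(r1 = pairs$bin1, r2 = pairs$bin1 + 1L,
               c1 = pairs$bin2, c2 = pairs$bin2 + 1L)
  }
}

#' Expand pixels to square submatrix footprints
#'
#' Every single-bin anchor pair `(b1, b2)` grows to a
#' `(2*buffer+1) x (2*buffer+1)` footprint: rows `[b1-buffer, b1+buffer+1)`,
#' columns `[b2-buffer, b2+buffer+1)` in bins. Footprints are never clipped:
#' pairs whose footprint would leave their chromosome are flagged in the
#' `.oor` column for the caller to drop (see [drop_out_of_range()]).
#'
#' @param pairs A `BinnedPairSet` whose anchors are single bins.
#' @param buffer_bins Non-negative number of bins added on every side.
#' @return The input with footprint columns `r1,r2,c1,c2` and flag `.oor`.
#' @export
expand_pixels <- function(pairs, buffer_bins) {
  .assert_binned(pairs)
  stopifnot(buffer_bins >= 0)
  buffer_bins <- as.integer(buffer_bins)
  cs <- attr(pairs, "chromsizes"); bs <- attr(pairs, "binsize")
  off <- .chrom_offsets(cs, bs)
  df <- as.data.frame(pairs)
  df$r1 <- df$bin1 - buffer_bins; df$r2 <- df$bin1 + buffer_bins + 1L
  df$c1 <- df$bin2 - buffer_bins; df$c2 <- df$bin2 + buffer_bins + 1L
  ci1 <- match(df$chrom1, cs$chrom); ci2 <- match(df$chrom2, cs$chrom)
  df$.oor <- df$r1 < off[ci1] | df$r2 > off[ci1 + 1L] |
    df$c1 < off[ci2] | df$c2 > off[ci2 + 1L]
  structure(df, chromsizes = cs, binsize = bs,
            class = c("BinnedPairSet", "PairSet", "data.frame"))
}

#' Drop pairs flagged out of range
#'
#' Removes pairs flagged by [expand_pixels()] whose footprint leaves the
#' chromosome, with a message stating the dropped count.
#' @param pairs A `BinnedPairSet` with an `.oor` column.
#' @return The surviving pairs (original order) with the flag removed.
#' @export
drop_out_of_range <- function(pairs) {
  if (is.null(pairs$.oor)) return(pairs)
  n_drop <- sum(pairs$.oor)
  if (n_drop) message(sprintf("dropped %d pair(s) with out-of-range footprints", n_drop))
  out <- pairs[!pairs$.oor, , drop = FALSE]
  out$.oor <- NULL
  rownames(out) <- NULL
  out
}

#' Filter pairs too close to the diagonal
#'
#' Keeps inter-chromosomal pairs always; keeps an intra-chromosomal pair iff
#' the gap between its footprint and the diagonal -- lowest column bin minus
#' highest row bin -- is at least `padding`. With `padding = 0` this retains
#' exactly the footprints lying fully above the diagonal. Padding given in bp
#' is converted to bins with a ceiling, since the diagonal is a bin-grid
#' object. Survivor order is preserved; the dropped count is attached as
#' attribute `n_dropped` and reported in a message.
#'
#' @param pairs A `BinnedPairSet` (single pixels or expanded footprints).
#' @param padding Non-negative padding, in bins (default) or bp.
#' @param units `"bins"` or `"bp"`.
#' @return The surviving `BinnedPairSet`.
#' @export
remove_short_pairs <- function(pairs, padding, units = c("bins", "bp")) {
  .assert_binned(pairs)
  units <- match.arg(units)
  stopifnot(padding >= 0)
  pad <- if (units == "bp") as.integer(ceiling(padding / attr(pairs, "binsize")))
         else as.integer(padding)
  fp <- .footprints(pairs)
  gap <- fp$c1 - (fp$r2 - 1L)
  keep <- pairs$chrom1 != pairs$chrom2 | gap >= pad
  n_drop <- sum(!keep)
  if (n_drop) message(sprintf("removed %d short pair(s) within %d bin(s) of the diagonal",
                              n_drop, pad))
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_drop
  out
}
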