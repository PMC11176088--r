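#' Selection masks for local-background scoring
#'
#' A selection mask is a boolean `side x side` stencil picking cells of the
#' submatrix surrounding a pixel. Kinds (all centered on the middle cell of
#' an odd-sided window):
#' \describe{
#'   \item{focal}{the center cell only.}
#'   \item{donut}{cells at Chebyshev distance `inner <= d <= outer` from the
#'     center, excluding the center row and column (stripe contamination);
#'     set `include_axes = TRUE` to keep them.}
#'   \item{inner_square}{the `(2k+1)^2` block around the center.}
#'   \item{top_left, bottom_right}{`k x k` corner blocks.}
#'   \item{rows_cols}{center row and center column, minus the center.}
#' }
#' Masks compose with [mask_union()], [mask_diff()], [mask_complement()].
#'
#' @param kind Mask kind (see above).
#' @param side Odd window side (>= 1), `2*buffer + 1`.
#' @param inner,outer Donut radii (`inner >= 1`, `inner <= outer <= side %/% 2`).
#' @param k Half-width (`inner_square`) or corner size (`top_left`,
#'   `bottom_right`).
#' @param include_axes Keep the center row/column inside a donut.
#' @return A `SelectionMask`: logical matrix with a `name` attribute.
#' @examples
#' sum(make_mask("donut", 5, inner = 1, outer = 2))  # 16 cells
#' @export
make_mask <- function(kind = c("focal", "donut", "inner_square", "outer_ring",
                               "top_left", "bottom_right", "rows_cols"),
                      side, inner = NULL, outer = NULL, k = NULL,
                      include_axes = FALSE) {
  kind <- match.arg(kind)
  side <- as.integer(side)
  if (side < 1L || side %% 2L == 0L) .stopf("side must be an odd integer >= 1")
  ctr <- (side + 1L) %/% 2L
  idx <- seq_len(side)
  cheb <- outer(abs(idx - ctr), abs(idx - ctr), pmax)
  m <- switch(kind,
    focal = cheb == 0L,
    donut = , outer_ring = {
      if (kind == "outer_ring") { inner <- side %/% 2L; outer <- side %/% 2L }
      if (is.null(inner) || is.null(outer)) .stopf("donut needs inner and outer")
      if (inner < 1L || inner > outer || outer > side %/% 2L)
        .stopf("invalid donut geometry: need 1 <= inner <= outer <= %d", side %/% 2L)
      ring <- cheb >= inner & cheb <= outer
      if (!include_axes) {
        ring[ctr, ] <- FALSE
        ring[, ctr] <- FALSE
      }
      ring
    },
    inner_square = {
      if (is.null(k)) .stopf("inner_square needs k")
      if (2L * k + 1L > side) .stopf("k = %d exceeds the window", k)
      cheb <= k
    },
    top_left = , bottom_right = {
      if (is.null(k)) .stopf("%s needs k", kind)
      if (k > side) .stopf("k = %d exceeds the window", k)
      mm <- matrix(FALSE, side, side)
      if (kind == "top_left") mm[seq_len(k), seq_len(k)] <- TRUE
      else mm[side - seq_len(k) + 1L, side - seq_len(k) + 1L] <- TRUE
      mm
    },
    rows_cols = {
      mm <- matrix(FALSE, side, side)
      mm[ctr, ] <- TRUE; mm[, ctr] <- TRUE; mm[ctr, ctr] <- FALSE
      mm
    })
  if (!any(m)) .stopf("mask selects no cells")
  structure(m, name = kind, class = c("SelectionMask", "matrix", "array"))
}

.as_mask <- function(m, name) {
  structure(m, name = name, class = c("SelectionMask", "matrix", "array"))
}

.check_same_side <- function(a, b) {
  if (!all(dim(a) == dim(b))) .stopf("masks have different sides")
}

#' Mask algebra
#' @param a,b `SelectionMask` objects of equal side.
#' @return A combined `SelectionMask`.
#' @rdname mask_algebra
#' @export
mask_union <- function(a, b) {
  .check_same_side(a, b)
  .as_mask(unclass(a) | unclass(b),
           paste0("union(", attr(a, "name"), ",", attr(b, "name"), ")"))
}

#' @rdname mask_algebra
#' @export
mask_intersect <- function(a, b) {
  .check_same_side(a, b)
  .as_mask(unclass(a) & unclass(b),
           paste0("intersect(", attr(a, "name"), ",", attr(b, "name"), ")"))
}

#' @rdname mask_algebra
#' @export
mask_diff <- function(a, b) {
  .check_same_side(a, b)
  .as_mask(unclass(a) & !unclass(b),
           paste0("diff(", attr(a, "name"), ",", attr(b, "name"), ")"))
}

#' @rdname mask_algebra
#' @export
mask_complement <- function(a) {
  .as_mask(!unclass(a), paste0("complement(", attr(a, "name"), ")"))
}

#' Score pixels against a customizable local background
#'
#' For every pair and file, extracts the `(2*buffer+1)^2` submatrix around
#' the pixel and scores the foreground selection against the background
#' selection. The default score is the pseudocounted median ratio
#' `(median(fg) + 1) / (median(bg) + 1)`; the pseudocount guards sparse
#' windows and makes a flat window score exactly 1. Missing cells are
#' excluded from the medians; a background left empty after missing-value
#' removal yields a missing score (not an error).
#'
#' @param files A `ContactStore` or list of them.
#' @param pairs A `BinnedPairSet` of single-pixel anchors on the files' grid.
#' @param buffer_bins Half-width of the window in bins (default 5: an 11x11
#'   window).
#' @param fg,bg Foreground/background `SelectionMask`s of side
#'   `2*buffer_bins + 1` (defaults: focal center vs. a donut spanning
#'   Chebyshev radii `min(2, buffer)` to `buffer` -- at the default buffer a
#'   2-5 donut, the conventional APA-style local background clear of the
#'   peak). They must not overlap.
#' @param score `"median_ratio"` or a `function(fg_values, bg_values)`.
#' @param config An [extraction_config()] (raw counts by default; balanced
#'   input is allowed and missing cells are excluded).
#' @return An `EnrichmentResult`: list with `scores` (pairs x files matrix;
#'   rows follow the pairs that survive footprint bounds checks, recorded in
#'   `kept`), masks, and `score_definition`.
#' @export
calc_loop_enrichment <- function(files, pairs, buffer_bins = 5L,
                                 fg = make_mask("focal", 2L * buffer_bins + 1L),
                                 bg = make_mask("donut", 2L * buffer_bins + 1L,
                                                inner = min(2L, as.integer(buffer_bins)),
                                                outer = as.integer(buffer_bins)),
                                 score = "median_ratio",
                                 config = extraction_config()) {
  .assert_binned(pairs)
  side <- 2L * as.integer(buffer_bins) + 1L
  if (!all(dim(fg) == c(side, side)) || !all(dim(bg) == c(side, side)))
    .stopf("masks must have side 2*buffer_bins + 1 = %d", side)
  if (any(unclass(fg) & unclass(bg))) .stopf("foreground and background masks overlap")
  score_fun <- if (is.function(score)) {
    score
  } else {
    match.arg(score, "median_ratio")
    function(f, b) (stats::median(f) + 1) / (stats::median(b) + 1)
  }
  score_def <- if (is.function(score)) "user function"
               else "(median(fg) + 1) / (median(bg) + 1)"

  ex <- expand_pixels(pairs, buffer_bins)
  kept <- which(!ex$.oor)
  ex <- drop_out_of_range(ex)
  if (!nrow(ex)) .stopf("no pair has an in-range window")
  gap <- .footprints(ex)$c1 - (.footprints(ex)$r2 - 1L)
  if (any(ex$chrom1 == ex$chrom2 & gap < 0))
    .warnf("%d window(s) cross the diagonal; scores include diagonal contamination",
           sum(ex$chrom1 == ex$chrom2 & gap < 0))
  arr <- pull_submatrices(files, ex, config)
  nf <- length(file_labels(arr))
  scores <- matrix(NA_real_, nrow(ex), nf,
                   dimnames = list(NULL, file_labels(arr)))
  fg_i <- which(unclass(fg)); bg_i <- which(unclass(bg))
  for (f in seq_len(nf)) {
    sub <- counts(arr, files = f)            # side x side x n x 1
    for (p in seq_len(nrow(ex))) {
      w <- sub[, , p, 1]
      fv <- w[fg_i]; bv <- w[bg_i]
      fv <- fv[!is.na(fv)]; bv <- bv[!is.na(bv)]
      if (length(fv) && length(bv)) scores[p, f] <- score_fun(fv, bv)
    }
  }
  structure(list(scores = scores, fg = fg, bg = bg,
                 score_definition = score_def, pairs = ex, kept = kept),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: %d pairs x %d file(s); score = %s\n",
              nrow(x$scores), ncol(x$scores), x$score_definition))
  cat(sprintf("  fg: %s | bg: %s\n", attr(x$fg, "name"), attr(x$bg, "name")))
  invisible(x)
}

#' Write enrichment scores as BEDPE with score columns
#'
#' @param x An `EnrichmentResult`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  stopifnot(inherits(x, "EnrichmentResult"))
  out <- as.data.frame(x$pairs)
  sc <- x$scores
  colnames(sc) <- paste0("score_", colnames(sc))
  out <- cbind(out, sc)
  out <- structure(out, chromsizes = attr(x$pairs, "chromsizes"),
                   binsize = attr(x$pairs, "binsize"),
                   class = class(x$pairs))
  write_bedpe(out, path)
}
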