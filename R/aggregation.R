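## Aggregation of extracted submatrices: reductions across interactions
## and/or files, bilinear regularization of jagged stacks, and the three
## all-in-one pileups (APA, aggregate domains, boundary windows).

.new_agg <- function(values, n_contributing, provenance) {
  structure(list(values = values, n_contributing = n_contributing,
                 provenance = provenance),
            class = "AggregateMatrix")
}

#' @export
print.AggregateMatrix <- function(x, ...) {
  cat(sprintf("AggregateMatrix %dx%d (%s)\n", nrow(x$values), ncol(x$values),
              x$provenance))
  invisible(x)
}

#' Aggregate a stack of submatrices
#'
#' Reduces a regular `SubmatrixArray` across interactions, files, or both.
#' Missing values are excluded cell-wise; `n_contributing` tracks how many
#' values entered each cell. Counts are streamed from disk in chunks along
#' the interaction axis for `sum`/`mean`; `median` materializes the stack.
#'
#' @param arr A `SubmatrixArray` (jagged input errors -- [regularize()] first).
#' @param by `"both"` (one matrix), `"interactions"` (one matrix per file) or
#'   `"files"` (one matrix per interaction).
#' @param fn `"sum"`, `"mean"` or `"median"`.
#' @return An `AggregateMatrix` (`by = "both"`), a list of them per file
#'   (`by = "interactions"`), or a 3-d array `[row, col, interaction]` with a
#'   matching `n_contributing` attribute (`by = "files"`).
#' @export
agg_matrices <- function(arr, by = c("both", "interactions", "files"),
                         fn = c("sum", "mean", "median")) {
  if (inherits(arr, "JaggedSubmatrixArray"))
    .stopf("jagged input: regularize() to a common shape first")
  stopifnot(inherits(arr, "SubmatrixArray"))
  by <- match.arg(by); fn <- match.arg(fn)
  if (!arr$n_pairs) .stopf("empty array")
  nr <- arr$dims[1]; nc <- arr$dims[2]
  nf <- length(arr$file_labels); np <- arr$n_pairs
  prov <- function(what) sprintf("%s over %s of %d interactions x %d files (%s)",
                                 fn, what, np, nf, arr$normalization)

  if (fn == "median") {
    x <- counts(arr)                               # nr x nc x np x nf
    red <- switch(by,
      both = .new_agg(apply(x, c(1, 2), stats::median, na.rm = TRUE),
                      apply(!is.na(x), c(1, 2), sum), prov("both axes")),
      interactions = lapply(seq_len(nf), function(f)
        .new_agg(apply(x[, , , f, drop = FALSE], c(1, 2), stats::median, na.rm = TRUE),
                 apply(!is.na(x[, , , f, drop = FALSE]), c(1, 2), sum),
                 prov(sprintf("interactions [%s]", arr$file_labels[f])))),
      files = {
        v <- apply(x, c(1, 2, 3), stats::median, na.rm = TRUE)
        attr(v, "n_contributing") <- apply(!is.na(x), c(1, 2, 3), sum)
        v
      })
    return(red)
  }

  ## streamed sum / mean
  tot <- array(0, c(nr, nc, if (by == "both") 1 else if (by == "interactions") nf else np))
  ncontrib <- array(0L, dim(tot))
  chunk <- max(1L, 2^22 %/% max(1, (nr * nc * nf)))    # ~32 MB of doubles
  for (i0 in seq(1L, np, by = chunk)) {
    idx <- i0:min(np, i0 + chunk - 1L)
    x <- counts(arr, pairs = idx)
    ok <- !is.na(x)
    x[!ok] <- 0
    if (by == "both") {
      tot[, , 1] <- tot[, , 1] + rowSums(x, dims = 2)
      ncontrib[, , 1] <- ncontrib[, , 1] + rowSums(ok, dims = 2)
    } else if (by == "interactions") {
      for (f in seq_len(nf)) {
        tot[, , f] <- tot[, , f] + rowSums(x[, , , f, drop = FALSE], dims = 2)
        ncontrib[, , f] <- ncontrib[, , f] + rowSums(ok[, , , f, drop = FALSE], dims = 2)
      }
    } else {
      tot[, , idx] <- rowSums(x, dims = 3)
      ncontrib[, , idx] <- rowSums(ok, dims = 3)
    }
  }
  vals <- if (fn == "mean") {
    out <- tot / ncontrib
    out[ncontrib == 0] <- NA_real_
    out
  } else {
    tot[array(ncontrib == 0, dim(tot))] <- NA_real_
    tot
  }
  switch(by,
    both = .new_agg(vals[, , 1], ncontrib[, , 1], prov("both axes")),
    interactions = lapply(seq_len(nf), function(f)
      .new_agg(vals[, , f], ncontrib[, , f],
               prov(sprintf("interactions [%s]", arr$file_labels[f])))),
    files = { attr(vals, "n_contributing") <- ncontrib; vals })
}

## bilinear interpolation weights mapping src cell centers to ndim centers
## on the unit interval; rows sum to 1
.bilinear_weights <- function(src, ndim) {
  u <- ((seq_len(ndim) - 0.5) / ndim) * src - 0.5
  u <- pmin(pmax(u, 0), src - 1)
  i0 <- pmin(floor(u), src - 1)
  fr <- u - i0
  W <- matrix(0, ndim, src)
  W[cbind(seq_len(ndim), i0 + 1)] <- W[cbind(seq_len(ndim), i0 + 1)] + (1 - fr)
  hi <- pmin(i0 + 2, src)
  W[cbind(seq_len(ndim), hi)] <- W[cbind(seq_len(ndim), hi)] + fr
  W
}

.resample_bilinear <- function(m, ndim) {
  Wr <- .bilinear_weights(nrow(m), ndim)
  Wc <- .bilinear_weights(ncol(m), ndim)
  Wr %*% m %*% t(Wc)
}

#' Resample jagged submatrices to a common shape
#'
#' Each `rows x cols` source matrix is resampled to `ndim x ndim` by bilinear
#' interpolation of cell centers mapped onto the unit square; a source
#' already at `ndim x ndim` passes through unchanged. Sources with any
#' dimension below 2 cannot be interpolated and are dropped with a message.
#'
#' @param arr A `JaggedSubmatrixArray` (a regular `SubmatrixArray` is
#'   accepted and resampled the same way).
#' @param ndim Target side (>= 2).
#' @param scale_to_sum Rescale every output so its total equals the source
#'   total.
#' @param on_disk_path Optional path for the resampled container.
#' @return A `SubmatrixArray` of `ndim x ndim` matrices.
#' @export
regularize <- function(arr, ndim = 100L, scale_to_sum = FALSE,
                       on_disk_path = NULL) {
  stopifnot(inherits(arr, "HicResult"))
  if (arr$type == "pixels") .stopf("pixel matrices have no shape to regularize")
  ndim <- as.integer(ndim)
  if (ndim < 2L) .stopf("ndim must be >= 2")
  dims <- if (arr$type == "jagged") arr$dims
          else matrix(rep(arr$dims, each = arr$n_pairs), ncol = 2)
  ok <- dims[, 1] >= 2L & dims[, 2] >= 2L
  if (!any(ok)) .stopf("no source matrix is at least 2x2")
  if (any(!ok)) message(sprintf("dropped %d source matrix(ces) smaller than 2x2",
                                sum(!ok)))
  keep <- which(ok)
  nf <- length(arr$file_labels)
  path <- if (is.null(on_disk_path)) tempfile(fileext = ".h5") else on_disk_path
  if (file.exists(path)) file.remove(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  d <- c(ndim, ndim, length(keep), nf)
  rhdf5::h5createDataset(path, "counts", dims = d, storage.mode = "double",
                         fillValue = NaN, chunk = c(ndim, ndim, 1L, nf))
  for (j in seq_along(keep)) {
    p <- keep[j]
    for (f in seq_len(nf)) {
      m <- submatrix(arr, p, f)
      out <- if (all(dim(m) == c(ndim, ndim))) m else .resample_bilinear(m, ndim)
      if (scale_to_sum) {
        s_in <- sum(m, na.rm = TRUE); s_out <- sum(out, na.rm = TRUE)
        if (s_out != 0) out <- out * (s_in / s_out)
      }
      rhdf5::h5write(out, path, "counts", index = list(NULL, NULL, j, f))
    }
  }
  pairs <- arr$pairs[keep, , drop = FALSE]
  stats <- list(n_blocks = arr$stats$n_blocks %||% 0L,
                max_block_cells = arr$stats$max_block_cells %||% 0)
  cfg <- list(normalization = arr$normalization)
  .finish_result(path, "submatrices", pairs, arr$file_labels, cfg, stats,
                 list(dims = d[1:2]))
  .new_result(path, "submatrices", pairs, arr$file_labels, arr$normalization,
              stats, dims = d[1:2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate peak analysis (APA) pileup
#'
#' All-in-one pixel pileup: snap calls to the bin grid, expand to
#' `(2*buffer+1)^2` footprints, drop footprints leaving the chromosome,
#' optionally drop pairs whose window comes within `buffer_bins` of the
#' diagonal, pull submatrices and average them per file.
#'
#' @param files A `ContactStore` or list of them.
#' @param pairs A `PairSet` of loop calls (or an already-snapped
#'   `BinnedPairSet` on the right grid).
#' @param binsize_bp Bin grid for snapping (defaults to the files'
#'   resolution).
#' @param buffer_bins Window half-width in bins.
#' @param normalization `"raw"` or `"balanced"`.
#' @param drop_short Apply [remove_short_pairs()] with `padding =
#'   buffer_bins` so no window touches the diagonal band.
#' @param config Optional [extraction_config()] override.
#' @return A list of `AggregateMatrix`, one per file.
#' @export
pileup_pixels <- function(files, pairs, binsize_bp = NULL, buffer_bins = 5L,
                          normalization = c("raw", "balanced"),
                          drop_short = TRUE, config = NULL) {
  normalization <- match.arg(normalization)
  stores <- .as_store_list(files)
  if (is.null(binsize_bp)) binsize_bp <- stores[[1]]$resolution
  bp <- if (inherits(pairs, "BinnedPairSet")) pairs
        else snap_to_bins(pairs, binsize_bp)
  ex <- drop_out_of_range(expand_pixels(bp, buffer_bins))
  if (drop_short) ex <- remove_short_pairs(ex, buffer_bins)
  if (!nrow(ex)) .stopf("no pairs survive footprint and diagonal filtering")
  if (is.null(config)) config <- extraction_config(normalization)
  config$normalization <- normalization
  arr <- pull_submatrices(stores, ex, config)
  agg_matrices(arr, by = "interactions", fn = "mean")
}

## snap a domain interval outward to the bin grid; returns global bin interval
.domain_bins <- function(cs, binsize, chrom, start, end) {
  ci <- match(chrom, cs$chrom)
  nb <- .bins_per_chrom(cs, binsize)[ci]
  b0 <- floor(start / binsize); b1 <- ceiling(end / binsize)
  oor <- start < 0 | b1 > nb
  off <- .chrom_offsets(cs, binsize)[ci]
  data.frame(r1 = off + b0, r2 = off + b1, oor = oor)
}

.domain_pairset <- function(cs, binsize, dom) {
  df <- data.frame(chrom1 = dom$chrom, start1 = dom$start, end1 = dom$end,
                   chrom2 = dom$chrom, start2 = dom$start, end2 = dom$end,
                   stringsAsFactors = FALSE)
  structure(df, chromsizes = cs, binsize = binsize,
            class = c("BinnedPairSet", "PairSet", "data.frame"))
}

#' Aggregate domain (TAD) pileup
#'
#' Each domain `[s, e)` is expanded by `buffer_frac` of its width on both
#' sides, snapped outward to bins, and its on-diagonal square block is
#' extracted (a jagged stack, as domains differ in width). Blocks are
#' optionally normalized to unit total so each domain carries equal weight
#' regardless of depth, resampled to `ndim x ndim` and averaged per file.
#'
#' @param files A `ContactStore` or list of them.
#' @param domains A data.frame with columns `chrom`, `start`, `end` (e.g.
#'   from [read_bed()]).
#' @param binsize_bp Bin grid (defaults to the files' resolution).
#' @param buffer_frac Flank fraction of the domain width added on each side.
#' @param ndim Common resampled side.
#' @param normalization `"raw"` or `"balanced"`.
#' @param per_matrix_norm `"sum"` (divide each block by its total) or
#'   `"none"`.
#' @return A list of `AggregateMatrix`, one per file.
#' @export
pileup_domains <- function(files, domains, binsize_bp = NULL,
                           buffer_frac = 0.5, ndim = 100L,
                           normalization = c("raw", "balanced"),
                           per_matrix_norm = c("sum", "none")) {
  normalization <- match.arg(normalization)
  per_matrix_norm <- match.arg(per_matrix_norm)
  stores <- .as_store_list(files)
  if (is.null(binsize_bp)) binsize_bp <- stores[[1]]$resolution
  if (buffer_frac < 0) .stopf("buffer_frac must be >= 0")
  cs <- stores[[1]]$chromsizes
  if (!nrow(domains)) .stopf("no domains given")
  w <- domains$end - domains$start
  s <- domains$start - buffer_frac * w
  e <- domains$end + buffer_frac * w
  db <- .domain_bins(cs, binsize_bp, domains$chrom, s, e)
  if (all(db$oor)) .stopf("all expanded domains exceed their chromosome")
  if (any(db$oor)) message(sprintf("dropped %d domain(s) whose window leaves the chromosome",
                                   sum(db$oor)))
  keep <- !db$oor
  dom <- data.frame(chrom = domains$chrom[keep],
                    start = pmax(0, s[keep]), end = e[keep])
  bp <- .domain_pairset(cs, binsize_bp, dom)
  bp$r1 <- db$r1[keep]; bp$r2 <- db$r2[keep]
  bp$c1 <- db$r1[keep]; bp$c2 <- db$r2[keep]
  arr <- pull_submatrices(stores, bp, extraction_config(normalization))
  if (per_matrix_norm == "sum" || inherits(arr, "JaggedSubmatrixArray") ||
      !all(arr$dims == ndim)) {
    reg <- regularize(arr, ndim, scale_to_sum = FALSE)
    if (per_matrix_norm == "sum") {
      ## divide each resampled block by its own total
      nf <- length(reg$file_labels)
      for (p in seq_len(reg$n_pairs)) for (f in seq_len(nf)) {
        m <- submatrix(reg, p, f)
        tt <- sum(m, na.rm = TRUE)
        if (tt != 0)
          rhdf5::h5write(m / tt, reg$h5, "counts", index = list(NULL, NULL, p, f))
      }
      rhdf5::h5closeAll()
    }
    arr <- reg
  }
  agg_matrices(arr, by = "interactions", fn = "mean")
}

#' Boundary-centered pileup
#'
#' Extracts the on-diagonal square window `boundary +/- flank_bp` (snapped so
#' the boundary bin is the exact center of an odd-sided window) for every
#' boundary and averages the windows per file.
#'
#' @param files A `ContactStore` or list of them.
#' @param boundaries A data.frame with columns `chrom` and `pos` (bp), or a
#'   BED-style frame with `start`/`end` whose midpoint is used.
#' @param binsize_bp Bin grid (defaults to the files' resolution).
#' @param flank_bp Flank on each side (>= one bin); the window spans
#'   `2 * (flank_bp %/% binsize) + 1` bins.
#' @param normalization `"raw"` or `"balanced"`.
#' @return A list of `AggregateMatrix`, one per file.
#' @export
pileup_boundaries <- function(files, boundaries, binsize_bp = NULL,
                              flank_bp, normalization = c("raw", "balanced")) {
  normalization <- match.arg(normalization)
  stores <- .as_store_list(files)
  if (is.null(binsize_bp)) binsize_bp <- stores[[1]]$resolution
  if (flank_bp < binsize_bp) .stopf("flank_bp must be at least one bin")
  cs <- stores[[1]]$chromsizes
  pos <- if ("pos" %in% names(boundaries)) boundaries$pos
         else floor((boundaries$start + boundaries$end) / 2)
  ci <- match(boundaries$chrom, cs$chrom)
  if (anyNA(ci)) .stopf("unknown chromosome: %s", boundaries$chrom[which(is.na(ci))[1]])
  fl <- flank_bp %/% binsize_bp
  ctr <- floor(pos / binsize_bp)
  nb <- .bins_per_chrom(cs, binsize_bp)[ci]
  oor <- ctr - fl < 0 | ctr + fl + 1 > nb
  if (all(oor)) .stopf("all boundary windows leave their chromosome")
  if (any(oor)) message(sprintf("dropped %d boundary window(s) out of range", sum(oor)))
  keep <- !oor
  off <- .chrom_offsets(cs, binsize_bp)[ci[keep]]
  dom <- data.frame(chrom = boundaries$chrom[keep],
                    start = (ctr[keep] - fl) * binsize_bp,
                    end = pmin((ctr[keep] + fl + 1) * binsize_bp,
                               cs$length[ci[keep]]))
  bp <- .domain_pairset(cs, binsize_bp, dom)
  bp$r1 <- off + ctr[keep] - fl; bp$r2 <- off + ctr[keep] + fl + 1
  bp$c1 <- bp$r1; bp$c2 <- bp$r2
  arr <- pull_submatrices(stores, bp, extraction_config(normalization))
  agg_matrices(arr, by = "interactions", fn = "mean")
}

#' Write an aggregate matrix as tab-separated text
#'
#' @param x An `AggregateMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aggregate <- function(x, path) {
  stopifnot(inherits(x, "AggregateMatrix"))
  utils::write.table(x$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Plot an aggregate matrix as a heatmap
#'
#' Diagnostic `image()` heatmap with rows running top to bottom.
#'
#' @param x An `AggregateMatrix`.
#' @param main Title.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.AggregateMatrix <- function(x, main = x$provenance, ...) {
  v <- x$values
  graphics::image(t(v)[, rev(seq_len(nrow(v))), drop = FALSE], axes = FALSE,
                  main = main, col = grDevices::hcl.colors(64, "Reds", rev = TRUE), ...)
  invisible(x)
}
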