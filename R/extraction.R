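#' Extraction configuration
#'
#' Controls the block-processing engine. Contacts are read one square genome
#' block at a time, so peak working memory is bounded by one dense block per
#' file in flight -- not by the number of queries. Exactly one of
#' `block_span_bp` / `max_blocks` governs planning.
#'
#' @param normalization `"raw"` or `"balanced"`.
#' @param block_span_bp Side of the square genome blocks, in bp. The default
#'   10 Mb keeps a dense block at 10 kb resolution near 1000 x 1000 cells.
#' @param max_blocks Optional override: choose the block span so the longest
#'   chromosome is covered by at most this many blocks per axis.
#' @param on_disk_path Optional path for the result container (default: a
#'   temporary file).
#' @param missing_policy How a query lands on a missing balanced value:
#'   `"zero"` or `"missing"`. Default: `"zero"` for raw (an absent pixel is
#'   an observed zero), `"missing"` for balanced (a value at a filtered bin
#'   is undefined).
#' @return An `ExtractionConfig` list.
#' @export
extraction_config <- function(normalization = c("raw", "balanced"),
                              block_span_bp = 1e7, max_blocks = NULL,
                              on_disk_path = NULL, missing_policy = NULL) {
  normalization <- match.arg(normalization)
  if (is.null(missing_policy))
    missing_policy <- if (normalization == "raw") "zero" else "missing"
  missing_policy <- match.arg(missing_policy, c("zero", "missing"))
  if (!is.null(max_blocks) && max_blocks < 1) .stopf("max_blocks must be >= 1")
  if (block_span_bp <= 0) .stopf("block_span_bp must be positive")
  structure(list(normalization = normalization, block_span_bp = block_span_bp,
                 max_blocks = max_blocks, on_disk_path = on_disk_path,
                 missing_policy = missing_policy),
            class = "ExtractionConfig")
}

.as_store_list <- function(files) {
  if (inherits(files, "ContactStore")) files <- list(files)
  if (!length(files) || !all(vapply(files, inherits, TRUE, "ContactStore")))
    .stopf("files must be a ContactStore or a list of them")
  labs <- names(files)
  if (is.null(labs) || any(!nzchar(labs)))
    labs <- make.unique(basename(vapply(files, `[[`, "", "path")))
  names(files) <- labs
  files
}

.check_grid <- function(pairs, stores) {
  bs <- attr(pairs, "binsize")
  for (s in stores) {
    if (s$resolution != bs)
      .stopf("pairs are on a %s bp grid but %s stores %s bp",
             format(bs, scientific = FALSE), s$path,
             format(s$resolution, scientific = FALSE))
    cs <- attr(pairs, "chromsizes")
    if (!identical(as.character(cs$chrom), as.character(s$chromsizes$chrom)) ||
        !isTRUE(all.equal(as.numeric(cs$length), as.numeric(s$chromsizes$length))))
      .stopf("chromosome table of %s differs from the query genome", s$path)
  }
  bs
}

#' Plan genome blocks covering a query set
#'
#' Groups query footprints into square genome blocks so every footprint is
#' fetched exactly once; a footprint straddling a block boundary is assigned
#' to its starting tile, which is enlarged just enough to contain it. Blocks
#' never cross chromosome pairs.
#'
#' @param pairs A `BinnedPairSet` (single pixels or footprints).
#' @param files A `ContactStore` or list of them (shared bin size).
#' @param config An [extraction_config()].
#' @return A `BlockPlan`: list of blocks with row/col bin intervals and
#'   member query indices; the same plan is executed once per file.
#' @export
plan_blocks <- function(pairs, files, config = extraction_config()) {
  .assert_binned(pairs)
  stores <- .as_store_list(files)
  bs <- .check_grid(pairs, stores)
  cs <- attr(pairs, "chromsizes")
  if (!is.null(config$max_blocks)) {
    side <- ceiling(max(.bins_per_chrom(cs, bs)) / config$max_blocks)
  } else {
    side <- max(1, config$block_span_bp %/% bs)
  }
  fp <- .footprints(pairs)
  if (!is.null(pairs$.oor) && any(pairs$.oor))
    .stopf("query set contains out-of-range footprints; drop_out_of_range() first")
  wmax <- max(c(fp$r2 - fp$r1, fp$c2 - fp$c1))
  if (wmax > side)
    .stopf(paste0("a query footprint spans %d bins but blocks span only %d; ",
                  "raise block_span_bp to at least %s"),
           wmax, side, format(wmax * bs, scientific = FALSE))
  off <- .chrom_offsets(cs, bs)
  ci1 <- .bin_chrom_index(cs, bs, fp$r1)
  ci2 <- .bin_chrom_index(cs, bs, fp$c1)
  key <- paste(ci1, ci2, fp$r1 %/% side, fp$c1 %/% side)
  blocks <- lapply(split(seq_len(nrow(fp)), key), function(idx) {
    i1 <- ci1[idx[1]]; i2 <- ci2[idx[1]]
    tr <- fp$r1[idx[1]] %/% side; tc <- fp$c1[idx[1]] %/% side
    rs <- max(tr * side, off[i1]); re <- min((tr + 1) * side, off[i1 + 1])
    cs_ <- max(tc * side, off[i2]); ce <- min((tc + 1) * side, off[i2 + 1])
    list(rs = min(rs, min(fp$r1[idx])), re = max(re, max(fp$r2[idx])),
         cs = min(cs_, min(fp$c1[idx])), ce = max(ce, max(fp$c2[idx])),
         members = idx)
  })
  names(blocks) <- NULL
  structure(list(blocks = blocks, side_bins = side, binsize = bs,
                 n_blocks = length(blocks),
                 n_fetches = length(blocks) * length(stores)),
            class = "BlockPlan")
}

#' @export
print.BlockPlan <- function(x, ...) {
  cat(sprintf("BlockPlan: %d block(s) of %d bins per file (%d planned fetches)\n",
              x$n_blocks, x$side_bins, x$n_fetches))
  invisible(x)
}

## shared executor: fetch each planned block once per file and scatter into
## the result dataset via `scatter(blk, members, file_index)`
.run_blocks <- function(stores, plan, config, scatter) {
  max_cells <- 0
  for (f in seq_along(stores)) {
    for (b in plan$blocks) {
      blk <- fetch_block(stores[[f]], c(b$rs, b$re), c(b$cs, b$ce),
                         config$normalization)
      max_cells <- max(max_cells, length(blk$values))
      scatter(blk, b, f)
    }
  }
  list(n_blocks = plan$n_blocks, max_block_cells = max_cells)
}

.apply_missing <- function(vals, config) {
  if (config$missing_policy == "zero") vals[is.na(vals)] <- 0
  vals
}

.result_path <- function(config) {
  p <- config$on_disk_path
  if (is.null(p)) p <- tempfile(fileext = ".h5")
  if (file.exists(p)) file.remove(p)
  p
}

.finish_result <- function(path, type, pairs, labels, config, stats, extra_attrs = list()) {
  .write_interactions(path, pairs)
  .h5_write_attrs(path, "/", c(list(
    layout_version = .RESULT_LAYOUT, type = type,
    normalization = config$normalization,
    binsize = as.numeric(attr(pairs, "binsize")),
    file_labels = labels, n_pairs = nrow(pairs), n_files = length(labels),
    n_blocks = stats$n_blocks, max_block_cells = stats$max_block_cells),
    extra_attrs))
  rhdf5::h5closeAll()
}

#' Pull pixel counts across files
#'
#' Extracts the (symmetrized) count of every single-bin interaction from
#' every file into a disk-backed interactions x files matrix, using the
#' block-processing engine. Result rows follow the input pair order
#' regardless of block traversal order.
#'
#' @param files A `ContactStore` or (optionally named) list of them.
#' @param pairs A `BinnedPairSet` from [snap_to_bins()] (single-bin anchors),
#'   on the files' bin grid.
#' @param config An [extraction_config()].
#' @return A `PixelMatrix` (see [counts()], [persist()]).
#' @export
pull_pixels <- function(files, pairs, config = extraction_config()) {
  .assert_binned(pairs)
  if (.has_footprints(pairs))
    .stopf("pairs carry expanded footprints; use pull_submatrices()")
  stores <- .as_store_list(files)
  plan <- plan_blocks(pairs, stores, config)
  path <- .result_path(config)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  rhdf5::h5createDataset(path, "counts", dims = c(nrow(pairs), length(stores)),
                         storage.mode = "double", fillValue = NaN,
                         chunk = c(min(nrow(pairs), 4096L), length(stores)))
  stats <- .run_blocks(stores, plan, config, function(blk, b, f) {
    vals <- blk$values[cbind(pairs$bin1[b$members] - b$rs + 1L,
                             pairs$bin2[b$members] - b$cs + 1L)]
    vals <- .apply_missing(vals, config)
    rhdf5::h5write(vals, path, "counts", index = list(b$members, f))
  })
  .finish_result(path, "pixels", pairs, names(stores), config, stats)
  .new_result(path, "pixels", pairs, names(stores), config$normalization, stats)
}

#' Pull submatrices across files
#'
#' Extracts the count submatrix of every footprint from every file. If all
#' footprints share one shape the result is a disk-backed `SubmatrixArray`
#' `[row, col, interaction, file]`; mixed shapes give a
#' `JaggedSubmatrixArray` with an offsets index. Rows follow anchor1 and
#' columns anchor2, both in ascending genomic order.
#'
#' @inheritParams pull_pixels
#' @param pairs A `BinnedPairSet` with footprints ([expand_pixels()] or the
#'   domain/boundary helpers), none flagged out of range.
#' @param force_jagged Store the result in the jagged layout even when all
#'   footprints share one shape (the two layouts hold identical values;
#'   mainly useful for validation).
#' @return A `SubmatrixArray` or `JaggedSubmatrixArray`.
#' @export
pull_submatrices <- function(files, pairs, config = extraction_config(),
                             force_jagged = FALSE) {
  .assert_binned(pairs)
  if (!.has_footprints(pairs))
    .stopf("pairs have no footprints; expand_pixels() or query domains first")
  if (!is.null(pairs$.oor) && any(pairs$.oor))
    .stopf("query set contains out-of-range footprints; drop_out_of_range() first")
  stores <- .as_store_list(files)
  plan <- plan_blocks(pairs, stores, config)
  fp <- .footprints(pairs)
  nr <- fp$r2 - fp$r1; nc <- fp$c2 - fp$c1
  regular <- !force_jagged &&
    length(unique(nr)) == 1L && length(unique(nc)) == 1L
  path <- .result_path(config)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)

  if (regular) {
    d <- c(nr[1], nc[1], nrow(pairs), length(stores))
    rhdf5::h5createDataset(path, "counts", dims = d, storage.mode = "double",
                           fillValue = NaN, chunk = c(d[1], d[2], 1L, d[4]))
    stats <- .run_blocks(stores, plan, config, function(blk, b, f) {
      sub <- vapply(b$members, function(p) {
        .apply_missing(blk$values[(fp$r1[p] - b$rs + 1L):(fp$r2[p] - b$rs),
                                  (fp$c1[p] - b$cs + 1L):(fp$c2[p] - b$cs),
                                  drop = FALSE], config)
      }, matrix(0, d[1], d[2]))
      rhdf5::h5write(array(sub, c(d[1], d[2], length(b$members), 1L)), path,
                     "counts", index = list(NULL, NULL, b$members, f))
    })
    .finish_result(path, "submatrices", pairs, names(stores), config, stats,
                   list(dims = d[1:2]))
    return(.new_result(path, "submatrices", pairs, names(stores),
                       config$normalization, stats, dims = d[1:2]))
  }

  cell <- nr * nc * length(stores)
  offsets <- c(0, cumsum(cell))
  rhdf5::h5createDataset(path, "counts", dims = offsets[length(offsets)],
                         storage.mode = "double", fillValue = NaN,
                         chunk = min(offsets[length(offsets)], 65536))
  rhdf5::h5write(cbind(nr, nc), path, "dims")
  rhdf5::h5write(as.numeric(offsets), path, "offsets")
  stats <- .run_blocks(stores, plan, config, function(blk, b, f) {
    for (p in b$members) {
      sub <- .apply_missing(
        blk$values[(fp$r1[p] - b$rs + 1L):(fp$r2[p] - b$rs),
                   (fp$c1[p] - b$cs + 1L):(fp$c2[p] - b$cs), drop = FALSE],
        config)
      at <- offsets[p] + (f - 1) * nr[p] * nc[p]
      rhdf5::h5write(as.vector(sub), path, "counts",
                     index = list((at + 1):(at + length(sub))))
    }
  })
  .finish_result(path, "jagged", pairs, names(stores), config, stats)
  .new_result(path, "jagged", pairs, names(stores), config$normalization,
              stats, dims = cbind(nr, nc), offsets = as.numeric(offsets))
}
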