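## HDF5-backed result containers for extracted counts.
##
## One self-describing container per result:
##   counts            pixels: (n_pairs x n_files); regular submatrices:
##                     (nr x nc x n_pairs x n_files); jagged: flat vector
##   dims, offsets     jagged only; offsets[p] is the 0-based start of pair
##                     p's data, each pair holding rows*cols*n_files values
##                     (file-major within a pair)
##   interactions/*    one dataset per column of the query table
##   genome/*          chromosome names and lengths
## Root attributes: layout_version, type, normalization, binsize, file_labels,
## and block-processing statistics. Chunking along the interaction axis keeps
## per-interaction random access to one chunk read.

.RESULT_LAYOUT <- "hicblocks-result-1"

.write_interactions <- function(path, pairs) {
  rhdf5::h5createGroup(path, "interactions")
  df <- as.data.frame(pairs)
  cls <- vapply(df, function(x) class(x)[1], "")
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.factor(v)) v <- as.character(v)
    if (is.logical(v)) v <- as.integer(v)
    rhdf5::h5write(v, path, paste0("interactions/", .h5_safe(nm)))
  }
  cs <- attr(pairs, "chromsizes")
  rhdf5::h5createGroup(path, "genome")
  rhdf5::h5write(cs$chrom, path, "genome/chrom")
  rhdf5::h5write(as.numeric(cs$length), path, "genome/length")
  .h5_write_attrs(path, "interactions",
                  list(colnames = names(df), classes = cls,
                       binsize = as.numeric(attr(pairs, "binsize"))))
}

## dataset names cannot contain "/"; queries can carry odd metadata names
.h5_safe <- function(nm) gsub("/", "_SLASH_", nm, fixed = TRUE)

.read_interactions <- function(path) {
  at <- .h5_read_attrs(path, "interactions")
  cols <- lapply(at$colnames, function(nm)
    rhdf5::h5read(path, paste0("interactions/", .h5_safe(nm))))
  names(cols) <- at$colnames
  df <- data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(df)) {
    if (at$classes[i] == "logical") df[[i]] <- as.logical(df[[i]])
    if (at$classes[i] == "character") df[[i]] <- as.character(df[[i]])
  }
  cs <- chrom_sizes(as.character(rhdf5::h5read(path, "genome/chrom")),
                    as.numeric(rhdf5::h5read(path, "genome/length")))
  structure(df, chromsizes = cs, binsize = as.numeric(at$binsize),
            class = c("BinnedPairSet", "PairSet", "data.frame"))
}

.new_result <- function(path, type, pairs, file_labels, normalization,
                        stats, dims = NULL, offsets = NULL) {
  structure(list(h5 = path, type = type, pairs = pairs,
                 n_pairs = nrow(pairs), file_labels = file_labels,
                 normalization = normalization, stats = stats,
                 dims = dims, offsets = offsets),
            class = c(switch(type, pixels = "PixelMatrix",
                             submatrices = "SubmatrixArray",
                             jagged = "JaggedSubmatrixArray"),
                      "HicResult"))
}

#' Extracted-count accessors
#'
#' `counts()` reads count values from a disk-backed result, optionally only
#' for a subset of interactions/files (one chunked read; the full dataset is
#' never materialized unless asked for). `interactions()` returns the query
#' table, `file_labels()` the file names.
#'
#' @param x A `PixelMatrix`, `SubmatrixArray` or `JaggedSubmatrixArray`.
#' @param pairs,files Optional integer indices to slice.
#' @return For a `PixelMatrix`, an interactions x files matrix; for a
#'   `SubmatrixArray`, a 4-d array `[row, col, interaction, file]`. Jagged
#'   arrays have no rectangular `counts`; use [submatrix()].
#' @export
counts <- function(x, pairs = NULL, files = NULL) UseMethod("counts")

#' @rdname counts
#' @export
counts.PixelMatrix <- function(x, pairs = NULL, files = NULL) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (is.null(pairs)) pairs <- seq_len(x$n_pairs)
  if (is.null(files)) files <- seq_along(x$file_labels)
  m <- rhdf5::h5read(x$h5, "counts", index = list(pairs, files))
  dimnames(m) <- list(NULL, x$file_labels[files])
  m
}

#' @rdname counts
#' @export
counts.SubmatrixArray <- function(x, pairs = NULL, files = NULL) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (is.null(pairs)) pairs <- seq_len(x$n_pairs)
  if (is.null(files)) files <- seq_along(x$file_labels)
  rhdf5::h5read(x$h5, "counts",
                index = list(seq_len(x$dims[1]), seq_len(x$dims[2]),
                             pairs, files))
}

#' @rdname counts
#' @export
counts.JaggedSubmatrixArray <- function(x, pairs = NULL, files = NULL) {
  .stopf("jagged arrays have per-interaction shapes; use submatrix(x, pair, file) or regularize()")
}

#' @rdname counts
#' @export
interactions <- function(x) UseMethod("interactions")

#' @export
interactions.HicResult <- function(x) x$pairs

#' @rdname counts
#' @export
file_labels <- function(x) UseMethod("file_labels")

#' @export
file_labels.HicResult <- function(x) x$file_labels

#' Read one stored submatrix
#'
#' Random access to the count matrix of a single interaction in a single
#' file; reads only that slice from disk.
#'
#' @param x A `SubmatrixArray` or `JaggedSubmatrixArray`.
#' @param pair Interaction index (1-based, input order).
#' @param file File index (1-based).
#' @return A numeric matrix (rows follow anchor1, columns anchor2).
#' @export
submatrix <- function(x, pair, file = 1L) UseMethod("submatrix")

#' @export
submatrix.SubmatrixArray <- function(x, pair, file = 1L) {
  counts(x, pairs = pair, files = file)[, , 1, 1, drop = TRUE]
}

#' @export
submatrix.JaggedSubmatrixArray <- function(x, pair, file = 1L) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  stopifnot(pair >= 1, pair <= x$n_pairs)
  rc <- x$dims[pair, 1] * x$dims[pair, 2]
  at <- x$offsets[pair] + (file - 1) * rc
  v <- rhdf5::h5read(x$h5, "counts", index = list((at + 1):(at + rc)))
  matrix(as.numeric(v), x$dims[pair, 1], x$dims[pair, 2])
}

#' @export
print.HicResult <- function(x, ...) {
  what <- switch(x$type, pixels = "pixel counts",
                 submatrices = sprintf("%dx%d submatrices", x$dims[1], x$dims[2]),
                 jagged = "jagged submatrices")
  cat(sprintf("%s: %d interactions x %d file(s), %s (%s)\n", class(x)[1],
              x$n_pairs, length(x$file_labels), what, x$normalization))
  cat(sprintf("  on disk: %s\n", x$h5))
  if (!is.null(x$stats))
    cat(sprintf("  blocks: %d fetched per file | largest dense block: %s cells\n",
                x$stats$n_blocks,
                format(x$stats$max_block_cells, big.mark = ",")))
  invisible(x)
}

#' Persist or reload an extraction result
#'
#' Results already live in a self-describing HDF5 container; `persist()`
#' copies it to a chosen location and `load_result()` reopens it. Counts are
#' not read into memory on load -- random access per interaction remains
#' available through [counts()] and [submatrix()].
#'
#' @param x A `PixelMatrix`, `SubmatrixArray` or `JaggedSubmatrixArray`.
#' @param path Destination (`persist`) or source (`load_result`) file.
#' @return `persist()`: the relocated result object; `load_result()`: the
#'   reconstructed object (errors on an unknown on-disk layout version).
#' @export
persist <- function(x, path) {
  stopifnot(inherits(x, "HicResult"))
  rhdf5::h5closeAll()
  if (!file.copy(x$h5, path, overwrite = TRUE))
    .stopf("could not write %s", path)
  x$h5 <- normalizePath(path)
  x
}

#' @rdname persist
#' @export
load_result <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  at <- .h5_read_attrs(path, "/")
  if (is.null(at$layout_version) || at$layout_version != .RESULT_LAYOUT)
    .stopf("unsupported result layout version '%s' (expected '%s')",
           if (is.null(at$layout_version)) "<none>" else at$layout_version,
           .RESULT_LAYOUT)
  pairs <- .read_interactions(path)
  dims <- offsets <- NULL
  if (at$type == "submatrices") dims <- as.integer(at$dims)
  if (at$type == "jagged") {
    dims <- matrix(as.integer(rhdf5::h5read(path, "dims")), ncol = 2)
    offsets <- as.numeric(rhdf5::h5read(path, "offsets"))
  }
  .new_result(normalizePath(path), at$type, pairs,
              as.character(at$file_labels), at$normalization,
              stats = list(n_blocks = as.integer(at$n_blocks),
                           max_block_cells = as.numeric(at$max_block_cells)),
              dims = dims, offsets = offsets)
}
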