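## cooler-dialect contact file I/O.
##
## Layout (single resolution, ".cool"):
##   chroms/{name,length}  bins/{chrom,start,end[,weight]}
##   pixels/{bin1_id,bin2_id,count}  indexes/{bin1_offset,chrom_offset}
## Multi-resolution ".mcool" files hold the same tree under
## "resolutions/<binsize>/".  Pixels are stored upper-triangle only
## (bin1_id <= bin2_id), counts > 0, bin ids 0-based and genome-wide.

.cool_root <- function(path, resolution_bp = NULL) {
  top <- rhdf5::h5ls(path, recursive = FALSE)$name
  if ("resolutions" %in% top) {
    avail <- rhdf5::h5ls(path, recursive = FALSE, index_type = "H5_INDEX_NAME")
    res <- rhdf5::h5ls(path)$name[rhdf5::h5ls(path)$group == "/resolutions"]
    res <- sort(as.numeric(res))
    if (is.null(resolution_bp))
      .stopf("multi-resolution file: choose resolution_bp from {%s}",
             paste(res, collapse = ", "))
    if (!(resolution_bp %in% res))
      .stopf("resolution %d not present; available resolutions: {%s}",
             as.integer(resolution_bp), paste(res, collapse = ", "))
    sprintf("resolutions/%d", as.integer(resolution_bp))
  } else {
    if (!all(c("bins", "pixels", "chroms") %in% top))
      .stopf("malformed contact file: missing chroms/bins/pixels groups in %s", path)
    ""
  }
}

.g <- function(root, name) if (nzchar(root)) paste(root, name, sep = "/") else name

#' Open one resolution of a contact file
#'
#' Opens a `.cool` (single resolution) or `.mcool` (multi-resolution) contact
#' container and returns a validated handle. The pixel table stays on disk;
#' only the chromosome table, bin table, balancing weights and the `bin1_id`
#' index are loaded.
#'
#' @param path Path to a `.cool`/`.mcool` file.
#' @param resolution_bp Bin size to open. Required for `.mcool` files (the
#'   error message lists the stored resolutions); optional for `.cool` files,
#'   where it must match the stored bin size if given.
#' @param weight_col Name of the balancing-weight column in the bin table
#'   (cooler convention: `"weight"`). If the column is absent the store has no
#'   weights and balanced queries raise an error.
#' @return A `ContactStore` object: a list with elements `path`, `root`,
#'   `resolution`, `chromsizes`, `n_bins`, `bins`, `weights`, `bin1_offset`.
#' @seealso [fetch_block()], [write_contacts()]
#' @export
open_contacts <- function(path, resolution_bp = NULL, weight_col = "weight") {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  root <- .cool_root(path, resolution_bp)
  for (grp in c("chroms", "bins", "pixels")) {
    if (!.h5_exists(path, .g(root, grp)))
      .stopf("malformed contact file: missing group '%s'", .g(root, grp))
  }
  ch_name <- as.character(rhdf5::h5read(path, .g(root, "chroms/name")))
  ch_len <- as.numeric(rhdf5::h5read(path, .g(root, "chroms/length")))
  cs <- chrom_sizes(ch_name, ch_len)

  attrs <- .h5_read_attrs(path, if (nzchar(root)) root else "/")
  binsize <- if (!is.null(attrs[["bin-size"]])) as.numeric(attrs[["bin-size"]]) else NA
  bstart <- as.numeric(rhdf5::h5read(path, .g(root, "bins/start")))
  if (is.na(binsize)) binsize <- max(diff(sort(unique(bstart))), bstart[2] - bstart[1])
  if (!is.null(resolution_bp) && binsize != resolution_bp)
    .stopf("resolution %d not present; available resolutions: {%s}",
           as.integer(resolution_bp), format(binsize, scientific = FALSE))
  n_bins <- length(bstart)
  if (n_bins != .n_bins(cs, binsize))
    .stopf("bin table (%d bins) inconsistent with chromsizes at resolution %d",
           n_bins, as.integer(binsize))

  bin_fields <- rhdf5::h5ls(path)$name[
    rhdf5::h5ls(path)$group == paste0("/", .g(root, "bins"))]
  weights <- NULL
  if (weight_col %in% bin_fields) {
    weights <- as.numeric(rhdf5::h5read(path, .g(root, paste0("bins/", weight_col))))
    weights[!is.finite(weights)] <- NA_real_
  }

  if (.h5_exists(path, .g(root, "indexes/bin1_offset"))) {
    bin1_offset <- as.numeric(rhdf5::h5read(path, .g(root, "indexes/bin1_offset")))
  } else {
    b1 <- as.numeric(rhdf5::h5read(path, .g(root, "pixels/bin1_id")))
    bin1_offset <- c(0, cumsum(tabulate(b1 + 1L, nbins = n_bins)))
  }

  structure(list(path = normalizePath(path), root = root,
                 resolution = as.numeric(binsize), chromsizes = cs,
                 n_bins = n_bins, weights = weights,
                 bin1_offset = bin1_offset, weight_col = weight_col),
            class = "ContactStore")
}

#' @export
print.ContactStore <- function(x, ...) {
  nnz <- x$bin1_offset[length(x$bin1_offset)]
  cat(sprintf("ContactStore: %s\n", x$path))
  cat(sprintf("  resolution: %s bp | %d chromosomes | %d bins | %s pixels | weights: %s\n",
              format(x$resolution, scientific = FALSE), nrow(x$chromsizes),
              x$n_bins, format(nnz, big.mark = ","),
              if (is.null(x$weights)) "none" else x$weight_col))
  invisible(x)
}

## read the pixel-table slice with bin1_id in [lo, hi) (0-based, half-open)
.read_pixel_rows <- function(store, lo, hi) {
  o <- store$bin1_offset
  i0 <- o[lo + 1L] + 1L
  i1 <- o[hi + 1L]
  if (i1 < i0)
    return(data.frame(bin1 = integer(), bin2 = integer(), count = numeric()))
  idx <- list(i0:i1)
  data.frame(
    bin1 = as.integer(rhdf5::h5read(store$path, .g(store$root, "pixels/bin1_id"), index = idx)),
    bin2 = as.integer(rhdf5::h5read(store$path, .g(store$root, "pixels/bin2_id"), index = idx)),
    count = as.numeric(rhdf5::h5read(store$path, .g(store$root, "pixels/count"), index = idx)))
}

.validate_region <- function(store, region, what) {
  region <- as.integer(region)
  if (length(region) != 2L || region[1] < 0L || region[2] <= region[1] ||
      region[2] > store$n_bins)
    .stopf("%s: bin interval [%s, %s) out of range [0, %d)", what,
           region[1], region[2], store$n_bins)
  ci <- .bin_chrom_index(store$chromsizes, store$resolution,
                         c(region[1], region[2] - 1L))
  if (ci[1] != ci[2])
    .stopf("%s: bin interval [%d, %d) spans more than one chromosome",
           what, region[1], region[2])
  region
}

#' Fetch a dense rectangular block of contacts
#'
#' Returns the dense, symmetrized count matrix for a pair of bin intervals.
#' Stored pixels live in the upper triangle only; queries are mirrored across
#' the diagonal so any row/column orientation works. Balanced values follow
#' the cooler convention `raw * w[bin1] * w[bin2]`; a missing weight makes the
#' whole row/column of the balanced block missing.
#'
#' @param store A `ContactStore` from [open_contacts()].
#' @param region1,region2 Half-open genome-wide bin-index intervals
#'   `c(start, end)` (0-based), each on a single chromosome. The two regions
#'   may be on different chromosomes.
#' @param normalization `"raw"` or `"balanced"`.
#' @return A `DenseBlock`: list with `values` (matrix of
#'   `length(region1) x length(region2)`), `region1`, `region2`,
#'   `normalization`.
#' @examples
#' \donttest{
#' cs <- chrom_sizes("chrS", 5e3)
#' m <- matrix(0, 5, 5); m[2, 4] <- m[4, 2] <- 3
#' f <- tempfile(fileext = ".cool")
#' write_contacts(list(chrS = m), cs, 1e3, path = f)
#' fetch_block(open_contacts(f), c(3, 5), c(0, 3))$values
#' }
#' @export
fetch_block <- function(store, region1, region2, normalization = c("raw", "balanced")) {
  stopifnot(inherits(store, "ContactStore"))
  normalization <- match.arg(normalization)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  r1 <- .validate_region(store, region1, "region1")
  r2 <- .validate_region(store, region2, "region2")
  n1 <- r1[2] - r1[1]; n2 <- r2[2] - r2[1]
  M <- matrix(0, n1, n2)

  up <- .read_pixel_rows(store, r1[1], r1[2])       # bin1 in rows
  up <- up[up$bin2 >= r2[1] & up$bin2 < r2[2], , drop = FALSE]
  if (nrow(up))
    M[cbind(up$bin1 - r1[1] + 1L, up$bin2 - r2[1] + 1L)] <- up$count
  lo <- .read_pixel_rows(store, r2[1], r2[2])       # mirrored: bin1 in cols
  lo <- lo[lo$bin2 >= r1[1] & lo$bin2 < r1[2] & lo$bin1 != lo$bin2, , drop = FALSE]
  if (nrow(lo))
    M[cbind(lo$bin2 - r1[1] + 1L, lo$bin1 - r2[1] + 1L)] <- lo$count

  if (normalization == "balanced") {
    if (is.null(store$weights))
      .stopf("no '%s' column in the bin table: balanced counts unavailable",
             store$weight_col)
    w1 <- store$weights[(r1[1] + 1L):r1[2]]
    w2 <- store$weights[(r2[1] + 1L):r2[2]]
    M <- M * outer(w1, w2)
  }
  structure(list(values = M, region1 = r1, region2 = r2,
                 normalization = normalization),
            class = "DenseBlock")
}

#' Write dense per-chromosome matrices as a cooler-dialect file
#'
#' Fixture/simulator writer: stores the upper triangle of symmetric,
#' non-negative integer intra-chromosomal matrices as a `.cool` container
#' (or one resolution of an `.mcool` when `path` ends in `.mcool`),
#' readable by [open_contacts()] and by community readers of the format.
#'
#' @param dense_by_chrom Named list (chromosome -> square symmetric matrix of
#'   non-negative integer counts, side `ceiling(length/resolution)`).
#' @param chromsizes A [chrom_sizes] table covering every listed chromosome.
#' @param resolution_bp Bin size in bp.
#' @param weights Optional per-bin balancing weights (length = total bins;
#'   `NA` marks filtered bins, stored as NaN).
#' @param path Output file path (`.cool`, or `.mcool` for multi-resolution --
#'   repeated calls with the same `.mcool` path add resolutions).
#' @return A `ContactStore` opened on the written file, invisibly.
#' @export
write_contacts <- function(dense_by_chrom, chromsizes, resolution_bp,
                           weights = NULL, path) {
  cs <- .validate_chromsizes(chromsizes)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (is.null(names(dense_by_chrom)) ||
      !all(names(dense_by_chrom) %in% cs$chrom))
    .stopf("dense_by_chrom must be named by chromosomes present in chromsizes")
  cs <- cs[cs$chrom %in% names(dense_by_chrom), , drop = FALSE]
  nb <- .bins_per_chrom(cs, resolution_bp)
  off <- .chrom_offsets(cs, resolution_bp)
  n_bins <- sum(nb)
  if (!is.null(weights) && length(weights) != n_bins)
    .stopf("weights must have one value per bin (%d)", n_bins)

  b1 <- b2 <- cnt <- vector("list", nrow(cs))
  for (i in seq_len(nrow(cs))) {
    m <- dense_by_chrom[[cs$chrom[i]]]
    if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) != nb[i])
      .stopf("matrix for %s must be square with side %d", cs$chrom[i], nb[i])
    if (any(m < 0) || any(m != round(m)))
      .stopf("matrix for %s must hold non-negative integer counts", cs$chrom[i])
    if (!isTRUE(all.equal(m, t(m))))
      .stopf("matrix for %s is not symmetric", cs$chrom[i])
    keep <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    ord <- order(keep[, 1], keep[, 2])
    keep <- keep[ord, , drop = FALSE]
    b1[[i]] <- off[i] + keep[, 1] - 1L
    b2[[i]] <- off[i] + keep[, 2] - 1L
    cnt[[i]] <- m[keep]
  }
  b1 <- as.integer(unlist(b1)); b2 <- as.integer(unlist(b2))
  cnt <- as.numeric(unlist(cnt))
  ord <- order(b1, b2)
  b1 <- b1[ord]; b2 <- b2[ord]; cnt <- cnt[ord]

  mcool <- grepl("\\.mcool$", path)
  root <- if (mcool) sprintf("resolutions/%d", as.integer(resolution_bp)) else ""
  if (!file.exists(path)) rhdf5::h5createFile(path)
  if (mcool) {
    if (!.h5_exists(path, "resolutions")) rhdf5::h5createGroup(path, "resolutions")
    if (.h5_exists(path, root)) .stopf("resolution %d already present in %s",
                                       as.integer(resolution_bp), path)
    rhdf5::h5createGroup(path, root)
  }
  for (grp in c("chroms", "bins", "pixels", "indexes"))
    rhdf5::h5createGroup(path, .g(root, grp))

  rhdf5::h5write(cs$chrom, path, .g(root, "chroms/name"))
  rhdf5::h5write(as.numeric(cs$length), path, .g(root, "chroms/length"))
  bt <- .bin_table(cs, resolution_bp)
  rhdf5::h5write(match(bt$chrom, cs$chrom) - 1L, path, .g(root, "bins/chrom"))
  rhdf5::h5write(as.numeric(bt$start), path, .g(root, "bins/start"))
  rhdf5::h5write(as.numeric(bt$end), path, .g(root, "bins/end"))
  if (!is.null(weights)) {
    w <- as.numeric(weights); w[is.na(w)] <- NaN
    rhdf5::h5write(w, path, .g(root, "bins/weight"))
  }
  rhdf5::h5write(b1, path, .g(root, "pixels/bin1_id"))
  rhdf5::h5write(b2, path, .g(root, "pixels/bin2_id"))
  rhdf5::h5write(cnt, path, .g(root, "pixels/count"))
  bin1_offset <- c(0, cumsum(tabulate(b1 + 1L, nbins = n_bins)))
  rhdf5::h5write(as.numeric(bin1_offset), path, .g(root, "indexes/bin1_offset"))
  rhdf5::h5write(as.numeric(off), path, .g(root, "indexes/chrom_offset"))
  .h5_write_attrs(path, if (nzchar(root)) root else "/", list(
    `format` = "HDF5::Cooler", `format-version` = 3L,
    `bin-size` = as.integer(resolution_bp), `bin-type` = "fixed",
    `storage-mode` = "symmetric-upper", nbins = as.integer(n_bins),
    nchroms = nrow(cs), nnz = length(cnt), sum = sum(cnt)))
  rhdf5::h5closeAll()
  invisible(open_contacts(path, resolution_bp))
}
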