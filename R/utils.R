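## Internal helpers shared across modules.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded at `seed` and
#' restores the previous RNG state afterwards, so simulator calls never
#' perturb user code.
#' @noRd
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## HDF5 attribute helpers built on rhdf5 low-level handles.

.h5_write_attrs <- function(path, obj, attrs) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- if (identical(obj, "/")) fid else rhdf5::H5Gopen(fid, obj)
  if (!identical(obj, "/")) on.exit(rhdf5::H5Gclose(oid), add = TRUE)
  for (nm in names(attrs)) {
    val <- attrs[[nm]]
    rhdf5::h5writeAttribute(val, oid, nm, asScalar = length(val) == 1L)
  }
  invisible(NULL)
}

.h5_read_attrs <- function(path, obj = "/") {
  rhdf5::h5readAttributes(path, obj)
}

.h5_exists <- function(path, name) {
  fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::H5Lexists(fid, name)
}
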