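## Internal helpers: seeded evaluation, seed derivation, minimal NPY I/O.

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's RNG
# stream is restored afterwards.  seed = NULL uses the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive n child seeds (< 2^31) from a master seed.
deriveSeeds <- function(masterSeed, n) {
  withSeed(masterSeed, sample.int(.Machine$integer.max, n))
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (positive && x <= 0))
    stop(sprintf("'%s' must be a single %snumber", name,
                 if (positive) "positive " else ""), call. = FALSE)
  invisible(x)
}

## ---- minimal NumPy .npy (v1.0, float64, C order) ----

npyWrite <- function(x, path) {
  dims <- dim(x)
  if (is.null(dims)) dims <- length(x)
  shape <- paste0("(", paste(dims, collapse = ", "),
                  if (length(dims) == 1L) "," else "", ")")
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': %s, }",
                    shape)
  # pad so that magic(6)+version(2)+len(2)+header is a multiple of 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  # C order = reversed-dimension F order
  xr <- if (length(dims) > 1L) aperm(array(x, dims), rev(seq_along(dims))) else x
  writeBin(as.numeric(xr), con, size = 8, endian = "little")
  invisible(path)
}

npyRead <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file: ", path, call. = FALSE)
  ver <- readBin(con, "raw", 2)
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  if (!grepl("'<f8'", header, fixed = TRUE))
    stop("unsupported NPY dtype (only float64 '<f8' is supported)", call. = FALSE)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shp <- regmatches(header, regexpr("\\(([^)]*)\\)", header))
  dims <- as.integer(strsplit(gsub("[()]|\\s", "", shp), ",")[[1]])
  n <- prod(dims)
  x <- readBin(con, "numeric", n, size = 8, endian = "little")
  if (length(x) != n) stop("truncated NPY payload", call. = FALSE)
  if (length(dims) <= 1L) return(x)
  if (fortran) array(x, dims) else aperm(array(x, rev(dims)), rev(seq_along(dims)))
}
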