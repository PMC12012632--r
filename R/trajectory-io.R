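## Trajectory file I/O: NPY (frames x particles x dims float64), CSV
## (frame, particle, x, y columns), and XYZ (one block per frame).

.traj_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("npy", "csv", "xyz")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("npy", "csv", "xyz")) ext else
    stop("cannot infer trajectory format from '", path,
         "'; pass format = \"npy\"/\"csv\"/\"xyz\"", call. = FALSE)
}

#' Write a trajectory to disk
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @param format \code{"npy"}, \code{"csv"} or \code{"xyz"}; inferred from
#'   the file extension when omitted.  Round trips preserve coordinates to
#'   float64 (npy/csv) or the printed precision (xyz).
#' @return the path, invisibly.
#' @export
writeTrajectory <- function(traj, path, format = NULL) {
  stopifnot(is(traj, "Trajectory"))
  format <- .traj_format(path, format)
  fr <- frames(traj)
  d <- dim(fr)
  switch(format,
    npy = npyWrite(fr, path),
    csv = {
      df <- data.frame(
        frame = rep(seq_len(d[1]), each = d[2]),
        particle = rep(seq_len(d[2]), times = d[1]),
        x = as.vector(t(fr[, , 1, drop = TRUE])),
        y = as.vector(t(fr[, , 2, drop = TRUE])))
      # t() on a 1-frame slice needs the matrix kept
      if (d[1] == 1L) { df$x <- fr[1, , 1]; df$y <- fr[1, , 2] }
      write.csv(df, path, row.names = FALSE)
    },
    xyz = {
      con <- file(path, "w")
      on.exit(close(con))
      for (f in seq_len(d[1])) {
        writeLines(as.character(d[2]), con)
        writeLines(sprintf("frame %d", f), con)
        writeLines(sprintf("X %.12g %.12g 0.0", fr[f, , 1], fr[f, , 2]), con)
      }
    })
  invisible(path)
}

#' Read a trajectory from disk
#'
#' @param path input file written by [writeTrajectory()] (or compatible).
#' @param format see [writeTrajectory()].
#' @param dtPerFrame time per frame to attach (file formats carry none).
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, format = NULL, dtPerFrame = 1) {
  format <- .traj_format(path, format)
  fr <- switch(format,
    npy = {
      a <- npyRead(path)
      if (length(dim(a)) == 2L) a <- array(a, c(dim(a)[1], 1L, dim(a)[2]))
      if (length(dim(a)) != 3L) stop("NPY trajectory must be 2D or 3D")
      a
    },
    csv = {
      df <- read.csv(path)
      need <- c("frame", "particle", "x", "y")
      if (!all(need %in% names(df)))
        stop("CSV trajectory must have columns frame, particle, x, y")
      for (cl in c("x", "y")) {
        bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cl]]))))
        if (length(bad))
          stop(sprintf("parse error: non-numeric '%s' at data row %d",
                       cl, bad[1]))
      }
      nf <- max(df$frame); np <- max(df$particle)
      if (nrow(df) != nf * np) stop("CSV trajectory has missing frame/particle rows")
      o <- order(df$frame, df$particle)
      array(c(matrix(as.numeric(df$x[o]), nf, np, byrow = TRUE),
              matrix(as.numeric(df$y[o]), nf, np, byrow = TRUE)),
            dim = c(nf, np, 2L))
    },
    xyz = {
      lines <- readLines(path)
      i <- 1L; framesList <- list()
      while (i <= length(lines)) {
        if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
        n <- suppressWarnings(as.integer(trimws(lines[i])))
        if (is.na(n)) stop(sprintf("parse error at line %d: expected atom count", i))
        if (i + 1L + n > length(lines))
          stop(sprintf("parse error: frame starting at line %d truncated (header says %d atoms)",
                       i, n))
        block <- lines[(i + 2L):(i + 1L + n)]
        xy <- t(vapply(seq_along(block), function(k) {
          parts <- strsplit(trimws(block[k]), "\\s+")[[1]]
          if (length(parts) < 3L)
            stop(sprintf("parse error at line %d: expected 'name x y [z]'", i + 1L + k))
          v <- suppressWarnings(as.numeric(parts[2:3]))
          if (any(is.na(v)))
            stop(sprintf("parse error at line %d: non-numeric coordinate", i + 1L + k))
          v
        }, numeric(2)))
        framesList[[length(framesList) + 1L]] <- xy
        i <- i + 2L + n
      }
      np <- unique(vapply(framesList, nrow, integer(1)))
      if (length(np) != 1L) stop("parse error: inconsistent atom counts across frames")
      a <- array(0, c(length(framesList), np, 2L))
      for (f in seq_along(framesList)) a[f, , ] <- framesList[[f]]
      a
    })
  new("Trajectory", frames = fr, dtPerFrame = dtPerFrame,
      meta = list(source = path, format = format))
}
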