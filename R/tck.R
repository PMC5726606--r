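#' Write streamlines to a TCK tractogram
#'
#' Writes the MRtrix track-file format: a text header followed by
#' little-endian float32 world-coordinate triplets, with streamlines
#' separated by a NaN triplet and the file terminated by an Inf triplet.
#'
#' @param streamlines a `streamline_set` (see [track_seed()]) or a list of
#'   n x 3 matrices of world coordinates (mm).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(streamlines, path) {
  if (inherits(streamlines, "streamline_set")) streamlines <- streamlines$streamlines
  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                   length(streamlines), "\nfile: . ")
  # offset must include its own digits; header ends with "<offset>\nEND\n"
  base <- nchar(header, type = "bytes")
  offset <- base
  repeat {
    cand <- base + nchar(as.character(offset)) + nchar("\nEND\n")
    if (cand == offset) break
    offset <- cand
  }
  writeChar(paste0(header, offset, "\nEND\n"), con, eos = NULL)
  for (s in streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a TCK tractogram
#'
#' @param path path to a `.tck` file (Float32LE data).
#' @return List of n x 3 matrices of world coordinates (mm).
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("truncated TCK header in ", path)
    if (identical(ln, "END")) break
    lines <- c(lines, ln)
  }
  if (!identical(lines[1], "mrtrix tracks")) stop("not a TCK file: ", path)
  kv <- strsplit(lines[-1], ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), "")
  dt <- vals[match("datatype", keys)]
  if (!identical(dt, "Float32LE")) stop("unsupported TCK datatype: ", dt)
  offset <- as.integer(strsplit(vals[match("file", keys)], " ")[[1]][2])
  seek(con, offset)
  raw <- readBin(con, "numeric", n = file.size(path), size = 4L, endian = "little")
  m <- matrix(raw, ncol = 3L, byrow = TRUE)
  ends <- which(!is.finite(m[, 1]) & !is.nan(m[, 1]))  # Inf terminator
  breaks <- which(is.nan(m[, 1]))
  stop_at <- if (length(ends)) ends[1] else nrow(m) + 1L
  breaks <- breaks[breaks < stop_at]
  out <- list()
  start <- 1L
  for (b in breaks) {
    if (b > start) out[[length(out) + 1L]] <- m[start:(b - 1L), , drop = FALSE]
    start <- b + 1L
  }
  out
}
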