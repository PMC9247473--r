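#' Read a GRO coordinate file
#'
#' Parses one fixed-width GROMACS GRO frame (title line, atom count, atom
#' records, box line) into a [membrane_frame()]. Positions are in nm.
#' Velocity columns, if present, are ignored. Residue and bead names are
#' whitespace-stripped. Only orthorhombic boxes are supported: a box line
#' with any nonzero off-diagonal component is rejected.
#'
#' @param path Path to a `.gro` file.
#' @return A [membrane_frame()].
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("GRO parse error: file has fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 0)
    stop("GRO parse error: line 2 is not an atom count: '", lines[2], "'")
  if (length(lines) < 2 + n + 1)
    stop(sprintf("GRO parse error: header declares %d atom records but only %d lines follow (line %d)",
                 n, length(lines) - 2L, length(lines)))
  rec <- lines[seq.int(3, 2 + n)]
  short <- which(nchar(rec) < 44)
  if (length(short))
    stop(sprintf("GRO parse error: atom record too short at line %d", 2L + short[1]))
  num <- function(s) suppressWarnings(as.numeric(s))
  resid <- suppressWarnings(as.integer(substr(rec, 1, 5)))
  resname <- trimws(substr(rec, 6, 10))
  bead <- trimws(substr(rec, 11, 15))
  x <- num(substr(rec, 21, 28))
  y <- num(substr(rec, 29, 36))
  z <- num(substr(rec, 37, 44))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop(sprintf("GRO parse error: malformed atom record at line %d", 2L + bad[1]))
  boxv <- num(strsplit(trimws(lines[2 + n + 1]), "\\s+")[[1]])
  if (length(boxv) < 3 || anyNA(boxv[1:3]))
    stop("GRO parse error: malformed box line")
  if (length(boxv) > 3 && any(abs(boxv[-(1:3)]) > 1e-9))
    stop("unsupported geometry: non-orthorhombic box (nonzero off-diagonal components)")
  membrane_frame(
    beads = data.frame(resid = resid, species = resname, bead = bead,
                       x = x, y = y, z = z, stringsAsFactors = FALSE),
    box = boxv[1:3])
}

#' Write a membrane frame as a GRO file
#'
#' Emits fixed-width GRO records with 3-decimal positions in nm and a
#' 3-component box line. Residue and atom numbers are written modulo 100000
#' as the format requires (larger ids wrap silently).
#'
#' @param frame A [membrane_frame()].
#' @param path Output path.
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path, title = "curvsort frame") {
  stopifnot(inherits(frame, "membrane_frame"))
  b <- frame$beads
  n <- nrow(b)
  rec <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                 b$resid %% 100000L,
                 substr(b$species, 1, 5),
                 substr(b$bead, 1, 5),
                 seq_len(n) %% 100000L,
                 b$x, b$y, b$z)
  box <- sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3])
  writeLines(c(title, sprintf("%5d", n), rec, box), path)
  invisible(path)
}
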