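#' Read MS2 spectra from an MGF or MSP peak-list file
#'
#' Both dialects carry one record per spectrum: a metadata block followed by
#' whitespace-separated `m/z intensity` peak lines.
#'
#' MGF records are delimited by `BEGIN IONS`/`END IONS`; the precursor m/z is
#' the first token of `PEPMASS=` and the collision energy is read from
#' `COLLISION_ENERGY=`. MSP records start at `Name:` and announce their peak
#' count with `Num Peaks:`; precursor m/z comes from `PrecursorMZ:` and the
#' collision energy from `CollisionEnergy:`. A `LABEL=` (MGF) or `Label:`
#' (MSP) key, written by [write_spectra()], restores quality labels.
#'
#' Collision energy is required metadata (it is a model feature), so a record
#' without it is an error, as is one without a precursor m/z. Peaks are
#' returned sorted ascending by m/z.
#'
#' @param path path to the peak-list file.
#' @param format `"mgf"` or `"msp"`; defaults to the file extension.
#' @return List of [ms2_spectrum()] objects (empty list for an empty file).
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, format = c("mgf", "msp")) {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("mgf", "msp")) ext else "mgf"
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "mgf") parse_mgf(lines, path) else parse_msp(lines, path)
}

parse_peak_line <- function(line, lineno, path) {
  toks <- strsplit(trimws(line), "[ \t]+")[[1]]
  vals <- suppressWarnings(as.numeric(toks[1:2]))
  if (length(toks) < 2L || anyNA(vals))
    stop("malformed peak line ", lineno, " in ", path, ": '", line, "'")
  vals
}

parse_mgf <- function(lines, path) {
  spectra <- list()
  i <- 1L
  n <- length(lines)
  rec <- 0L
  while (i <= n) {
    if (trimws(lines[i]) != "BEGIN IONS") { i <- i + 1L; next }
    rec <- rec + 1L
    meta <- list()
    mz <- numeric(0); int <- numeric(0)
    i <- i + 1L
    while (i <= n && trimws(lines[i]) != "END IONS") {
      ln <- trimws(lines[i])
      if (nzchar(ln) && !startsWith(ln, "#")) {
        if (grepl("=", ln, fixed = TRUE)) {
          key <- toupper(sub("=.*$", "", ln))
          meta[[key]] <- sub("^[^=]*=", "", ln)
        } else {
          p <- parse_peak_line(ln, i, path)
          mz <- c(mz, p[1]); int <- c(int, p[2])
        }
      }
      i <- i + 1L
    }
    if (i > n) stop("unterminated MGF record (missing END IONS) in ", path)
    i <- i + 1L
    id <- if (!is.null(meta$TITLE)) meta$TITLE else sprintf("spectrum_%d", rec)
    if (is.null(meta$PEPMASS))
      stop("record '", id, "' in ", path, " has no PEPMASS (precursor m/z required)")
    if (is.null(meta$COLLISION_ENERGY))
      stop("record '", id, "' in ", path, " has no COLLISION_ENERGY")
    premz <- as.numeric(strsplit(trimws(meta$PEPMASS), "[ \t]+")[[1]][1])
    ce <- as.numeric(meta$COLLISION_ENERGY)
    label <- if (!is.null(meta$LABEL)) tolower(trimws(meta$LABEL)) else NA_character_
    spectra[[length(spectra) + 1L]] <-
      ms2_spectrum(id, premz, ce, mz, int, label = label)
  }
  spectra
}

parse_msp <- function(lines, path) {
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (!grepl("^Name:", ln, ignore.case = TRUE)) { i <- i + 1L; next }
    meta <- list(NAME = trimws(sub("^[Nn]ame:", "", ln)))
    i <- i + 1L
    npk <- NA_integer_
    while (i <= n) {
      ln <- trimws(lines[i])
      if (!nzchar(ln)) break
      if (grepl("^Num ?Peaks:", ln, ignore.case = TRUE)) {
        npk <- as.integer(trimws(sub("^[^:]*:", "", ln)))
        i <- i + 1L
        break
      }
      if (grepl(":", ln, fixed = TRUE)) {
        key <- toupper(gsub("[ _]", "", sub(":.*$", "", ln)))
        meta[[key]] <- trimws(sub("^[^:]*:", "", ln))
      }
      i <- i + 1L
    }
    mz <- numeric(0); int <- numeric(0)
    while (i <= n && nzchar(trimws(lines[i]))) {
      p <- parse_peak_line(lines[i], i, path)
      mz <- c(mz, p[1]); int <- c(int, p[2])
      i <- i + 1L
    }
    if (!is.na(npk) && length(mz) != npk)
      stop("record '", meta$NAME, "' in ", path, ": Num Peaks says ", npk,
           " but ", length(mz), " peak lines found")
    if (is.null(meta$PRECURSORMZ))
      stop("record '", meta$NAME, "' in ", path, " has no PrecursorMZ")
    if (is.null(meta$COLLISIONENERGY))
      stop("record '", meta$NAME, "' in ", path, " has no CollisionEnergy")
    label <- if (!is.null(meta$LABEL)) tolower(meta$LABEL) else NA_character_
    spectra[[length(spectra) + 1L]] <-
      ms2_spectrum(meta$NAME, as.numeric(meta$PRECURSORMZ),
                   as.numeric(meta$COLLISIONENERGY), mz, int, label = label)
  }
  spectra
}

#' Write MS2 spectra to an MGF or MSP peak-list file
#'
#' Lossless counterpart of [read_spectra()]: id, precursor m/z, collision
#' energy, peaks and (if present) the quality label round-trip. m/z and
#' intensity are printed with 15 significant digits.
#'
#' @param spectra list of [ms2_spectrum()] objects.
#' @param path output path.
#' @inheritParams read_spectra
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, format = c("mgf", "msp")) {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("mgf", "msp")) ext else "mgf"
  }
  format <- match.arg(format)
  fmt_num <- function(x) formatC(x, digits = 15, format = "g")
  out <- character(0)
  for (s in spectra) {
    pk <- paste(fmt_num(s$peaks[, "mz"]), fmt_num(s$peaks[, "intensity"]))
    if (format == "mgf") {
      block <- c("BEGIN IONS",
                 paste0("TITLE=", s$id),
                 paste0("PEPMASS=", fmt_num(s$precursor_mz)),
                 paste0("COLLISION_ENERGY=", fmt_num(s$collision_energy)),
                 if (!is.na(s$label)) paste0("LABEL=", s$label),
                 pk,
                 "END IONS", "")
    } else {
      block <- c(paste0("Name: ", s$id),
                 paste0("PrecursorMZ: ", fmt_num(s$precursor_mz)),
                 paste0("CollisionEnergy: ", fmt_num(s$collision_energy)),
                 if (!is.na(s$label)) paste0("Label: ", s$label),
                 paste0("Num Peaks: ", nrow(s$peaks)),
                 pk, "")
    }
    out <- c(out, block)
  }
  writeLines(out, path)
  invisible(path)
}
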