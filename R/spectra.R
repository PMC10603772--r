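#' Construct an MS2 spectrum
#'
#' The elementary data object of the package: one centroided tandem mass
#' (MS2) spectrum, i.e. a peak list of (m/z, intensity) pairs together with
#' the precursor m/z, the collision energy at which the spectrum was
#' acquired, an identifier, and an optional diagnostic-quality label.
#'
#' Peaks are stored sorted ascending by m/z. Both precursor m/z and
#' collision energy are required metadata because they enter every feature
#' vector the classifier sees.
#'
#' @param id character identifier, unique within a dataset.
#' @param precursor_mz precursor ion m/z in Da; must be > 0.
#' @param collision_energy normalized HCD collision energy in percent; >= 0.
#' @param mz numeric vector of fragment m/z values in Da (> 0).
#' @param intensity numeric vector of intensities (arbitrary counts, >= 0),
#'   same length as `mz`.
#' @param label optional quality label, `"good"` or `"poor"`; `NA` if the
#'   spectrum is unlabeled.
#' @param meta optional named list of additional metadata (kept verbatim).
#'
#' @return An object of class `ms2_spectrum`: a list with elements `id`,
#'   `precursor_mz`, `collision_energy`, `peaks` (two-column matrix with
#'   columns `mz`, `intensity`), `label`, `meta`.
#' @examples
#' sp <- ms2_spectrum("demo", precursor_mz = 300.1, collision_energy = 35,
#'                    mz = c(77.04, 105.03, 151.05), intensity = c(120, 800, 9500))
#' sp
#' @export
ms2_spectrum <- function(id, precursor_mz, collision_energy,
                         mz = numeric(0), intensity = numeric(0),
                         label = NA_character_, meta = list()) {
  id <- as.character(id)
  precursor_mz <- as.numeric(precursor_mz)
  collision_energy <- as.numeric(collision_energy)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length (spectrum '", id, "')")
  if (length(precursor_mz) != 1L || !is.finite(precursor_mz) || precursor_mz <= 0)
    stop("precursor_mz must be a single positive number (spectrum '", id, "')")
  if (length(collision_energy) != 1L || !is.finite(collision_energy) || collision_energy < 0)
    stop("collision_energy must be a single nonnegative number (spectrum '", id, "')")
  if (anyNA(mz) || anyNA(intensity))
    stop("NA values in peak list (spectrum '", id, "')")
  if (length(mz) && (any(mz <= 0) || any(intensity < 0)))
    stop("peaks must have mz > 0 and intensity >= 0 (spectrum '", id, "')")
  if (!is.na(label) && !label %in% c("good", "poor"))
    stop("label must be 'good', 'poor' or NA (spectrum '", id, "')")
  ord <- order(mz)
  structure(
    list(id = id,
         precursor_mz = precursor_mz,
         collision_energy = collision_energy,
         peaks = cbind(mz = mz[ord], intensity = intensity[ord]),
         label = label,
         meta = meta),
    class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum '%s'>  precursor m/z %.4f  CE %g%%  %d peaks  label: %s\n",
              x$id, x$precursor_mz, x$collision_energy,
              nrow(x$peaks), ifelse(is.na(x$label), "<none>", x$label)))
  invisible(x)
}

n_peaks <- function(spectrum) nrow(spectrum$peaks)

#' Extract labels from a list of spectra
#'
#' @param spectra list of [ms2_spectrum()] objects.
#' @return Character vector of labels (`NA` where unlabeled), named by id.
#' @export
spectrum_labels <- function(spectra) {
  stats::setNames(vapply(spectra, function(s) s$label, character(1)),
                  vapply(spectra, function(s) s$id, character(1)))
}

#' Attach quality labels to spectra from a label table
#'
#' Labels live in a sidecar table (id, label) mirroring a manual labeling
#' workflow; this joins them onto the spectra by id. Spectra whose id is
#' absent from the table are left unlabeled; table ids that match no
#' spectrum trigger a warning and are ignored.
#'
#' @param spectra list of [ms2_spectrum()] objects with unique ids.
#' @param label_table data.frame with columns `id` and `label`
#'   (values `"good"`/`"poor"`), e.g. from [read_label_table()].
#' @return The list of spectra with labels attached.
#' @export
attach_labels <- function(spectra, label_table) {
  stopifnot(is.data.frame(label_table), all(c("id", "label") %in% names(label_table)))
  ids <- vapply(spectra, function(s) s$id, character(1))
  if (anyDuplicated(ids))
    stop("spectrum ids are not unique: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- !label_table$label %in% c("good", "poor")
  if (any(bad))
    stop("label values outside {good, poor}: ", paste(unique(label_table$label[bad]), collapse = ", "))
  unknown <- setdiff(label_table$id, ids)
  if (length(unknown))
    warning(length(unknown), " label table id(s) match no spectrum: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  idx <- match(ids, label_table$id)
  for (i in seq_along(spectra))
    if (!is.na(idx[i])) spectra[[i]]$label <- label_table$label[idx[i]]
  unmatched <- sum(is.na(idx))
  if (unmatched)
    message(unmatched, " spectrum/spectra left unlabeled (no row in label table)")
  spectra
}

#' Read or write a label table
#'
#' CSV with header `id,label`.
#' @param path file path.
#' @return `read_label_table`: data.frame with character columns `id`, `label`.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character")
  if (!all(c("id", "label") %in% names(tab)))
    stop("label table must have columns 'id' and 'label': ", path)
  tab[, c("id", "label")]
}

#' @rdname read_label_table
#' @param spectra list of labeled spectra whose (id, label) pairs are written;
#'   unlabeled spectra are skipped.
#' @export
write_label_table <- function(spectra, path) {
  lab <- spectrum_labels(spectra)
  keep <- !is.na(lab)
  utils::write.csv(data.frame(id = names(lab)[keep], label = unname(lab[keep])),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
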