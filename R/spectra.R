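# MS2 spectrum container and MGF peak-list I/O.
#
# No installed R package reads MGF peak lists (mzR covers mzML/mzXML),
# so a minimal reader/writer for the fields this workflow uses (TITLE,
# PEPMASS as m/z, CHARGE, RTINSECONDS, peak rows) lives here. Precursor
# masses are stored internally as neutral monoisotopic masses.

#' Construct an MS2 spectrum
#'
#' @param scan_id Scan identifier.
#' @param precursor_neutral_mass Neutral monoisotopic precursor mass, Da.
#' @param charge Precursor charge (integer >= 1).
#' @param rt Retention time in minutes.
#' @param mz,intensity Peak list; re-sorted by m/z on construction.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(scan_id, precursor_neutral_mass, charge, rt,
                     mz = numeric(0), intensity = numeric(0)) {
  stopifnot(length(mz) == length(intensity), charge >= 1)
  if (any(intensity < 0)) stop("negative peak intensity")
  o <- order(mz)
  structure(
    list(scan_id = as.character(scan_id),
         precursor_neutral_mass = precursor_neutral_mass,
         charge = as.integer(charge),
         rt = rt,
         mz = mz[o], intensity = intensity[o]),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s  M %.4f Da  z%d  RT %.2f min  %d peaks\n",
              x$scan_id, x$precursor_neutral_mass, x$charge, x$rt,
              length(x$mz)))
  invisible(x)
}

#' Write spectra to an MGF peak list
#'
#' PEPMASS is written as precursor m/z (computed from the stored neutral
#' mass and charge), RTINSECONDS in seconds.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output file.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(inherits(s, "spectrum"))
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", s$scan_id),
      sprintf("PEPMASS=%.6f", mass_to_mz(s$precursor_neutral_mass, s$charge)),
      sprintf("CHARGE=%d+", s$charge),
      sprintf("RTINSECONDS=%.4f", s$rt * 60)
    ), con)
    if (length(s$mz))
      writeLines(sprintf("%.6f %.4f", s$mz, s$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read spectra from an MGF peak list
#'
#' @param path MGF file.
#' @return List of [spectrum()] objects; `PEPMASS` m/z values are
#'   converted to neutral masses using the `CHARGE` line.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  out <- vector("list", length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1L)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    z <- as.integer(sub("\\+$", "", get("CHARGE")))
    if (is.na(z)) stop("MGF block ", i, " lacks a CHARGE line")
    pepmz <- as.numeric(get("PEPMASS"))
    if (is.na(pepmz)) stop("MGF block ", i, " lacks a PEPMASS line")
    rt_s <- as.numeric(get("RTINSECONDS"))
    peak_lines <- block[!hdr]
    peak_lines <- peak_lines[nzchar(trimws(peak_lines))]
    if (length(peak_lines)) {
      pk <- do.call(rbind, strsplit(trimws(peak_lines), "[ \t]+"))
      mz <- as.numeric(pk[, 1]); int <- as.numeric(pk[, 2])
    } else {
      mz <- numeric(0); int <- numeric(0)
    }
    out[[i]] <- spectrum(
      scan_id = if (is.na(get("TITLE"))) paste0("scan_", i) else get("TITLE"),
      precursor_neutral_mass = mz_to_mass(pepmz, z),
      charge = z,
      rt = if (is.na(rt_s)) NA_real_ else rt_s / 60,
      mz = mz, intensity = int
    )
  }
  out
}
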