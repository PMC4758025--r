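# Monoisotopic mass bookkeeping: residues, modifications, the BS3
# light/heavy linker, and peptide/precursor/fragment arithmetic.
# All masses in Da, monoisotopic throughout (Orbitrap data; average
# masses are never used). Single constants table so results are
# bit-stable across the package and its test oracles.

.ATOMIC <- c(
  H  = 1.00782503207,
  D  = 2.01410177785,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100
)

.PROTON <- 1.00727646688
.WATER  <- 2 * .ATOMIC[["H"]] + .ATOMIC[["O"]]

# residue (i.e. amino-acid minus water) monoisotopic masses
.AA_MONO <- c(
  G =  57.02146372, A =  71.03711379, S =  87.03202840, P =  97.05276385,
  V =  99.06841391, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496301, E = 129.04259309, M = 131.04048491, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

.MOX <- .ATOMIC[["O"]]  # methionine oxidation, +15.9949 Da

# BS3 bridge (octanedioyl, C8H10O2): what both peptides gain together in a
# cross-link. Heavy form carries 12 deuteriums in place of 12 hydrogens.
.BS3_BRIDGE_LIGHT <- 8 * .ATOMIC[["C"]] + 10 * .ATOMIC[["H"]] + 2 * .ATOMIC[["O"]]
.BS3_HEAVY_SHIFT  <- 12 * (.ATOMIC[["D"]] - .ATOMIC[["H"]])

#' Mass constants used throughout the package
#'
#' Returns the embedded monoisotopic constants table: residue masses,
#' atomic masses, proton and water masses, the BS3 bridge mass and the
#' heavy-linker (D12 vs H12) shift. Exposed so external oracles and
#' scripts can reproduce every mass computed by the package.
#'
#' @return A list with elements `residues` (named numeric, Da),
#'   `atoms` (named numeric, Da), `proton`, `water`, `mox`,
#'   `bs3_bridge_light` and `bs3_heavy_shift` (all Da).
#' @export
#' @examples
#' mass_constants()$bs3_heavy_shift  # 12.0753 Da
mass_constants <- function() {
  list(
    residues         = .AA_MONO,
    atoms            = .ATOMIC,
    proton           = .PROTON,
    water            = .WATER,
    mox              = .MOX,
    bs3_bridge_light = .BS3_BRIDGE_LIGHT,
    bs3_heavy_shift  = .BS3_HEAVY_SHIFT
  )
}

#' BS3 linker specification
#'
#' The homobifunctional amine-reactive cross-linker BS3
#' (bis(sulfosuccinimidyl)suberate), available as a light (H12) and a
#' deuterated heavy (D12) isotopologue. The first reactive site class is
#' a lysine side chain or a protein N-terminus; the second additionally
#' admits serine, threonine and tyrosine hydroxyls.
#'
#' @param spacer_length Spacer arm length in Angstrom (11.4 for BS3).
#' @return An object of class `linker_spec`.
#' @export
bs3_linker <- function(spacer_length = 11.4) {
  stopifnot(spacer_length > 0)
  structure(
    list(
      name = "BS3",
      spacer_length = spacer_length,
      first_site_residues  = c("K", "N-term"),
      second_site_residues = c("K", "S", "T", "Y", "N-term")
    ),
    class = "linker_spec"
  )
}

#' @export
print.linker_spec <- function(x, ...) {
  cat(sprintf("<linker_spec> %s, spacer %.1f A\n", x$name, x$spacer_length))
  cat("  site 1:", paste(x$first_site_residues, collapse = ", "), "\n")
  cat("  site 2:", paste(x$second_site_residues, collapse = ", "), "\n")
  invisible(x)
}

#' Neutral mass added by the linker
#'
#' Mass delta contributed by the BS3 linker to the peptide(s), by
#' isotopic form and attachment chemistry: `cross-link` (bridge between
#' two sites), `dead-end` (one end reacted, the other hydrolyzed, so the
#' bridge retains a water) or `loop` (both ends on one peptide).
#' The heavy minus light difference is 12 x (m(2H) - m(1H)) = 12.0753 Da
#' for every attachment form.
#'
#' @param form `"light"` or `"heavy"`.
#' @param attachment `"cross-link"`, `"dead-end"` or `"loop"`.
#' @return Neutral mass delta in Da.
#' @export
#' @examples
#' linker_mass_delta("light", "cross-link")                     # 138.0681
#' linker_mass_delta("heavy", "dead-end") -
#'   linker_mass_delta("light", "dead-end")                     # 12.0753
linker_mass_delta <- function(form = c("light", "heavy"),
                              attachment = c("cross-link", "dead-end", "loop")) {
  if (!is.character(form) || !all(form %in% c("light", "heavy")))
    stop("unknown linker form: ", paste(setdiff(form, c("light", "heavy")), collapse = ", "))
  if (!is.character(attachment) ||
      !all(attachment %in% c("cross-link", "dead-end", "loop")))
    stop("unknown linker attachment: ",
         paste(setdiff(attachment, c("cross-link", "dead-end", "loop")), collapse = ", "))
  form <- match.arg(form)
  attachment <- match.arg(attachment)
  base <- switch(attachment,
    "cross-link" = .BS3_BRIDGE_LIGHT,
    "dead-end"   = .BS3_BRIDGE_LIGHT + .WATER,
    "loop"       = .BS3_BRIDGE_LIGHT
  )
  base + if (form == "heavy") .BS3_HEAVY_SHIFT else 0
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus water, plus any modification deltas and an
#' optional linker contribution.
#'
#' @param sequence Peptide sequence (standard one-letter codes).
#' @param mod_masses Numeric vector of modification mass deltas in Da
#'   (positions are irrelevant for the total mass); default none.
#' @param linker_contrib Linker mass delta carried by this peptide, Da.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' peptide_neutral_mass("G")  # 75.0320
peptide_neutral_mass <- function(sequence, mod_masses = numeric(0),
                                 linker_contrib = 0) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- .AA_MONO[aa]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop(sprintf("unknown residue '%s' at position %d of '%s'",
                 aa[bad], bad, sequence))
  }
  sum(m) + .WATER + sum(mod_masses) + linker_contrib
}

#' Convert a neutral mass to m/z and back
#'
#' @param neutral_mass Neutral monoisotopic mass, Da.
#' @param z Positive integer charge.
#' @return `mass_to_mz`: m/z of the protonated species; `mz_to_mass`:
#'   the neutral mass.
#' @export
#' @examples
#' mass_to_mz(2388.329, 4)  # 598.0895
mass_to_mz <- function(neutral_mass, z) {
  if (any(z < 1) || any(z != as.integer(z)))
    stop("charge z must be a positive integer")
  (neutral_mass + z * .PROTON) / z
}

#' @rdname mass_to_mz
#' @param mz Observed m/z.
#' @export
mz_to_mass <- function(mz, z) {
  if (any(z < 1) || any(z != as.integer(z)))
    stop("charge z must be a positive integer")
  mz * z - z * .PROTON
}
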