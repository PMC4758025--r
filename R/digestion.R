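# Protein database handling and in-silico tryptic digestion.

#' Read a protein database from FASTA
#'
#' @param path FASTA file.
#' @param decoy_prefix Identifier prefix marking decoy entries.
#' @return A data frame with columns `id`, `description`, `sequence`,
#'   `is_decoy`.
#' @export
read_fasta <- function(path, decoy_prefix = "REV_") {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no sequences in FASTA file: ", path)
  nm <- names(aa)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  db <- data.frame(
    id = id, description = desc,
    sequence = toupper(as.character(aa)),
    is_decoy = startsWith(id, decoy_prefix),
    stringsAsFactors = FALSE
  )
  validate_protein_db(db)
  db
}

#' Write a protein database to FASTA
#'
#' @param db Protein database data frame (`id`, `description`, `sequence`).
#' @param path Output file.
#' @export
write_fasta <- function(db, path) {
  validate_protein_db(db)
  hdr <- ifelse(nzchar(db$description),
                paste(db$id, db$description), db$id)
  aa <- Biostrings::AAStringSet(db$sequence)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

validate_protein_db <- function(db) {
  stopifnot(is.data.frame(db),
            all(c("id", "sequence") %in% names(db)))
  if (anyDuplicated(db$id)) stop("duplicate protein ids in database")
  if (any(!nzchar(db$sequence))) stop("empty protein sequence in database")
  if (any(grepl("[^A-Z]", db$sequence)))
    stop("protein sequences must be uppercase residue letters")
  invisible(db)
}

#' Build a reversed-sequence decoy database
#'
#' Every sequence is reversed and ids are prefixed with a decoy marker.
#' Applying the operation to a decoy database restores the original
#' sequences (involution). Entries whose reversal equals the original
#' (palindromic sequences) are flagged with a warning but kept.
#'
#' @param db Protein database data frame.
#' @param decoy_prefix Prefix marking decoy ids.
#' @return Decoy database data frame with `is_decoy` toggled.
#' @export
reverse_decoy <- function(db, decoy_prefix = "REV_") {
  validate_protein_db(db)
  rev_seq <- vapply(strsplit(db$sequence, "", fixed = TRUE),
                    function(x) paste(rev(x), collapse = ""), character(1))
  pal <- rev_seq == db$sequence
  if (any(pal))
    warning("decoy identical to target for: ",
            paste(db$id[pal], collapse = ", "))
  already <- startsWith(db$id, decoy_prefix)
  out <- data.frame(
    id = ifelse(already,
                substring(db$id, nchar(decoy_prefix) + 1L),
                paste0(decoy_prefix, db$id)),
    description = db$description,
    sequence = rev_seq,
    is_decoy = !already,
    stringsAsFactors = FALSE
  )
  out
}

# Trypsin cleavage site positions: after K or R, optionally blocked by a
# following proline. Returns integer positions i such that cleavage
# occurs between i and i+1 (never after the last residue).
cleavage_sites <- function(sequence, proline_rule = TRUE) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  if (n < 2L) return(integer(0))
  pos <- which(aa[-n] %in% c("K", "R"))
  if (proline_rule && length(pos))
    pos <- pos[aa[pos + 1L] != "P"]
  pos
}

#' In-silico tryptic digestion of one protein
#'
#' Enumerates every peptide bounded by tryptic cleavage sites (or the
#' protein ends) whose internal missed-cleavage counts satisfy the
#' per-residue-type limits, mirroring a "K:3, R:1" style setting.
#' Cleavage occurs C-terminal to K and R; by default no cleavage occurs
#' when the following residue is proline.
#'
#' @param sequence Protein sequence.
#' @param max_missed_K,max_missed_R Maximum internal missed cleavages at
#'   lysine and arginine respectively.
#' @param proline_rule Suppress cleavage before proline (default TRUE).
#' @param protein_id Identifier carried into the peptide table.
#' @param is_decoy Decoy flag carried into the peptide table.
#' @return Data frame of peptides: `protein_id`, `sequence`, `start`,
#'   `end`, `protein_length`, `is_protein_nterm`, `missed_K`,
#'   `missed_R`, `is_decoy`, `n_mox`, `mox_pos` (list column),
#'   `mass` (neutral monoisotopic, Da, including modifications).
#' @export
#' @examples
#' digest("AKRG")$sequence
digest <- function(sequence, max_missed_K = 3L, max_missed_R = 1L,
                   proline_rule = TRUE, protein_id = "protein",
                   is_decoy = FALSE) {
  stopifnot(max_missed_K >= 0L, max_missed_R >= 0L)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("empty protein sequence")
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  sites <- cleavage_sites(sequence, proline_rule)
  bounds <- c(0L, sites, n)
  nb <- length(bounds)
  rows <- vector("list", nb * (nb - 1L) / 2L)
  k <- 0L
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):nb) {
      internal <- bounds[(i + 1L):(j - 1L)]
      if (i + 1L > j - 1L) internal <- integer(0)
      mk <- sum(aa[internal] == "K")
      mr <- sum(aa[internal] == "R")
      if (mk > max_missed_K) next
      if (mr > max_missed_R) break  # more internal sites only add more
      k <- k + 1L
      rows[[k]] <- c(start = bounds[i] + 1L, end = bounds[j],
                     missed_K = mk, missed_R = mr)
    }
  }
  rows <- rows[seq_len(k)]
  m <- do.call(rbind, rows)
  pep <- data.frame(
    protein_id = protein_id,
    sequence = substring(sequence, m[, "start"], m[, "end"]),
    start = m[, "start"], end = m[, "end"],
    protein_length = n,
    is_protein_nterm = m[, "start"] == 1L,
    missed_K = m[, "missed_K"], missed_R = m[, "missed_R"],
    is_decoy = is_decoy,
    stringsAsFactors = FALSE
  )
  pep$n_mox <- 0L
  pep$mox_pos <- replicate(nrow(pep), integer(0), simplify = FALSE)
  pep$mass <- vapply(pep$sequence, peptide_neutral_mass, numeric(1),
                     USE.NAMES = FALSE)
  pep
}

#' Enumerate variable methionine-oxidation forms
#'
#' Expands each peptide into all modification states with up to
#' `max_mox` oxidized methionines (+15.9949 Da per site), the only
#' variable modification considered.
#'
#' @param peptides Peptide table as returned by [digest()].
#' @param max_mox Maximum number of oxidized methionines per peptide.
#' @return Expanded peptide table; `n_mox` and `mox_pos` describe the
#'   modification state and `mass` includes it.
#' @export
enumerate_modified_forms <- function(peptides, max_mox = 2L) {
  stopifnot(max_mox >= 0L)
  out <- vector("list", nrow(peptides))
  for (r in seq_len(nrow(peptides))) {
    p <- peptides[r, , drop = FALSE]
    mpos <- which(strsplit(p$sequence, "", fixed = TRUE)[[1]] == "M")
    forms <- list(integer(0))
    if (length(mpos) && max_mox > 0L) {
      for (sz in seq_len(min(max_mox, length(mpos)))) {
        cmb <- utils::combn(mpos, sz, simplify = FALSE)
        forms <- c(forms, cmb)
      }
    }
    reps <- p[rep(1L, length(forms)), , drop = FALSE]
    reps$n_mox <- vapply(forms, length, integer(1))
    reps$mox_pos <- forms
    reps$mass <- p$mass + reps$n_mox * .MOX
    out[[r]] <- reps
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Digest a whole protein database
#'
#' Tryptic digestion of every entry, methionine-oxidation enumeration,
#' and the configured peptide mass window applied after modification
#' enumeration.
#'
#' @param db Protein database data frame.
#' @param max_missed_K,max_missed_R,proline_rule See [digest()].
#' @param max_mox See [enumerate_modified_forms()].
#' @param mass_min,mass_max Peptide neutral mass window in Da.
#' @return Peptide table over the whole database.
#' @export
digest_db <- function(db, max_missed_K = 3L, max_missed_R = 1L,
                      proline_rule = TRUE, max_mox = 2L,
                      mass_min = 200, mass_max = 5000) {
  validate_protein_db(db)
  peps <- do.call(rbind, lapply(seq_len(nrow(db)), function(i) {
    digest(db$sequence[i], max_missed_K, max_missed_R, proline_rule,
           protein_id = db$id[i], is_decoy = db$is_decoy[i])
  }))
  peps <- enumerate_modified_forms(peps, max_mox)
  peps <- peps[peps$mass >= mass_min & peps$mass <= mass_max, , drop = FALSE]
  rownames(peps) <- NULL
  peps
}
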