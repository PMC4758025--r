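# Light/heavy isotope-pair validation: the workflow's core filter.
# A cross-link identification is accepted only when (1) it is found in
# both the light (H12) and heavy (D12) linker form, (2) the two
# precursors co-elute, and (3) their fragment-ion patterns agree.

.assignment_key <- function(psms) {
  paste(psms$alpha_seq, psms$site_a,
        ifelse(is.na(psms$beta_seq), "", psms$beta_seq),
        ifelse(is.na(psms$site_b), "", psms$site_b),
        psms$alpha_mox, ifelse(is.na(psms$beta_mox), "", psms$beta_mox),
        psms$xl_type, sep = "|")
}

#' Pair light and heavy PSMs (criteria 1 and 2)
#'
#' Pairs PSMs from the light- and heavy-form searches that carry the
#' identical peptide/site/modification assignment and whose observed
#' precursor mass difference (heavy minus light) lies within
#' `mass_tol_ppm` (of the light precursor) of the 12.0753 Da
#' twelve-deuterium shift. Pairing is 1:1 greedy, preferring co-eluting
#' pairs, then larger score sums, ties broken by smaller retention-time
#' difference. The co-elution criterion `|dRT| <= rt_tol_min` is
#' evaluated and recorded; pairs failing it are kept (and later
#' rejected) so the audit trail shows which criterion failed.
#'
#' @param light_psms,heavy_psms PSM tables from [search_spectra()]
#'   restricted to one linker form each.
#' @param mass_tol_ppm Tolerance on the isotope shift, ppm of the light
#'   precursor mass (default 5).
#' @param rt_tol_min Co-elution tolerance, minutes (default 0.5).
#' @param shift Expected heavy-minus-light precursor shift, Da
#'   (negate it to swap the roles of the two runs).
#' @return A list with `pairs` (one row per matched pair, criteria
#'   flags `dual_identification` and `co_elution` set) and `unpaired`
#'   (PSMs with no partner, with the missing-partner reason).
#' @export
find_pairs <- function(light_psms, heavy_psms, mass_tol_ppm = 5,
                       rt_tol_min = 0.5, shift = .BS3_HEAVY_SHIFT) {
  empty_pairs <- data.frame()
  if (is.null(light_psms) || is.null(heavy_psms) ||
      !nrow(light_psms) || !nrow(heavy_psms)) {
    un <- rbind(
      if (!is.null(light_psms) && nrow(light_psms))
        cbind(light_psms[, setdiff(names(light_psms), "annotations")],
              reason = "no heavy partner"),
      if (!is.null(heavy_psms) && nrow(heavy_psms))
        cbind(heavy_psms[, setdiff(names(heavy_psms), "annotations")],
              reason = "no light partner")
    )
    return(list(pairs = empty_pairs, unpaired = un))
  }
  lk <- .assignment_key(light_psms)
  hk <- .assignment_key(heavy_psms)
  cand <- list()
  for (i in seq_len(nrow(light_psms))) {
    js <- which(hk == lk[i])
    for (j in js) {
      dm <- heavy_psms$precursor_obs[j] - light_psms$precursor_obs[i]
      err_ppm <- (dm - shift) / light_psms$precursor_obs[i] * 1e6
      if (abs(err_ppm) > mass_tol_ppm) next
      drt <- heavy_psms$rt[j] - light_psms$rt[i]
      cand[[length(cand) + 1L]] <- data.frame(
        li = i, hi = j,
        delta_mass = dm, delta_mass_error_ppm = err_ppm,
        delta_rt = drt,
        co_elution = abs(drt) <= rt_tol_min,
        score_sum = light_psms$score[i] + heavy_psms$score[j]
      )
    }
  }
  if (!length(cand)) {
    un <- rbind(
      cbind(light_psms[, setdiff(names(light_psms), "annotations")],
            reason = "no heavy partner"),
      cbind(heavy_psms[, setdiff(names(heavy_psms), "annotations")],
            reason = "no light partner")
    )
    return(list(pairs = empty_pairs, unpaired = un))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$co_elution, -cand$score_sum, abs(cand$delta_rt)), ,
               drop = FALSE]
  used_l <- logical(nrow(light_psms)); used_h <- logical(nrow(heavy_psms))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$li[r]; j <- cand$hi[r]
    if (!used_l[i] && !used_h[j]) {
      keep[r] <- TRUE; used_l[i] <- TRUE; used_h[j] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]

  carry <- c("xl_type", "alpha_protein", "alpha_seq", "alpha_start",
             "alpha_end", "alpha_protein_length", "alpha_mox", "site_a",
             "beta_protein", "beta_seq", "beta_start", "beta_end",
             "beta_protein_length", "beta_mox", "site_b")
  pairs <- cbind(
    data.frame(light_scan = light_psms$scan_id[cand$li],
               heavy_scan = heavy_psms$scan_id[cand$hi],
               stringsAsFactors = FALSE),
    light_psms[cand$li, carry],
    data.frame(
      light_score = light_psms$score[cand$li],
      heavy_score = heavy_psms$score[cand$hi],
      light_rt = light_psms$rt[cand$li],
      heavy_rt = heavy_psms$rt[cand$hi],
      delta_mass = cand$delta_mass,
      delta_mass_error_ppm = cand$delta_mass_error_ppm,
      delta_rt = cand$delta_rt,
      is_decoy = light_psms$is_decoy[cand$li] | heavy_psms$is_decoy[cand$hi],
      trypsin_ok = light_psms$trypsin_ok[cand$li] &
        heavy_psms$trypsin_ok[cand$hi],
      dual_identification = TRUE,
      co_elution = cand$co_elution
    )
  )
  pairs$light_annotations <- light_psms$annotations[cand$li]
  pairs$heavy_annotations <- heavy_psms$annotations[cand$hi]
  rownames(pairs) <- NULL

  un <- rbind(
    if (any(!used_l))
      cbind(light_psms[!used_l, setdiff(names(light_psms), "annotations")],
            reason = "no heavy partner"),
    if (any(!used_h))
      cbind(heavy_psms[!used_h, setdiff(names(heavy_psms), "annotations")],
            reason = "no light partner")
  )
  list(pairs = pairs, unpaired = un)
}

#' Fragment-pattern similarity of a light/heavy PSM pair
#'
#' Jaccard similarity of the matched-fragment label sets (series, index,
#' source peptide, charge). Labels matched in both spectra must also be
#' mass-consistent - the observed m/z difference must equal 0 for
#' linker-free ions or 12.0753/z for linker-containing ions, within
#' `mz_tol` - otherwise the label is dropped from the intersection (but
#' stays in the union). The comparison is label-based, so
#' linker-containing fragments are comparable despite their mass shift.
#'
#' @param light_ann,heavy_ann Matched-fragment tables (the
#'   `annotations` entries of a PSM), with columns `label`, `charge`,
#'   `contains_linker`, `peak_mz`.
#' @param mz_tol Tolerance on the per-fragment shift consistency, Da.
#' @param shift Expected heavy-minus-light shift on linker-containing
#'   singly charged ions, Da.
#' @return A fraction in \[0, 1\]; 0 with a warning when both
#'   annotation sets are empty.
#' @export
pattern_similarity <- function(light_ann, heavy_ann, mz_tol = 1.0,
                               shift = .BS3_HEAVY_SHIFT) {
  la <- light_ann$label; ha <- heavy_ann$label
  uni <- union(la, ha)
  if (!length(uni)) {
    warning("both PSMs unannotated; similarity 0")
    return(0)
  }
  inter <- intersect(la, ha)
  if (length(inter)) {
    il <- match(inter, la); ih <- match(inter, ha)
    expected <- ifelse(light_ann$contains_linker[il],
                       shift / light_ann$charge[il], 0)
    obs <- heavy_ann$peak_mz[ih] - light_ann$peak_mz[il]
    inter <- inter[abs(obs - expected) <= mz_tol]
  }
  length(inter) / length(uni)
}

#' Apply the third criterion and set the verdict
#'
#' Computes the fragment-pattern similarity for each pair from
#' [find_pairs()], sets the `pattern_similar` flag
#' (`similarity >= similarity_min`) and the final verdict: `validated`
#' iff all three criteria hold. A `reason` column records the first
#' failing criterion.
#'
#' @param pairs The `pairs` table from [find_pairs()].
#' @param similarity_min Minimum Jaccard similarity (default 0.6).
#' @param mz_tol,shift See [pattern_similarity()].
#' @return The table with `pattern_similarity`, `pattern_similar`,
#'   `verdict` and `reason` columns appended.
#' @export
validate_pairs <- function(pairs, similarity_min = 0.6, mz_tol = 1.0,
                           shift = .BS3_HEAVY_SHIFT) {
  if (!nrow(pairs)) {
    pairs$pattern_similarity <- numeric(0)
    pairs$pattern_similar <- logical(0)
    pairs$verdict <- character(0)
    pairs$reason <- character(0)
    return(pairs)
  }
  sim <- vapply(seq_len(nrow(pairs)), function(r) {
    pattern_similarity(pairs$light_annotations[[r]],
                       pairs$heavy_annotations[[r]], mz_tol, shift)
  }, numeric(1))
  pairs$pattern_similarity <- sim
  pairs$pattern_similar <- sim >= similarity_min
  ok <- pairs$dual_identification & pairs$co_elution & pairs$pattern_similar
  pairs$verdict <- ifelse(ok, "validated", "rejected")
  pairs$reason <- ifelse(ok, "",
    ifelse(!pairs$dual_identification, "dual_identification",
      ifelse(!pairs$co_elution, "co_elution", "pattern_similarity")))
  pairs
}

#' Validate cross-links from a mixed PSM table
#'
#' Convenience wrapper: splits PSMs by linker form, pairs them,
#' evaluates all three criteria and returns the validated cross-link
#' table plus the unpaired remainder.
#'
#' @param psms PSM table from [search_spectra()] (both forms).
#' @param mass_tol_ppm,rt_tol_min See [find_pairs()].
#' @param similarity_min,mz_tol See [validate_pairs()].
#' @export
validate_crosslinks <- function(psms, mass_tol_ppm = 5, rt_tol_min = 0.5,
                                similarity_min = 0.6, mz_tol = 1.0) {
  light <- psms[psms$form == "light", , drop = FALSE]
  heavy <- psms[psms$form == "heavy", , drop = FALSE]
  fp <- find_pairs(light, heavy, mass_tol_ppm, rt_tol_min)
  pairs <- validate_pairs(fp$pairs, similarity_min, mz_tol)
  list(pairs = pairs, unpaired = fp$unpaired)
}

# protein residue position of a link site (0 = protein N-terminus)
.protein_site <- function(start, site) {
  ifelse(is.na(site), NA_integer_, ifelse(site == 0L, 0L, start + site - 1L))
}

#' Collapse validated peptide pairs to unique residue-pair cross-links
#'
#' Several peptide identifications (missed cleavages, methionine
#' oxidation states, repeated elution) can carry the same cross-link;
#' they are grouped by the (protein, residue position) pair, with the
#' protein N-terminus recorded as position 0. Pairs are canonically
#' ordered.
#'
#' @param pairs Validated pair table ([validate_pairs()]); only rows
#'   with verdict `"validated"` are used.
#' @return One row per unique cross-link: proteins, residue positions,
#'   `xl_type`, supporting peptide-pair count and best scores.
#' @export
collapse_links <- function(pairs) {
  v <- pairs[pairs$verdict == "validated", , drop = FALSE]
  if (!nrow(v))
    return(data.frame(protein1 = character(0), site1 = integer(0),
                      protein2 = character(0), site2 = integer(0),
                      xl_type = character(0), n_pairs = integer(0),
                      best_light_score = numeric(0),
                      best_heavy_score = numeric(0),
                      stringsAsFactors = FALSE))
  p1 <- v$alpha_protein
  s1 <- .protein_site(v$alpha_start, v$site_a)
  p2 <- ifelse(v$xl_type %in% c("loop", "dead-end"),
               v$alpha_protein, v$beta_protein)
  s2 <- ifelse(v$xl_type == "loop",
               .protein_site(v$alpha_start, v$site_b),
               ifelse(v$xl_type == "dead-end", NA_integer_,
                      .protein_site(v$beta_start, v$site_b)))
  flip <- !is.na(s2) & (p2 < p1 | (p2 == p1 & s2 < s1))
  tmp_p <- p1[flip]; tmp_s <- s1[flip]
  p1[flip] <- p2[flip]; s1[flip] <- s2[flip]
  p2[flip] <- tmp_p; s2[flip] <- tmp_s
  key <- paste(p1, s1, p2, s2, v$xl_type, sep = "|")
  agg <- split(seq_len(nrow(v)), key)
  out <- do.call(rbind, lapply(agg, function(ix) {
    data.frame(protein1 = p1[ix[1]], site1 = s1[ix[1]],
               protein2 = p2[ix[1]], site2 = s2[ix[1]],
               xl_type = v$xl_type[ix[1]],
               n_pairs = length(ix),
               best_light_score = max(v$light_score[ix]),
               best_heavy_score = max(v$heavy_score[ix]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$protein1, out$site1, out$protein2, out$site2), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
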