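# Cross-linked peptide search: candidate enumeration against observed
# precursor masses, theoretical b/y fragment generation, spectrum
# matching and scoring, and decoy-based FDR estimation.

#' Precompute the candidate mass index for a peptide table
#'
#' Builds sorted mass tables for single-peptide forms (dead-end, loop)
#' and all viable two-peptide combinations, so that repeated precursor
#' queries are binary searches. Site viability follows the linker's two
#' reactive-site classes: site 1 is a lysine or the protein N-terminus,
#' site 2 additionally admits S, T and Y.
#'
#' @param peptides Peptide table from [digest_db()].
#' @param linker A [bs3_linker()] specification.
#' @return An opaque index object consumed by [enumerate_candidates()].
#' @export
build_xl_index <- function(peptides, linker = bs3_linker()) {
  n <- nrow(peptides)
  seqs <- strsplit(peptides$sequence, "", fixed = TRUE)
  k_pos <- lapply(seqs, function(a) which(a == "K"))
  sty_pos <- lapply(seqs, function(a) which(a %in% c("S", "T", "Y")))
  nterm <- peptides$is_protein_nterm
  sites1 <- lapply(seq_len(n), function(i)
    c(if (nterm[i]) 0L, k_pos[[i]]))
  sites2 <- lapply(seq_len(n), function(i)
    c(if (nterm[i]) 0L, sort(c(k_pos[[i]], sty_pos[[i]]))))
  n1 <- lengths(sites1); n2 <- lengths(sites2)

  # two-peptide pairs: viable if one peptide offers a class-1 site and
  # the other a class-2 site
  elig <- which(n1 > 0L | n2 > 0L)
  pair_i <- pair_j <- integer(0)
  if (length(elig) >= 1L) {
    grid <- expand.grid(a = elig, b = elig)
    grid <- grid[grid$a <= grid$b, , drop = FALSE]
    ok <- (n1[grid$a] > 0L & n2[grid$b] > 0L) |
          (n2[grid$a] > 0L & n1[grid$b] > 0L)
    pair_i <- grid$a[ok]; pair_j <- grid$b[ok]
  }
  pair_mass <- peptides$mass[pair_i] + peptides$mass[pair_j]
  o <- order(pair_mass)

  loop_ok <- vapply(seq_len(n), function(i) {
    s1 <- sites1[[i]]; s2 <- sites2[[i]]
    length(s1) > 0L && length(s2) > 0L &&
      length(unique(c(s1, s2))) >= 2L
  }, logical(1))

  list(
    peptides = peptides,
    linker = linker,
    sites1 = sites1, sites2 = sites2,
    deadend_idx = which(n1 > 0L),
    loop_idx = which(loop_ok),
    pair_i = pair_i[o], pair_j = pair_j[o], pair_mass = pair_mass[o]
  )
}

# window lookup in a sorted vector
.in_window <- function(sorted, lo, hi) {
  if (!length(sorted)) return(integer(0))
  a <- findInterval(lo, sorted) + 1L
  b <- findInterval(hi, sorted)
  if (a > b) integer(0) else a:b
}

#' Enumerate cross-link candidates for one precursor mass
#'
#' All single-peptide (dead-end, loop) and two-peptide candidates whose
#' computed neutral mass lies within a ppm tolerance of the query, for
#' light and heavy linker forms. Pairs are reported in canonical
#' orientation: the alpha peptide is the longer one (ties broken
#' lexicographically).
#'
#' @param peptides Peptide table, or `NULL` when `index` is supplied.
#' @param precursor_mass Observed neutral precursor mass, Da.
#' @param tol_ppm Precursor tolerance in ppm (default 3.0).
#' @param linker A [bs3_linker()].
#' @param forms Linker forms to enumerate.
#' @param index Optional precomputed [build_xl_index()] result.
#' @return Data frame of candidates: `alpha`, `beta` (row indices into
#'   the peptide table, `beta` `NA` for single-peptide forms), `site_a`,
#'   `site_b` (1-based positions, 0 for the protein N-terminus), `form`,
#'   `xl_type`, `precursor_mass` (theoretical), `error_ppm`.
#' @export
enumerate_candidates <- function(peptides, precursor_mass, tol_ppm = 3.0,
                                 linker = bs3_linker(),
                                 forms = c("light", "heavy"),
                                 index = NULL) {
  if (is.null(index)) index <- build_xl_index(peptides, linker)
  peptides <- index$peptides
  tol <- tol_ppm * 1e-6 * precursor_mass
  out <- list()

  add <- function(alpha, beta, site_a, site_b, form, xl_type, mass) {
    out[[length(out) + 1L]] <<- data.frame(
      alpha = alpha, beta = beta, site_a = site_a, site_b = site_b,
      form = form, xl_type = xl_type, precursor_mass = mass,
      error_ppm = (precursor_mass - mass) / mass * 1e6,
      stringsAsFactors = FALSE
    )
  }

  for (form in forms) {
    bridge <- linker_mass_delta(form, "cross-link")
    deadend <- linker_mass_delta(form, "dead-end")

    # dead-end: one class-1 site, other linker arm hydrolyzed
    for (i in index$deadend_idx) {
      m <- peptides$mass[i] + deadend
      if (abs(m - precursor_mass) <= tol)
        for (s in index$sites1[[i]])
          add(i, NA_integer_, s, NA_integer_, form, "dead-end", m)
    }
    # intra-peptide loop
    for (i in index$loop_idx) {
      m <- peptides$mass[i] + bridge
      if (abs(m - precursor_mass) <= tol) {
        sp <- unique(do.call(rbind, lapply(index$sites1[[i]], function(s1) {
          s2 <- setdiff(index$sites2[[i]], s1)
          if (length(s2)) cbind(pmin(s1, s2), pmax(s1, s2)) else NULL
        })))
        if (!is.null(sp))
          for (r in seq_len(nrow(sp)))
            add(i, NA_integer_, sp[r, 1], sp[r, 2], form, "loop", m)
      }
    }
    # two-peptide cross-links
    hits <- .in_window(index$pair_mass,
                       precursor_mass - bridge - tol,
                       precursor_mass - bridge + tol)
    for (h in hits) {
      i <- index$pair_i[h]; j <- index$pair_j[h]
      m <- index$pair_mass[h] + bridge
      # canonical orientation: alpha is the longer peptide
      li <- nchar(peptides$sequence[i]); lj <- nchar(peptides$sequence[j])
      swap <- lj > li ||
        (lj == li && peptides$sequence[j] < peptides$sequence[i])
      a <- if (swap) j else i
      b <- if (swap) i else j
      xt <- if (peptides$protein_id[a] == peptides$protein_id[b])
        "intra-protein" else "inter-protein"
      sp <- rbind(
        if (length(index$sites1[[a]]) && length(index$sites2[[b]]))
          expand.grid(sa = index$sites1[[a]], sb = index$sites2[[b]]),
        if (length(index$sites2[[a]]) && length(index$sites1[[b]]))
          expand.grid(sa = index$sites2[[a]], sb = index$sites1[[b]])
      )
      sp <- unique(sp)
      for (r in seq_len(nrow(sp)))
        add(a, b, sp$sa[r], sp$sb[r], form, xt, m)
    }
  }
  if (!length(out))
    return(data.frame(alpha = integer(0), beta = integer(0),
                      site_a = integer(0), site_b = integer(0),
                      form = character(0), xl_type = character(0),
                      precursor_mass = numeric(0), error_ppm = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  unique(res)
}

#' Theoretical b/y fragment ions of a cross-link candidate
#'
#' Fragments spanning the link site carry the linker mass; for
#' two-peptide candidates that includes the entire partner peptide, so
#' the light/heavy forms differ by 12 Da/z exactly on linker-containing
#' ions and not at all on the others. For dead-end candidates the
#' spanning fragments carry the hydrolyzed-linker mass; for loop links,
#' fragments spanning either site carry the bridge.
#'
#' @param alpha_seq,beta_seq Peptide sequences (`beta_seq = NULL` for
#'   single-peptide candidates).
#' @param site_a,site_b Link sites (1-based, 0 = protein N-terminus; for
#'   a loop both sites are on the alpha peptide).
#' @param form `"light"` or `"heavy"`.
#' @param xl_type One of `"inter-protein"`, `"intra-protein"`, `"loop"`,
#'   `"dead-end"`.
#' @param alpha_mox,beta_mox Integer positions of oxidized methionines.
#' @param max_charge Fragment charges 1..max_charge are generated.
#' @param mz_range Instrument m/z window; fragments outside are dropped.
#' @param linker A [bs3_linker()].
#' @return Data frame: `series`, `index`, `source`, `contains_linker`,
#'   `charge`, `mz`, `label`.
#' @export
generate_fragments <- function(alpha_seq, site_a, beta_seq = NULL,
                               site_b = NULL, form = "light",
                               xl_type = "inter-protein",
                               alpha_mox = integer(0),
                               beta_mox = integer(0),
                               max_charge = 2L,
                               mz_range = c(300, 2000),
                               linker = bs3_linker()) {
  bridge <- linker_mass_delta(form, "cross-link")
  one_pep <- function(seqstr, mox, sites, extra, source) {
    aa <- strsplit(seqstr, "", fixed = TRUE)[[1]]
    L <- length(aa)
    if (L < 2L) return(NULL)
    res <- .AA_MONO[aa]
    if (length(mox)) res[mox] <- res[mox] + .MOX
    idx <- seq_len(L - 1L)
    b_neutral <- cumsum(res)[idx]
    y_neutral <- cumsum(rev(res))[idx] + .WATER
    spans_b <- rep(FALSE, L - 1L); spans_y <- rep(FALSE, L - 1L)
    for (s in sites) {
      if (s == 0L) spans_b <- spans_b | TRUE
      else {
        spans_b <- spans_b | (idx >= s)
        spans_y <- spans_y | (idx >= L - s + 1L)
      }
    }
    data.frame(
      series = rep(c("b", "y"), each = L - 1L),
      index = c(idx, idx),
      source = source,
      contains_linker = c(spans_b, spans_y),
      neutral = c(b_neutral + spans_b * extra,
                  y_neutral + spans_y * extra),
      stringsAsFactors = FALSE
    )
  }

  if (xl_type == "dead-end") {
    extra <- linker_mass_delta(form, "dead-end")
    fr <- one_pep(alpha_seq, alpha_mox, site_a, extra, "alpha")
  } else if (xl_type == "loop") {
    fr <- one_pep(alpha_seq, alpha_mox, c(site_a, site_b), bridge, "alpha")
  } else {
    if (is.null(beta_seq)) stop("two-peptide candidate needs beta_seq")
    beta_mass <- peptide_neutral_mass(beta_seq, rep(.MOX, length(beta_mox)))
    alpha_mass <- peptide_neutral_mass(alpha_seq, rep(.MOX, length(alpha_mox)))
    fr <- rbind(
      one_pep(alpha_seq, alpha_mox, site_a, bridge + beta_mass, "alpha"),
      one_pep(beta_seq, beta_mox, site_b, bridge + alpha_mass, "beta")
    )
  }
  if (is.null(fr))
    return(data.frame(series = character(0), index = integer(0),
                      source = character(0), contains_linker = logical(0),
                      charge = integer(0), mz = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(max_charge), function(z) {
    d <- fr
    d$charge <- z
    d$mz <- (d$neutral + z * .PROTON) / z
    d
  }))
  out <- out[out$mz >= mz_range[1] & out$mz <= mz_range[2], , drop = FALSE]
  out$neutral <- NULL
  out$label <- sprintf("%s%d%s+%d", out$series, out$index,
                       ifelse(out$source == "alpha", "a", "b"), out$charge)
  rownames(out) <- NULL
  out
}

# Surviving peaks after the S/N noise floor: the floor is the median
# peak intensity times the configured S/N ratio.
.surviving_peaks <- function(spec, snr_min) {
  if (!length(spec$mz)) return(list(mz = numeric(0), intensity = numeric(0)))
  floor_int <- stats::median(spec$intensity) * snr_min
  keep <- spec$intensity >= floor_int
  list(mz = spec$mz[keep], intensity = spec$intensity[keep])
}

#' Match theoretical fragments against a spectrum
#'
#' Peaks below the noise floor (median intensity times `snr_min`) are
#' removed; each theoretical fragment is matched to the nearest
#' surviving peak within `tol_da`. One peak may satisfy several
#' fragments (flagged `ambiguous`); each fragment matches at most one
#' peak.
#'
#' @param spec A [spectrum()].
#' @param frags Fragment table from [generate_fragments()].
#' @param tol_da Fragment m/z tolerance in Da (default 0.8).
#' @param snr_min Signal-to-noise ratio for the noise floor (default 2).
#' @return The matched subset of `frags` with `peak_mz`,
#'   `peak_intensity`, `peak_index` and `ambiguous` columns appended.
#' @export
match_spectrum <- function(spec, frags, tol_da = 0.8, snr_min = 2.0) {
  stopifnot(inherits(spec, "spectrum"))
  pk <- .surviving_peaks(spec, snr_min)
  empty <- cbind(frags[0, , drop = FALSE],
                 peak_mz = numeric(0), peak_intensity = numeric(0),
                 peak_index = integer(0), ambiguous = logical(0))
  if (!length(pk$mz) || !nrow(frags)) return(empty)
  lo <- findInterval(frags$mz, pk$mz)
  cand_lo <- pmax(lo, 1L)
  cand_hi <- pmin(lo + 1L, length(pk$mz))
  d_lo <- abs(frags$mz - pk$mz[cand_lo])
  d_hi <- abs(frags$mz - pk$mz[cand_hi])
  pick <- ifelse(d_lo <= d_hi, cand_lo, cand_hi)
  dist <- pmin(d_lo, d_hi)
  ok <- dist <= tol_da
  if (!any(ok)) return(empty)
  m <- frags[ok, , drop = FALSE]
  m$peak_mz <- pk$mz[pick[ok]]
  m$peak_intensity <- pk$intensity[pick[ok]]
  m$peak_index <- pick[ok]
  m$ambiguous <- duplicated(m$peak_index) | duplicated(m$peak_index, fromLast = TRUE)
  rownames(m) <- NULL
  m
}

#' Score a peptide-spectrum match
#'
#' The score is `-10 log10 P(X >= k)` for `X ~ Binomial(n, p)`, where
#' `k` is the number of matched fragments, `n` the number of theoretical
#' fragments inside the scanned m/z range, and `p` the per-fragment
#' random-match probability `2 * tol_da * n_peaks / span` over the
#' surviving peaks (clamped to (0, 1)), plus an intensity bonus of
#' `20 * matched intensity / total intensity`. Deterministic,
#' non-negative, and monotone in `k` for fixed `n` and `p`.
#'
#' @param matched Output of [match_spectrum()].
#' @param spec The matched [spectrum()].
#' @param frags The full theoretical fragment table.
#' @param tol_da,snr_min Matching parameters (must equal those used for
#'   matching).
#' @return A non-negative score.
#' @export
score_psm <- function(matched, spec, frags, tol_da = 0.8, snr_min = 2.0) {
  n <- nrow(frags)
  if (n == 0L) {
    warning("no theoretical fragments in range; score 0")
    return(0)
  }
  pk <- .surviving_peaks(spec, snr_min)
  npk <- length(pk$mz)
  if (npk == 0L) return(0)
  span <- max(pk$mz) - min(pk$mz)
  if (span <= 0) span <- 2 * tol_da  # single surviving peak
  p <- min(max(2 * tol_da * npk / span, 1e-9), 1 - 1e-9)
  k <- nrow(matched)
  tail_p <- stats::pbinom(k - 1L, n, p, lower.tail = FALSE)
  base <- max(0, -10 * log10(tail_p))
  bonus <- if (k > 0L) {
    20 * sum(pk$intensity[unique(matched$peak_index)]) / sum(pk$intensity)
  } else 0
  base + bonus
}

#' Decoy-based false discovery rate
#'
#' `fdr_at_threshold` estimates the FDR at a score threshold as the
#' number of decoy PSMs at or above the threshold divided by the number
#' of target PSMs at or above it (floored at one). `fdr_threshold`
#' returns the smallest threshold achieving a requested FDR.
#'
#' @param target_scores,decoy_scores Numeric PSM scores from searches of
#'   the target and decoy databases with the same scoring function.
#' @param threshold Score threshold (inclusive).
#' @return `fdr_at_threshold`: a rate in \[0, 1\] (capped at 1).
#' @export
fdr_at_threshold <- function(target_scores, decoy_scores, threshold) {
  nt <- sum(target_scores >= threshold)
  nd <- sum(decoy_scores >= threshold)
  min(1, nd / max(1L, nt))
}

#' @rdname fdr_at_threshold
#' @param fdr_target Requested FDR (default 0.05).
#' @return `fdr_threshold`: a list with `threshold`, `fdr`, `n_target`,
#'   `n_decoy`; `threshold` is `Inf` when no threshold attains the
#'   requested rate.
#' @export
fdr_threshold <- function(target_scores, decoy_scores, fdr_target = 0.05) {
  cand <- sort(unique(target_scores))
  for (t in cand) {
    f <- fdr_at_threshold(target_scores, decoy_scores, t)
    if (f <= fdr_target) {
      return(list(threshold = t, fdr = f,
                  n_target = sum(target_scores >= t),
                  n_decoy = sum(decoy_scores >= t)))
    }
  }
  list(threshold = Inf, fdr = NA_real_, n_target = 0L, n_decoy = 0L)
}

#' Trypsin consistency of a cross-link site
#'
#' Trypsin cannot cleave C-terminal to a linker-modified lysine, so a
#' link site on a peptide's C-terminal lysine contradicts the cleavage
#' that produced the peptide - unless that lysine is the protein
#' C-terminus. Vectorized.
#'
#' @param sequence Peptide sequence(s).
#' @param site Link site (1-based position, 0 = protein N-terminus).
#' @param end Peptide end position in the parent protein.
#' @param protein_length Parent protein length.
#' @return Logical: `TRUE` when consistent, `FALSE` on violation.
#' @export
trypsin_consistent <- function(sequence, site, end, protein_length) {
  mapply(function(sq, s, e, pl) {
    if (is.na(sq) || is.na(s) || s == 0L) return(TRUE)
    if (substring(sq, s, s) != "K") return(TRUE)
    if (s < nchar(sq)) return(TRUE)      # internal: a missed cleavage
    e >= pl                              # C-terminal K: only ok at protein end
  }, sequence, site, end, protein_length, USE.NAMES = FALSE)
}

#' Search a set of MS2 spectra for cross-linked peptides
#'
#' For each spectrum with precursor charge >= 3 (singly and doubly
#' charged precursors are rejected), candidates within the precursor
#' tolerance are enumerated for both linker forms, fragment-matched and
#' scored; the best-scoring candidate per spectrum and linker form is
#' reported as a PSM. A PSM is a decoy hit when either constituent
#' peptide derives from the decoy database.
#'
#' @param spectra List of [spectrum()] objects.
#' @param peptides Peptide table from [digest_db()] (target plus decoy).
#' @param linker A [bs3_linker()].
#' @param tol_ppm Precursor tolerance, ppm.
#' @param tol_da Fragment tolerance, Da.
#' @param snr_min Noise-floor S/N ratio.
#' @param max_charge Maximum fragment charge.
#' @param mz_range Scanned m/z range.
#' @param min_charge Minimum accepted precursor charge.
#' @return PSM data frame (one row per spectrum and form with any
#'   candidate); the `annotations` list column holds the matched
#'   fragment table used for pattern comparison.
#' @export
search_spectra <- function(spectra, peptides, linker = bs3_linker(),
                           tol_ppm = 3.0, tol_da = 0.8, snr_min = 2.0,
                           max_charge = 2L, mz_range = c(300, 2000),
                           min_charge = 3L) {
  index <- build_xl_index(peptides, linker)
  rows <- list()
  for (spec in spectra) {
    if (spec$charge < min_charge) next
    cands <- enumerate_candidates(NULL, spec$precursor_neutral_mass,
                                  tol_ppm = tol_ppm, linker = linker,
                                  index = index)
    if (!nrow(cands)) next
    best <- list()
    for (r in seq_len(nrow(cands))) {
      cn <- cands[r, ]
      a <- cn$alpha; b <- cn$beta
      frags <- generate_fragments(
        alpha_seq = peptides$sequence[a], site_a = cn$site_a,
        beta_seq = if (is.na(b)) NULL else peptides$sequence[b],
        site_b = if (is.na(cn$site_b)) NULL else cn$site_b,
        form = cn$form, xl_type = cn$xl_type,
        alpha_mox = peptides$mox_pos[[a]],
        beta_mox = if (is.na(b)) integer(0) else peptides$mox_pos[[b]],
        max_charge = max_charge, mz_range = mz_range, linker = linker
      )
      if (!nrow(frags)) next
      matched <- match_spectrum(spec, frags, tol_da, snr_min)
      sc <- score_psm(matched, spec, frags, tol_da, snr_min)
      f <- cn$form
      if (is.null(best[[f]]) || sc > best[[f]]$score) {
        best[[f]] <- list(cand = cn, score = sc, matched = matched,
                          n_frags = nrow(frags))
      }
    }
    for (f in names(best)) {
      bb <- best[[f]]
      cn <- bb$cand
      a <- cn$alpha; b <- cn$beta
      two <- !is.na(b)
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = spec$scan_id, rt = spec$rt, charge = spec$charge,
        precursor_obs = spec$precursor_neutral_mass,
        form = f, xl_type = cn$xl_type,
        alpha_protein = peptides$protein_id[a],
        alpha_seq = peptides$sequence[a],
        alpha_start = peptides$start[a], alpha_end = peptides$end[a],
        alpha_protein_length = peptides$protein_length[a],
        alpha_mox = paste(peptides$mox_pos[[a]], collapse = ","),
        site_a = cn$site_a,
        beta_protein = if (two) peptides$protein_id[b] else NA_character_,
        beta_seq = if (two) peptides$sequence[b] else NA_character_,
        beta_start = if (two) peptides$start[b] else NA_integer_,
        beta_end = if (two) peptides$end[b] else NA_integer_,
        beta_protein_length = if (two) peptides$protein_length[b] else NA_integer_,
        beta_mox = if (two) paste(peptides$mox_pos[[b]], collapse = ",") else NA_character_,
        site_b = cn$site_b,
        precursor_theo = cn$precursor_mass,
        precursor_error_ppm = cn$error_ppm,
        score = bb$score, n_matched = nrow(bb$matched),
        n_frags = bb$n_frags,
        is_decoy = peptides$is_decoy[a] || (two && peptides$is_decoy[b]),
        stringsAsFactors = FALSE
      )
      rows[[length(rows)]]$annotations <- list(bb$matched)
    }
  }
  if (!length(rows)) return(NULL)
  psms <- do.call(rbind, rows)
  psms$trypsin_ok <- trypsin_consistent(psms$alpha_seq, psms$site_a,
                                        psms$alpha_end,
                                        psms$alpha_protein_length) &
    ifelse(is.na(psms$beta_seq) | psms$xl_type == "loop" |
             psms$xl_type == "dead-end",
           trypsin_consistent(psms$alpha_seq,
                              ifelse(psms$xl_type == "loop", psms$site_b, NA),
                              psms$alpha_end, psms$alpha_protein_length),
           trypsin_consistent(psms$beta_seq, psms$site_b, psms$beta_end,
                              psms$beta_protein_length))
  rownames(psms) <- NULL
  psms
}
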