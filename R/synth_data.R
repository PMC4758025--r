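# Synthetic fixtures: a toy multi-chain complex with coordinates,
# planted cross-links, and paired light/heavy MS2 spectra, so every
# pipeline stage can be exercised end to end with known ground truth.
# All randomness flows through the single R RNG stream seeded once per
# generator call; the order of draws is fixed and documented inline.

.SYNTH_AA_WEIGHTS <- c(A = 8, G = 7, L = 8, V = 6, E = 6, D = 5, F = 4,
                       N = 4, Q = 4, H = 2, W = 1, I = 5, C = 1,
                       R = 6, M = 4, S = 6, T = 5, Y = 3, P = 4)

#' Generate a toy multi-chain complex
#'
#' Random sequences with a controlled lysine density are laid out as
#' ideal helical CA traces packed on a grid, so inter-chain
#' reactive-atom distances span roughly 5-60 A - both sides of the
#' 35 A cross-linker constraint. A configurable set of chains has its
#' first residues marked unresolved (emulating flexible termini that
#' crystal structures do not resolve): those residues are present in
#' the full model and in SEQRES but carry no ATOM records in the
#' emitted PDB.
#'
#' Draw order under the seed: per chain, lysine positions, then the
#' remaining residues; then the unresolved-chain subset.
#'
#' @param seed RNG seed.
#' @param n_chains Number of chains (grid-packed).
#' @param chain_length Residues per chain.
#' @param k_frac Minimum lysine fraction (default 0.09).
#' @param unresolved_nterm Number of N-terminal residues left
#'   unresolved on affected chains.
#' @param unresolved_chain_frac Fraction of chains whose N-terminus is
#'   unresolved.
#' @return A `toy_complex`: list with `db` (protein database),
#'   `model` (unresolved termini redacted), `model_full` (every residue
#'   resolved - the generator's ground-truth geometry), and
#'   `chain_map` (protein id -> chain id).
#' @export
make_toy_complex <- function(seed = 1, n_chains = 4, chain_length = 40,
                             k_frac = 0.09, unresolved_nterm = 2,
                             unresolved_chain_frac = 0.5) {
  stopifnot(n_chains >= 1, chain_length >= 10)
  set.seed(seed)
  chains <- LETTERS[seq_len(n_chains)]
  seqs <- character(n_chains)
  for (i in seq_len(n_chains)) {
    n_k <- ceiling(k_frac * chain_length)
    kpos <- sample(2:chain_length, n_k)  # keep residue 1 linker-free
    rest <- sample(names(.SYNTH_AA_WEIGHTS),
                   chain_length - n_k, replace = TRUE,
                   prob = .SYNTH_AA_WEIGHTS)
    aa <- character(chain_length)
    aa[kpos] <- "K"
    aa[-kpos] <- rest
    seqs[i] <- paste(aa, collapse = "")
  }
  n_unres <- round(unresolved_chain_frac * n_chains)
  unres_chains <- if (n_unres > 0) sort(sample(chains, n_unres)) else character(0)

  # ideal helical CA traces on a grid: rise 1.5 A, 100 deg/residue,
  # helix radius 2.3 A, chains 18 A apart
  atom_rows <- list()
  for (i in seq_len(n_chains)) {
    cx <- ((i - 1) %% 2) * 18
    cy <- ((i - 1) %/% 2) * 18
    aa <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (r in seq_len(chain_length)) {
      th <- (r - 1) * 100 * pi / 180
      ca <- c(cx + 2.3 * cos(th), cy + 2.3 * sin(th), (r - 1) * 1.5)
      dir_out <- c(cos(th), sin(th), 0)
      b <- 20 + 60 * exp(-min(r - 1, chain_length - r) / 4)
      add <- function(name, element, xyz) {
        atom_rows[[length(atom_rows) + 1L]] <<- data.frame(
          chain = chains[i], resno = r, resname = .aa_three(aa[r]),
          atom = name, element = element,
          x = xyz[1], y = xyz[2], z = xyz[3], b = b,
          stringsAsFactors = FALSE)
      }
      add("N", "N", ca + c(0, 0, -0.6))
      add("CA", "C", ca)
      add("C", "C", ca + c(0, 0, 0.6))
      add("O", "O", ca + 0.6 * dir_out + c(0, 0, 0.9))
      if (!aa[r] %in% c("G")) add("CB", "C", ca + 1.5 * dir_out)
      if (aa[r] == "K") add("NZ", "N", ca + 4.0 * dir_out)
      if (aa[r] == "S") add("OG", "O", ca + 2.4 * dir_out)
      if (aa[r] == "T") add("OG1", "O", ca + 2.4 * dir_out)
      if (aa[r] == "Y") add("OH", "O", ca + 5.0 * dir_out)
    }
  }
  atoms <- do.call(rbind, atom_rows)
  seqres <- as.list(seqs)
  names(seqres) <- chains
  model_full <- structure_model(atoms, seqres)

  redact <- atoms$chain %in% unres_chains & atoms$resno <= unresolved_nterm
  model <- structure_model(atoms[!redact, , drop = FALSE], seqres)

  db <- data.frame(id = paste0("chain", chains),
                   description = paste("synthetic chain", chains),
                   sequence = seqs, is_decoy = FALSE,
                   stringsAsFactors = FALSE)
  structure(list(db = db, model = model, model_full = model_full,
                 chain_map = stats::setNames(chains, db$id),
                 unresolved_chains = unres_chains,
                 seed = seed),
            class = "toy_complex")
}

# smallest tryptic peptide of `sequence` that contains `pos` strictly
# internally (a linked K must not sit on the cleavage boundary) and has
# mass inside the search window; pos 0 = N-terminal peptide. Returns
# c(start, end) or NULL.
.site_peptide <- function(sequence, pos, max_missed_K = 3L,
                          max_missed_R = 1L, mass_min = 250,
                          mass_max = 4500) {
  sites <- cleavage_sites(sequence)
  bounds <- c(0L, sites, nchar(sequence))
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  start_b <- if (pos == 0L) 0L else max(bounds[bounds < pos])
  ends <- bounds[bounds > max(pos, start_b)]
  for (e in ends) {
    start <- start_b + 1L
    internal <- sites[sites > start_b & sites < e]
    mk <- sum(aa[internal] == "K"); mr <- sum(aa[internal] == "R")
    if (mk > max_missed_K || mr > max_missed_R) return(NULL)
    m <- peptide_neutral_mass(substring(sequence, start, e))
    if (m > mass_max) return(NULL)
    if (m >= mass_min && (e - start + 1L) >= 4L) return(c(start, e))
  }
  NULL
}

#' Plant ground-truth cross-links in a toy complex
#'
#' Samples residue-pair cross-links whose solvent-accessible surface
#' distance on the generator's full geometry is at most `max_sas`, with
#' a configurable fraction involving a protein N-terminus (the
#' empirically dominant reactive site class). Every planted site is
#' checked to lie on a usable tryptic peptide so the link is
#' recoverable downstream, and each link occupies a distinct peptide
#' pair so planted links stay mutually distinguishable by mass.
#'
#' Draw order under the seed: candidate pairs are shuffled once, then
#' consumed in order (terminal pairs first).
#'
#' @param tc A [make_toy_complex()] result.
#' @param n_links Number of links to plant.
#' @param max_sas Maximum SAS distance, A (must be positive).
#' @param frac_terminal Fraction of links that must involve an
#'   N-terminus (default 0.9).
#' @param seed RNG seed.
#' @param grid_spacing SAS grid spacing, A.
#' @return A `ground_truth`: list with `complex` and `links` (data
#'   frame: `link_id`, `protein_a`, `chain_a`, `pos_a` (0 = N-term),
#'   `protein_b`, `chain_b`, `pos_b`, `xl_type`, `euclidean`, `sas`).
#' @export
plant_crosslinks <- function(tc, n_links = 15, max_sas = 35,
                             frac_terminal = 0.9, seed = 1,
                             grid_spacing = 1.0) {
  stopifnot(inherits(tc, "toy_complex"))
  if (max_sas <= 0) stop("max_sas must be positive")
  set.seed(seed)
  model <- tc$model_full
  chains <- tc$chain_map
  prot_of <- stats::setNames(names(chains), chains)

  # candidate sites, each pre-checked for a usable tryptic peptide
  site_rows <- list()
  for (i in seq_len(nrow(tc$db))) {
    sq <- tc$db$sequence[i]
    ch <- chains[[tc$db$id[i]]]
    aa <- strsplit(sq, "", fixed = TRUE)[[1]]
    pos1 <- c(0L, which(aa == "K"))                  # class 1: K, N-term
    pos2 <- c(0L, which(aa %in% c("K", "S", "T", "Y")))
    for (p in unique(c(pos1, pos2))) {
      if (is.null(.site_peptide(sq, p))) next
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        protein = tc$db$id[i], chain = ch, pos = p,
        class1 = p %in% pos1, class2 = p %in% pos2,
        is_nterm = p == 0L, stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, site_rows)

  coords <- lapply(seq_len(nrow(sites)), function(i)
    reactive_atom(model, sites$chain[i], sites$pos[i]))
  ok <- vapply(coords, function(x) x$status == "ok", logical(1))
  sites <- sites[ok, , drop = FALSE]
  coords <- coords[ok]

  # all admissible pairs with Euclidean prefilter (SAS >= Euclidean)
  pair_rows <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(sites))) {
      if (j <= i) next
      if (!((sites$class1[i] && sites$class2[j]) ||
              (sites$class2[i] && sites$class1[j]))) next
      if (sites$chain[i] == sites$chain[j] &&
            abs(sites$pos[i] - sites$pos[j]) < 8) next  # avoid loop-scale pairs
      eu <- euclidean_distance(coords[[i]]$xyz, coords[[j]]$xyz)
      if (eu > max_sas) next
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        i = i, j = j, euclidean = eu,
        terminal = sites$is_nterm[i] || sites$is_nterm[j])
    }
  }
  if (!length(pair_rows))
    stop("no eligible site pairs within max_sas; achievable maximum is 0")
  pairs <- do.call(rbind, pair_rows)
  pairs <- pairs[sample(nrow(pairs)), , drop = FALSE]

  n_term <- round(frac_terminal * n_links)
  queue <- rbind(pairs[pairs$terminal, , drop = FALSE],
                 pairs[!pairs$terminal, , drop = FALSE])
  taken <- list()
  used_pep <- character(0)
  n_term_taken <- 0L
  for (r in seq_len(nrow(queue))) {
    if (length(taken) >= n_links) break
    need_term <- n_term_taken < n_term
    if (!queue$terminal[r] && need_term &&
          (n_links - length(taken)) <= (n_term - n_term_taken)) next
    i <- queue$i[r]; j <- queue$j[r]
    # keep peptide assignments unique so links map to distinct spectra
    pep_i <- paste(sites$protein[i],
                   paste(.site_peptide(tc$db$sequence[match(sites$protein[i], tc$db$id)],
                                       sites$pos[i]), collapse = "-"))
    pep_j <- paste(sites$protein[j],
                   paste(.site_peptide(tc$db$sequence[match(sites$protein[j], tc$db$id)],
                                       sites$pos[j]), collapse = "-"))
    if (pep_i == pep_j) next
    pair_key <- paste(sort(c(pep_i, pep_j)), collapse = "||")
    if (pair_key %in% used_pep) next
    sd <- sas_distance(model, coords[[i]], coords[[j]],
                       grid_spacing = grid_spacing,
                       max_dist = max_sas * 1.05)
    if (sd$status != "ok" || sd$distance > max_sas) next
    taken[[length(taken) + 1L]] <- data.frame(
      link_id = length(taken) + 1L,
      protein_a = sites$protein[i], chain_a = sites$chain[i],
      pos_a = sites$pos[i],
      protein_b = sites$protein[j], chain_b = sites$chain[j],
      pos_b = sites$pos[j],
      xl_type = if (sites$chain[i] == sites$chain[j])
        "intra-protein" else "inter-protein",
      euclidean = queue$euclidean[r], sas = sd$distance,
      stringsAsFactors = FALSE)
    used_pep <- c(used_pep, pair_key)
    if (queue$terminal[r]) n_term_taken <- n_term_taken + 1L
  }
  if (length(taken) < n_links)
    stop("only ", length(taken), " eligible cross-links available (",
         n_links, " requested)")
  structure(list(complex = tc, links = do.call(rbind, taken)),
            class = "ground_truth")
}

# deterministic retention-time base from the peptide sequences: the
# isotopologues share it exactly
.rt_base <- function(key) {
  20 + (sum(utf8ToInt(key)) %% 1600) / 10
}

#' Simulate paired light/heavy MS2 spectra for planted cross-links
#'
#' For every ground-truth link a light and a heavy spectrum are emitted
#' at precursor charge >= 3: theoretical b/y peaks are each retained
#' with probability `fragment_efficiency`, with log-normal intensities,
#' plus uniform noise peaks. Fragment retention and base intensity are
#' drawn once per link and shared between the two forms (isotopologues
#' fragment identically - small multiplicative jitter is applied per
#' form), the pair shares its retention time up to `rt_jitter_sd`, and
#' the precursor masses differ by exactly 12.0753 Da.
#'
#' Draw order under the seed: per link (in `link_id` order): precursor
#' charge; light and heavy RT jitter; fragment retention; fragment base
#' intensities; light intensity jitter; heavy intensity jitter; light
#' noise peaks (m/z then intensity); heavy noise peaks; the
#' missing-form uniform. Then the noise-only spectra in order.
#'
#' @param truth A [plant_crosslinks()] result.
#' @param fragment_efficiency Probability a theoretical fragment is
#'   observed (default 0.7).
#' @param noise_peaks Uniform noise peaks per spectrum (default 30).
#' @param rt_jitter_sd Retention-time jitter SD, minutes (default 0.05).
#' @param missing_form_prob Probability the heavy spectrum of a link is
#'   suppressed (default 0; used to probe the dual-identification
#'   criterion).
#' @param n_noise_spectra Additional noise-only spectra with random
#'   precursors (default 0).
#' @param precursor_charges Charges sampled for precursors (>= 3).
#' @param max_fragment_charge Fragment charges 1..this are generated.
#' @param mz_range Instrument m/z range.
#' @param seed RNG seed.
#' @param linker A [bs3_linker()].
#' @return A list: `spectra` (list of [spectrum()]), `scan_truth`
#'   (data frame scan_id -> link_id/form), `truth` (the input ground
#'   truth with peptide columns appended).
#' @export
simulate_spectra <- function(truth, fragment_efficiency = 0.7,
                             noise_peaks = 30, rt_jitter_sd = 0.05,
                             missing_form_prob = 0,
                             n_noise_spectra = 0,
                             precursor_charges = c(3L, 4L),
                             max_fragment_charge = 2L,
                             mz_range = c(300, 2000),
                             seed = 1, linker = bs3_linker()) {
  stopifnot(inherits(truth, "ground_truth"), all(precursor_charges >= 3L))
  set.seed(seed)
  tc <- truth$complex
  links <- truth$links
  spectra <- list()
  scan_rows <- list()
  pep_cols <- list()

  for (r in seq_len(nrow(links))) {
    sq_a <- tc$db$sequence[match(links$protein_a[r], tc$db$id)]
    sq_b <- tc$db$sequence[match(links$protein_b[r], tc$db$id)]
    se_a <- .site_peptide(sq_a, links$pos_a[r])
    se_b <- .site_peptide(sq_b, links$pos_b[r])
    pep_a <- substring(sq_a, se_a[1], se_a[2])
    pep_b <- substring(sq_b, se_b[1], se_b[2])
    site_a <- if (links$pos_a[r] == 0L) 0L else links$pos_a[r] - se_a[1] + 1L
    site_b <- if (links$pos_b[r] == 0L) 0L else links$pos_b[r] - se_b[1] + 1L
    # canonical orientation, as the search reports it
    if (nchar(pep_b) > nchar(pep_a) ||
          (nchar(pep_b) == nchar(pep_a) && pep_b < pep_a)) {
      tmp <- list(pep_a, site_a, sq_a, se_a)
      pep_a <- pep_b; site_a <- site_b; sq_a <- sq_b; se_a <- se_b
      pep_b <- tmp[[1]]; site_b <- tmp[[2]]; sq_b <- tmp[[3]]; se_b <- tmp[[4]]
    }
    z <- if (length(precursor_charges) > 1L)
      sample(precursor_charges, 1L) else precursor_charges
    rt0 <- .rt_base(paste0(pep_a, pep_b))
    rt_l <- rt0 + stats::rnorm(1, 0, rt_jitter_sd)
    rt_h <- rt0 + stats::rnorm(1, 0, rt_jitter_sd)

    # generate without the m/z window so the light/heavy rows stay in
    # label correspondence; the window is applied per form at emission
    frag_l <- generate_fragments(pep_a, site_a, pep_b, site_b,
                                 form = "light", xl_type = "inter-protein",
                                 max_charge = max_fragment_charge,
                                 mz_range = c(0, Inf), linker = linker)
    frag_h <- generate_fragments(pep_a, site_a, pep_b, site_b,
                                 form = "heavy", xl_type = "inter-protein",
                                 max_charge = max_fragment_charge,
                                 mz_range = c(0, Inf), linker = linker)
    nf <- nrow(frag_l)
    in_l <- frag_l$mz >= mz_range[1] & frag_l$mz <= mz_range[2]
    in_h <- frag_h$mz >= mz_range[1] & frag_h$mz <= mz_range[2]
    retained <- stats::runif(nf) < fragment_efficiency
    base_int <- stats::rlnorm(nf, meanlog = 6.5, sdlog = 0.8)
    jit_l <- exp(stats::rnorm(nf, 0, 0.1))
    jit_h <- exp(stats::rnorm(nf, 0, 0.1))
    noise_mz_l <- stats::runif(noise_peaks, mz_range[1], mz_range[2])
    noise_int_l <- stats::rlnorm(noise_peaks, meanlog = 3.5, sdlog = 0.8)
    noise_mz_h <- stats::runif(noise_peaks, mz_range[1], mz_range[2])
    noise_int_h <- stats::rlnorm(noise_peaks, meanlog = 3.5, sdlog = 0.8)
    drop_heavy <- stats::runif(1) < missing_form_prob

    mass_l <- peptide_neutral_mass(pep_a) + peptide_neutral_mass(pep_b) +
      linker_mass_delta("light", "cross-link")
    mass_h <- mass_l + linker_mass_delta("heavy", "cross-link") -
      linker_mass_delta("light", "cross-link")

    spectra[[length(spectra) + 1L]] <- spectrum(
      scan_id = sprintf("XL%d_L", links$link_id[r]),
      precursor_neutral_mass = mass_l, charge = z, rt = rt_l,
      mz = c(frag_l$mz[retained & in_l], noise_mz_l),
      intensity = c(base_int[retained & in_l] * jit_l[retained & in_l],
                    noise_int_l))
    scan_rows[[length(scan_rows) + 1L]] <- data.frame(
      scan_id = sprintf("XL%d_L", links$link_id[r]),
      link_id = links$link_id[r], form = "light", rt = rt_l,
      stringsAsFactors = FALSE)
    if (!drop_heavy) {
      spectra[[length(spectra) + 1L]] <- spectrum(
        scan_id = sprintf("XL%d_H", links$link_id[r]),
        precursor_neutral_mass = mass_h, charge = z, rt = rt_h,
        mz = c(frag_h$mz[retained & in_h], noise_mz_h),
        intensity = c(base_int[retained & in_h] * jit_h[retained & in_h],
                      noise_int_h))
      scan_rows[[length(scan_rows) + 1L]] <- data.frame(
        scan_id = sprintf("XL%d_H", links$link_id[r]),
        link_id = links$link_id[r], form = "heavy", rt = rt_h,
        stringsAsFactors = FALSE)
    }
    pep_cols[[r]] <- data.frame(alpha_seq = pep_a, site_a_pep = site_a,
                                beta_seq = pep_b, site_b_pep = site_b,
                                precursor_light = mass_l, charge = z,
                                stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_noise_spectra)) {
    z <- if (length(precursor_charges) > 1L)
      sample(precursor_charges, 1L) else precursor_charges
    pm <- stats::runif(1, 1200, 4800)
    rt <- stats::runif(1, 5, 200)
    nmz <- stats::runif(2 * noise_peaks, mz_range[1], mz_range[2])
    nint <- stats::rlnorm(2 * noise_peaks, meanlog = 3.5, sdlog = 0.8)
    spectra[[length(spectra) + 1L]] <- spectrum(
      scan_id = sprintf("NOISE%d", i), precursor_neutral_mass = pm,
      charge = z, rt = rt, mz = nmz, intensity = nint)
  }

  truth$links <- cbind(links, do.call(rbind, pep_cols))
  list(spectra = spectra,
       scan_truth = do.call(rbind, scan_rows),
       truth = truth)
}

#' Write the full synthetic fixture set
#'
#' Emits FASTA (sequences), PDB (coordinates with unresolved termini
#' redacted), MGF (paired spectra) and a ground-truth TSV into a
#' directory.
#'
#' @param sim A [simulate_spectra()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture_set <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tc <- sim$truth$complex
  write_fasta(tc$db, file.path(dir, "proteins.fasta"))
  write_structure_pdb(tc$model, file.path(dir, "complex.pdb"))
  write_mgf(sim$spectra, file.path(dir, "spectra.mgf"))
  utils::write.table(sim$truth$links, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
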