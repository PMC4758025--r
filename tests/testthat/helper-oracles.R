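# Independent oracles and shared fixtures. Oracles are deliberately
# naive (brute-force enumeration, plain Dijkstra in R) and share no
# code path with the implementation they check.

CONST <- mass_constants()

# brute-force tryptic digestion: every substring checked against the
# boundary and per-residue-type missed-cleavage rules
oracle_digest <- function(sequence, max_k = 3, max_r = 1,
                          proline_rule = TRUE) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  is_site <- function(p) {
    p >= 1 && p < n && aa[p] %in% c("K", "R") &&
      !(proline_rule && aa[p + 1] == "P")
  }
  out <- list()
  for (i in 1:n) for (j in i:n) {
    if (!(i == 1 || is_site(i - 1))) next
    if (!(j == n || is_site(j))) next
    internal <- Filter(is_site, if (j > i) i:(j - 1) else integer(0))
    if (sum(aa[internal] == "K") > max_k) next
    if (sum(aa[internal] == "R") > max_r) next
    out[[length(out) + 1]] <- c(start = i, end = j)
  }
  m <- do.call(rbind, out)
  data.frame(sequence = substring(sequence, m[, 1], m[, 2]),
             start = m[, 1], end = m[, 2], stringsAsFactors = FALSE)
}

# brute-force candidate enumeration over all peptides, peptide pairs
# and reactive-site pairs; returns canonical keys
oracle_candidates <- function(peptides, precursor_mass, tol_ppm = 3,
                              forms = c("light", "heavy")) {
  tol <- tol_ppm * 1e-6 * precursor_mass
  keys <- character(0)
  sites_of <- function(k, classes) {
    aa <- strsplit(peptides$sequence[k], "")[[1]]
    s <- which(aa %in% classes)
    if (peptides$is_protein_nterm[k]) s <- c(0L, s)
    s
  }
  cls1 <- "K"; cls2 <- c("K", "S", "T", "Y")
  for (form in forms) {
    bridge <- linker_mass_delta(form, "cross-link")
    deadend <- linker_mass_delta(form, "dead-end")
    for (k in seq_len(nrow(peptides))) {
      if (abs(peptides$mass[k] + deadend - precursor_mass) <= tol)
        for (s in sites_of(k, cls1))
          keys <- c(keys, paste("dead-end", peptides$sequence[k], s, "",
                                form))
      if (abs(peptides$mass[k] + bridge - precursor_mass) <= tol)
        for (s1 in sites_of(k, cls1))
          for (s2 in setdiff(sites_of(k, cls2), s1))
            keys <- c(keys, paste("loop", peptides$sequence[k],
                                  min(s1, s2), max(s1, s2), form))
    }
    for (k in seq_len(nrow(peptides))) for (l in seq_len(nrow(peptides))) {
      if (l < k) next
      if (abs(peptides$mass[k] + peptides$mass[l] + bridge -
                precursor_mass) > tol) next
      for (ori in list(c(k, l), c(l, k))) {
        for (s1 in sites_of(ori[1], cls1))
          for (s2 in sites_of(ori[2], cls2)) {
            a <- ori[1]; b <- ori[2]; sa <- s1; sb <- s2
            la <- nchar(peptides$sequence[a])
            lb <- nchar(peptides$sequence[b])
            if (lb > la || (lb == la &&
                              peptides$sequence[b] < peptides$sequence[a])) {
              tmp <- a; a <- b; b <- tmp
              tmp <- sa; sa <- sb; sb <- tmp
            }
            keys <- c(keys, paste("pair", peptides$sequence[a], sa,
                                  paste(peptides$sequence[b], sb), form))
          }
      }
    }
  }
  sort(unique(keys))
}

candidate_keys <- function(cands, peptides) {
  if (!nrow(cands)) return(character(0))
  k <- vapply(seq_len(nrow(cands)), function(r) {
    if (cands$xl_type[r] == "dead-end")
      paste("dead-end", peptides$sequence[cands$alpha[r]], cands$site_a[r],
            "", cands$form[r])
    else if (cands$xl_type[r] == "loop")
      paste("loop", peptides$sequence[cands$alpha[r]], cands$site_a[r],
            cands$site_b[r], cands$form[r])
    else
      paste("pair", peptides$sequence[cands$alpha[r]], cands$site_a[r],
            paste(peptides$sequence[cands$beta[r]], cands$site_b[r]),
            cands$form[r])
  }, character(1))
  sort(unique(k))
}

# 26-connected shortest path over an explicit 3-D occupancy grid by
# iterated relaxation to the fixed point (exact for non-negative step
# costs); independent of the package's priority-queue search
oracle_grid_dijkstra <- function(blocked, spacing, src, dst) {
  dims <- dim(blocked)
  dist <- array(Inf, dims)
  dist[src[1], src[2], src[3]] <- 0
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  costs <- spacing * sqrt(rowSums(offs^2))
  shift_plus <- function(a, o) {
    out <- array(Inf, dims)
    sx <- max(1, 1 + o[1]):min(dims[1], dims[1] + o[1])
    sy <- max(1, 1 + o[2]):min(dims[2], dims[2] + o[2])
    sz <- max(1, 1 + o[3]):min(dims[3], dims[3] + o[3])
    out[sx, sy, sz] <- a[sx - o[1], sy - o[2], sz - o[3]]
    out
  }
  for (iter in 1:500) {
    new <- dist
    for (t in seq_len(nrow(offs)))
      new <- pmin(new, shift_plus(dist, offs[t, ]) + costs[t])
    new[blocked] <- Inf
    if (identical(new, dist)) break
    dist <- new
  }
  dist[dst[1], dst[2], dst[3]]
}

# bare structure with two lysine query sites and optional obstacle atoms
make_two_site_model <- function(p1, p2, obstacles = NULL) {
  rows <- list(
    data.frame(chain = "A", resno = 1L, resname = "LYS", atom = "NZ",
               element = "N", x = p1[1], y = p1[2], z = p1[3], b = 10),
    data.frame(chain = "A", resno = 5L, resname = "LYS", atom = "NZ",
               element = "N", x = p2[1], y = p2[2], z = p2[3], b = 10)
  )
  if (!is.null(obstacles)) {
    rows[[3]] <- data.frame(chain = "W", resno = 100 + seq_len(nrow(obstacles)),
                            resname = "UNK", atom = "C1", element = "C",
                            x = obstacles[, 1], y = obstacles[, 2],
                            z = obstacles[, 3], b = 10)
  }
  structure_model(do.call(rbind, rows))
}

# flat two-chain interface for docking tests: 4 backbone atoms per
# residue, ligand chain shifted along y by `shift`
make_interface_model <- function(shift = 0, n_rec = 6, n_lig = 4) {
  rows <- list()
  add <- function(ch, rn, at, el, x, y, z)
    rows[[length(rows) + 1]] <<- data.frame(
      chain = ch, resno = rn, resname = "ALA", atom = at, element = el,
      x = x, y = y, z = z, b = 10, stringsAsFactors = FALSE)
  for (i in seq_len(n_rec)) {
    add("A", i, "N", "N", i * 3, 0, 0); add("A", i, "CA", "C", i * 3, 1, 0)
    add("A", i, "C", "C", i * 3, 2, 0); add("A", i, "O", "O", i * 3, 3, 0)
  }
  for (i in seq_len(n_lig)) {
    add("B", i, "N", "N", i * 3 + 1, 4 + shift, 0)
    add("B", i, "CA", "C", i * 3 + 1, 5 + shift, 0)
    add("B", i, "C", "C", i * 3 + 1, 6 + shift, 0)
    add("B", i, "O", "O", i * 3 + 1, 7 + shift, 0)
  }
  structure_model(do.call(rbind, rows))
}

# minimal PSM row for pairing tests
make_psm <- function(scan_id, form, mass, rt, score = 200,
                     alpha_seq = "AKGLVR", site_a = 2, beta_seq = "GKSELR",
                     site_b = 2, annotations = NULL, is_decoy = FALSE) {
  p <- data.frame(
    scan_id = scan_id, rt = rt, charge = 4L, precursor_obs = mass,
    form = form, xl_type = "inter-protein",
    alpha_protein = "P1", alpha_seq = alpha_seq, alpha_start = 1L,
    alpha_end = nchar(alpha_seq), alpha_protein_length = 100L,
    alpha_mox = "", site_a = site_a,
    beta_protein = "P2", beta_seq = beta_seq, beta_start = 1L,
    beta_end = nchar(beta_seq), beta_protein_length = 100L,
    beta_mox = "", site_b = site_b,
    precursor_theo = mass, precursor_error_ppm = 0,
    score = score, n_matched = 10L, n_frags = 20L,
    is_decoy = is_decoy, trypsin_ok = TRUE,
    stringsAsFactors = FALSE)
  p$annotations <- list(if (is.null(annotations))
    data.frame(series = "b", index = 2L, source = "alpha",
               contains_linker = TRUE, charge = 1L, mz = 300,
               label = "b2a+1", peak_mz = 300, peak_intensity = 100,
               peak_index = 1L, ambiguous = FALSE)
    else annotations)
  p
}

# memoized end-to-end fixture: 20 planted links, paired spectra, 400
# noise-only spectra, full pipeline run (shared across test files)
.fixture_env <- new.env(parent = emptyenv())

e2e_fixture <- function() {
  if (!is.null(.fixture_env$e2e)) return(.fixture_env$e2e)
  tc <- make_toy_complex(seed = 42, n_chains = 5, chain_length = 40)
  gt <- plant_crosslinks(tc, n_links = 20, seed = 5)
  sim <- simulate_spectra(gt, n_noise_spectra = 400, seed = 11)
  dir <- file.path(tempdir(), "xlinkr-e2e")
  write_fixture_set(sim, dir)
  res <- run_pipeline(file.path(dir, "proteins.fasta"),
                      file.path(dir, "spectra.mgf"))
  truth_keys <- vapply(seq_len(nrow(gt$links)), function(i) {
    a <- gt$links$protein_a[i]; b <- gt$links$protein_b[i]
    pa <- gt$links$pos_a[i]; pb <- gt$links$pos_b[i]
    if (b < a || (b == a && pb < pa)) paste(b, pb, a, pa)
    else paste(a, pa, b, pb)
  }, character(1))
  .fixture_env$e2e <- list(tc = tc, gt = gt, sim = sim, dir = dir,
                           res = res, truth_keys = truth_keys)
  .fixture_env$e2e
}

small_fixture <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  tc <- make_toy_complex(seed = 7, n_chains = 4, chain_length = 40)
  gt <- plant_crosslinks(tc, n_links = 6, seed = 3)
  sim <- simulate_spectra(gt, n_noise_spectra = 30, seed = 11)
  dir <- file.path(tempdir(), "xlinkr-small")
  write_fixture_set(sim, dir)
  .fixture_env$small <- list(tc = tc, gt = gt, sim = sim, dir = dir)
  .fixture_env$small
}
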