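toy_db <- function() {
  data.frame(id = c("P1", "P2"), description = "",
             sequence = c("AGKLVRSTMK", "GGKSEYRLLK"),
             is_decoy = FALSE, stringsAsFactors = FALSE)
}

test_that("candidate enumeration matches the all-pairs brute-force oracle", {
  peps <- digest_db(toy_db(), mass_min = 0, mass_max = 10000)
  # query at the exact mass of a known K-K pair
  m <- peptide_neutral_mass("AGKLVR") + peptide_neutral_mass("GGKSEYR") +
    linker_mass_delta("light", "cross-link")
  got <- enumerate_candidates(peps, m, tol_ppm = 3)
  expect_setequal(candidate_keys(got, peps),
                  oracle_candidates(peps, m, tol_ppm = 3))
  expect_true(any(got$xl_type == "inter-protein"))
  # several random query masses, both forms
  set.seed(4)
  for (q in runif(6, 800, 3000)) {
    got <- enumerate_candidates(peps, q, tol_ppm = 3)
    expect_setequal(candidate_keys(got, peps),
                    oracle_candidates(peps, q, tol_ppm = 3))
  }
})

test_that("enumeration respects the ppm tolerance and site availability", {
  peps <- digest_db(toy_db(), mass_min = 0, mass_max = 10000)
  m <- peptide_neutral_mass("AGKLVR") + peptide_neutral_mass("GGKSEYR") +
    linker_mass_delta("light", "cross-link")
  off <- m * (1 + 10e-6)   # 10 ppm away
  got <- enumerate_candidates(peps, off, tol_ppm = 3)
  expect_false(any(abs(got$precursor_mass - m) < 1e-6))
  # no reactive sites at all -> nothing
  noK <- data.frame(id = "P9", description = "", sequence = "AGLVDEFG",
                    is_decoy = FALSE, stringsAsFactors = FALSE)
  peps9 <- digest_db(noK, mass_min = 0, mass_max = 10000)
  peps9$is_protein_nterm <- FALSE  # suppress the N-terminal site too
  expect_equal(nrow(enumerate_candidates(
    peps9, peps9$mass[1] + linker_mass_delta("light", "dead-end"), 3)), 0L)
})

test_that("fragments shift by 12 Da/z exactly when and only when they span the link", {
  fl <- generate_fragments("AGKLV", 3, "GKSE", 2, form = "light",
                           mz_range = c(0, 1e5))
  fh <- generate_fragments("AGKLV", 3, "GKSE", 2, form = "heavy",
                           mz_range = c(0, 1e5))
  expect_equal(fl$label, fh$label)  # bijection by label
  dmz <- fh$mz - fl$mz
  expect_equal(dmz[!fl$contains_linker], rep(0, sum(!fl$contains_linker)))
  expect_equal(dmz[fl$contains_linker],
               CONST$bs3_heavy_shift / fl$charge[fl$contains_linker])
  # spanning pattern on the alpha peptide: b-ions from the site onward
  b_alpha <- fl[fl$series == "b" & fl$source == "alpha" & fl$charge == 1, ]
  expect_equal(b_alpha$contains_linker[order(b_alpha$index)],
               c(FALSE, FALSE, TRUE, TRUE))
})

test_that("dead-end fragments carry the hydrolyzed-linker mass", {
  f0 <- generate_fragments("AGKLV", 0, xl_type = "dead-end",
                           site_a = 3, mz_range = c(0, 1e5))
  plain <- generate_fragments("AGKLV", 3, "GKSE", 2, form = "light",
                              mz_range = c(0, 1e5))
  expect_true(all(f0$source == "alpha"))
  y1_free <- f0$mz[f0$label == "y1a+1"]
  b4_link <- f0$mz[f0$label == "b4a+1"]
  b4_bare <- peptide_neutral_mass("AGKL") - CONST$water + CONST$proton
  expect_equal(b4_link - b4_bare, 156.0786, tolerance = 1e-4)
  expect_equal(y1_free, CONST$residues[["V"]] + CONST$water + CONST$proton)
  expect_false(any(plain$source == "beta" & plain$index >= nchar("GKSE")))
})

test_that("matching respects the noise floor and the Da tolerance", {
  frags <- generate_fragments("AGKLVR", 3, "GKSER", 2, mz_range = c(0, 1e5))
  s_empty <- spectrum("s0", 2000, 4, 10)
  expect_equal(nrow(match_spectrum(s_empty, frags)), 0L)
  # exact peak -> matched; peak 0.9 Da off -> not matched at 0.8
  target <- frags$mz[5]
  s1 <- spectrum("s1", 2000, 4, 10,
                 mz = c(target, target + 50.9), intensity = c(100, 100))
  m1 <- match_spectrum(s1, frags, tol_da = 0.8, snr_min = 1)
  expect_true(any(abs(m1$peak_mz - target) < 1e-9))
  s2 <- spectrum("s2", 2000, 4, 10, mz = frags$mz[7] + 0.9, intensity = 100)
  expect_equal(nrow(match_spectrum(s2, frags, tol_da = 0.8, snr_min = 1)), 0L)
  # peaks below median * snr are discarded
  s3 <- spectrum("s3", 2000, 4, 10,
                 mz = c(target, 500, 600, 700, 800),
                 intensity = c(1, 100, 100, 100, 100))
  expect_equal(nrow(match_spectrum(s3, frags, tol_da = 0.8, snr_min = 2)), 0L)
})

test_that("the binomial-survival score matches a hand computation and is monotone", {
  frags <- generate_fragments("AGKLVR", 3, "GKSER", 2, mz_range = c(0, 1e5))
  n <- nrow(frags)
  # spectrum holding every fragment peak, equal intensities
  s_all <- spectrum("sa", 2000, 4, 10, mz = frags$mz,
                    intensity = rep(100, n))
  m_all <- match_spectrum(s_all, frags, snr_min = 1)
  sc_all <- score_psm(m_all, s_all, frags, snr_min = 1)
  # half the fragments
  half <- seq_len(n) <= n / 2
  s_half <- spectrum("sh", 2000, 4, 10, mz = frags$mz[half],
                     intensity = rep(100, sum(half)))
  m_half <- match_spectrum(s_half, frags, snr_min = 1)
  sc_half <- score_psm(m_half, s_half, frags, snr_min = 1)
  expect_gt(sc_all, sc_half)
  expect_gte(sc_half, 0)
  # zero matches scores zero
  s_none <- spectrum("sn", 2000, 4, 10, mz = c(3000, 3100),
                     intensity = c(10, 10))
  expect_equal(score_psm(match_spectrum(s_none, frags, snr_min = 1),
                         s_none, frags, snr_min = 1), 0)
  # hand recomputation on the all-matched fixture
  span <- max(s_all$mz) - min(s_all$mz)
  p <- min(max(2 * 0.8 * n / span, 1e-9), 1 - 1e-9)
  k <- nrow(m_all)
  expected <- -10 * log10(pbinom(k - 1, n, p, lower.tail = FALSE)) +
    20 * sum(m_all$peak_intensity[!duplicated(m_all$peak_index)]) /
      sum(s_all$intensity)
  expect_equal(sc_all, expected, tolerance = 1e-10)
})

test_that("decoy FDR estimation counts hits above threshold and finds thresholds", {
  t_sc <- c(10, 50, 90, 120, 150, 200)
  d_sc <- c(5, 8, 60)
  expect_equal(fdr_at_threshold(t_sc, d_sc, 100), 0)
  expect_equal(fdr_at_threshold(c(100, 200), c(150, 250), 100), 1.0)
  expect_equal(fdr_at_threshold(t_sc, d_sc, 50), 1 / 5)
  th <- fdr_threshold(t_sc, d_sc, fdr_target = 0.05)
  expect_true(fdr_at_threshold(t_sc, d_sc, th$threshold) <= 0.05)
  expect_true(all(t_sc[t_sc >= th$threshold] > 60))
  none <- fdr_threshold(numeric(0), d_sc, 0.05)
  expect_equal(none$threshold, Inf)
})

test_that("trypsin consistency flags C-terminal modified lysines only", {
  # link on the peptide's C-terminal K, peptide ends before the protein end
  expect_false(trypsin_consistent("AGKLK", 5, end = 20, protein_length = 80))
  # internal K (missed cleavage) is fine
  expect_true(trypsin_consistent("AGKLK", 3, end = 20, protein_length = 80))
  # protein C-terminus is exempt
  expect_true(trypsin_consistent("AGKLK", 5, end = 80, protein_length = 80))
  # N-terminal site implies no cleavage
  expect_true(trypsin_consistent("AGKLK", 0, end = 20, protein_length = 80))
  # serine at the C-terminus is not a tryptic site at all
  expect_true(trypsin_consistent("AGKLS", 5, end = 20, protein_length = 80))
})
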