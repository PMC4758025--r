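test_that("the reported precursor pair at z = 4 passes isotope-pair matching", {
  light <- make_psm("scanL", "light", 2388.329, rt = 95.0)
  heavy <- make_psm("scanH", "heavy", 2400.404, rt = 95.1)
  fp <- find_pairs(light, heavy, mass_tol_ppm = 5, rt_tol_min = 0.5)
  expect_equal(nrow(fp$pairs), 1L)
  expect_equal(round(fp$pairs$delta_mass), 12)
  expect_true(fp$pairs$dual_identification)
  expect_true(fp$pairs$co_elution)
})

test_that("a zero mass shift is not an isotope pair", {
  light <- make_psm("scanL", "light", 2388.329, rt = 95.0)
  heavy <- make_psm("scanH", "heavy", 2388.329, rt = 95.0)
  fp <- find_pairs(light, heavy)
  expect_equal(nrow(fp$pairs), 0L)
  expect_true(all(c("no heavy partner", "no light partner") %in%
                    fp$unpaired$reason))
})

test_that("pairing on many planted partners equals the all-pairs oracle", {
  set.seed(9)
  n <- 100
  shift <- CONST$bs3_heavy_shift
  seqs <- replicate(n, paste(sample(names(CONST$residues), 8,
                                    replace = TRUE), collapse = ""))
  masses <- 1500 + cumsum(runif(n, 1, 5))
  rts <- runif(n, 10, 180)
  partner_rt_ok <- runif(n) < 0.7
  rts_h <- ifelse(partner_rt_ok, rts + runif(n, -0.3, 0.3),
                  rts + runif(n, 2, 30))
  light <- do.call(rbind, lapply(seq_len(n), function(i)
    make_psm(paste0("L", i), "light", masses[i], rts[i],
             alpha_seq = seqs[i])))
  heavy <- do.call(rbind, lapply(seq_len(n), function(i)
    make_psm(paste0("H", i), "heavy", masses[i] + shift, rts_h[i],
             alpha_seq = seqs[i])))
  # shuffle row order
  heavy <- heavy[sample(n), ]
  fp <- find_pairs(light, heavy, mass_tol_ppm = 5, rt_tol_min = 0.5)
  # oracle: unique sequences pair by construction; co-elution per plant
  expect_equal(nrow(fp$pairs), n)
  got <- fp$pairs[order(match(fp$pairs$light_scan, paste0("L", 1:n))), ]
  expect_equal(got$heavy_scan, paste0("H", 1:n))
  expect_equal(got$co_elution, partner_rt_ok)
})

test_that("pattern similarity is the Jaccard of shift-consistent labels", {
  ann <- function(labels, mz, linker = FALSE, charge = 1L) {
    n <- length(labels)
    data.frame(series = substr(labels, 1, 1), index = rep(1L, n),
               source = rep("alpha", n),
               contains_linker = rep(linker, n),
               charge = rep(charge, n), mz = mz,
               label = labels, peak_mz = mz,
               peak_intensity = rep(100, n),
               peak_index = seq_len(n), ambiguous = rep(FALSE, n),
               stringsAsFactors = FALSE)
  }
  a <- ann(c("b1a+1", "b2a+1", "y1a+1"), c(100, 200, 300))
  expect_equal(pattern_similarity(a, a), 1.0)
  b <- ann(c("b5a+1", "b6a+1", "y9a+1"), c(400, 500, 600))
  expect_equal(pattern_similarity(a, b), 0.0)
  # |intersection| = 3, |union| = 6
  x <- ann(sprintf("b%da+1", 1:4), 100 * (1:4))
  y <- ann(sprintf("b%da+1", 2:6), 100 * (2:6))
  expect_equal(pattern_similarity(x, y), 0.5)
  # a linker-containing label must shift by 12.0753/z to stay matched
  lx <- ann("b3a+2", 700, linker = TRUE, charge = 2L)
  ly_ok <- ann("b3a+2", 700 + CONST$bs3_heavy_shift / 2,
               linker = TRUE, charge = 2L)
  ly_bad <- ann("b3a+2", 700, linker = TRUE, charge = 2L)
  expect_equal(pattern_similarity(lx, ly_ok), 1.0)
  expect_equal(pattern_similarity(lx, ly_bad), 0.0)
  empty <- ann(character(0), numeric(0))
  expect_warning(s0 <- pattern_similarity(empty, empty), "unannotated")
  expect_equal(s0, 0)
})

test_that("the verdict requires all three criteria and records the failure", {
  shift <- CONST$bs3_heavy_shift
  light <- make_psm("L1", "light", 2000, rt = 50)
  heavy <- make_psm("H1", "heavy", 2000 + shift, rt = 55)  # 5 min apart
  fp <- find_pairs(light, heavy, rt_tol_min = 0.5)
  expect_equal(nrow(fp$pairs), 1L)
  v <- validate_pairs(fp$pairs)
  expect_equal(v$verdict, "rejected")
  expect_equal(v$reason, "co_elution")
  # co-eluting identical annotations validate
  heavy2 <- make_psm("H2", "heavy", 2000 + shift, rt = 50.1)
  heavy2$annotations[[1]]$peak_mz <- heavy2$annotations[[1]]$peak_mz + shift
  heavy2$annotations[[1]]$mz <- heavy2$annotations[[1]]$mz + shift
  v2 <- validate_pairs(find_pairs(light, heavy2)$pairs)
  expect_equal(v2$verdict, "validated")
  expect_equal(v2$pattern_similarity, 1.0)
})

test_that("validation is symmetric under swapping the light and heavy labels", {
  fx <- e2e_fixture()
  psms <- fx$res$psms
  keepL <- psms[psms$form == "light" & !psms$is_decoy, ]
  keepH <- psms[psms$form == "heavy" & !psms$is_decoy, ]
  fwd <- validate_pairs(find_pairs(keepL, keepH)$pairs)
  rev <- validate_pairs(find_pairs(keepH, keepL,
                                   shift = -CONST$bs3_heavy_shift)$pairs,
                        shift = -CONST$bs3_heavy_shift)
  key <- function(p, a, b) sort(paste(p[[a]], p[[b]], p$verdict))
  expect_equal(key(fwd, "light_scan", "heavy_scan"),
               key(rev, "heavy_scan", "light_scan"))
})

test_that("unique residue-pair links collapse over redundant peptide evidence", {
  shift <- CONST$bs3_heavy_shift
  mk <- function(l, h, seq_a = "AKGLVR", mox = "") {
    light <- make_psm(l, "light", 2000, rt = 50, alpha_seq = seq_a)
    light$alpha_mox <- mox
    heavy <- make_psm(h, "heavy", 2000 + shift, rt = 50, alpha_seq = seq_a)
    heavy$alpha_mox <- mox
    heavy$annotations[[1]]$peak_mz <- heavy$annotations[[1]]$peak_mz + shift
    find_pairs(light, heavy)$pairs
  }
  pairs <- validate_pairs(rbind(mk("L1", "H1"), mk("L2", "H2")))
  links <- collapse_links(pairs)
  expect_equal(nrow(links), 1L)
  expect_equal(links$n_pairs, 2L)
  expect_equal(links$site1, 2L)  # protein residue position of the K
})
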