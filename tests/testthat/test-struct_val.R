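test_that("PDB round trip preserves residues and flags unresolved ones", {
  tc <- make_toy_complex(seed = 3, n_chains = 2, chain_length = 20,
                         unresolved_nterm = 3, unresolved_chain_frac = 0.5)
  f <- tempfile(fileext = ".pdb")
  write_structure_pdb(tc$model, f)
  m <- read_structure(f)
  expect_equal(nrow(m$residues), 40L)
  expect_equal(sum(!m$residues$resolved), 3L)
  expect_equal(m$residues$resolved, tc$model$residues$resolved)
})

test_that("declared-but-absent residues are counted unresolved", {
  # SEQRES declares 10 residues, ATOM records cover 7
  lines <- c(
    "SEQRES   1 A   10  ALA GLY LEU LYS VAL ALA GLY LEU LYS VAL",
    sprintf("ATOM  %5d  CA  %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            1:7, c("ALA","GLY","LEU","LYS","VAL","ALA","GLY"), 1:7,
            (1:7) * 3.8, 0, 0, 1, 20),
    "TER", "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  m <- read_structure(f)
  expect_equal(sum(m$residues$resolved), 7L)
  expect_equal(sum(!m$residues$resolved), 3L)
  # empty file errors
  f0 <- tempfile(fileext = ".pdb")
  file.create(f0)
  expect_error(read_structure(f0), "empty")
})

test_that("reactive atoms follow the site chemistry with CB/CA fallback", {
  tc <- make_toy_complex(seed = 3, n_chains = 2, chain_length = 20,
                         unresolved_nterm = 3, unresolved_chain_frac = 0.5)
  m <- tc$model_full
  kpos <- which(strsplit(tc$db$sequence[1], "")[[1]] == "K")[1]
  ra <- reactive_atom(m, "A", kpos)
  expect_equal(ra$atom, "NZ")
  expect_equal(ra$slack, 0)
  # truncate the side chain: fallback CB, recorded slack
  m2 <- m
  m2$atoms <- m2$atoms[!(m2$atoms$chain == "A" & m2$atoms$resno == kpos &
                           m2$atoms$atom == "NZ"), ]
  rb <- reactive_atom(m2, "A", kpos)
  expect_equal(rb$atom, "CB")
  expect_equal(rb$slack, 3)
  # unresolved N-terminal residue is unconstrained, not an error
  unres_ch <- tc$unresolved_chains[1]
  expect_equal(reactive_atom(tc$model, unres_ch, 0)$status, "unconstrained")
  expect_error(reactive_atom(m, "Z", 0), "chain")
})

test_that("euclidean distance is the plain L2 norm", {
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(2)
  for (i in 1:5) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(euclidean_distance(a, b), sqrt(sum((a - b)^2)))
  }
})

test_that("SAS distance in empty space approaches the Euclidean distance", {
  m <- make_two_site_model(c(0, 0, 0), c(10, 0, 0))
  d <- sas_distance(m, list(chain = "A", site = 1), list(chain = "A", site = 5),
                    grid_spacing = 1, max_dist = 40, margin = 8)
  expect_equal(d$status, "ok")
  expect_lt(abs(d$distance - 10) / 10, 0.10)  # 26-connectivity overestimate
})

test_that("SAS path around a wall equals the independent grid Dijkstra", {
  # wall of carbon atoms in the y-z plane at x = 0
  wall <- as.matrix(expand.grid(x = 0, y = seq(-6, 6, by = 1.5),
                                z = seq(-6, 6, by = 1.5)))
  p1 <- c(-5, 0, 0); p2 <- c(5, 0, 0)
  m <- make_two_site_model(p1, p2, wall)
  spacing <- 1; probe <- 1.4; margin <- 6; max_dist <- 70
  d <- sas_distance(m, list(chain = "A", site = 1), list(chain = "A", site = 5),
                    grid_spacing = spacing, probe_radius = probe,
                    max_dist = max_dist, margin = margin)
  expect_equal(d$status, "ok")
  expect_gt(d$distance, 10)   # cannot go straight through

  # oracle: rebuild the documented grid and run plain Dijkstra
  lo <- pmin(apply(wall, 2, min), p1, p2) - margin
  hi <- pmax(apply(wall, 2, max), p1, p2) + margin
  dims <- floor((hi - lo) / spacing) + 1
  blocked <- array(FALSE, dims)
  r2 <- (1.7 + probe)^2
  gx <- lo[1] + (slice.index(blocked, 1) - 1) * spacing
  gy <- lo[2] + (slice.index(blocked, 2) - 1) * spacing
  gz <- lo[3] + (slice.index(blocked, 3) - 1) * spacing
  for (a in seq_len(nrow(wall)))
    blocked <- blocked | ((gx - wall[a, 1])^2 + (gy - wall[a, 2])^2 +
                            (gz - wall[a, 3])^2 <= r2)
  snap <- function(p) {
    best <- NULL; bestd <- Inf
    c0 <- round((p - lo) / spacing) + 1
    for (dx in -2:2) for (dy in -2:2) for (dz in -2:2) {
      v <- c0 + c(dx, dy, dz)
      if (any(v < 1) || any(v > dims)) next
      if (blocked[v[1], v[2], v[3]]) next
      off <- sqrt(sum((lo + (v - 1) * spacing - p)^2))
      if (off <= 2 * spacing && off < bestd) { bestd <- off; best <- v }
    }
    list(cell = best, off = bestd)
  }
  s1 <- snap(p1); s2 <- snap(p2)
  want <- oracle_grid_dijkstra(blocked, spacing, s1$cell, s2$cell) +
    s1$off + s2$off
  expect_equal(d$distance, want, tolerance = 1e-9)
})

test_that("a boxed-in endpoint is reported unreachable", {
  box <- as.matrix(expand.grid(x = c(-3, 3), y = seq(-3, 3, 1.5),
                               z = seq(-3, 3, 1.5)))
  box <- rbind(box,
               as.matrix(expand.grid(x = seq(-3, 3, 1.5), y = c(-3, 3),
                                     z = seq(-3, 3, 1.5))),
               as.matrix(expand.grid(x = seq(-3, 3, 1.5),
                                     y = seq(-3, 3, 1.5), z = c(-3, 3))))
  m <- make_two_site_model(c(0, 0, 0), c(20, 0, 0), box)
  d <- sas_distance(m, list(chain = "A", site = 1), list(chain = "A", site = 5),
                    grid_spacing = 1, max_dist = 70, margin = 6)
  expect_true(d$status %in% c("unreachable", "buried"))
  expect_true(is.na(d$distance))
})

test_that("SAS dominates Euclidean, is symmetric, and refines stably", {
  tc <- make_toy_complex(seed = 5, n_chains = 3, chain_length = 30)
  m <- tc$model_full
  set.seed(6)
  ks <- lapply(1:3, function(i)
    which(strsplit(tc$db$sequence[i], "")[[1]] == "K"))
  pairs_checked <- 0
  for (t in 1:8) {
    c1 <- sample(1:3, 1); c2 <- sample(1:3, 1)
    s1 <- sample(ks[[c1]], 1); s2 <- sample(ks[[c2]], 1)
    if (c1 == c2 && s1 == s2) next
    a <- list(chain = LETTERS[c1], site = s1)
    b <- list(chain = LETTERS[c2], site = s2)
    ra <- reactive_atom(m, a$chain, a$site)
    rb <- reactive_atom(m, b$chain, b$site)
    eu <- euclidean_distance(ra$xyz, rb$xyz)
    d_ab <- sas_distance(m, a, b, grid_spacing = 1.5, max_dist = 120,
                         margin = 10)
    if (d_ab$status != "ok") next
    d_ba <- sas_distance(m, b, a, grid_spacing = 1.5, max_dist = 120,
                         margin = 10)
    expect_gte(d_ab$distance, eu - 1e-9)
    expect_equal(d_ab$distance, d_ba$distance)
    pairs_checked <- pairs_checked + 1
  }
  expect_gte(pairs_checked, 3)
  # grid refinement 2.0 -> 1.0 never lengthens the path by more than
  # one coarse step cost
  m2 <- make_two_site_model(c(0, 0, 0), c(9, 3, 2))
  a <- list(chain = "A", site = 1); b <- list(chain = "A", site = 5)
  d2 <- sas_distance(m2, a, b, grid_spacing = 2, max_dist = 40, margin = 6)
  d1 <- sas_distance(m2, a, b, grid_spacing = 1, max_dist = 40, margin = 6)
  expect_lte(d1$distance, d2$distance + sqrt(3) * 2)
})

test_that("cross-link filtering applies the cutoff and spares unresolved termini", {
  # two lysines 36.5 A apart in empty space: fail at 35, pass at 40
  m <- make_two_site_model(c(0, 0, 0), c(36.5, 0, 0))
  links <- data.frame(chain_a = "A", pos_a = 1L, chain_b = "A", pos_b = 5L,
                      stringsAsFactors = FALSE)
  r35 <- filter_crosslinks(links, m, cutoff = 35)
  expect_equal(r35$within_cutoff, "fail")
  r40 <- filter_crosslinks(links, m, cutoff = 40)
  expect_equal(r40$within_cutoff, "pass")
  expect_gte(r40$sas, r40$euclidean)
  # unresolved terminus -> unconstrained, never a contradiction
  tc <- make_toy_complex(seed = 3, n_chains = 2, chain_length = 20,
                         unresolved_nterm = 3, unresolved_chain_frac = 0.5)
  unres <- tc$unresolved_chains[1]
  other <- setdiff(c("A", "B"), unres)
  kpos <- which(strsplit(tc$db$sequence[match(paste0("chain", other),
                                              tc$db$id)], "")[[1]] == "K")[1]
  l2 <- data.frame(chain_a = unres, pos_a = 0L, chain_b = other,
                   pos_b = kpos, stringsAsFactors = FALSE)
  expect_equal(filter_crosslinks(l2, tc$model)$within_cutoff, "unconstrained")
  expect_error(filter_crosslinks(
    data.frame(chain_a = "Q", pos_a = 1L, chain_b = "A", pos_b = 5L),
    m), "chain")
})

test_that("the pass set grows monotonically with the cutoff", {
  fx <- small_fixture()
  links <- fx$gt$links[, c("chain_a", "pos_a", "chain_b", "pos_b")]
  r30 <- filter_crosslinks(links, fx$tc$model_full, cutoff = 30,
                           grid_spacing = 1.5)
  r35 <- filter_crosslinks(links, fx$tc$model_full, cutoff = 35,
                           grid_spacing = 1.5)
  pass30 <- which(r30$within_cutoff == "pass")
  pass35 <- which(r35$within_cutoff == "pass")
  expect_true(all(pass30 %in% pass35))
})

test_that("hotspot reporting counts links per site and ranks hubs first", {
  links <- data.frame(
    chain_a = c("A", "A", "A", "A", "B"),
    pos_a = c(0L, 0L, 0L, 0L, 4L),
    chain_b = c("B", "B", "C", "C", "C"),
    pos_b = c(4L, 9L, 2L, 7L, 2L),
    stringsAsFactors = FALSE)
  tc <- make_toy_complex(seed = 3, n_chains = 3, chain_length = 20,
                         unresolved_chain_frac = 0)
  h <- hotspot_report(links, tc$model)
  expect_equal(h$chain[1], "A")
  expect_equal(h$pos[1], 0L)
  expect_equal(h$n_links[1], 4L)
  expect_true(h$is_nterm[1])
  expect_true(all(diff(h$n_links) <= 0))
  empty <- hotspot_report(links[0, ], tc$model)
  expect_equal(nrow(empty), 0L)
})
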