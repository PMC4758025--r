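test_that("native contacts equal the all-pairs brute-force oracle", {
  ref <- make_interface_model(0)
  nc <- native_contacts(ref, "A", "B")
  # oracle: plain double loop over heavy atoms
  at <- ref$atoms
  rec <- at[at$chain == "A", ]; lig <- at[at$chain == "B", ]
  want <- character(0)
  for (i in seq_len(nrow(rec))) for (j in seq_len(nrow(lig))) {
    d <- sqrt((rec$x[i] - lig$x[j])^2 + (rec$y[i] - lig$y[j])^2 +
                (rec$z[i] - lig$z[j])^2)
    if (d <= 5) want <- c(want, paste(rec$resno[i], lig$resno[j]))
  }
  expect_setequal(paste(nc$rec_resno, nc$lig_resno), unique(want))
  # partners far apart everywhere -> no contacts
  far <- make_interface_model(100)
  expect_equal(nrow(native_contacts(far, "A", "B")), 0L)
  expect_error(native_contacts(ref, "A", "Z"), "empty")
})

test_that("fnat is the recovered fraction of reference contacts", {
  ref <- make_interface_model(0)
  expect_equal(fnat(ref, ref, "A", "B"), 1.0)
  displaced <- make_interface_model(100)
  expect_equal(fnat(displaced, ref, "A", "B"), 0.0)
  expect_error(fnat(ref, displaced, "A", "B"), "no contacts")
  # constructed 3-of-5 case: five single-atom contacts, two broken
  single <- function(ys) {
    rows <- lapply(seq_along(ys), function(i) rbind(
      data.frame(chain = "A", resno = i, resname = "GLY", atom = "CA",
                 element = "C", x = i * 4, y = 0, z = 0, b = 10),
      data.frame(chain = "B", resno = i, resname = "GLY", atom = "CA",
                 element = "C", x = i * 4, y = ys[i], z = 0, b = 10)))
    structure_model(do.call(rbind, rows))
  }
  ref5 <- single(rep(4.5, 5))
  mod3 <- single(c(4.5, 4.5, 4.5, 40, 40))
  expect_equal(fnat(mod3, ref5, "A", "B"), 0.6)
})

test_that("superposition recovers rigid transforms and matches bio3d", {
  set.seed(8)
  x <- matrix(rnorm(150), ncol = 3)
  expect_equal(superpose(x, x)$rmsd, 0, tolerance = 1e-12)
  expect_equal(superpose(x, sweep(x, 2, c(5, -2, 9), `+`))$rmsd, 0,
               tolerance = 1e-12)
  # random rotation + translation + noise
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  y <- x %*% t(R) + matrix(rnorm(150, 0, 0.1), ncol = 3)
  y <- sweep(y, 2, c(1, 2, 3), `+`)
  fit <- superpose(y, x)
  # cross-check against bio3d's least-squares fit
  moved <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(x)), mobile = as.vector(t(y))))
  rmsd_bio3d <- sqrt(mean(rowSums(
    (matrix(moved, ncol = 3, byrow = TRUE) - x)^2)))
  expect_equal(fit$rmsd, rmsd_bio3d, tolerance = 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_error(superpose(x[1:2, ], x[1:2, ]), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
})

test_that("ligand RMSD measures placement after receptor superposition", {
  ref <- make_interface_model(0)
  expect_equal(ligand_rmsd(ref, ref, "A", "B"), 0, tolerance = 1e-12)
  mod5 <- make_interface_model(5)    # ligand rigidly shifted 5 A
  expect_equal(ligand_rmsd(mod5, ref, "A", "B"), 5, tolerance = 1e-9)
  # invariant under a rigid transform of the whole model
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  rot <- mod5
  xyz <- as.matrix(rot$atoms[, c("x", "y", "z")]) %*% t(R)
  rot$atoms$x <- xyz[, 1] + 7; rot$atoms$y <- xyz[, 2] - 3
  rot$atoms$z <- xyz[, 3] + 2
  expect_equal(ligand_rmsd(rot, ref, "A", "B"), 5, tolerance = 1e-9)
})

test_that("CAPRI classes follow the published thresholds and are monotone in fnat", {
  expect_equal(capri_class(0.60, 5.2, 3), "acceptable")
  expect_equal(capri_class(1.0, 0, 0), "high")
  expect_equal(capri_class(0.05, 20, 10), "incorrect")
  expect_equal(capri_class(0.45, 4.0, 1.8), "medium")
  ranks <- c(incorrect = 0, acceptable = 1, medium = 2, high = 3)
  for (lr in c(0.5, 3, 8, 20)) for (ir in c(0.5, 1.5, 3, 8)) {
    cls <- ranks[vapply(seq(0, 1, 0.05), capri_class,
                        character(1), ligand_rmsd = lr, interface_rmsd = ir)]
    expect_true(all(diff(cls) >= 0))
  }
  ref <- make_interface_model(0)
  expect_equal(assess_model(ref, ref, "A", "B")$quality, "high")
})
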