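test_that("chain masses follow the average-mass table", {
  expect_equal(chain_mass("G"), 75.07, tolerance = 1e-3)
  expect_equal(chain_mass("GG"), 132.12, tolerance = 1e-3)
  expect_error(chain_mass("GXG"), "non-standard residue 'X' at position 2")
})

test_that("chain mass is additive up to one condensation water", {
  set.seed(7)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:5) {
    s1 <- paste(sample(aa, 12, replace = TRUE), collapse = "")
    s2 <- paste(sample(aa, 9, replace = TRUE), collapse = "")
    expect_equal(chain_mass(paste0(s1, s2)),
                 chain_mass(s1) + chain_mass(s2) - 18.0153,
                 tolerance = 1e-9)
  }
})

test_that("chain mass agrees with an independent implementation", {
  skip_if_not_installed("seqinr")
  set.seed(9)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  s <- paste(sample(aa, 60, replace = TRUE), collapse = "")
  expect_equal(chain_mass(s), seqinr::pmw(strsplit(s, "")[[1]]),
               tolerance = 1)
})

test_that("kabsch superposition is exact on rigid motions", {
  set.seed(3)
  x <- matrix(rnorm(30, sd = 4), 10, 3)
  id <- kabsch_superpose(x, x)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)
  expect_equal(id$rotation, diag(3), tolerance = 1e-10)

  # 90 degrees about z plus a translation
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  y <- x %*% t(R90) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(x, y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  moved <- x %*% fit$rotation + matrix(fit$translation, 10, 3, byrow = TRUE)
  expect_equal(moved, y, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(t(fit$rotation) %*% fit$rotation, diag(3), tolerance = 1e-8)
})

test_that("kabsch matches the numeric brute-force minimiser", {
  set.seed(21)
  for (k in 1:6) {
    n <- sample(4:10, 1)
    x <- matrix(rnorm(3 * n, sd = 3), n, 3)
    y <- x %*% t(gen_perturbed_coords(4, seed = k)$rotation) +
      matrix(rnorm(3, sd = 2), n, 3, byrow = TRUE) +
      matrix(rnorm(3 * n, sd = 0.3), n, 3)
    expect_equal(kabsch_superpose(x, y)$rmsd, brute_rigid_rmsd(x, y),
                 tolerance = 1e-6)
  }
  # single perturbed coordinate, as a sharp check
  x <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  y <- x
  y[4, 3] <- y[4, 3] + 0.3
  expect_equal(kabsch_superpose(x, y)$rmsd, brute_rigid_rmsd(x, y),
               tolerance = 1e-6)
})

test_that("kabsch agrees with bio3d's fitting routine", {
  set.seed(13)
  x <- matrix(rnorm(45, sd = 5), 15, 3)
  y <- x %*% t(gen_perturbed_coords(4, angle = 0.8, seed = 2)$rotation) +
    matrix(rnorm(45, sd = 0.2), 15, 3)
  ours <- kabsch_superpose(x, y)$rmsd
  theirs <- bio3d::rmsd(as.vector(t(y)), as.vector(t(x)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("rmsd is invariant under global rigid motions of either input", {
  set.seed(15)
  x <- matrix(rnorm(24, sd = 3), 8, 3)
  y <- x + matrix(rnorm(24, sd = 0.4), 8, 3)
  base <- kabsch_superpose(x, y)$rmsd
  R <- gen_perturbed_coords(4, angle = 1.9, axis = c(1, 1, 0), seed = 5)$rotation
  x2 <- x %*% t(R) + matrix(c(5, -1, 2), 8, 3, byrow = TRUE)
  y2 <- y %*% t(R) + matrix(c(-3, 7, 1), 8, 3, byrow = TRUE)
  expect_equal(kabsch_superpose(x2, y)$rmsd, base, tolerance = 1e-8)
  expect_equal(kabsch_superpose(x, y2)$rmsd, base, tolerance = 1e-8)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(kabsch_superpose(line, line), "collinear")
  expect_error(kabsch_superpose(line[1:2, ], line[1:2, ]), "at least 3")
})

test_that("structure readers extract chains, cell and space group", {
  s <- read_structure(extdata("spa17_asu_synthetic.pdb"))
  expect_length(s$chains, 4)
  expect_equal(unname(vapply(s$chains, function(ch) nrow(ch$ca),
                             integer(1))), rep(75L, 4))
  expect_equal(unname(s$cell["a"]), 60.96)
  expect_equal(unname(s$cell["gamma"]), 120)
  expect_equal(s$space_group, "P 32")

  r_cif <- suppressWarnings(read_structure(extdata("riia_dd_synthetic.cif")))
  r_pdb <- read_structure(extdata("riia_dd_synthetic.pdb"))
  expect_length(r_cif$chains, 2)
  expect_equal(r_cif$chains[["A"]]$sequence, r_pdb$chains[["A"]]$sequence)
  expect_equal(r_cif$chains[["A"]]$ca, r_pdb$chains[["A"]]$ca,
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(unname(r_cif$cell["a"]), 45)
  expect_error(read_structure("no/such/file.pdb"), "not found")
})

test_that("residue pairing handles offsets and chain swaps", {
  s <- read_structure(extdata("spa17_asu_synthetic.pdb"))
  a <- s$chains[["A"]]
  # identical chains pair completely and in order
  p <- pair_ca(list(a), list(a))
  expect_equal(p$n_pairs, 75)
  # an N-terminally extended copy pairs with a constant offset
  ext <- list(sequence = paste0("GSH", a$sequence),
              ca = rbind(matrix(c(-40, 0, 0, -44, 0, 1, -48, 1, 0),
                                3, 3, byrow = TRUE), a$ca))
  p2 <- pair_ca(list(ext), list(a))
  expect_equal(p2$n_pairs, 75)
  expect_equal(p2$xyz_a, a$ca, ignore_attr = TRUE)
  # dimer-vs-dimer is label-invariant: both assignments are tried
  b <- s$chains[["B"]]
  f1 <- kabsch_superpose(pair_ca(list(a, b), list(a, b))$xyz_a,
                         pair_ca(list(a, b), list(a, b))$xyz_b)
  f2 <- kabsch_superpose(pair_ca(list(b, a), list(a, b))$xyz_a,
                         pair_ca(list(b, a), list(a, b))$xyz_b)
  expect_equal(f1$rmsd, f2$rmsd, tolerance = 1e-8)
})

test_that("noisy rigid pairs superpose near the analytic expectation", {
  pc <- gen_perturbed_coords(500, angle = 0.9, axis = c(1, 0, 2),
                             translation = c(2, 2, -1), noise_sd = 0.2,
                             seed = 33)
  fit <- kabsch_superpose(pc$x, pc$y)
  # residual rmsd under one-sided isotropic noise ~ sqrt(3) * sd
  expect_equal(fit$rmsd, sqrt(3) * 0.2 * sqrt(1 - 6 / (2 * 500)),
               tolerance = 0.1)
  # noise-free clouds recover the generating transform exactly
  pc0 <- gen_perturbed_coords(50, angle = 0.9, axis = c(1, 0, 2),
                              translation = c(2, 2, -1), seed = 34)
  fit0 <- kabsch_superpose(pc0$x, pc0$y)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$rotation, t(pc0$rotation), tolerance = 1e-9)
})
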