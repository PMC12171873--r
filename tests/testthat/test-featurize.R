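test_that("chi1 of a constructed anti-periplanar quadruplet is 180 degrees", {
  at <- data.frame(name = c("N", "CA", "CB", "CG"), resname = "LYS",
                   resno = 1L, chain = "A")
  co <- array(0, c(1, 4, 3))
  co[1, , ] <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0))
  tr <- trajectory(at, co)
  expect_equal(unname(compute_chi1(tr, 1)$values[1, 1]), 180)
})

test_that("chi1 recovers rotamer-toy targets within 1e-6 degrees", {
  targets <- c(-60, 60, 180, 0, -172.35, 119.999)
  chi <- compute_chi1(generate_rotamer_toy(targets), 1)$values[, 1]
  expect_equal(chi, targets, tolerance = 1e-6)
})

test_that("residues without a gamma atom are skipped with a warning", {
  at <- data.frame(name = c("N", "CA", "CB", "CG", "N", "CA"),
                   resname = c(rep("LYS", 4), rep("GLY", 2)),
                   resno = c(rep(1L, 4), rep(2L, 2)), chain = "A")
  co <- array(rnorm(2 * 6 * 3), c(2, 6, 3))
  tr <- trajectory(at, co)
  expect_warning(ft <- compute_chi1(tr, c(1, 2)), "GLY")
  expect_identical(ncol(ft$values), 1L)
})

test_that("rotamer classification follows the field's labelling convention", {
  expect_identical(classify_rotamer(180), "trans")
  expect_identical(classify_rotamer(-60), "gauche_plus")
  expect_identical(classify_rotamer(60), "gauche_minus")
  # boundary convention: bins centered on -60/+60/180, edges at 0, +/-120
  expect_identical(classify_rotamer(119.999), "gauche_minus")
  expect_identical(classify_rotamer(120), "trans")
  expect_identical(classify_rotamer(-120), "trans")
  expect_identical(classify_rotamer(0), "gauche_minus")
  expect_error(classify_rotamer(200), "-180")
})

test_that("helix distances match geometry and rigid-motion invariance", {
  toy <- toy_system()
  expect_equal(compute_helix_distance(toy, "A:1", "A:2")$values[, 1], c(5, 5))
  expect_equal(compute_helix_distance(toy, "A:1", "A:1")$values[, 1], c(0, 0))
  shifted <- toy
  shifted$coords <- sweep(toy$coords, 3, c(1, 2, 3), "+")
  expect_equal(compute_helix_distance(shifted, "A:1", "A:2")$values,
               compute_helix_distance(toy, "A:1", "A:2")$values)
  expect_error(compute_helix_distance(toy, "resname=LIG", "A:1"), "CA")
})

test_that("features are invariant to rigid rotation of each frame", {
  toy <- generate_rotamer_toy(c(-60, 137.2))
  th <- 0.83
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rotated <- toy
  for (f in 1:2) rotated$coords[f, , ] <- toy$coords[f, , ] %*% rot
  expect_equal(compute_chi1(rotated, 1)$values, compute_chi1(toy, 1)$values,
               tolerance = 1e-9)
})

test_that("ligand distances are minimum atom-pair distances, capped", {
  toy <- toy_system(lig_x = c(3.2, 15))
  ld <- compute_ligand_distances(toy, "resname=LIG", "A:1-2")
  expect_equal(ld$values[, 1], c(3.2, 12))     # 15 A capped at 12
  expect_equal(ld$values[, 2], c(1.8, 10))     # below cap untouched
  unc <- compute_ligand_distances(toy, "resname=LIG", "A:1-2", cap = Inf)
  expect_equal(unc$values[, 1], c(3.2, 15))
  expect_error(compute_ligand_distances(toy, "resname=XXX", "A:1-2"), "ligand")
})

test_that("residence occupancy matches hand enumeration with a strict rule", {
  at <- data.frame(name = c("C1", "C2"), resname = c("LIG", "PRT"),
                   resno = 1:2, chain = "A")
  dists <- c(3.5, 3.9, 4.2, 3.0, 5.1)
  co <- array(0, c(5, 2, 3))
  co[, 2, 1] <- dists
  tr <- trajectory(at, co)
  rep5 <- residence_time(tr, "resname=LIG", "resname=PRT", cutoff = 4)
  expect_equal(rep5$occupancy, 0.6)
  expect_true(rep5$consistent)
  co[, 2, 1] <- 10
  none <- residence_time(trajectory(at, co), "resname=LIG", "resname=PRT")
  expect_equal(none$occupancy, 0)
  expect_false(none$consistent)
  # exactly 50% occupancy is not "consistent" (strictly above 50%)
  co4 <- array(0, c(4, 2, 3))
  co4[, 2, 1] <- c(3, 5, 3, 5)
  half <- residence_time(trajectory(at, co4), "resname=LIG", "resname=PRT")
  expect_equal(half$occupancy, 0.5)
  expect_false(half$consistent)
})

test_that("SASA matches the isolated-sphere closed form and additivity", {
  at1 <- data.frame(name = "C1", resname = "LIG", resno = 1, chain = "A")
  tr1 <- trajectory(at1, array(0, c(1, 1, 3)))
  s1 <- unname(compute_sasa(tr1, "resname=LIG")$values[1, 1])
  expect_equal(s1, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  at2 <- data.frame(name = c("C1", "C2"), resname = "LIG", resno = 1,
                    chain = "A")
  co <- array(0, c(1, 2, 3)); co[1, 2, 1] <- 100
  s2 <- unname(compute_sasa(trajectory(at2, co), "resname=LIG")$values[1, 1])
  expect_equal(s2, 2 * s1, tolerance = 1e-9)
})

test_that("a tightly enclosed atom has zero accessible surface", {
  # central atom caged by 26 overlapping neighbors on a 2 A lattice
  offsets <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)) * 2
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  at <- data.frame(name = "C1", resname = c("LIG", rep("CAG", 26)),
                   resno = c(1L, rep(2L, 26)), chain = "A")
  co <- array(0, c(1, 27, 3))
  co[1, 2:27, ] <- offsets
  s <- unname(compute_sasa(trajectory(at, co), "resname=LIG")$values[1, 1])
  expect_equal(s, 0, tolerance = 1e-8)
})

test_that("SASA agrees with a dense-quadrature oracle on random clusters", {
  set.seed(42)
  for (rep in 1:3) {
    n <- 10
    at <- data.frame(name = sample(c("C1", "N1", "O1", "S1"), n, TRUE),
                     resname = "LIG", resno = 1L, chain = "A")
    co <- array(0, c(1, n, 3))
    co[1, , ] <- matrix(rnorm(3 * n, sd = 2.5), n, 3)
    tr <- trajectory(at, co)
    coarse <- compute_sasa(tr, "resname=LIG", n_points = 960)$values[1, 1]
    dense <- compute_sasa(tr, "resname=LIG", n_points = 10000)$values[1, 1]
    expect_lt(abs(coarse - dense) / dense, 0.02)
  }
})

test_that("unknown elements fall back to a 1.5 A radius with a warning", {
  at <- data.frame(name = "X9", resname = "LIG", resno = 1, chain = "A")
  tr <- trajectory(at, array(0, c(1, 1, 3)))
  expect_warning(s <- compute_sasa(tr, "resname=LIG"), "unknown element")
  expect_equal(unname(s$values[1, 1]), 4 * pi * (1.5 + 1.4)^2,
               tolerance = 0.01)
})
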