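test_that("isolated sphere area matches the analytic value within 0.1%", {
  a <- data.frame(x = 0, y = 0, z = 0, radius = 1.7)
  s <- compute_sasa(a, probe_radius = 1.4, n_points = 960)
  expect_equal(s$per_atom, 4 * pi * 3.1^2, tolerance = 1e-3)
})

test_that("a fully enclosed atom has zero accessible area", {
  shell <- golden_spiral_points(200) * 4.0
  atoms <- rbind(data.frame(x = 0, y = 0, z = 0, radius = 1.7),
                 data.frame(x = shell[, 1], y = shell[, 2], z = shell[, 3],
                            radius = 1.7))
  s <- compute_sasa(atoms, 1.4, 960)
  expect_equal(s$per_atom[1], 0)
})

test_that("two-sphere case matches the closed-form cap area within 2%", {
  # equal spheres, expanded radius R = 3.1, centers d = 3.1 apart:
  # each area = 4*pi*R^2 - 2*pi*R*h with h = R - d/2
  a <- data.frame(x = c(0, 3.1), y = 0, z = 0, radius = 1.7)
  analytic <- 4 * pi * 3.1^2 - 2 * pi * 3.1 * 1.55
  s <- compute_sasa(a, 1.4, 960)
  expect_equal(s$per_atom[1], analytic, tolerance = 0.02)
  expect_equal(s$per_atom[2], analytic, tolerance = 0.02)
})

test_that("two-sphere error shrinks as the point count grows", {
  a <- data.frame(x = c(0, 3.1), y = 0, z = 0, radius = 1.7)
  analytic <- 4 * pi * 3.1^2 - 2 * pi * 3.1 * 1.55
  errs <- vapply(c(96, 240, 960), function(np) {
    abs(compute_sasa(a, 1.4, np)$per_atom[1] - analytic)
  }, numeric(1))
  expect_true(errs[3] < errs[1])
  expect_true(errs[3] < errs[2] + 1e-9)
})

test_that("neighbor-list computation equals the all-pairs oracle exactly", {
  toy <- make_toy_oligomer(n_subunits = 2, surface_positions = c(3, 9),
                           buried_positions = 40, seed = 5)
  prot <- protein_atoms(toy$structure)
  fast <- compute_sasa(prot, 1.4, 240)$per_atom
  slow <- naive_sasa(prot, 1.4, 240)
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("per-residue totals are sums of per-atom areas", {
  toy <- make_toy_oligomer(n_subunits = 2, seed = 6)
  prot <- protein_atoms(toy$structure)
  s <- compute_sasa(prot, 1.4, 240)
  by_res <- residue_sasa(toy$structure, s)
  key <- paste(prot$chain, prot$resno)
  manual <- tapply(s$per_atom, key, sum)
  expect_equal(by_res$area, as.numeric(manual[paste(by_res$chain, by_res$resno)]))
  # mismatched structure is rejected
  s2 <- s; s2$per_atom <- s2$per_atom[-1]
  expect_error(residue_sasa(toy$structure, s2), "match")
})

test_that("removing an atom never decreases any remaining atom's area", {
  toy <- make_toy_oligomer(n_subunits = 1, surface_positions = c(2, 4),
                           buried_positions = 30, seed = 7)
  prot <- protein_atoms(toy$structure)
  prot <- prot[seq_len(min(nrow(prot), 40)), ]  # keep it quick
  full <- compute_sasa(prot, 1.4, 96)$per_atom
  for (drop in c(1L, 10L, 25L)) {
    reduced <- compute_sasa(prot[-drop, ], 1.4, 96)$per_atom
    expect_true(all(reduced >= full[-drop] - 1e-9))
  }
})

test_that("areas are invariant to rigid-body motion", {
  toy <- make_toy_oligomer(n_subunits = 2, seed = 8)
  prot <- protein_atoms(toy$structure)
  base <- compute_sasa(prot, 1.4, 240)$per_atom
  # translation
  shifted <- prot
  shifted$x <- shifted$x + 13.7; shifted$y <- shifted$y - 4.2
  expect_equal(compute_sasa(shifted, 1.4, 240)$per_atom, base,
               tolerance = 1e-6)
  # rotation: the sphere-point lattice has a fixed orientation, so rotating
  # the molecule re-samples the occlusion test and areas agree only to the
  # finite-point sampling resolution (about 1 point's worth of area per
  # atom), not exactly; the total area is much tighter
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(prot[, c("x", "y", "z")]) %*% R
  rotated <- prot
  rotated$x <- xyz[, 1]; rotated$y <- xyz[, 2]; rotated$z <- xyz[, 3]
  rot_area <- compute_sasa(rotated, 1.4, 240)$per_atom
  per_point <- 4 * pi * max(prot$radius + 1.4)^2 / 240
  expect_lt(max(abs(rot_area - base)), 4 * per_point)
  expect_equal(sum(rot_area), sum(base), tolerance = 0.01)
})

test_that("degenerate inputs are rejected or warned about", {
  expect_error(compute_sasa(data.frame(x = 0, y = 0, z = 0, radius = 0)),
               "positive radii")
  dup <- data.frame(x = c(0, 0), y = 0, z = 0, radius = 1.7)
  expect_warning(compute_sasa(dup, 1.4, 96), "duplicate")
})
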