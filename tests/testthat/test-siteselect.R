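make_metrics <- function(...) {
  # rows: list(resno, chain, area, dist)
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(resno = r[[1]], resname = "GLY", chain = r[[2]],
               area = r[[3]], min_ligand_dist = r[[4]])
  }))
}

test_that("ligand distances use the minimum over all ligand copies", {
  # dimer with CAs at (+-30, 0, 0) and one ligand at the origin
  lines <- c(
    "ATOM      1  CA  GLY A   1      30.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY B   1     -30.000   0.000   0.000  1.00  0.00           C",
    "HETATM    3  C5  UAC A 500       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    4  C5  UAC B 501      20.000   0.000   0.000  1.00  0.00           C",
    "END"
  )
  st <- read_structure(write_minimal_pdb(lines))
  sasa <- residue_sasa(st, compute_sasa(protein_atoms(st), 1.4, 96))
  m <- candidate_metrics(st, sasa, select_ligand_atoms(st, "UAC", "C5"))
  # chain A: 30 to origin copy, 10 to the copy at x=20 -> min 10
  expect_equal(m$min_ligand_dist[m$chain == "A"], 10)
  # chain B: 30 vs 50 -> min 30
  expect_equal(m$min_ligand_dist[m$chain == "B"], 30)
  expect_error(candidate_metrics(st, sasa, matrix(numeric(0), 0, 3)),
               "empty")
})

test_that("the all-subunit rule rejects a position failing in one chain", {
  m <- make_metrics(
    list(10, "A", 120, 40), list(10, "B", 120, 40),
    list(10, "C", 120, 40), list(10, "D", 80, 40),
    list(20, "A", 150, 30), list(20, "B", 130, 30),
    list(20, "C", 140, 30), list(20, "D", 110, 30)
  )
  expect_equal(filter_candidates(m, site_criteria()), 20L)
  # strict inequality: exactly at the threshold fails
  m2 <- make_metrics(list(5, "A", 100, 40), list(5, "B", 120, 40))
  expect_equal(filter_candidates(m2, site_criteria()), integer(0))
  m3 <- make_metrics(list(5, "A", 120, 25), list(5, "B", 120, 40))
  expect_equal(filter_candidates(m3, site_criteria()), integer(0))
  expect_equal(filter_candidates(m[0, ], site_criteria()), integer(0))
})

test_that("raising thresholds never enlarges the passing set", {
  toy <- make_toy_oligomer(seed = 21, near_positions = 60)
  rep0 <- site_selection_report(toy$structure, "UAC", n_points = 240)
  for (sasa_min in c(50, 100, 150, 200)) {
    for (lig_min in c(10, 25, 33)) {
      cr <- site_criteria(sasa_min = sasa_min, ligand_min_dist = lig_min)
      p <- filter_candidates(rep0$metrics, cr)
      expect_true(all(p %in% filter_candidates(
        rep0$metrics, site_criteria(sasa_min = 50, ligand_min_dist = 10))))
    }
  }
})

test_that("pair matrix takes minima over all chain combinations", {
  # two positions on a C2 dimer with hand-computed distances
  lines <- c(
    "ATOM      1  CA  GLY A   1       5.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       0.000   9.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY B   1      -5.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY B   2       0.000  -9.000   0.000  1.00  0.00           C",
    "END"
  )
  st <- read_structure(write_minimal_pdb(lines))
  pm <- pairwise_ca_matrix(st, c(1, 2))
  # pairs (1,2): A1-A2 sqrt(25+81), A1-B2 sqrt(25+81), B1-A2, B1-B2 all equal
  expect_equal(pm["1", "2"], sqrt(106))
  expect_equal(pm["2", "1"], sqrt(106))
  # self pairs: A1-B1 = 10, A2-B2 = 18
  expect_equal(pm["1", "1"], 10)
  expect_equal(pm["2", "2"], 18)
})

test_that("single-chain structures give the plain within-chain distance", {
  lines <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       7.250   0.000   0.000  1.00  0.00           C",
    "END"
  )
  st <- read_structure(write_minimal_pdb(lines))
  pm <- pairwise_ca_matrix(st, c(1, 2))
  expect_equal(pm["1", "2"], 7.25)
  expect_equal(pm["1", "1"], Inf)  # no second copy of position 1
})

test_that("subset selection enumerates exhaustively with the SA tie-break", {
  pm <- matrix(c(Inf, 25, 25, 25, Inf, 10, 25, 10, Inf), 3, 3,
               dimnames = list(c(101, 102, 103), c(101, 102, 103)))
  cr <- site_criteria()
  # {101,102} and {101,103} both feasible at size 2; SASA breaks the tie
  m <- make_metrics(list(101, "A", 120, 40), list(102, "A", 150, 40),
                    list(103, "A", 130, 40))
  expect_equal(select_sites(c(101, 102, 103), pm, cr, k = 2, metrics = m),
               c(101L, 102L))
  m2 <- make_metrics(list(101, "A", 120, 40), list(102, "A", 130, 40),
                     list(103, "A", 150, 40))
  expect_equal(select_sites(c(101, 102, 103), pm, cr, k = 2, metrics = m2),
               c(101L, 103L))
  # exact tie -> lexicographically smallest residue numbers
  m3 <- make_metrics(list(101, "A", 120, 40), list(102, "A", 130, 40),
                     list(103, "A", 130, 40))
  expect_equal(select_sites(c(101, 102, 103), pm, cr, k = 2, metrics = m3),
               c(101L, 102L))
  # k = "max" cannot take all three (102-103 too close)
  expect_equal(select_sites(c(101, 102, 103), pm, cr, k = "max", metrics = m),
               c(101L, 102L))
  # singleton and infeasible-k behavior
  expect_equal(select_sites(101, pm[1, 1, drop = FALSE], cr, k = "max"), 101L)
  expect_error(select_sites(c(102, 103), pm[2:3, 2:3], cr, k = 2),
               "largest feasible size is 1")
})

test_that("on a symmetric oligomer equivalent residues share SASA", {
  toy <- make_toy_oligomer(n_subunits = 4, seed = 31)
  rep <- site_selection_report(toy$structure, "UAC", n_points = 240)
  m <- rep$metrics
  for (p in unique(m$resno)) {
    areas <- m$area[m$resno == p]
    expect_equal(max(areas) - min(areas), 0, tolerance = 1e-6 * max(areas, 1))
  }
})

test_that("planted truth is recovered end-to-end on toy oligomers", {
  toy <- make_toy_oligomer(n_subunits = 4, surface_positions = c(5, 8),
                           buried_positions = c(40, 44),
                           near_positions = 60, seed = 3)
  rep <- site_selection_report(toy$structure, "UAC", n_points = 240)
  expect_equal(rep$passing, toy$truth$pass)
  m <- rep$metrics
  for (p in toy$truth$fail_sasa) {
    expect_true(all(m$area[m$resno == p] < 100))
  }
  for (p in toy$truth$fail_ligand) {
    expect_true(all(m$min_ligand_dist[m$resno == p] < 25))
  }
})

test_that("filter and selection agree with brute-force enumeration", {
  # a quick randomized batch here; the full 50-oligomer sweep runs in the
  # acceptance suite
  set.seed(99)
  for (i in 1:8) {
    toy <- tryCatch(
      make_toy_oligomer(
        n_subunits = sample(2:4, 1),
        surface_positions = sort(sample(1:20, sample(1:2, 1))),
        buried_positions = sort(sample(30:50, sample(0:2, 1))),
        ring_radius = runif(1, 11, 15), seed = 1000 + i),
      error = function(e) NULL)
    if (is.null(toy)) next
    rep <- site_selection_report(toy$structure, "UAC", n_points = 96)
    cr <- site_criteria(pair_min_dist = runif(1, 5, 30))
    expect_identical(rep$passing, oracle_filter(rep$metrics, rep$criteria))
    if (length(rep$passing)) {
      pm <- rep$pair_matrix
      expect_identical(
        select_sites(rep$passing, pm, cr, metrics = rep$metrics),
        oracle_select(rep$passing, pm, cr, metrics = rep$metrics))
    }
  }
})
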