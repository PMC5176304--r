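# Independent reference implementations used as oracles. Deliberately naive:
# straight loops, no shared code paths with the package internals beyond the
# deterministic sphere-point set (which both sides must share for the areas
# to be comparable point-for-point).

# All-pairs Shrake-Rupley: every atom tested against every other atom.
naive_sasa <- function(atoms, probe = 1.4, n_points = 960) {
  pts <- golden_spiral_points(n_points)
  r <- atoms$radius + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  out <- numeric(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    keep <- rep(TRUE, n_points)
    for (j in seq_len(nrow(atoms))) {
      if (j == i) next
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      keep <- keep & d2 >= r[j]^2
    }
    out[i] <- 4 * pi * r[i]^2 * mean(keep)
  }
  out
}

# Criterion filter recomputed with explicit loops over positions and chains.
oracle_filter <- function(metrics, criteria) {
  pass <- integer(0)
  for (p in sort(unique(metrics$resno))) {
    rows <- metrics[metrics$resno == p, ]
    ok <- all(rows$area > criteria$sasa_min) &&
      all(rows$min_ligand_dist > criteria$ligand_min_dist)
    if (ok) pass <- c(pass, p)
  }
  pass
}

# Exhaustive subset enumeration by bitmask; same objective and tie rules.
oracle_select <- function(passing, pair_matrix, criteria, k = "max",
                          metrics = NULL) {
  n <- length(passing)
  if (n == 0) return(integer(0))
  lab <- as.character(passing)
  pm <- pair_matrix[lab, lab, drop = FALSE]
  sc <- if (is.null(metrics)) setNames(rep(0, n), lab) else
    tapply(metrics$area, metrics$resno, min)[lab]
  best <- NULL; best_size <- -1; best_score <- -Inf
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (identical(k, "max")) {
      if (length(idx) < best_size) next
    } else if (length(idx) != k) next
    ok <- TRUE
    if (length(idx) >= 2) {
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (a < b && pm[idx[a], idx[b]] < criteria$pair_min_dist) ok <- FALSE
      }
    }
    if (!ok) next
    score <- sum(sc[idx])
    better <- length(idx) > best_size ||
      (length(idx) == best_size && score > best_score + 1e-12) ||
      (length(idx) == best_size && abs(score - best_score) <= 1e-12 &&
         !is.null(best) && lex_less(passing[idx], best))
    if (better) {
      best <- passing[idx]; best_size <- length(idx); best_score <- score
    }
  }
  if (is.null(best)) NULL else sort(best)
}

lex_less <- function(a, b) {
  a <- sort(a); b <- sort(b)
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  length(a) < length(b)
}

# Coarse-to-fine grid search for the Michaelis-Menten parameters.
oracle_mm_grid <- function(rates, s, e0) {
  sse <- function(kcat, km) sum((rates - kcat * e0 * s / (km + s))^2)
  kc <- seq(0.1 * max(rates) / e0, 3 * max(rates) / e0, length.out = 60)
  km <- seq(min(s) / 10, max(s) * 10, length.out = 60)
  for (round in 1:6) {
    grid <- expand.grid(kcat = kc, km = km)
    err <- mapply(sse, grid$kcat, grid$km)
    b <- grid[which.min(err), ]
    wk <- diff(range(kc)) / 8; wm <- diff(range(km)) / 8
    kc <- seq(max(b$kcat - wk, 1e-9), b$kcat + wk, length.out = 30)
    km <- seq(max(b$km - wm, 1e-9), b$km + wm, length.out = 30)
  }
  c(kcat = b$kcat, km = b$km)
}

# Small hand-written PDB fixture text.
minimal_pdb_lines <- function() {
  c(
    "HEADER    SYNTHETIC TEST RECORD",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.759   5.058  -5.301  1.00  0.00           C",
    "ATOM      4  CA AGLY A   2      14.639   7.071  -5.147  0.60  0.00           C",
    "ATOM      5  CA BGLY A   2      14.739   7.171  -5.247  0.40  0.00           C",
    "ATOM      6  H   GLY A   2      14.000   7.000  -5.000  1.00  0.00           H",
    "HETATM    7  C5  UAC A 500       1.000   2.000   3.000  1.00  0.00           C",
    "HETATM    8  O   HOH A 600       9.000   2.000   3.000  1.00  0.00           O",
    "END"
  )
}

write_minimal_pdb <- function(lines = minimal_pdb_lines()) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}
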