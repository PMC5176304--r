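#' Deterministic quasi-uniform sphere points (golden-spiral lattice)
#'
#' Generates `n` points on the unit sphere by the Fibonacci/golden-spiral
#' construction. Fully deterministic: no RNG is involved, so surface areas are
#' reproducible bit-for-bit for a fixed `n`.
#'
#' @param n Number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area by the Shrake-Rupley method
#'
#' For each atom, the van der Waals sphere is expanded by the probe radius and
#' sampled with a deterministic golden-spiral point set; the accessible area
#' is the fraction of points not inside any other atom's expanded sphere,
#' times the expanded-sphere area 4*pi*(r+probe)^2. A grid-based neighbor
#' search keeps the cost near-linear in atom count; it is exact (neighbor
#' cells cover the maximal interaction distance), so results are identical to
#' the all-pairs computation.
#'
#' @param atoms Data frame with columns `x`, `y`, `z`, `radius` (one row per
#'   atom), e.g. `protein_atoms(struct)`. Hetero/ligand atoms are excluded by
#'   the caller: the site-selection workflow computes SASA of the protein
#'   alone so candidate surfaces are not shielded by bound substrate.
#' @param probe_radius Probe sphere radius in Angstrom (water: 1.4).
#' @param n_points Sphere points per atom; 960 is the workflow default.
#' @return Object of class `uox_sasa`: list with `per_atom` (numeric vector,
#'   Angstrom^2, one entry per input row), `probe_radius`, `n_points`.
#' @export
compute_sasa <- function(atoms, probe_radius = 1.4, n_points = 960) {
  stopifnot(nrow(atoms) >= 1, n_points >= 1, probe_radius >= 0)
  if (any(atoms$radius <= 0)) {
    stop("all atoms must have positive radii")
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (anyDuplicated(round(xyz, 6))) {
    warning("duplicate atom coordinates; areas computed anyway")
  }
  r <- atoms$radius + probe_radius
  n <- nrow(xyz)
  pts <- golden_spiral_points(n_points)
  area <- numeric(n)

  # neighbor candidates via cell lists; cell size = max interaction distance
  rmax <- max(r)
  cell <- 2 * rmax
  key <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  keystr <- paste(key[, 1], key[, 2], key[, 3], sep = ",")
  cells <- split(seq_len(n), keystr)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))

  neighbor_idx <- function(i) {
    k <- key[i, ]
    ks <- paste(k[1] + offsets[, 1], k[2] + offsets[, 2], k[3] + offsets[, 3],
                sep = ",")
    cand <- unlist(cells[ks], use.names = FALSE)
    cand <- cand[cand != i]
    if (!length(cand)) return(integer(0))
    d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
      (xyz[cand, 3] - xyz[i, 3])^2
    cand[d2 < (r[i] + r[cand])^2]
  }

  for (i in seq_len(n)) {
    nb <- neighbor_idx(i)
    full <- 4 * pi * r[i]^2
    if (!length(nb)) {
      area[i] <- full
      next
    }
    p <- pts * r[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      idx <- which(exposed)
      d2 <- (p[idx, 1] - xyz[j, 1])^2 + (p[idx, 2] - xyz[j, 2])^2 +
        (p[idx, 3] - xyz[j, 3])^2
      exposed[idx[d2 < r[j]^2]] <- FALSE
    }
    area[i] <- full * sum(exposed) / n_points
  }
  structure(list(per_atom = area, probe_radius = probe_radius,
                 n_points = n_points),
            class = "uox_sasa")
}

#' Total solvent-accessible area per residue and chain
#'
#' Sums per-atom areas over ALL atoms of each residue (backbone plus side
#' chain), per chain: the site-selection criterion is on *total* residue
#' surface area.
#'
#' @param struct A `uox_structure`.
#' @param sasa Result of [compute_sasa()] over `protein_atoms(struct)` (row
#'   order must match).
#' @return Data frame: `chain`, `resno`, `resname`, `area` (Angstrom^2).
#' @export
residue_sasa <- function(struct, sasa) {
  stopifnot(inherits(struct, "uox_structure"), inherits(sasa, "uox_sasa"))
  prot <- protein_atoms(struct)
  if (length(sasa$per_atom) != nrow(prot)) {
    stop("SASA result does not match the structure's protein atoms")
  }
  key <- paste(prot$chain, prot$resno, sep = "\r")
  tot <- tapply(sasa$per_atom, key, sum)
  first <- !duplicated(key)
  out <- data.frame(chain = prot$chain[first], resno = prot$resno[first],
                    resname = prot$resname[first],
                    area = as.numeric(tot[key[first]]))
  out[order(out$chain, out$resno), , drop = FALSE]
}
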