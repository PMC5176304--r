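# Run code under a temporary RNG seed, restoring global RNG state afterwards:
# generators are pure functions of (spec, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic C-n-symmetric toy oligomer with planted surface and buried sites
#'
#' Builds a small homo-oligomer for exercising the whole site-selection
#' stack offline, with known ground truth. Each subunit is the same rigid
#' unit rotated about the z axis:
#'
#' * *surface* pseudo-residues (N/CA/C triads) sit on an upper ring, fully
#'   exposed and more than 25 Angstrom from every ligand copy - they must
#'   pass both the SASA and the active-site-distance criteria;
#' * *buried* pseudo-residues sit in the body of the subunit, each enclosed
#'   by a tight spherical cage of carbon blocker atoms so their accessible
#'   area is (near) zero, and within a few Angstrom of the subunit's ligand
#'   copy - they must fail both criteria;
#' * optional *exposed-but-near* pseudo-residues are solvent exposed yet
#'   close to a ligand copy - they must fail the distance criterion only;
#' * one single-atom ligand copy (hetero residue `UAC`, atom `C5`) per
#'   subunit stands in for the bound substrate.
#'
#' Cage residues carry no CA atom, so the candidate scan skips them by
#' construction (they are scaffolding, not sites).
#'
#' @param n_subunits Number of subunits (default 4).
#' @param surface_positions Residue numbers of planted surface sites.
#' @param buried_positions Residue numbers of planted buried sites.
#' @param near_positions Residue numbers of planted exposed-but-near sites
#'   (default none).
#' @param ring_radius Radius of the surface ring, Angstrom.
#' @param ligand_offset Radial distance of each ligand copy from the symmetry
#'   axis, Angstrom.
#' @param seed Integer seed for the (small) random placement jitter.
#' @return List: `structure` (a `uox_structure`), `truth` (list with
#'   `pass`, `fail_sasa`, `fail_ligand` position vectors),
#'   `ligand_resname`, `ligand_atom`.
#' @export
make_toy_oligomer <- function(n_subunits = 4,
                              surface_positions = c(5, 8),
                              buried_positions = c(40, 44),
                              near_positions = integer(0),
                              ring_radius = 14,
                              ligand_offset = 6,
                              seed = 1) {
  stopifnot(n_subunits >= 1, ring_radius > 4, ligand_offset > 0)
  if (length(intersect(surface_positions, buried_positions)) ||
      length(intersect(surface_positions, near_positions)) ||
      length(intersect(buried_positions, near_positions))) {
    stop("planted position sets must be disjoint")
  }
  surface_positions <- sort(as.integer(surface_positions))
  buried_positions <- sort(as.integer(buried_positions))
  near_positions <- sort(as.integer(near_positions))

  rot <- function(m, theta) {
    R <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3)
    m %*% t(R)
  }
  triad <- function(center) {
    rbind(N = center + c(0, 0, 1.5), CA = center, C = center - c(0, 0, 1.5))
  }

  base <- with_seed(seed, {
    ns <- length(surface_positions)
    # surface ring: evenly spread inside this subunit's wedge plus a small
    # seeded jitter; wedge width shrinks with n_subunits so copies never
    # collide across subunits
    wedge <- 2 * pi / n_subunits
    ang <- if (ns) {
      (seq_len(ns) - 0.5) / ns * wedge * 0.72 +
        stats::runif(ns, -0.015, 0.015) * wedge
    } else numeric(0)
    nb <- length(buried_positions)
    bang <- if (nb) (seq_len(nb) - 0.5) / max(nb, 1) * wedge * 0.4 +
      stats::runif(nb, -0.02, 0.02) else numeric(0)
    nn <- length(near_positions)
    nang <- if (nn) (seq_len(nn) - 0.5) / max(nn, 1) * wedge * 0.6 +
      stats::runif(nn, -0.02, 0.02) else numeric(0)
    list(ang = ang, bang = bang, nang = nang)
  })

  cage_points <- 120
  cage_radius <- 4.5
  cage <- golden_spiral_points(cage_points) * cage_radius

  rows <- list()
  add_atom <- function(name, resname, chain, resno, xyz, het = FALSE,
                       element = substr(name, 1, 1)) {
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = 0L, name = name, alt = "", resname = resname, chain = chain,
      resno = resno, ins = "", x = xyz[1], y = xyz[2], z = xyz[3], occ = 1,
      element = element, is_hetero = het, stringsAsFactors = FALSE)
  }

  chains <- LETTERS[seq_len(n_subunits)]
  for (k in seq_len(n_subunits)) {
    th <- 2 * pi * (k - 1) / n_subunits
    ch <- chains[k]
    # surface sites: upper ring, far from every ligand copy
    for (i in seq_along(surface_positions)) {
      ctr <- c(ring_radius * cos(base$ang[i]), ring_radius * sin(base$ang[i]), 26)
      tri <- rot(triad(ctr), th)
      add_atom("N", "GLY", ch, surface_positions[i], tri[1, ], element = "N")
      add_atom("CA", "GLY", ch, surface_positions[i], tri[2, ], element = "C")
      add_atom("C", "GLY", ch, surface_positions[i], tri[3, ], element = "C")
    }
    # exposed-but-near sites: mid-height, close to this subunit's ligand
    for (i in seq_along(near_positions)) {
      ctr <- c((ligand_offset + 4) * cos(base$nang[i]),
               (ligand_offset + 4) * sin(base$nang[i]), 4)
      tri <- rot(triad(ctr), th)
      add_atom("N", "GLY", ch, near_positions[i], tri[1, ], element = "N")
      add_atom("CA", "GLY", ch, near_positions[i], tri[2, ], element = "C")
      add_atom("C", "GLY", ch, near_positions[i], tri[3, ], element = "C")
    }
    # buried sites + blocker cages, low in the body, near the ligand
    for (i in seq_along(buried_positions)) {
      ctr <- c(10 * cos(base$bang[i]), 10 * sin(base$bang[i]), -6)
      tri <- rot(triad(ctr), th)
      add_atom("N", "GLY", ch, buried_positions[i], tri[1, ], element = "N")
      add_atom("CA", "GLY", ch, buried_positions[i], tri[2, ], element = "C")
      add_atom("C", "GLY", ch, buried_positions[i], tri[3, ], element = "C")
      cg <- rot(sweep(cage, 2, ctr, "+"), th)
      for (j in seq_len(cage_points)) {
        add_atom(sprintf("D%03d", j), "BLK", ch, 900L + i, cg[j, ],
                 element = "C")
      }
    }
    # one ligand copy per subunit
    lig <- rot(matrix(c(ligand_offset, 0, -6), 1, 3), th)
    add_atom("C5", "UAC", ch, 500L, lig[1, ], het = TRUE, element = "C")
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  radii <- vdw_radii("default")
  atoms$radius <- unname(ifelse(atoms$element %in% names(radii),
                                radii[atoms$element], attr(radii, "fallback")))
  ord <- order(atoms$is_hetero, atoms$chain, atoms$resno, atoms$serial)
  atoms <- atoms[ord, , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL

  # geometric feasibility: planted surface copies must not crowd each other
  sca <- atoms[atoms$name == "CA" & atoms$resno %in% surface_positions, ]
  if (nrow(sca) > 1) {
    dmin <- min(stats::dist(as.matrix(sca[, c("x", "y", "z")])))
    # expanded spheres (r + probe = 3.1 A) touch below 6.2 A; keep a margin
    if (dmin < 6.8) {
      stop("geometrically infeasible: surface sites only ",
           round(dmin, 1), " Angstrom apart; reduce the position count or ",
           "enlarge ring_radius")
    }
  }

  struct <- structure(list(atoms = atoms, source_id = "toy_oligomer",
                           radii_set = "default"),
                      class = "uox_structure")
  list(structure = struct,
       truth = list(pass = surface_positions,
                    fail_sasa = buried_positions,
                    fail_ligand = sort(c(buried_positions, near_positions))),
       ligand_resname = "UAC", ligand_atom = "C5")
}

#' Synthetic substrate-depletion progress curves
#'
#' Integrates the Michaelis-Menten depletion law
#' `dS/dt = -kcat * e0 * S / (km + S)` with fixed-step 4th-order
#' Runge-Kutta on a 1-second grid, samples the trace on the assay's
#' `dt`-second grid, converts substrate to absorbance at 292 nm via the
#' molar absorptivity and path length, and optionally adds Gaussian
#' absorbance noise.
#'
#' @param kcat Turnover number, uM UA / s / uM enzyme.
#' @param km Michaelis constant, uM.
#' @param e0 Enzyme concentration (monomer-equivalent), uM.
#' @param s0_list Initial substrate concentrations, uM (e.g.
#'   [dilution_series()]).
#' @param dt Sampling interval, seconds (default 20).
#' @param duration Total assay time, seconds (default 600, i.e. 10 min).
#' @param noise_sd Gaussian noise s.d. on absorbance units (0 = noise free).
#' @param seed Seed for the noise.
#' @param epsilon292 Molar absorptivity, 1/(M cm).
#' @param path_length Path, cm.
#' @return List of [progress_curve()] objects, one per `s0`.
#' @export
make_progress_curves <- function(kcat, km, e0, s0_list, dt = 20,
                                 duration = 600, noise_sd = 0, seed = 1,
                                 epsilon292 = EPSILON292_DEFAULT,
                                 path_length = 1) {
  stopifnot(kcat > 0, km > 0, e0 > 0, all(s0_list > 0), dt > 0,
            duration >= 3 * dt, noise_sd >= 0)
  grid <- seq(0, duration, by = 1)
  sample_t <- seq(0, duration, by = dt)
  curves <- lapply(seq_along(s0_list), function(i) {
    s0 <- s0_list[i]
    sol <- deSolve::ode(
      y = c(S = s0), times = grid,
      func = function(t, y, p) list(-kcat * e0 * y[1] / (km + y[1])),
      parms = NULL, method = "rk4"
    )
    s <- sol[match(sample_t, sol[, "time"]), "S"]
    a <- s * 1e-6 * epsilon292 * path_length
    if (noise_sd > 0) {
      a <- with_seed(seed + i, a + stats::rnorm(length(a), 0, noise_sd))
    }
    progress_curve(sample_t, a, s0 = s0, e0 = e0, path_length = path_length)
  })
  names(curves) <- sprintf("s0_%g", s0_list)
  curves
}

#' Synthetic serum concentration-time profile
#'
#' IV: `c(t) = c0 * 2^(-t / half_life)`. SC: a one-absorption/one-elimination
#' shape `c(t) = A * (exp(-ke t) - exp(-ka t))` with `ke = ln2 / half_life`,
#' scaled so the peak equals `cmax`. Optional multiplicative lognormal noise
#' with coefficient of variation `noise_cv`.
#'
#' @param half_life Elimination (terminal) half-life, in the same time unit
#'   as `times`.
#' @param times Sampling times.
#' @param dose Dose, mg/kg (carried into the profile).
#' @param route `"IV"` or `"SC"`.
#' @param c0 Concentration at time zero (IV).
#' @param cmax Peak concentration (SC).
#' @param ka Absorption rate constant (SC), 1/time-unit; should be much
#'   larger than `ln2/half_life` for a clean terminal phase.
#' @param noise_cv Lognormal noise CV (0 = noise free).
#' @param seed Seed for the noise.
#' @return A [pk_profile()].
#' @export
make_pk_profile <- function(half_life, times, dose, route = c("IV", "SC"),
                            c0 = NULL, cmax = NULL, ka = NULL,
                            noise_cv = 0, seed = 1) {
  route <- match.arg(route)
  stopifnot(half_life > 0, all(times >= 0), noise_cv >= 0)
  ke <- log(2) / half_life
  if (route == "IV") {
    if (is.null(c0)) stop("IV profiles need c0")
    conc <- c0 * 2^(-times / half_life)
  } else {
    if (is.null(cmax)) stop("SC profiles need cmax")
    if (is.null(ka)) ka <- 50 * ke
    stopifnot(ka > ke)
    shape <- function(t) exp(-ke * t) - exp(-ka * t)
    tmax <- log(ka / ke) / (ka - ke)
    conc <- cmax * shape(times) / shape(tmax)
  }
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    conc <- with_seed(seed,
      conc * stats::rlnorm(length(conc), -sdlog^2 / 2, sdlog))
  }
  pk_profile(times, conc, dose = dose, route = route)
}

#' Synthetic replicate PBMC proliferation counts for a donor panel
#'
#' Reference (untreated) well counts are negative binomial with mean
#' `baseline_mean` and the given dispersion (variance = mu + dispersion *
#' mu^2; overdispersed counts are the realistic null for per-well
#' proliferating-cell counts); treated wells share the dispersion with mean
#' `baseline_mean * true_si`. `dispersion = 0` degenerates to Poisson.
#'
#' @param baseline_mean Mean untreated count per well (> 0).
#' @param true_si True stimulation index planted in the treated condition.
#' @param n_replicates Wells per condition per donor (default 8).
#' @param dispersion Negative-binomial dispersion (default 0.1).
#' @param n_donors Number of donors.
#' @param seed Integer seed.
#' @return List of length `n_donors`; each element a list with `reference`
#'   and `treated` [donor_wells()] objects.
#' @export
make_pbmc_counts <- function(baseline_mean, true_si, n_replicates = 8,
                             dispersion = 0.1, n_donors = 1, seed = 1) {
  stopifnot(baseline_mean > 0, true_si > 0, n_replicates >= 2,
            dispersion >= 0, n_donors >= 1)
  rcounts <- function(n, mu) {
    if (dispersion < 1e-12) stats::rpois(n, mu)
    else stats::rnbinom(n, size = 1 / dispersion, mu = mu)
  }
  with_seed(seed, {
    lapply(seq_len(n_donors), function(d) {
      id <- sprintf("donor%03d", d)
      list(
        reference = donor_wells(id, "buffer",
                                rcounts(n_replicates, baseline_mean)),
        treated = donor_wells(id, "test",
                              rcounts(n_replicates, baseline_mean * true_si))
      )
    })
  })
}
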