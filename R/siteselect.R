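#' Criteria for cysteine substitution / conjugation sites
#'
#' The three structure-based criteria for nominating PEGylation sites on a
#' homo-oligomer: the residue must be solvent exposed (total SASA strictly
#' greater than `sasa_min` in every subunit), far from every copy of the
#' active site (alpha-carbon to ligand-anchor distance strictly greater than
#' `ligand_min_dist` in every subunit), and selected sites must be mutually
#' well separated (minimum cross-oligomer alpha-carbon pair distance at least
#' `pair_min_dist`).
#'
#' @param sasa_min Minimum total residue SASA, Angstrom^2 (strict >).
#' @param ligand_min_dist Minimum CA-to-ligand-atom distance, Angstrom
#'   (strict >).
#' @param pair_min_dist Minimum pairwise CA-CA separation among selected
#'   sites, Angstrom (>=).
#' @param require_all_subunits If `TRUE` (default), the SASA and ligand
#'   criteria must hold in every subunit.
#' @return A list of class `uox_criteria`.
#' @export
site_criteria <- function(sasa_min = 100, ligand_min_dist = 25,
                          pair_min_dist = 19.5, require_all_subunits = TRUE) {
  stopifnot(sasa_min > 0, ligand_min_dist > 0, pair_min_dist > 0)
  structure(list(sasa_min = sasa_min, ligand_min_dist = ligand_min_dist,
                 pair_min_dist = pair_min_dist,
                 require_all_subunits = require_all_subunits),
            class = "uox_criteria")
}

#' Per-position candidate metrics across all subunits
#'
#' For every residue position shared by all chains, collects the total SASA
#' in each subunit and the minimum distance from that subunit's alpha carbon
#' to any ligand anchor point (e.g. the C5 atom of each bound uric-acid
#' copy). Positions without an alpha carbon in some chain are excluded and
#' listed in the `skipped_no_ca` attribute.
#'
#' @param struct A `uox_structure`.
#' @param sasa_by_residue Result of [residue_sasa()].
#' @param ligand_points Matrix of ligand anchor coordinates (rows = copies,
#'   columns x,y,z); must be non-empty.
#' @return Data frame with one row per (position, chain): `resno`, `resname`,
#'   `chain`, `area`, `min_ligand_dist`.
#' @export
candidate_metrics <- function(struct, sasa_by_residue, ligand_points) {
  if (is.null(dim(ligand_points)) || nrow(ligand_points) == 0) {
    stop("ligand_points is empty: no active-site anchors to measure against")
  }
  eq <- map_equivalent_residues(struct)
  if (nrow(eq) == 0) stop("no residue positions shared by all chains")
  chains <- protein_chains(struct)
  prot <- protein_atoms(struct)
  ca <- prot[prot$name == "CA", ]
  have_ca <- vapply(eq$resno, function(p) {
    all(vapply(chains, function(ch) any(ca$chain == ch & ca$resno == p),
               logical(1)))
  }, logical(1))
  skipped <- eq$resno[!have_ca]
  eq <- eq[have_ca, , drop = FALSE]
  cc <- ca_coordinates(struct, eq$resno)
  lig <- as.matrix(ligand_points)
  rows <- lapply(chains, function(ch) {
    m <- cc[[ch]]
    # distance from each CA to each ligand copy; keep the minimum
    d <- vapply(seq_len(nrow(lig)), function(k) {
      sqrt((m[, 1] - lig[k, 1])^2 + (m[, 2] - lig[k, 2])^2 +
             (m[, 3] - lig[k, 3])^2)
    }, numeric(nrow(m)))
    d <- matrix(d, nrow = nrow(m))
    key <- paste(ch, eq$resno, sep = "\r")
    sas <- sasa_by_residue$area[match(key, paste(sasa_by_residue$chain,
                                                 sasa_by_residue$resno,
                                                 sep = "\r"))]
    data.frame(resno = eq$resno, resname = eq$resname, chain = ch,
               area = sas, min_ligand_dist = apply(d, 1, min))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$resno, out$chain), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_no_ca") <- skipped
  out
}

#' Filter candidate positions by the exposure and active-site criteria
#'
#' A position passes iff its total SASA is strictly greater than
#' `criteria$sasa_min` in every subunit AND its minimum CA-ligand distance is
#' strictly greater than `criteria$ligand_min_dist` in every subunit (the
#' all-subunit requirement; with `require_all_subunits = FALSE`, passing in
#' any one subunit suffices).
#'
#' @param metrics Result of [candidate_metrics()].
#' @param criteria A [site_criteria()] object.
#' @return Sorted integer vector of passing residue positions.
#' @export
filter_candidates <- function(metrics, criteria = site_criteria()) {
  stopifnot(inherits(criteria, "uox_criteria"))
  if (nrow(metrics) == 0) return(integer(0))
  ok <- metrics$area > criteria$sasa_min &
    metrics$min_ligand_dist > criteria$ligand_min_dist
  agg <- if (criteria$require_all_subunits) all else any
  pass <- tapply(ok, metrics$resno, agg)
  sort(as.integer(names(pass)[pass]))
}

#' Cross-oligomer alpha-carbon distance matrix for a position set
#'
#' For each unordered pair of positions (i, j), the minimum CA-CA distance
#' over ALL chain combinations (same chain and different chains): a PEG
#' clash is a whole-oligomer constraint, so intra- and inter-subunit
#' distances both count. The diagonal holds the self-pair distance: the
#' minimum distance between copies of the same position on distinct chains
#' (reported as a diagnostic; it does not reject sites, since every copy of
#' a chosen site gets conjugated).
#'
#' @param struct A `uox_structure`.
#' @param positions Integer residue positions (present, with CA, in all
#'   chains).
#' @return Symmetric matrix (Angstrom) with dimnames = positions; diagonal =
#'   self-pair distance (`Inf` for a single-chain structure).
#' @export
pairwise_ca_matrix <- function(struct, positions) {
  positions <- sort(unique(as.integer(positions)))
  cc <- ca_coordinates(struct, positions)
  chains <- names(cc)
  npos <- length(positions)
  # stack all copies: row per (chain, position)
  coords <- do.call(rbind, cc)
  pos_of <- rep(positions, times = length(chains))
  chain_of <- rep(chains, each = npos)
  dall <- as.matrix(stats::dist(coords))
  m <- matrix(Inf, npos, npos, dimnames = list(positions, positions))
  for (i in seq_len(npos)) {
    for (j in seq_len(npos)) {
      sel_i <- pos_of == positions[i]
      sel_j <- pos_of == positions[j]
      d <- dall[sel_i, sel_j, drop = FALSE]
      if (i == j) {
        # distinct-chain copies only
        same <- outer(chain_of[sel_i], chain_of[sel_j], "==")
        d[same] <- Inf
      }
      m[i, j] <- min(d)
    }
  }
  m
}

#' Select a mutually well-separated subset of passing sites
#'
#' Exhaustively enumerates subsets of the passing positions and returns the
#' feasible subset (every pairwise cross-oligomer distance at least
#' `criteria$pair_min_dist`) of the requested size. Among equal-size feasible
#' subsets the one maximizing the summed per-position minimum-over-chains
#' SASA wins; any remaining tie goes to the lexicographically smallest
#' residue-number vector. Candidate counts are small (order 10), so
#' exhaustive search is exact and instant.
#'
#' @param passing Integer vector of positions that passed
#'   [filter_candidates()].
#' @param pair_matrix Result of [pairwise_ca_matrix()] covering `passing`.
#' @param criteria A [site_criteria()] object (uses `pair_min_dist`).
#' @param k Subset size, or `"max"` for the largest feasible subset.
#' @param metrics Optional [candidate_metrics()] result used for the SASA
#'   tie-break; without it ties fall through to residue-number order.
#' @return Sorted integer vector of selected positions.
#' @export
select_sites <- function(passing, pair_matrix, criteria = site_criteria(),
                         k = "max", metrics = NULL) {
  stopifnot(inherits(criteria, "uox_criteria"))
  passing <- sort(unique(as.integer(passing)))
  n <- length(passing)
  if (n == 0) {
    if (identical(k, "max")) return(integer(0))
    stop("no feasible subset of size ", k, "; largest feasible size is 0")
  }
  lab <- as.character(passing)
  pm <- pair_matrix[lab, lab, drop = FALSE]
  min_sasa <- if (is.null(metrics)) {
    stats::setNames(rep(0, n), lab)
  } else {
    tapply(metrics$area, metrics$resno, min)[lab]
  }
  feasible <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    sub <- pm[idx, idx]
    all(sub[upper.tri(sub)] >= criteria$pair_min_dist)
  }
  best_of_size <- function(sz) {
    if (sz == 0) return(integer(0))
    combs <- utils::combn(n, sz, simplify = FALSE)
    best <- NULL
    best_score <- -Inf
    for (idx in combs) {
      if (!feasible(idx)) next
      sc <- sum(min_sasa[idx])
      if (sc > best_score + 1e-12) {
        best <- idx
        best_score <- sc
      }
      # exact tie: keep lexicographically smallest (combn enumerates in
      # lexicographic order, so the first winner already is)
    }
    if (is.null(best)) NULL else passing[best]
  }
  if (identical(k, "max")) {
    for (sz in n:1) {
      res <- best_of_size(sz)
      if (!is.null(res)) return(sort(res))
    }
    return(integer(0))
  }
  k <- as.integer(k)
  stopifnot(k >= 1)
  if (k > n) stop("k = ", k, " exceeds the number of passing positions (", n, ")")
  res <- best_of_size(k)
  if (is.null(res)) {
    largest <- 0L
    for (sz in seq_len(k - 1)) {
      if (!is.null(best_of_size(sz))) largest <- sz
    }
    stop("no feasible subset of size ", k, "; largest feasible size is ", largest)
  }
  sort(res)
}

#' Full site-selection report for an oligomeric structure
#'
#' Runs the whole chain: SASA over protein atoms only (the bound ligand never
#' shields a candidate surface, unless `occlude_hetero = TRUE`), per-residue
#' totals, candidate metrics against the ligand anchors, criterion filtering,
#' the cross-oligomer pair matrix, and the subset selection.
#'
#' @param struct A `uox_structure`.
#' @param ligand_resname,ligand_atom Identify the ligand anchor atom (e.g.
#'   the uric-acid hetero code and `"C5"`).
#' @param criteria A [site_criteria()] object.
#' @param k Subset size for [select_sites()].
#' @param n_points,probe_radius Shrake-Rupley settings.
#' @param occlude_hetero If `TRUE`, hetero atoms occlude the protein surface
#'   during SASA (default `FALSE`).
#' @return List of class `uox_site_report`: `criteria`, `settings`, `metrics`,
#'   `passing`, `pair_matrix`, `self_pair`, `selected`.
#' @export
site_selection_report <- function(struct, ligand_resname, ligand_atom = "C5",
                                  criteria = site_criteria(), k = "max",
                                  n_points = 960, probe_radius = 1.4,
                                  occlude_hetero = FALSE) {
  prot <- protein_atoms(struct)
  occl <- if (occlude_hetero) struct$atoms else prot
  sasa <- compute_sasa(occl, probe_radius = probe_radius, n_points = n_points)
  if (occlude_hetero) {
    sasa$per_atom <- sasa$per_atom[!struct$atoms$is_hetero]
  }
  by_res <- residue_sasa(struct, sasa)
  lig <- select_ligand_atoms(struct, ligand_resname, ligand_atom)
  metrics <- candidate_metrics(struct, by_res, lig)
  passing <- filter_candidates(metrics, criteria)
  pm <- if (length(passing)) pairwise_ca_matrix(struct, passing) else
    matrix(numeric(0), 0, 0)
  selected <- if (length(passing)) {
    select_sites(passing, pm, criteria, k = k, metrics = metrics)
  } else integer(0)
  structure(list(
    criteria = criteria,
    settings = list(n_points = n_points, probe_radius = probe_radius,
                    radii_set = struct$radii_set,
                    occlude_hetero = occlude_hetero,
                    ligand_resname = ligand_resname, ligand_atom = ligand_atom),
    metrics = metrics, passing = passing, pair_matrix = pm,
    self_pair = if (length(passing)) diag(pm) else numeric(0),
    selected = selected
  ), class = "uox_site_report")
}
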