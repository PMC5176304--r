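#' Van der Waals radii sets
#'
#' Element-based van der Waals radii (in Angstrom) used to expand atoms before
#' surface-area integration. Two sets are shipped because published SASA
#' values are sensitive to the radii convention:
#' `"default"` (C 1.70, N 1.55, O 1.52, S 1.80, fallback 1.70) and
#' `"chothia"` (C 1.87, N 1.65, O 1.40, S 1.85, fallback 1.80).
#'
#' @param set Name of the radii set, `"default"` or `"chothia"`.
#' @return Named numeric vector of radii keyed by element symbol, with an
#'   attribute `fallback` giving the radius used for unlisted elements and an
#'   attribute `name` recording the set, so every downstream report can stamp
#'   which convention produced it.
#' @export
vdw_radii <- function(set = c("default", "chothia")) {
  set <- match.arg(set)
  r <- switch(set,
    default = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20),
    chothia = c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90, H = 1.00)
  )
  attr(r, "fallback") <- if (set == "default") 1.70 else 1.80
  attr(r, "name") <- set
  r
}

#' Read a PDB coordinate file into a validated structure model
#'
#' Parses fixed-column PDB records (via the bio3d reader) and applies the
#' conventions used throughout the site-selection workflow: hydrogens and
#' waters (HOH/WAT) are always dropped, exactly one alternate-location
#' conformer is kept per atom, ATOM records become protein chains and
#' non-water HETATM records become ligand groups.
#'
#' @param path Path to a PDB-format file.
#' @param altloc_policy How to resolve alternate locations. `"occupancy"`
#'   (default) keeps the conformer with the highest occupancy, breaking ties
#'   by alphabetically first altloc code; `"first"` keeps the alphabetically
#'   first altloc code unconditionally.
#' @param radii_set Radii set name passed to [vdw_radii()]; radii are assigned
#'   to every atom post-parse.
#' @return An object of class `uox_structure`: a list with `atoms` (data frame
#'   of all retained atoms: `serial`, `name`, `alt`, `resname`, `chain`,
#'   `resno`, `ins`, `x`, `y`, `z`, `occ`, `element`, `is_hetero`, `radius`),
#'   `source_id`, and `radii_set`.
#' @export
read_structure <- function(path, altloc_policy = c("occupancy", "first"),
                           radii_set = "default") {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) {
    stop("PDB file not found: ", path)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  if (!any(at$type == "ATOM")) {
    stop("no ATOM records in ", path)
  }
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    resname = at$resid,
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = at$resno,
    ins = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     element_from_name(at$elety), toupper(at$elesy)),
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in ", path)
  }
  atoms <- atoms[atoms$element != "H" & atoms$element != "D", , drop = FALSE]
  atoms <- atoms[!(atoms$resname %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  atoms <- resolve_altlocs(atoms, altloc_policy)
  if (!any(!atoms$is_hetero)) {
    stop("no protein atoms remain after filtering in ", path)
  }
  radii <- vdw_radii(radii_set)
  fallback <- attr(radii, "fallback")
  atoms$radius <- unname(ifelse(atoms$element %in% names(radii),
                                radii[atoms$element], fallback))
  rownames(atoms) <- NULL
  ord <- order(atoms$is_hetero, atoms$chain, atoms$resno, atoms$ins, atoms$serial)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, source_id = basename(path),
         radii_set = attr(radii, "name")),
    class = "uox_structure"
  )
}

# PDB v2 atom-name convention: element in columns 13-14 of the record, i.e.
# the first character of a left-justified 4-char name (or the second when the
# first is a digit, as in "1HB1").
element_from_name <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "SE"),
         two, one)
}

# Keep exactly one conformer per (chain, resno, ins, resname, atom name).
resolve_altlocs <- function(atoms, policy) {
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$resname, atoms$name,
               sep = "\r")
  if (!anyDuplicated(key)) {
    return(atoms)
  }
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    sub <- atoms[idx, ]
    if (policy == "occupancy") {
      best <- idx[sub$occ == max(sub$occ)]
      if (length(best) > 1L) {
        best <- best[order(atoms$alt[best])][1L]
      }
      best
    } else {
      idx[order(sub$alt)][1L]
    }
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Write a structure back to PDB fixed-column text
#'
#' Emits canonical 80-column ATOM/HETATM records (coordinates to 3 decimals)
#' followed by END. Used for the parse/write round-trip guarantee and to
#' export synthetic oligomers.
#'
#' @param struct A `uox_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path) {
  stopifnot(inherits(struct, "uox_structure"))
  a <- struct$atoms
  rec <- ifelse(a$is_hetero, "HETATM", "ATOM  ")
  # atom names: 1-3 char names start in column 14 by convention
  nm <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  lines <- sprintf("%6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, a$serial %% 100000L, nm,
                   ifelse(a$alt == "", " ", a$alt),
                   a$resname, a$chain, a$resno,
                   ifelse(a$ins == "", " ", a$ins),
                   a$x, a$y, a$z, a$occ, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Extract protein atoms from a structure
#' @param struct A `uox_structure`.
#' @return Data frame of non-hetero atoms.
#' @export
protein_atoms <- function(struct) {
  stopifnot(inherits(struct, "uox_structure"))
  struct$atoms[!struct$atoms$is_hetero, , drop = FALSE]
}

#' Chain identifiers of the protein component
#' @param struct A `uox_structure`.
#' @return Character vector of chain ids, sorted.
#' @export
protein_chains <- function(struct) {
  sort(unique(protein_atoms(struct)$chain))
}

#' Select ligand atoms by residue and atom name
#'
#' Returns one 3D point per ligand copy that carries the named atom, e.g. the
#' C5 atom of each bound uric-acid molecule in a uricase tetramer. Order
#' follows chain then residue number. An empty result is valid (downstream
#' distance criteria reject it).
#'
#' @param struct A `uox_structure`.
#' @param residue_name 3-letter hetero residue code of the ligand.
#' @param atom_name Atom name to pick from each ligand copy.
#' @return Matrix with one row per matching ligand copy and columns x, y, z;
#'   row names identify chain/residue of each copy.
#' @export
select_ligand_atoms <- function(struct, residue_name, atom_name) {
  stopifnot(inherits(struct, "uox_structure"))
  a <- struct$atoms
  sel <- a$is_hetero & a$resname == residue_name & a$name == atom_name
  m <- as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
  rownames(m) <- if (any(sel)) paste0(a$chain[sel], a$resno[sel]) else NULL
  m
}

#' Map equivalent residue positions across subunits
#'
#' Establishes the residue-number correspondence between the chains of a
#' homo-oligomer. Only positions present in every chain are kept; positions
#' missing from any chain are reported in the `skipped` attribute. Chains
#' whose residue names disagree at a shared number are an error (the chains
#' are expected to be identical copies; no alignment is attempted).
#'
#' @param struct A `uox_structure`.
#' @return Data frame with one row per shared position: `resno`, `resname`,
#'   and attribute `skipped` (integer vector of excluded positions).
#' @export
map_equivalent_residues <- function(struct) {
  prot <- protein_atoms(struct)
  chains <- protein_chains(struct)
  per_chain <- lapply(chains, function(ch) {
    sub <- prot[prot$chain == ch, ]
    u <- !duplicated(sub$resno)
    data.frame(resno = sub$resno[u], resname = sub$resname[u])
  })
  shared <- Reduce(intersect, lapply(per_chain, function(d) d$resno))
  all_pos <- sort(unique(unlist(lapply(per_chain, function(d) d$resno))))
  skipped <- setdiff(all_pos, shared)
  shared <- sort(shared)
  names_by_chain <- vapply(per_chain, function(d) {
    d$resname[match(shared, d$resno)]
  }, character(length(shared)))
  names_by_chain <- matrix(names_by_chain, nrow = length(shared))
  bad <- which(apply(names_by_chain, 1L, function(r) length(unique(r)) > 1L))
  if (length(bad)) {
    stop("residue name mismatch across chains at position(s): ",
         paste(shared[bad], collapse = ", "))
  }
  out <- data.frame(resno = shared, resname = names_by_chain[, 1L])
  attr(out, "skipped") <- skipped
  out
}

#' Alpha-carbon coordinates for given positions on every chain
#'
#' @param struct A `uox_structure`.
#' @param positions Integer residue numbers; must have a CA atom in every
#'   protein chain.
#' @return List keyed by chain id; each element a matrix (rows = positions,
#'   in the order given, columns x,y,z).
#' @export
ca_coordinates <- function(struct, positions) {
  prot <- protein_atoms(struct)
  chains <- protein_chains(struct)
  ca <- prot[prot$name == "CA", ]
  out <- lapply(chains, function(ch) {
    sub <- ca[ca$chain == ch, ]
    idx <- match(positions, sub$resno)
    if (anyNA(idx)) {
      stop("position(s) without a CA atom in chain ", ch, ": ",
           paste(positions[is.na(idx)], collapse = ", "))
    }
    m <- as.matrix(sub[idx, c("x", "y", "z"), drop = FALSE])
    rownames(m) <- positions
    m
  })
  names(out) <- chains
  out
}
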