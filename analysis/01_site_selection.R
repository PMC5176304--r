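#!/usr/bin/env Rscript
# Stage 1: structure-based selection of cysteine/PEGylation sites.
#
# Scans an oligomeric structure for residues that are (i) solvent exposed
# (total SASA > 100 A^2 in every subunit), (ii) far from every active site
# (CA-to-ligand-C5 distance > 25 A in every subunit) and (iii) mutually well
# separated (pairwise cross-oligomer CA distance >= 19.5 A). By default the
# scan runs on the package's synthetic C4 toy oligomer, whose ground truth is
# known, so the whole stage is reproducible offline. Point --pdb at a real
# tetramer (with its bound-ligand hetero code) to run the same scan on it.

suppressMessages({
  library(optparse)
  library(uoxkit)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--pdb", type = "character", default = NULL,
              help = "optional PDB file of an oligomer with bound ligand"),
  make_option("--ligand-res", type = "character", default = "UAC"),
  make_option("--ligand-atom", type = "character", default = "C5"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/sites")
)))
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)

if (is.null(opts$pdb)) {
  toy <- make_toy_oligomer(n_subunits = 4, surface_positions = c(11, 33),
                           buried_positions = c(119, 142),
                           near_positions = 196, ring_radius = 20,
                           seed = opts$seed)
  struct <- toy$structure
  lig_res <- toy$ligand_resname
  write_structure(struct, file.path(opts$out, "input_structure.pdb"))
  cat("synthetic toy oligomer: planted pass =",
      paste(toy$truth$pass, collapse = ", "), "\n")
} else {
  struct <- read_structure(opts$pdb)
  lig_res <- opts$`ligand-res`
}

rep <- site_selection_report(struct, lig_res, opts$`ligand-atom`,
                             criteria = site_criteria(100, 25, 19.5),
                             k = "max", n_points = 960)

write.table(rep$metrics, file.path(opts$out, "candidate_metrics.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
pm <- rep$pair_matrix
if (length(pm)) {
  write.table(cbind(position = rownames(pm), round(pm, 2)),
              file.path(opts$out, "ca_pair_matrix.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
jsonlite::write_json(list(
  criteria = unclass(rep$criteria), settings = rep$settings,
  passing = rep$passing, selected = rep$selected,
  self_pair = as.list(rep$self_pair)
), file.path(opts$out, "selection.json"), auto_unbox = TRUE, digits = 6)

cat("positions scanned:", length(unique(rep$metrics$resno)), "\n")
cat("passing all-subunit criteria:", paste(rep$passing, collapse = ", "), "\n")
cat("selected (>= 19.5 A apart):", paste(rep$selected, collapse = ", "), "\n")
cat("reports written to", opts$out, "\n")
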