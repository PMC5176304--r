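#!/usr/bin/env Rscript
# Stage 2: sequence-liability engineering on the (synthetic stand-in)
# uricase monomer: find and neutralize the integrin-binding RGD motif
# (R -> S from the family consensus), truncate the non-conserved C-terminal
# tail carrying the lone cysteine, and compute the identity matrix, masses
# and extinction coefficients of the resulting variants.

suppressMessages({
  library(optparse)
  library(uoxkit)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/sequence")
)))
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)

native <- synthetic_uricase_sequence()

# liability scan: the RGD tripeptide and its consensus-guided repair
hit <- scan_and_replace_motif(native, "RGD", replace_offset = 0,
                              new_residue = "S")
cat("RGD motif at position(s):", paste(hit$positions, collapse = ", "), "\n")
sgd <- hit$sequence

# C-terminal truncation: drop the 11-residue tail (removes the only Cys)
tail_pep <- "HPIWSNIAGFC"
engineered <- truncate_cterm(sgd, tail_pep)
cat("truncated", nchar(sgd) - nchar(engineered), "residues;",
    "Cys remaining:", lengths(regmatches(engineered, gregexpr("C", engineered))),
    "\n")

# a small synthetic 'family' (mutated copies) to demonstrate the consensus
set.seed(opts$seed)
mutate <- function(seq, n_mut) {
  aa <- strsplit(seq, "")[[1]]
  idx <- sample(seq_along(aa), n_mut)
  aa[idx] <- sample(strsplit("ADEFGHIKLMNPQRSTVWY", "")[[1]],
                    n_mut, replace = TRUE)
  paste(aa, collapse = "")
}
family <- c(native = native,
            var1 = mutate(native, 20), var2 = mutate(native, 40),
            var3 = mutate(native, 60), var4 = mutate(native, 90))
consensus <- build_consensus(unname(family))   # equal lengths: no gaps needed
family <- c(family, consensus = consensus)
write_fasta(family, file.path(opts$out, "family_synthetic.fasta"))

idm <- identity_matrix(family)
write.table(cbind(id = rownames(idm), idm),
            file.path(opts$out, "identity_matrix.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("identity of consensus vs native:", idm["consensus", "native"], "%\n")

variants <- c(native = native, sgd = sgd, engineered = engineered)
report <- lapply(names(variants), function(nm) {
  s <- variants[[nm]]
  list(name = nm, length = nchar(s),
       mass_kda = average_mass(s),
       tetramer_kda = round(4 * average_mass(s), 2),
       e280 = extinction_coefficient(s))
})
jsonlite::write_json(report, file.path(opts$out, "variants.json"),
                     auto_unbox = TRUE, digits = 6)
for (r in report) {
  cat(sprintf("%-10s %3d aa  %.2f kDa (tetramer %.2f)  e280 %d\n",
              r$name, r$length, r$mass_kda, r$tetramer_kda, r$e280))
}
cat("reports written to", opts$out, "\n")
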