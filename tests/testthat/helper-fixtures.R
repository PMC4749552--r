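# Fixture builders shared across test files; everything is generated in code.

# Write a minimal CA-only PDB file with the given residue numbers and
# B-factors; returns the path.
write_test_pdb <- function(residues, bfactors = rep(30, length(residues)),
                           chain = "A", aa3 = "ALA",
                           path = tempfile(fileext = ".pdb")) {
  stopifnot(length(residues) == length(bfactors))
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_along(residues), aa3, chain, residues,
    1.5 * seq_along(residues), 0, 0, 1.00, bfactors)
  writeLines(c(lines, "END"), path)
  path
}

# A small fully-crossed ddG record table: every mutation present in both
# states, with chosen energies.
make_energy_records <- function(positions = c(600L, 487L),
                                wt = c("V", "V"),
                                mut_aas = c("E", "V"),
                                templates = c(A1 = "active", I1 = "inactive"),
                                ddg = 1) {
  grid <- expand.grid(template = names(templates), position = positions,
                      mut_aa = mut_aas, stringsAsFactors = FALSE)
  grid$state <- unname(templates[grid$template])
  grid$wt_aa <- wt[match(grid$position, positions)]
  grid$ddg_total <- ddg
  grid$ddg_solvh <- 0
  grid[, c("template", "state", "position", "wt_aa", "mut_aa",
           "ddg_total", "ddg_solvh")]
}

# Flat presence profile over the loop for correction tests.
flat_profile <- function(presence = 1, residues = 597:615) {
  data.frame(residue_number = residues,
             presence_fraction = rep(presence, length(residues)),
             mean_norm_bfactor = 0, n_structures = 28L)
}
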