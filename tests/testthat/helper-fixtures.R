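# hand-built peptide tables and small configs shared across test files

peptide_row <- function(run_id, group, accession, peptide, intensity,
                        charge = 2L, description = accession) {
  tibble::tibble(run_id = run_id, group = group, accession = accession,
                 description = description, peptide = peptide,
                 charge = as.integer(charge), intensity = intensity)
}

# two proteins + bait over a 1-vs-1 run design, all unique peptides
tiny_peptide_table <- function() {
  dplyr::bind_rows(
    peptide_row("WT_1", "WT", "BAIT", c("AAAK", "CCCK"), c(4e6, 4e6)),
    peptide_row("KO_1", "KO", "BAIT", c("AAAK", "CCCK"), c(2e6, 2e6)),
    peptide_row("WT_1", "WT", "P1", c("DDDK", "EEEK", "FFFK"), c(100, 200, 300)),
    peptide_row("KO_1", "KO", "P1", c("DDDK", "EEEK", "FFFK"), c(150, 250, 350)),
    peptide_row("WT_1", "WT", "P2", "GGGK", 500),
    peptide_row("KO_1", "KO", "P2", "GGGK", 400)
  )
}

small_config <- function(...) {
  sim_config(n_proteins = 25, peptides_per_protein = c(2L, 6L),
             base_log_sd = 0.2, ...)
}
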