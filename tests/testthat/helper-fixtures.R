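# Shared in-code fixtures, built once per test run.

# small transcriptome used across module tests
fix_tx <- make_toy_transcriptome(60, mean_length = 300, seed = 1)

# a mid-sized cohort on it
fix_records <- simulate_neutral(fix_tx, 6000, seed = 2)
fix_spectra <- count_sites(fix_tx, "SSB7", by = "gene")

# write a small MAF-dialect file for I/O tests
write_toy_maf <- function(df, path = tempfile(fileext = ".tsv")) {
  write_maf(df, path)
  path
}

make_records <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}
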