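# Shared fixtures: small alignments built in code, plus the transcribed
# haplotype-frequency table shipped in extdata.

char_aln <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

toy_trio <- function() {
  char_aln(c(a = "AAAA", b = "AAAT", c = "CAAA"))
}

# deterministic small simulated alignment for oracle tests
fixture_alignment <- function(n = 8, theta = 4, L = 200, seed = 42,
                              infinite_sites = TRUE) {
  d <- simulate_dataset(demography_constant(theta, n, L), seed = seed,
                        infinite_sites = infinite_sites)
  d$alignment
}

freq_table_path <- function() {
  system.file("extdata", "coi_haplotype_frequencies.tsv",
              package = "phylodem")
}

write_tmp_fasta <- function(seqs) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(seq_along(seqs), function(i) {
    c(paste0(">", names(seqs)[i]), seqs[i])
  })), tf)
  tf
}
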