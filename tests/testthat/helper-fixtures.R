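# Shared fixtures: tiny transcripts and reads built in code.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a transcript with `sites` AluI sites separated by `gap`-nt A/T spacers
# (spacers never contain AGCT)
make_sited_transcript <- function(sites, gap = 30L, id = "tx",
                                  gene = "GeneX") {
  spacer <- function(n) paste(rep(c("A", "T"), length.out = n), collapse = "")
  seq <- spacer(gap)
  for (i in seq_len(sites)) seq <- paste0(seq, "AGCT", spacer(gap))
  list(id = id, gene_label = gene, seq = seq)
}

# a perfect sequenced insert read for a guide, matching the generator layout
perfect_read <- function(guide, config = lego_config(),
                         flank5 = "GACGCCACCG", flank3 = "TTTTTGGAAC") {
  stem <- paste0("G", guide)
  paste0(flank5, stem, config$loop_seq, reverse_complement(stem), flank3)
}

mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

# independent character-by-character reverse-complement oracle
revcomp_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

table1_path <- function() {
  system.file("extdata", "table1_suppressors.tsv", package = "legoscreen")
}
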