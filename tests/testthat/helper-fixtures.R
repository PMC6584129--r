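# Deterministic fixtures built in code.

# 200-mer at exactly 58% GC (116 G/C, 84 A/T) containing three isolated
# AT-rich cores (AATTAA runs); the remaining A/T is spread as AAGG repeats,
# which never reach 5 A/T in any hexamer.
variant_test_seq <- function() {
  paste0(
    strrep("G", 10), "AATTAA",
    strrep("G", 10), "AATTAA",
    strrep("G", 10), "AATTAA",
    strrep("G", 6),
    strrep("AAGG", 33),
    strrep("G", 14)
  )
}

# small hand-laid gene table: two divergent genes and one isolated gene
divergent_gene_table <- function() {
  validate_genes(data.frame(
    locus_id = c("TST_0001", "TST_0002", "TST_0003"),
    start = c(1000L, 2500L, 9000L),
    end = c(2000L, 3500L, 9500L),
    strand = c("-", "+", "+"),
    stringsAsFactors = FALSE
  ))
}

# path to the bundled specialized-metabolic-cluster transcription
cluster_fixture_path <- function() {
  system.file("extdata", "sven_cluster_table.tsv", package = "silencescan")
}

# DE table that reproduces the worked cluster rows: one significant gene in
# the 12-locus ectoine span and five in the 12-locus siderophore span, plus
# sub-threshold noise genes elsewhere
table1_de_fixture <- function() {
  sig <- data.frame(
    locus_id = c("SVEN_0230", sprintf("SVEN_%04d", 2570:2574)),
    wt_expr = 2, mut_expr = 40, fold_change = 20, q_value = 0.001,
    stringsAsFactors = FALSE
  )
  noise <- data.frame(
    locus_id = sprintf("SVEN_%04d", 3000:3019),
    wt_expr = 100, mut_expr = 150, fold_change = 1.5, q_value = 0.5,
    stringsAsFactors = FALSE
  )
  rbind(sig, noise)
}
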