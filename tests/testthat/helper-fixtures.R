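# Small generator configurations shared across tests. Element lengths use
# the package defaults (4.2 kb DIRS-like, 4.8 kb Ngaro-like); genomes are
# kept small so the whole suite stays fast.

tiny_config <- function(seed = 101L, n1 = 4L, n2 = 3L, K1 = 0.05, K2 = 0.15,
                        genome_length = 60000L, est_count = 0L, ...) {
  generator_config(
    seed = seed, genome_length = genome_length,
    families = list(family_spec("DIRS-t1", "DIRS-like"),
                    family_spec("Ngaro-t1", "Ngaro-like")),
    waves = list(wave_spec("DIRS-t1", n1, K1),
                 wave_spec("Ngaro-t1", n2, K2)),
    est_count = est_count, ...)
}

# a random ancestor plus n mutated descendants
mutated_family <- function(ancestor_len, n, K, gc = 0.4, cpg_factor = 1) {
  anc <- random_dna(ancestor_len, gc)
  copies <- setNames(
    vapply(seq_len(n), function(i) mutate_copy(anc, K, cpg_factor = cpg_factor), ""),
    sprintf("c%02d", seq_len(n)))
  list(ancestor = anc, copies = copies)
}

scan_sorted <- function(df) {
  df <- df[, c("start1", "end1", "start2", "end2", "orientation")]
  df <- df[order(df$start1, df$start2, df$orientation), ]
  rownames(df) <- NULL
  df
}
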