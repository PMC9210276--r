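test_that("DIRS-like consensus carries the full terminal architecture", {
  set.seed(1)
  spec <- family_spec("D1", "DIRS-like")
  el <- make_dirs_like_consensus(spec)
  s <- el$sequence
  L <- nchar(s)
  expect_equal(nchar(s), spec$length)
  expect_equal(substr(s, 1, 3), "TTT")
  expect_equal(substr(s, L - 2, L), "TTT")
  ann <- el$annotations
  litr <- substr(s, ann$itr5[1], ann$itr5[2])
  ritr <- substr(s, ann$itr3[1], ann$itr3[2])
  expect_equal(nchar(litr), 120L)
  expect_identical(revcomp(litr), ritr)
  # ICR halves are reverse-complementary to the element's termini
  icr_l <- substr(s, ann$icr_l[1], ann$icr_l[2])
  icr_r <- substr(s, ann$icr_r[1], ann$icr_r[2])
  w <- nchar(icr_l)
  expect_identical(icr_l, revcomp(substr(s, 1, w)))
  expect_identical(icr_r, revcomp(substr(s, L - nchar(icr_r) + 1, L)))
})

test_that("Ngaro-like consensus has identical SDR blocks in A1..B1A2B2 order", {
  set.seed(2)
  spec <- family_spec("N1", "Ngaro-like", sdr_a_length = 236,
                      sdr_b_length = 152)
  el <- make_ngaro_like_consensus(spec)
  s <- el$sequence
  ann <- el$annotations
  a1 <- substr(s, ann$sdr_a1[1], ann$sdr_a1[2])
  a2 <- substr(s, ann$sdr_a2[1], ann$sdr_a2[2])
  b1 <- substr(s, ann$sdr_b1[1], ann$sdr_b1[2])
  b2 <- substr(s, ann$sdr_b2[1], ann$sdr_b2[2])
  expect_equal(nchar(a1), 236L)
  expect_equal(nchar(b1), 152L)
  expect_identical(a1, a2)   # 100% identity by construction
  expect_identical(b1, b2)
  expect_true(ann$sdr_a1[2] < ann$sdr_b1[1] &&
                ann$sdr_b1[2] < ann$sdr_a2[1] &&
                ann$sdr_a2[2] < ann$sdr_b2[1])
  # the four ORFs overlap their neighbours in different reading frames
  orfs <- ann$orfs
  expect_equal(nrow(orfs), 4L)
  for (i in 1:3) {
    expect_lt(orfs$start[i + 1], orfs$end[i])
    expect_false(orfs$frame[i + 1] == orfs$frame[i])
  }
})

test_that("generated ORFs are clean reading frames with planted markers", {
  set.seed(3)
  for (sf in c("DIRS-like", "Ngaro-like")) {
    el <- make_consensus(family_spec("x", sf))
    for (i in seq_len(nrow(el$annotations$orfs))) {
      o <- el$annotations$orfs[i, ]
      cds <- substr(el$sequence, o$start, o$end)
      expect_equal(substr(cds, 1, 3), "ATG")
      prot <- translate_dna(cds)
      expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
      expect_false(grepl("*", substr(prot, 1, nchar(prot) - 1), fixed = TRUE))
      for (lab in strsplit(o$markers, ",")[[1]]) {
        expect_true(grepl(domain_markers()[[lab]], prot, fixed = TRUE),
                    label = paste(sf, "marker", lab))
      }
    }
  }
})

test_that("generation is deterministic under a fixed seed", {
  set.seed(7); a <- make_consensus(family_spec("d", "DIRS-like"))
  set.seed(7); b <- make_consensus(family_spec("d", "DIRS-like"))
  expect_identical(a$sequence, b$sequence)
  cfg <- tiny_config(seed = 55L, est_count = 5L)
  b1 <- build_genome(cfg)
  b2 <- build_genome(cfg)
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$ests, b2$ests)
})

test_that("mutate_copy hits its target divergence", {
  set.seed(11)
  s <- random_dna(50000, 0.4)
  expect_identical(mutate_copy(s, 0), s)
  m <- mutate_copy(s, 0.10, cpg_factor = 1)
  k <- kimura2p(m, s)
  expect_lt(abs(k$K - 0.10), 0.01)
})

test_that("realized divergence is an unbiased estimator of target_K", {
  set.seed(12)
  anc <- random_dna(10000, 0.4)
  for (K in c(0.1, 0.3)) {
    ks <- vapply(1:20, function(i) {
      kimura2p(mutate_copy(anc, K, cpg_factor = 1), anc)$K
    }, 0)
    expect_lt(abs(mean(ks) - K) / K, 0.05)
  }
})

test_that("kappa controls the transition/transversion balance", {
  set.seed(13)
  s <- random_dna(20000, 0.5)
  m <- mutate_copy(s, 0.2, kappa = 1e9, cpg_factor = 1)
  k <- kimura2p(m, s)
  expect_equal(k$Q, 0)
  expect_gt(k$P, 0.1)
})

test_that("build_genome plants copies per config with a faithful truth table", {
  cfg0 <- generator_config(seed = 9L, genome_length = 20000L,
                           families = list(), waves = list())
  b0 <- build_genome(cfg0)
  expect_equal(nchar(b0$genome), 20000L)
  expect_equal(nrow(b0$truth), 0L)

  cfg <- tiny_config(seed = 21L, n1 = 5L, n2 = 3L, est_count = 10L)
  b <- build_genome(cfg)
  expect_equal(nrow(b$truth), 8L)
  expect_true(all(b$truth$start >= 1 & b$truth$end <= nchar(b$genome)))
  expect_true(all(b$truth$end > b$truth$start))
  # planted intervals do not overlap
  o <- order(b$truth$start)
  expect_true(all(b$truth$start[o][-1] > b$truth$end[o][-length(o)]))
  # planted copies really sit at their recorded positions
  i <- which(b$truth$intact)[1]
  ins <- substr(b$genome, b$truth$start[i], b$truth$end[i])
  cons <- b$library[[b$truth$family[i]]]
  oriented <- if (b$truth$strand[i] == "+") ins else revcomp(ins)
  expect_lt(kimura2p(oriented, cons)$K, b$truth$target_K[i] + 0.25)
  # ESTs are >= 100 bp subsequence reads with recorded provenance
  expect_equal(length(b$ests), 10L)
  expect_true(all(nchar(b$ests) >= 100))
  expect_equal(nrow(b$est_truth), 10L)
  expect_true(all(b$est_truth$family %in% names(b$library)))
})

test_that("config invariants are enforced", {
  expect_error(generator_config(1, 1000, gc_content = 1.2), "gc_content")
  expect_error(generator_config(
    seed = 1, genome_length = 5000,
    families = list(family_spec("a", "DIRS-like")),
    waves = list(wave_spec("a", 10, 0.1))), "smaller")
  expect_error(generator_config(
    seed = 1, genome_length = 50000,
    families = list(family_spec("a", "DIRS-like")),
    waves = list(wave_spec("zzz", 1, 0.1))), "unknown family")
})

test_that("genome bundles round-trip through FASTA/BED text outputs", {
  cfg <- tiny_config(seed = 31L, n1 = 2L, n2 = 1L, est_count = 3L)
  b <- build_genome(cfg)
  dir <- withr::local_tempdir()
  write_genome_bundle(b, dir)
  g <- read_fasta(file.path(dir, "genome.fasta"))
  expect_identical(unname(g[1]), b$genome)
  lib <- read_fasta(file.path(dir, "library.fasta"))
  expect_identical(unname(lib), unname(b$library))
  bed <- read.table(file.path(dir, "truth.bed"), sep = "\t")
  expect_equal(nrow(bed), nrow(b$truth))
  expect_equal(bed$V2, b$truth$start - 1L)  # BED is 0-based half-open
  expect_equal(bed$V3, b$truth$end)
  expect_equal(bed$V5, round(1000 * b$truth$target_K))
})
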