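test_that("translated search retrieves a planted protein exactly", {
  set.seed(61)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  prot <- paste(sample(aas, 120, replace = TRUE), collapse = "")
  cds <- paste(vapply(strsplit(prot, "")[[1]], function(aa) {
    gc <- Biostrings::GENETIC_CODE
    names(gc)[match(aa, gc)]
  }, ""), collapse = "")
  genome <- paste0(random_dna(4000, 0.4), cds, random_dna(4000, 0.4))
  hits <- translated_search(prot, genome, top_n = 3)
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$g_start[1], 4001L)
  expect_equal(hits$g_end[1], 4000L + nchar(cds))
  expect_equal(hits$strand[1], "+")
  # flanks are attached and clipped at sequence ends
  expect_equal(hits$flank_start[1], 1001L)
  expect_equal(nchar(hits$flank_seq[1]), hits$flank_end[1] - hits$flank_start[1] + 1L)
})

test_that("translated search returns exactly top_n of many planted copies", {
  set.seed(62)
  cfg <- generator_config(
    62, 120000, families = list(family_spec("D1", "DIRS-like")),
    waves = list(wave_spec("D1", 12, 0.08)), est_count = 0)
  b <- build_genome(cfg)
  orfs <- annotate_orfs(b$library[[1]], both_strands = FALSE)
  i <- which(vapply(orfs$domains, function(d) "RT" %in% d, TRUE))[1]
  rt <- orfs$protein[i]
  hits <- translated_search(rt, b$genome, top_n = 10, min_score = 100)
  expect_equal(nrow(hits), 10L)
  # every returned hit lies inside a planted copy
  inside <- vapply(seq_len(nrow(hits)), function(h) {
    any(b$truth$start <= hits$g_start[h] & b$truth$end >= hits$g_end[h])
  }, TRUE)
  expect_true(all(inside))
})

test_that("seeded search agrees with full Smith-Waterman on each frame", {
  set.seed(63)
  cfg <- generator_config(
    63, 30000, families = list(family_spec("D1", "DIRS-like")),
    waves = list(wave_spec("D1", 2, 0.10)), est_count = 0)
  b <- build_genome(cfg)
  orfs <- annotate_orfs(b$library[[1]], both_strands = FALSE)
  i <- which(vapply(orfs$domains, function(d) "RT" %in% d, TRUE))[1]
  rt <- substr(orfs$protein[i], 1, 150)
  hits <- translated_search(rt, b$genome, top_n = 2, min_score = 80)
  # oracle: full local DP against each complete six-frame translation
  b62 <- yrscout:::get_blosum62()
  best <- -Inf
  for (fr in yrscout:::six_frame(b$genome)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(rt), Biostrings::AAString(fr$protein),
      type = "local", substitutionMatrix = b62,
      gapOpening = 11, gapExtension = 1)
    best <- max(best, Biostrings::score(pa))
  }
  expect_equal(hits$score[1], best)
})

test_that("masking recovers planted copies with correct families", {
  set.seed(64)
  cfg <- tiny_config(seed = 64L, n1 = 4L, n2 = 3L, K1 = 0.05, K2 = 0.18,
                     genome_length = 70000L)
  b <- build_genome(cfg)
  mk <- mask_genome(b$library, b$genome)
  tt <- b$truth
  planted <- sum(tt$end - tt$start + 1)
  covered <- 0
  fam_ok <- 0
  for (i in seq_len(nrow(tt))) {
    j <- which(pmin(tt$end[i], mk$hits$g_end) -
                 pmax(tt$start[i], mk$hits$g_start) + 1 > 0)
    if (length(j)) {
      covered <- covered + sum(pmin(tt$end[i], mk$hits$g_end[j]) -
                                 pmax(tt$start[i], mk$hits$g_start[j]) + 1)
      fam_ok <- fam_ok + all(mk$hits$family[j] == tt$family[i])
    }
  }
  expect_gte(covered / planted, 0.95)
  expect_gte(fam_ok / nrow(tt), 0.95)
  # summary conservation: family rows sum to the total row
  s <- mk$summary
  expect_equal(sum(s$masked_bp[s$family != "total"]),
               s$masked_bp[s$family == "total"])
  expect_equal(s$pct_genome[s$family == "total"],
               100 * s$masked_bp[s$family == "total"] / nchar(b$genome))
})

test_that("an empty library masks nothing", {
  mk <- mask_genome(character(0), random_dna(5000, 0.4))
  expect_equal(nrow(mk$hits), 0L)
  expect_equal(mk$summary$masked_bp, 0)
})

test_that("masking is strand symmetric", {
  set.seed(65)
  cfg <- generator_config(
    65, 30000, families = list(family_spec("D1", "DIRS-like")),
    waves = list(wave_spec("D1", 3, 0.05)), est_count = 0)
  b <- build_genome(cfg)
  L <- nchar(b$genome)
  mk1 <- mask_genome(b$library, b$genome)
  mk2 <- mask_genome(b$library, revcomp(b$genome))
  m1 <- mk1$hits[order(mk1$hits$g_start), ]
  m2 <- mk2$hits
  m2$ns <- L - m2$g_end + 1L
  m2$ne <- L - m2$g_start + 1L
  m2 <- m2[order(m2$ns), ]
  expect_equal(m1$g_start, m2$ns)
  expect_equal(m1$g_end, m2$ne)
  expect_true(all(m1$strand != m2$strand))
})

test_that("hit scores decay with mutation load", {
  set.seed(66)
  el <- make_consensus(family_spec("d", "DIRS-like"))
  cons <- el$sequence
  score_at <- function(K) {
    copies <- vapply(1:3, function(i) mutate_copy(cons, K, cpg_factor = 1), "")
    genome <- paste0(random_dna(2000, 0.4),
                     paste0(copies, collapse = random_dna(2000, 0.4)),
                     random_dna(2000, 0.4))
    mk <- mask_genome(setNames(cons, "d"), genome)
    mean(mk$hits$score)
  }
  s <- vapply(c(0.02, 0.15, 0.30), score_at, 0)
  expect_true(all(diff(s) < 0))
})

test_that("EST filters keep only >85% identity, >100 bp matches", {
  set.seed(67)
  lib <- setNames(vapply(1:2, function(i) random_dna(3000, 0.4), ""),
                  c("famA", "famB"))
  ests <- c(
    exact150 = substr(lib[["famA"]], 500, 649),          # kept
    low_ident = mutate_copy(substr(lib[["famA"]], 1000, 1199), 0.35,
                            cpg_factor = 1),             # ~20% diverged, dropped
    short90 = substr(lib[["famB"]], 100, 189),           # too short, dropped
    ok_b = mutate_copy(substr(lib[["famB"]], 700, 899), 0.03,
                       cpg_factor = 1)                   # kept
  )
  res <- match_ests(ests, lib)
  expect_true(all(c("exact150", "ok_b") %in% res$matches$est))
  expect_false("short90" %in% res$matches$est)
  expect_false("low_ident" %in% res$matches$est)
  expect_true(res$evidence[["famA"]])
  expect_true(res$evidence[["famB"]])
  expect_true(all(res$matches$identity > 0.85))
  expect_true(all(res$matches$match_len > 100))
})

test_that("generator EST provenance is recovered end to end", {
  set.seed(68)
  cfg <- tiny_config(seed = 68L, n1 = 1L, n2 = 1L, est_count = 20L)
  b <- build_genome(cfg)
  res <- match_ests(b$ests, b$library)
  # each matched EST maps to its true source family
  m <- merge(res$matches, b$est_truth, by.x = "est", by.y = "est_id")
  agree <- mean(m$family.x == m$family.y)
  expect_gte(agree, 0.95)
  expect_gte(nrow(m), 15)
})
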