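# helper: build an equal-length alignment with prescribed substitutions
forced_alignment <- function(n = 100, n_ts = 0, n_tv = 0, base = "A") {
  cons <- rep(base, n)                 # A: transition G, transversions C/T
  copy <- cons
  if (n_ts > 0) copy[seq_len(n_ts)] <- "G"
  if (n_tv > 0) copy[n_ts + seq_len(n_tv)] <- "C"
  list(copy = paste(copy, collapse = ""), cons = paste(cons, collapse = ""))
}

test_that("K2P closed form evaluates the textbook cases", {
  al <- forced_alignment(100)
  k0 <- kimura2p(al$copy, al$cons)
  expect_equal(k0$P, 0)
  expect_equal(k0$Q, 0)
  expect_equal(k0$K, 0)

  al <- forced_alignment(100, n_ts = 10, n_tv = 5)
  k <- kimura2p(al$copy, al$cons)
  expect_equal(k$P, 0.10)
  expect_equal(k$Q, 0.05)
  # frozen from the closed form: -1/2 ln((1-2*0.1-0.05) * sqrt(1-2*0.05))
  expect_equal(k$K, 0.170181165, tolerance = 1e-8)
  expect_false(k$saturated)
})

test_that("gap and ambiguity columns are excluded from K2P", {
  k <- kimura2p("AG-CN", "AAACA")
  expect_equal(k$n_sites, 3L)   # columns 1, 2, 4
  expect_equal(k$P, 1 / 3)
})

test_that("saturated alignments are flagged, not given a distance", {
  al <- forced_alignment(100, n_ts = 60)
  k <- kimura2p(al$copy, al$cons)
  expect_true(k$saturated)
  expect_true(is.na(k$K))
})

test_that("CpG adjustment reduces to K2P without CpG and shrinks K with it", {
  # consensus free of CpG dinucleotides
  al <- forced_alignment(100, n_ts = 10, n_tv = 5, base = "A")
  expect_false(grepl("CG", al$cons))
  expect_equal(cpg_adjusted_kimura(al$copy, al$cons)$K,
               kimura2p(al$copy, al$cons)$K)
  # one CpG with a single transition: effective count 0.1
  cons <- paste0("CG", paste(rep("A", 98), collapse = ""))
  copy <- paste0("TG", paste(rep("A", 98), collapse = ""))  # C->T transition
  adj <- cpg_adjusted_kimura(copy, cons, cpg_weight = 0.1)
  raw <- kimura2p(copy, cons)
  expect_equal(adj$P, 0.1 / 100)
  expect_lt(adj$K, raw$K)
  # double transition at one CpG counts as one full transition
  copy2 <- paste0("TA", paste(rep("A", 98), collapse = ""))
  adj2 <- cpg_adjusted_kimura(copy2, cons, cpg_weight = 0.1)
  expect_equal(adj2$P, 1 / 100)
})

test_that("CpG adjustment corrects hypermutated copies toward target_K", {
  set.seed(81)
  anc <- random_dna(10000, 0.5)
  target <- 0.15
  err <- t(vapply(1:20, function(i) {
    m <- mutate_copy(anc, target, cpg_factor = 10)
    c(adj = cpg_adjusted_kimura(m, anc)$K, raw = kimura2p(m, anc)$K)
  }, c(0, 0)))
  expect_lt(abs(mean(err[, "adj"]) - target), abs(mean(err[, "raw"]) - target))
  expect_gt(mean(err[, "raw"]), target)  # hypermutation inflates raw K
})

test_that("K estimation is consistent for clean copies", {
  set.seed(82)
  anc <- random_dna(10000, 0.4)
  for (K in c(0.05, 0.3)) {
    ks <- vapply(1:20, function(i) {
      kimura2p(mutate_copy(anc, K, cpg_factor = 1), anc)$K
    }, 0)
    expect_lt(abs(mean(ks) - K) / K, 0.05)
  }
})

test_that("ages follow T = K/r with r = 3.1e-9", {
  expect_equal(age_from_divergence(0)$years, 0)
  expect_equal(age_from_divergence(0.031)$mya, 10.0)
  expect_equal(round(age_from_divergence(0.01)$mya, 1), 3.2)
  # linearity: doubling K doubles the age exactly
  expect_equal(age_from_divergence(0.2)$mya, 2 * age_from_divergence(0.1)$mya)
})

test_that("landscape bins conserve masked proportions", {
  rec <- data.frame(
    copy_id = c("a", "b", "c"), family = c("f1", "f1", "f2"),
    superfamily = c("DIRS-like", "DIRS-like", "Ngaro-like"),
    g_start = 1L, g_end = 2L, strand = "+",
    aligned_bp = c(1000L, 500L, 2000L),
    P = 0, Q = 0, K = c(0.005, 0.012, 0.005), saturated = FALSE,
    age_mya = 0)
  ls <- build_landscape(rec, genome_size = 100000)
  pf <- ls$per_family
  # single 1 kb copy at K = 0.005 in 100 kb -> 1% in bin [0, 0.01)
  expect_equal(pf$pct_genome[pf$group == "f1" & pf$bin_lo == 0], 1.0)
  expect_equal(pf$pct_genome[pf$group == "f1" & pf$bin_lo == 0.01], 0.5)
  # per-family bin sums equal that family's total masked proportion
  sums <- tapply(pf$pct_genome, pf$group, sum)
  expect_equal(unname(sums[["f1"]]), 100 * 1500 / 100000)
  expect_equal(unname(sums[["f2"]]), 100 * 2000 / 100000)
  # age axis is the bin midpoint over r
  expect_equal(pf$age_mya, pf$bin_mid / 3.1e-9 / 1e6)
})

test_that("the landscape is invariant to record order", {
  set.seed(83)
  rec <- data.frame(
    copy_id = paste0("c", 1:20), family = sample(c("f1", "f2"), 20, TRUE),
    superfamily = "DIRS-like", g_start = 1L, g_end = 2L, strand = "+",
    aligned_bp = sample(500:3000, 20), P = 0, Q = 0,
    K = runif(20, 0, 0.3), saturated = FALSE, age_mya = 0)
  l1 <- build_landscape(rec, 1e5)
  l2 <- build_landscape(rec[sample(20), ], 1e5)
  rownames(l1$per_family) <- rownames(l2$per_family) <- NULL
  expect_equal(l1$per_family, l2$per_family)
})

test_that("planted waves appear as modes in the right bins", {
  set.seed(84)
  cfg <- generator_config(
    84, 100000,
    families = list(family_spec("D1", "DIRS-like")),
    waves = list(wave_spec("D1", 6, 0.025), wave_spec("D1", 6, 0.255)),
    est_count = 0)
  b <- build_genome(cfg)
  mk <- mask_genome(b$library, b$genome)
  rec <- divergence_records(mk$hits, c(D1 = "DIRS-like"))
  ls <- build_landscape(rec, nchar(b$genome))
  pf <- ls$per_family
  low <- pf[pf$bin_lo < 0.12, ]
  high <- pf[pf$bin_lo >= 0.12, ]
  expect_equal(low$bin_lo[which.max(low$pct_genome)], 0.02)
  expect_equal(high$bin_lo[which.max(high$pct_genome)], 0.25)
})
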