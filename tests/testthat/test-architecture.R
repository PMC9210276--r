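test_that("self-similarity scan finds constructed terminal repeats", {
  set.seed(41)
  x <- random_dna(120, 0.4)
  seq <- paste0(x, random_dna(800, 0.4), revcomp(x))
  res <- self_similarity_scan(seq)
  inv <- res[res$orientation == "inverted", ]
  expect_equal(nrow(inv), 1L)
  expect_equal(c(inv$start1, inv$end1), c(1L, 120L))
  expect_equal(c(inv$start2, inv$end2), c(921L, 1040L))
  expect_equal(inv$identity, 1)

  a <- random_dna(150, 0.4); b <- random_dna(90, 0.4)
  seq2 <- paste0(a, random_dna(400, 0.4), b, a, b)
  res2 <- self_similarity_scan(seq2)
  dir <- res2[res2$orientation == "direct", ]
  expect_equal(nrow(dir), 2L)
  expect_setequal(dir$length, c(150L, 90L))
  expect_true(all(dir$identity == 1))
})

test_that("scan agrees with the exhaustive all-pairs oracle", {
  set.seed(42)
  for (rep in 1:3) {
    x <- random_dna(80, 0.4)
    y <- random_dna(60, 0.4)
    seq <- paste0(random_dna(200, 0.4), x, random_dna(500, 0.4), y,
                  random_dna(300, 0.4), revcomp(x), random_dna(200, 0.4), y,
                  random_dna(150, 0.4))
    got <- scan_sorted(self_similarity_scan(seq, min_length = 50))
    want <- scan_sorted(oracle_exact_repeats(seq, min_len = 50))
    expect_equal(got[, names(want)], want)
  }
  # a plain random sequence has no >= 50 bp repeats: both report none
  seq0 <- random_dna(2000, 0.4)
  expect_equal(nrow(self_similarity_scan(seq0, min_length = 50)),
               nrow(oracle_exact_repeats(seq0, 50)))
})

test_that("scan is strand symmetric", {
  set.seed(43)
  el <- make_consensus(family_spec("d", "DIRS-like"))
  L <- nchar(el$sequence)
  fwd <- self_similarity_scan(el$sequence)
  rev <- self_similarity_scan(revcomp(el$sequence))
  mirror <- data.frame(start1 = L - rev$end2 + 1L, end1 = L - rev$start2 + 1L,
                       start2 = L - rev$end1 + 1L, end2 = L - rev$start1 + 1L,
                       orientation = rev$orientation)
  expect_equal(scan_sorted(fwd)[, 1:5], scan_sorted(mirror))
})

test_that("ITR detection round-trips generator truth exactly at K = 0", {
  set.seed(44)
  el <- make_consensus(family_spec("d", "DIRS-like"))
  itr <- find_itrs(el$sequence)
  expect_equal(itr$itr5, el$annotations$itr5)
  expect_equal(itr$itr3, el$annotations$itr3)
  ng <- make_consensus(family_spec("n", "Ngaro-like"))
  expect_null(find_itrs(ng$sequence))
})

test_that("ITR intervals keep >= 90% Jaccard overlap with truth at K = 0.05", {
  set.seed(45)
  jac <- replicate(8, {
    el <- make_consensus(family_spec("d", "DIRS-like"))
    mut <- mutate_copy(el$sequence, 0.05, cpg_factor = 1)
    itr <- find_itrs(mut)
    if (is.null(itr)) return(0)
    j1 <- length(intersect(seq(itr$itr5[1], itr$itr5[2]),
                           seq(el$annotations$itr5[1], el$annotations$itr5[2]))) /
      length(union(seq(itr$itr5[1], itr$itr5[2]),
                   seq(el$annotations$itr5[1], el$annotations$itr5[2])))
    j1
  })
  expect_gte(mean(jac), 0.9)
})

test_that("ICR detection recovers truth and degrades gracefully", {
  set.seed(46)
  el <- make_consensus(family_spec("d", "DIRS-like"))
  itr <- find_itrs(el$sequence)
  icr <- find_icr(el$sequence, itr)
  expect_equal(icr$icr_l, el$annotations$icr_l)
  expect_equal(icr$icr_r, el$annotations$icr_r)
  # delete the ICR: replace it by random bases
  s <- el$sequence
  iv <- c(el$annotations$icr_l[1], el$annotations$icr_r[2])
  s2 <- paste0(substr(s, 1, iv[1] - 1), random_dna(iv[2] - iv[1] + 1, 0.4),
               substr(s, iv[2] + 1, nchar(s)))
  expect_null(find_icr(s2, find_itrs(s2)))
  expect_error(find_icr(s, NULL), "ITR")
})

test_that("SDR detection enforces the A1..B1 A2 B2 arrangement", {
  set.seed(47)
  el <- make_consensus(family_spec("n", "Ngaro-like"))
  sdr <- find_sdrs(el$sequence)
  expect_equal(sdr$sdr_a1, el$annotations$sdr_a1)
  expect_equal(sdr$sdr_b1, el$annotations$sdr_b1)
  expect_equal(sdr$sdr_a2, el$annotations$sdr_a2)
  expect_equal(sdr$sdr_b2, el$annotations$sdr_b2)
  expect_equal(sdr$sdr_a1[2] - sdr$sdr_a1[1] + 1L, 236L)
  expect_equal(sdr$sdr_b1[2] - sdr$sdr_b1[1] + 1L, 152L)

  # deleting the 3' blocks removes the signal (as in degenerate families)
  s <- el$sequence
  s2 <- paste0(substr(s, 1, el$annotations$sdr_b1[1] - 1),
               random_dna(nchar(s) - el$annotations$sdr_b1[1] + 1, 0.4))
  expect_null(find_sdrs(s2))

  # shuffled block order (A1 B1 B2 A2) is rejected
  a <- random_dna(236, 0.4); b <- random_dna(152, 0.4)
  bad <- paste0(a, random_dna(2500, 0.4), b, random_dna(40, 0.4), b,
                random_dna(40, 0.4), a)
  expect_null(find_sdrs(bad))
})

test_that("superfamily classification is exclusive and completeness-aware", {
  set.seed(48)
  el <- make_consensus(family_spec("d", "DIRS-like"))
  arch <- detect_architecture(el$sequence)
  orfs <- annotate_orfs(el$sequence)
  cls <- classify_superfamily(arch, orfs)
  expect_equal(cls$superfamily, "DIRS-like")
  expect_equal(cls$completeness, "complete")

  # break ORF2: stop codons across the RT/RH region degrade completeness
  o2 <- el$annotations$orfs[2, ]
  s <- el$sequence
  mid <- seq(o2$start + 90, o2$end - 90, by = 90)
  for (p in mid) substr(s, p, p + 2) <- "TAA"
  cls2 <- classify_superfamily(detect_architecture(s), annotate_orfs(s))
  expect_equal(cls2$superfamily, "DIRS-like")
  expect_true(cls2$completeness != "complete")

  # unclassified when no diagnostic repeats exist
  plain <- random_dna(3000, 0.4)
  cls3 <- classify_superfamily(detect_architecture(plain), NULL)
  expect_equal(cls3$superfamily, "unclassified")
  expect_false(is.na(cls3$reason))
})

test_that("a DIRS-like and a Ngaro-like call are never produced together", {
  set.seed(49)
  for (sf in c("DIRS-like", "Ngaro-like")) {
    el <- make_consensus(family_spec("x", sf))
    arch <- detect_architecture(el$sequence)
    dirs_call <- !is.null(arch$itr5)
    ngaro_call <- !is.null(arch$sdr_a1)
    expect_false(dirs_call && ngaro_call)
  }
})
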