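#' Specify a synthetic element family
#'
#' Describes the architecture of one consensus element to be generated:
#' DIRS-like elements get terminal trinucleotides, an inverted-terminal-repeat
#' (ITR) pair and an internal complementary region (ICR); Ngaro-like elements
#' get split direct repeats (SDRs) laid out as A1 ... B1 A2 B2. ORF layout
#' defaults to the canonical three (DIRS-like: gag / RT-RH-MT / YR) or four
#' (Ngaro-like: gag / RT-RH / YR / SGNH) overlapping reading frames.
#'
#' @param name Family label (e.g. `"DIRS-sim1"`).
#' @param superfamily `"DIRS-like"` or `"Ngaro-like"`.
#' @param length Element length in bp (default 4200 DIRS-like, 4800 Ngaro-like).
#' @param itr_length ITR length in bp (DIRS-like; ~120 bp in vivo).
#' @param icr_segment_length Length of each ICR half-segment in bp (DIRS-like).
#' @param icr_offset Gap between the lITR end and the ICR start, bp.
#' @param sdr_a_length,sdr_b_length SDR block lengths in bp (Ngaro-like;
#'   defaults 236 and 152 bp).
#' @param orf_layout Optional list of ORF descriptors
#'   `list(start =, end =, markers = c(LABEL = codon_offset, ...))` with
#'   1-based closed nucleotide intervals (length divisible by 3, stop codon
#'   included) and marker peptides placed at the given codon offsets.
#' @param terminal_trinucleotide Terminal 3-mer of DIRS-like elements
#'   (default `"TTT"`).
#' @param with_mt Whether the DIRS-like ORF2 carries the MT marker.
#' @return A `FamilySpec` list.
#' @export
family_spec <- function(name, superfamily = c("DIRS-like", "Ngaro-like"),
                        length = NULL, itr_length = 120L,
                        icr_segment_length = 35L, icr_offset = 40L,
                        sdr_a_length = 236L, sdr_b_length = 152L,
                        orf_layout = NULL, terminal_trinucleotide = "TTT",
                        with_mt = TRUE) {
  superfamily <- match.arg(superfamily)
  if (is.null(length)) length <- if (superfamily == "DIRS-like") 4200L else 4800L
  length <- as.integer(length)
  if (superfamily == "DIRS-like") {
    stopifnot(itr_length > 0, icr_segment_length > 0,
              nchar(terminal_trinucleotide) == 3)
    sdr_a_length <- sdr_b_length <- NA_integer_
  } else {
    stopifnot(sdr_a_length > 0, sdr_b_length > 0)
    itr_length <- icr_segment_length <- NA_integer_
  }
  if (is.null(orf_layout)) {
    orf_layout <- default_orf_layout(superfamily, length, with_mt)
  }
  for (o in orf_layout) {
    if (o$start < 1 || o$end > length || (o$end - o$start + 1) %% 3 != 0)
      stop("ORF layout does not fit the element: ", name)
  }
  structure(list(
    name = name, superfamily = superfamily, length = length,
    itr_length = itr_length, icr_segment_length = icr_segment_length,
    icr_offset = as.integer(icr_offset),
    sdr_a_length = as.integer(sdr_a_length),
    sdr_b_length = as.integer(sdr_b_length),
    orf_layout = orf_layout,
    terminal_trinucleotide = toupper(terminal_trinucleotide),
    with_mt = with_mt
  ), class = "FamilySpec")
}

# Canonical ORF layouts. Starts are chosen so that consecutive ORFs overlap by
# 29 nt in different reading frames (reading frames of real YR elements
# overlap, primarily ORF2/ORF3).
default_orf_layout <- function(superfamily, length, with_mt = TRUE) {
  if (superfamily == "DIRS-like") {
    if (length < 4200) stop("default DIRS-like layout needs length >= 4200")
    markers2 <- c(RT = 30, RH = 90)
    if (with_mt) markers2 <- c(markers2, MT = 150)
    list(
      list(start = 301L,  end = 1500L, markers = c(GAG = 50)),
      list(start = 1472L, end = 2971L, markers = markers2),
      list(start = 2943L, end = 4040L, markers = c(YR = 60))
    )
  } else {
    if (length < 4800) stop("default Ngaro-like layout needs length >= 4800")
    list(
      list(start = 301L,  end = 1200L, markers = c(GAG = 40)),
      list(start = 1172L, end = 2671L, markers = c(RT = 40, RH = 120)),
      list(start = 2643L, end = 3740L, markers = c(YR = 60)),
      list(start = 3712L, end = 4161L, markers = c(SGNH = 30))
    )
  }
}

#' Specify one amplification wave
#'
#' A wave plants `n_copies` copies of one family at a common target Kimura
#' divergence, emulating a burst of transposition whose copies have since
#' diverged by `target_K` from the ancestral (consensus) sequence.
#'
#' @param family Family label, matching a [family_spec()] name.
#' @param n_copies Number of copies to plant.
#' @param target_K Target Kimura-2-parameter divergence (substitutions/site).
#' @param intact_fraction Fraction of copies left structurally complete; the
#'   rest are 5'- and/or 3'-truncated.
#' @param max_truncation Maximum fraction of the element removed from a
#'   truncated end.
#' @return A `WaveSpec` list.
#' @export
wave_spec <- function(family, n_copies, target_K, intact_fraction = 1,
                      max_truncation = 0.5) {
  stopifnot(target_K >= 0, intact_fraction >= 0, intact_fraction <= 1,
            n_copies >= 0)
  structure(list(family = family, n_copies = as.integer(n_copies),
                 target_K = target_K, intact_fraction = intact_fraction,
                 max_truncation = max_truncation), class = "WaveSpec")
}

#' Full generator configuration
#'
#' @param seed Integer master seed; every stage draws from a named substream
#'   derived from it, so a fixed config+seed gives byte-identical outputs.
#' @param genome_length Background genome length in bp.
#' @param gc_content GC fraction of the background and of generated elements.
#' @param families List of [family_spec()] objects.
#' @param waves List of [wave_spec()] objects.
#' @param est_count Number of expressed-sequence-tag reads to simulate.
#' @param est_families Families the ESTs are drawn from (default: all).
#' @param est_K Light divergence applied to EST reads.
#' @param kappa Transition/transversion rate ratio used when mutating copies.
#' @param cpg_factor Multiplier on the transition rate at CpG sites of the
#'   source sequence. The default 10 emulates vertebrate CpG
#'   hypermutability and is the inverse of the 0.1 CpG weight used by the
#'   divergence adjustment, so adjusted divergences center on `target_K`.
#' @return A `GeneratorConfig` list.
#' @export
generator_config <- function(seed, genome_length, gc_content = 0.4,
                             families = list(), waves = list(),
                             est_count = 0L, est_families = NULL,
                             est_K = 0.02, kappa = 2, cpg_factor = 10) {
  stopifnot(gc_content > 0, gc_content < 1, genome_length > 0)
  fam_names <- vapply(families, function(f) f$name, "")
  for (w in waves) {
    if (!w$family %in% fam_names) stop("wave refers to unknown family: ", w$family)
  }
  total_copy_bp <- sum(vapply(waves, function(w) {
    f <- families[[match(w$family, fam_names)]]
    as.numeric(w$n_copies) * f$length
  }, 0))
  if (total_copy_bp > genome_length)
    stop("genome_length smaller than total planted copy length")
  if (is.null(est_families)) est_families <- fam_names
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 gc_content = gc_content, families = families, waves = waves,
                 est_count = as.integer(est_count),
                 est_families = est_families, est_K = est_K,
                 kappa = kappa, cpg_factor = cpg_factor),
            class = "GeneratorConfig")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# random sense codon drawn uniformly from the 61 non-stop codons
sense_codons <- function() {
  all <- names(Biostrings::GENETIC_CODE)
  setdiff(all, STOP_CODONS)
}

# reverse-translate a peptide with random synonymous codons (keeps the
# nucleotide sequences of the same marker distinct across elements)
peptide_to_codons <- function(peptide) {
  gc <- Biostrings::GENETIC_CODE
  vapply(seq_chars(peptide), function(aa) {
    cands <- names(gc)[gc == aa]
    if (length(cands) == 1) cands else sample(cands, 1)
  }, "")
}

# Write the coding layout into a character vector of bases under the frame
# constraints: each ORF starts with ATG, ends with a stop, has no internal
# in-frame stop, keeps its marker peptides, and (where room permits) has an
# in-frame stop immediately upstream so the ORF is maximal. Overlapping ORFs
# sit in different frames; free bases in conflict regions are re-sampled until
# all constraints hold.
write_orfs <- function(chars, orf_layout) {
  n <- length(chars)
  fixed <- logical(n)
  sense <- sense_codons()

  put <- function(chars, pos, bases, force = FALSE) {
    idx <- pos:(pos + length(bases) - 1L)
    take <- force | !fixed[idx]
    chars[idx[take]] <- bases[take]
    chars
  }
  mark_fixed <- function(pos, len) fixed[pos:(pos + len - 1L)] <<- TRUE

  # first pass: write content, fix features
  for (o in orf_layout) {
    ncod <- (o$end - o$start + 1L) %/% 3L
    codons <- sample(sense, ncod, replace = TRUE)
    codons[1] <- "ATG"
    codons[ncod] <- "TAA"
    if (!is.null(o$markers) && length(o$markers)) {
      for (k in seq_along(o$markers)) {
        lab <- names(o$markers)[k]
        off <- o$markers[[k]]
        pep <- domain_markers()[[lab]]
        codons[off:(off + nchar(pep) - 1L)] <- peptide_to_codons(pep)
      }
    }
    bases <- seq_chars(paste(codons, collapse = ""))
    chars <- put(chars, o$start, bases)
    mark_fixed(o$start, 3L)            # ATG
    mark_fixed(o$end - 2L, 3L)         # stop
    if (!is.null(o$markers) && length(o$markers)) {
      for (k in seq_along(o$markers)) {
        off <- o$markers[[k]]
        mark_fixed(o$start + (off - 1L) * 3L, nchar(domain_markers()[[names(o$markers)[k]]]) * 3L)
      }
    }
    # upstream in-frame stop enforcing ORF maximality, where the bases are free
    if (o$start >= 4L) {
      up <- (o$start - 3L):(o$start - 1L)
      if (!any(fixed[up])) {
        chars[up] <- c("T", "G", "A")
        fixed[up] <- TRUE
      }
    }
  }

  # repair pass: resample free bases of violating codons
  orf_ok <- function(o) {
    s <- chars[o$start:o$end]
    if (!identical(s[1:3], c("A", "T", "G"))) return(FALSE)
    cods <- apply(matrix(s, nrow = 3), 2, paste, collapse = "")
    ncod <- length(cods)
    if (!(cods[ncod] %in% STOP_CODONS)) return(FALSE)
    !any(cods[-ncod] %in% STOP_CODONS)
  }
  for (iter in 1:2000) {
    bad <- NULL
    for (o in orf_layout) {
      s <- chars[o$start:o$end]
      cods <- apply(matrix(s, nrow = 3), 2, paste, collapse = "")
      ncod <- length(cods)
      hit <- which(cods[-ncod] %in% STOP_CODONS)
      hit <- hit[hit > 1L]  # never the ATG codon
      if (length(hit)) {
        bad <- c(bad, lapply(hit, function(h) o$start + (h - 1L) * 3L))
      }
    }
    if (is.null(bad)) break
    for (pos in bad) {
      idx <- pos:(pos + 2L)
      free <- idx[!fixed[idx]]
      if (!length(free)) stop("unresolvable ORF layout conflict at position ", pos)
      chars[free] <- sample(DNA_BASES4, length(free), replace = TRUE)
    }
    if (iter == 2000) stop("could not satisfy ORF frame constraints")
  }
  for (o in orf_layout) {
    if (!orf_ok(o)) stop("ORF constraint violated after repair at ", o$start)
  }
  chars
}

in_any_orf <- function(pos, orf_layout) {
  any(vapply(orf_layout, function(o) pos >= o$start - 3L && pos <= o$end, TRUE))
}

orf_truth <- function(orf_layout) {
  do.call(rbind, lapply(seq_along(orf_layout), function(i) {
    o <- orf_layout[[i]]
    data.frame(orf = i, start = o$start, end = o$end,
               frame = ((o$start - 1L) %% 3L) + 1L,
               markers = paste(names(o$markers), collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Generate a DIRS-like consensus element
#'
#' Builds a sequence that begins and ends with the terminal trinucleotide,
#' carries an exact inverted terminal repeat pair (lITR / rITR), an internal
#' complementary region ICR = lICR+rICR whose halves are the reverse
#' complements of the element's 5'- and 3'-terminal segments, and the ORFs of
#' `spec$orf_layout` with their domain-marker peptides.
#'
#' @param spec A DIRS-like [family_spec()].
#' @param gc GC content of unconstrained positions.
#' @return An `ElementConsensus` list: `name`, `superfamily`, `sequence`, and
#'   `annotations` (true coordinates of every structural feature, 1-based
#'   closed intervals).
#' @export
make_dirs_like_consensus <- function(spec, gc = 0.4) {
  stopifnot(inherits(spec, "FamilySpec"), spec$superfamily == "DIRS-like")
  L <- spec$length
  t3 <- spec$terminal_trinucleotide
  tl <- nchar(t3)
  itr <- spec$itr_length
  icr <- spec$icr_segment_length
  icr_start <- tl + itr + spec$icr_offset + 1L
  if (icr_start + 2L * icr - 1L >= min(vapply(spec$orf_layout, function(o) o$start, 1L)))
    stop("ICR does not fit before the first ORF")
  if (2L * (tl + itr) + 2L * icr > L) stop("repeats cannot be packed into element length")

  chars <- seq_chars(random_dna(L, gc))
  chars[1:tl] <- seq_chars(t3)
  chars[(L - tl + 1L):L] <- seq_chars(t3)
  litr <- random_dna(itr, gc)
  chars[(tl + 1L):(tl + itr)] <- seq_chars(litr)
  ritr_iv <- c(L - tl - itr + 1L, L - tl)
  chars[ritr_iv[1]:ritr_iv[2]] <- seq_chars(revcomp(litr))

  chars <- write_orfs(chars, spec$orf_layout)

  # ICR written after the termini/ORFs so its complementarity is exact
  l_ter <- chars_seq(chars[1:icr])
  r_ter <- chars_seq(chars[(L - icr + 1L):L])
  icr_seq <- paste0(revcomp(l_ter), revcomp(r_ter))
  icr_end <- icr_start + 2L * icr - 1L
  chars[icr_start:icr_end] <- seq_chars(icr_seq)

  # boundary guards: the base just outside each repeat must not extend the
  # complementarity by chance, so true coordinates are unambiguous
  for (g in list(c(tl + itr + 1L, ritr_iv[1] - 1L),
                 c(icr_start - 1L, icr + 1L),
                 c(icr_end + 1L, L - icr))) {
    if (!in_any_orf(g[1], spec$orf_layout))
      chars[g[1]] <- guard_base(chars[g[1]], comp_base(chars[g[2]]))
  }

  ann <- list(
    terminal_trinucleotide = t3,
    itr5 = c(tl + 1L, tl + itr),
    itr3 = ritr_iv,
    icr_l = c(icr_start, icr_start + icr - 1L),
    icr_r = c(icr_start + icr, icr_start + 2L * icr - 1L),
    orfs = orf_truth(spec$orf_layout)
  )
  structure(list(name = spec$name, superfamily = "DIRS-like",
                 sequence = chars_seq(chars), annotations = ann),
            class = "ElementConsensus")
}

#' Generate a Ngaro-like consensus element
#'
#' Layout: A1 (5' end), internal body with the overlapping ORFs (including the
#' SGNH hydrolase marker), then B1 A2 B2 at the 3' end, with A1 identical to
#' A2 and B1 identical to B2 (100% identity split direct repeats).
#'
#' @inheritParams make_dirs_like_consensus
#' @return An `ElementConsensus` list.
#' @export
make_ngaro_like_consensus <- function(spec, gc = 0.4) {
  stopifnot(inherits(spec, "FamilySpec"), spec$superfamily == "Ngaro-like")
  L <- spec$length
  a <- spec$sdr_a_length
  b <- spec$sdr_b_length
  if (2L * (a + b) >= L) stop("SDR blocks cannot be packed into element length")
  b2 <- c(L - b + 1L, L)
  a2 <- c(b2[1] - a, b2[1] - 1L)
  b1 <- c(a2[1] - b, a2[1] - 1L)
  last_orf_end <- max(vapply(spec$orf_layout, function(o) o$end, 1L))
  if (last_orf_end >= b1[1]) stop("ORFs collide with the 3' SDR blocks")

  chars <- seq_chars(random_dna(L, gc))
  chars <- write_orfs(chars, spec$orf_layout)
  a_seq <- random_dna(a, 0.4)
  b_seq <- random_dna(b, 0.4)
  chars[1:a] <- seq_chars(a_seq)
  chars[a2[1]:a2[2]] <- seq_chars(a_seq)
  chars[b1[1]:b1[2]] <- seq_chars(b_seq)
  chars[b2[1]:b2[2]] <- seq_chars(b_seq)

  # boundary guards so direct-repeat extension stops at the true coordinates
  if (!in_any_orf(a + 1L, spec$orf_layout))
    chars[a + 1L] <- guard_base(chars[a + 1L], chars[a2[2] + 1L])
  if (!in_any_orf(b1[1] - 1L, spec$orf_layout))
    chars[b1[1] - 1L] <- guard_base(chars[b1[1] - 1L], chars[b2[1] - 1L])

  ann <- list(
    sdr_a1 = c(1L, a), sdr_b1 = b1, sdr_a2 = a2, sdr_b2 = b2,
    orfs = orf_truth(spec$orf_layout)
  )
  structure(list(name = spec$name, superfamily = "Ngaro-like",
                 sequence = chars_seq(chars), annotations = ann),
            class = "ElementConsensus")
}

#' Generate the consensus for any family spec
#' @param spec A [family_spec()].
#' @param gc GC content.
#' @return An `ElementConsensus`.
#' @export
make_consensus <- function(spec, gc = 0.4) {
  if (spec$superfamily == "DIRS-like") make_dirs_like_consensus(spec, gc)
  else make_ngaro_like_consensus(spec, gc)
}

#' Mutate a sequence to a target Kimura divergence
#'
#' Applies independent site-wise substitutions under the Kimura 2-parameter
#' model so that the expected K2P distance between input and output is
#' `target_K`. With `kappa` the transition/transversion *rate* ratio
#' (alpha/beta), the per-site transition and transversion probabilities follow
#' the closed forms P(t) = 1/4 - 1/2 e^(-2(a+b)t) + 1/4 e^(-4bt) and
#' Q(t) = 1/2 - 1/2 e^(-4bt) with (a+2b)t = K. Transitions at CpG dinucleotide
#' positions of the input (both the C and the G) use a transition rate
#' multiplied by `cpg_factor`, emulating CpG hypermutability.
#'
#' @param seq Input DNA character string.
#' @param target_K Target K2P divergence (substitutions/site), >= 0.
#' @param kappa Transition/transversion rate ratio alpha/beta (> 0).
#' @param cpg_factor Transition-rate multiplier at CpG sites.
#' @param indel_rate Per-site indel initiation probability (default 0 = off);
#'   indel lengths are geometric with mean 2.
#' @return Mutated DNA character string.
#' @export
mutate_copy <- function(seq, target_K, kappa = 2, cpg_factor = 1,
                        indel_rate = 0) {
  stopifnot(target_K >= 0, kappa > 0, cpg_factor > 0)
  if (target_K == 0 && indel_rate == 0) return(seq)
  chars <- seq_chars(seq)
  n <- length(chars)
  bt <- target_K / (kappa + 2)
  at <- kappa * bt
  at_site <- rep(at, n)
  if (cpg_factor != 1 && n >= 2) {
    cpg_c <- which(chars[-n] == "C" & chars[-1] == "G")
    boost <- unique(c(cpg_c, cpg_c + 1L))
    at_site[boost] <- at_site[boost] * cpg_factor
  }
  p_ts <- 0.25 - 0.5 * exp(-2 * (at_site + bt)) + 0.25 * exp(-4 * bt)
  q_tv <- 0.5 - 0.5 * exp(-4 * bt)
  u <- runif(n)
  is_ts <- u < p_ts
  is_tv <- !is_ts & (u < p_ts + q_tv)
  out <- chars
  if (any(is_ts)) out[is_ts] <- TRANSITION[chars[is_ts]]
  if (any(is_tv)) {
    # the two transversion partners of each base, chosen uniformly
    purine <- chars[is_tv] %in% c("A", "G")
    pick <- runif(sum(is_tv)) < 0.5
    out[is_tv] <- ifelse(purine, ifelse(pick, "C", "T"), ifelse(pick, "A", "G"))
  }
  if (indel_rate > 0) {
    out <- apply_indels(out, indel_rate)
  }
  chars_seq(out)
}

# small indels: geometric lengths (mean 2), half deletions half insertions
apply_indels <- function(chars, rate) {
  n <- length(chars)
  sites <- which(runif(n) < rate)
  if (!length(sites)) return(chars)
  pieces <- character(0)
  prev <- 1L
  for (s in sites) {
    if (s < prev) next
    len <- 1L + stats::rgeom(1, 0.5)
    if (runif(1) < 0.5) {  # deletion of len bases starting at s
      if (s > prev) pieces <- c(pieces, chars_seq(chars[prev:(s - 1L)]))
      prev <- min(n + 1L, s + len)
    } else {               # insertion after s
      pieces <- c(pieces, chars_seq(chars[prev:s]), random_dna(len, 0.5))
      prev <- s + 1L
    }
  }
  if (prev <= n) pieces <- c(pieces, chars_seq(chars[prev:n]))
  seq_chars(paste(pieces, collapse = ""))
}

#' Build a synthetic genome bundle
#'
#' Generates the family consensus library, plants mutated (optionally
#' truncated) copies at non-overlapping random positions on random strands to
#' form the configured amplification waves, simulates EST reads as lightly
#' mutated consensus subsequences, and records a machine-readable truth table.
#'
#' @param config A [generator_config()].
#' @return A `GenomeBundle` list: `genome` (character string), `library`
#'   (named character vector of consensuses), `consensus` (list of
#'   `ElementConsensus`), `truth` (data frame: copy_id, family, superfamily,
#'   start, end, strand, target_K, intact, trunc5, trunc3; 1-based closed
#'   coordinates on the forward strand), `ests` (named character vector),
#'   `est_truth`, and `config`.
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  fam_names <- vapply(config$families, function(f) f$name, "")

  set.seed(substream_seed(config$seed, "consensus"))
  consensus <- lapply(config$families, make_consensus, gc = config$gc_content)
  names(consensus) <- fam_names
  library <- vapply(consensus, function(x) x$sequence, "")

  set.seed(substream_seed(config$seed, "background"))
  genome <- seq_chars(random_dna(config$genome_length, config$gc_content))

  set.seed(substream_seed(config$seed, "copies"))
  placed <- matrix(numeric(0), ncol = 2)
  rows <- list()
  copy_no <- 0L
  for (w in config$waves) {
    f <- config$families[[match(w$family, fam_names)]]
    cons <- library[[w$family]]
    for (i in seq_len(w$n_copies)) {
      copy_no <- copy_no + 1L
      intact <- runif(1) < w$intact_fraction
      s <- cons
      trunc5 <- trunc3 <- 0L
      if (!intact) {
        # lose a uniform fraction from the 5' and/or 3' end
        side <- sample(c("5", "3", "both"), 1)
        if (side %in% c("5", "both"))
          trunc5 <- as.integer(runif(1, 0.05, w$max_truncation) * nchar(s))
        if (side %in% c("3", "both"))
          trunc3 <- as.integer(runif(1, 0.05, w$max_truncation) * nchar(s))
        s <- substr(s, trunc5 + 1L, nchar(s) - trunc3)
      }
      s <- mutate_copy(s, w$target_K, kappa = config$kappa,
                       cpg_factor = config$cpg_factor)
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") s else revcomp(s)
      len <- nchar(ins)
      pos <- NA
      for (try in 1:500) {
        cand <- sample.int(config$genome_length - len + 1L, 1)
        if (!nrow(placed) ||
            !any(cand <= placed[, 2] & cand + len - 1L >= placed[, 1])) {
          pos <- cand
          break
        }
      }
      if (is.na(pos)) stop("could not place copy without overlap; genome too dense")
      placed <- rbind(placed, c(pos, pos + len - 1L))
      genome[pos:(pos + len - 1L)] <- seq_chars(ins)
      rows[[copy_no]] <- data.frame(
        copy_id = sprintf("%s_copy%03d", w$family, copy_no),
        family = w$family, superfamily = f$superfamily,
        start = pos, end = pos + len - 1L, strand = strand,
        target_K = w$target_K, intact = intact,
        trunc5 = trunc5, trunc3 = trunc3, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(copy_id = character(0), family = character(0),
               superfamily = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               target_K = numeric(0), intact = logical(0),
               trunc5 = integer(0), trunc3 = integer(0))

  set.seed(substream_seed(config$seed, "est"))
  ests <- character(0)
  est_rows <- list()
  if (config$est_count > 0 && length(config$est_families)) {
    for (i in seq_len(config$est_count)) {
      fam <- sample(config$est_families, 1)
      cons <- library[[fam]]
      len <- sample(100:min(600L, nchar(cons)), 1)
      start <- sample.int(nchar(cons) - len + 1L, 1)
      read <- mutate_copy(substr(cons, start, start + len - 1L), config$est_K,
                          kappa = config$kappa)
      id <- sprintf("est%04d", i)
      ests[[id]] <- read
      est_rows[[i]] <- data.frame(est_id = id, family = fam, cons_start = start,
                                  cons_end = start + len - 1L,
                                  stringsAsFactors = FALSE)
    }
  }
  est_truth <- if (length(est_rows)) do.call(rbind, est_rows) else
    data.frame(est_id = character(0), family = character(0),
               cons_start = integer(0), cons_end = integer(0))

  structure(list(genome = chars_seq(genome), library = library,
                 consensus = consensus, truth = truth, ests = ests,
                 est_truth = est_truth, config = config),
            class = "GenomeBundle")
}

#' Write a genome bundle to disk
#'
#' Writes `genome.fasta`, `library.fasta`, `ests.fasta`, the truth table as
#' BED6 (`truth.bed`: 0-based half-open, name = family, score =
#' round(1000 * target_K), strand) and as TSV (`truth.tsv`), plus the
#' generator config as YAML.
#'
#' @param bundle A [build_genome()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(c(genome = bundle$genome), file.path(dir, "genome.fasta"))
  write_fasta(bundle$library, file.path(dir, "library.fasta"))
  if (length(bundle$ests))
    write_fasta(bundle$ests, file.path(dir, "ests.fasta"))
  tt <- bundle$truth
  bed <- data.frame(chrom = "genome", start = tt$start - 1L, end = tt$end,
                    name = tt$family, score = round(1000 * tt$target_K),
                    strand = tt$strand)
  write.table(bed, file.path(dir, "truth.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(tt, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- bundle$config
  yaml::write_yaml(list(seed = cfg$seed, genome_length = cfg$genome_length,
                        gc_content = cfg$gc_content,
                        families = vapply(cfg$families, function(f) f$name, ""),
                        est_count = cfg$est_count),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
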