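# k-mer index of a long subject string: list mapping k-mer -> start positions
kmer_index <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(list())
  km <- substring(s, 1:(n - k + 1L), k:n)
  split(seq_along(km), km)
}

# seed positions of query k-mers in a prebuilt index: matrix (qpos, spos)
kmer_seeds <- function(query, index, k) {
  nq <- nchar(query)
  if (nq < k) return(cbind(qpos = integer(0), spos = integer(0)))
  kq <- substring(query, 1:(nq - k + 1L), k:nq)
  hits <- index[kq]
  nh <- lengths(hits)
  have <- which(nh > 0L)
  cbind(qpos = rep(have, nh[have]),
        spos = unlist(hits[have], use.names = FALSE))
}

# cluster seeds into candidate subject windows for a query of length qlen;
# clusters with fewer than min_seeds seeds are discarded as spurious.
# returns matrix of (win_start, win_end) on the subject
seed_windows <- function(seeds, qlen, slen, band = 200L, gap = 1000L,
                         margin = 100L, min_seeds = 1L) {
  if (!nrow(seeds)) return(cbind(start = integer(0), end = integer(0)))
  d <- seeds[, "spos"] - seeds[, "qpos"]
  o <- order(round(d / band), seeds[, "spos"])
  d <- d[o]; qp <- seeds[o, "qpos"]; sp <- seeds[o, "spos"]
  brk <- c(TRUE, abs(diff(round(d / band))) > 0 | diff(sp) > gap)
  grp <- cumsum(brk)
  groups <- split(seq_along(grp), grp)
  groups <- groups[lengths(groups) >= min_seeds]
  if (!length(groups)) return(cbind(start = integer(0), end = integer(0)))
  wins <- t(vapply(groups, function(g) {
    ws <- min(sp[g] - qp[g]) + 1L - margin
    we <- max(sp[g] + (qlen - qp[g])) + margin
    c(max(1L, ws), min(slen, we))
  }, c(0L, 0L)))
  colnames(wins) <- c("start", "end")
  merge_windows(wins)
}

merge_windows <- function(wins) {
  if (nrow(wins) < 2) return(wins)
  o <- order(wins[, 1])
  wins <- wins[o, , drop = FALSE]
  out <- wins[1, , drop = FALSE]
  for (i in 2:nrow(wins)) {
    if (wins[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], wins[i, 2])
    } else {
      out <- rbind(out, wins[i, , drop = FALSE])
    }
  }
  out
}

nuc_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = TRUE)
}

#' Mask a genome with a consensus library
#'
#' Nucleotide seed-and-extend screening of a genome against every library
#' consensus (the in-package analog of a RepeatMasker run with alignment
#' output): exact 11-mer seeds on both strands are clustered into candidate
#' loci, each locus is aligned locally to the consensus, and overlapping hits
#' across families are resolved to the best-scoring one. The per-copy gapped
#' alignments are returned for downstream divergence analysis.
#'
#' @param library Named character vector of consensus sequences.
#' @param genome Single genome character string.
#' @param k Seed word size (nt).
#' @param min_score Minimum alignment score (match +1 / mismatch -1) to keep.
#' @param min_seeds Minimum seeds per candidate locus (guards against
#'   spurious word matches triggering costly alignments).
#' @param gap_opening,gap_extension Affine gap penalties (positive numbers).
#' @return `list(hits, summary)`. `hits`: data frame with `family`, `g_start`,
#'   `g_end`, `strand`, `c_start`, `c_end` (consensus coordinates), `score`,
#'   `aligned_copy`, `aligned_cons` (gapped strings, consensus orientation),
#'   `copy_bp`. `summary`: per-family masked bp and percent of genome, plus a
#'   `total` row.
#' @export
mask_genome <- function(library, genome, k = 11L, min_score = 50,
                        min_seeds = 5L, gap_opening = 5, gap_extension = 1) {
  glen <- nchar(genome)
  hits <- list()
  if (length(library) && glen >= k) {
    gindex <- kmer_index(genome, k)
    mat <- nuc_submat()
    for (fi in seq_along(library)) {
      fam <- names(library)[fi]
      cons <- library[[fi]]
      clen <- nchar(cons)
      for (strand in c("+", "-")) {
        q <- if (strand == "+") cons else revcomp(cons)
        seeds <- kmer_seeds(q, gindex, k)
        wins <- seed_windows(seeds, clen, glen, min_seeds = min_seeds)
        for (wi in seq_len(nrow(wins))) {
          hits <- c(hits, align_locus(cons, fam, genome, wins[wi, 1],
                                      wins[wi, 2], strand, mat, min_score,
                                      gap_opening, gap_extension))
        }
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(family = character(0), g_start = integer(0),
               g_end = integer(0), strand = character(0),
               c_start = integer(0), c_end = integer(0), score = numeric(0),
               aligned_cons = character(0), aligned_copy = character(0),
               copy_bp = integer(0))
  hits <- resolve_overlaps(hits)
  fams <- names(library)
  bp <- vapply(fams, function(f) {
    sum(hits$copy_bp[hits$family == f])
  }, 0)
  summary <- data.frame(family = c(fams, "total"),
                        masked_bp = c(bp, sum(bp)),
                        pct_genome = 100 * c(bp, sum(bp)) / glen,
                        row.names = NULL)
  list(hits = hits, summary = summary)
}

# Locally align a consensus to one genomic window; a merged window can hold
# several copies, so after recording a hit the flanking sub-windows are
# searched recursively. Returns a list of hit data frames.
align_locus <- function(cons, fam, genome, ws, we, strand, mat, min_score,
                        gap_opening, gap_extension, depth = 0L) {
  if (we - ws + 1L < 100L || depth > 6L) return(list())
  win <- substr(genome, ws, we)
  subj <- if (strand == "+") win else revcomp(win)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(cons),
    subject = Biostrings::DNAString(subj),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  if (Biostrings::score(pa) < min_score) return(list())
  ps <- pa@pattern@range
  ss <- pa@subject@range
  s1 <- BiocGenerics::start(ss); s2 <- BiocGenerics::end(ss)
  if (strand == "+") {
    g1 <- ws + s1 - 1L
    g2 <- ws + s2 - 1L
  } else {
    wlen <- nchar(win)
    g1 <- ws + (wlen - s2)
    g2 <- ws + (wlen - s1)
  }
  hit <- data.frame(
    family = fam, g_start = g1, g_end = g2, strand = strand,
    c_start = BiocGenerics::start(ps), c_end = BiocGenerics::end(ps),
    score = Biostrings::score(pa),
    aligned_cons = as.character(Biostrings::alignedPattern(pa)),
    aligned_copy = as.character(Biostrings::alignedSubject(pa)),
    copy_bp = g2 - g1 + 1L, stringsAsFactors = FALSE)
  c(list(hit),
    align_locus(cons, fam, genome, ws, g1 - 10L, strand, mat, min_score,
                gap_opening, gap_extension, depth + 1L),
    align_locus(cons, fam, genome, g2 + 10L, we, strand, mat, min_score,
                gap_opening, gap_extension, depth + 1L))
}

# higher score wins; a hit overlapping a kept hit by > 50% of its own span is
# dropped (ties resolved by library/input order)
resolve_overlaps <- function(hits) {
  if (nrow(hits) < 2) return(hits)
  o <- order(-hits$score, seq_len(nrow(hits)))
  hits <- hits[o, ]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(hits)) > i)
    if (!length(j)) next
    ov <- pmin(hits$g_end[j], hits$g_end[i]) -
      pmax(hits$g_start[j], hits$g_start[i]) + 1L
    drop <- ov > 0.5 * (hits$g_end[j] - hits$g_start[j] + 1L)
    keep[j][drop] <- FALSE
  }
  hits <- hits[keep, ]
  hits <- hits[order(hits$g_start), ]
  rownames(hits) <- NULL
  hits
}

# six-frame translation of a genome: list of (strand, frame, protein)
six_frame <- function(genome) {
  L <- nchar(genome)
  rc <- revcomp(genome)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome else rc
    for (f in 1:3) {
      out[[length(out) + 1L]] <- list(
        strand = strand, frame = f,
        protein = translate_dna(substr(s, f, L)))
    }
  }
  out
}

# map a protein interval of frame f back to forward-strand nt coordinates
frame_to_nt <- function(aa_start, aa_end, frame, strand, L) {
  nt1 <- frame + 3L * (aa_start - 1L)
  nt2 <- frame + 3L * aa_end - 1L
  if (strand == "+") c(nt1, nt2) else c(L - nt2 + 1L, L - nt1 + 1L)
}

#' Translated homology search of a protein against a genome
#'
#' Six-frame translation of the genome is scanned by exact amino-acid k-mer
#' seeding; seed clusters are aligned locally (BLOSUM62, affine gaps) to the
#' query, mirroring a tBLASTn search. The best `top_n` hits are returned,
#' each with `flank_bp` of nucleotide context on both sides (clipped at the
#' sequence ends).
#'
#' @param query_protein Amino-acid character string (e.g. an RT domain).
#' @param genome Genome character string.
#' @param top_n Number of hits to return (default 10).
#' @param flank_bp Flanking nucleotides to attach to each hit (default 3000).
#' @param k Amino-acid seed word size.
#' @param min_score Minimum BLOSUM62 alignment score to keep.
#' @return Data frame: `g_start`, `g_end`, `strand`, `frame`, `score`,
#'   `aa_start`, `aa_end` (query coordinates), `hit_protein`,
#'   `flank_start`, `flank_end`, `flank_seq`.
#' @export
translated_search <- function(query_protein, genome, top_n = 10L,
                              flank_bp = 3000L, k = 4L, min_score = 40) {
  L <- nchar(genome)
  b62 <- get_blosum62()
  frames <- six_frame(genome)
  hits <- list()
  for (fr in frames) {
    prot <- fr$protein
    if (nchar(prot) < k) next
    index <- kmer_index(prot, k)
    seeds <- kmer_seeds(query_protein, index, k)
    wins <- seed_windows(seeds, nchar(query_protein), nchar(prot),
                         band = 60L, gap = 300L, margin = 50L)
    for (wi in seq_len(nrow(wins))) {
      wprot <- substr(prot, wins[wi, 1], wins[wi, 2])
      pa <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::AAString(query_protein),
        subject = Biostrings::AAString(wprot),
        type = "local", substitutionMatrix = b62,
        gapOpening = 11, gapExtension = 1)
      if (Biostrings::score(pa) < min_score) next
      ss <- pa@subject@range
      aa1 <- wins[wi, 1] + BiocGenerics::start(ss) - 1L
      aa2 <- wins[wi, 1] + BiocGenerics::end(ss) - 1L
      nt <- frame_to_nt(aa1, aa2, fr$frame, fr$strand, L)
      hits[[length(hits) + 1L]] <- data.frame(
        g_start = nt[1], g_end = nt[2], strand = fr$strand, frame = fr$frame,
        score = Biostrings::score(pa),
        aa_start = BiocGenerics::start(pa@pattern@range),
        aa_end = BiocGenerics::end(pa@pattern@range),
        hit_protein = gsub("-", "", as.character(Biostrings::alignedSubject(pa))),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(g_start = integer(0), g_end = integer(0),
                      strand = character(0), frame = integer(0),
                      score = numeric(0), aa_start = integer(0),
                      aa_end = integer(0), hit_protein = character(0),
                      flank_start = integer(0), flank_end = integer(0),
                      flank_seq = character(0)))
  }
  hits <- do.call(rbind, hits)
  # drop duplicate/contained hits on the same locus, keep best score
  o <- order(-hits$score)
  hits <- hits[o, ]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(hits)) > i)
    if (!length(j)) next
    ov <- pmin(hits$g_end[j], hits$g_end[i]) -
      pmax(hits$g_start[j], hits$g_start[i]) + 1L
    keep[j][ov > 0.5 * (hits$g_end[j] - hits$g_start[j] + 1L)] <- FALSE
  }
  hits <- hits[keep, ][seq_len(min(top_n, sum(keep))), ]
  hits$flank_start <- pmax(1L, hits$g_start - flank_bp)
  hits$flank_end <- pmin(L, hits$g_end + flank_bp)
  hits$flank_seq <- substr(rep(genome, nrow(hits)), hits$flank_start,
                           hits$flank_end)
  rownames(hits) <- NULL
  hits
}

#' Filter EST matches against family consensuses
#'
#' Aligns every EST locally against every consensus and keeps pairs passing
#' the identity and length filters (identity is matches over alignment
#' columns, BLAST-style; both filters are strict inequalities).
#'
#' @param ests Named character vector of EST sequences.
#' @param library Named character vector of family consensuses.
#' @param min_identity Identity threshold (kept if identity > this; default 0.85).
#' @param min_match_len Alignment length threshold in bp (kept if longer;
#'   default 100).
#' @return `list(matches, evidence)`: `matches` has one row per passing
#'   EST-family pair (`est`, `family`, `identity`, `match_len`, `score`);
#'   `evidence` is a per-family logical ("has transcript evidence").
#' @export
match_ests <- function(ests, library, min_identity = 0.85,
                       min_match_len = 100L) {
  mat <- nuc_submat()
  out <- list()
  for (ei in seq_along(ests)) {
    for (fi in seq_along(library)) {
      pa <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(ests[[ei]]),
        subject = Biostrings::DNAString(library[[fi]]),
        type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 1)
      alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
      if (alen == 0) next
      ident <- Biostrings::nmatch(pa) / alen
      if (ident > min_identity && alen > min_match_len) {
        out[[length(out) + 1L]] <- data.frame(
          est = names(ests)[ei], family = names(library)[fi],
          identity = ident, match_len = alen,
          score = Biostrings::score(pa), stringsAsFactors = FALSE)
      }
    }
  }
  matches <- if (length(out)) do.call(rbind, out) else
    data.frame(est = character(0), family = character(0),
               identity = numeric(0), match_len = integer(0),
               score = numeric(0))
  evidence <- vapply(names(library), function(f) f %in% matches$family, TRUE)
  list(matches = matches, evidence = evidence)
}
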