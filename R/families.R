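#' Pairwise divergence of two sequences
#'
#' Two scales are offered. `"aligned"` (the direct per-column measure):
#' global alignment with affine gaps, divergence = 1 - identity over aligned
#' columns where neither sequence has a gap. `"coverage"` (the family-
#' membership measure): local alignment, divergence = 1 - matches /
#' max(sequence lengths), so unrelated sequences — whose optimal global
#' alignment still pairs roughly half the bases by chance — score close to 1
#' and fall apart at the 80% family threshold, in the spirit of the
#' 80-80-80 family rule. The two scales agree on gap-free alignments of
#' equal-length sequences.
#'
#' @param seq_a,seq_b DNA character strings.
#' @param scale `"aligned"` or `"coverage"`.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Divergence fraction in \[0, 1\].
#' @export
pairwise_divergence <- function(seq_a, seq_b, scale = c("aligned", "coverage"),
                                gap_opening = 5, gap_extension = 1) {
  scale <- match.arg(scale)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(seq_a),
    subject = Biostrings::DNAString(seq_b),
    type = if (scale == "aligned") "global" else "local",
    substitutionMatrix = nuc_submat(),
    gapOpening = gap_opening, gapExtension = gap_extension)
  if (scale == "coverage") {
    return(max(0, 1 - Biostrings::nmatch(pa) / max(nchar(seq_a), nchar(seq_b))))
  }
  a <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  b <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  shared <- a != "-" & b != "-"
  if (!any(shared)) return(1)
  1 - mean(a[shared] == b[shared])
}

#' Pairwise divergence matrix
#'
#' @param seqs Named character vector of sequences.
#' @param ... Passed to [pairwise_divergence()] (notably `scale`).
#' @return Symmetric matrix with zero diagonal.
#' @export
divergence_matrix <- function(seqs, ...) {
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- pairwise_divergence(seqs[[i]], seqs[[j]], ...)
      }
    }
  }
  m
}

#' Cluster sequences into families by divergence
#'
#' Single-linkage grouping: sequences with pairwise divergence at or below
#' `threshold` are connected, and connected components are families
#' (sequences separated by more than the threshold from every member of a
#' group form distinct families).
#'
#' @param matrix Symmetric divergence matrix.
#' @param threshold Maximum within-family divergence (default 0.80).
#' @return Integer vector of cluster ids (1-based, numbered by first member).
#' @export
cluster_families <- function(matrix, threshold = 0.80) {
  n <- nrow(matrix)
  if (n == 0) return(integer(0))
  id <- rep(NA_integer_, n)
  nxt <- 0L
  for (s in seq_len(n)) {
    if (!is.na(id[s])) next
    nxt <- nxt + 1L
    queue <- s
    id[s] <- nxt
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(matrix[v, ] <= threshold & is.na(id))
      id[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  names(id) <- rownames(matrix)
  id
}

#' Center-star multiple alignment
#'
#' Progressive alignment against the center sequence (the one minimizing
#' summed divergence to all others); pairwise alignments to the center are
#' merged under the once-a-gap-always-a-gap rule. Adequate at the
#' within-family divergences used here; not a substitute for an iterative
#' refinement aligner.
#'
#' @param seqs Named character vector (2 or more sequences; DNA or protein).
#' @param type `"dna"` or `"protein"` (controls the substitution matrix).
#' @return Named character vector of equal-width gapped sequences.
#' @export
center_star_align <- function(seqs, type = c("dna", "protein")) {
  type <- match.arg(type)
  n <- length(seqs)
  if (n == 1) return(seqs)
  submat <- if (type == "dna") nuc_submat() else get_blosum62()
  make <- if (type == "dna") Biostrings::DNAString else Biostrings::AAString
  # center = minimum summed divergence (p-distance over the pairwise
  # alignments used for the star)
  pas <- vector("list", n * n)
  div <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      pa <- Biostrings::pairwiseAlignment(
        pattern = make(seqs[[j]]), subject = make(seqs[[i]]),
        type = "global", substitutionMatrix = submat,
        gapOpening = if (type == "dna") 5 else 11, gapExtension = 1)
      pas[[(i - 1) * n + j]] <- pa
      a <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
      b <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
      sh <- a != "-" & b != "-"
      d <- if (any(sh)) 1 - mean(a[sh] == b[sh]) else 1
      div[i, j] <- div[j, i] <- d
    }
  }
  center <- which.min(rowSums(div))
  m <- nchar(seqs[[center]])
  others <- setdiff(seq_len(n), center)
  gp <- list()  # per sequence: pattern chars split by center-gap slots
  g <- rep(0L, m + 1L)  # master insertion counts before center base j
  for (i in others) {
    lo <- min(i, center); hi <- max(i, center)
    pa <- pas[[(lo - 1) * n + hi]]
    pat <- if (i > center) as.character(Biostrings::alignedPattern(pa))
      else as.character(Biostrings::alignedSubject(pa))
    cen <- if (i > center) as.character(Biostrings::alignedSubject(pa))
      else as.character(Biostrings::alignedPattern(pa))
    pc <- seq_chars(pat); cc <- seq_chars(cen)
    isbase <- cc != "-"
    slot <- cumsum(isbase)           # center base index; gap cols keep prior
    slot[!isbase] <- slot[!isbase]   # gap col belongs to slot = bases so far
    gaps <- lapply(0:m, function(j) pc[!isbase & slot == j])
    base <- pc[isbase]
    gp[[as.character(i)]] <- list(gaps = gaps, base = base)
    g <- pmax(g, lengths(gaps))
  }
  pad <- function(x, len) c(x, rep("-", len - length(x)))
  rows <- vector("list", n)
  cenb <- seq_chars(seqs[[center]])
  crow <- character(0)
  for (j in 0:m) {
    crow <- c(crow, rep("-", g[j + 1L]), if (j < m) cenb[j + 1L])
  }
  rows[[center]] <- chars_seq(crow)
  for (i in others) {
    e <- gp[[as.character(i)]]
    r <- character(0)
    for (j in 0:m) {
      r <- c(r, pad(e$gaps[[j + 1L]], g[j + 1L]), if (j < m) e$base[j + 1L])
    }
    rows[[i]] <- chars_seq(r)
  }
  setNames(unlist(rows), names(seqs))
}

#' Majority-rule consensus of aligned sequences
#'
#' Per column: the most frequent residue if it is a unique mode reaching
#' `threshold` of the non-gap characters; otherwise the IUPAC ambiguity code
#' of the residues above 25% (or `N` when none qualifies). Columns where gaps
#' are the majority are dropped.
#'
#' @param aligned Character vector of equal-width gapped sequences.
#' @param threshold Majority threshold on non-gap frequency (default 0.50).
#' @return Consensus character string.
#' @export
majority_consensus <- function(aligned, threshold = 0.50) {
  stopifnot(length(aligned) >= 1)
  w <- unique(nchar(aligned))
  stopifnot(length(w) == 1)
  mat <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  nrows <- nrow(mat)
  out <- character(0)
  for (col in seq_len(w)) {
    x <- mat[, col]
    ngap <- sum(x == "-")
    if (ngap > nrows / 2) next
    xx <- x[x != "-"]
    tab <- table(xx) / length(xx)
    top <- max(tab)
    modes <- names(tab)[tab == top]
    if (top >= threshold && length(modes) == 1) {
      out <- c(out, modes)
    } else {
      amb <- sort(names(tab)[tab > 0.25])
      key <- paste(amb, collapse = "")
      out <- c(out, if (key %in% names(IUPAC_OF)) IUPAC_OF[[key]] else "N")
    }
  }
  chars_seq(out)
}

#' Filter aligned proteins by coverage
#'
#' Drops sequences whose non-gap fraction of the alignment width is below
#' `min_coverage` (boundary kept: coverage exactly at the threshold passes).
#'
#' @param aligned Named character vector of equal-width gapped proteins.
#' @param min_coverage Minimum non-gap fraction (default 0.70).
#' @return The retained subset of `aligned`.
#' @export
filter_rt_coverage <- function(aligned, min_coverage = 0.70) {
  if (!length(aligned)) return(aligned)
  w <- unique(nchar(aligned))
  stopifnot(length(w) == 1)
  cov <- vapply(aligned, function(s) {
    1 - sum(seq_chars(s) == "-") / w
  }, 0)
  aligned[cov >= min_coverage]
}

#' Group sequences into families and build their consensuses
#'
#' Runs [divergence_matrix()], [cluster_families()] at the 80% divergence
#' threshold, and per cluster a [center_star_align()] +
#' [majority_consensus()] at the 50% threshold.
#'
#' @param seqs Named character vector of sequences.
#' @param threshold Family divergence threshold (default 0.80).
#' @param consensus_threshold Majority threshold (default 0.50).
#' @param scale Divergence scale for clustering (default `"coverage"`, the
#'   family-membership measure; see [pairwise_divergence()]).
#' @return A `FamilySet` list: `divergence` (matrix), `clusters` (integer
#'   vector), `consensus` (character vector, one per cluster).
#' @export
build_family_set <- function(seqs, threshold = 0.80,
                             consensus_threshold = 0.50,
                             scale = "coverage") {
  dm <- divergence_matrix(seqs, scale = scale)
  cl <- cluster_families(dm, threshold)
  cons <- vapply(sort(unique(cl)), function(k) {
    members <- seqs[cl == k]
    if (length(members) == 1) return(unname(members))
    aln <- center_star_align(members, type = "dna")
    majority_consensus(aln, consensus_threshold)
  }, "")
  names(cons) <- paste0("family", sort(unique(cl)))
  structure(list(divergence = dm, clusters = cl, consensus = cons),
            class = "FamilySet")
}
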