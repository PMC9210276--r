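# Independent brute-force oracles used to validate the seed-and-extend and
# scanning code paths. These deliberately share no code with the package
# internals: repeats are found by run-length analysis of shifted base
# vectors, ORFs by a per-position codon walk, clusters by boolean matrix
# reachability, and alignments by a plain quadratic DP.

# All maximal EXACT repeat pairs (direct + inverted) of length >= min_len.
# Direct: compare seq to itself shifted by every offset; inverted: compare
# seq to its reverse complement the same way and map coordinates back.
oracle_exact_repeats <- function(seq, min_len) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- rev(unname(comp[ch]))
  out <- list()
  runs_of <- function(eq) {
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    cbind(start = starts[keep], end = ends[keep])
  }
  for (d in 1:(L - min_len)) {
    eq <- ch[1:(L - d)] == ch[(1 + d):L]
    m <- runs_of(eq)
    for (i in seq_len(nrow(m))) {
      out[[length(out) + 1L]] <- data.frame(
        start1 = m[i, 1], end1 = m[i, 2],
        start2 = m[i, 1] + d, end2 = m[i, 2] + d,
        orientation = "direct")
    }
  }
  for (d in 0:(L - 1)) {  # seq vs rc offsets (both directions)
    n <- L - d
    if (n < min_len) next
    eq <- ch[1:n] == rc[(1 + d):L]
    m <- runs_of(eq)
    for (i in seq_len(nrow(m))) {
      a1 <- m[i, 1]; a2 <- m[i, 2]
      b1 <- L - (d + a2) + 1L; b2 <- L - (d + a1) + 1L
      s1 <- min(a1, b1); e1 <- min(a2, b2)
      s2 <- max(a1, b1); e2 <- max(a2, b2)
      if (s1 == s2 && e1 == e2) next       # self-reverse-complementary
      inter <- min(e1, e2) - max(s1, s2) + 1L
      if (inter >= 0.5 * min(e1 - s1 + 1L, e2 - s2 + 1L)) next
      out[[length(out) + 1L]] <- data.frame(
        start1 = s1, end1 = e1, start2 = s2, end2 = e2,
        orientation = "inverted")
    }
    if (d > 0) {
      eq <- ch[(1 + d):L] == rc[1:n]
      m <- runs_of(eq)
      for (i in seq_len(nrow(m))) {
        a1 <- m[i, 1] + d; a2 <- m[i, 2] + d
        b1 <- L - (a2 - d) + 1L; b2 <- L - (a1 - d) + 1L
        s1 <- min(a1, b1); e1 <- min(a2, b2)
        s2 <- max(a1, b1); e2 <- max(a2, b2)
        if (s1 == s2 && e1 == e2) next
        inter <- min(e1, e2) - max(s1, s2) + 1L
        if (inter >= 0.5 * min(e1 - s1 + 1L, e2 - s2 + 1L)) next
        out[[length(out) + 1L]] <- data.frame(
          start1 = s1, end1 = e1, start2 = s2, end2 = e2,
          orientation = "inverted")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      orientation = character(0)))
  }
  unique(do.call(rbind, out))
}

# Naive six-frame ORF finder: walk every position, check ATG, extend codon by
# codon to the first stop (or sequence end).
oracle_orfs <- function(seq, min_nt = 75L, both_strands = TRUE,
                        include_stop = TRUE) {
  stops <- c("TAA", "TAG", "TGA")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  scan1 <- function(s) {
    ch <- strsplit(s, "")[[1]]
    L <- length(ch)
    found <- list()
    claimed <- list()  # (frame, stop end) already reported
    for (p in seq_len(L - 2L)) {
      if (paste(ch[p:(p + 2L)], collapse = "") != "ATG") next
      q <- p
      hit_stop <- FALSE
      while (q + 2L <= L) {
        cod <- paste(ch[q:(q + 2L)], collapse = "")
        if (cod %in% stops && q > p) { hit_stop <- TRUE; break }
        q <- q + 3L
      }
      end <- if (hit_stop) {
        if (include_stop) q + 2L else q - 1L
      } else q - 1L
      key <- paste(p %% 3L, if (hit_stop) q else -1L)
      if (!is.null(claimed[[key]])) next   # not the first ATG of this run
      claimed[[key]] <- TRUE
      if (end - p + 1L >= min_nt) {
        found[[length(found) + 1L]] <- c(start = p, end = end)
      }
    }
    found
  }
  res <- lapply(scan1(seq), function(x) c(x, strand = "+"))
  if (both_strands) {
    ch <- strsplit(seq, "")[[1]]
    rcs <- paste(rev(unname(comp[ch])), collapse = "")
    L <- nchar(seq)
    res <- c(res, lapply(scan1(rcs), function(x) {
      c(start = L - x[["end"]] + 1L, end = L - x[["start"]] + 1L,
        strand = "-")
    }))
  }
  if (!length(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  df <- data.frame(start = as.integer(vapply(res, `[[`, "", "start")),
                   end = as.integer(vapply(res, `[[`, "", "end")),
                   strand = vapply(res, `[[`, "", "strand"))
  df[order(df$start, df$end), ]
}

# Connected components under (divergence <= threshold) via boolean matrix
# reachability (transitive closure), independent of the BFS implementation.
oracle_components <- function(m, threshold) {
  adj <- m <= threshold
  n <- nrow(adj)
  reach <- adj
  for (step in seq_len(n)) reach <- reach | (reach %*% adj > 0)
  comp <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      nxt <- nxt + 1L
      comp[reach[i, ]] <- nxt
    }
  }
  comp
}

# Plain Needleman-Wunsch with affine gaps (match 1 / mismatch -1), returning
# only the optimal score; used to validate the alignment-backed divergence.
oracle_nw_score <- function(a, b, gap_open = 5, gap_ext = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -gap_open - gap_ext * (i - 1)
  for (j in 2:(m + 1)) Iy[1, j] <- -gap_open - gap_ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) 1 else -1
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                      Ix[i - 1, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                      Iy[i, j - 1] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Random additive distance matrix from a random bifurcating tree; returns the
# tree (ape::phylo) and its cophenetic (path-length) matrix.
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE, br = function(k) runif(k, 0.05, 1))
  list(tree = tr, d = cophenetic(tr))
}
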