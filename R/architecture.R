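#' Self-similarity scan of a single sequence
#'
#' Seed-and-extend detection of repeated segments within one element, the
#' in-package analog of an all-vs-self BLASTn at minimum word size: exact
#' `min_word`-mers seed candidate repeat pairs in both orientations, seeds on
#' a common diagonal are chained, and each chain is extended ungapped under an
#' X-drop rule, then trimmed to mismatch-free ends.
#'
#' @param seq DNA character string.
#' @param min_word Seed word size in bp.
#' @param min_length Minimum reported repeat length in bp.
#' @param max_mismatch_frac Maximum mismatch fraction of a reported pair.
#' @param merge_gap Maximum gap between chained seed starts on one diagonal.
#' @return Data frame with one row per repeat pair: `start1, end1, start2,
#'   end2` (1-based closed; pair 1 is 5' of pair 2), `orientation`
#'   (`"direct"` or `"inverted"`), `length`, `identity`.
#' @export
self_similarity_scan <- function(seq, min_word = 11L, min_length = 50L,
                                 max_mismatch_frac = 0.2, merge_gap = 60L) {
  L <- nchar(seq)
  empty <- data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      orientation = character(0), length = integer(0),
                      identity = numeric(0))
  if (L < 2L * min_length) return(empty)
  a <- seq_chars(seq)
  rc <- seq_chars(revcomp(seq))

  res <- rbind(
    scan_pair_chars(a, a, min_word, min_length, max_mismatch_frac,
                    merge_gap, self = TRUE),
    {
      inv <- scan_pair_chars(a, rc, min_word, min_length, max_mismatch_frac,
                             merge_gap, self = FALSE)
      if (nrow(inv)) {
        # map the rc-space interval back to forward coordinates
        s2 <- L - inv$end2 + 1L
        e2 <- L - inv$start2 + 1L
        inv$start2 <- s2
        inv$end2 <- e2
      }
      inv
    }
  )
  if (!nrow(res)) return(empty)
  res$orientation <- ifelse(res$ori == "d", "direct", "inverted")
  res$ori <- NULL
  # canonical order: pair 1 is the 5'-most member
  flip <- res$start2 < res$start1
  if (any(flip)) {
    tmp <- res[flip, c("start1", "end1")]
    res[flip, c("start1", "end1")] <- res[flip, c("start2", "end2")]
    res[flip, c("start2", "end2")] <- tmp
  }
  # drop self-overlapping (palindromic/diagonal) hits and duplicates
  keep <- pmin(res$end1, res$end2) - pmax(res$start1, res$start2) + 1L <
    0.5 * pmin(res$end1 - res$start1 + 1L, res$end2 - res$start2 + 1L)
  res <- res[keep & !(res$start1 == res$start2 & res$end1 == res$end2), ]
  res <- dedupe_pairs(res)
  rownames(res) <- NULL
  res
}

# seed + diagonal-chain + ungapped extension between two base vectors
scan_pair_chars <- function(a, b, k, min_len, frac, merge_gap, self) {
  na <- length(a); nb <- length(b)
  if (na < k || nb < k) {
    return(data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      ori = character(0), length = integer(0),
                      identity = numeric(0)))
  }
  astr <- chars_seq(a); bstr <- chars_seq(b)
  ka <- substring(astr, 1:(na - k + 1L), k:na)
  kb <- substring(bstr, 1:(nb - k + 1L), k:nb)
  idx_b <- split(seq_along(kb), kb)
  hits_i <- integer(0); hits_j <- integer(0)
  pos_b <- idx_b[ka]
  nhit <- lengths(pos_b)
  have <- which(nhit > 0L)
  if (length(have)) {
    hits_i <- rep(have, nhit[have])
    hits_j <- unlist(pos_b[have], use.names = FALSE)
  }
  if (self) {
    sel <- hits_j > hits_i  # upper triangle, excludes the trivial diagonal
    hits_i <- hits_i[sel]; hits_j <- hits_j[sel]
  }
  out <- list()
  if (length(hits_i)) {
    d <- hits_j - hits_i
    o <- order(d, hits_i)
    d <- d[o]; hi <- hits_i[o]
    brk <- c(TRUE, diff(d) != 0 | diff(hi) > merge_gap)
    grp <- cumsum(brk)
    for (g in split(seq_along(grp), grp)) {
      i1 <- hi[g[1]]; i2 <- hi[g[length(g)]] + k - 1L
      dd <- d[g[1]]
      ext <- extend_ungapped(a, b, i1, i2, dd, frac)
      if (is.null(ext)) next
      len <- ext[2] - ext[1] + 1L
      if (len < min_len) next
      ident <- mean(a[ext[1]:ext[2]] == b[(ext[1] + dd):(ext[2] + dd)])
      if (ident < 1 - frac) next
      out[[length(out) + 1L]] <- data.frame(
        start1 = ext[1], end1 = ext[2],
        start2 = ext[1] + dd, end2 = ext[2] + dd,
        ori = if (self) "d" else "i", length = len, identity = ident)
    }
  }
  if (!length(out)) {
    return(data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      ori = character(0), length = integer(0),
                      identity = numeric(0)))
  }
  do.call(rbind, out)
}

# X-drop ungapped extension of a[i1..i2] vs b[i1+d..i2+d]; returns the
# extended interval on `a`, trimmed so both ends are matches
extend_ungapped <- function(a, b, i1, i2, d, frac, xdrop = 6) {
  na <- length(a); nb <- length(b)
  step <- function(p) if (a[p] == b[p + d]) 1 else -3
  # left
  sc <- 0; best <- 0; bestp <- i1
  p <- i1 - 1L
  while (p >= 1L && p + d >= 1L) {
    sc <- sc + step(p)
    if (sc > best) { best <- sc; bestp <- p }
    if (best - sc > xdrop) break
    p <- p - 1L
  }
  i1 <- bestp
  # right
  sc <- 0; best <- 0; bestp <- i2
  p <- i2 + 1L
  while (p <= na && p + d <= nb) {
    sc <- sc + step(p)
    if (sc > best) { best <- sc; bestp <- p }
    if (best - sc > xdrop) break
    p <- p + 1L
  }
  i2 <- bestp
  # trim mismatched ends
  while (i1 <= i2 && a[i1] != b[i1 + d]) i1 <- i1 + 1L
  while (i2 >= i1 && a[i2] != b[i2 + d]) i2 <- i2 - 1L
  if (i2 < i1) return(NULL)
  c(i1, i2)
}

# collapse near-duplicate pairs (both members overlapping >= 80%), keep the
# highest identity x length
dedupe_pairs <- function(res) {
  if (nrow(res) < 2) return(res)
  score <- res$identity * res$length
  o <- order(-score)
  res <- res[o, ]
  keep <- rep(TRUE, nrow(res))
  ov <- function(s1, e1, s2, e2) {
    inter <- pmin(e1, e2) - pmax(s1, s2) + 1L
    inter / pmin(e1 - s1 + 1L, e2 - s2 + 1L)
  }
  for (i in seq_len(nrow(res) - 1L)) {
    if (!keep[i]) next
    j <- (i + 1L):nrow(res)
    dup <- keep[j] &
      res$orientation[j] == res$orientation[i] &
      ov(res$start1[j], res$end1[j], res$start1[i], res$end1[i]) >= 0.8 &
      ov(res$start2[j], res$end2[j], res$start2[i], res$end2[i]) >= 0.8
    keep[j][dup] <- FALSE
  }
  res[keep, ]
}

#' Find the inverted terminal repeat pair
#'
#' Selects, among the inverted pairs of a [self_similarity_scan()], the
#' highest-scoring one (identity x length, ties to the 5'-most) whose 5'
#' member lies in the 5' terminal window and whose 3' member lies in the 3'
#' terminal window of the element.
#'
#' @param seq DNA character string.
#' @param scan Result of [self_similarity_scan()] (computed if `NULL`).
#' @param terminal_window Fraction of the element length considered
#'   "terminal" at each end.
#' @param ... Passed to [self_similarity_scan()] when `scan` is `NULL`.
#' @return `list(itr5 =, itr3 =, identity =)` or `NULL` when no pair
#'   qualifies.
#' @export
find_itrs <- function(seq, scan = NULL, terminal_window = 0.15, ...) {
  if (is.null(scan)) scan <- self_similarity_scan(seq, ...)
  L <- nchar(seq)
  win <- ceiling(terminal_window * L)
  cand <- scan[scan$orientation == "inverted" &
                 scan$start1 <= win & scan$end2 >= L - win + 1L, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  sc <- cand$identity * cand$length
  best <- cand[order(-sc, cand$start1)[1], ]
  list(itr5 = c(best$start1, best$end1), itr3 = c(best$start2, best$end2),
       identity = best$identity)
}

#' Find the internal complementary region
#'
#' Searches the region between the ITRs for two adjacent segments, lICR and
#' rICR, reverse-complementary to the element's 5'-terminal and 3'-terminal
#' segments respectively. The lICR is anchored by a probe (the reverse
#' complement of the 5'-terminal `seg_length` bases) and both segments are
#' extended base-by-base while complementarity to the respective terminus
#' holds.
#'
#' @param seq DNA character string.
#' @param itrs Result of [find_itrs()]; must be non-`NULL`.
#' @param seg_length Minimum ICR half-segment length in bp.
#' @param max_mismatch Maximum mismatches allowed in the probe match.
#' @return `list(icr_l =, icr_r =)` or `NULL`.
#' @export
find_icr <- function(seq, itrs, seg_length = 30L, max_mismatch = 6L) {
  if (is.null(itrs)) stop("find_icr requires a detected ITR pair")
  L <- nchar(seq)
  a <- seq_chars(seq)
  lo <- itrs$itr5[2] + 1L
  hi <- itrs$itr3[1] - 1L
  if (hi - lo + 1L < 2L * seg_length) return(NULL)
  inner <- substr(seq, lo, hi)
  probe <- revcomp(substr(seq, 1, seg_length))
  m <- Biostrings::matchPattern(probe, Biostrings::DNAString(inner),
                                max.mismatch = max_mismatch)
  if (length(m) == 0) return(NULL)
  # best probe hit = fewest mismatches, then 5'-most
  mm <- vapply(seq_along(m), function(i) {
    sum(seq_chars(as.character(m[[i]])) != seq_chars(probe))
  }, 0)
  pick <- order(mm, BiocGenerics::start(m))[1]
  e <- lo + BiocGenerics::end(m)[pick] - 1L     # lICR end in element coords
  # extend lICR leftwards: position e-j+1 pairs with complement of base j
  w <- seg_length
  while (e - w >= lo && w + 1L <= e && a[e - w] == comp_base(a[w + 1L])) {
    w <- w + 1L
  }
  icr_l <- c(e - w + 1L, e)
  # rICR: position (e+j) pairs with complement of base L-j+1
  v <- 0L
  while (e + v + 1L <= hi && a[e + v + 1L] == comp_base(a[L - v])) {
    v <- v + 1L
  }
  if (v < seg_length) return(NULL)
  list(icr_l = icr_l, icr_r = c(e + 1L, e + v))
}

#' Find the split direct repeat blocks
#'
#' Selects direct-repeat pairs (A1, A2) and (B1, B2) arranged as
#' A1 ... B1 A2 B2, with A1 in the 5' terminal window; among consistent
#' arrangements the one maximizing summed identity x length wins.
#'
#' @inheritParams find_itrs
#' @return `list(sdr_a1 =, sdr_b1 =, sdr_a2 =, sdr_b2 =)` or `NULL`.
#' @export
find_sdrs <- function(seq, scan = NULL, terminal_window = 0.15, ...) {
  if (is.null(scan)) scan <- self_similarity_scan(seq, ...)
  L <- nchar(seq)
  win <- ceiling(terminal_window * L)
  dir <- scan[scan$orientation == "direct", , drop = FALSE]
  if (nrow(dir) < 2) return(NULL)
  acand <- which(dir$start1 <= win)
  best <- NULL; best_score <- -Inf
  for (ai in acand) {
    a1 <- c(dir$start1[ai], dir$end1[ai])
    a2 <- c(dir$start2[ai], dir$end2[ai])
    for (bi in seq_len(nrow(dir))) {
      if (bi == ai) next
      b1 <- c(dir$start1[bi], dir$end1[bi])
      b2 <- c(dir$start2[bi], dir$end2[bi])
      ok <- a1[2] < b1[1] && b1[2] < a2[1] && a2[2] < b2[1]
      if (!ok) next
      sc <- dir$identity[ai] * dir$length[ai] +
        dir$identity[bi] * dir$length[bi]
      if (sc > best_score) {
        best_score <- sc
        best <- list(sdr_a1 = a1, sdr_b1 = b1, sdr_a2 = a2, sdr_b2 = b2)
      }
    }
  }
  best
}

#' Detect the full repeat architecture of one element
#'
#' Runs the self-similarity scan once and applies [find_itrs()],
#' [find_icr()] and [find_sdrs()].
#'
#' @param seq DNA character string.
#' @param min_word,min_length,max_mismatch_frac Scan parameters.
#' @param terminal_window Terminal window fraction.
#' @return A `RepeatArchitecture` list: detected intervals (or `NULL`),
#'   terminal trinucleotides, and the raw scan table.
#' @export
detect_architecture <- function(seq, min_word = 11L, min_length = 50L,
                                max_mismatch_frac = 0.2,
                                terminal_window = 0.15) {
  scan <- self_similarity_scan(seq, min_word = min_word,
                               min_length = min_length,
                               max_mismatch_frac = max_mismatch_frac)
  itrs <- find_itrs(seq, scan, terminal_window)
  icr <- if (!is.null(itrs)) find_icr(seq, itrs) else NULL
  sdrs <- find_sdrs(seq, scan, terminal_window)
  structure(list(
    itr5 = itrs$itr5, itr3 = itrs$itr3,
    icr_l = icr$icr_l, icr_r = icr$icr_r,
    sdr_a1 = sdrs$sdr_a1, sdr_b1 = sdrs$sdr_b1,
    sdr_a2 = sdrs$sdr_a2, sdr_b2 = sdrs$sdr_b2,
    terminal_5_trinucleotide = substr(seq, 1, 3),
    terminal_3_trinucleotide = substr(seq, nchar(seq) - 2, nchar(seq)),
    scan = scan
  ), class = "RepeatArchitecture")
}

#' Classify an element into a YR superfamily
#'
#' DIRS-like iff an ITR pair is present (an ICR and terminal "TTT"
#' trinucleotides raise completeness); Ngaro-like iff the SDR arrangement is
#' present, or a hydrolase (SGNH) marker ORF co-occurs with direct repeats;
#' conflicting or absent evidence gives `"unclassified"` with a reason code.
#' Completeness is `"complete"` only when all expected repeats and all
#' expected coding domains are intact, `"partial"` when the repeats are
#' complete but coding domains are missing, else `"degenerate"`.
#'
#' @param arch A [detect_architecture()] result.
#' @param orfs Optional [find_orfs()] result annotated by [scan_domains()]
#'   (as returned by [annotate_orfs()]); used for domain completeness.
#' @return `list(superfamily =, completeness =, reason =)`.
#' @export
classify_superfamily <- function(arch, orfs = NULL) {
  has_itr <- !is.null(arch$itr5)
  has_sdr <- !is.null(arch$sdr_a1)
  domains <- if (!is.null(orfs)) unique(unlist(orfs$domains)) else character(0)
  has_hydro <- "SGNH" %in% domains
  has_direct <- !is.null(arch$scan) && any(arch$scan$orientation == "direct")
  ngaro_evidence <- has_sdr || (has_hydro && has_direct)

  if (has_itr && ngaro_evidence) {
    return(list(superfamily = "unclassified", completeness = "degenerate",
                reason = "conflicting ITR and SDR evidence"))
  }
  if (has_itr) {
    repeats_ok <- !is.null(arch$icr_l) &&
      arch$terminal_5_trinucleotide == "TTT" &&
      arch$terminal_3_trinucleotide == "TTT"
    need <- c("GAG", "RT", "RH", "YR")
    dom_ok <- length(domains) > 0 && all(need %in% domains)
    completeness <- if (repeats_ok && dom_ok) "complete"
      else if (repeats_ok) "partial" else "degenerate"
    return(list(superfamily = "DIRS-like", completeness = completeness,
                reason = NA_character_))
  }
  if (ngaro_evidence) {
    need <- c("GAG", "RT", "RH", "YR", "SGNH")
    dom_ok <- length(domains) > 0 && all(need %in% domains)
    completeness <- if (has_sdr && dom_ok) "complete"
      else if (has_sdr) "partial" else "degenerate"
    return(list(superfamily = "Ngaro-like", completeness = completeness,
                reason = NA_character_))
  }
  list(superfamily = "unclassified", completeness = "degenerate",
       reason = "no diagnostic terminal repeats")
}
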