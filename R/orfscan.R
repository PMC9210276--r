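#' Find open reading frames in all six frames
#'
#' Reports every maximal ATG-to-stop stretch of at least `min_orf_nt`
#' nucleotides (stop codon included by default, the common ORF-finder
#' convention) in the three forward and, optionally, three reverse frames.
#' An ORF truncated by the sequence end (no stop reached) is reported ending
#' at the last complete codon. Coordinates are 1-based closed on the forward
#' strand; for minus-strand ORFs `start`/`end` still delimit the forward-
#' strand footprint.
#'
#' @param seq DNA character string (non-ACGT characters never match ATG or a
#'   stop and translate to `X`).
#' @param min_orf_nt Minimum ORF length in nt (default 75).
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @param include_stop Count the stop codon in the ORF length and interval.
#' @return Data frame: `start`, `end`, `strand`, `frame` (1-3 within strand),
#'   `length_nt`, `protein` (without the stop).
#' @export
find_orfs <- function(seq, min_orf_nt = 75L, both_strands = TRUE,
                      include_stop = TRUE) {
  res <- orfs_one_strand(seq, min_orf_nt, include_stop)
  if (nrow(res)) res$strand <- "+"
  if (both_strands) {
    L <- nchar(seq)
    rev <- orfs_one_strand(revcomp(seq), min_orf_nt, include_stop)
    if (nrow(rev)) {
      rev$strand <- "-"
      s <- L - rev$end + 1L
      e <- L - rev$start + 1L
      rev$start <- s
      rev$end <- e
      res <- rbind(res, rev)
    }
  }
  if (!nrow(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      length_nt = integer(0), protein = character(0)))
  }
  res <- res[order(res$start, res$end), ]
  rownames(res) <- NULL
  res[, c("start", "end", "strand", "frame", "length_nt", "protein")]
}

orfs_one_strand <- function(seq, min_orf_nt, include_stop) {
  L <- nchar(seq)
  out <- list()
  chars <- seq_chars(toupper(seq))
  for (f in 1:3) {
    n_cod <- (L - f + 1L) %/% 3L
    if (n_cod < 1) next
    starts <- f + 3L * (seq_len(n_cod) - 1L)
    cod <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    is_stop <- cod %in% STOP_CODONS
    is_atg <- cod == "ATG"
    # segment index between stops
    seg <- cumsum(c(0L, head(is_stop, -1L)))
    for (s in split(seq_len(n_cod), seg)) {
      # codons of one stop-terminated (or end-truncated) segment; the last
      # element may be the stop itself
      seg_stop <- is_stop[s[length(s)]]
      coding <- if (seg_stop) s[-length(s)] else s
      if (!length(coding)) next
      first_atg <- coding[which(is_atg[coding])[1]]
      if (is.na(first_atg)) next
      last <- s[length(s)]
      end_cod <- if (include_stop || !seg_stop) last else last - 1L
      len <- (end_cod - first_atg + 1L) * 3L
      if (len < min_orf_nt) next
      prot_cod <- if (seg_stop) (last - 1L) else last
      prot <- if (prot_cod >= first_atg) {
        translate_dna(chars_seq(chars[starts[first_atg]:(starts[prot_cod] + 2L)]))
      } else ""
      out[[length(out) + 1L]] <- data.frame(
        start = starts[first_atg], end = starts[end_cod] + 2L,
        frame = f, length_nt = len, protein = prot,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), length_nt = integer(0),
                      protein = character(0)))
  }
  do.call(rbind, out)
}

#' Report overlapping ORF pairs
#'
#' @param orfs A [find_orfs()] data frame.
#' @return Data frame of pairs `i`, `j` (row indices into `orfs`) with
#'   `overlap_nt`, the length of the shared forward-strand footprint.
#' @export
detect_overlaps <- function(orfs) {
  n <- nrow(orfs)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ov <- min(orfs$end[i], orfs$end[j]) - max(orfs$start[i], orfs$start[j]) + 1L
        if (ov > 0L) {
          out[[length(out) + 1L]] <- data.frame(i = i, j = j, overlap_nt = ov)
        }
      }
    }
  }
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0),
                                      overlap_nt = integer(0)))
  do.call(rbind, out)
}

# null-calibrated score thresholds per marker, cached; the null is the
# BLOSUM62 window score of the marker against random 30-aa windows drawn at
# uniform amino-acid frequencies
marker_threshold_cache <- new.env(parent = emptyenv())

marker_min_score <- function(marker, n_null = 1000L, sd_mult = 5) {
  key <- paste0(marker, "|", n_null, "|", sd_mult)
  if (!is.null(marker_threshold_cache[[key]])) return(marker_threshold_cache[[key]])
  b62 <- get_blosum62()
  aas <- rownames(b62)[1:20]
  mk <- seq_chars(marker)
  old <- .Random.seed_save()
  set.seed(1000003L)
  null <- vapply(seq_len(n_null), function(i) {
    win <- sample(aas, length(mk), replace = TRUE)
    sum(b62[cbind(mk, win)])
  }, 0)
  .Random.seed_restore(old)
  thr <- mean(null) + sd_mult * stats::sd(null)
  marker_threshold_cache[[key]] <- thr
  thr
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Scan a protein for packaged domain markers
#'
#' Ungapped sliding-window similarity: each 30-aa marker is scored against
#' every window of the protein by its BLOSUM62 sum; hits at or above
#' `min_score` are reported at their best position. The default threshold is
#' calibrated per marker as mean + 5 SD of the score against random windows.
#'
#' @param protein Amino-acid character string.
#' @param marker_library Named character vector of marker peptides
#'   (default [domain_markers()]).
#' @param min_score Numeric threshold, or `NULL` for the calibrated default.
#' @return Data frame: `marker`, `score`, `start`, `end` (1-based protein
#'   coordinates of the best window).
#' @export
scan_domains <- function(protein, marker_library = domain_markers(),
                         min_score = NULL) {
  empty <- data.frame(marker = character(0), score = numeric(0),
                      start = integer(0), end = integer(0))
  if (is.na(protein) || !nchar(protein)) return(empty)
  b62 <- get_blosum62()
  p <- seq_chars(protein)
  p[!p %in% rownames(b62)] <- "*"
  np <- length(p)
  out <- list()
  for (lab in names(marker_library)) {
    mk <- seq_chars(marker_library[[lab]])
    w <- length(mk)
    if (np < w) next
    # per-position scores then window sums via cumsum
    sc_pos <- b62[cbind(rep(mk, times = np - w + 1L),
                        p[outer(seq_len(w), 0:(np - w), `+`)])]
    sc <- colSums(matrix(sc_pos, nrow = w))
    thr <- if (is.null(min_score)) marker_min_score(marker_library[[lab]]) else min_score
    if (max(sc) >= thr) {
      best <- which.max(sc)
      out[[length(out) + 1L]] <- data.frame(
        marker = lab, score = max(sc), start = best, end = best + w - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Find ORFs and annotate their domain content
#'
#' @param seq DNA character string.
#' @param ... Passed to [find_orfs()].
#' @return The [find_orfs()] frame with a `domains` list-column of marker
#'   labels per ORF (ordered by protein position).
#' @export
annotate_orfs <- function(seq, ...) {
  orfs <- find_orfs(seq, ...)
  orfs$domains <- lapply(seq_len(nrow(orfs)), function(i) {
    hits <- scan_domains(orfs$protein[i])
    hits$marker[order(hits$start)]
  })
  orfs
}

#' Domain order across an element
#'
#' Concatenates the domain hits of all plus-strand ORFs in genomic order,
#' giving the element-level conserved-domain order (e.g. gag, RT, RH, MT, YR
#' for a complete DIRS-like element).
#'
#' @param orfs An [annotate_orfs()] result.
#' @return Character vector of marker labels.
#' @export
domain_order <- function(orfs) {
  plus <- orfs[orfs$strand == "+", , drop = FALSE]
  plus <- plus[order(plus$start), , drop = FALSE]
  out <- character(0)
  for (i in seq_len(nrow(plus))) out <- c(out, plus$domains[[i]])
  unique(out)
}
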