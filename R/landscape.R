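#' Kimura 2-parameter distance from a gapped alignment
#'
#' Columns with a gap or ambiguous base in either sequence are excluded.
#' With transition fraction P and transversion fraction Q over the remaining
#' columns, K = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q)). When the logarithm's
#' domain is violated (saturation) K is reported missing with a flag.
#'
#' @param aligned_copy,aligned_consensus Equal-length gapped strings.
#' @return `list(P, Q, K, n_sites, saturated)`.
#' @export
kimura2p <- function(aligned_copy, aligned_consensus) {
  stopifnot(nchar(aligned_copy) == nchar(aligned_consensus))
  a <- seq_chars(toupper(aligned_copy))
  b <- seq_chars(toupper(aligned_consensus))
  use <- a %in% DNA_BASES4 & b %in% DNA_BASES4
  a <- a[use]; b <- b[use]
  n <- length(a)
  if (n == 0) return(list(P = NA_real_, Q = NA_real_, K = NA_real_,
                          n_sites = 0L, saturated = FALSE))
  diff <- a != b
  ts <- diff & TRANSITION[b] == a
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  k2p_from_pq(P, Q, n)
}

k2p_from_pq <- function(P, Q, n) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(P = P, Q = Q, K = NA_real_, n_sites = as.integer(n),
                saturated = TRUE))
  }
  K <- -0.5 * log(w1 * sqrt(w2))
  list(P = P, Q = Q, K = K, n_sites = as.integer(n), saturated = FALSE)
}

#' CpG-adjusted Kimura distance
#'
#' Follows the repeat-landscape convention for CpG hypermutability: a
#' transition at an alignment position where the consensus carries a CpG
#' dinucleotide counts only `cpg_weight` of a transition, and two transitions
#' at the same CpG site together count as one full transition. The adjusted
#' transition fraction then enters the K2P closed form unchanged. CpG sites
#' are read off the consensus strand as written; orient reverse-strand copies
#' to the consensus first.
#'
#' @inheritParams kimura2p
#' @param cpg_weight Weight of a single transition at a CpG site (default 0.1).
#' @return `list(P, Q, K, n_sites, saturated)` with `P` the adjusted fraction.
#' @export
cpg_adjusted_kimura <- function(aligned_copy, aligned_consensus,
                                cpg_weight = 0.1) {
  stopifnot(nchar(aligned_copy) == nchar(aligned_consensus))
  a <- seq_chars(toupper(aligned_copy))
  b <- seq_chars(toupper(aligned_consensus))
  use <- a %in% DNA_BASES4 & b %in% DNA_BASES4
  if (!any(use)) return(list(P = NA_real_, Q = NA_real_, K = NA_real_,
                             n_sites = 0L, saturated = FALSE))
  # CpG = consecutive consensus bases C,G ignoring consensus gap columns
  bases <- which(b %in% DNA_BASES4 | b == "-")
  cons_cols <- which(b %in% DNA_BASES4)
  in_cpg <- rep(FALSE, length(b))
  if (length(cons_cols) >= 2) {
    c1 <- cons_cols[-length(cons_cols)]
    c2 <- cons_cols[-1]
    hit <- b[c1] == "C" & b[c2] == "G"
    in_cpg[c1[hit]] <- TRUE
    in_cpg[c2[hit]] <- TRUE
    cpg_pair_first <- c1[hit]
    cpg_pair_second <- c2[hit]
  } else {
    cpg_pair_first <- cpg_pair_second <- integer(0)
  }
  n <- sum(use)
  diff <- a != b & use
  is_ts <- diff & TRANSITION[b] == a
  ts_plain <- sum(is_ts & !in_cpg)
  # per CpG site: one transition contributes cpg_weight, a double counts 1
  ts_cpg <- 0
  if (length(cpg_pair_first)) {
    t1 <- is_ts[cpg_pair_first]
    t2 <- is_ts[cpg_pair_second]
    ts_cpg <- sum(ifelse(t1 & t2, 1, (t1 + t2) * cpg_weight))
  }
  # CpG transitions at columns whose partner column is unusable
  orphan <- is_ts & in_cpg
  orphan[c(cpg_pair_first, cpg_pair_second)] <- FALSE
  ts_cpg <- ts_cpg + sum(orphan) * cpg_weight
  P <- (ts_plain + ts_cpg) / n
  Q <- sum(diff & !is_ts) / n
  k2p_from_pq(P, Q, n)
}

#' Convert divergence to age
#'
#' T = K / r, with r the nucleotide substitution rate per site per year
#' (default 3.1e-9, the average rate estimated for the *Xenopus* genomes).
#'
#' @param K Kimura divergence (may be a vector).
#' @param r Substitution rate per site per year.
#' @return `list(years, mya)`.
#' @export
age_from_divergence <- function(K, r = 3.1e-9) {
  stopifnot(r > 0)
  years <- K / r
  list(years = years, mya = years / 1e6)
}

#' Divergence records from masking alignments
#'
#' Applies [cpg_adjusted_kimura()] to every alignment record of
#' [mask_genome()] and attaches ages.
#'
#' @param hits The `hits` frame of [mask_genome()].
#' @param superfamily_map Named character vector family -> superfamily
#'   (optional).
#' @param cpg_weight Passed to [cpg_adjusted_kimura()].
#' @param r Substitution rate for [age_from_divergence()].
#' @return Data frame: `copy_id`, `family`, `superfamily`, `g_start`,
#'   `g_end`, `strand`, `aligned_bp`, `P`, `Q`, `K`, `saturated`, `age_mya`.
#' @export
divergence_records <- function(hits, superfamily_map = NULL, cpg_weight = 0.1,
                               r = 3.1e-9) {
  n <- nrow(hits)
  rows <- lapply(seq_len(n), function(i) {
    k <- cpg_adjusted_kimura(hits$aligned_copy[i], hits$aligned_cons[i],
                             cpg_weight)
    data.frame(
      copy_id = sprintf("hit%04d", i), family = hits$family[i],
      superfamily = if (!is.null(superfamily_map))
        unname(superfamily_map[hits$family[i]]) else NA_character_,
      g_start = hits$g_start[i], g_end = hits$g_end[i],
      strand = hits$strand[i], aligned_bp = hits$copy_bp[i],
      P = k$P, Q = k$Q, K = k$K, saturated = k$saturated,
      age_mya = if (is.na(k$K)) NA_real_ else age_from_divergence(k$K, r)$mya,
      stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(copy_id = character(0), family = character(0),
                      superfamily = character(0), g_start = integer(0),
                      g_end = integer(0), strand = character(0),
                      aligned_bp = integer(0), P = numeric(0), Q = numeric(0),
                      K = numeric(0), saturated = logical(0),
                      age_mya = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Build the repeat evolutionary landscape
#'
#' Bins copies by their divergence K (default bin width 0.01) and reports,
#' per family and per superfamily, the percentage of the genome occupied by
#' the copies in each bin; the age axis is the bin midpoint divided by the
#' substitution rate. Saturated (K missing) records are dropped.
#'
#' @param records A [divergence_records()] frame.
#' @param genome_size Genome length in bp.
#' @param bin_width Bin width on K.
#' @param r Substitution rate (age axis).
#' @return `list(per_family, per_superfamily)`: long data frames with
#'   `bin_lo`, `bin_mid`, `age_mya`, the grouping column, and `pct_genome`.
#' @export
build_landscape <- function(records, genome_size, bin_width = 0.01,
                            r = 3.1e-9) {
  rec <- records[!is.na(records$K), , drop = FALSE]
  bin <- floor(rec$K / bin_width)
  rec$bin_lo <- bin * bin_width
  one <- function(group) {
    if (!nrow(rec)) {
      return(data.frame(bin_lo = numeric(0), bin_mid = numeric(0),
                        age_mya = numeric(0), group = character(0),
                        pct_genome = numeric(0)))
    }
    agg <- aggregate(rec$aligned_bp,
                     by = list(bin_lo = rec$bin_lo, group = rec[[group]]),
                     FUN = sum)
    names(agg)[names(agg) == "x"] <- "bp"
    agg$bin_mid <- agg$bin_lo + bin_width / 2
    agg$age_mya <- age_from_divergence(agg$bin_mid, r)$mya
    agg$pct_genome <- 100 * agg$bp / genome_size
    agg[order(agg$group, agg$bin_lo),
        c("bin_lo", "bin_mid", "age_mya", "group", "pct_genome")]
  }
  list(per_family = one("family"), per_superfamily = one("superfamily"))
}

#' Plot a repeat landscape
#'
#' Stacked-bar landscape: genome percentage per divergence bin, filled by
#' family, with a secondary age axis in My.
#'
#' @param landscape A [build_landscape()] result.
#' @param r Substitution rate used for the age axis.
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape, r = 3.1e-9) {
  df <- landscape$per_family
  bin_mid <- pct_genome <- group <- NULL  # silence R CMD check notes
  ggplot2::ggplot(df, ggplot2::aes(x = bin_mid, y = pct_genome,
                                   fill = group)) +
    ggplot2::geom_col(width = min(diff(sort(unique(df$bin_mid))), 0.01)) +
    ggplot2::scale_x_continuous(
      name = "Kimura divergence (K, CpG adjusted)",
      sec.axis = ggplot2::sec_axis(~ . / r / 1e6, name = "age (My)")) +
    ggplot2::labs(y = "% of genome", fill = "family")
}
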