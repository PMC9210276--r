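#' Configuration of a full pipeline run
#'
#' Bundles the generator (or input paths) with every stage threshold. All
#' randomness flows from the single `seed` through named per-stage
#' substreams, so a rerun with the same config is byte-identical.
#'
#' @param generator A [generator_config()], or `NULL` when `genome`,
#'   `library` and `ests` are supplied directly.
#' @param seed Master seed (defaults to the generator's).
#' @param genome,library,ests Optional pre-built inputs (character string /
#'   named character vectors), used when `generator` is `NULL`.
#' @param out_dir Optional output directory; when set, all tables, FASTA and
#'   plots are written there.
#' @param family_threshold Family clustering divergence threshold.
#' @param consensus_threshold Majority-consensus threshold.
#' @param rt_coverage Minimum RT alignment coverage.
#' @param boot_reps Bootstrap replicates for the RT tree.
#' @param bin_width Landscape bin width on K.
#' @param r Substitution rate per site per year.
#' @param cpg_weight CpG transition weight.
#' @param est_min_identity,est_min_len EST filter thresholds.
#' @param min_copy_frac Minimum fraction of the consensus a masked copy must
#'   cover to enter the family-clustering and tree stages.
#' @return A `RunConfig` list.
#' @export
run_config <- function(generator = NULL, seed = NULL, genome = NULL,
                       library = NULL, ests = NULL, out_dir = NULL,
                       family_threshold = 0.80, consensus_threshold = 0.50,
                       rt_coverage = 0.70, boot_reps = 100L,
                       bin_width = 0.01, r = 3.1e-9, cpg_weight = 0.1,
                       est_min_identity = 0.85, est_min_len = 100L,
                       min_copy_frac = 0.6) {
  if (is.null(generator) && (is.null(genome) || is.null(library)))
    stop("either a generator config or genome + library inputs are required")
  if (is.null(seed)) seed <- if (!is.null(generator)) generator$seed else
    stop("seed is mandatory")
  structure(list(generator = generator, seed = as.integer(seed),
                 genome = genome, library = library, ests = ests,
                 out_dir = out_dir, family_threshold = family_threshold,
                 consensus_threshold = consensus_threshold,
                 rt_coverage = rt_coverage, boot_reps = as.integer(boot_reps),
                 bin_width = bin_width, r = r, cpg_weight = cpg_weight,
                 est_min_identity = est_min_identity,
                 est_min_len = as.integer(est_min_len),
                 min_copy_frac = min_copy_frac),
            class = "RunConfig")
}

#' Demo generator configuration
#'
#' Two DIRS-like families and one Ngaro-like family in a 200 kb genome, with
#' a recent and an ancient amplification wave (K = 0.02 and K = 0.25), a
#' small recent Ngaro-like wave, and 30 EST reads.
#'
#' @param seed Master seed.
#' @return A [generator_config()].
#' @export
demo_config <- function(seed = 42L) {
  fams <- list(
    family_spec("DIRS-sim1", "DIRS-like"),
    family_spec("DIRS-sim2", "DIRS-like"),
    family_spec("Ngaro-sim1", "Ngaro-like")
  )
  waves <- list(
    wave_spec("DIRS-sim1", n_copies = 8, target_K = 0.02,
              intact_fraction = 0.75),
    wave_spec("DIRS-sim2", n_copies = 8, target_K = 0.25,
              intact_fraction = 0.5),
    wave_spec("Ngaro-sim1", n_copies = 5, target_K = 0.02,
              intact_fraction = 0.8)
  )
  generator_config(seed = seed, genome_length = 200000L, gc_content = 0.4,
                   families = fams, waves = waves, est_count = 30L)
}

#' Run the full analysis pipeline
#'
#' generate (optional) -> annotate library architecture -> mask genome ->
#' divergence records + landscape -> family clustering and consensus
#' building on the recovered copies -> RT distance tree with bootstrap ->
#' EST evidence -> summary. Every stage seeds its own RNG substream from the
#' config seed.
#'
#' @param config A [run_config()].
#' @return A report bundle list: `bundle` (generator output or inputs),
#'   `architecture` (per-element table), `classification`, `mask`,
#'   `records`, `landscape`, `families`, `tree`, `est_evidence`, `summary`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  bundle <- stage("generate", {
    if (!is.null(config$generator)) build_genome(config$generator)
    else list(genome = config$genome, library = config$library,
              ests = config$ests, truth = NULL,
              consensus = NULL, config = NULL)
  })
  superfamily_map <- if (!is.null(config$generator)) {
    setNames(vapply(config$generator$families, function(f) f$superfamily, ""),
             vapply(config$generator$families, function(f) f$name, ""))
  } else NULL

  annot <- stage("annotate", annotate_library(bundle$library))

  mask <- stage("mask", mask_genome(bundle$library, bundle$genome))

  records <- stage("divergence",
                   divergence_records(mask$hits, superfamily_map,
                                      cpg_weight = config$cpg_weight,
                                      r = config$r))
  landscape <- stage("landscape",
                     build_landscape(records, nchar(bundle$genome),
                                     bin_width = config$bin_width,
                                     r = config$r))

  fams <- stage("families", {
    copies <- copy_sequences(mask$hits, bundle$library, config$min_copy_frac)
    if (length(copies) >= 2) build_family_set(copies, config$family_threshold,
                                              config$consensus_threshold)
    else NULL
  })

  tree <- stage("tree", {
    rt <- rt_proteins(bundle$library, mask$hits, config$min_copy_frac)
    if (length(rt) >= 4) {
      aln <- center_star_align(rt, type = "protein")
      aln <- filter_rt_coverage(aln, config$rt_coverage)
      if (length(aln) >= 4) {
        bootstrap_support(aln, n_reps = config$boot_reps,
                          seed = substream_seed(config$seed, "bootstrap"))
      } else NULL
    } else NULL
  })

  est_evidence <- stage("ests", {
    if (length(bundle$ests)) {
      match_ests(bundle$ests, bundle$library,
                 min_identity = config$est_min_identity,
                 min_match_len = config$est_min_len)
    } else NULL
  })

  report <- list(bundle = bundle, architecture = annot$table,
                 classification = annot$classification, mask = mask,
                 records = records, landscape = landscape, families = fams,
                 tree = tree, est_evidence = est_evidence)
  report$summary <- summarize_report(report)

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Annotate a consensus library
#'
#' Architecture detection, ORF + domain annotation and superfamily
#' classification for every element of a library.
#'
#' @param library Named character vector of element sequences.
#' @return `list(table, classification, orfs)`: `table` is a one-row-per-
#'   element data frame of calls, completeness and repeat intervals.
#' @export
annotate_library <- function(library) {
  iv <- function(x) if (is.null(x)) NA_character_ else paste0(x[1], "-", x[2])
  rows <- list()
  classification <- list()
  orfs_all <- list()
  for (nm in names(library)) {
    seq <- library[[nm]]
    arch <- detect_architecture(seq)
    orfs <- annotate_orfs(seq)
    cls <- classify_superfamily(arch, orfs)
    classification[[nm]] <- cls
    orfs_all[[nm]] <- orfs
    rows[[nm]] <- data.frame(
      element = nm, superfamily = cls$superfamily,
      completeness = cls$completeness,
      itr5 = iv(arch$itr5), itr3 = iv(arch$itr3),
      icr_l = iv(arch$icr_l), icr_r = iv(arch$icr_r),
      sdr_a1 = iv(arch$sdr_a1), sdr_b1 = iv(arch$sdr_b1),
      sdr_a2 = iv(arch$sdr_a2), sdr_b2 = iv(arch$sdr_b2),
      terminal_5 = arch$terminal_5_trinucleotide,
      terminal_3 = arch$terminal_3_trinucleotide,
      domains = paste(domain_order(orfs), collapse = ","),
      stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       classification = classification, orfs = orfs_all)
}

# gap-free genomic copy sequences (consensus orientation) covering at least
# min_frac of their consensus
copy_sequences <- function(hits, library, min_frac = 0.6) {
  out <- character(0)
  for (i in seq_len(nrow(hits))) {
    clen <- nchar(library[[hits$family[i]]])
    span <- hits$c_end[i] - hits$c_start[i] + 1L
    if (span < min_frac * clen) next
    out[[sprintf("%s_hit%03d", hits$family[i], i)]] <-
      gsub("-", "", hits$aligned_copy[i], fixed = TRUE)
  }
  out
}

# RT-domain proteins of the library consensuses plus the recovered
# near-full-length copies: the RT marker hit (+/- 10 aa context) of the best
# matching ORF
rt_proteins <- function(library, hits, min_frac = 0.6) {
  grab <- function(seq, id) {
    orfs <- annotate_orfs(seq, both_strands = FALSE)
    for (i in seq_len(nrow(orfs))) {
      hit <- scan_domains(orfs$protein[i], domain_markers()["RT"])
      if (nrow(hit)) {
        p <- orfs$protein[i]
        lo <- max(1L, hit$start[1] - 10L)
        hi <- min(nchar(p), hit$end[1] + 10L)
        return(setNames(substr(p, lo, hi), id))
      }
    }
    NULL
  }
  out <- character(0)
  for (nm in names(library)) {
    g <- grab(library[[nm]], nm)
    if (!is.null(g)) out <- c(out, g)
  }
  copies <- copy_sequences(hits, library, min_frac)
  for (nm in names(copies)) {
    g <- grab(copies[[nm]], nm)
    if (!is.null(g)) out <- c(out, g)
  }
  out
}

summarize_report <- function(report) {
  cls <- report$classification
  sf <- vapply(cls, function(x) x$superfamily, "")
  comp <- vapply(cls, function(x) x$completeness, "")
  msk <- report$mask$summary
  per_sf <- if (!is.null(report$records) && nrow(report$records)) {
    aggregate(report$records$aligned_bp,
              by = list(superfamily = report$records$superfamily), FUN = sum)
  } else NULL
  genome_bp <- nchar(report$bundle$genome)
  list(
    n_elements = length(cls),
    n_by_superfamily = table(sf),
    n_complete = sum(comp == "complete"),
    n_degenerate = sum(comp != "complete"),
    masked_pct_total = msk$pct_genome[msk$family == "total"],
    pct_by_superfamily = if (!is.null(per_sf))
      setNames(100 * per_sf$x / genome_bp, per_sf$superfamily) else NULL,
    n_recovered_families = if (!is.null(report$families))
      length(report$families$consensus) else 0L,
    est_families_with_evidence = if (!is.null(report$est_evidence))
      sum(report$est_evidence$evidence) else NA_integer_
  )
}

#' One-page text summary of a report bundle
#'
#' @param report A [run_full_analysis()] result.
#' @return Character vector of report lines (also printed).
#' @export
summarize <- function(report) {
  s <- report$summary
  lines <- c(
    "== yrscout run summary ==",
    sprintf("library elements: %d (%s)", s$n_elements,
            paste(sprintf("%s: %d", names(s$n_by_superfamily),
                          s$n_by_superfamily), collapse = ", ")),
    sprintf("complete: %d, partial/degenerate: %d", s$n_complete,
            s$n_degenerate),
    sprintf("genome masked: %.3f%%", s$masked_pct_total),
    if (!is.null(s$pct_by_superfamily))
      sprintf("  %s: %.3f%%", names(s$pct_by_superfamily),
              s$pct_by_superfamily),
    sprintf("recovered families (80%% divergence rule): %d",
            s$n_recovered_families),
    if (!is.na(s$est_families_with_evidence))
      sprintf("families with EST evidence: %d", s$est_families_with_evidence)
  )
  cat(lines, sep = "\n")
  invisible(lines)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(report$architecture, file.path(dir, "architecture.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- report$mask$hits
  write.table(hits[, setdiff(names(hits), c("aligned_cons", "aligned_copy"))],
              file.path(dir, "mask_hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$mask$summary, file.path(dir, "mask_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$records, file.path(dir, "divergence_records.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$landscape$per_family, file.path(dir, "landscape.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$families))
    write_fasta(report$families$consensus,
                file.path(dir, "family_consensus.fasta"))
  if (!is.null(report$tree))
    ape::write.tree(report$tree$tree, file.path(dir, "rt_tree.nwk"))
  if (!is.null(report$est_evidence))
    write.table(report$est_evidence$matches, file.path(dir, "est_matches.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(utils::capture.output(summarize(report)),
             file.path(dir, "summary.txt"))
  tryCatch({
    p <- plot_landscape(report$landscape)
    ggplot2::ggsave(file.path(dir, "landscape.png"), p, width = 7, height = 4,
                    dpi = 120)
  }, error = function(e) invisible(NULL))
  invisible(dir)
}
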