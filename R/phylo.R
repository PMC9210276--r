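#' Protein distance matrix from an alignment
#'
#' Pairwise distances over shared non-gap columns: p-distance, Poisson
#' correction -ln(1 - p), or gamma-corrected Poisson
#' a((1 - p)^(-1/a) - 1) with shape `a`. The gamma-corrected Poisson stands
#' in for maximum-likelihood JTT distances: at the divergences involved the
#' distances, not the substitution model, drive the clustering.
#'
#' @param aligned Named character vector of equal-width gapped proteins.
#' @param model `"p"`, `"poisson"` or `"gamma"`.
#' @param gamma_shape Gamma shape parameter (default 1.0).
#' @return Symmetric distance matrix, zero diagonal.
#' @export
protein_distance <- function(aligned, model = c("p", "poisson", "gamma"),
                             gamma_shape = 1.0) {
  model <- match.arg(model)
  n <- length(aligned)
  stopifnot(n >= 2)
  w <- unique(nchar(aligned))
  stopifnot(length(w) == 1)
  mat <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  d <- matrix(0, n, n, dimnames = list(names(aligned), names(aligned)))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sh <- mat[i, ] != "-" & mat[j, ] != "-"
      p <- if (any(sh)) mean(mat[i, sh] != mat[j, sh]) else NA_real_
      p <- min(p, 0.999)
      d[i, j] <- d[j, i] <- switch(model,
        p = p,
        poisson = -log(1 - p),
        gamma = gamma_shape * ((1 - p)^(-1 / gamma_shape) - 1))
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei agglomeration with the Studier-Keppler Q criterion.
#' Negative branch lengths are clamped to zero with the excess moved to the
#' sister branch (their sum to the new node is preserved). Returns an
#' unrooted `ape::phylo` tree.
#'
#' @param matrix Symmetric distance matrix with taxa dimnames.
#' @return An object of class `phylo`.
#' @export
neighbor_joining <- function(matrix) {
  d <- as.matrix(matrix)
  n <- nrow(d)
  stopifnot(n >= 2, isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  reps <- as.list(labels)
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    ij <- which(q == min(q), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_rep <- paste0("(", reps[[i]], ":", fmt(vi), ",",
                      reps[[j]], ":", fmt(vj), ")")
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    reps <- c(reps[keep], list(new_rep))
    d <- d2
  }
  if (nrow(d) == 3) {
    v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    nwk <- paste0("(", reps[[1]], ":", fmt(v1), ",", reps[[2]], ":", fmt(v2),
                  ",", reps[[3]], ":", fmt(v3), ");")
  } else {
    h <- d[1, 2] / 2
    nwk <- paste0("(", reps[[1]], ":", fmt(h), ",", reps[[2]], ":", fmt(h), ");")
  }
  ape::read.tree(text = nwk)
}

#' Bootstrap support for a distance tree
#'
#' Resamples alignment columns with replacement, rebuilds the distance
#' matrix and NJ tree for each replicate, and reports for every internal
#' edge of the full-data tree the percentage of replicate trees containing
#' the same bipartition.
#'
#' @param aligned Named character vector of equal-width gapped proteins.
#' @param n_reps Number of bootstrap replicates (1000 in full analyses; 100
#'   is adequate for quick runs).
#' @param seed Integer RNG seed (mandatory: resampling is stochastic).
#' @param model,gamma_shape Passed to [protein_distance()].
#' @return `list(tree, support)`: the full-data `phylo` with `node.label`
#'   set to supports (0-100, `NA` on the root node), and the support vector.
#' @export
bootstrap_support <- function(aligned, n_reps = 100L, seed,
                              model = "gamma", gamma_shape = 1.0) {
  stopifnot(!missing(seed))
  full <- neighbor_joining(protein_distance(aligned, model, gamma_shape))
  mat <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  w <- ncol(mat)
  set.seed(as.integer(seed))
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(w, w, replace = TRUE)
    res <- mat[, cols, drop = FALSE]
    aln <- setNames(apply(res, 1, paste, collapse = ""), names(aligned))
    boots[[b]] <- neighbor_joining(protein_distance(aln, model, gamma_shape))
  }
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  support <- round(100 * counts / n_reps)
  full$node.label <- support
  list(tree = full, support = support)
}
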