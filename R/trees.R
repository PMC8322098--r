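# sample one base (0 = major, 1 = minor) per individual per site from the
# posterior argmax genotype; heterozygotes resolve by a fair coin.  NA for
# missing entries.  Deterministic given the RNG state.
sample_consensus_bases <- function(gl, freqs = NULL) {
  pd <- posterior_dosage(gl, freqs)
  w0 <- (1 - pd$freqs)^2; w1 <- 2 * pd$freqs * (1 - pd$freqs)
  w2 <- pd$freqs^2
  S <- n_sites(gl); N <- n_ind(gl)
  B <- matrix(NA_integer_, S, N, dimnames = list(NULL, gl$inds$id))
  for (j in seq_len(N)) {
    post <- cbind(gl$lik[, j, 1] * w0, gl$lik[, j, 2] * w1,
                  gl$lik[, j, 3] * w2)
    gmax <- max.col(post, ties.method = "first") - 1L
    b <- ifelse(gmax == 1L, as.integer(runif(S) < 0.5), gmax %/% 2L)
    b[pd$missing[, j]] <- NA_integer_
    B[, j] <- b
  }
  B
}

#' Pairwise identity-by-state distance matrix by consensus-base sampling
#'
#' For each individual and site one base is drawn from the posterior
#' (HWE-prior) genotype; the distance between two individuals is the
#' fraction of jointly non-missing sites where their sampled bases differ.
#'
#' @param gl a `gl_matrix`.
#' @param seed RNG seed making the heterozygote coin flips reproducible.
#' @return symmetric distance matrix labelled by individual id.
#' @export
ibs_distance_matrix <- function(gl, seed = 1) {
  set.seed(seed)
  B <- sample_consensus_bases(gl)
  M0 <- B == 0L; M0[is.na(M0)] <- FALSE
  M1 <- B == 1L; M1[is.na(M1)] <- FALSE
  nm <- !is.na(B)
  same <- crossprod(M0) + crossprod(M1)
  tot <- crossprod(nm)
  if (any(tot == 0))
    stopf("some individual pair shares no non-missing site")
  d <- 1 - same / tot
  dimnames(d) <- list(gl$inds$id, gl$inds$id)
  d
}

#' Neighbor-joining tree from a distance matrix, rooted on an outgroup
#'
#' Canonical Saitou-Nei agglomeration (Studier-Keppler Q criterion); the
#' unrooted topology is then rooted on the outgroup's pendant edge.
#' Negative branch lengths are retained (clamp for display only).
#'
#' @param d symmetric distance matrix with labels (n >= 3).
#' @param outgroup label to root on (optional: unrooted tree otherwise).
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(d, outgroup = NULL) {
  if (!isSymmetric(unname(as.matrix(d))))
    stopf("distance matrix must be symmetric")
  if (nrow(as.matrix(d)) < 3) stopf("need at least 3 taxa")
  tr <- ape::nj(as.dist(d))
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) stopf("unknown outgroup '%s'", outgroup)
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

#' Block-bootstrap support for a neighbor-joining tree
#'
#' Sites are grouped into contiguous blocks of `block_bp`; each replicate
#' resamples blocks with replacement, rebuilds the sampled-base distance
#' matrix and the NJ tree, and internal-node support is the percentage of
#' replicates containing each bipartition.
#'
#' @param gl a `gl_matrix`.
#' @param n_reps bootstrap replicates (default 100, minimum 2).
#' @param block_bp block span in bp (default 5 Mb).
#' @param seed RNG seed (base sampling and block resampling).
#' @param outgroup optional outgroup label for rooting.
#' @return the main tree with `node.label` set to support percentages.
#' @export
bootstrap_support <- function(gl, n_reps = 100, block_bp = 5e6, seed = 1,
                              outgroup = NULL) {
  if (n_reps < 2) stopf("need at least 2 bootstrap replicates")
  set.seed(seed)
  B <- sample_consensus_bases(gl)
  blk <- assign_blocks(gl$sites, block_bp)
  ublk <- unique(blk)
  dist_from <- function(rows) {
    Bs <- B[rows, , drop = FALSE]
    M0 <- Bs == 0L; M0[is.na(M0)] <- FALSE
    M1 <- Bs == 1L; M1[is.na(M1)] <- FALSE
    nm <- !is.na(Bs)
    d <- 1 - (crossprod(M0) + crossprod(M1)) / crossprod(nm)
    dimnames(d) <- list(gl$inds$id, gl$inds$id)
    d
  }
  main <- nj_tree(dist_from(seq_len(nrow(B))), outgroup)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    bs <- sample(ublk, length(ublk), replace = TRUE)
    rows <- unlist(lapply(bs, function(b) which(blk == b)))
    reps[[r]] <- nj_tree(dist_from(rows), outgroup)
  }
  cl <- ape::prop.clades(main, reps, rooted = FALSE)
  cl[is.na(cl)] <- 0
  main$node.label <- round(100 * cl / n_reps)
  main
}

#' Clamp negative branch lengths to zero for display
#'
#' Neighbor joining can produce small negative branch lengths; analyses
#' keep the raw values, and this helper zeroes them for plotting only.
#'
#' @param tree a `phylo`.
#' @export
clamp_negative_branches <- function(tree) {
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Do a set of tips form a monophyletic clade with given support?
#'
#' Convenience check combining `ape::is.monophyletic` with the minimum
#' bootstrap support of the clade's stem node.
#'
#' @param tree a `phylo` with `node.label` support values.
#' @param tips tip labels.
#' @return list `monophyletic` (logical), `support` (stem support or NA).
#' @export
clade_support <- function(tree, tips) {
  mono <- ape::is.monophyletic(tree, tips)
  supp <- NA_real_
  if (mono) {
    node <- ape::getMRCA(tree, tips)
    lab <- tree$node.label[node - ape::Ntip(tree)]
    supp <- suppressWarnings(as.numeric(lab))
  }
  list(monophyletic = mono, support = supp)
}
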