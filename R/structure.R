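#' PCA of a genotype-likelihood panel
#'
#' Posterior mean genotypes under a HWE prior at the EM allele frequency
#' are standardized by \eqn{\sqrt{2f(1-f)}}; the individual covariance is
#' averaged over the sites non-missing in both members of each pair, and
#' eigendecomposed.  Eigenvector signs are fixed so the largest-magnitude
#' entry is positive.
#'
#' @param gl a `gl_matrix` with at least 2 individuals.
#' @return object of class `gl_pca`: `cov`, `values`, `vectors`,
#'   `var_explained`, `inds`.
#' @export
pca_gl <- function(gl) {
  if (n_ind(gl) < 2) stopf("need at least 2 individuals")
  pd <- posterior_dosage(gl)
  f <- pd$freqs
  keep <- f > 0 & f < 1
  if (!all(keep)) {
    warn(sprintf("%d sites with frequency 0 or 1 excluded", sum(!keep)))
    pd$dosage <- pd$dosage[keep, , drop = FALSE]
    pd$missing <- pd$missing[keep, , drop = FALSE]
    f <- f[keep]
  }
  x <- (pd$dosage - 2 * f) / sqrt(2 * f * (1 - f))
  x[pd$missing] <- 0
  nm <- 1 - pd$missing
  m_pair <- crossprod(nm)
  cv <- crossprod(x) / m_pair
  eig <- eigen(cv, symmetric = TRUE)
  vec <- eig$vectors
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  pos <- pmax(eig$values, 0)
  structure(list(cov = cv, values = eig$values, vectors = vec,
                 var_explained = pos / sum(pos), inds = gl$inds),
            class = "gl_pca")
}

#' @export
print.gl_pca <- function(x, ...) {
  cat(sprintf("<gl_pca> %d individuals; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$inds), 100 * x$var_explained[1],
              100 * x$var_explained[2]))
  invisible(x)
}

#' Admixture proportions by EM on genotype likelihoods
#'
#' Maximum-likelihood estimation of per-individual ancestry fractions Q and
#' cluster allele frequencies F for K clusters, maximizing
#' \eqn{\sum_{s,i} \log \sum_g L_{is}(g) P(g \mid Q_i, F_{\cdot s})} with a
#' binomial genotype mixture.  Q rows start from a flat Dirichlet, F from
#' Uniform(0.05, 0.95); frequencies are floored at 1e-5.  The observed
#' log-likelihood is non-decreasing across iterations.
#'
#' @param gl a `gl_matrix`.
#' @param K number of clusters (1 to `n_ind(gl)`).
#' @param seed RNG seed for the random initialization.
#' @param max_iter iteration cap (default 2000).
#' @param tol absolute log-likelihood change declaring convergence
#'   (default 1e-4).
#' @return object of class `qmatrix`: `Q` (individuals x K), `F`,
#'   `loglik`, `loglik_trace`, `iterations`, `K`, `seed`, `inds`.
#' @export
admixture_em <- function(gl, K, seed = 1, max_iter = 2000, tol = 1e-4) {
  N <- n_ind(gl)
  if (K < 1) stopf("K must be >= 1")
  if (K > N) stopf("K = %d exceeds the %d individuals", K, N)
  set.seed(seed)
  Q <- matrix(rexp(N * K), N, K)
  Q <- Q / rowSums(Q)
  F <- matrix(runif(K * n_sites(gl), 0.05, 0.95), K, n_sites(gl))
  slice <- function(g) matrix(gl$lik[, , g], nrow = n_sites(gl))
  fit <- admix_em_cpp(slice(1), slice(2), slice(3),
                      Q, F, as.integer(max_iter), tol, 1e-5)
  rownames(fit$Q) <- gl$inds$id
  structure(list(Q = fit$Q, F = fit$F, loglik = fit$loglik,
                 loglik_trace = fit$loglik_trace,
                 iterations = fit$iterations, K = K, seed = seed,
                 inds = gl$inds),
            class = "qmatrix")
}

#' @export
print.qmatrix <- function(x, ...) {
  cat(sprintf("<qmatrix> K = %d, logL = %.2f (%d iterations, seed %d)\n",
              x$K, x$loglik, x$iterations, x$seed))
  invisible(x)
}

# best column permutation of `run` against `ref` maximizing summed column
# correlation; exact search over all K! permutations for K <= 8
align_columns <- function(run, ref) {
  K <- ncol(ref)
  cc <- suppressWarnings(cor(run, ref))
  cc[is.na(cc)] <- 0
  if (K <= 8) {
    perms <- all_permutations(K)
    scores <- apply(perms, 1, function(p) sum(cc[cbind(p, seq_len(K))]))
    perms[which.max(scores), ]
  } else {
    # greedy fallback for large K
    perm <- integer(K)
    used <- logical(K)
    for (j in order(-apply(cc, 2, max))) {
      pick <- which.max(ifelse(used, -Inf, cc[, j]))
      perm[j] <- pick
      used[pick] <- TRUE
    }
    perm
  }
}

#' Align replicate admixture runs and average the major mode
#'
#' Columns of every run are permuted to best agree with the
#' highest-likelihood run (exact assignment on column correlations); runs
#' are then clustered by root-mean-square deviation of their aligned Q
#' matrices and the mean Q over the largest cluster is returned, rows
#' renormalized.
#'
#' @param runs list of `qmatrix` objects with identical K and individuals.
#' @param rmsd_threshold similarity radius defining a cluster of runs
#'   (default 0.1).
#' @return object of class `qmatrix_avg`: `Q`, `K`, `n_runs`,
#'   `major_cluster` (indices of averaged runs), `cluster` assignment.
#' @export
align_and_average_replicates <- function(runs, rmsd_threshold = 0.1) {
  if (length(runs) == 1L)
    return(structure(list(Q = runs[[1]]$Q, K = runs[[1]]$K, n_runs = 1L,
                          major_cluster = 1L, cluster = 1L),
                     class = "qmatrix_avg"))
  Ks <- vapply(runs, `[[`, numeric(1), "K")
  if (length(unique(Ks)) != 1L) stopf("runs differ in K")
  ref <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
  aligned <- lapply(runs, function(r) r$Q[, align_columns(r$Q, ref$Q),
                                          drop = FALSE])
  R <- length(runs)
  adj <- matrix(FALSE, R, R)
  for (i in seq_len(R)) for (j in seq_len(R))
    adj[i, j] <- sqrt(mean((aligned[[i]] - aligned[[j]])^2)) <
      rmsd_threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  major <- as.integer(names(which.max(table(memb))))
  idx <- which(memb == major)
  Q <- Reduce(`+`, aligned[idx]) / length(idx)
  Q <- Q / rowSums(Q)
  rownames(Q) <- rownames(runs[[1]]$Q)
  structure(list(Q = Q, K = runs[[1]]$K, n_runs = R,
                 major_cluster = idx, cluster = memb),
            class = "qmatrix_avg")
}

#' Evanno delta-K model choice across replicate admixture runs
#'
#' From replicate log-likelihoods per K: \eqn{L'(K) = \bar L(K) - \bar
#' L(K-1)}, \eqn{L''(K) = |L'(K+1) - L'(K)|}, \eqn{\Delta K = L''(K) /
#' \mathrm{sd}(L(K))}; the best K maximizes \eqn{\Delta K} over interior K.
#' Zero replicate spread yields an infinite \eqn{\Delta K}, reported but
#' excluded from the argmax with a warning.
#'
#' @param runs_by_k named list (names = K values) of lists of `qmatrix`
#'   objects (or bare numeric log-likelihood vectors), at least 3
#'   replicates each for interior K.
#' @return object of class `evanno`: `table` tibble (per K: `n_reps`,
#'   `mean_l`, `sd_l`, `l_prime`, `l_doubleprime`, `delta_k`) and `best_k`
#'   (`NA` when no interior K has a finite positive peak).
#' @export
evanno_best_k <- function(runs_by_k) {
  ks <- as.integer(names(runs_by_k))
  if (anyNA(ks)) stopf("runs_by_k must be named by K")
  o <- order(ks); ks <- ks[o]; runs_by_k <- runs_by_k[o]
  ll <- lapply(runs_by_k, function(runs) {
    if (is.numeric(runs)) runs else
      vapply(runs, `[[`, numeric(1), "loglik")
  })
  if (any(!is.finite(unlist(ll)))) stopf("non-finite log-likelihoods")
  mean_l <- unname(vapply(ll, mean, numeric(1)))
  sd_l <- unname(vapply(ll, sd, numeric(1)))
  nk <- length(ks)
  l_prime <- c(NA, diff(mean_l))
  l_pp <- rep(NA_real_, nk)
  if (nk >= 3)
    l_pp[2:(nk - 1)] <- abs(l_prime[3:nk] - l_prime[2:(nk - 1)])
  delta_k <- l_pp / sd_l
  tab <- tibble(K = ks, n_reps = lengths(ll), mean_l = mean_l,
                sd_l = sd_l, l_prime = l_prime, l_doubleprime = l_pp,
                delta_k = delta_k)
  cand <- which(!is.na(delta_k))
  inf_k <- cand[is.infinite(delta_k[cand])]
  if (length(inf_k)) {
    warn(sprintf("delta K infinite at K = %s (zero replicate spread); %s",
                 paste(ks[inf_k], collapse = ", "),
                 "excluded from the argmax"))
    cand <- setdiff(cand, inf_k)
  }
  best <- if (length(cand) && max(delta_k[cand]) > 0)
    ks[cand[which.max(delta_k[cand])]] else NA_integer_
  structure(list(table = tab, best_k = best), class = "evanno")
}

#' @export
print.evanno <- function(x, ...) {
  print(x$table)
  cat("best K:", x$best_k, "\n")
  invisible(x)
}

#' Run replicate admixture analyses over a range of K
#'
#' Convenience wrapper running [admixture_em()] for each K and replicate
#' with deterministic per-run seeds derived from `seed`.
#'
#' @param gl a `gl_matrix`.
#' @param k_range integer vector of K values.
#' @param n_reps replicates per K (default 10).
#' @param seed base seed.
#' @param ... passed to [admixture_em()].
#' @return named list (by K) of lists of `qmatrix` objects.
#' @export
admixture_scan <- function(gl, k_range = 1:6, n_reps = 10, seed = 1, ...) {
  out <- lapply(k_range, function(k)
    lapply(seq_len(n_reps), function(r)
      admixture_em(gl, k, seed = seed * 1000L + k * 100L + r, ...)))
  names(out) <- k_range
  out
}
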