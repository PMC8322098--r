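# P(data at site | minor-allele count k among the 2N chromosomes), for all
# sites and k = 0..2N, by dynamic programming over individuals with
# per-genotype multiplicities (1, 2, 1), normalized by choose(2N, k).
# Returns a sites x (2N + 1) matrix; per-site scale is arbitrary (the EM
# renormalizes per site).
site_class_likelihood <- function(gl) {
  S <- n_sites(gl); N <- n_ind(gl)
  h <- matrix(1, S, 1)
  for (i in seq_len(N)) {
    l0 <- gl$lik[, i, 1]; l1 <- gl$lik[, i, 2]; l2 <- gl$lik[, i, 3]
    zero <- matrix(0, S, 1)
    h <- cbind(h, zero, zero) * l0 +
      cbind(zero, h, zero) * (2 * l1) +
      cbind(zero, zero, h) * l2
  }
  sweep(h, 2, choose(2 * N, 0:(2 * N)), "/")
}

fold_index <- function(n_chrom) pmin(0:n_chrom, n_chrom - (0:n_chrom))

#' Folded one-dimensional site frequency spectrum by EM
#'
#' Maximizes \eqn{\sum_s \log \sum_k \eta_k P(\mathrm{data}_s \mid k)} over
#' the spectrum \eqn{\eta} with an EM whose observed log-likelihood is
#' non-decreasing.  Genotype-configuration likelihoods come from a dynamic
#' program over individuals.  The estimate is folded onto minor-allele
#' counts \eqn{k = 0..N}.
#'
#' @param gl a `gl_matrix` restricted to one population (or individual).
#' @param tol convergence tolerance on max spectrum change (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @return object of class `folded_sfs`: list with `n_chrom`, `counts`
#'   (folded expected site counts, classes `0..n_chrom/2`), `total`,
#'   `unfolded` and the attained `loglik` trace.
#' @export
sfs1d_em <- function(gl, tol = 1e-6, max_iter = 500) {
  if (n_sites(gl) == 0L) stopf("no sites")
  if (all(gl_missing(gl))) stopf("all sites missing in all individuals")
  q <- site_class_likelihood(gl)
  if (any(rowSums(q) <= 0))
    stopf("sites with no usable data")
  S <- nrow(q); K <- ncol(q)
  eta <- rep(1 / K, K)
  ll <- numeric(0)
  for (it in seq_len(max_iter)) {
    d <- as.vector(q %*% eta)
    ll <- c(ll, sum(log(d)))
    eta_new <- colMeans(q * rep(eta, each = S) / d)
    delta <- max(abs(eta_new - eta))
    eta <- eta_new
    if (delta < tol) break
  }
  unfolded <- eta * S
  fi <- fold_index(K - 1L)
  counts <- as.vector(tapply(unfolded, fi, sum))
  structure(list(n_chrom = K - 1L, counts = counts, total = S,
                 unfolded = unfolded, loglik = ll),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf("<folded_sfs> 2N = %d, %g sites\n", x$n_chrom, x$total))
  print(round(x$counts, 2))
  invisible(x)
}

#' Folded two-dimensional (joint) site frequency spectrum by EM
#'
#' Joint spectrum over minor-allele counts in two populations; the two
#' populations' genotype-configuration likelihoods are independent given
#' the counts, so the per-site cell likelihood is their outer product.
#'
#' @param gl_a,gl_b `gl_matrix` objects for the two populations covering the
#'   same sites (in the same order).
#' @inheritParams sfs1d_em
#' @return object of class `folded_sfs2d`: `n1`, `n2` (chromosome counts),
#'   `counts` (folded joint matrix), `full` (unfolded), `total`, `loglik`.
#' @export
sfs2d_em <- function(gl_a, gl_b, tol = 1e-6, max_iter = 500) {
  if (n_sites(gl_a) != n_sites(gl_b))
    stopf("the two populations must cover the same sites")
  qa <- site_class_likelihood(gl_a)
  qb <- site_class_likelihood(gl_b)
  S <- nrow(qa); A <- ncol(qa); B <- ncol(qb)
  eta <- matrix(1 / (A * B), A, B)
  ll <- numeric(0)
  for (it in seq_len(max_iter)) {
    d <- rowSums((qa %*% eta) * qb)
    ll <- c(ll, sum(log(d)))
    eta_new <- (t(qa / d) %*% qb) * eta / S
    delta <- max(abs(eta_new - eta))
    eta <- eta_new
    if (delta < tol) break
  }
  full <- eta * S
  # joint folding: cell (k1, k2) pairs with (n1-k1, n2-k2); keep the cell
  # with the smaller total minor count (lexicographic tie-break)
  n1 <- A - 1L; n2 <- B - 1L
  folded <- matrix(0, A, B)
  for (k1 in 0:n1) for (k2 in 0:n2) {
    p1 <- n1 - k1; p2 <- n2 - k2
    keep <- (k1 + k2 < p1 + p2) ||
      (k1 + k2 == p1 + p2 && (k1 < p1 || (k1 == p1 && k2 <= p2)))
    if (keep) folded[k1 + 1, k2 + 1] <-
        full[k1 + 1, k2 + 1] +
        if (k1 == p1 && k2 == p2) 0 else full[p1 + 1, p2 + 1]
  }
  structure(list(n1 = n1, n2 = n2, counts = folded, full = full,
                 total = S, loglik = ll),
            class = "folded_sfs2d")
}

#' Write / read a folded spectrum as a whitespace-separated count vector
#'
#' One line of expected counts per spectrum, smallest class first — the
#' layout of `.sfs` files in genotype-likelihood toolchains.
#'
#' @param sfs a `folded_sfs`.
#' @param path file path.
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(format(sfs$counts, trim = TRUE, digits = 10,
                          scientific = FALSE), collapse = " "), con)
  invisible(path)
}

#' @rdname write_sfs
#' @param n_chrom chromosome count 2N of the stored spectrum.
#' @export
read_sfs <- function(path, n_chrom) {
  counts <- scan(path, quiet = TRUE)
  if (length(counts) != n_chrom %/% 2 + 1)
    stopf("expected %d folded classes, found %d", n_chrom %/% 2 + 1,
          length(counts))
  structure(list(n_chrom = n_chrom, counts = counts,
                 total = sum(counts), unfolded = NULL, loglik = NULL),
            class = "folded_sfs")
}

#' Diversity statistics from a folded spectrum
#'
#' Per-site pairwise nucleotide diversity \eqn{\theta_\pi}, Watterson
#' \eqn{\theta_W} and Tajima's D (1989 variance constants) computed from the
#' folded spectrum; the pairwise-difference weight \eqn{k(n-k)/\binom{n}{2}}
#' is symmetric under folding so no unfolding is needed.
#'
#' @param sfs a `folded_sfs`.
#' @return one-row tibble: `theta_pi`, `theta_w` (per site), `tajima_d`
#'   (`NA` when no segregating sites), `segregating`, `n_sites`.
#' @export
sfs_summary_stats <- function(sfs) {
  n <- sfs$n_chrom
  if (n < 4) stopf("need at least 4 chromosomes")
  k <- seq_along(sfs$counts) - 1L
  pi_total <- sum(sfs$counts * k * (n - k)) / choose(n, 2)
  s_total <- sum(sfs$counts[-1])
  kc <- tajima_constants(n)
  tibble(theta_pi = pi_total / sfs$total,
         theta_w = s_total / kc$a1 / sfs$total,
         tajima_d = tajima_d(pi_total, s_total, n),
         segregating = s_total, n_sites = sfs$total)
}

#' Individual heterozygosity from a single-individual folded spectrum
#'
#' The fraction of sites estimated heterozygous: `counts[k=1] / total`.
#'
#' @param sfs a `folded_sfs` with `n_chrom == 2`.
#' @export
individual_heterozygosity <- function(sfs) {
  if (sfs$n_chrom != 2L) stopf("expected a single-individual spectrum")
  if (sfs$total <= 0) stopf("empty spectrum")
  sfs$counts[2] / sum(sfs$counts)
}
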