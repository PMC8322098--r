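# likelihood slice as a sites x individuals matrix even when a dimension
# drops to 1
lik_slice <- function(gl, g) matrix(gl$lik[, , g], nrow = n_sites(gl))

#' Genotype likelihoods from biallelic read counts
#'
#' Standard read-sampling likelihood for a diploid site: each minor-allele
#' read arises with probability \eqn{(g/2)(1-\epsilon) + (1-g/2)\epsilon}
#' given genotype \eqn{g} minor-allele copies, and conversely for
#' major-allele reads.  Triples are rescaled to maximum 1.  Zero total reads
#' yields the flat (missing) triple.
#'
#' @param n_major,n_minor non-negative read counts (vectors recycle).
#' @param error base-calling error rate, in (0, 0.5).
#' @return matrix with columns `L0`, `L1`, `L2` (one row per input pair).
#' @export
gl_from_counts <- function(n_major, n_minor, error = 0.01) {
  check_number(error, "error", 0, 0.5, open_lower = TRUE, open_upper = TRUE)
  if (any(n_major < 0) || any(n_minor < 0)) stopf("read counts must be >= 0")
  n <- length(n_major <- as.numeric(n_major))
  n_minor <- as.numeric(n_minor)
  p_minor <- c(error, 0.5, 1 - error)  # P(minor read | g = 0, 1, 2)
  ll <- outer(n_minor, log(p_minor)) + outer(n_major, log1p(-p_minor))
  ll <- ll - apply(ll, 1, max)
  out <- exp(ll)
  out[n_major + n_minor == 0, ] <- 1  # missing: flat triple
  colnames(out) <- c("L0", "L1", "L2")
  out
}

# per-site EM minor-allele frequencies for a whole panel, vectorized over
# sites; flat (missing) triples contribute their HWE prior expectation and
# therefore leave the fixed point untouched
em_freqs <- function(gl, tol = 1e-8, max_iter = 200) {
  L0 <- lik_slice(gl, 1)
  L1 <- lik_slice(gl, 2)
  L2 <- lik_slice(gl, 3)
  f <- rowMeans((L1 + 2 * L2) / (L0 + L1 + L2)) / 2
  f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
  for (it in seq_len(max_iter)) {
    w0 <- (1 - f)^2; w1 <- 2 * f * (1 - f); w2 <- f^2
    d <- L0 * w0 + L1 * w1 + L2 * w2
    fn <- rowMeans((L1 * w1 + 2 * L2 * w2) / d) / 2
    done <- max(abs(fn - f)) < tol
    f <- fn
    if (done) break
  }
  f
}

#' Maximum-likelihood minor-allele frequency at one site by EM
#'
#' Maximizes \eqn{\sum_i \log \sum_g L_i(g)\,\mathrm{HWE}(g \mid f)} over
#' \eqn{f}.  Flat triples (missing individuals) are allowed but at least one
#' individual must be non-missing.
#'
#' @param triples numeric matrix `n_ind x 3` of likelihood triples.
#' @param tol convergence tolerance on `f` (default 1e-8).
#' @param max_iter iteration cap (default 200).
#' @param trace if `TRUE`, attach the per-iteration observed log-likelihood
#'   as attribute `"loglik"`.
#' @return the ML frequency in \[0, 1\].
#' @export
allele_freq_em <- function(triples, tol = 1e-8, max_iter = 200,
                           trace = FALSE) {
  triples <- matrix(as.numeric(triples), ncol = 3)
  miss <- triples[, 1] == triples[, 2] & triples[, 2] == triples[, 3]
  if (all(miss)) stopf("all individuals missing at this site")
  f <- mean((triples[, 2] + 2 * triples[, 3]) / rowSums(triples)) / 2
  f <- min(max(f, 1e-6), 1 - 1e-6)
  ll <- numeric(0)
  for (it in seq_len(max_iter)) {
    w <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    d <- as.vector(triples %*% w)
    if (trace) ll <- c(ll, sum(log(d)))
    fn <- mean((triples[, 2] * w[2] + 2 * triples[, 3] * w[3]) / d) / 2
    if (abs(fn - f) < tol) { f <- fn; break }
    f <- fn
  }
  if (trace) attr(f, "loglik") <- ll
  f
}

#' Posterior mean genotypes under a HWE prior
#'
#' @param gl a `gl_matrix`.
#' @param freqs optional per-site minor-allele frequencies; estimated by EM
#'   when absent.
#' @return list with `dosage` (sites x individuals expected minor-allele
#'   count), `missing` (logical matrix) and `freqs`.
#' @export
posterior_dosage <- function(gl, freqs = NULL) {
  if (is.null(freqs)) freqs <- em_freqs(gl)
  w0 <- (1 - freqs)^2; w1 <- 2 * freqs * (1 - freqs); w2 <- freqs^2
  L0 <- lik_slice(gl, 1); L1 <- lik_slice(gl, 2); L2 <- lik_slice(gl, 3)
  d <- L0 * w0 + L1 * w1 + L2 * w2
  list(dosage = (L1 * w1 + 2 * L2 * w2) / d, missing = gl_missing(gl),
       freqs = freqs)
}

#' Filter a panel on minor-allele frequency and missingness
#'
#' Keeps sites whose EM minor-allele frequency is at least `maf_min` and
#' whose fraction of missing individuals is at most `max_missing` (default
#' 0: covered in all individuals).  Site order is preserved.
#'
#' @param gl a `gl_matrix`.
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @param max_missing maximum missing fraction per site (default 0).
#' @return filtered `gl_matrix`; attribute `"filter_report"` is a tibble of
#'   counts removed per rule (missingness is applied first).
#' @export
filter_sites <- function(gl, maf_min = 0.05, max_missing = 0) {
  check_number(maf_min, "maf_min", 0, 1)
  check_number(max_missing, "max_missing", 0, 1)
  missfrac <- rowMeans(gl_missing(gl))
  ok_miss <- missfrac <= max_missing
  f <- em_freqs(gl)
  maf <- pmin(f, 1 - f)
  ok_maf <- maf >= maf_min
  keep <- ok_miss & ok_maf
  report <- tibble(
    rule = c("missingness", "maf", "kept"),
    n = c(sum(!ok_miss), sum(ok_miss & !ok_maf), sum(keep)))
  if (!any(keep))
    warn("no sites survive filtering")
  out <- gl_subset(gl, sites = which(keep))
  attr(out, "filter_report") <- report
  attr(out, "freqs") <- f[keep]
  out
}

#' Prune linked sites, keeping the most central site per linked block
#'
#' Pairwise \eqn{r^2} is the squared Pearson correlation of posterior mean
#' genotypes between sites within `max_dist_bp` on the same chromosome.
#' Blocks are connected components of the \eqn{r^2 >} `r2_threshold` graph;
#' the member closest to the block's bp midpoint survives (ties resolve to
#' the lower position).  Unlinked sites are all kept.
#'
#' @param gl a `gl_matrix` (sites sorted; enforced by the container).
#' @param r2_threshold linkage threshold (default 0.2).
#' @param max_dist_bp maximal pair distance considered (default 1e5).
#' @return pruned `gl_matrix` with attribute `"linked_blocks"`, a tibble
#'   describing each multi-site block and its representative.
#' @export
ld_prune <- function(gl, r2_threshold = 0.2, max_dist_bp = 1e5) {
  pd <- posterior_dosage(gl)
  S <- n_sites(gl)
  x <- matrix(pd$dosage, nrow = S)
  sdx <- apply(x, 1, sd)
  pos <- gl$sites$pos
  chrom <- gl$sites$chrom
  from <- integer(0); to <- integer(0)
  for (i in seq_len(S)) {
    j <- i + 1L
    while (j <= S && chrom[j] == chrom[i] && pos[j] - pos[i] <= max_dist_bp) {
      if (sdx[i] > 0 && sdx[j] > 0 &&
          cor(x[i, ], x[j, ])^2 > r2_threshold) {
        from <- c(from, i); to <- c(to, j)
      }
      j <- j + 1L
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, S - igraph::gorder(g)))
  comp <- igraph::components(g)$membership
  keep <- logical(S)
  blocks <- list()
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) == 1L) { keep[members] <- TRUE; next }
    mid <- (min(pos[members]) + max(pos[members])) / 2
    dmid <- abs(pos[members] - mid)
    rep_site <- members[order(dmid, pos[members])][1]
    keep[rep_site] <- TRUE
    blocks[[length(blocks) + 1L]] <-
      tibble(block = length(blocks) + 1L, chrom = chrom[rep_site],
             n_members = length(members),
             first_pos = min(pos[members]), last_pos = max(pos[members]),
             representative_pos = pos[rep_site])
  }
  out <- gl_subset(gl, sites = which(keep))
  attr(out, "linked_blocks") <-
    if (length(blocks)) bind_rows(blocks) else
      tibble(block = integer(0), chrom = character(0),
             n_members = integer(0), first_pos = integer(0),
             last_pos = integer(0), representative_pos = integer(0))
  out
}
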