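# Hudson per-cell numerator/denominator over a joint allele-count grid;
# with finite chromosome counts the numerator carries the unbiased
# within-population sampling correction.  Both members of a folded cell
# pair give identical values (the formulas are invariant under jointly
# complementing both frequencies), so folded and unfolded spectra agree.
hudson_cells <- function(n1, n2) {
  p1 <- outer((0:n1) / n1, rep(1, n2 + 1))
  p2 <- outer(rep(1, n1 + 1), (0:n2) / n2)
  alpha <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  beta <- p1 * (1 - p2) + p2 * (1 - p1)
  list(alpha = alpha, beta = beta)
}

#' Hudson F_ST per site from population allele frequencies
#'
#' \eqn{\alpha = (p_1-p_2)^2}, \eqn{\beta = p_1(1-p_2) + p_2(1-p_1)};
#' finite sample sizes (chromosomes) add the unbiased correction
#' \eqn{-\,p_i(1-p_i)/(n_i-1)} per population.  With `n1 = n2 = Inf` the
#' inputs are treated as population (not sample) frequencies.
#'
#' @param p1,p2 allele frequencies (vectors recycle).
#' @param n1,n2 chromosome counts (default `Inf`).
#' @return list of vectors `alpha`, `beta`, and `fst = sum(alpha)/sum(beta)`.
#' @export
hudson_fst <- function(p1, p2, n1 = Inf, n2 = Inf) {
  corr1 <- if (is.finite(n1)) p1 * (1 - p1) / (n1 - 1) else 0
  corr2 <- if (is.finite(n2)) p2 * (1 - p2) / (n2 - 1) else 0
  alpha <- (p1 - p2)^2 - corr1 - corr2
  beta <- p1 * (1 - p2) + p2 * (1 - p1)
  list(alpha = alpha, beta = beta, fst = sum(alpha) / sum(beta))
}

#' F_ST and Slatkin's linearized F_ST from a folded 2D spectrum
#'
#' Ratio-of-averages Hudson/Bhatia estimator: per-cell unbiased numerator
#' and denominator weighted by the spectrum's mass.
#'
#' @param sfs a `folded_sfs2d` from [sfs2d_em()].
#' @return object of class `fst_estimate`: `alpha`, `beta` (weighted
#'   sums), `fst`, `slatkin`; all `NA`-flagged when no variation.
#' @export
fst_from_sfs2d <- function(sfs) {
  if (sfs$n1 < 2 || sfs$n2 < 2) stopf("need >= 2 chromosomes per side")
  cells <- hudson_cells(sfs$n1, sfs$n2)
  mass <- sfs$full
  a <- sum(mass * cells$alpha)
  b <- sum(mass * cells$beta)
  fst <- if (b > 0) a / b else NA_real_
  structure(list(alpha = a, beta = b, fst = fst,
                 slatkin = slatkin_linearized(fst)),
            class = "fst_estimate")
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("F_ST = %.5f (Slatkin F' = %.5f)\n", x$fst, x$slatkin))
  invisible(x)
}

#' Slatkin's linearization F_ST / (1 - F_ST)
#' @param fst F_ST value(s) in \[0, 1).
#' @export
slatkin_linearized <- function(fst) fst / (1 - fst)

#' Pairwise F_ST matrix between colonies of a panel
#'
#' Runs [sfs2d_em()] and [fst_from_sfs2d()] for every colony pair.
#'
#' @param gl a `gl_matrix` with colony labels.
#' @param colonies subset of colonies (default all).
#' @param linearized return Slatkin's linearized values instead of F_ST.
#' @param ... passed to [sfs2d_em()].
#' @return symmetric labelled matrix.
#' @export
pairwise_fst <- function(gl, colonies = NULL, linearized = FALSE, ...) {
  if (is.null(colonies)) colonies <- unique(gl$inds$colony)
  k <- length(colonies)
  out <- matrix(0, k, k, dimnames = list(colonies, colonies))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    s2 <- sfs2d_em(gl_subset(gl, inds = colonies[i]),
                   gl_subset(gl, inds = colonies[j]), ...)
    est <- fst_from_sfs2d(s2)
    out[i, j] <- out[j, i] <- if (linearized) est$slatkin else est$fst
  }
  out
}

# per-site expected Hudson alpha/beta under the posterior over joint
# allele counts with the global 2D spectrum as prior
site_alpha_beta <- function(gl_a, gl_b, sfs) {
  qa <- site_class_likelihood(gl_a)
  qb <- site_class_likelihood(gl_b)
  eta <- sfs$full
  cells <- hudson_cells(sfs$n1, sfs$n2)
  d <- rowSums((qa %*% eta) * qb)
  alpha <- rowSums((qa %*% (eta * cells$alpha)) * qb) / d
  beta <- rowSums((qa %*% (eta * cells$beta)) * qb) / d
  list(alpha = alpha, beta = beta)
}

#' Sliding-window F_ST between two populations
#'
#' Per-site Hudson numerator and denominator are posterior expectations
#' under the global 2D spectrum prior; windows (default 50 kb sliding by
#' 12.5 kb) sum the per-site terms.  Window placement covers every site by
#' exactly `window/step` windows, so the genome-wide ratio of summed
#' window numerators to denominators equals the global estimate exactly.
#'
#' @param gl_a,gl_b per-population `gl_matrix` objects on the same sites;
#'   `gl_a` must carry `chrom_lengths`.
#' @param window,step window and slide in bp (step must not exceed
#'   window).
#' @param sfs optional precomputed `folded_sfs2d` (estimated when absent).
#' @param min_sites windows with fewer sites are flagged (`fst = NA`).
#' @return object of class `fst_windows`: tibble `windows` (`chrom`,
#'   `start`, `end`, `n_sites`, `alpha`, `beta`, `fst`), `global`
#'   (`fst_estimate` from the per-site sums) and per-site vectors.
#' @export
sliding_window_fst <- function(gl_a, gl_b, window = 5e4, step = 1.25e4,
                               sfs = NULL, min_sites = 5) {
  if (step > window) stopf("step must not exceed window")
  if (is.null(gl_a$chrom_lengths)) stopf("gl_a carries no chrom_lengths")
  if (is.null(sfs)) sfs <- sfs2d_em(gl_a, gl_b)
  ab <- site_alpha_beta(gl_a, gl_b, sfs)
  sites <- gl_a$sites
  rows <- list()
  for (chrom in names(gl_a$chrom_lengths)) {
    len <- gl_a$chrom_lengths[[chrom]]
    starts <- seq(-window + step, max(0, len - 1), by = step)
    on_chrom <- which(sites$chrom == chrom)
    pos <- sites$pos[on_chrom]
    for (st in starts) {
      en <- st + window
      sel <- on_chrom[pos > st & pos <= en]
      a <- sum(ab$alpha[sel]); b <- sum(ab$beta[sel])
      rows[[length(rows) + 1L]] <- tibble(
        chrom = chrom, start = max(0, st), end = min(en, len),
        n_sites = length(sel), alpha = a, beta = b,
        fst = if (length(sel) >= min_sites && b > 0) a / b else NA_real_)
    }
  }
  windows <- bind_rows(rows)
  ga <- sum(ab$alpha); gb <- sum(ab$beta)
  global <- structure(list(alpha = ga, beta = gb, fst = ga / gb,
                           slatkin = slatkin_linearized(ga / gb)),
                      class = "fst_estimate")
  structure(list(windows = windows, global = global,
                 site_alpha = ab$alpha, site_beta = ab$beta),
            class = "fst_windows")
}

#' Weighted delete-one block jackknife for genome-wide statistics
#'
#' Delete-one re-estimates over contiguous genomic blocks with the
#' weighted jackknife variance (blocks may carry unequal weights, e.g.
#' informative-site counts); Z = estimate / SE.
#'
#' @param blocks tibble/data.frame with one row per block.
#' @param statistic function mapping a subset of `blocks` to a scalar.
#' @param weights per-block weights (default equal).
#' @return list: `estimate`, `se`, `z`, `n_blocks`, `loo` (delete-one
#'   values).  `se = 0` yields an infinite Z, flagged by `z_finite`.
#' @export
block_jackknife <- function(blocks, statistic, weights = NULL) {
  g <- nrow(blocks)
  if (g < 10) stopf("need at least 10 blocks (got %d)", g)
  if (is.null(weights)) weights <- rep(1, g)
  if (any(weights <= 0)) stopf("weights must be positive")
  theta <- statistic(blocks)
  loo <- vapply(seq_len(g), function(j) statistic(blocks[-j, , drop = FALSE]),
                numeric(1))
  n <- sum(weights)
  h <- n / weights
  theta_j <- g * theta - sum((1 - weights / n) * loo)
  tau <- h * theta - (h - 1) * loo
  var_j <- mean((tau - theta_j)^2 / (h - 1))
  se <- sqrt(max(var_j, 0))
  degenerate <- se <= 1e-12 * max(1, abs(theta))
  z <- if (degenerate) sign(theta) * Inf else theta / se
  list(estimate = theta, se = se, z = z, z_finite = !degenerate,
       n_blocks = g, loo = loo)
}

# per-population per-site ML allele frequencies (minor allele of the panel)
population_freqs <- function(gl, pops) {
  vapply(pops, function(p) em_freqs(gl_subset(gl, inds = p)),
         numeric(n_sites(gl)))
}

assign_blocks <- function(sites, block_bp) {
  paste(sites$chrom, floor((sites$pos - 1) / block_bp))
}

#' ABBA-BABA D-statistic with block-jackknife Z-score
#'
#' The outgroup's consensus base defines the ancestral allele per site
#' (sites where the outgroup looks polymorphic are skipped and counted);
#' one base is sampled per focal population, weighted by its posterior
#' allele frequency; \eqn{D = (n_{ABBA} - n_{BABA}) / (n_{ABBA} +
#' n_{BABA})}, Z from the weighted block jackknife over `block_bp` blocks.
#'
#' @param gl a `gl_matrix`.
#' @param p1,p2,p3,outgroup colony names (or character vectors of colonies).
#' @param block_bp jackknife block span (default 5 Mb).
#' @param seed RNG seed for the per-population base sampling.
#' @param outgroup_maf sites with outgroup minor-allele frequency above
#'   this are treated as polymorphic and skipped (default 0.2).
#' @return object of class `dstat_result`: `d`, `z`, `se`, `n_abba`,
#'   `n_baba`, `n_skipped`, `n_blocks`.
#' @export
dstat <- function(gl, p1, p2, p3, outgroup, block_bp = 5e6, seed = 1,
                  outgroup_maf = 0.2) {
  set.seed(seed)
  pops <- list(p1 = p1, p2 = p2, p3 = p3, out = outgroup)
  f <- population_freqs(gl, pops)
  poly <- pmin(f[, "out"], 1 - f[, "out"]) > outgroup_maf
  anc_minor <- f[, "out"] > 0.5  # consensus base is the minor allele
  S <- n_sites(gl)
  draw <- matrix(runif(3 * S), S, 3) < f[, c("p1", "p2", "p3")]
  # derived = sampled base opposite to the outgroup consensus
  derived <- (draw & !anc_minor) | (!draw & anc_minor)
  abba <- !poly & !derived[, 1] & derived[, 2] & derived[, 3]
  baba <- !poly & derived[, 1] & !derived[, 2] & derived[, 3]
  blk <- assign_blocks(gl$sites, block_bp)
  tab <- tibble(block = blk, abba = as.numeric(abba),
                baba = as.numeric(baba)) |>
    group_by(.data$block) |>
    summarise(abba = sum(.data$abba), baba = sum(.data$baba),
              .groups = "drop") |>
    filter(.data$abba + .data$baba > 0)
  dfun <- function(b) (sum(b$abba) - sum(b$baba)) /
    (sum(b$abba) + sum(b$baba))
  jk <- block_jackknife(tab, dfun, weights = tab$abba + tab$baba)
  structure(list(d = jk$estimate, z = jk$z, se = jk$se,
                 n_abba = sum(abba), n_baba = sum(baba),
                 n_skipped = sum(poly), n_blocks = jk$n_blocks),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D = %.4f (Z = %.2f; ABBA %d, BABA %d; %d blocks)\n",
              x$d, x$z, x$n_abba, x$n_baba, x$n_blocks))
  invisible(x)
}

#' Three-population f3 test for admixture
#'
#' \eqn{f_3(C; A, B) = \mathrm{E}[(c-a)(c-b)]} with the unbiased
#' finite-sample correction \eqn{-\,\hat c(1-\hat c)/(n_C - 1)} for the
#' \eqn{n_C} chromosomes of the target; significantly negative values mark
#' C as admixed between sources related to A and B.  Z by weighted block
#' jackknife.
#'
#' @param gl a `gl_matrix`.
#' @param target,source_a,source_b colony names (target needs >= 2
#'   diploids for the correction).
#' @param block_bp jackknife block span (default 5 Mb).
#' @return object of class `f3_result`: `f3`, `z`, `se`, `n_sites`,
#'   `n_blocks`.
#' @export
f3stat <- function(gl, target, source_a, source_b, block_bp = 5e6) {
  n_c <- 2 * sum(gl$inds$colony %in% target)
  if (n_c < 4) stopf("target needs at least 2 diploids")
  f <- population_freqs(gl, list(c = target, a = source_a, b = source_b))
  f3_site <- (f[, "c"] - f[, "a"]) * (f[, "c"] - f[, "b"]) -
    f[, "c"] * (1 - f[, "c"]) / (n_c - 1)
  blk <- assign_blocks(gl$sites, block_bp)
  tab <- tibble(block = blk, num = f3_site) |>
    group_by(.data$block) |>
    summarise(num = sum(.data$num), n = n(), .groups = "drop")
  f3fun <- function(b) sum(b$num) / sum(b$n)
  jk <- block_jackknife(tab, f3fun, weights = tab$n)
  structure(list(f3 = jk$estimate, z = jk$z, se = jk$se,
                 n_sites = sum(tab$n), n_blocks = jk$n_blocks),
            class = "f3_result")
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3 = %.5f (Z = %.2f; %d sites, %d blocks)\n",
              x$f3, x$z, x$n_sites, x$n_blocks))
  invisible(x)
}
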