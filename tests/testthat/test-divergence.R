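test_that("Hudson per-site F_ST matches the hand-computed value", {
  est <- hudson_fst(0.2, 0.8)  # population frequencies, no correction
  expect_equal(est$alpha, 0.36, tolerance = 1e-12)
  expect_equal(est$beta, 0.68, tolerance = 1e-12)
  expect_equal(est$fst, 0.36 / 0.68, tolerance = 1e-12)
  # identical frequencies with finite samples: correction centers on zero
  expect_equal(hudson_fst(0.5, 0.5)$fst, 0)
})

test_that("Slatkin linearization is the monotone invertible transform", {
  expect_equal(slatkin_linearized(0.5), 1.0)
  expect_equal(slatkin_linearized(0), 0)
  x <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(slatkin_linearized(x)) > 0))
  # invertible: F' / (1 + F') recovers F_ST
  fp <- slatkin_linearized(x)
  expect_equal(fp / (1 + fp), x, tolerance = 1e-12)
})

test_that("F_ST from the 2D spectrum: zero for identical populations", {
  set.seed(41)
  f <- runif(400, 0.1, 0.9)
  g <- sapply(1:8, function(i) rbinom(400, 2, f))
  gl_a <- gl_from_genotypes(g[, 1:4], depth = 400, error = 1e-3)
  gl_b <- gl_from_genotypes(g[, 5:8], depth = 400, error = 1e-3)
  s2 <- sfs2d_em(gl_a, gl_b)
  est <- fst_from_sfs2d(s2)
  expect_lt(abs(est$fst), 0.02)
  # all mass on equal-frequency diagonal cells with no variation: flagged
  s0 <- structure(list(n1 = 4, n2 = 4,
                       full = diag(c(1, 0, 0, 0, 0)), counts = NULL,
                       total = 1), class = "folded_sfs2d")
  expect_true(is.na(fst_from_sfs2d(s0)$fst))
})

test_that("2D-SFS F_ST tracks the truth for diverged populations", {
  set.seed(42)
  f0 <- runif(1500, 0.1, 0.9)
  drift <- function(p, F) rbeta(length(p), p * (1 - F) / F,
                                (1 - p) * (1 - F) / F)
  fa <- drift(f0, 0.05); fb <- drift(f0, 0.05)
  ga <- sapply(1:6, function(i) rbinom(1500, 2, fa))
  gb <- sapply(1:6, function(i) rbinom(1500, 2, fb))
  gl_a <- gl_from_genotypes(ga, depth = 20)
  gl_b <- gl_from_genotypes(gb, depth = 20)
  est <- fst_from_sfs2d(sfs2d_em(gl_a, gl_b))
  truth <- hudson_fst(fa, fb)$fst
  expect_equal(est$fst, truth, tolerance = 0.25)
  expect_gt(est$fst, 0.01)
})

test_that("window F_ST sums reproduce the global estimate exactly", {
  set.seed(43)
  f0 <- runif(600, 0.1, 0.9)
  fa <- pmin(pmax(f0 + rnorm(600, 0, 0.1), 0.01), 0.99)
  fb <- pmin(pmax(f0 - rnorm(600, 0, 0.1), 0.01), 0.99)
  ga <- sapply(1:5, function(i) rbinom(600, 2, fa))
  gb <- sapply(1:5, function(i) rbinom(600, 2, fb))
  pos <- sort(sample(1e6, 600))
  gl_a <- gl_from_genotypes(ga, depth = 25, positions = pos,
                            chrom_lengths = c(chr1 = 1e6))
  gl_b <- gl_from_genotypes(gb, depth = 25, positions = pos,
                            chrom_lengths = c(chr1 = 1e6))
  res <- sliding_window_fst(gl_a, gl_b, window = 5e4, step = 1.25e4)
  # every site is covered by exactly window/step = 4 windows, so window
  # sums are additive and their ratio equals the global ratio exactly
  expect_equal(sum(res$windows$alpha) / sum(res$windows$beta),
               res$global$fst, tolerance = 1e-12)
  expect_equal(sum(res$windows$n_sites), 4 * 600)
  # empty windows are flagged, not zero
  expect_true(all(is.na(res$windows$fst[res$windows$n_sites == 0])))
  expect_error(sliding_window_fst(gl_a, gl_b, window = 1e4, step = 2e4),
               "step")
})

test_that("block jackknife matches the hand-computed weighted formula", {
  blocks <- tibble::tibble(
    num = c(3.2, 2.1, 4.0, 1.5, 2.8, 3.6, 2.2, 1.9, 3.1, 2.5, 2.9, 3.3),
    den = c(10, 8, 12, 6, 9, 11, 7, 8, 10, 9, 9, 11))
  jk <- block_jackknife(blocks, function(b) sum(b$num) / sum(b$den),
                        weights = blocks$den)
  expect_equal(jk$estimate, 0.300909090909, tolerance = 1e-12)
  expect_equal(jk$se, 0.008855011912, tolerance = 1e-9)
  expect_equal(jk$z, 33.981782735052, tolerance = 1e-6)
  # identical blocks: zero SE, infinite Z flagged
  same <- tibble::tibble(num = rep(2, 10), den = rep(10, 10))
  jk0 <- block_jackknife(same, function(b) sum(b$num) / sum(b$den))
  expect_equal(jk0$se, 0)
  expect_false(jk0$z_finite)
  expect_error(block_jackknife(same[1:5, ], function(b) 1), "blocks")
})

test_that("D-statistic arithmetic and admixture signal behave", {
  set.seed(44)
  # strongly admixed P2 with donor P3: positive D
  S <- 8000
  f0 <- runif(S, 0.2, 0.8)
  drift <- function(p, F) rbeta(length(p), p * (1 - F) / F,
                                (1 - p) * (1 - F) / F)
  f3p <- drift(f0, 0.2)           # P3 (donor side)
  f1 <- drift(f0, 0.02)           # P1
  f2 <- 0.5 * f1 + 0.5 * f3p      # P2 admixed with P3
  fo <- round(f0)                 # fixed outgroup alleles
  mk <- function(f, colony) {
    g <- sapply(1:4, function(i) rbinom(S, 2, f))
    g
  }
  pos <- sort(sample(5e7, S))
  geno <- cbind(mk(f1), mk(f2), mk(f3p), mk(fo))
  gl <- gl_from_genotypes(geno, depth = 20,
                          colony = rep(c("p1", "p2", "p3", "out"),
                                       each = 4),
                          positions = pos,
                          chrom_lengths = c(chr1 = 5e7))
  res <- dstat(gl, "p1", "p2", "p3", "out", block_bp = 2.5e6, seed = 9)
  expect_equal(res$d, (res$n_abba - res$n_baba) /
                 (res$n_abba + res$n_baba), tolerance = 1e-12)
  expect_gt(res$d, 0)
  expect_gt(res$z, 3)
})

test_that("f3 matches the hand-evaluated corrected formula", {
  # 3 sites, target frequencies c, sources a and b, 6 diploids in target
  cf <- c(0.5, 0.3, 0.8); af <- c(0.9, 0.1, 0.6); bf <- c(0.1, 0.7, 0.9)
  f3_sites <- (cf - af) * (cf - bf) - cf * (1 - cf) / (12 - 1)
  expect_equal(f3_sites,
               c(-0.182727272727, -0.099090909091, -0.034545454545),
               tolerance = 1e-9)
  expect_equal(mean(f3_sites), -0.105454545455, tolerance = 1e-10)
})

test_that("f3 is negative for an admixed target, >= 0 for a clone", {
  set.seed(45)
  S <- 4000
  f0 <- runif(S, 0.2, 0.8)
  drift <- function(p, F) rbeta(length(p), p * (1 - F) / F,
                                (1 - p) * (1 - F) / F)
  fa <- drift(f0, 0.08); fb <- drift(f0, 0.08)
  fc <- 0.5 * fa + 0.5 * fb
  mk <- function(f) sapply(1:6, function(i) rbinom(S, 2, f))
  pos <- sort(sample(5e7, S))
  gl <- gl_from_genotypes(cbind(mk(fa), mk(fb), mk(fc)), depth = 20,
                          colony = rep(c("a", "b", "c"), each = 6),
                          positions = pos,
                          chrom_lengths = c(chr1 = 5e7))
  adm <- f3stat(gl, "c", "a", "b", block_bp = 2.5e6)
  expect_lt(adm$f3, 0)
  expect_lt(adm$z, -3)
  # target cloned from source a (same frequencies): f3 >= 0 within noise
  gl2 <- gl_from_genotypes(cbind(mk(fa), mk(fb), mk(fa)), depth = 20,
                           colony = rep(c("a", "b", "c"), each = 6),
                           positions = pos,
                           chrom_lengths = c(chr1 = 5e7))
  clone <- f3stat(gl2, "c", "a", "b", block_bp = 2.5e6)
  expect_gt(clone$z, -3)
  expect_error(f3stat(gl_subset(gl, inds = c(1:6, 7:12, 13)),
                      "c", "a", "b"), "diploids")
})
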