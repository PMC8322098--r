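test_that("gl_from_counts matches the direct product likelihood", {
  # no reads: flat (missing) triple
  expect_equal(unname(gl_from_counts(0, 0, 0.01)[1, ]), c(1, 1, 1))
  # 5 minor reads, no major reads, eps = 0.01: unnormalized likelihoods
  # are (0.01^5, 0.5^5, 0.99^5); the function reports them relative to
  # the maximum
  tri <- gl_from_counts(0, 5, 0.01)[1, ]
  direct <- c(0.01^5, 0.5^5, 0.99^5)
  expect_equal(unname(tri), direct / max(direct), tolerance = 1e-12)
  # balanced reads at tiny error force the heterozygote
  tri <- gl_from_counts(3, 3, 1e-9)[1, ]
  expect_equal(unname(which.max(tri)), 2L)
  expect_lt(tri[1] / tri[2], 1e-12)
  expect_lt(tri[3] / tri[2], 1e-12)
})

test_that("gl_from_counts is scale-invariant in the argmax", {
  for (counts in list(c(4, 0), c(0, 3), c(2, 2), c(5, 1))) {
    a <- gl_from_counts(counts[1], counts[2], 1e-6)
    b <- gl_from_counts(2 * counts[1], 2 * counts[2], 1e-6)
    expect_equal(which.max(a[1, ]), which.max(b[1, ]))
  }
  expect_error(gl_from_counts(-1, 2), "counts")
  expect_error(gl_from_counts(1, 2, error = 0.7), "error")
})

test_that("allele_freq_em finds the ML frequency", {
  # all homozygous major
  trips <- matrix(rep(c(1, 0, 0), 5), ncol = 3, byrow = TRUE)
  expect_lt(allele_freq_em(trips), 1e-5)
  # all heterozygous, n = 4
  trips <- matrix(rep(c(0, 1, 0), 4), ncol = 3, byrow = TRUE)
  expect_equal(allele_freq_em(trips), 0.5, tolerance = 1e-6)
  expect_error(allele_freq_em(matrix(1, 3, 3)), "missing")
})

test_that("allele_freq_em agrees with a grid search and is monotone", {
  set.seed(42)
  for (rep in 1:5) {
    trips <- matrix(runif(18), ncol = 3)
    f_em <- allele_freq_em(trips, trace = TRUE)
    grid <- seq(0, 1, by = 1e-4)
    ll <- vapply(grid, function(f) {
      w <- c((1 - f)^2, 2 * f * (1 - f), f^2)
      sum(log(trips %*% w))
    }, numeric(1))
    expect_lt(abs(as.numeric(f_em) - grid[which.max(ll)]), 1e-3)
    trace <- attr(f_em, "loglik")
    expect_true(all(diff(trace) > -1e-9))
  }
})

test_that("filter_sites applies MAF and missingness rules", {
  set.seed(1)
  geno <- cbind(c(0, 0, 0, 0), c(0, 1, 2, 0), c(0, 1, 2, 1),
                c(0, 0, 1, 1), c(0, 2, 0, 1), c(0, 1, 1, 0))
  gl <- gl_from_genotypes(t(geno))  # 6 sites x 4 individuals
  # site 1 is monomorphic: dropped at maf_min = 0.05
  out <- filter_sites(gl, maf_min = 0.05, max_missing = 0)
  expect_false(1000 %in% out$sites$pos)
  rep <- attr(out, "filter_report")
  expect_tibble_names(rep, c("rule", "n"))
  expect_equal(sum(rep$n[rep$rule == "kept"]), n_sites(out))
  # make one individual missing at site 2: dropped when max_missing = 0
  gl$lik[2, 3, ] <- c(1, 1, 1)
  out0 <- filter_sites(gl, maf_min = 0, max_missing = 0)
  expect_false(2000 %in% out0$sites$pos)
  out1 <- filter_sites(gl, maf_min = 0, max_missing = 0.5)
  expect_true(2000 %in% out1$sites$pos)
})

test_that("filter_sites survivors equal a brute-force recount", {
  set.seed(7)
  f_true <- runif(60, 0.01, 0.5)
  geno <- sapply(1:8, function(i) rbinom(60, 2, f_true))
  gl <- gl_from_genotypes(geno, depth = 500, error = 1e-3)
  out <- filter_sites(gl, maf_min = 0.1, max_missing = 0)
  # at near-certain genotypes the EM frequency is the sample frequency
  f_hat <- rowMeans(geno) / 2
  maf <- pmin(f_hat, 1 - f_hat)
  expect_equal(sort(out$sites$pos), sort((1:60 * 1000L)[maf >= 0.1]))
})

test_that("ld_prune keeps the most central site of a linked block", {
  set.seed(3)
  g <- rbinom(12, 2, 0.5)
  geno <- cbind(g, g, g, rbinom(12, 2, 0.4))  # 3 identical + 1 free site
  gl <- gl_from_genotypes(t(geno), depth = 400, error = 1e-3,
                          positions = c(1000L, 5000L, 9000L, 60000L))
  out <- ld_prune(gl, r2_threshold = 0.2, max_dist_bp = 1e5)
  # middle of the identical trio survives; the unlinked site survives
  expect_equal(out$sites$pos, c(5000L, 60000L))
  blocks <- attr(out, "linked_blocks")
  expect_equal(blocks$n_members, 3L)
  expect_equal(blocks$representative_pos, 5000L)
})

test_that("pruning is idempotent and ties break to the lower position", {
  set.seed(4)
  g <- rbinom(10, 2, 0.5)
  gl <- gl_from_genotypes(t(cbind(g, g)), depth = 400, error = 1e-3,
                          positions = c(2000L, 4000L))
  out <- ld_prune(gl)
  expect_equal(out$sites$pos, 2000L)  # equidistant from midpoint: lower
  # idempotence on a larger random panel
  f <- runif(40, 0.1, 0.5)
  geno <- sapply(1:10, function(i) rbinom(40, 2, f))
  gl2 <- gl_from_genotypes(geno, depth = 300, error = 1e-3)
  p1 <- ld_prune(gl2)
  p2 <- ld_prune(p1)
  expect_equal(p2$sites$pos, p1$sites$pos)
})

test_that("VCF-GL export reimports to the same triples", {
  set.seed(6)
  geno <- sapply(1:3, function(i) rbinom(10, 2, 0.4))
  gl <- gl_from_genotypes(geno, depth = 15)
  path <- tempfile(fileext = ".vcf")
  write_vcf_gl(gl, path)
  back <- suppressWarnings(vcf_to_gl(path, inds = gl$inds))
  expect_equal(back$sites$pos, gl$sites$pos)
  expect_equal(back$lik, gl$lik, tolerance = 1e-3)
  unlink(path)
})

test_that("SFS text files round trip", {
  sfs <- structure(list(n_chrom = 10L, counts = c(900, 40, 25, 15, 12, 8),
                        total = 1000, unfolded = NULL, loglik = NULL),
                   class = "folded_sfs")
  path <- tempfile(fileext = ".sfs")
  write_sfs(sfs, path)
  back <- read_sfs(path, n_chrom = 10)
  expect_equal(back$counts, sfs$counts)
  expect_error(read_sfs(path, n_chrom = 20), "classes")
  unlink(path)
})

test_that("block-copy linkage in the generator is caught by the pruner", {
  m <- build_population_model(list(
    colonies = tibble::tibble(name = "colA", cluster = "c1",
                              n_diploids = 8L, lat = 60, lon = 0),
    tree = tibble::tibble(node = "colA", parent = "root", f = 0),
    admixture = tibble::tibble(target = character(0),
                               source_a = character(0),
                               source_b = character(0),
                               alpha = numeric(0)),
    bottleneck = NULL, n_sites = 400L,
    chrom_lengths = c(chr1 = 4e5),  # dense sites: neighbors within range
    depth_range = c(60, 60), ld_rho = 0.5, seed = 31L))
  set.seed(31)
  fr <- draw_allele_frequencies(m)
  sgr <- sample_genotypes_and_reads(fr, m)
  gl <- filter_sites(sgr$gl, maf_min = 0.05)
  pruned <- ld_prune(gl, max_dist_bp = 5e3)
  blocks <- attr(pruned, "linked_blocks")
  expect_gt(nrow(blocks), 20)           # many duplicated-site blocks
  expect_lt(n_sites(pruned), n_sites(gl) * 0.8)
  expect_error(build_population_model(list(ld_rho = 1)), "ld_rho")
})

test_that("Beagle round trip preserves sites and likelihood triples", {
  set.seed(5)
  geno <- sapply(1:4, function(i) rbinom(15, 2, 0.3))
  gl <- gl_from_genotypes(geno, depth = 20, colony = rep("c1", 4))
  path <- tempfile(fileext = ".beagle")
  write_beagle(gl, path)
  back <- read_beagle(path, inds = gl$inds, chrom_lengths = NULL)
  expect_equal(back$sites$pos, gl$sites$pos)
  expect_equal(back$sites$chrom, gl$sites$chrom)
  expect_equal(back$inds$id, gl$inds$id)
  expect_equal(back$lik, gl$lik, tolerance = 1e-4)
  unlink(path)
})
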