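test_that("default model instantiates the 12-colony survey", {
  m <- build_population_model()
  expect_equal(nrow(m$colonies), 12L)
  expect_equal(sum(m$colonies$n_diploids), 72L)
  expect_equal(length(setdiff(unique(m$colonies$cluster), "admixed")), 4L)
  expect_equal(m$admixture$target, "bjornoya")
  expect_equal(m$bottleneck$colony, "spitsbergen")
})

test_that("model validation names the offending field", {
  expect_error(build_population_model(list(nonsense = 1)), "unknown")
  expect_error(build_population_model(list(
    admixture = tibble::tibble(target = "bjornoya",
                               source_a = "spitsbergen",
                               source_b = "hornoya", alpha = 1.2))),
    "alpha")
  expect_error(build_population_model(list(
    colonies = dplyr::mutate(glpop:::default_colonies(),
                             n_diploids = -1L))), "n_diploids")
  expect_error(build_population_model(list(
    chrom_lengths = c(chr1 = -5))), "chrom_lengths")
  # drift coefficient 1 is degenerate for the Beta drift model
  bad_tree <- glpop:::default_tree()
  bad_tree$f[1] <- 1
  expect_error(build_population_model(list(tree = bad_tree)), "drift")
  # cyclic tree
  cyc <- tibble::tibble(node = c("a", "b"), parent = c("b", "a"),
                        f = c(0.1, 0.1))
  expect_error(build_population_model(list(
    tree = cyc,
    colonies = tibble::tibble(name = "a", cluster = "x",
                              n_diploids = 2L, lat = 50, lon = 0),
    admixture = glpop:::model_defaults()$admixture[0, ],
    bottleneck = NULL)), "cyclic")
})

test_that("zero drift everywhere leaves ancestral frequencies intact", {
  tr <- glpop:::default_tree()
  tr$f <- 0
  m <- build_population_model(list(tree = tr, bottleneck = NULL,
                                   n_sites = 200L, seed = 3L))
  set.seed(3)
  fr <- draw_allele_frequencies(m)
  for (i in 2:nrow(fr)) expect_equal(fr[i, ], fr[1, ])
  expect_true(all(fr >= 0.05 & fr <= 0.95))
})

test_that("admixed colony frequencies are exactly the parent mixture", {
  m <- build_population_model(list(n_sites = 300L, seed = 4L))
  set.seed(4)
  fr <- draw_allele_frequencies(m)
  expect_equal(fr["bjornoya", ],
               0.5 * fr["spitsbergen", ] + 0.5 * fr["hornoya", ])
  # alpha = 0 makes the target identical to source B
  m0 <- build_population_model(list(
    n_sites = 300L, seed = 4L,
    admixture = tibble::tibble(target = "bjornoya",
                               source_a = "spitsbergen",
                               source_b = "hornoya", alpha = 0)))
  set.seed(4)
  fr0 <- draw_allele_frequencies(m0)
  expect_equal(fr0["bjornoya", ], fr0["hornoya", ])
})

test_that("stepping-stone drift grows with chain distance", {
  set.seed(6)
  m <- build_population_model(list(n_sites = 30000L, seed = 6L))
  fr <- draw_allele_frequencies(m)
  chain <- c("hornoya", "rost", "faroe", "papey", "westman", "breida",
             "grimsey")
  fst_from_first <- vapply(chain[-1], function(cn)
    hudson_fst(fr["hornoya", ], fr[cn, ])$fst, numeric(1))
  expect_gt(cor(fst_from_first, seq_along(fst_from_first),
                method = "spearman"), 0.8)
})

test_that("Balding-Nichols drift matches its expected F_ST", {
  # two colonies drifting F = 0.1 from a common ancestor: the Hudson
  # ratio-of-sums over true frequencies has expectation
  # E[alpha]/E[beta] = (F + F) E[p(1-p)] / (2 E[p(1-p)]) = F
  # (per-branch Beta drift has Var = F p(1-p); branches independent)
  set.seed(8)
  S <- 50000
  p0 <- glpop:::rbeta_truncated(S, 0.8, 0.8, c(0.05, 0.95))
  f <- 0.1
  pa <- glpop:::bn_step(p0, f)
  pb <- glpop:::bn_step(p0, f)
  est <- hudson_fst(pa, pb)$fst
  expect_equal(est, f, tolerance = 0.03)
})

test_that("genotype and read emission honor depth and ancestry", {
  m <- build_population_model(list(n_sites = 400L, seed = 5L))
  set.seed(5)
  fr <- draw_allele_frequencies(m)
  dg <- draw_genotypes(fr, m)
  expect_true(all(dg$genotypes %in% 0:2))
  expect_equal(unname(rowSums(dg$ancestry)), rep(1, 72))
  # ancestry truth: admixed colony is half arctic, half central
  bj <- dg$inds$colony == "bjornoya"
  expect_equal(unname(dg$ancestry[bj, "arctic"]), rep(0.5, 6))
  # extreme depth: argmax-GL genotype equals truth almost everywhere
  m2 <- build_population_model(list(n_sites = 400L, seed = 5L,
                                    depth_range = c(1000, 1000),
                                    error_rate = 0.001))
  rd <- reads_from_genotypes(dg$genotypes, m2)
  call <- apply(rd$lik, c(1, 2), which.max) - 1L
  expect_gt(mean(call == dg$genotypes), 0.999)
  # zero depth: everything missing (flat triples)
  rd0 <- reads_from_genotypes(dg$genotypes[, 1, drop = FALSE], m,
                              depths = 0)
  expect_true(all(rd0$lik == 1))
})

test_that("implanted tracts merge when they abut or overlap", {
  m <- build_population_model(list(n_sites = 500L, seed = 12L,
                                   chrom_lengths = c(chr1 = 1e6)))
  merged <- glpop:::merge_intervals(c(0, 2e5, 5e5), c(2e5, 3e5, 6e5))
  expect_equal(nrow(merged), 2L)
  expect_equal(merged[1, ], c(start = 0, end = 3e5))
  expect_error(
    implant_roh_tracts(matrix(0L, 5, 1),
                       tibble::tibble(chrom = "chr1", pos = 1:5),
                       matrix(0.5, 1, 5,
                              dimnames = list("spitsbergen", NULL)),
                       m, tibble::tibble(id = "x", colony = "spitsbergen"),
                       n_tracts = 1L, tract_length = 5e6),
    "longer")
})

test_that("the full dataset simulation is seed-deterministic", {
  m <- build_population_model(list(n_sites = 300L, seed = 99L))
  a <- simulate_dataset(m)
  b <- simulate_dataset(m)
  expect_identical(a$gl$lik, b$gl$lik)
  expect_identical(a$truth$genotypes, b$truth$genotypes)
  expect_identical(as.character(a$mito), as.character(b$mito))
  # a different seed changes the draw
  m2 <- build_population_model(list(n_sites = 300L, seed = 100L))
  c2 <- simulate_dataset(m2)
  expect_false(identical(a$gl$lik, c2$gl$lik))
})

test_that("panmictic model yields near-zero F_ST between any split", {
  tr <- glpop:::default_tree(); tr$f <- 0
  m <- build_population_model(list(tree = tr, bottleneck = NULL,
                                   n_sites = 2000L, seed = 13L))
  sim <- simulate_dataset(m)
  fr <- sim$truth$freqs
  expect_equal(hudson_fst(fr["hornoya", ], fr["gannet", ])$fst, 0,
               tolerance = 1e-12)
})
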