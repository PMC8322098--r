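aln_from_strings <- function(x, ids = NULL) {
  m <- do.call(rbind, strsplit(x, ""))
  rownames(m) <- if (is.null(ids)) paste0("s", seq_along(x)) else ids
  m
}

test_that("haplotype collapsing counts designed groups", {
  x <- c(rep("ACGTACGT", 5), rep("ACGTACGA", 3), rep("TCGTACGT", 2))
  hs <- collapse_haplotypes(aln_from_strings(x))
  expect_equal(hs$n_haplotypes, 3L)
  expect_equal(sort(hs$haplotypes$n, decreasing = TRUE), c(5L, 3L, 2L))
  # all identical -> 1; all distinct -> n with unit counts
  one <- collapse_haplotypes(aln_from_strings(rep("AAAA", 6)))
  expect_equal(one$n_haplotypes, 1L)
  all_diff <- collapse_haplotypes(aln_from_strings(
    c("AAAA", "AAAC", "AACA", "ACAA")))
  expect_equal(all_diff$n_haplotypes, 4L)
  expect_true(all(all_diff$haplotypes$n == 1L))
})

test_that("sequences differing only by missingness collapse together", {
  x <- c("ACGTACGT", "ACGTACGN", "ANGTACGT", "ACCTACGT")
  hs <- collapse_haplotypes(aln_from_strings(x))
  expect_equal(hs$n_haplotypes, 2L)
  # the complete variant represents the merged haplotype
  expect_true("s1" %in% hs$haplotypes$representative)
  expect_error(collapse_haplotypes(list(c("A", "C"), c("A", "C", "G"))),
               "length")
})

test_that("diversity statistics match hand counts on a toy alignment", {
  # 4 sequences, 10 bp; pairwise differences counted by hand:
  # s1-s2: 1, s1-s3: 2, s1-s4: 3, s2-s3: 1, s2-s4: 2, s3-s4: 1
  x <- c("AAAAAAAAAA", "AAAAAAAAAC", "AAAAAAAACC", "AAAAAAACCC")
  dv <- mito_diversity(aln_from_strings(x))
  expect_equal(dv$pi, mean(c(1, 2, 3, 1, 2, 1)) / 10)
  expect_equal(dv$segregating, 3L)
  expect_equal(dv$n_haplotypes, 4L)
  # all haplotypes unique: h = n/(n-1) * (1 - 1/n) = 1
  expect_equal(dv$h, 1)
  # single haplotype: h = 0, pi = 0, D undefined
  dv0 <- mito_diversity(aln_from_strings(rep("ACGT", 5)))
  expect_equal(dv0$h, 0)
  expect_equal(dv0$pi, 0)
  expect_true(is.na(dv0$tajima_d))
})

test_that("the substitution-model hook inflates saturated distances", {
  x <- c("AAAAAAAAAA", "AACCAACCAA")  # 4 of 10 differ
  m <- do.call(rbind, strsplit(x, ""))
  raw <- glpop:::pairwise_diff_matrix(m)
  jc <- glpop:::pairwise_diff_matrix(m, "jc69")
  expect_equal(raw[1, 2], 4)
  expect_equal(jc[1, 2], -0.75 * 10 * log(1 - 4 / 3 * 0.4),
               tolerance = 1e-12)
  expect_gt(jc[1, 2], raw[1, 2])
})

test_that("Phi_ST hits its landmarks", {
  set.seed(71)
  # identical composition in both groups: Phi ~ 0, not significant
  x <- rep(c("AAAA", "AAAC", "AACC"), 4)
  labs <- rep(c("g1", "g2"), each = 6)
  res <- pairwise_phist(aln_from_strings(x), labs, n_perm = 99, seed = 1)
  # identical composition: no positive among-group structure (the raw
  # moment estimate is negative for a deterministic duplicate design)
  expect_lt(res$phi_st["g1", "g2"], 0.05)
  expect_gt(res$p["g1", "g2"], 0.05)
  # groups fixed for different haplotypes: Phi = 1
  y <- c(rep("AAAA", 5), rep("CCCC", 5))
  labs2 <- rep(c("g1", "g2"), each = 5)
  res2 <- pairwise_phist(aln_from_strings(y), labs2, n_perm = 99,
                         seed = 1)
  expect_equal(unname(res2$phi_st["g1", "g2"]), 1, tolerance = 1e-12)
  expect_lt(res2$p["g1", "g2"], 0.05)
})

test_that("two-level variance components match a brute-force script", {
  set.seed(72)
  # toy 2 x 3 design: explicit sums-of-squares oracle with loops
  x <- c("AAAA", "AAAC", "AACC", "CCCA", "CCCC", "CCAA")
  labs <- rep(c("g1", "g2"), each = 3)
  m <- aln_from_strings(x)
  d <- glpop:::pairwise_diff_matrix(m)
  got <- glpop:::amova_two_level(d, labs)
  # oracle: direct Excoffier moment equations written independently
  n <- 6; sizes <- c(3, 3)
  ss_tot <- 0
  for (i in 1:5) for (j in (i + 1):6) ss_tot <- ss_tot + d[i, j]
  ss_tot <- ss_tot / n
  ss_w <- sum(d[1:3, 1:3][upper.tri(d[1:3, 1:3])]) / 3 +
    sum(d[4:6, 4:6][upper.tri(d[4:6, 4:6])]) / 3
  sigma_w <- ss_w / (n - 2)
  n0 <- (n - sum(sizes^2) / n) / 1
  sigma_a <- ((ss_tot - ss_w) / 1 - sigma_w) / n0
  expect_equal(got$sigma_a, sigma_a, tolerance = 1e-10)
  expect_equal(got$sigma_w, sigma_w, tolerance = 1e-10)
  expect_equal(got$phi_st, sigma_a / (sigma_a + sigma_w),
               tolerance = 1e-10)
})

test_that("hierarchical AMOVA components match an independent oracle", {
  set.seed(73)
  # 3 groups x 2 colonies x 3 individuals, random sequences
  bases <- c("A", "C", "G", "T")
  m <- matrix(sample(bases, 18 * 30, replace = TRUE), 18, 30)
  rownames(m) <- paste0("i", 1:18)
  colonies <- rep(paste0("col", 1:6), each = 3)
  groups <- rep(paste0("grp", 1:3), each = 6)
  res <- amova(m, colonies, groups, n_perm = 49, seed = 2)
  d <- glpop:::pairwise_diff_matrix(m)
  # independent oracle: explicit loops over the three strata
  n <- 18; P <- 6; G <- 3
  ss <- function(rows) {
    s <- 0
    rows <- sort(rows)
    for (a in seq_along(rows)[-length(rows)])
      for (b in seq(a + 1, length(rows)))
        s <- s + d[rows[a], rows[b]]
    s / length(rows)
  }
  ss_tot <- ss(1:18)
  ss_wp <- sum(vapply(unique(colonies),
                      function(p) ss(which(colonies == p)), numeric(1)))
  ss_g <- sum(vapply(unique(groups),
                     function(g) ss(which(groups == g)), numeric(1)))
  sigma_c <- ss_wp / (n - P)
  npg <- 3; ng <- 6
  n1 <- (n - sum(rep(npg^2 / ng, G) * 2)) / (P - G)
  n2 <- (G * 2 * npg^2 / ng - sum(rep(npg, P)^2) / n) / (G - 1)
  n3 <- (n - G * ng^2 / n) / (G - 1)
  sigma_b <- ((ss_g - ss_wp) / (P - G) - sigma_c) / n1
  sigma_a <- ((ss_tot - ss_g) / (G - 1) - sigma_c - n2 * sigma_b) / n3
  expect_equal(res$components$sigma,
               c(sigma_a, sigma_b, sigma_c), tolerance = 1e-10)
  expect_equal(unname(res$phi["phi_ct"]),
               sigma_a / (sigma_a + sigma_b + sigma_c),
               tolerance = 1e-10)
})

test_that("groups fixed for distinct haplotypes give Phi_CT = 1", {
  x <- c(rep("AAAAAA", 6), rep("CCCCCC", 6), rep("GGGGGG", 6))
  colonies <- rep(paste0("col", 1:6), each = 3)
  groups <- rep(paste0("grp", 1:3), each = 6)
  res <- amova(aln_from_strings(x), colonies, groups, n_perm = 49,
               seed = 1)
  expect_equal(unname(res$phi["phi_ct"]), 1, tolerance = 1e-12)
})

test_that("single-group AMOVA reduces to pairwise Phi_ST", {
  set.seed(74)
  x <- c(rep("AAAA", 3), rep("AACC", 2), "ACCC",
         rep("CCCC", 4), "CCCA", "AAAC")
  colonies <- rep(c("c1", "c2"), each = 6)
  res <- amova(aln_from_strings(x), colonies, n_perm = 99, seed = 5)
  ph <- pairwise_phist(aln_from_strings(x), colonies, n_perm = 99,
                       seed = 5)
  expect_equal(unname(res$phi["phi_st"]), ph$phi_st["c1", "c2"],
               tolerance = 1e-12)
})

test_that("expansion-model alignments look star-like", {
  model <- build_population_model(list(seed = 9L))
  set.seed(9)
  aln <- simulate_mito_alignment(model, mu_private = 3)
  hs <- collapse_haplotypes(aln)
  expect_gte(hs$n_haplotypes, 60)
  dv <- mito_diversity(aln)
  expect_lt(dv$tajima_d, 0)
  # mu = 0: everyone identical
  set.seed(9)
  aln0 <- simulate_mito_alignment(model, mu_private = 0)
  expect_equal(collapse_haplotypes(aln0)$n_haplotypes, 1L)
  # two-island mode: positive differentiation between groups
  set.seed(10)
  aln2 <- simulate_mito_alignment(model, mu_private = 1, mu_group = 5)
  grp <- rep(model$colonies$cluster, model$colonies$n_diploids)
  keep <- grp %in% c("arctic", "canada")
  m2 <- glpop:::alignment_matrix(aln2)[keep, ]
  res <- pairwise_phist(m2, grp[keep], n_perm = 49, seed = 2)
  expect_gt(res$phi_st["arctic", "canada"], 0)
})
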