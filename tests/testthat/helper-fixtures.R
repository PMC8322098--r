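# fixture builders shared across test files; everything is generated in
# code so the suite carries no data files

# gl_matrix with exact (near-certain) likelihoods from a genotype matrix:
# high depth makes the argmax genotype equal the true genotype
gl_from_genotypes <- function(geno, depth = 200, error = 0.001,
                              colony = NULL, chrom_lengths = NULL,
                              positions = NULL, chrom = NULL) {
  S <- nrow(geno); N <- ncol(geno)
  lik <- array(1, dim = c(S, N, 3))
  for (j in seq_len(N)) {
    p_minor <- (geno[, j] / 2) * (1 - error) + (1 - geno[, j] / 2) * error
    nmin <- rbinom(S, depth, p_minor)
    lik[, j, ] <- gl_from_counts(depth - nmin, nmin, error)
  }
  if (is.null(positions)) positions <- seq_len(S) * 1000L
  if (is.null(chrom)) chrom <- rep("chr1", S)
  if (is.null(colony)) colony <- rep("popA", N)
  gl_matrix(
    tibble::tibble(chrom = chrom, pos = positions, major = "A",
                   minor = "C"),
    tibble::tibble(id = sprintf("ind%02d", seq_len(N)), colony = colony),
    lik, chrom_lengths)
}

# two-population fixture with known allele frequencies
two_pop_gl <- function(fa, fb, n_per_pop = 6, depth = 30, error = 0.01,
                       seed = 1) {
  set.seed(seed)
  S <- length(fa)
  ga <- sapply(seq_len(n_per_pop), function(i) rbinom(S, 2, fa))
  gb <- sapply(seq_len(n_per_pop), function(i) rbinom(S, 2, fb))
  gl_from_genotypes(cbind(ga, gb), depth = depth, error = error,
                    colony = rep(c("popA", "popB"), each = n_per_pop))
}

# tiny geography on an arbitrary water matrix (row 1 = southmost)
toy_geography <- function(water, coords, cell_deg = 1, lat0 = 50,
                          lon0 = 0) {
  structure(list(
    coords = tibble::as_tibble(coords),
    lat = seq(lat0 + cell_deg / 2, by = cell_deg,
              length.out = nrow(water)),
    lon = seq(lon0 + cell_deg / 2, by = cell_deg,
              length.out = ncol(water)),
    water = water, cell_deg = cell_deg),
    class = "geography")
}

expect_tibble_names <- function(x, nms) {
  testthat::expect_true(all(nms %in% names(x)))
}
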