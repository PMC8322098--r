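default_colonies <- function() {
  tibble(
    name = c("spitsbergen", "bjornoya", "hornoya", "rost", "faroe",
             "papey", "westman", "breida", "grimsey", "iom",
             "gannet", "gull"),
    cluster = c("arctic", "admixed", rep("central", 7), "iom",
                "canada", "canada"),
    n_diploids = 6L,
    lat = c(78.2, 74.4, 70.4, 67.5, 62.0, 64.9, 63.4, 65.2, 66.5,
            56.2, 53.9, 47.3),
    lon = c(15.6, 19.0, 31.1, 12.1, -6.8, -14.2, -20.3, -24.5, -28.0,
            -2.6, -59.2, -52.8))
}

# the default drift topology: three isolated clusters plus a stepping-stone
# chain (backbone nodes step_1..step_7; each chain colony hangs off its
# backbone node as a zero-drift leaf), one admixed colony and one
# bottlenecked colony.  Per-step drift along the chain is proportional to
# the sea distance between adjacent colonies (a uniform per-km rate,
# total chain drift 0.012), so the within-cluster structure is genuine
# isolation by distance rather than isolation by step count.
default_tree <- function() {
  chain <- c("hornoya", "rost", "faroe", "papey", "westman", "breida",
             "grimsey")
  backbone <- paste0("step_", seq_along(chain))
  step_f <- c(0.00305, 0.00401, 0.00182, 0.00126, 0.00106, 0.0008)
  tibble(
    node   = c("central_anc", backbone, chain,
               "spitsbergen", "iom", "canada_anc", "gannet", "gull"),
    parent = c("root", "central_anc", head(backbone, -1), backbone,
               "root", "root", "root", "canada_anc", "canada_anc"),
    f      = c(0.02, 0.002, step_f, rep(0, length(chain)),
               0.15, 0.15, 0.075, 0.005, 0.005))
}

model_defaults <- function() {
  list(
    colonies = default_colonies(),
    tree = default_tree(),
    admixture = tibble(target = "bjornoya", source_a = "spitsbergen",
                       source_b = "hornoya", alpha = 0.5),
    bottleneck = list(colony = "spitsbergen", f_extra = 0.02,
                      n_tracts = 16L, tract_length = 5e5),
    n_sites = 15000L,
    chrom_lengths = setNames(rep(5e6, 10), paste0("chr", 1:10)),
    anc_beta = c(0.8, 0.8),
    anc_dist = "beta",
    anc_range = c(0.05, 0.95),
    depth_range = c(3, 10),
    error_rate = 0.01,
    missing_rate = 0,
    ld_rho = 0,
    seed = 42L)
}

#' Build a multi-colony population model
#'
#' The default instantiation emulates a 12-colony, 72-diploid seabird
#' survey with four divergent clusters: three isolated clusters, a central
#' stepping-stone chain of colonies, one admixed colony drawing half its
#' ancestry from the most divergent cluster, and one bottlenecked colony
#' carrying implanted runs of homozygosity.  Drift follows a rooted tree
#' with a Balding-Nichols coefficient per branch.
#'
#' @param config named list overriding any of: `colonies` (tibble `name`,
#'   `cluster`, `n_diploids`, `lat`, `lon`), `tree` (tibble `node`,
#'   `parent`, `f`), `admixture` (tibble `target`, `source_a`, `source_b`,
#'   `alpha`), `bottleneck` (list `colony`, `f_extra`, `n_tracts`,
#'   `tract_length`, or `NULL`), `n_sites`, `chrom_lengths`, `anc_beta`,
#'   `anc_dist` (`"beta"` or `"neutral"` for a 1/p standing spectrum),
#'   `anc_range`, `depth_range`, `error_rate`, `missing_rate`,
#'   `ld_rho` (block-copy linkage probability between adjacent sites,
#'   default 0: independent sites), `seed`.  Unknown keys are rejected.
#' @return validated object of class `pop_model`.
#' @export
build_population_model <- function(config = list()) {
  defaults <- model_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  model <- defaults
  for (k in names(config)) model[k] <- list(config[[k]])
  model$colonies <- as_tibble(model$colonies)
  model$tree <- as_tibble(model$tree)
  model$admixture <- as_tibble(model$admixture)
  validate_pop_model(structure(model, class = "pop_model"))
}

validate_pop_model <- function(model) {
  tr <- model$tree
  if (any(tr$f < 0 | tr$f >= 1))
    stopf("tree$f: all drift coefficients must lie in [0, 1)")
  if (anyDuplicated(tr$node)) stopf("tree$node: duplicated node names")
  # acyclicity + connectivity to root via topological order
  order <- topo_order(tr)
  admixed <- model$admixture$target
  plain <- setdiff(model$colonies$name, admixed)
  missing_leaf <- setdiff(plain, tr$node)
  if (length(missing_leaf))
    stopf("colonies: '%s' does not map to a tree node",
          missing_leaf[1])
  internal <- unique(tr$parent)
  bad_leaf <- intersect(plain, internal)
  if (length(bad_leaf))
    stopf("colonies: '%s' must map to a leaf, not an internal node",
          bad_leaf[1])
  if (nrow(model$admixture)) {
    a <- model$admixture
    if (any(a$alpha < 0 | a$alpha > 1))
      stopf("admixture$alpha: proportions must lie in [0, 1]")
    src <- c(a$source_a, a$source_b)
    bad <- setdiff(src, model$colonies$name)
    if (length(bad)) stopf("admixture: unknown source colony '%s'", bad[1])
  }
  if (any(model$colonies$n_diploids <= 0))
    stopf("colonies$n_diploids: sizes must be positive")
  if (any(model$chrom_lengths <= 0))
    stopf("chrom_lengths: lengths must be positive")
  check_number(model$error_rate, "error_rate", 0, 0.5,
               open_lower = TRUE, open_upper = TRUE)
  if (!model$anc_dist %in% c("beta", "neutral"))
    stopf("anc_dist: must be 'beta' or 'neutral'")
  if (model$ld_rho < 0 || model$ld_rho >= 1)
    stopf("ld_rho: must lie in [0, 1)")
  if (!is.null(model$bottleneck)) {
    b <- model$bottleneck
    if (!b$colony %in% model$colonies$name)
      stopf("bottleneck$colony: unknown colony '%s'", b$colony)
    check_number(b$f_extra, "bottleneck$f_extra", 0, 1, open_upper = TRUE)
    if (b$tract_length > max(model$chrom_lengths))
      stopf("bottleneck$tract_length: tract longer than every chromosome")
  }
  attr(model, "topo_order") <- order
  model
}

topo_order <- function(tree) {
  placed <- "root"
  remaining <- tree
  order <- character(0)
  while (nrow(remaining)) {
    ready <- remaining$parent %in% placed
    if (!any(ready))
      stopf("tree: cyclic or disconnected (nodes %s)",
            paste(remaining$node, collapse = ", "))
    order <- c(order, remaining$node[ready])
    placed <- c(placed, remaining$node[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  order
}

#' @export
print.pop_model <- function(x, ...) {
  cat(sprintf("<pop_model> %d colonies, %d diploids, %d clusters, %d sites\n",
              nrow(x$colonies), sum(x$colonies$n_diploids),
              length(unique(x$colonies$cluster)), x$n_sites))
  invisible(x)
}

rbeta_truncated <- function(n, shape1, shape2, range) {
  x <- rbeta(n, shape1, shape2)
  bad <- which(x < range[1] | x > range[2])
  while (length(bad)) {
    x[bad] <- rbeta(length(bad), shape1, shape2)
    bad <- bad[x[bad] < range[1] | x[bad] > range[2]]
  }
  x
}

# one Balding-Nichols drift step: child frequency given parent p and F
bn_step <- function(p, f) {
  if (f == 0) return(p)
  lambda <- (1 - f) / f
  rbeta(length(p), p * lambda, (1 - p) * lambda)
}

#' Draw per-colony allele frequencies down the drift tree
#'
#' Ancestral frequencies are symmetric-Beta distributed truncated to a
#' polymorphic range; each branch applies a Balding-Nichols Beta drift step
#' with its coefficient F.  Admixed colonies receive exactly
#' \eqn{\alpha f_A + (1-\alpha) f_B} of their parents' rows.  Uses the
#' current RNG state (seed once per pipeline, see [simulate_dataset()]).
#'
#' @param model a `pop_model`.
#' @return matrix colonies x sites with rownames the colony names.
#' @export
draw_allele_frequencies <- function(model) {
  S <- model$n_sites
  anc <- if (model$anc_dist == "neutral") {
    # frequency density proportional to 1/p on anc_range: the standing
    # neutral spectrum, used for diversity-statistic calibration
    a <- model$anc_range[1]; b <- model$anc_range[2]
    a * (b / a)^runif(S)
  } else {
    rbeta_truncated(S, model$anc_beta[1], model$anc_beta[2],
                    model$anc_range)
  }
  node_freq <- list(root = anc)
  tr <- model$tree
  for (nd in attr(validate_pop_model(model), "topo_order")) {
    row <- tr[tr$node == nd, ]
    node_freq[[nd]] <- bn_step(node_freq[[row$parent]], row$f)
  }
  cols <- model$colonies$name
  freq <- matrix(NA_real_, length(cols), S, dimnames = list(cols, NULL))
  for (cn in setdiff(cols, model$admixture$target))
    freq[cn, ] <- node_freq[[cn]]
  if (!is.null(model$bottleneck)) {
    b <- model$bottleneck
    if (!b$colony %in% model$admixture$target && b$f_extra > 0)
      freq[b$colony, ] <- bn_step(freq[b$colony, ], b$f_extra)
  }
  if (nrow(model$admixture))
    for (i in seq_len(nrow(model$admixture))) {
      a <- model$admixture[i, ]
      freq[a$target, ] <- a$alpha * freq[a$source_a, ] +
        (1 - a$alpha) * freq[a$source_b, ]
    }
  freq
}

# uniformly scatter the panel's sites over the genome, sorted, unique
draw_site_positions <- function(model) {
  cl <- model$chrom_lengths
  chrom <- sample(names(cl), model$n_sites, replace = TRUE,
                  prob = cl / sum(cl))
  pos <- floor(runif(model$n_sites, 1, cl[chrom] + 1))
  sites <- tibble(chrom = factor(chrom, levels = names(cl)), pos = pos) |>
    arrange(.data$chrom, .data$pos)
  dup <- duplicated(sites)
  while (any(dup)) {
    sites$pos[dup] <- sites$pos[dup] + 1L
    sites <- arrange(sites, .data$chrom, .data$pos)
    dup <- duplicated(sites)
  }
  mutate(sites, chrom = as.character(.data$chrom))
}

#' Draw true genotypes for every individual
#'
#' Unadmixed individuals draw both allele copies binomially from their
#' colony frequency; individuals of an admixed colony draw each copy from a
#' parent population chosen by their ancestry vector.
#'
#' @param freqs matrix from [draw_allele_frequencies()].
#' @param model a `pop_model`.
#' @return list: `genotypes` (sites x individuals, 0/1/2), `inds` tibble,
#'   `ancestry` (individuals x clusters true fractions).
#' @export
draw_genotypes <- function(freqs, model) {
  S <- model$n_sites
  cols <- model$colonies
  ids <- unlist(lapply(seq_len(nrow(cols)), function(i)
    sprintf("%s_%02d", cols$name[i], seq_len(cols$n_diploids[i]))))
  colony_of <- rep(cols$name, cols$n_diploids)
  N <- length(ids)
  g <- matrix(0L, S, N)
  clusters <- setdiff(unique(cols$cluster), "admixed")
  q_true <- matrix(0, N, length(clusters),
                   dimnames = list(ids, clusters))
  adm <- model$admixture
  for (j in seq_len(N)) {
    cn <- colony_of[j]
    ai <- match(cn, adm$target)
    if (!is.na(ai)) {
      a <- adm[ai, ]
      fa <- freqs[a$source_a, ]; fb <- freqs[a$source_b, ]
      from_a1 <- runif(S) < a$alpha
      from_a2 <- runif(S) < a$alpha
      copy1 <- rbinom(S, 1, ifelse(from_a1, fa, fb))
      copy2 <- rbinom(S, 1, ifelse(from_a2, fa, fb))
      g[, j] <- copy1 + copy2
      ca <- cols$cluster[cols$name == a$source_a]
      cb <- cols$cluster[cols$name == a$source_b]
      q_true[j, ca] <- q_true[j, ca] + a$alpha
      q_true[j, cb] <- q_true[j, cb] + 1 - a$alpha
    } else {
      g[, j] <- rbinom(S, 2, freqs[cn, ])
      q_true[j, cols$cluster[cols$name == cn]] <- 1
    }
  }
  if (model$ld_rho > 0 && S > 1) {
    # optional block-copy linkage: a site duplicates its predecessor's
    # genotype column with probability ld_rho (for exercising the pruner)
    copy <- which(runif(S - 1) < model$ld_rho) + 1L
    for (s in copy) g[s, ] <- g[s - 1L, ]
  }
  list(genotypes = g, inds = tibble(id = ids, colony = colony_of),
       ancestry = q_true)
}

#' Implant homozygous tracts (runs of homozygosity) into true genotypes
#'
#' Inside each tract the individual becomes homozygous at every site for a
#' single haplotype sampled from the colony frequencies.  Tracts are placed
#' uniformly (chromosome chosen proportional to length), and overlapping or
#' abutting tracts merge in the returned truth intervals.
#'
#' @param genotypes sites x individuals matrix from [draw_genotypes()].
#' @param sites tibble (`chrom`, `pos`) aligned with `genotypes` rows.
#' @param freqs colony frequency matrix.
#' @param model a `pop_model`.
#' @param colony colony receiving tracts; defaults to
#'   `model$bottleneck$colony`.
#' @param individuals character ids; defaults to all members of `colony`.
#' @param n_tracts,tract_length tract count and length (bp); default from
#'   `model$bottleneck`.
#' @param inds individual metadata tibble (`id`, `colony`).
#' @return list: `genotypes` (modified) and `roh_truth` tibble
#'   (`individual`, `chrom`, `start`, `end`) of merged implanted intervals.
#' @export
implant_roh_tracts <- function(genotypes, sites, freqs, model, inds,
                               colony = model$bottleneck$colony,
                               individuals = NULL,
                               n_tracts = model$bottleneck$n_tracts,
                               tract_length = model$bottleneck$tract_length) {
  cl <- model$chrom_lengths
  if (tract_length > max(cl)) stopf("tract longer than every chromosome")
  if (is.null(individuals))
    individuals <- inds$id[inds$colony == colony]
  truth <- list()
  for (id in individuals) {
    j <- match(id, inds$id)
    ok_chrom <- names(cl)[cl >= tract_length]
    tchrom <- sample(ok_chrom, n_tracts, replace = TRUE,
                     prob = cl[ok_chrom] / sum(cl[ok_chrom]))
    tstart <- floor(runif(n_tracts, 0, cl[tchrom] - tract_length + 1))
    for (t in seq_len(n_tracts)) {
      sel <- which(sites$chrom == tchrom[t] & sites$pos > tstart[t] &
                     sites$pos <= tstart[t] + tract_length)
      if (length(sel)) {
        hap <- rbinom(length(sel), 1, freqs[colony, sel])
        genotypes[sel, j] <- 2L * hap
      }
    }
    for (ch in unique(tchrom)) {
      m <- merge_intervals(tstart[tchrom == ch],
                           tstart[tchrom == ch] + tract_length)
      truth[[length(truth) + 1L]] <-
        tibble(individual = id, chrom = ch,
               start = m[, "start"], end = m[, "end"])
    }
  }
  list(genotypes = genotypes, roh_truth = bind_rows(truth))
}

#' Emit read counts and genotype likelihoods from true genotypes
#'
#' Per-individual mean depth is uniform over `model$depth_range`; site read
#' counts are Poisson; minor-allele reads are binomial with the
#' error-perturbed genotype probability; triples come from
#' [gl_from_counts()].  A `missing_rate` fraction of entries is zeroed out
#' (flat triples).
#'
#' @param genotypes sites x individuals 0/1/2 matrix.
#' @param model a `pop_model`.
#' @param depths optional per-individual mean depths (recycled).
#' @return list: `lik` array (sites x individuals x 3), `depths`.
#' @export
reads_from_genotypes <- function(genotypes, model, depths = NULL) {
  S <- nrow(genotypes); N <- ncol(genotypes)
  if (is.null(depths))
    depths <- runif(N, model$depth_range[1], model$depth_range[2])
  if (any(depths < 0)) stopf("depth must be >= 0")
  eps <- model$error_rate
  lik <- array(1, dim = c(S, N, 3))
  for (j in seq_len(N)) {
    nreads <- rpois(S, depths[j])
    if (model$missing_rate > 0)
      nreads[runif(S) < model$missing_rate] <- 0L
    p_minor <- (genotypes[, j] / 2) * (1 - eps) +
      (1 - genotypes[, j] / 2) * eps
    nmin <- rbinom(S, nreads, p_minor)
    lik[, j, ] <- gl_from_counts(nreads - nmin, nmin, eps)
  }
  list(lik = lik, depths = depths)
}

#' Draw genotypes and emit genotype likelihoods in one call
#'
#' @inheritParams draw_genotypes
#' @param sites optional site table; drawn uniformly when absent.
#' @return list: `gl` (a `gl_matrix`) and `truth` (genotypes, ancestry,
#'   depths, freqs).
#' @export
sample_genotypes_and_reads <- function(freqs, model, sites = NULL) {
  if (is.null(sites)) sites <- draw_site_positions(model)
  dg <- draw_genotypes(freqs, model)
  rd <- reads_from_genotypes(dg$genotypes, model)
  gl <- gl_matrix(mutate(sites, major = "A", minor = "C"), dg$inds, rd$lik,
                  model$chrom_lengths)
  list(gl = gl,
       truth = list(genotypes = dg$genotypes, ancestry = dg$ancestry,
                    depths = rd$depths, freqs = freqs))
}

#' Simulate a mitochondrial haplotype alignment
#'
#' Star-like genealogy emulating a recent population expansion: every
#' individual carries private Poisson-distributed mutations on an otherwise
#' shared ancestral sequence, producing an excess of rare variants
#' (negative Tajima's D) and nearly as many distinct haplotypes as
#' individuals when the mutation intensity is high.  Optional group-level
#' branch mutations (`mu_group > 0`) create island-model structure with
#' positive Phi_ST.
#'
#' @param model a `pop_model`.
#' @param seq_length alignment length in bp (default 2500).
#' @param mu_private expected private mutations per individual (default 3).
#' @param mu_group expected shared mutations per group branch (default 0).
#' @param group_by colony column used for group branches: `"colony"` or
#'   `"cluster"` (default).
#' @return `ape::DNAbin` matrix, one row per individual.
#' @export
simulate_mito_alignment <- function(model, seq_length = 2500,
                                    mu_private = 3, mu_group = 0,
                                    group_by = "cluster") {
  if (seq_length <= 0) stopf("seq_length must be positive")
  bases <- c("a", "c", "g", "t")
  anc <- sample(bases, seq_length, replace = TRUE)
  cols <- model$colonies
  ids <- unlist(lapply(seq_len(nrow(cols)), function(i)
    sprintf("%s_%02d", cols$name[i], seq_len(cols$n_diploids[i]))))
  grp <- rep(cols[[group_by]], cols$n_diploids)
  aln <- matrix(rep(anc, length(ids)), nrow = length(ids), byrow = TRUE,
                dimnames = list(ids, NULL))
  mutate_seq <- function(seq, k) {
    if (k == 0) return(seq)
    at <- sample.int(length(seq), min(k, length(seq)))
    seq[at] <- vapply(seq[at],
                      function(b) sample(setdiff(bases, b), 1), "")
    seq
  }
  if (mu_group > 0) {
    for (g in unique(grp)) {
      gseq <- mutate_seq(anc, rpois(1, mu_group))
      aln[grp == g, ] <- matrix(rep(gseq, sum(grp == g)),
                                nrow = sum(grp == g), byrow = TRUE)
    }
  }
  for (i in seq_along(ids))
    aln[i, ] <- mutate_seq(aln[i, ], rpois(1, mu_private))
  ape::as.DNAbin(aln)
}

#' Simulate the complete multi-colony dataset
#'
#' Runs the whole generator under a single seed: allele frequencies down
#' the drift tree, true genotypes, implanted RoH tracts in the bottlenecked
#' colony, read emission to genotype likelihoods, a mitochondrial
#' alignment, and the water-mask geography.  Identical model (including
#' seed) gives identical output.
#'
#' @param model a `pop_model` from [build_population_model()].
#' @return list: `gl`, `truth` (freqs, genotypes, ancestry, roh, depths,
#'   expected pairwise F_ST), `mito`, `geography`, `model`.
#' @export
simulate_dataset <- function(model) {
  set.seed(model$seed)
  freqs <- draw_allele_frequencies(model)
  sites <- draw_site_positions(model)
  dg <- draw_genotypes(freqs, model)
  roh_truth <- tibble(individual = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0))
  if (!is.null(model$bottleneck) && model$bottleneck$n_tracts > 0) {
    imp <- implant_roh_tracts(dg$genotypes, sites, freqs, model, dg$inds)
    dg$genotypes <- imp$genotypes
    roh_truth <- imp$roh_truth
  }
  rd <- reads_from_genotypes(dg$genotypes, model)
  gl <- gl_matrix(mutate(sites, major = "A", minor = "C"), dg$inds, rd$lik,
                  model$chrom_lengths)
  mito <- simulate_mito_alignment(model)
  geo <- make_geography(model)
  list(gl = gl,
       truth = list(freqs = freqs, genotypes = dg$genotypes,
                    ancestry = dg$ancestry, roh = roh_truth,
                    depths = rd$depths,
                    expected_fst = true_fst_matrix(freqs)),
       mito = mito, geography = geo, model = model)
}

# Hudson ratio-of-sums F_ST between all colony pairs from true population
# frequencies (no sampling correction: these are parameters, not samples)
true_fst_matrix <- function(freqs) {
  cn <- rownames(freqs)
  k <- length(cn)
  out <- matrix(0, k, k, dimnames = list(cn, cn))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    p <- freqs[i, ]; q <- freqs[j, ]
    a <- sum((p - q)^2)
    b <- sum(p * (1 - q) + q * (1 - p))
    out[i, j] <- out[j, i] <- if (b > 0) a / b else 0
  }
  out
}
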