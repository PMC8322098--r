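# alignment input: ape::DNAbin matrix or character matrix -> upper-case
# character matrix with non-ACGT (IUPAC ambiguity, gaps, N) as NA
alignment_matrix <- function(aln) {
  if (inherits(aln, "DNAbin")) aln <- as.character(as.matrix(aln))
  if (is.list(aln)) {
    if (length(unique(lengths(aln))) != 1L)
      stopf("sequences differ in length")
    aln <- do.call(rbind, aln)
  }
  m <- toupper(as.matrix(aln))
  m[!m %in% c("A", "C", "G", "T")] <- NA_character_
  m
}

# pairwise count of differing called positions; correction = "jc69"
# applies the Jukes-Cantor distance (scaled back to expected differences
# over the compared length) as the configurable substitution-model hook
pairwise_diff_matrix <- function(m, correction = c("none", "jc69")) {
  correction <- match.arg(correction)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    nd <- sum(m[i, ok] != m[j, ok])
    if (correction == "jc69" && sum(ok) > 0) {
      p <- min(nd / sum(ok), 0.749)
      nd <- -0.75 * sum(ok) * log1p(-4 * p / 3)
    }
    d[i, j] <- d[j, i] <- nd
  }
  d
}

#' Collapse aligned sequences into haplotypes
#'
#' Two sequences belong to the same haplotype when they agree at every
#' column where both are called; sequences differing only by missingness
#' collapse together, with the haplotype represented by its most complete
#' member (sequences are processed in order of decreasing completeness).
#' IUPAC ambiguity codes count as missing.
#'
#' @param aln `ape::DNAbin` matrix or character matrix, equal-length rows.
#' @param colonies character vector of colony labels per sequence (named
#'   by sequence, or in row order).
#' @return object of class `haplotype_set`: `haplotypes` tibble
#'   (`haplotype`, `representative`, `n`), `assignment` tibble
#'   (`individual`, `colony`, `haplotype`), `counts` (haplotype x colony
#'   matrix), `n_haplotypes`.
#' @export
collapse_haplotypes <- function(aln, colonies = NULL) {
  m <- alignment_matrix(aln)
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  if (is.null(colonies)) colonies <- rep("all", nrow(m))
  if (!is.null(names(colonies))) colonies <- colonies[rownames(m)]
  if (length(colonies) != nrow(m))
    stopf("need one colony label per sequence")
  ord <- order(-rowSums(!is.na(m)))
  rep_idx <- integer(0)           # representative row per haplotype
  hap_of <- integer(nrow(m))
  for (i in ord) {
    assigned <- FALSE
    for (h in seq_along(rep_idx)) {
      r <- rep_idx[h]
      ok <- !is.na(m[i, ]) & !is.na(m[r, ])
      if (all(m[i, ok] == m[r, ok])) {
        hap_of[i] <- h
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_idx <- c(rep_idx, i)
      hap_of[i] <- length(rep_idx)
    }
  }
  counts <- table(factor(hap_of, levels = seq_along(rep_idx)),
                  factor(colonies, levels = unique(colonies)))
  counts <- matrix(counts, nrow = length(rep_idx),
                   dimnames = list(paste0("H", seq_along(rep_idx)),
                                   unique(colonies)))
  structure(list(
    haplotypes = tibble(haplotype = paste0("H", seq_along(rep_idx)),
                        representative = rownames(m)[rep_idx],
                        n = as.integer(rowSums(counts))),
    assignment = tibble(individual = rownames(m), colony = colonies,
                        haplotype = paste0("H", hap_of)),
    counts = counts, n_haplotypes = length(rep_idx)),
    class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes over %d sequences\n",
              x$n_haplotypes, nrow(x$assignment)))
  invisible(x)
}

#' Haplotype diversity, nucleotide diversity and Tajima's D per group
#'
#' \eqn{h = \frac{n}{n-1}(1 - \sum_i p_i^2)} from haplotype frequencies;
#' \eqn{\pi} = mean pairwise difference per site; Tajima's D from the
#' number of segregating sites and the mean pairwise differences with the
#' 1989 variance constants.
#'
#' @param aln alignment (`DNAbin` or character matrix).
#' @param groups group label per sequence (default: one global group).
#' @return tibble per group (plus `"global"`): `n`, `n_haplotypes`, `h`,
#'   `pi`, `segregating`, `tajima_d`.
#' @export
mito_diversity <- function(aln, groups = NULL) {
  m <- alignment_matrix(aln)
  if (is.null(groups)) groups <- rep("global", nrow(m))
  one_group <- function(rows, label) {
    n <- length(rows)
    if (n < 2) stopf("group '%s' has fewer than 2 sequences", label)
    mm <- m[rows, , drop = FALSE]
    hs <- collapse_haplotypes(mm)
    p <- hs$haplotypes$n / n
    h <- n / (n - 1) * (1 - sum(p^2))
    d <- pairwise_diff_matrix(mm)
    pi_total <- mean(d[lower.tri(d)])
    called <- colSums(!is.na(mm)) >= 2
    seg <- sum(vapply(which(called), function(j)
      length(unique(na.omit(mm[, j]))) > 1, logical(1)))
    tibble(group = label, n = n, n_haplotypes = hs$n_haplotypes, h = h,
           pi = pi_total / ncol(mm), segregating = seg,
           tajima_d = if (n >= 4) tajima_d(pi_total, seg, n) else NA_real_)
  }
  out <- bind_rows(lapply(unique(groups), function(g)
    one_group(which(groups == g), g)))
  if (length(unique(groups)) > 1)
    out <- bind_rows(out, one_group(seq_len(nrow(m)), "global"))
  out
}

# two-level AMOVA variance components from a pairwise squared-distance
# matrix and a group factor; returns sigma_among, sigma_within, phi_st
amova_two_level <- function(d, groups) {
  n <- nrow(d)
  glev <- unique(groups)
  ss_total <- sum(d[lower.tri(d)]) / n
  ss_within <- 0
  for (g in glev) {
    rows <- which(groups == g)
    dg <- d[rows, rows, drop = FALSE]
    ss_within <- ss_within + sum(dg[lower.tri(dg)]) / length(rows)
  }
  ss_among <- ss_total - ss_within
  df_a <- length(glev) - 1
  df_w <- n - length(glev)
  sigma_w <- ss_within / df_w
  n0 <- (n - sum(table(groups)^2) / n) / df_a
  sigma_a <- (ss_among / df_a - sigma_w) / n0
  phi <- if (sigma_a + sigma_w > 0) sigma_a / (sigma_a + sigma_w)
         else NA_real_
  list(sigma_a = sigma_a, sigma_w = sigma_w, phi_st = phi)
}

#' Pairwise Phi_ST between populations with permutation p-values
#'
#' Two-level AMOVA on the pairwise sequence-difference matrix for each
#' pair of populations; \eqn{\Phi_{ST} = \sigma^2_a / (\sigma^2_a +
#' \sigma^2_w)}, significance by permuting individuals between the two
#' groups.
#'
#' @param aln alignment (`DNAbin` or character matrix).
#' @param labels population label per sequence.
#' @param n_perm permutations (default 999).
#' @param seed optional RNG seed.
#' @param correction distance model: `"none"` (plain differences,
#'   default) or `"jc69"`.
#' @return list of labelled matrices `phi_st` and `p` (`NA` diagonal).
#' @export
pairwise_phist <- function(aln, labels, n_perm = 999, seed = NULL,
                           correction = "none") {
  m <- alignment_matrix(aln)
  if (!is.null(seed)) set.seed(seed)
  d <- pairwise_diff_matrix(m, correction)
  pops <- unique(labels)
  k <- length(pops)
  phi <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pval <- phi
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    rows <- which(labels %in% pops[c(i, j)])
    if (sum(labels == pops[i]) < 2 || sum(labels == pops[j]) < 2)
      stopf("each population needs >= 2 sequences")
    dd <- d[rows, rows]
    grp <- labels[rows]
    obs <- amova_two_level(dd, grp)
    phi[i, j] <- phi[j, i] <- obs$phi_st
    if (is.na(obs$phi_st)) next
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      pphi <- amova_two_level(dd, sample(grp))$phi_st
      if (!is.na(pphi) && pphi >= obs$phi_st) cnt <- cnt + 1L
    }
    pval[i, j] <- pval[j, i] <- (cnt + 1) / (n_perm + 1)
  }
  list(phi_st = phi, p = pval)
}

# three-level sums of squares and variance components (Excoffier-style
# moment equations, unbalanced designs supported)
amova_components <- function(d, colonies, groups) {
  n <- nrow(d)
  pops <- unique(colonies)
  glev <- unique(groups)
  group_of_pop <- vapply(pops, function(p)
    unique(groups[colonies == p])[1], "")
  ss_total <- sum(d[lower.tri(d)]) / n
  ss_wp <- 0
  for (p in pops) {
    rows <- which(colonies == p)
    dp <- d[rows, rows, drop = FALSE]
    ss_wp <- ss_wp + sum(dp[lower.tri(dp)]) / length(rows)
  }
  ss_group_tot <- 0
  for (g in glev) {
    rows <- which(groups == g)
    dg <- d[rows, rows, drop = FALSE]
    ss_group_tot <- ss_group_tot + sum(dg[lower.tri(dg)]) / length(rows)
  }
  ss_ap <- ss_group_tot - ss_wp      # among colonies within groups
  ss_ag <- ss_total - ss_group_tot   # among groups
  P <- length(pops); G <- length(glev)
  df_ag <- G - 1; df_ap <- P - G; df_wp <- n - P
  n_p <- table(factor(colonies, levels = pops))
  n_g <- table(factor(groups, levels = glev))
  sigma_c <- ss_wp / df_wp
  # moment coefficients (standard unbalanced-design forms)
  sum_np2_over_ng <- sum(vapply(glev, function(g) {
    pg <- pops[group_of_pop == g]
    sum(n_p[pg]^2) / n_g[[g]]
  }, numeric(1)))
  n_prime <- (n - sum_np2_over_ng) / df_ap
  n_dprime <- (sum_np2_over_ng - sum(n_p^2) / n) / df_ag
  n_tprime <- (n - sum(n_g^2) / n) / df_ag
  sigma_b <- if (df_ap > 0) (ss_ap / df_ap - sigma_c) / n_prime else 0
  sigma_a <- if (df_ag > 0)
    (ss_ag / df_ag - sigma_c - n_dprime * sigma_b) / n_tprime else 0
  list(ss = c(among_groups = ss_ag, among_colonies = ss_ap,
              within_colonies = ss_wp),
       df = c(df_ag, df_ap, df_wp),
       sigma = c(among_groups = sigma_a, among_colonies = sigma_b,
                 within_colonies = sigma_c))
}

#' Hierarchical AMOVA with permutation tests
#'
#' Partitions sequence variation among groups, among colonies within
#' groups, and within colonies, from the squared pairwise-difference
#' matrix; variance components by moment equations (reported raw, possibly
#' negative).  \eqn{\Phi_{CT}}: permute colonies among groups;
#' \eqn{\Phi_{SC}}: permute individuals among colonies within groups;
#' \eqn{\Phi_{ST}}: permute individuals among all colonies.  With a single
#' group the analysis reduces to two levels and only \eqn{\Phi_{ST}} is
#' reported.
#'
#' @param aln alignment (`DNAbin` or character matrix) or a precomputed
#'   squared-distance matrix.
#' @param colonies colony label per sequence.
#' @param groups group label per colony membership (per sequence).
#' @param n_perm permutations (default 999).
#' @param seed optional RNG seed.
#' @param correction distance model, as in [pairwise_phist()].
#' @return object of class `amova_result`: `components` tibble (level,
#'   df, ss, sigma), `phi` named vector (`phi_ct`, `phi_sc`, `phi_st`),
#'   `p` named vector of permutation p-values.
#' @export
amova <- function(aln, colonies, groups = NULL, n_perm = 999,
                  seed = NULL, correction = "none") {
  d <- if (is.matrix(aln) && is.numeric(aln)) aln else
    pairwise_diff_matrix(alignment_matrix(aln), correction)
  if (!is.null(seed)) set.seed(seed)
  if (length(unique(colonies)) < 2) stopf("need at least 2 colonies")
  if (is.null(groups)) groups <- rep("all", length(colonies))
  if (length(unique(groups)) == 1) {
    obs <- amova_two_level(d, colonies)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      pp <- amova_two_level(d, sample(colonies))$phi_st
      if (!is.na(pp) && pp >= obs$phi_st) cnt <- cnt + 1L
    }
    return(structure(list(
      components = tibble(
        level = c("among_colonies", "within_colonies"),
        df = c(length(unique(colonies)) - 1,
               nrow(d) - length(unique(colonies))),
        sigma = c(obs$sigma_a, obs$sigma_w)),
      phi = c(phi_st = obs$phi_st),
      p = c(phi_st = (cnt + 1) / (n_perm + 1))),
      class = "amova_result"))
  }
  obs <- amova_components(d, colonies, groups)
  tot <- sum(obs$sigma)
  phi <- c(phi_ct = obs$sigma[[1]] / tot,
           phi_sc = obs$sigma[[2]] / (obs$sigma[[2]] + obs$sigma[[3]]),
           phi_st = (obs$sigma[[1]] + obs$sigma[[2]]) / tot)
  pops <- unique(colonies)
  group_of_pop <- vapply(pops, function(p)
    unique(groups[colonies == p])[1], "")
  cnt <- c(phi_ct = 0L, phi_sc = 0L, phi_st = 0L)
  for (b in seq_len(n_perm)) {
    # phi_ct: permute whole colonies among groups
    gp <- setNames(sample(group_of_pop), pops)
    c_ct <- amova_components(d, colonies, unname(gp[colonies]))
    t1 <- sum(c_ct$sigma)
    if (isTRUE(c_ct$sigma[[1]] / t1 >= phi[["phi_ct"]]))
      cnt[["phi_ct"]] <- cnt[["phi_ct"]] + 1L
    # phi_sc: permute individuals among colonies within their group
    col_sc <- colonies
    for (g in unique(groups)) {
      rows <- which(groups == g)
      col_sc[rows] <- sample(colonies[rows])
    }
    c_sc <- amova_components(d, col_sc, groups)
    if (isTRUE(c_sc$sigma[[2]] / (c_sc$sigma[[2]] + c_sc$sigma[[3]]) >=
               phi[["phi_sc"]]))
      cnt[["phi_sc"]] <- cnt[["phi_sc"]] + 1L
    # phi_st: permute individuals among all colonies
    perm <- sample(length(colonies))
    c_st <- amova_components(d, colonies[perm], groups[perm])
    t3 <- sum(c_st$sigma)
    if (isTRUE((c_st$sigma[[1]] + c_st$sigma[[2]]) / t3 >=
               phi[["phi_st"]]))
      cnt[["phi_st"]] <- cnt[["phi_st"]] + 1L
  }
  structure(list(
    components = tibble(
      level = c("among_groups", "among_colonies", "within_colonies"),
      df = obs$df, ss = unname(obs$ss), sigma = unname(obs$sigma)),
    phi = phi, p = (cnt + 1) / (n_perm + 1)),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  print(x$components)
  cat("Phi:", paste(sprintf("%s = %.4f", names(x$phi), x$phi),
                    collapse = ", "), "\n")
  cat("p:  ", paste(sprintf("%s = %.4g", names(x$p), x$p),
                    collapse = ", "), "\n")
  invisible(x)
}
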