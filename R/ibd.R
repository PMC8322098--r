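check_dist_pair <- function(d1, d2) {
  if (!identical(rownames(d1), rownames(d2)))
    stopf("distance matrices must share labels in the same order")
  if (!isSymmetric(unname(d1)) || !isSymmetric(unname(d2)))
    stopf("distance matrices must be symmetric")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles; significance by jointly
#' permuting the rows and columns of the second matrix.  One-tailed
#' (positive association): \eqn{p = (\#\{r_{perm} \ge r_{obs}\} + 1) /
#' (n_{perm} + 1)}.
#'
#' @param d1,d2 square symmetric matrices with identical labels.
#' @param n_perm number of permutations (default 999).
#' @param seed optional RNG seed for reproducible permutations.
#' @return object of class `mantel_result`: list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  check_dist_pair(d1, d2)
  if (!is.null(seed)) set.seed(seed)
  v1 <- lower_tri(d1); v2 <- lower_tri(d2)
  if (sd(v1) == 0 || sd(v2) == 0)
    stopf("constant distance matrix: correlation undefined")
  r <- cor(v1, v2)
  n <- nrow(d1)
  count <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    rp <- cor(v1, lower_tri(d2[p, p]))
    if (rp >= r) count <- count + 1L
  }
  structure(list(r = r, p = (count + 1) / (n_perm + 1), n_perm = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, one-tailed p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}

#' Multiple regression on distance matrices (MRM)
#'
#' Ordinary least squares on the vectorized lower triangles; coefficient
#' significance by permuting the labels of the response matrix (two-tailed
#' on |coefficient|, one-tailed for R-squared).
#'
#' @param response square symmetric response matrix.
#' @param predictors named list of predictor matrices (same labels).
#' @param n_perm permutations (default 999); 0 skips the permutation test.
#' @param seed optional RNG seed.
#' @param log_predictors take the natural log of the predictor distances
#'   (default `FALSE`: untransformed).
#' @return object of class `mrm_result`: coefficient tibble (`term`,
#'   `estimate`, `p_value`), `r_squared`, `r_squared_p`.
#' @export
mrm <- function(response, predictors, n_perm = 999, seed = NULL,
                log_predictors = FALSE) {
  if (!length(predictors)) stopf("need at least one predictor")
  for (p in predictors) check_dist_pair(response, p)
  if (!is.null(seed)) set.seed(seed)
  y <- lower_tri(response)
  xfun <- if (log_predictors) function(m) log(lower_tri(m)) else lower_tri
  X <- cbind(`(Intercept)` = 1,
             vapply(predictors, xfun, numeric(length(y))))
  if (kappa(X, exact = TRUE) > 1e10)
    stopf("collinear predictors (condition number > 1e10)")
  fit_b <- function(yy) qr.solve(X, yy)
  b <- fit_b(y)
  yhat <- X %*% b
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  p_coef <- rep(NA_real_, length(b)); p_r2 <- NA_real_
  if (n_perm > 0) {
    n <- nrow(response)
    cnt <- rep(0L, length(b)); cnt_r2 <- 0L
    for (bb in seq_len(n_perm)) {
      pm <- sample.int(n)
      yp <- lower_tri(response[pm, pm])
      bp <- fit_b(yp)
      r2p <- 1 - sum((yp - X %*% bp)^2) / sum((yp - mean(yp))^2)
      cnt <- cnt + (abs(bp) >= abs(b))
      if (r2p >= r2) cnt_r2 <- cnt_r2 + 1L
    }
    p_coef <- (cnt + 1) / (n_perm + 1)
    p_r2 <- (cnt_r2 + 1) / (n_perm + 1)
  }
  structure(list(
    coefficients = tibble(term = names(b), estimate = unname(b),
                          p_value = unname(p_coef)),
    r_squared = r2, r_squared_p = p_r2, n_perm = n_perm),
    class = "mrm_result")
}

#' @export
print.mrm_result <- function(x, ...) {
  cat(sprintf("MRM: R-squared = %.4f (p = %.4g)\n",
              x$r_squared, x$r_squared_p))
  print(x$coefficients)
  invisible(x)
}

#' Greedy colony removal maximizing isolation-by-distance fit
#'
#' Repeatedly refits the regression of genetic on geographic distance
#' without each remaining colony and removes the colony whose removal
#' yields the largest gain in R-squared, stopping after `max_removals`
#' removals, when the best gain drops below `min_gain`, or when fewer than
#' five colonies would remain.
#'
#' @param genetic square matrix of linearized genetic distances (e.g.
#'   Slatkin \eqn{F_{ST}/(1-F_{ST})}).
#' @param geographic square matrix of geographic distances (same labels).
#' @param max_removals cap on removals (default 4).
#' @param min_gain minimum R-squared improvement to keep going
#'   (default 0.01).
#' @return object of class `removal_trajectory`: tibble (`step`,
#'   `removed`, `r_squared`) starting at step 0 (nothing removed), plus the
#'   stopping reason.
#' @export
progressive_removal <- function(genetic, geographic, max_removals = 4,
                                min_gain = 0.01) {
  check_dist_pair(genetic, geographic)
  labels <- rownames(genetic)
  if (length(labels) < 5) stopf("need at least 5 colonies")
  fit_r2 <- function(keep) {
    mrm(genetic[keep, keep], list(geo = geographic[keep, keep]),
        n_perm = 0)$r_squared
  }
  keep <- labels
  steps <- tibble(step = 0L, removed = NA_character_,
                  r_squared = fit_r2(keep))
  reason <- "max_removals"
  for (s in seq_len(max_removals)) {
    if (length(keep) - 1 < 5) { reason <- "min_colonies"; break }
    gains <- vapply(keep, function(cn) fit_r2(setdiff(keep, cn)),
                    numeric(1))
    best <- names(gains)[which.max(gains)]
    if (max(gains) - steps$r_squared[nrow(steps)] < min_gain) {
      reason <- "no_gain"; break
    }
    keep <- setdiff(keep, best)
    steps <- bind_rows(steps, tibble(step = s, removed = best,
                                     r_squared = max(gains)))
  }
  structure(list(trajectory = steps, kept = keep,
                 stopping_reason = reason),
            class = "removal_trajectory")
}

#' @export
print.removal_trajectory <- function(x, ...) {
  print(x$trajectory)
  cat("stopped:", x$stopping_reason, "\n")
  invisible(x)
}
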