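# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be a single number", name)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stopf("`%s` = %g is outside %s%g, %g%s", name, x,
          if (open_lower) "(" else "[", lower, upper,
          if (open_upper) ")" else "]")
  invisible(x)
}

# lower-triangle vectorization used by all distance-matrix machinery;
# column-major order so that it is reproducible across functions
lower_tri <- function(m) m[lower.tri(m)]

# Watterson / Tajima constants for n sampled chromosomes (haploid count)
tajima_constants <- function(n) {
  stopifnot(n >= 4)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# Tajima's D from segregating sites S and total pairwise diversity
# (sum over sites of pairwise-difference probability), n chromosomes
tajima_d <- function(pi_total, s, n) {
  if (s <= 0) return(NA_real_)
  k <- tajima_constants(n)
  (pi_total - s / k$a1) / sqrt(k$e1 * s + k$e2 * s * (s - 1))
}

# union length of a set of [start, end) intervals (single chromosome)
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0)
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e) {
      cur_e <- max(cur_e, end[i])
    } else {
      tot <- tot + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  tot + (cur_e - cur_s)
}

# merge overlapping or abutting [start, end) intervals, returns matrix
merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                            sub[, seq(pos, k - 1L)[seq_len(k - pos)],
                                drop = FALSE]))
  }
  out
}
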