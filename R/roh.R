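# single-individual 3-class EM for one window; likelihood triples only
window_het_em <- function(L, tol = 1e-8, max_iter = 200) {
  eta <- rep(1 / 3, 3)
  for (it in seq_len(max_iter)) {
    d <- as.vector(L %*% eta)
    eta_new <- colMeans(L * rep(eta, each = nrow(L)) / d)
    delta <- max(abs(eta_new - eta))
    eta <- eta_new
    if (delta < tol) break
  }
  eta[2]  # heterozygous class
}

# deterministic window tiling: anchored at multiples of `step` from 0,
# truncated at the chromosome end, trailing windows shorter than `step`
# dropped
tile_windows <- function(chrom_len, window, step) {
  starts <- seq(0, max(0, chrom_len - 1), by = step)
  ends <- pmin(starts + window, chrom_len)
  keep <- (ends - starts) >= step
  tibble(start = starts[keep], end = ends[keep])
}

#' Sliding-window heterozygosity track for one individual
#'
#' Local heterozygosity in 100 kb windows sliding by 50 kb (defaults), each
#' estimated by the single-individual folded-SFS EM restricted to the
#' window's sites.  Windows with fewer than `min_sites` sites are flagged
#' unusable (`het = NA`).
#'
#' @param gl a `gl_matrix`; must carry `chrom_lengths`.
#' @param individual individual id (default: the only individual).
#' @param window,step window and slide in bp.
#' @param min_sites minimum sites for a usable window (default 10).
#' @return tibble: `individual`, `chrom`, `start` (0-based), `end`,
#'   `n_sites`, `het`, `usable`.
#' @export
window_het_track <- function(gl, individual = NULL, window = 1e5,
                             step = 5e4, min_sites = 10) {
  if (step <= 0 || window < step) stopf("need window >= step > 0")
  if (is.null(gl$chrom_lengths)) stopf("gl carries no chrom_lengths")
  if (is.null(individual)) {
    if (n_ind(gl) != 1L) stopf("specify `individual`")
    individual <- gl$inds$id[1]
  }
  ii <- match(individual, gl$inds$id)
  if (is.na(ii)) stopf("unknown individual '%s'", individual)
  L <- gl$lik[, ii, , drop = TRUE]
  if (is.null(dim(L))) L <- matrix(L, ncol = 3)
  out <- list()
  for (chrom in names(gl$chrom_lengths)) {
    win <- tile_windows(gl$chrom_lengths[[chrom]], window, step)
    if (nrow(win) == 0L) next
    on_chrom <- gl$sites$chrom == chrom
    pos <- gl$sites$pos[on_chrom]
    Lc <- L[on_chrom, , drop = FALSE]
    het <- rep(NA_real_, nrow(win))
    nsit <- integer(nrow(win))
    for (w in seq_len(nrow(win))) {
      sel <- pos > win$start[w] & pos <= win$end[w]
      nsit[w] <- sum(sel)
      if (nsit[w] >= min_sites)
        het[w] <- window_het_em(Lc[sel, , drop = FALSE])
    }
    out[[chrom]] <- tibble(individual = individual, chrom = chrom,
                           start = win$start, end = win$end,
                           n_sites = nsit, het = het,
                           usable = nsit >= min_sites)
  }
  bind_rows(out)
}

#' Heterozygosity tracks for every individual in a panel
#'
#' @inheritParams window_het_track
#' @return row-bound tibble of [window_het_track()] results.
#' @export
window_het_tracks <- function(gl, window = 1e5, step = 5e4, min_sites = 10) {
  bind_rows(lapply(gl$inds$id, function(id)
    window_het_track(gl, id, window, step, min_sites)))
}

#' Low-heterozygosity cutoff from all individuals' tracks
#'
#' Averages local heterozygosity across individuals per window, then takes
#' the `q` quantile (linear interpolation) of those per-window averages.
#'
#' @param tracks tibble from [window_het_tracks()].
#' @param q quantile (default 0.10).
#' @export
roh_cutoff <- function(tracks, q = 0.10) {
  usable <- tracks[tracks$usable & !is.na(tracks$het), ]
  if (nrow(usable) == 0L) stopf("no usable windows")
  avg <- usable |>
    group_by(.data$chrom, .data$start) |>
    summarise(het = mean(.data$het), .groups = "drop")
  unname(quantile(avg$het, q, type = 7))
}

#' Call runs of homozygosity and the inbreeding fraction F_RoH
#'
#' A RoH is a run of at least two consecutive usable windows with
#' heterozygosity below `cutoff`; the segment spans from the first window's
#' start to the last window's end (overlapping windows merge).  F_RoH is
#' the summed length of segments of at least `min_len` divided by the total
#' span scanned (union of the individual's usable windows).
#'
#' @param track one individual's tibble from [window_het_track()].
#' @param cutoff heterozygosity threshold (> 0), e.g. from [roh_cutoff()].
#' @param min_len minimum segment length in bp counted towards F_RoH
#'   (default 150 kb).
#' @return list with `segments` (tibble: `individual`, `chrom`, `start`,
#'   `end`, `length`, `n_windows`) and `froh`.
#' @export
call_roh_and_froh <- function(track, cutoff, min_len = 1.5e5) {
  check_number(cutoff, "cutoff", 0, Inf, open_lower = TRUE)
  if (!any(track$usable)) stopf("all windows unusable")
  segs <- list()
  span <- 0
  for (chrom in unique(track$chrom)) {
    tc <- track[track$chrom == chrom, ]
    tc <- tc[order(tc$start), ]
    u <- tc[tc$usable, ]
    if (nrow(u) > 0)
      span <- span + interval_union_length(u$start, u$end)
    low <- tc$usable & !is.na(tc$het) & tc$het < cutoff
    r <- rle(low)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    hit <- which(r$values & r$lengths >= 2L)
    for (h in hit) {
      i0 <- starts_idx[h]; i1 <- ends_idx[h]
      segs[[length(segs) + 1L]] <-
        tibble(individual = tc$individual[1], chrom = chrom,
               start = tc$start[i0], end = tc$end[i1],
               length = tc$end[i1] - tc$start[i0],
               n_windows = i1 - i0 + 1L)
    }
  }
  segments <- if (length(segs)) bind_rows(segs) else
    tibble(individual = character(0), chrom = character(0),
           start = numeric(0), end = numeric(0), length = numeric(0),
           n_windows = integer(0))
  froh <- if (span > 0)
    sum(segments$length[segments$length >= min_len]) / span else NA_real_
  list(segments = segments, froh = froh)
}

#' RoH segments and F_RoH for every individual
#'
#' @param tracks tibble from [window_het_tracks()].
#' @inheritParams call_roh_and_froh
#' @return list with `segments` (all individuals) and `froh` tibble
#'   (`individual`, `froh`).
#' @export
call_roh <- function(tracks, cutoff, min_len = 1.5e5) {
  ids <- unique(tracks$individual)
  res <- lapply(ids, function(id)
    call_roh_and_froh(tracks[tracks$individual == id, ], cutoff, min_len))
  list(segments = bind_rows(lapply(res, `[[`, "segments")),
       froh = tibble(individual = ids,
                     froh = vapply(res, `[[`, numeric(1), "froh")))
}
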