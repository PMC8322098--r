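#' @export
generics::tidy

#' @export
generics::glance

#' Tidy PCA results into per-individual principal-component scores
#'
#' @param x a `gl_pca`.
#' @param n_pcs number of components to return (default 4).
#' @param ... unused.
#' @return tibble: `id`, `colony`, `PC1`, `PC2`, ...
#' @export
tidy.gl_pca <- function(x, n_pcs = 4, ...) {
  n_pcs <- min(n_pcs, ncol(x$vectors))
  sc <- x$vectors[, seq_len(n_pcs), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(n_pcs))
  bind_cols <- cbind(x$inds, as_tibble(sc))
  as_tibble(bind_cols)
}

#' @export
glance.gl_pca <- function(x, ...) {
  tibble(n_ind = nrow(x$inds),
         pc1_var = x$var_explained[1], pc2_var = x$var_explained[2])
}

#' Tidy ancestry fractions into long format
#'
#' @param x a `qmatrix` or `qmatrix_avg`.
#' @param ... unused.
#' @return tibble: `id`, `colony`, `cluster`, `ancestry`.
#' @export
tidy.qmatrix <- function(x, ...) {
  q <- x$Q
  inds <- x$inds %||% tibble(id = rownames(q), colony = NA_character_)
  tidyr::pivot_longer(
    as_tibble(cbind(inds, as_tibble(setNames(as.data.frame(q),
                                             paste0("K", seq_len(ncol(q))))))),
    cols = dplyr::starts_with("K"), names_to = "cluster",
    values_to = "ancestry")
}

#' @export
tidy.qmatrix_avg <- tidy.qmatrix

#' @export
glance.qmatrix <- function(x, ...) {
  tibble(K = x$K, loglik = x$loglik, iterations = x$iterations,
         seed = x$seed)
}

#' @export
tidy.evanno <- function(x, ...) x$table

#' @export
glance.evanno <- function(x, ...) tibble(best_k = x$best_k)

#' @export
tidy.mrm_result <- function(x, ...) x$coefficients

#' @export
glance.mrm_result <- function(x, ...) {
  tibble(r_squared = x$r_squared, r_squared_p = x$r_squared_p,
         n_perm = x$n_perm)
}

#' @export
glance.mantel_result <- function(x, ...) {
  tibble(r = x$r, p = x$p, n_perm = x$n_perm)
}

#' @export
tidy.amova_result <- function(x, ...) x$components

#' @export
glance.amova_result <- function(x, ...) {
  as_tibble(c(as.list(x$phi), setNames(as.list(x$p),
                                       paste0(names(x$p), "_p"))))
}

#' @export
tidy.removal_trajectory <- function(x, ...) x$trajectory

#' @export
tidy.fst_windows <- function(x, ...) x$windows

#' @export
glance.fst_windows <- function(x, ...) {
  tibble(fst = x$global$fst, slatkin = x$global$slatkin,
         n_windows = nrow(x$windows))
}
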