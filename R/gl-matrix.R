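#' Genotype-likelihood matrix
#'
#' The central container of the package: per-site, per-individual biallelic
#' genotype-likelihood triples \eqn{L(g)}, \eqn{g \in \{0,1,2\}} counting
#' copies of the minor allele.  Each triple is rescaled so its maximum is 1;
#' a site missing in an individual is stored as a flat triple (all equal).
#'
#' @param sites tibble with columns `chrom`, `pos` (1-based), `major`,
#'   `minor` (single bases); positions strictly increasing within chromosome.
#' @param inds tibble with columns `id` and `colony`.
#' @param lik numeric array of dimension `n_sites x n_ind x 3`,
#'   non-negative.
#' @param chrom_lengths optional named vector of chromosome lengths (bp).
#'
#' @return An object of class `gl_matrix`.
#' @export
gl_matrix <- function(sites, inds, lik, chrom_lengths = NULL) {
  sites <- as_tibble(sites)
  inds <- as_tibble(inds)
  stopifnot(all(c("chrom", "pos", "major", "minor") %in% names(sites)),
            all(c("id", "colony") %in% names(inds)))
  if (length(dim(lik)) != 3L || dim(lik)[3] != 3L)
    stopf("`lik` must be an n_sites x n_ind x 3 array")
  if (dim(lik)[1] != nrow(sites) || dim(lik)[2] != nrow(inds))
    stopf("dimensions of `lik` do not match `sites`/`inds`")
  if (any(lik < 0)) stopf("likelihoods must be non-negative")
  bad <- unlist(tapply(sites$pos, sites$chrom, function(p) any(diff(p) <= 0)))
  if (any(bad))
    stopf("positions must be strictly increasing within chromosome")
  mx <- pmax(lik[, , 1], lik[, , 2], lik[, , 3])
  if (any(mx <= 0)) stopf("each triple needs a positive maximum")
  lik <- lik / as.vector(mx)  # recycles over third dimension
  structure(list(sites = sites, inds = inds, lik = lik,
                 chrom_lengths = chrom_lengths),
            class = "gl_matrix")
}

#' @export
print.gl_matrix <- function(x, ...) {
  cat(sprintf("<gl_matrix> %d sites x %d individuals (%d colonies)\n",
              n_sites(x), n_ind(x), length(unique(x$inds$colony))))
  invisible(x)
}

#' @rdname gl_matrix
#' @param gl a `gl_matrix`.
#' @export
n_sites <- function(gl) nrow(gl$sites)

#' @rdname gl_matrix
#' @export
n_ind <- function(gl) nrow(gl$inds)

#' Logical matrix of missing (flat-triple) entries, sites x individuals
#' @param gl a `gl_matrix`.
#' @export
gl_missing <- function(gl) {
  (gl$lik[, , 1] == gl$lik[, , 2]) & (gl$lik[, , 2] == gl$lik[, , 3])
}

#' Subset a gl_matrix by sites and/or individuals
#'
#' @param gl a `gl_matrix`.
#' @param sites integer/logical index over sites.
#' @param inds integer/logical index over individuals, or a character vector
#'   of colony names (selects all their members).
#' @export
gl_subset <- function(gl, sites = NULL, inds = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(gl)) else sites
  if (is.character(inds)) inds <- which(gl$inds$colony %in% inds)
  ii <- if (is.null(inds)) seq_len(n_ind(gl)) else inds
  gl_matrix(gl$sites[si, , drop = FALSE], gl$inds[ii, , drop = FALSE],
            gl$lik[si, ii, , drop = FALSE], gl$chrom_lengths)
}

base_code <- function(b) {
  code <- match(toupper(b), c("A", "C", "G", "T")) - 1L
  if (anyNA(code)) stopf("alleles must be A/C/G/T")
  code
}

#' Write / read the Beagle genotype-likelihood text format
#'
#' Three columns per individual, one header row, marker names `chrom_pos`,
#' alleles coded 0-3 for A/C/G/T.
#'
#' @param gl a `gl_matrix`.
#' @param path file path.
#' @export
write_beagle <- function(gl, path) {
  ids <- gl$inds$id
  header <- c("marker", "allele1", "allele2",
              as.vector(t(matrix(rep(ids, 3), ncol = 3))))
  m <- matrix(aperm(gl$lik, c(3, 2, 1)), nrow = n_sites(gl), byrow = TRUE)
  tab <- cbind(paste(gl$sites$chrom, gl$sites$pos, sep = "_"),
               base_code(gl$sites$major), base_code(gl$sites$minor),
               format(m, trim = TRUE, digits = 6, scientific = FALSE))
  con <- file(path, "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(tab, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_beagle
#' @param inds optional tibble (`id`, `colony`) carrying sample metadata;
#'   defaults to ids from the header with colony `"unknown"`.
#' @param chrom_lengths optional named chromosome lengths.
#' @export
read_beagle <- function(path, inds = NULL, chrom_lengths = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  mark <- tab[[1]]
  us <- regexpr("_[^_]*$", mark)
  chrom <- substr(mark, 1, us - 1)
  pos <- as.integer(substr(mark, us + 1, nchar(mark)))
  bases <- c("A", "C", "G", "T")
  sites <- tibble(chrom = chrom, pos = pos,
                  major = bases[as.integer(tab[[2]]) + 1L],
                  minor = bases[as.integer(tab[[3]]) + 1L])
  ntrip <- ncol(tab) - 3L
  if (ntrip %% 3L != 0L) stopf("malformed Beagle file: %d GL columns", ntrip)
  nind <- ntrip / 3L
  ids <- names(tab)[seq(4, by = 3, length.out = nind)]
  vals <- vapply(tab[-(1:3)], as.numeric, numeric(nrow(tab)))
  lik <- aperm(array(t(vals), dim = c(3, nind, nrow(tab))), c(3, 2, 1))
  if (is.null(inds)) inds <- tibble(id = ids, colony = "unknown")
  gl_matrix(sites, inds, lik, chrom_lengths)
}

#' Export a gl_matrix as a minimal biallelic VCF 4.2 with a GL field
#'
#' Genotype likelihoods are written as log10 values in the GL FORMAT
#' field (order 0/0, 0/1, 1/1); genotype calls are omitted (`./.`).
#'
#' @param gl a `gl_matrix`.
#' @param path file path.
#' @export
write_vcf_gl <- function(gl, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GL,Number=G,Type=Float,Description=\"Genotype likelihood, log10\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", gl$inds$id),
                     collapse = "\t")), con)
  S <- n_sites(gl)
  gl10 <- round(log10(pmax(gl$lik, 1e-300)), 4)
  for (s in seq_len(S)) {
    cells <- paste0("./.:", gl10[s, , 1], ",", gl10[s, , 2], ",",
                    gl10[s, , 3])
    writeLines(paste(c(gl$sites$chrom[s], gl$sites$pos[s], ".",
                       gl$sites$major[s], gl$sites$minor[s], ".",
                       "PASS", ".", "GT:GL", cells), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Import a biallelic VCF with GL or PL genotype fields as a gl_matrix
#'
#' Requires the `vcfR` package.  Sites without a GL/PL field, indels and
#' multi-allelic records are dropped.  REF is taken as major allele.
#'
#' @param path VCF path.
#' @param inds optional metadata tibble (`id`, `colony`).
#' @export
vcf_to_gl <- function(path, inds = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("vcf_to_gl() needs the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  keep <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"])
  gl_field <- if ("GL" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID)
    "GL" else "PL"
  g <- vcfR::extract.gt(v, element = gl_field)
  g <- g[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  parse_one <- function(s) {
    out <- matrix(NA_real_, length(s), 3)
    ok <- !is.na(s) & s != "."
    if (any(ok)) {
      sp <- do.call(rbind, strsplit(s[ok], ","))
      out[ok, ] <- apply(sp, 2, as.numeric)
    }
    out
  }
  nsite <- nrow(g); nind <- ncol(g)
  lik <- array(1, dim = c(nsite, nind, 3))
  for (j in seq_len(nind)) {
    m <- parse_one(g[, j])
    tri <- if (gl_field == "GL") 10^(m - apply(m, 1, max)) else
      10^(-(m - apply(m, 1, min)) / 10)
    tri[is.na(tri)] <- 1
    lik[, j, ] <- tri
  }
  sites <- tibble(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                  major = fix[, "REF"], minor = fix[, "ALT"])
  if (is.null(inds)) inds <- tibble(id = colnames(g), colony = "unknown")
  gl_matrix(sites, inds, lik)
}
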