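#' Construct a genotype matrix
#'
#' The central container of the package: a samples x sites grid of diploid
#' genotype calls with per-call depth and genotype quality (GQ), plus per-site
#' metadata. Genotypes use dosage coding relative to the site's reference (or
#' major) allele: 0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' alternate, `NA` = missing. A call with depth 0 is always missing; the
#' constructor enforces this by masking.
#'
#' @param geno integer matrix, samples in rows and sites in columns, values in
#'   `c(0, 1, 2, NA)`.
#' @param depth integer matrix of per-call read depths (same shape), or `NULL`
#'   when depths are unrecorded (e.g. truth matrices from the simulator).
#' @param gq numeric matrix of Phred-scaled genotype qualities, or `NULL`.
#' @param sites data frame of per-site metadata with columns `id`, `contig`,
#'   `pos` (1-based), `ref`, `alt`, `source` (`"denovo"` or `"reference"`).
#'   Synthesized when omitted. Extra columns are preserved.
#' @param samples character vector of sample ids; defaults to `rownames(geno)`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `samples`, `sites`, `geno`, `depth`, `gq`.
#' @export
genotype_matrix <- function(geno, depth = NULL, gq = NULL, sites = NULL,
                            samples = rownames(geno)) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  ns <- nrow(geno)
  nt <- ncol(geno)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ns))
  samples <- as.character(samples)
  if (length(samples) != ns) stop("length(samples) must equal nrow(geno)")
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  bad <- !(geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")

  if (is.null(sites)) {
    sites <- data.frame(
      id = sprintf("site%04d", seq_len(nt)),
      contig = "contig01",
      pos = seq_len(nt),
      ref = "A", alt = "C",
      source = "reference",
      stringsAsFactors = FALSE
    )
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("id", "contig", "pos", "ref", "alt", "source")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(sites) != nt) stop("nrow(sites) must equal ncol(geno)")
  if (anyDuplicated(sites$id)) stop("duplicate site ids")
  if (any(nchar(sites$ref) != 1L | nchar(sites$alt) != 1L, na.rm = TRUE))
    stop("ref and alt must be single bases")

  if (is.null(depth)) {
    depth <- matrix(NA_integer_, ns, nt)
  } else {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!all(dim(depth) == c(ns, nt))) stop("depth has wrong dimensions")
    if (any(depth < 0, na.rm = TRUE)) stop("negative depths")
    geno[!is.na(depth) & depth == 0L] <- NA_integer_  # depth 0 => missing
  }
  if (is.null(gq)) {
    gq <- matrix(NA_real_, ns, nt)
  } else {
    gq <- as.matrix(gq)
    storage.mode(gq) <- "double"
    if (!all(dim(gq) == c(ns, nt))) stop("gq has wrong dimensions")
  }
  gq[is.na(geno)] <- NA_real_

  dimnames(geno) <- dimnames(depth) <- dimnames(gq) <- list(samples, sites$id)
  structure(
    list(samples = samples, sites = sites, geno = geno, depth = depth, gq = gq),
    class = "genotype_matrix"
  )
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$samples), nrow(x$sites))

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- dim(x)
  miss <- mean(is.na(x$geno))
  cat(sprintf("genotype_matrix: %d samples x %d sites (%.1f%% missing)\n",
              d[1], d[2], 100 * miss))
  src <- table(x$sites$source)
  cat("  sites by source:", paste(sprintf("%s=%d", names(src), src), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param i sample index (logical, integer or character).
#' @param j site index (logical, integer or character).
#' @param ... unused.
#' @return a `genotype_matrix` restricted to the selected samples and sites.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$sites))
  if (is.character(i)) i <- match(i, x$samples)
  if (is.character(j)) j <- match(j, x$sites$id)
  genotype_matrix(
    geno = x$geno[i, j, drop = FALSE],
    depth = x$depth[i, j, drop = FALSE],
    gq = x$gq[i, j, drop = FALSE],
    sites = x$sites[j, , drop = FALSE],
    samples = x$samples[i]
  )
}

#' Per-site and per-sample summary statistics
#'
#' `site_missing()` and `sample_missing()` return fractions of missing calls;
#' `site_maf()` the folded minor allele frequency over non-missing diploid
#' calls (`NA` for sites with no calls); `site_het()` the observed
#' heterozygosity (het calls / non-missing calls); `mean_call_depth()` the
#' mean depth over non-missing calls with recorded depth.
#'
#' @param m a `genotype_matrix`.
#' @return a named numeric vector (scalar for `mean_call_depth`).
#' @export
site_missing <- function(m) colMeans(is.na(m$geno))

#' @rdname site_missing
#' @export
sample_missing <- function(m) rowMeans(is.na(m$geno))

#' @rdname site_missing
#' @export
site_maf <- function(m) {
  g <- m$geno
  nn <- colSums(!is.na(g))
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n2 <- colSums(g == 2L, na.rm = TRUE)
  p_alt <- (2 * n2 + n1) / (2 * nn)
  maf <- pmin(p_alt, 1 - p_alt)
  maf[nn == 0] <- NA_real_
  setNames(maf, m$sites$id)
}

#' @rdname site_missing
#' @export
site_het <- function(m) {
  g <- m$geno
  nn <- colSums(!is.na(g))
  h <- colSums(g == 1L, na.rm = TRUE) / nn
  h[nn == 0] <- NA_real_
  setNames(h, m$sites$id)
}

#' @rdname site_missing
#' @export
mean_call_depth <- function(m) {
  keep <- !is.na(m$geno) & !is.na(m$depth)
  if (!any(keep)) return(NA_real_)
  mean(m$depth[keep])
}

#' Swap reference and alternate alleles at selected sites
#'
#' Recodes genotypes 0 <-> 2 and swaps the `ref`/`alt` site labels, leaving
#' heterozygotes, depths and GQs untouched. Genotype-based statistics that
#' fold allele labels (MAF, heterozygosity, allele-sharing distances) are
#' invariant under this relabeling.
#'
#' @param m a `genotype_matrix`.
#' @param sites site index (integer, logical or character) to flip.
#' @return the relabeled `genotype_matrix`.
#' @export
relabel_alleles <- function(m, sites) {
  if (is.character(sites)) sites <- match(sites, m$sites$id)
  if (is.logical(sites)) sites <- which(sites)
  g <- m$geno
  g[, sites] <- 2L - g[, sites]
  r <- m$sites$ref[sites]
  m$sites$ref[sites] <- m$sites$alt[sites]
  m$sites$alt[sites] <- r
  m$geno <- g
  m
}

# append extra site columns to a genotype matrix (internal)
gm_bind_sites <- function(m, geno2, depth2, gq2, sites2) {
  genotype_matrix(
    geno = cbind(m$geno, geno2),
    depth = cbind(m$depth, depth2),
    gq = cbind(m$gq, gq2),
    sites = rbind(m$sites[, c("id", "contig", "pos", "ref", "alt", "source")],
                  sites2[, c("id", "contig", "pos", "ref", "alt", "source")]),
    samples = m$samples
  )
}
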