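#' Pairwise allele-sharing distances from a genotype matrix
#'
#' For samples i and j, the distance is the mean of `|g_i - g_j| / 2` over
#' sites where both are non-missing, so identical genotypes contribute 0,
#' opposite homozygotes 1, and a het/hom difference 0.5. The computation is
#' done with one-hot crossproducts, so it scales to thousands of sites. A
#' pair of samples sharing zero called sites has no defined distance and is
#' an error (the pair is named).
#'
#' @param m a `genotype_matrix` with at least 3 samples.
#' @return symmetric numeric matrix with zero diagonal, dimnames the sample
#'   ids.
#' @export
pdistance_matrix <- function(m) {
  pdistance_core(m$geno, m$samples)
}

# distance from a raw genotype grid (rows = samples); lets the bootstrap
# resample site columns (with repeats) without touching site metadata
pdistance_core <- function(g, samples) {
  ns <- length(samples)
  if (ns < 3L) stop("need at least 3 samples for a distance matrix")
  i0 <- (!is.na(g) & g == 0L) * 1
  i1 <- (!is.na(g) & g == 1L) * 1
  i2 <- (!is.na(g) & g == 2L) * 1
  called <- i0 + i1 + i2
  shared <- tcrossprod(called)
  zero_pairs <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)
  if (nrow(zero_pairs)) {
    pairs <- apply(zero_pairs, 1L, function(rc)
      paste(samples[rc[1]], samples[rc[2]], sep = "/"))
    stop("sample pair(s) share zero called sites: ",
         paste(pairs, collapse = ", "))
  }
  # sum over shared sites of |g_i - g_j|: |0-1| = |1-2| = 1, |0-2| = 2
  absdiff <- tcrossprod(i0, i1) + tcrossprod(i1, i0) +
    tcrossprod(i1, i2) + tcrossprod(i2, i1) +
    2 * (tcrossprod(i0, i2) + tcrossprod(i2, i0))
  d <- absdiff / (2 * shared)
  diag(d) <- 0
  dimnames(d) <- list(samples, samples)
  d
}
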