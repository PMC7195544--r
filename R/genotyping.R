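#' Call a diploid genotype from two allele depths
#'
#' Binomial diploid likelihood with symmetric base error `e`: with
#' `d = depth_a + depth_b`,
#' `L(AA) = C(d, depth_b) e^depth_b (1-e)^depth_a`,
#' `L(BB)` symmetric, and `L(AB) = C(d, depth_b) 0.5^d`. The call is the
#' maximum-likelihood genotype; exact ties resolve toward the heterozygote,
#' then toward homozygous-A, with GQ 0. GQ is the Phred-scaled gap between
#' the best and second-best genotype likelihoods,
#' `10 log10(L_best / L_second)`, reported to 0.01 and capped at 99. Calls
#' with total depth below `min_depth` are missing.
#'
#' All arguments are vectorized; `depth_a`/`depth_b` are recycled to a common
#' length. Swapping the two depths flips genotype 0 <-> 2 and leaves the GQ
#' unchanged (allele-relabeling symmetry).
#'
#' @param depth_a,depth_b non-negative read counts for the two alleles.
#' @param error_rate per-read base error rate in `(0, 0.5)`, default 0.01.
#' @param min_depth minimum total depth for a call, default 1.
#' @return data frame with columns `genotype` (0/1/2 or `NA`), `depth`, `gq`.
#' @export
call_genotype <- function(depth_a, depth_b, error_rate = 0.01, min_depth = 1L) {
  stopifnot(error_rate > 0, error_rate < 0.5, min_depth >= 0)
  n <- max(length(depth_a), length(depth_b))
  a <- rep_len(as.numeric(depth_a), n)
  b <- rep_len(as.numeric(depth_b), n)
  if (any(a < 0 | b < 0)) stop("depths must be non-negative")
  d <- a + b
  e <- error_rate
  lc <- lchoose(d, b)
  ll <- cbind(
    het = lc + d * log(0.5),              # evaluated first: ties favor het,
    hom_a = lc + b * log(e) + a * log1p(-e),  # then homozygous-A
    hom_b = lc + a * log(e) + b * log1p(-e)
  )
  best <- max.col(ll, ties.method = "first")
  geno <- c(1L, 0L, 2L)[best]
  second <- apply(ll, 1L, function(x) max(x[-which.max(x)]))
  gq <- round(pmin(99, 10 / log(10) * (ll[cbind(seq_len(n), best)] - second)), 2)
  miss <- d < min_depth
  geno[miss] <- NA_integer_
  gq[miss] <- NA_real_
  data.frame(genotype = geno, depth = as.integer(d), gq = gq)
}

# shared assembly step: per-sample allele-depth matrices -> genotype_matrix
matrix_from_depths <- function(depth_a, depth_b, sites, samples,
                               error_rate = 0.01, min_depth = 1L) {
  ns <- length(samples); nt <- nrow(sites)
  stopifnot(all(dim(depth_a) == c(ns, nt)), all(dim(depth_b) == c(ns, nt)))
  if (anyDuplicated(sites$id)) stop("duplicate site ids")
  calls <- call_genotype(as.vector(depth_a), as.vector(depth_b),
                         error_rate = error_rate, min_depth = min_depth)
  genotype_matrix(
    geno = matrix(calls$genotype, ns, nt),
    depth = matrix(calls$depth, ns, nt),
    gq = matrix(calls$gq, ns, nt),
    sites = sites, samples = samples
  )
}

#' Assemble a genotype matrix from de novo tag pairs
#'
#' Each tag pair is one candidate site; a sample's allele depths are its read
#' counts for the two tags. Sites are oriented by the observed major allele
#' (the tag with the larger dataset-wide total; ties go to the
#' lexicographically smaller tag), written on synthetic per-pair contigs
#' (`pair00001`, ...) at position 33, the 1-based center of a 64-bp tag, to
#' mark them as non-genomic.
#'
#' @param pairs a `tag_pairs` data frame from [pair_tags()] (optionally after
#'   [network_error_filter()]).
#' @param tags the originating `tag_set`; defaults to the attribute carried
#'   by `pairs`.
#' @param error_rate,min_depth passed to [call_genotype()].
#' @return a `genotype_matrix` with site source `"denovo"`; extra site
#'   columns `tag_major`, `tag_minor`, `snp_offset` record the tag pairing.
#' @export
build_matrix_denovo <- function(pairs, tags = attr(pairs, "tag_set"),
                                error_rate = 0.01, min_depth = 1L) {
  if (is.null(tags)) stop("pairs carry no tag_set; pass `tags` explicitly")
  np <- nrow(pairs)
  if (np == 0L) stop("no tag pairs to genotype")
  samples <- colnames(tags$counts)
  major_is_a <- pairs$total_a >= pairs$total_b
  maj_idx <- ifelse(major_is_a, pairs$a_idx, pairs$b_idx)
  min_idx <- ifelse(major_is_a, pairs$b_idx, pairs$a_idx)
  depth_major <- t(tags$counts[maj_idx, , drop = FALSE])
  depth_minor <- t(tags$counts[min_idx, , drop = FALSE])
  pos_center <- if (is.na(tags$length)) 1L else as.integer(ceiling((tags$length + 1) / 2))
  sites <- data.frame(
    id = sprintf("pair%05d", seq_len(np)),
    contig = sprintf("pair%05d", seq_len(np)),
    pos = pos_center,
    ref = ifelse(major_is_a, pairs$allele_a, pairs$allele_b),
    alt = ifelse(major_is_a, pairs$allele_b, pairs$allele_a),
    source = "denovo",
    tag_major = tags$sequences[maj_idx],
    tag_minor = tags$sequences[min_idx],
    snp_offset = pairs$snp_offset,
    stringsAsFactors = FALSE
  )
  matrix_from_depths(depth_major, depth_minor, sites, samples,
                     error_rate = error_rate, min_depth = min_depth)
}

#' Assemble a genotype matrix from reference-mapped candidate sites
#'
#' A sample's allele depths at a site are the summed read counts of its
#' placed tags carrying the reference and alternate base at that position;
#' tags carrying other bases do not contribute.
#'
#' @param sites a `candidate_sites` data frame from [placements_to_sites()].
#' @param tags the originating `tag_set`; defaults to the attribute carried
#'   by `sites`.
#' @param error_rate,min_depth passed to [call_genotype()].
#' @return a `genotype_matrix` with site source `"reference"` and site ids
#'   `contig_pos`.
#' @export
build_matrix_reference <- function(sites, tags = attr(sites, "tag_set"),
                                   error_rate = 0.01, min_depth = 1L) {
  if (is.null(tags)) stop("sites carry no tag_set; pass `tags` explicitly")
  nt <- nrow(sites)
  if (nt == 0L) stop("no candidate sites to genotype")
  samples <- colnames(tags$counts)
  ns <- length(samples)
  depth_ref <- matrix(0L, ns, nt)
  depth_alt <- matrix(0L, ns, nt)
  for (j in seq_len(nt)) {
    obs <- sites$obs[[j]]
    ref_tags <- obs$tag_idx[obs$base == sites$ref[j]]
    alt_tags <- obs$tag_idx[obs$base == sites$alt[j]]
    if (length(ref_tags))
      depth_ref[, j] <- colSums(tags$counts[ref_tags, , drop = FALSE])
    if (length(alt_tags))
      depth_alt[, j] <- colSums(tags$counts[alt_tags, , drop = FALSE])
  }
  meta <- data.frame(
    id = paste0(sites$contig, "_", sites$pos),
    contig = sites$contig, pos = sites$pos,
    ref = sites$ref, alt = sites$alt,
    source = "reference", stringsAsFactors = FALSE
  )
  matrix_from_depths(depth_ref, depth_alt, meta, samples,
                     error_rate = error_rate, min_depth = min_depth)
}
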