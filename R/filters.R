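#' Filter threshold configuration
#'
#' Bundles the thresholds of the five-rule filter suite plus the two
#' housekeeping rules (sample missingness, invariant-site removal). The
#' defaults are the composite setting the toolkit treats as its reference
#' point: site missingness <= 50%, MAF >= 0.02, heterozygosity >= 0.01,
#' per-call depth floored at the dataset mean, and linked sites closer than
#' 128 bp (twice the 64-bp tag length) pruned.
#'
#' Boundary semantics are fixed and unit-tested: missingness keeps a site
#' (or sample) when its missing fraction is `<=` (`<` strictly above drops a
#' sample), MAF and heterozygosity keep when `>=` the minimum, and depth
#' floors/ceilings mask strictly below/above the threshold.
#'
#' @param max_site_missing keep a site iff its missing fraction is at most
#'   this, default 0.5.
#' @param max_sample_missing drop a sample iff its missing fraction strictly
#'   exceeds this, default 0.9.
#' @param min_maf keep a site iff its folded minor allele frequency is at
#'   least this, default 0.02 (monomorphic sites drop whenever > 0).
#' @param min_het keep a site iff its observed heterozygosity is at least
#'   this, default 0.01.
#' @param max_het optional upper heterozygosity bound (paralog-style excess
#'   het), default `NULL` (off).
#' @param depth_mode one of `"floor_mean"` (mask calls with depth strictly
#'   below the dataset mean call depth), `"floor_value"`, `"ceiling_value"`
#'   (mask strictly above `depth_value`), `"none"`.
#' @param depth_value numeric threshold for the `_value` modes.
#' @param min_link_dist prune a site whose distance to the last retained site
#'   on its contig is strictly less than this many bp, default 128.
#' @param drop_invariant remove sites with no allelic variation? Default `TRUE`.
#' @return a `filter_config` list.
#' @export
filter_config <- function(max_site_missing = 0.5, max_sample_missing = 0.9,
                          min_maf = 0.02, min_het = 0.01, max_het = NULL,
                          depth_mode = c("floor_mean", "floor_value",
                                         "ceiling_value", "none"),
                          depth_value = NULL, min_link_dist = 128L,
                          drop_invariant = TRUE) {
  depth_mode <- match.arg(depth_mode)
  stopifnot(max_site_missing >= 0, max_site_missing <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1,
            min_maf >= 0, min_maf <= 1, min_het >= 0, min_het <= 1,
            min_link_dist >= 0)
  if (!is.null(max_het)) stopifnot(max_het >= 0, max_het <= 1)
  if (depth_mode %in% c("floor_value", "ceiling_value") && is.null(depth_value))
    stop("depth_value is required for depth_mode '", depth_mode, "'")
  structure(
    list(max_site_missing = max_site_missing,
         max_sample_missing = max_sample_missing,
         min_maf = min_maf, min_het = min_het, max_het = max_het,
         depth_mode = depth_mode, depth_value = depth_value,
         min_link_dist = as.integer(min_link_dist),
         drop_invariant = drop_invariant),
    class = "filter_config"
  )
}

#' Remove samples with excessive missing data
#'
#' Drops every sample whose fraction of missing calls strictly exceeds
#' `max_sample_missing` (a sample missing at exactly the threshold is kept).
#'
#' @param m a `genotype_matrix`.
#' @param max_sample_missing fraction in `[0, 1]`, default 0.9.
#' @return the filtered `genotype_matrix`; attribute `removed_samples` lists
#'   the dropped ids.
#' @export
filter_sample_missing <- function(m, max_sample_missing = 0.9) {
  if (length(m$samples) == 0L) stop("empty matrix")
  keep <- sample_missing(m) <= max_sample_missing
  if (!any(keep)) stop("no samples survive the sample-missingness filter")
  out <- m[keep, ]
  attr(out, "removed_samples") <- m$samples[!keep]
  out
}

#' Remove sites with excessive missing data
#'
#' Keeps a site iff the fraction of samples missing at it is at most
#' `max_site_missing` (a site missing in exactly half the samples is kept at
#' the 0.5 default).
#'
#' @param m a `genotype_matrix`.
#' @param max_site_missing fraction in `[0, 1]`, default 0.5.
#' @return the filtered `genotype_matrix`; attribute `removed_sites` lists
#'   the dropped site ids.
#' @export
filter_site_missing <- function(m, max_site_missing = 0.5) {
  keep <- site_missing(m) <= max_site_missing
  out <- m[, keep]
  attr(out, "removed_sites") <- m$sites$id[!keep]
  out
}

#' Remove sites by minor allele frequency
#'
#' Allele counts are taken over non-missing diploid calls (genotype 0
#' contributes two reference alleles, 1 one of each, 2 two alternate
#' alleles); the MAF is folded, `min(p, 1 - p)`, so it never depends on
#' which allele is labeled reference. A site is kept iff MAF `>= min_maf`;
#' monomorphic sites (MAF 0) therefore drop whenever `min_maf > 0`. Sites
#' with zero non-missing calls are removed and counted separately.
#'
#' @param m a `genotype_matrix`.
#' @param min_maf fraction in `[0, 1]`, default 0.02.
#' @return the filtered `genotype_matrix`; attributes `removed_sites` and
#'   `removed_no_calls` (ids with zero non-missing calls).
#' @export
filter_maf <- function(m, min_maf = 0.02) {
  maf <- site_maf(m)
  no_calls <- is.na(maf)
  keep <- !no_calls & maf >= min_maf
  out <- m[, keep]
  attr(out, "removed_sites") <- m$sites$id[!keep]
  attr(out, "removed_no_calls") <- m$sites$id[no_calls]
  out
}

#' Remove sites by observed heterozygosity
#'
#' Observed heterozygosity is the fraction of non-missing calls that are
#' heterozygous. A site is kept iff it is at least `min_het` and, when
#' `max_het` is given, at most `max_het` (excess heterozygosity is the
#' classic paralog-collapse signature). Sites with zero non-missing calls
#' are removed.
#'
#' @param m a `genotype_matrix`.
#' @param min_het minimum heterozygosity, default 0.01.
#' @param max_het optional maximum heterozygosity, default `NULL` (off).
#' @return the filtered `genotype_matrix`; attribute `removed_sites`.
#' @export
filter_het <- function(m, min_het = 0.01, max_het = NULL) {
  h <- site_het(m)
  keep <- !is.na(h) & h >= min_het
  if (!is.null(max_het)) keep <- keep & h <= max_het
  out <- m[, keep]
  attr(out, "removed_sites") <- m$sites$id[!keep]
  out
}

#' Mask calls by read depth
#'
#' `floor_mean` masks (sets to missing) every call whose depth is strictly
#' below the dataset mean call depth, computed as a real number over
#' non-missing calls of the input matrix; `floor_value` does the same
#' against a fixed threshold, and `ceiling_value` masks calls strictly above
#' it. Sites left with zero non-missing calls are dropped; the site-level
#' missingness filter is not re-applied implicitly (callers compose filters
#' explicitly).
#'
#' @param m a `genotype_matrix` with per-call depths.
#' @param depth_mode `"floor_mean"`, `"floor_value"` or `"ceiling_value"`.
#' @param depth_value threshold for the `_value` modes.
#' @return the filtered `genotype_matrix`; attributes `depth_threshold`
#'   (the threshold used), `masked_calls` (count), `removed_sites`.
#' @export
filter_depth <- function(m, depth_mode = c("floor_mean", "floor_value",
                                           "ceiling_value"),
                         depth_value = NULL) {
  depth_mode <- match.arg(depth_mode)
  thr <- switch(depth_mode,
    floor_mean = mean_call_depth(m),
    floor_value = , ceiling_value = {
      if (is.null(depth_value)) stop("depth_value required")
      as.numeric(depth_value)
    }
  )
  if (is.na(thr)) stop("no called depths available to set a depth threshold")
  mask <- !is.na(m$geno) & !is.na(m$depth) &
    (if (depth_mode == "ceiling_value") m$depth > thr else m$depth < thr)
  m$geno[mask] <- NA_integer_
  m$gq[mask] <- NA_real_
  keep <- colSums(!is.na(m$geno)) > 0L
  out <- m[, keep]
  attr(out, "depth_threshold") <- thr
  attr(out, "masked_calls") <- sum(mask)
  attr(out, "removed_sites") <- m$sites$id[!keep]
  out
}

#' Remove invariant sites
#'
#' A site is invariant when all its non-missing genotypes are identical and
#' homozygous; an all-heterozygous site still carries both alleles and is
#' kept. Sites with zero non-missing calls are removed as well.
#'
#' @param m a `genotype_matrix`.
#' @return the filtered `genotype_matrix`; attribute `removed_sites`.
#' @export
drop_invariant <- function(m) {
  g <- m$geno
  nn <- colSums(!is.na(g))
  n0 <- colSums(g == 0L, na.rm = TRUE)
  n2 <- colSums(g == 2L, na.rm = TRUE)
  invariant <- nn == 0L | n0 == nn | n2 == nn
  out <- m[, !invariant]
  attr(out, "removed_sites") <- m$sites$id[invariant]
  out
}

#' Prune physically linked sites
#'
#' Greedy left-to-right thinning per contig: sites are scanned in position
#' order and a site is removed when its distance to the last retained site
#' on the same contig is strictly less than `min_link_dist` bp. Position
#' ties are broken toward the site with fewer missing calls, then the lower
#' site id. Only positioned sites (source `"reference"`) are pruned; de novo
#' sites on synthetic pair contigs pass through untouched with a warning.
#'
#' @param m a `genotype_matrix`.
#' @param min_link_dist minimum spacing in bp, default 128 (twice the 64-bp
#'   tag length).
#' @return list with `matrix` (the pruned `genotype_matrix`) and `report`
#'   (data frame of removed sites and the retained neighbor that blocked
#'   each: columns `site`, `contig`, `pos`, `blocked_by`, `distance`).
#' @export
prune_linked <- function(m, min_link_dist = 128L) {
  min_link_dist <- as.integer(min_link_dist)
  positioned <- m$sites$source == "reference"
  if (any(!positioned))
    warning(sprintf("%d unpositioned (de novo) site(s) pass through linkage pruning untouched",
                    sum(!positioned)))
  n_miss <- colSums(is.na(m$geno))
  removed <- character(0); blocker <- character(0); dist <- integer(0)
  for (ct in unique(m$sites$contig[positioned])) {
    idx <- which(positioned & m$sites$contig == ct)
    idx <- idx[order(m$sites$pos[idx], n_miss[idx], m$sites$id[idx])]
    last_pos <- NULL; last_id <- NULL
    for (i in idx) {
      p <- m$sites$pos[i]
      if (!is.null(last_pos) && p - last_pos < min_link_dist) {
        removed <- c(removed, m$sites$id[i])
        blocker <- c(blocker, last_id)
        dist <- c(dist, p - last_pos)
      } else {
        last_pos <- p; last_id <- m$sites$id[i]
      }
    }
  }
  keep <- !(m$sites$id %in% removed)
  report <- data.frame(
    site = removed,
    contig = m$sites$contig[match(removed, m$sites$id)],
    pos = m$sites$pos[match(removed, m$sites$id)],
    blocked_by = blocker, distance = dist, stringsAsFactors = FALSE
  )
  list(matrix = m[, keep], report = report)
}

default_filter_order <- function() {
  c("sample_missing", "depth", "site_missing", "maf", "het", "invariant",
    "linkage")
}

#' Apply a filter chain with logging
#'
#' Applies the named rules in order, recording one report row per rule
#' (sites before, sites and samples removed, threshold used). The default
#' order applies the depth mask before the site-missingness filter, so that
#' missingness created by depth masking is seen by the downstream rules;
#' order is an explicit, logged parameter because the rules interact.
#'
#' @param m a `genotype_matrix`.
#' @param config a [filter_config()].
#' @param order character vector of rule names among `"sample_missing"`,
#'   `"depth"`, `"site_missing"`, `"maf"`, `"het"`, `"invariant"`,
#'   `"linkage"`.
#' @return list with `matrix` (the filtered `genotype_matrix`) and `report`
#'   (a `filter_report` data frame: `rule`, `sites_before`, `sites_removed`,
#'   `samples_removed`, `threshold`).
#' @export
apply_filters <- function(m, config = filter_config(),
                          order = default_filter_order()) {
  stopifnot(inherits(config, "filter_config"))
  known <- default_filter_order()
  bad <- setdiff(order, known)
  if (length(bad)) stop("unknown filter rule(s): ", paste(bad, collapse = ", "))
  rows <- vector("list", length(order))
  for (k in seq_along(order)) {
    rule <- order[k]
    before <- nrow(m$sites)
    ns_before <- length(m$samples)
    thr <- ""
    res <- switch(rule,
      sample_missing = {
        thr <- sprintf("max_sample_missing=%g", config$max_sample_missing)
        filter_sample_missing(m, config$max_sample_missing)
      },
      depth = {
        if (config$depth_mode == "none") { thr <- "off"; m }
        else {
          r <- filter_depth(m, config$depth_mode, config$depth_value)
          thr <- sprintf("%s=%g", config$depth_mode,
                         attr(r, "depth_threshold"))
          r
        }
      },
      site_missing = {
        thr <- sprintf("max_site_missing=%g", config$max_site_missing)
        filter_site_missing(m, config$max_site_missing)
      },
      maf = {
        thr <- sprintf("min_maf=%g", config$min_maf)
        filter_maf(m, config$min_maf)
      },
      het = {
        thr <- if (is.null(config$max_het))
          sprintf("min_het=%g", config$min_het)
        else sprintf("min_het=%g,max_het=%g", config$min_het, config$max_het)
        filter_het(m, config$min_het, config$max_het)
      },
      invariant = {
        if (!config$drop_invariant) { thr <- "off"; m }
        else { thr <- "on"; drop_invariant(m) }
      },
      linkage = {
        thr <- sprintf("min_link_dist=%d", config$min_link_dist)
        if (config$min_link_dist > 0L) {
          pr <- suppressWarnings(prune_linked(m, config$min_link_dist))
          pr$matrix
        } else m
      }
    )
    m <- res
    rows[[k]] <- data.frame(
      rule = rule, sites_before = before,
      sites_removed = before - nrow(m$sites),
      samples_removed = ns_before - length(m$samples),
      threshold = thr, stringsAsFactors = FALSE
    )
  }
  report <- do.call(rbind, rows)
  class(report) <- c("filter_report", class(report))
  list(matrix = m, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
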