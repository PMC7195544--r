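sweep_rule_field <- c(
  sample_missing = "max_sample_missing",
  site_missing = "max_site_missing",
  maf = "min_maf",
  het = "min_het",
  depth = "depth_value",
  linkage = "min_link_dist"
)

#' Sweep one filter threshold over a grid
#'
#' For each threshold in `grid`, applies `base_config` with the chosen
#' rule's threshold overridden and records the surviving SNP count; the
#' count-vs-threshold curve is the standard diagnostic for choosing filter
#' settings. Optionally builds a neighbor-joining tree at every threshold
#' and records its Robinson-Foulds distance to the tree at the base setting,
#' operationalizing "did the tree change?" as a number. The input matrix is
#' never mutated.
#'
#' @param m a `genotype_matrix`.
#' @param rule one of `"site_missing"`, `"maf"`, `"het"`, `"depth"`,
#'   `"linkage"`, `"sample_missing"` (for `"depth"` the base config must use
#'   a `_value` depth mode).
#' @param grid numeric vector of thresholds, sorted (ascending or
#'   descending), non-empty.
#' @param base_config a [filter_config()]; the base-setting tree is built
#'   from it unchanged.
#' @param order filter order passed to [apply_filters()].
#' @param build_trees also build an NJ tree per threshold and RF distances
#'   to the base-setting tree? Default `FALSE`.
#' @return a `sweep_result`: list with `rule`, `grid`, `snp_counts`, and
#'   (when `build_trees`) `trees` and `rf_to_base`.
#' @export
sweep_filter <- function(m, rule, grid, base_config = filter_config(),
                         order = default_filter_order(),
                         build_trees = FALSE) {
  if (length(grid) == 0L) stop("empty sweep grid")
  if (is.unsorted(grid) && is.unsorted(rev(grid)))
    stop("grid must be sorted (ascending or descending)")
  field <- sweep_rule_field[rule]
  if (is.na(field)) stop("unknown sweep rule: ", rule)
  if (rule == "depth" && !(base_config$depth_mode %in% c("floor_value", "ceiling_value")))
    stop("sweeping 'depth' requires depth_mode 'floor_value' or 'ceiling_value'")

  base_tree <- NULL
  if (build_trees) {
    base_m <- apply_filters(m, base_config, order)$matrix
    base_tree <- nj_tree(pdistance_matrix(base_m))
  }
  counts <- integer(length(grid))
  trees <- if (build_trees) vector("list", length(grid)) else NULL
  rf <- if (build_trees) numeric(length(grid)) else NULL
  for (k in seq_along(grid)) {
    cfg <- base_config
    cfg[[field]] <- grid[k]
    res <- apply_filters(m, cfg, order)
    counts[k] <- nrow(res$matrix$sites)
    if (build_trees) {
      trees[[k]] <- nj_tree(pdistance_matrix(res$matrix))
      rf[k] <- rf_distance(trees[[k]], base_tree)$rf
    }
  }
  structure(
    list(rule = rule, grid = grid, snp_counts = counts,
         trees = trees, rf_to_base = rf),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: rule '%s' over %d thresholds\n", x$rule,
              length(x$grid)))
  df <- data.frame(threshold = x$grid, snp_count = x$snp_counts)
  if (!is.null(x$rf_to_base)) df$rf_to_base <- x$rf_to_base
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Simulate the effect of depth thresholds around the mean
#'
#' Sweeps a depth floor and a depth ceiling over `mean - span` ...
#' `mean + span` (unit steps around the real-valued dataset mean call
#' depth), recording surviving SNP counts in both directions, and flags the
#' plateau point of each sweep: scanning in the direction of increasing
#' stringency, the first threshold at which the count changes by less than
#' 1% relative to the previous threshold.
#'
#' @param m a `genotype_matrix` with per-call depths.
#' @param span non-negative integer half-width of the sweep; `span = 0`
#'   evaluates the mean itself in both directions only.
#' @return a `depth_sweep`: list with `mean_depth`, `floor` and `ceiling`
#'   data frames (`threshold`, `snp_count`), and `plateau_floor` /
#'   `plateau_ceiling` (threshold, or `NA` if no plateau).
#' @export
depth_simulation <- function(m, span = 3L) {
  stopifnot(span >= 0)
  mu <- mean_call_depth(m)
  if (is.na(mu)) stop("no called depths in matrix")
  offs <- seq(-span, span)
  thresholds <- mu + offs
  count_at <- function(mode, thr) {
    res <- filter_depth(m, mode, thr)
    nrow(res$sites)
  }
  floor_counts <- vapply(thresholds, function(t) count_at("floor_value", t),
                         integer(1))
  ceil_counts <- vapply(thresholds, function(t) count_at("ceiling_value", t),
                        integer(1))
  plateau <- function(thr, cnt) {
    # thr must be ordered from least to most stringent
    if (length(cnt) < 2L) return(NA_real_)
    rel <- abs(diff(cnt)) / pmax(cnt[-length(cnt)], 1L)
    i <- which(rel < 0.01)
    if (length(i)) thr[i[1] + 1L] else NA_real_
  }
  structure(
    list(
      mean_depth = mu,
      floor = data.frame(threshold = thresholds, snp_count = floor_counts),
      ceiling = data.frame(threshold = thresholds, snp_count = ceil_counts),
      # floor stringency grows with the threshold; ceiling stringency grows
      # as the threshold falls
      plateau_floor = plateau(thresholds, floor_counts),
      plateau_ceiling = plateau(rev(thresholds), rev(ceil_counts))
    ),
    class = "depth_sweep"
  )
}

#' @export
print.depth_sweep <- function(x, ...) {
  cat(sprintf("depth_sweep: mean call depth %.3f\n", x$mean_depth))
  cat(sprintf("  plateau (floor): %s   plateau (ceiling): %s\n",
              format(x$plateau_floor), format(x$plateau_ceiling)))
  df <- data.frame(threshold = x$floor$threshold,
                   floor_count = x$floor$snp_count,
                   ceiling_count = x$ceiling$snp_count)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
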