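# Canonical key for a bipartition: the side NOT containing the reference
# leaf (the alphabetically first), sorted and comma-joined.
split_key <- function(side, all_leaves) {
  ref <- min(all_leaves)
  if (ref %in% side) side <- setdiff(all_leaves, side)
  paste(sort(side), collapse = ",")
}

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge of an unrooted tree splits the leaves in two; the set
#' of such splits is the tree's topology fingerprint used by the
#' Robinson-Foulds machinery. Splits with fewer than two leaves on either
#' side are trivial and excluded. Keys are canonical (the side not
#' containing the alphabetically first leaf, sorted, comma-joined), so trees
#' with different rootings or tip orders compare directly.
#'
#' @param tree an [ape::phylo] tree (bifurcating or not).
#' @param supports also return node support values keyed by split (from
#'   `tree$node.label`)? Default `FALSE`.
#' @return character vector of split keys, or (with `supports`) a named
#'   numeric vector of supports keyed by split.
#' @export
tree_splits <- function(tree, supports = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  leaves <- tree$tip.label
  n <- length(leaves)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  sup <- numeric(0)
  labs <- tree$node.label
  for (i in seq_along(pp)) {
    side <- leaves[pp[[i]]]
    if (length(side) < 2L || length(side) > n - 2L) next
    k <- split_key(side, leaves)
    keys <- c(keys, k)
    if (supports) {
      s <- if (!is.null(labs) && i <= length(labs))
        suppressWarnings(as.numeric(labs[i])) else NA_real_
      sup <- c(sup, s)
    }
  }
  dup <- duplicated(keys)
  keys <- keys[!dup]
  if (supports) return(setNames(sup[!dup], keys))
  keys
}

#' Robinson-Foulds distance and concordance report between two trees
#'
#' Counts the non-trivial bipartitions present in exactly one of the two
#' trees (the symmetric difference); identical topologies score 0. The
#' report also lists shared clades with their support in each tree (when the
#' trees carry support labels) and the splits unique to each side. The
#' normalization divides by `2 (n - 3)`, the maximum for two fully
#' bifurcating trees on `n` leaves.
#'
#' @param tree_a,tree_b [ape::phylo] trees on the same leaf set.
#' @return a `concordance_report`: list with `rf`, `normalized_rf`,
#'   `n_leaves`, `shared_clades` (data frame `split`, `support_a`,
#'   `support_b`), `unique_to_a`, `unique_to_b`.
#' @export
rf_distance <- function(tree_a, tree_b) {
  la <- sort(tree_a$tip.label); lb <- sort(tree_b$tip.label)
  if (!identical(la, lb)) {
    stop("trees have different leaf sets; only in first: ",
         paste(setdiff(la, lb), collapse = ", "),
         "; only in second: ", paste(setdiff(lb, la), collapse = ", "))
  }
  n <- length(la)
  sa <- tree_splits(tree_a, supports = TRUE)
  sb <- tree_splits(tree_b, supports = TRUE)
  shared <- intersect(names(sa), names(sb))
  ua <- setdiff(names(sa), names(sb))
  ub <- setdiff(names(sb), names(sa))
  rf <- length(ua) + length(ub)
  structure(
    list(
      rf = rf,
      normalized_rf = if (n > 3L) rf / (2 * (n - 3)) else 0,
      n_leaves = n,
      shared_clades = data.frame(split = shared,
                                 support_a = unname(sa[shared]),
                                 support_b = unname(sb[shared]),
                                 stringsAsFactors = FALSE),
      unique_to_a = ua, unique_to_b = ub
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance_report: RF = %d (normalized %.3f) on %d leaves\n",
              x$rf, x$normalized_rf, x$n_leaves))
  cat(sprintf("  shared clades: %d; unique to A: %d; unique to B: %d\n",
              nrow(x$shared_clades), length(x$unique_to_a),
              length(x$unique_to_b)))
  invisible(x)
}

#' Collapse near-zero branches into polytopies
#'
#' Internal branches shorter than `tol` carry no signal (e.g. the arbitrary
#' resolution of identical samples) and are collapsed before topology
#' comparison. Thin wrapper over [ape::di2multi()].
#'
#' @param tree an [ape::phylo] tree.
#' @param tol branch-length tolerance, default `1e-10`.
#' @return the collapsed tree.
#' @export
collapse_zero_branches <- function(tree, tol = 1e-10) {
  ape::di2multi(tree, tol = tol)
}
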