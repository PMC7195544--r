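# run code with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Neighbor-joining tree with site-resampling bootstrap support
#'
#' Builds the main NJ tree from the full matrix, then resamples sites with
#' replacement `replicates` times, rebuilds the tree each time, and scores
#' every internal bipartition of the main tree by the percentage of
#' replicates containing it. Runs with the same seed are exactly
#' reproducible.
#'
#' @param m a `genotype_matrix` with at least 3 samples.
#' @param replicates number of bootstrap replicates, default 500.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @param keep_replicates also return the replicate trees? Default `FALSE`.
#' @return a `bootstrap_result`: list with `main_tree` (an [ape::phylo] with
#'   `node.label` supports), `supports` (named numeric vector in `[0, 100]`
#'   keyed by split), `replicates`, and optionally `replicate_trees`.
#' @export
bootstrap_trees <- function(m, replicates = 500L, seed = NULL,
                            keep_replicates = FALSE) {
  stopifnot(replicates >= 1L)
  nt <- nrow(m$sites)
  if (nt == 0L) stop("empty matrix")
  main <- nj_tree(pdistance_matrix(m))
  main_keys <- tree_splits(main)
  counts <- setNames(integer(length(main_keys)), main_keys)
  rep_trees <- if (keep_replicates) vector("list", replicates) else NULL

  with_seed(seed, {
    for (r in seq_len(replicates)) {
      idx <- sample.int(nt, nt, replace = TRUE)
      tr <- nj_tree(pdistance_core(m$geno[, idx, drop = FALSE], m$samples))
      keys <- tree_splits(tr)
      hit <- main_keys %in% keys
      counts[hit] <- counts[hit] + 1L
      if (keep_replicates) rep_trees[[r]] <- tr
    }
  })

  supports <- 100 * counts / replicates
  # attach supports as node labels of the main tree (prop.part node order)
  leaves <- main$tip.label
  pp <- ape::prop.part(main)
  labs <- rep("", main$Nnode)
  for (i in seq_along(pp)) {
    side <- leaves[pp[[i]]]
    if (length(side) < 2L || length(side) > length(leaves) - 2L) next
    labs[i] <- format(supports[split_key(side, leaves)])
  }
  main$node.label <- labs
  structure(
    list(main_tree = main, supports = supports, replicates = replicates,
         replicate_trees = rep_trees),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: %d replicates, %d internal splits\n",
              x$replicates, length(x$supports)))
  cat(sprintf("  support range: %.1f-%.1f%%\n",
              if (length(x$supports)) min(x$supports) else NA,
              if (length(x$supports)) max(x$supports) else NA))
  invisible(x)
}

#' Topology concordance across several genotype matrices
#'
#' The cross-assembly / cross-setting comparison: restricts all matrices to
#' their shared samples, builds a bootstrapped NJ tree per matrix, and
#' reports pairwise Robinson-Foulds concordance plus a summary (RF,
#' normalized RF, number of shared clades with support at least 80 in both
#' trees).
#'
#' @param matrices named list of at least two `genotype_matrix` objects
#'   sharing at least 3 samples.
#' @param replicates bootstrap replicates per matrix, default 100.
#' @param seed optional integer seed.
#' @return a `concordance_suite`: list with `trees` (named list of
#'   `bootstrap_result`), `reports` (named list of `concordance_report`,
#'   names `"a|b"`), `summary` (data frame), `shared_samples`.
#' @export
concordance_suite <- function(matrices, replicates = 100L, seed = NULL) {
  stopifnot(is.list(matrices), length(matrices) >= 2L,
            !is.null(names(matrices)))
  shared <- Reduce(intersect, lapply(matrices, `[[`, "samples"))
  if (length(shared) < 3L)
    stop(sprintf("only %d sample(s) shared across matrices; need at least 3",
                 length(shared)))
  shared <- sort(shared)
  boots <- vector("list", length(matrices))
  names(boots) <- names(matrices)
  for (k in seq_along(matrices)) {
    boots[[k]] <- bootstrap_trees(matrices[[k]][shared, ],
                                  replicates = replicates,
                                  seed = if (is.null(seed)) NULL else seed + k)
  }
  combos <- combn(names(matrices), 2L)
  reports <- vector("list", ncol(combos))
  rows <- vector("list", ncol(combos))
  for (k in seq_len(ncol(combos))) {
    a <- combos[1, k]; b <- combos[2, k]
    rep_k <- rf_distance(boots[[a]]$main_tree, boots[[b]]$main_tree)
    reports[[k]] <- rep_k
    strong <- with(rep_k$shared_clades,
                   sum(!is.na(support_a) & !is.na(support_b) &
                         support_a >= 80 & support_b >= 80))
    rows[[k]] <- data.frame(a = a, b = b, rf = rep_k$rf,
                            normalized_rf = rep_k$normalized_rf,
                            shared_clades = nrow(rep_k$shared_clades),
                            shared_clades_ge80 = strong,
                            stringsAsFactors = FALSE)
  }
  names(reports) <- paste(combos[1, ], combos[2, ], sep = "|")
  structure(
    list(trees = boots, reports = reports,
         summary = do.call(rbind, rows), shared_samples = shared),
    class = "concordance_suite"
  )
}

#' @export
print.concordance_suite <- function(x, ...) {
  cat(sprintf("concordance_suite: %d matrices, %d shared samples\n",
              length(x$trees), length(x$shared_samples)))
  print.data.frame(x$summary, row.names = FALSE)
  invisible(x)
}
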