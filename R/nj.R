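#' Neighbor-joining tree with deterministic tie-breaking
#'
#' Standard neighbor-joining agglomeration (Saitou-Nei with the usual
#' Q-criterion). Two behaviors are pinned down so that runs are exactly
#' reproducible: ties in the Q-criterion resolve toward the pair of clusters
#' whose (sorted) representative taxon labels are lexicographically
#' smallest, and negative branch lengths are clamped to zero with the total
#' deficit recorded in the `clamp_deficit` attribute. On an additive
#' distance matrix the output tree's path-length metric reproduces the input
#' exactly (the classical NJ consistency guarantee).
#'
#' @param d symmetric numeric matrix with zero diagonal and taxon labels as
#'   dimnames; at least 3 taxa, no `NA`/`NaN`/negative entries.
#' @return an unrooted [ape::phylo] tree (basal trifurcation); attribute
#'   `clamp_deficit` holds the summed absolute value of clamped negative
#'   branch lengths (0 when none).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (any(!is.finite(d))) stop("distance matrix contains NA/NaN/Inf")
  if (any(d < 0)) stop("distance matrix contains negative entries")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  labels <- rownames(d)

  nwk <- labels                # newick fragment per active cluster
  rep_lab <- labels            # representative (minimum) taxon label
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit + abs(x); 0 } else x
  }
  fmt <- function(x) sprintf("%.15g", x)

  while (nrow(d) > 3L) {
    k <- nrow(d)
    r <- rowSums(d)
    q <- (k - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1L) {
      keys <- apply(cand, 1L, function(rc) {
        p <- sort(c(rep_lab[rc[1]], rep_lab[rc[2]]))
        paste(p, collapse = "\r")
      })
      cand <- cand[order(keys)[1L], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))))
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    new_lab <- min(rep_lab[i], rep_lab[j])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    du <- du[-c(i, j)]
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, du), c(du, 0))
    nwk <- c(nwk[-c(i, j)], new_nwk)
    rep_lab <- c(rep_lab[-c(i, j)], new_lab)
    rownames(d) <- colnames(d) <- rep_lab
  }

  if (nrow(d) == 3L) {
    l1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
    l2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
    l3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(l1), nwk[2], fmt(l2),
                   nwk[3], fmt(l3))
  }
  tree <- ape::read.tree(text = txt)
  attr(tree, "clamp_deficit") <- deficit
  tree
}
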