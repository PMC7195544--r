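# Fixtures and independent brute-force oracles used across the suite.
# Every oracle is written as the most literal possible restatement of the
# definition it checks, separate from the package's optimized code path.

BASES4 <- c("A", "C", "G", "T")

# deterministic random genotype matrix spread over a few contigs
rand_gm <- function(ns = 30, nt = 300, missing_rate = 0.15, seed = NULL,
                    n_contigs = 3) {
  if (!is.null(seed)) set.seed(seed)
  geno <- matrix(sample(c(0L, 1L, 2L), ns * nt, replace = TRUE,
                        prob = c(0.5, 0.2, 0.3)), ns, nt)
  geno[matrix(runif(ns * nt) < missing_rate, ns, nt)] <- NA_integer_
  depth <- matrix(rnbinom(ns * nt, size = 1.5, mu = 7) + 1L, ns, nt)
  contig <- sort(rep_len(sprintf("chr%02d", seq_len(n_contigs)), nt))
  pos <- unlist(lapply(split(seq_len(nt), contig), function(ix)
    sort(sample.int(50000L, length(ix)))), use.names = FALSE)
  sites <- data.frame(id = sprintf("s%04d", seq_len(nt)), contig = contig,
                      pos = pos, ref = "A", alt = "G", source = "reference",
                      stringsAsFactors = FALSE)
  genotype_matrix(geno, depth = depth, sites = sites,
                  samples = sprintf("ind%02d", seq_len(ns)))
}

# small matrix from an explicit genotype grid (rows = samples)
gm <- function(geno, depth = NULL, pos = seq_len(ncol(as.matrix(geno))),
               contig = "chr01", ref = "A", alt = "G") {
  geno <- as.matrix(geno)
  nt <- ncol(geno)
  sites <- data.frame(id = sprintf("s%03d", seq_len(nt)),
                      contig = rep_len(contig, nt), pos = pos,
                      ref = rep_len(ref, nt), alt = rep_len(alt, nt),
                      source = "reference", stringsAsFactors = FALSE)
  genotype_matrix(geno, depth = depth, sites = sites,
                  samples = sprintf("S%02d", seq_len(nrow(geno))))
}

## ---- filter oracles: literal per-site / per-sample recounts ----

oracle_keep_samples <- function(m, max_missing) {
  keep <- character(0)
  for (s in m$samples) {
    frac <- mean(is.na(m$geno[s, ]))
    if (frac <= max_missing) keep <- c(keep, s)
  }
  keep
}

oracle_keep_site_missing <- function(m, max_missing) {
  keep <- character(0)
  for (j in seq_len(nrow(m$sites))) {
    frac <- sum(is.na(m$geno[, j])) / length(m$samples)
    if (frac <= max_missing) keep <- c(keep, m$sites$id[j])
  }
  keep
}

oracle_keep_maf <- function(m, min_maf) {
  keep <- character(0)
  for (j in seq_len(nrow(m$sites))) {
    g <- m$geno[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0L) next
    alt <- sum(g == 1L) + 2L * sum(g == 2L)
    p <- alt / (2 * length(g))
    if (min(p, 1 - p) >= min_maf) keep <- c(keep, m$sites$id[j])
  }
  keep
}

oracle_keep_het <- function(m, min_het, max_het = NULL) {
  keep <- character(0)
  for (j in seq_len(nrow(m$sites))) {
    g <- m$geno[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0L) next
    h <- sum(g == 1L) / length(g)
    ok <- h >= min_het && (is.null(max_het) || h <= max_het)
    if (ok) keep <- c(keep, m$sites$id[j])
  }
  keep
}

# returns list(keep = site ids with >= 1 surviving call, masked = count)
oracle_depth <- function(m, mode, value = NULL) {
  thr <- if (mode == "floor_mean") {
    ok <- !is.na(m$geno) & !is.na(m$depth)
    mean(m$depth[ok])
  } else value
  keep <- character(0); masked <- 0L
  for (j in seq_len(nrow(m$sites))) {
    alive <- 0L
    for (i in seq_along(m$samples)) {
      if (is.na(m$geno[i, j])) next
      d <- m$depth[i, j]
      bad <- !is.na(d) &&
        ((mode == "ceiling_value" && d > thr) ||
           (mode != "ceiling_value" && d < thr))
      if (bad) masked <- masked + 1L else alive <- alive + 1L
    }
    if (alive > 0L) keep <- c(keep, m$sites$id[j])
  }
  list(keep = keep, masked = masked, threshold = thr)
}

oracle_keep_invariant <- function(m) {
  keep <- character(0)
  for (j in seq_len(nrow(m$sites))) {
    g <- m$geno[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0L) next
    if (all(g == 0L) || all(g == 2L)) next
    keep <- c(keep, m$sites$id[j])
  }
  keep
}

oracle_prune <- function(m, min_dist) {
  keep <- character(0)
  n_miss <- colSums(is.na(m$geno))
  for (ct in unique(m$sites$contig)) {
    idx <- which(m$sites$contig == ct)
    idx <- idx[order(m$sites$pos[idx], n_miss[idx], m$sites$id[idx])]
    last <- -Inf
    for (i in idx) {
      if (m$sites$pos[i] - last >= min_dist) {
        keep <- c(keep, m$sites$id[i])
        last <- m$sites$pos[i]
      }
    }
  }
  sort(keep)
}

## ---- tag oracles ----

random_tag_seqs <- function(n, L = 64) {
  mat <- matrix(sample(BASES4, n * L, replace = TRUE), n, L)
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

as_tag_set <- function(seqs) collapse_tags(list(s1 = seqs))

# all-pairs Hamming distance via one-hot crossproducts; returns the pair
# set (indices into sort(unique(seqs))) at distance exactly 1
oracle_pairs_bf <- function(seqs) {
  u <- sort(unique(seqs))
  L <- nchar(u[1])
  mat <- matrix(unlist(strsplit(u, ""), use.names = FALSE), nrow = length(u),
                byrow = TRUE)
  S <- matrix(0L, length(u), length(u))
  for (b in BASES4) {
    I <- (mat == b) * 1L
    S <- S + tcrossprod(I)
  }
  D <- L - S
  hit <- which(D == 1L & upper.tri(D), arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  data.frame(a_idx = hit[, 1], b_idx = hit[, 2])
}

# exhaustive sliding-window Hamming scan over one reference string, both
# strands; returns per-tag hit table (start, strand, n_mismatch <= max_mm)
oracle_map_scan <- function(tag, ref_chars, max_mm = 3L) {
  L <- nchar(tag)
  n_win <- length(ref_chars) - L + 1L
  if (n_win < 1L) return(data.frame(start = integer(), strand = character(),
                                    n_mismatch = integer()))
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") tag else
      paste(rev(strsplit(chartr("ACGT", "TGCA", tag), "")[[1]]), collapse = "")
    tc <- strsplit(s, "")[[1]]
    mism <- integer(n_win)
    for (p in seq_len(L)) {
      mism <- mism + (ref_chars[p:(p + n_win - 1L)] != tc[p])
    }
    hit <- which(mism <= max_mm)
    if (length(hit))
      out[[strand]] <- data.frame(start = hit, strand = strand,
                                  n_mismatch = mism[hit],
                                  stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), strand = character(), n_mismatch = integer())
}

## ---- tree helpers ----

# random tree with additive (path-metric) distances
additive_instance <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# write a literal string to a temp file and return the path
textConnection_file <- function(txt) {
  f <- tempfile()
  writeLines(txt, f)
  f
}

balanced8_newick <- paste0(
  "(((sp1:0.25,sp2:0.25):0.25,(sp3:0.25,sp4:0.25):0.25):0.5,",
  "((sp5:0.25,sp6:0.25):0.25,(sp7:0.25,sp8:0.25):0.25):0.5);")
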