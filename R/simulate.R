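#' Configuration for the GBS read simulator
#'
#' The defaults emulate the data regime the toolkit targets: 64-bp
#' restriction-site tags, negative-binomial depth skew around a mean of 7
#' reads per sample and locus, 1% per-base sequencing error, and moderate
#' locus dropout. Genotypes are species-fixed by default (every sample of a
#' species is homozygous for its species' allele), which makes tree recovery
#' exact and testable; `polymorphism_rate` optionally makes a fraction of
#' variable loci segregate within the derived clade (heterozygous with
#' probability 1/2 per carrier).
#'
#' @param n_species number of species, default 8.
#' @param n_samples_per_species samples per species, default 3.
#' @param tree `"random_yule"` (a random birth-only ultrametric tree, scaled
#'   to height 1), a Newick string, or an [ape::phylo] object. Tip labels
#'   must be `sp1 ... spk` when a tree is supplied.
#' @param n_loci number of 64-bp tag loci, default 500.
#' @param tag_length tag length in bp, default 64.
#' @param mutation_rate per-site, per-unit-branch-length mutation rate,
#'   default 0.01 (with a height-1 tree most loci acquire one SNP; loci are
#'   infinite-sites, at most one SNP each).
#' @param mean_depth mean of the (untruncated) negative-binomial depth law,
#'   default 7. Per sample x locus, depth is drawn zero-truncated, so a locus
#'   present in a library yields at least one read and `missing_rate` is the
#'   single source of missing data.
#' @param depth_dispersion negative-binomial size parameter, default 1.5
#'   (smaller = more skewed).
#' @param error_rate per-base sequencing error probability, default 0.01,
#'   applied to the tag portion of each read.
#' @param missing_rate probability that a sample x locus combination drops
#'   out entirely (library failure), default 0.1.
#' @param polymorphism_rate fraction of variable loci that segregate within
#'   the derived clade, default 0 (species-fixed).
#' @param contig_gap gap in bp between consecutive tag windows on a contig,
#'   default 200 (so adjacent SNPs are never linked at the 128-bp rule).
#' @param loci_per_contig tag windows per reference contig, default 50.
#' @param barcode_length in-line barcode length, default 6.
#' @param seed optional integer seed; a seeded run is fully reproducible.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_species = 8L, n_samples_per_species = 3L,
                              tree = "random_yule", n_loci = 500L,
                              tag_length = 64L, mutation_rate = 0.01,
                              mean_depth = 7, depth_dispersion = 1.5,
                              error_rate = 0.01, missing_rate = 0.1,
                              polymorphism_rate = 0,
                              contig_gap = 200L, loci_per_contig = 50L,
                              barcode_length = 6L, seed = NULL) {
  stopifnot(n_species >= 2L, n_samples_per_species >= 1L, n_loci >= 1L,
            tag_length >= 4L, mutation_rate > 0, mean_depth > 0,
            depth_dispersion > 0, error_rate >= 0, error_rate < 1,
            missing_rate >= 0, missing_rate < 1,
            polymorphism_rate >= 0, polymorphism_rate <= 1,
            contig_gap >= 0L, loci_per_contig >= 1L, barcode_length >= 2L)
  if (4^barcode_length < 2L * n_species * n_samples_per_species)
    stop("infeasible config: barcode_length too short for the sample count")
  structure(as.list(environment()), class = "simulation_config")
}

BASES <- c("A", "C", "G", "T")

#' Simulate a GBS dataset with known truth
#'
#' Generates, fully seeded: (1) a species tree; (2) a synthetic reference of
#' non-overlapping tag windows; (3) one biallelic mutation per variable
#' locus, placed on a branch with probability proportional to branch length
#' (infinite-sites, ancestral allele in the reference); (4) diploid
#' genotypes per sample (species-fixed unless `polymorphism_rate > 0`);
#' (5) per sample x locus read depths (negative binomial), binomial allele
#' split for heterozygotes, per-base errors, and whole-locus dropout; and
#' (6) barcoded reads. The number of emitted reads always equals the sum of
#' drawn depths.
#'
#' @param config a [simulation_config()].
#' @return a `gbs_simulation`: list with `reads` (data frame `read_id`,
#'   `sequence`, `quality`), `key` (a [barcode_key()]), and `truth`: list of
#'   `tree` (sample-level [ape::phylo]; samples of a species attached as a
#'   zero-length polytomy), `species_tree`, `genotypes` (complete, error-free
#'   `genotype_matrix` over the variable loci), `loci` (per-locus table incl.
#'   ancestral/derived window sequences), `reference` (named character
#'   vector), and `config`.
#' @export
simulate_gbs <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_gbs_impl(config))
}

simulate_gbs_impl <- function(cf) {
  L <- cf$tag_length
  n_sp <- cf$n_species
  sp <- sprintf("sp%d", seq_len(n_sp))

  ## 1. species tree, scaled to height 1
  if (inherits(cf$tree, "phylo")) {
    sp_tree <- cf$tree
  } else if (identical(cf$tree, "random_yule")) {
    sp_tree <- ape::rphylo(n_sp, birth = 1, death = 0)
    sp_tree$tip.label <- sp
  } else {
    sp_tree <- ape::read.tree(text = cf$tree)
  }
  if (!setequal(sp_tree$tip.label, sp))
    stop("species tree tips must be ", paste(sp, collapse = ", "))
  ht <- max(ape::node.depth.edgelength(sp_tree))
  sp_tree$edge.length <- sp_tree$edge.length / ht

  samples <- as.vector(t(outer(sp, seq_len(cf$n_samples_per_species),
                               function(s, i) paste0(s, "_", i))))
  sample_sp <- rep(sp, each = cf$n_samples_per_species)

  ## 2. reference: non-overlapping tag windows, contig_gap apart
  n_contig <- ceiling(cf$n_loci / cf$loci_per_contig)
  locus_contig <- rep(seq_len(n_contig), each = cf$loci_per_contig)[seq_len(cf$n_loci)]
  locus_rank <- sequence(tabulate(locus_contig))
  win_start <- 1L + (locus_rank - 1L) * (L + cf$contig_gap)
  contig_names <- sprintf("contig%02d", seq_len(n_contig))
  contig_len <- vapply(seq_len(n_contig), function(ci) {
    max(win_start[locus_contig == ci]) + L - 1L + cf$contig_gap
  }, integer(1))
  reference <- vapply(contig_len, function(len) {
    paste(sample(BASES, len, replace = TRUE), collapse = "")
  }, character(1))
  names(reference) <- contig_names

  ## 3. mutations: at most one SNP per tag, branch chosen by length
  total_len <- sum(sp_tree$edge.length)
  p_var <- 1 - exp(-cf$mutation_rate * L * total_len)
  variable <- runif(cf$n_loci) < p_var
  edge_of <- sample.int(nrow(sp_tree$edge), cf$n_loci, replace = TRUE,
                        prob = sp_tree$edge.length)
  # species below each edge
  desc <- lapply(seq_len(nrow(sp_tree$edge)), function(e) {
    node <- sp_tree$edge[e, 2]
    if (node <= n_sp) sp_tree$tip.label[node]
    else sp_tree$tip.label[ape::prop.part(sp_tree)[[node - n_sp]]]
  })
  snp_offset <- sample.int(L, cf$n_loci, replace = TRUE)
  anc_allele <- vapply(seq_len(cf$n_loci), function(l) {
    substr(reference[locus_contig[l]],
           win_start[l] + snp_offset[l] - 1L,
           win_start[l] + snp_offset[l] - 1L)
  }, character(1))
  der_allele <- vapply(anc_allele, function(a) sample(setdiff(BASES, a), 1L),
                       character(1), USE.NAMES = FALSE)
  polymorphic <- variable & (runif(cf$n_loci) < cf$polymorphism_rate)

  ## 4. genotypes at variable loci (0 = ancestral hom, 2 = derived hom)
  var_idx <- which(variable)
  ns <- length(samples)
  geno <- matrix(0L, ns, length(var_idx),
                 dimnames = list(samples, NULL))
  for (k in seq_along(var_idx)) {
    l <- var_idx[k]
    carrier <- sample_sp %in% desc[[edge_of[l]]]
    g <- ifelse(carrier, 2L, 0L)
    if (polymorphic[l]) {
      het <- carrier & (runif(ns) < 0.5)
      g[het] <- 1L
    }
    geno[, k] <- g
  }
  truth_sites <- data.frame(
    id = sprintf("locus%04d", var_idx),
    contig = contig_names[locus_contig[var_idx]],
    pos = win_start[var_idx] + snp_offset[var_idx] - 1L,
    ref = anc_allele[var_idx], alt = der_allele[var_idx],
    source = "reference", stringsAsFactors = FALSE
  )
  truth_matrix <- genotype_matrix(geno, sites = truth_sites, samples = samples)

  ## window sequences per allele
  anc_window <- vapply(seq_len(cf$n_loci), function(l) {
    substr(reference[locus_contig[l]], win_start[l], win_start[l] + L - 1L)
  }, character(1))
  der_window <- anc_window
  substr(der_window, snp_offset, snp_offset) <- der_allele
  loci <- data.frame(
    locus = seq_len(cf$n_loci), contig = contig_names[locus_contig],
    window_start = win_start, snp_offset = snp_offset,
    snp_pos = win_start + snp_offset - 1L,
    variable = variable, polymorphic = polymorphic,
    anc_allele = anc_allele, der_allele = der_allele,
    anc_window = anc_window, der_window = der_window,
    stringsAsFactors = FALSE
  )

  ## sample-level true tree: species tips expanded into zero-length polytomies
  txt <- ape::write.tree(sp_tree)
  if (cf$n_samples_per_species > 1L) {
    for (s in sp) {
      reps <- paste0(s, "_", seq_len(cf$n_samples_per_species), ":0")
      txt <- sub(paste0(s, ":"), paste0("(", paste(reps, collapse = ","), "):"),
                 txt, fixed = TRUE)
    }
  } else {
    for (s in sp) txt <- sub(paste0(s, ":"), paste0(s, "_1:"), txt, fixed = TRUE)
  }
  sample_tree <- ape::read.tree(text = txt)

  ## 5-6. reads
  key <- barcode_key(samples, make_barcodes(ns, cf$barcode_length))
  # zero-truncated negative binomial: a locus present in a library yields at
  # least one read; absence is governed solely by missing_rate
  p0 <- stats::dnbinom(0, size = cf$depth_dispersion, mu = cf$mean_depth)
  depth <- matrix(stats::qnbinom(runif(ns * cf$n_loci, min = p0, max = 1),
                                 size = cf$depth_dispersion,
                                 mu = cf$mean_depth),
                  ns, cf$n_loci)
  storage.mode(depth) <- "integer"
  dropout <- matrix(runif(ns * cf$n_loci) < cf$missing_rate, ns, cf$n_loci)
  depth[dropout] <- 0L

  # genotype per sample x locus over ALL loci (invariant loci: all 0)
  geno_all <- matrix(0L, ns, cf$n_loci)
  geno_all[, var_idx] <- geno
  # derived-allele read counts: hom anc 0, hom der all, het ~ Binom(d, 1/2)
  der_reads <- matrix(0L, ns, cf$n_loci)
  der_reads[geno_all == 2L] <- depth[geno_all == 2L]
  het_cells <- which(geno_all == 1L)
  if (length(het_cells))
    der_reads[het_cells] <- rbinom(length(het_cells), depth[het_cells], 0.5)
  anc_reads <- depth - der_reads

  cell <- which(depth > 0L, arr.ind = TRUE)
  # emit ancestral-allele reads then derived-allele reads per cell
  n_anc <- anc_reads[cell]; n_der <- der_reads[cell]
  seq_anc <- rep(anc_window[cell[, 2]], n_anc)
  seq_der <- rep(der_window[cell[, 2]], n_der)
  samp_of <- c(rep(cell[, 1], n_anc), rep(cell[, 1], n_der))
  locus_of <- c(rep(cell[, 2], n_anc), rep(cell[, 2], n_der))
  tag_seq <- c(seq_anc, seq_der)
  if (cf$error_rate > 0 && length(tag_seq))
    tag_seq <- inject_errors(tag_seq, cf$error_rate)
  reads <- data.frame(
    read_id = sprintf("sim_%s_l%04d_r%07d", samples[samp_of], locus_of,
                      seq_along(tag_seq)),
    sequence = paste0(key$barcode[samp_of], tag_seq),
    quality = strrep("I", cf$barcode_length + L),
    stringsAsFactors = FALSE
  )

  structure(
    list(
      reads = reads, key = key,
      truth = list(tree = sample_tree, species_tree = sp_tree,
                   genotypes = truth_matrix, loci = loci,
                   reference = reference, depth_drawn = sum(depth),
                   config = cf)
    ),
    class = "gbs_simulation"
  )
}

# distinct fixed-length barcodes (same length => mutually prefix-free)
make_barcodes <- function(n, len) {
  pool <- character(0)
  while (length(pool) < n) {
    cand <- vapply(seq_len(2L * n), function(i)
      paste(sample(BASES, len, replace = TRUE), collapse = ""), character(1))
    pool <- unique(c(pool, cand))
  }
  pool[seq_len(n)]
}

# substitute bases at rate e (uniform over the three alternatives)
inject_errors <- function(seqs, e) {
  L <- nchar(seqs[1])
  n <- length(seqs)
  mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE), nrow = n,
                byrow = TRUE)
  hit <- which(matrix(runif(n * L) < e, n, L))
  if (length(hit)) {
    old <- match(mat[hit], BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    mat[hit] <- BASES[((old - 1L + shift) %% 4L) + 1L]
  }
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

#' @export
print.gbs_simulation <- function(x, ...) {
  cf <- x$truth$config
  cat(sprintf("gbs_simulation: %d reads, %d samples (%d species), %d/%d variable loci\n",
              nrow(x$reads), length(x$key$sample_id), cf$n_species,
              sum(x$truth$loci$variable), cf$n_loci))
  invisible(x)
}

#' Inject physically linked SNP pairs into a simulated truth matrix
#'
#' Appends `n_pairs` pairs of biallelic sites, each pair on its own fresh
#' contig with the two members `spacing_bp` apart, and records which member
#' a correct linkage pruning at a threshold above `spacing_bp` must remove
#' (the second of each pair under greedy left-to-right thinning with equal
#' missingness). Site genotypes follow a random species split of the
#' simulated tree so the injected sites look like ordinary SNPs to every
#' other filter.
#'
#' @param sim a `gbs_simulation` from [simulate_gbs()].
#' @param n_pairs number of linked pairs to add.
#' @param spacing_bp distance between pair members; must be smaller than the
#'   simulation's `contig_gap` (otherwise the pair would be no closer than
#'   ordinary neighboring loci, and an error is raised).
#' @return the modified `gbs_simulation`; `truth$genotypes` gains `2 *
#'   n_pairs` sites and `truth$linked_expected_removed` lists the site ids
#'   pruning must remove.
#' @export
inject_linked_pairs <- function(sim, n_pairs, spacing_bp) {
  stopifnot(inherits(sim, "gbs_simulation"), n_pairs >= 0L)
  cf <- sim$truth$config
  if (spacing_bp >= cf$contig_gap)
    stop(sprintf("spacing_bp (%d) must be below the simulation's contig gap (%d)",
                 spacing_bp, cf$contig_gap))
  if (n_pairs == 0L) {
    sim$truth$linked_expected_removed <- character(0)
    return(sim)
  }
  m <- sim$truth$genotypes
  ns <- length(m$samples)
  sp_tree <- sim$truth$species_tree
  n_sp <- length(sp_tree$tip.label)
  sample_sp <- sub("_[0-9]+$", "", m$samples)
  desc <- lapply(seq_len(nrow(sp_tree$edge)), function(e) {
    node <- sp_tree$edge[e, 2]
    if (node <= n_sp) sp_tree$tip.label[node]
    else sp_tree$tip.label[ape::prop.part(sp_tree)[[node - n_sp]]]
  })
  geno2 <- matrix(0L, ns, 2L * n_pairs)
  sites2 <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    e <- sample.int(length(desc), 1L)
    carrier <- sample_sp %in% desc[[e]]
    g <- ifelse(carrier, 2L, 0L)
    geno2[, 2L * k - 1L] <- g
    geno2[, 2L * k] <- g
    p1 <- 1000L
    sites2[[k]] <- data.frame(
      id = sprintf("link%03d_%s", k, c("a", "b")),
      contig = sprintf("linked%03d", k),
      pos = c(p1, p1 + as.integer(spacing_bp)),
      ref = "A", alt = "G", source = "reference",
      stringsAsFactors = FALSE
    )
  }
  sites2 <- do.call(rbind, sites2)
  sim$truth$genotypes <- gm_bind_sites(m, geno2,
                                       matrix(NA_integer_, ns, 2L * n_pairs),
                                       matrix(NA_real_, ns, 2L * n_pairs),
                                       sites2)
  sim$truth$linked_expected_removed <- sprintf("link%03d_b", seq_len(n_pairs))
  sim
}

#' Match called de novo or reference sites to the simulated truth
#'
#' De novo sites are matched by their tag-pair sequences against the
#' ancestral/derived window sequences of each simulated locus; reference
#' sites are matched by contig and position. The returned map records, per
#' matched site, whether its allele orientation is flipped relative to the
#' truth (de novo sites are oriented by observed major allele, the truth by
#' the ancestral allele); apply [relabel_alleles()] to the flipped sites
#' before any cell-by-cell comparison.
#'
#' @param m a called `genotype_matrix`.
#' @param truth the `truth` element of a `gbs_simulation`.
#' @return data frame with columns `site` (id in `m`), `locus` (simulated
#'   locus index), `truth_id` (site id in `truth$genotypes`), `flip`
#'   (logical). Unmatched sites are absent.
#' @export
match_sites_to_truth <- function(m, truth) {
  loci <- truth$loci
  var <- loci[loci$variable, , drop = FALSE]
  if (all(m$sites$source == "denovo") && !is.null(m$sites$tag_major)) {
    keys_anc <- var$anc_window
    keys_der <- var$der_window
    maj <- m$sites$tag_major; mnr <- m$sites$tag_minor
    hit_fwd <- match(maj, keys_anc)        # major is ancestral
    hit_rev <- match(maj, keys_der)        # major is derived (flip)
    rows <- lapply(seq_len(nrow(m$sites)), function(j) {
      if (!is.na(hit_fwd[j]) && mnr[j] == keys_der[hit_fwd[j]]) {
        data.frame(site = m$sites$id[j], locus = var$locus[hit_fwd[j]],
                   flip = FALSE, stringsAsFactors = FALSE)
      } else if (!is.na(hit_rev[j]) && mnr[j] == keys_anc[hit_rev[j]]) {
        data.frame(site = m$sites$id[j], locus = var$locus[hit_rev[j]],
                   flip = TRUE, stringsAsFactors = FALSE)
      } else NULL
    })
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  } else {
    key_m <- paste(m$sites$contig, m$sites$pos)
    key_t <- paste(var$contig, var$snp_pos)
    hit <- match(key_m, key_t)
    ok <- !is.na(hit)
    out <- data.frame(site = m$sites$id[ok], locus = var$locus[hit[ok]],
                      flip = m$sites$ref[ok] != var$anc_allele[hit[ok]],
                      stringsAsFactors = FALSE)
  }
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(site = character(), locus = integer(),
                      truth_id = character(), flip = logical()))
  out$truth_id <- sprintf("locus%04d", out$locus)
  rownames(out) <- NULL
  out
}
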