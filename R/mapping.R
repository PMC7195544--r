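# coerce a reference (named character vector, DNAStringSet, or FASTA path)
# to a DNAStringSet
as_reference <- function(reference) {
  if (is(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference) && !grepl("^[ACGTN]+$", reference)) {
    return(Biostrings::readDNAStringSet(reference))
  }
  if (is.character(reference)) {
    if (is.null(names(reference)))
      names(reference) <- sprintf("contig%02d", seq_along(reference))
    return(Biostrings::DNAStringSet(reference))
  }
  stop("reference must be a FASTA path, a named character vector, or a DNAStringSet")
}

#' Place tags on a reference genome by unique-best ungapped alignment
#'
#' Searches each tag on both strands of every contig for ungapped placements
#' with at most `max_mismatch` mismatches. A tag is kept only when it has
#' exactly one placement at its minimum mismatch count; ties at the minimum
#' make it a multimapper, which is discarded, and tags with no placement are
#' unaligned. The kept/unaligned/multimapped fractions always sum to one over
#' the input tags.
#'
#' @param tags a `tag_set` from [collapse_tags()].
#' @param reference FASTA path, named character vector of contig sequences,
#'   or `DNAStringSet`.
#' @param max_mismatch maximum mismatches allowed per placement, default 3.
#' @return a `tag_placements` object: data frame with columns `tag_idx`,
#'   `tag`, `aligned_seq` (tag in reference orientation), `contig`, `start`
#'   (1-based), `strand`, `n_mismatch`, plus a `mismatches` list column of
#'   per-placement data frames (`offset` on the reference window, `ref`,
#'   `obs`). Attributes: `stats` (named fractions `kept_frac`,
#'   `unaligned_frac`, `multimapped_frac`), `tag_set`, `reference`.
#' @export
map_tags <- function(tags, reference, max_mismatch = 3L) {
  stopifnot(inherits(tags, "tag_set"))
  ref <- as_reference(reference)
  if (length(ref) == 0L || sum(Biostrings::width(ref)) == 0L)
    stop("reference is empty")
  L <- tags$length
  n <- length(tags$sequences)
  contig_names <- names(ref)
  ref_chars <- lapply(seq_along(ref), function(i) {
    strsplit(as.character(ref[[i]]), "")[[1]]
  })

  res <- vector("list", n)
  status <- character(n)
  for (t in seq_len(n)) {
    pat_f <- Biostrings::DNAString(tags$sequences[t])
    pat_r <- Biostrings::reverseComplement(pat_f)
    hits <- list()
    for (ci in seq_along(ref)) {
      subj <- ref[[ci]]
      if (length(subj) < L) next
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") pat_f else pat_r
        mt <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
        if (length(mt) == 0L) next
        st <- Biostrings::start(mt)
        # matchPattern with max.mismatch can return out-of-bounds starts when
        # indels are off but edges overlap; restrict to full-length windows
        ok <- st >= 1L & st + L - 1L <= length(subj)
        st <- st[ok]
        if (length(st) == 0L) next
        ned <- Biostrings::neditStartingAt(pat, subj, starting.at = st)
        hits[[length(hits) + 1L]] <- data.frame(
          contig = contig_names[ci], start = st, strand = strand,
          n_mismatch = ned, stringsAsFactors = FALSE
        )
      }
    }
    if (length(hits) == 0L) { status[t] <- "unaligned"; next }
    h <- do.call(rbind, hits)
    h <- h[h$n_mismatch <= max_mismatch, , drop = FALSE]
    if (nrow(h) == 0L) { status[t] <- "unaligned"; next }
    best <- h[h$n_mismatch == min(h$n_mismatch), , drop = FALSE]
    if (nrow(best) > 1L) { status[t] <- "multimapped"; next }
    status[t] <- "kept"
    best$tag_idx <- t
    res[[t]] <- best
  }

  kept <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(kept)) {
    kept <- data.frame(contig = character(), start = integer(),
                       strand = character(), n_mismatch = integer(),
                       tag_idx = integer(), stringsAsFactors = FALSE)
  }
  aligned <- character(nrow(kept))
  mismatches <- vector("list", nrow(kept))
  for (k in seq_len(nrow(kept))) {
    tseq <- tags$sequences[kept$tag_idx[k]]
    aseq <- if (kept$strand[k] == "+") tseq else revcomp(tseq)
    aligned[k] <- aseq
    ci <- match(kept$contig[k], contig_names)
    win <- ref_chars[[ci]][kept$start[k]:(kept$start[k] + L - 1L)]
    obs <- strsplit(aseq, "")[[1]]
    d <- which(win != obs)
    mismatches[[k]] <- data.frame(offset = d, ref = win[d], obs = obs[d],
                                  stringsAsFactors = FALSE)
  }
  out <- data.frame(
    tag_idx = kept$tag_idx, tag = tags$sequences[kept$tag_idx],
    aligned_seq = aligned, contig = kept$contig, start = kept$start,
    strand = kept$strand, n_mismatch = kept$n_mismatch,
    stringsAsFactors = FALSE
  )
  out$mismatches <- mismatches
  ord <- order(out$contig, out$start, out$tag)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  n_in <- max(n, 1L)
  attr(out, "stats") <- c(
    kept_frac = sum(status == "kept") / n_in,
    unaligned_frac = sum(status == "unaligned") / n_in,
    multimapped_frac = sum(status == "multimapped") / n_in
  )
  attr(out, "tag_set") <- tags
  attr(out, "reference") <- ref
  class(out) <- c("tag_placements", class(out))
  out
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Derive candidate SNP sites from tag placements
#'
#' Scans every reference position covered by at least one placed tag. Where
#' placed tags disagree with the reference or with each other, the observed
#' allele set is `{reference base} U {tag bases}`: if it has exactly two
#' members a biallelic candidate site is emitted; positions with three or
#' more alleles are discarded and counted.
#'
#' @param placements a `tag_placements` object from [map_tags()].
#' @return a `candidate_sites` data frame with columns `contig`, `pos`
#'   (1-based), `ref`, `alt`, and a list column `obs` giving, per site, the
#'   covering placements (`tag_idx`, `base`). Attributes: `triallelic_count`,
#'   `tag_set`.
#' @export
placements_to_sites <- function(placements) {
  stopifnot(inherits(placements, "tag_placements"))
  tags <- attr(placements, "tag_set")
  L <- tags$length
  mm <- placements$mismatches
  n_mm <- vapply(mm, nrow, integer(1))
  if (sum(n_mm) == 0L) {
    out <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
    out$obs <- list()
    attr(out, "triallelic_count") <- 0L
    attr(out, "tag_set") <- tags
    class(out) <- c("candidate_sites", class(out))
    return(out)
  }
  var_pos <- unique(data.frame(
    contig = rep(placements$contig, n_mm),
    pos = rep(placements$start, n_mm) +
      unlist(lapply(mm, `[[`, "offset"), use.names = FALSE) - 1L,
    ref = unlist(lapply(mm, `[[`, "ref"), use.names = FALSE),
    stringsAsFactors = FALSE
  ))
  var_pos <- var_pos[order(var_pos$contig, var_pos$pos), , drop = FALSE]

  contigs <- split(seq_len(nrow(placements)), placements$contig)
  rows <- vector("list", nrow(var_pos))
  triallelic <- 0L
  for (v in seq_len(nrow(var_pos))) {
    ct <- var_pos$contig[v]; p <- var_pos$pos[v]; rb <- var_pos$ref[v]
    pl <- contigs[[ct]]
    cover <- pl[placements$start[pl] <= p & p <= placements$start[pl] + L - 1L]
    base <- substr(placements$aligned_seq[cover],
                   p - placements$start[cover] + 1L,
                   p - placements$start[cover] + 1L)
    alleles <- union(rb, unique(base))
    if (length(alleles) > 2L) { triallelic <- triallelic + 1L; next }
    alt <- setdiff(alleles, rb)
    rows[[v]] <- list(contig = ct, pos = p, ref = rb, alt = alt,
                      obs = data.frame(tag_idx = placements$tag_idx[cover],
                                       base = base, stringsAsFactors = FALSE))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- data.frame(
    contig = vapply(rows, `[[`, character(1), "contig"),
    pos = vapply(rows, `[[`, integer(1), "pos"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"),
    stringsAsFactors = FALSE
  )
  out$obs <- lapply(rows, `[[`, "obs")
  attr(out, "triallelic_count") <- triallelic
  attr(out, "tag_set") <- tags
  class(out) <- c("candidate_sites", class(out))
  out
}
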