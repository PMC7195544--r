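#' Demultiplex barcoded reads and trim to fixed-length tags
#'
#' Assigns each read to a sample by the longest barcode matching the read
#' prefix, then keeps the `tag_length` bases immediately after the barcode.
#' Reads matching no barcode, reads with fewer than `tag_length` bases after
#' the barcode, and reads with an `N` inside the kept window are discarded
#' and counted by reason.
#'
#' @param reads data frame of reads (`read_id`, `sequence`, ...), e.g. from
#'   [read_fastq()] or [simulate_gbs()].
#' @param key a [barcode_key()].
#' @param tag_length length of the retained tag, default 64.
#' @return list with `tags` (named list, per sample, of tag sequences in read
#'   order) and `discards` (named integer vector: `no_barcode`, `too_short`,
#'   `ambiguous_base`).
#' @export
demultiplex_and_trim <- function(reads, key, tag_length = 64L) {
  if (!inherits(key, "barcode_key")) key <- barcode_key(key$sample_id, key$barcode)
  if (nrow(key) == 0L) stop("empty barcode key")
  stopifnot(tag_length >= 1L)
  seqs <- toupper(reads$sequence)
  n <- length(seqs)
  assigned <- integer(n)        # 0 = unassigned
  assigned_len <- integer(n)
  ord <- order(nchar(key$barcode))  # longest barcode wins
  for (k in ord) {
    hit <- startsWith(seqs, key$barcode[k])
    assigned[hit] <- k
    assigned_len[hit] <- nchar(key$barcode[k])
  }
  no_barcode <- assigned == 0L
  window <- substr(seqs, assigned_len + 1L, assigned_len + tag_length)
  too_short <- !no_barcode & nchar(window) < tag_length
  has_n <- !no_barcode & !too_short & grepl("N", window, fixed = TRUE)
  keep <- !no_barcode & !too_short & !has_n
  tags <- split(window[keep], factor(key$sample_id[assigned[keep]],
                                     levels = key$sample_id))
  list(
    tags = tags,
    discards = c(no_barcode = sum(no_barcode), too_short = sum(too_short),
                 ambiguous_base = sum(has_n))
  )
}

#' Collapse identical reads into tags
#'
#' Clusters identical fixed-length sequences into tags and counts how often
#' each tag was read in each sample. The sum of all tag totals equals the
#' number of input sequences. Tags are stored in lexicographic order so the
#' result is independent of input order.
#'
#' @param sample_seqs named list (one element per sample) of equal-length
#'   sequences, e.g. the `tags` element of [demultiplex_and_trim()].
#' @return a `tag_set`: list with `sequences` (sorted character vector),
#'   `counts` (tags x samples integer matrix), `totals` (row sums) and
#'   `length` (the common sequence length).
#' @export
collapse_tags <- function(sample_seqs) {
  stopifnot(is.list(sample_seqs), !is.null(names(sample_seqs)))
  samples <- names(sample_seqs)
  all_seqs <- unlist(sample_seqs, use.names = FALSE)
  if (length(all_seqs)) {
    L <- unique(nchar(all_seqs))
    if (length(L) != 1L) stop("sequences are not all the same length")
  } else {
    L <- NA_integer_
  }
  sample_f <- factor(rep(samples, lengths(sample_seqs)), levels = samples)
  uniq <- sort(unique(all_seqs))
  if (length(uniq)) {
    counts <- table(factor(all_seqs, levels = uniq), sample_f)
    counts <- matrix(as.integer(counts), nrow = length(uniq),
                     dimnames = list(uniq, samples))
  } else {
    counts <- matrix(integer(0), nrow = 0L, ncol = length(samples),
                     dimnames = list(NULL, samples))
  }
  structure(
    list(sequences = uniq, counts = counts, totals = rowSums(counts),
         length = L),
    class = "tag_set"
  )
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("tag_set: %d tags of length %s across %d samples (%d reads)\n",
              length(x$sequences),
              ifelse(is.na(x$length), "?", x$length),
              ncol(x$counts), sum(x$totals)))
  invisible(x)
}

#' Find all tag pairs at Hamming distance one
#'
#' Two tags differing at exactly one position form a candidate biallelic SNP.
#' The search hashes each tag 64 ways (each position masked in turn), so tags
#' sharing a masked key differ only at the masked position; this equals the
#' all-pairs Hamming scan without the quadratic cost. Each unordered pair is
#' reported once, with `tag_a` the lexicographically smaller sequence.
#'
#' @param tags a `tag_set` from [collapse_tags()].
#' @return a `tag_pairs` data frame with columns `tag_a`, `tag_b`, `a_idx`,
#'   `b_idx`, `snp_offset` (1-based position of the mismatch), `allele_a`,
#'   `allele_b`, `total_a`, `total_b`; the originating `tag_set` is attached
#'   as attribute `tag_set`.
#' @export
pair_tags <- function(tags) {
  stopifnot(inherits(tags, "tag_set"))
  s <- tags$sequences
  n <- length(s)
  L <- tags$length
  a_idx <- integer(0); b_idx <- integer(0); off <- integer(0)
  if (n >= 2L) {
    for (p in seq_len(L)) {
      keys <- paste0(substr(s, 1L, p - 1L), "*", substr(s, p + 1L, L))
      dup <- duplicated(keys) | duplicated(keys, fromLast = TRUE)
      if (!any(dup)) next
      idx <- which(dup)
      groups <- split(idx, keys[idx])
      for (g in groups) {
        # tags in a group are identical except at position p => every pair is
        # at Hamming distance exactly 1
        cmb <- combn(g, 2L)
        a_idx <- c(a_idx, cmb[1L, ])
        b_idx <- c(b_idx, cmb[2L, ])
        off <- c(off, rep.int(p, ncol(cmb)))
      }
    }
  }
  # sequences are unique and sorted, so a_idx < b_idx means tag_a < tag_b
  out <- data.frame(
    tag_a = s[a_idx], tag_b = s[b_idx],
    a_idx = a_idx, b_idx = b_idx,
    snp_offset = off,
    allele_a = substr(s[a_idx], off, off),
    allele_b = substr(s[b_idx], off, off),
    total_a = unname(tags$totals[a_idx]),
    total_b = unname(tags$totals[b_idx]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$tag_a, out$tag_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tag_set") <- tags
  class(out) <- c("tag_pairs", class(out))
  out
}

#' Remove putative sequencing-error tag pairs
#'
#' Two rules, mirroring network-based error curation of de novo GBS
#' pipelines: (1) a pair whose rarer tag contributes less than `etr` of the
#' pair's combined read total is treated as a sequencing-error pair and
#' dropped; (2) unless `allow_complex`, any tag participating in more than
#' one surviving pair has all of its pairs dropped, so only reciprocal
#' one-to-one tag networks survive.
#'
#' @param pairs a `tag_pairs` data frame from [pair_tags()].
#' @param etr error-tolerance ratio in `[0, 0.5)`, default 0.03.
#' @param allow_complex keep tags involved in multiple pairs? Default `FALSE`.
#' @return the surviving `tag_pairs`, with attribute `network_filter_report`
#'   (named integer vector: `dropped_error_ratio`, `dropped_complex`).
#' @export
network_error_filter <- function(pairs, etr = 0.03, allow_complex = FALSE) {
  stopifnot(etr >= 0, etr < 0.5)
  ratio <- pmin(pairs$total_a, pairs$total_b) /
    (pairs$total_a + pairs$total_b)
  keep1 <- ratio >= etr
  dropped_err <- sum(!keep1)
  out <- pairs[keep1, , drop = FALSE]
  dropped_cx <- 0L
  if (!allow_complex && nrow(out) > 0L) {
    deg <- table(c(out$a_idx, out$b_idx))
    multi <- as.integer(names(deg)[deg > 1L])
    drop2 <- out$a_idx %in% multi | out$b_idx %in% multi
    dropped_cx <- sum(drop2)
    out <- out[!drop2, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "tag_set") <- attr(pairs, "tag_set")
  attr(out, "network_filter_report") <- c(dropped_error_ratio = dropped_err,
                                          dropped_complex = dropped_cx)
  class(out) <- c("tag_pairs", setdiff(class(out), "tag_pairs"))
  out
}

#' Dump a tag set as TSV
#'
#' @param tags a `tag_set`.
#' @param path output path; columns are `sequence`, `total`, then one count
#'   column per sample.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path) {
  df <- data.frame(sequence = tags$sequences, total = unname(tags$totals),
                   tags$counts, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
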