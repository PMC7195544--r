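#' Read a FASTQ file
#'
#' Parses a 4-line-per-record FASTQ file (optionally gzip-compressed) into a
#' data frame of read records. Qualities are kept as Phred+33 strings; use
#' [phred_scores()] to decode them to integer vectors.
#'
#' @param path path to a FASTQ or FASTQ.gz file.
#' @return data frame with columns `read_id`, `sequence`, `quality` and class
#'   `c("fastq_reads", "data.frame")`, in file order.
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4 (truncated record %d)",
                 path, n, n %/% 4L + 1L))
  if (n == 0L) {
    out <- data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE)
    class(out) <- c("fastq_reads", class(out))
    return(out)
  }
  ids <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(ids, "@"))
  if (length(bad))
    stop(sprintf("malformed FASTQ record %d: header does not start with '@'", bad[1]))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("malformed FASTQ record %d: separator line does not start with '+'", bad[1]))
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop(sprintf("malformed FASTQ record %d: sequence and quality lengths differ (%d vs %d)",
                 bad[1], nchar(seqs[bad[1]]), nchar(quals[bad[1]])))
  out <- data.frame(
    read_id = sub("^@", "", ids),
    sequence = toupper(seqs),
    quality = quals,
    stringsAsFactors = FALSE
  )
  class(out) <- c("fastq_reads", class(out))
  out
}

#' Write reads as FASTQ
#'
#' @param reads data frame with columns `read_id`, `sequence`, `quality`
#'   (Phred+33 strings), e.g. from [read_fastq()] or [simulate_gbs()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stop("sequence and quality lengths differ")
  n <- nrow(reads)
  lines <- character(4L * n)
  if (n) {
    lines[seq(1L, 4L * n, by = 4L)] <- paste0("@", reads$read_id)
    lines[seq(2L, 4L * n, by = 4L)] <- reads$sequence
    lines[seq(3L, 4L * n, by = 4L)] <- "+"
    lines[seq(4L, 4L * n, by = 4L)] <- reads$quality
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Decode Phred+33 quality strings
#'
#' @param quality character vector of Phred+33 quality strings.
#' @return list of integer vectors of per-base quality scores.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}
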