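#' Write a genotype matrix as VCF 4.2
#'
#' Emits one biallelic record per site with GT, DP and GQ per call; missing
#' calls are written as `./.`. Records are sorted by contig and position; if
#' the input sites were unsorted the writer sorts them and reports it with a
#' message. GQ is declared as a Float so that the 0.01-Phred precision used
#' by [call_genotype()] survives the round trip exactly. De novo sites, which
#' have no genomic position, are carried on their synthetic per-pair contigs.
#' The site `source` is preserved in the INFO field (`SRC=`).
#'
#' @param m a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path) {
  sites <- m$sites
  nt <- nrow(sites)
  ord <- order(sites$contig, sites$pos)
  if (is.unsorted(ord)) {
    message("write_vcf: sites were not position-sorted; sorting for output")
    m <- m[, ord]
    sites <- m$sites
  }
  contigs <- unique(sites$contig)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=gbsphylo-%s", as.character(packageVersion("gbsphylo"))),
    sprintf("##contig=<ID=%s>", contigs),
    "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Site provenance: denovo or reference\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Float,Description=\"Phred-scaled genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", m$samples), collapse = "\t")
  )
  gt <- matrix("./.", length(m$samples), nt)
  gt[!is.na(m$geno) & m$geno == 0L] <- "0/0"
  gt[!is.na(m$geno) & m$geno == 1L] <- "0/1"
  gt[!is.na(m$geno) & m$geno == 2L] <- "1/1"
  dp <- ifelse(is.na(m$depth), ".", as.character(m$depth))
  gq <- ifelse(is.na(m$gq), ".", sprintf("%.2f", m$gq))
  cell <- matrix(paste(gt, dp, gq, sep = ":"), length(m$samples), nt)
  body <- vapply(seq_len(nt), function(j) {
    paste(c(sites$contig[j], sites$pos[j], sites$id[j], sites$ref[j],
            sites$alt[j], ".", "PASS", paste0("SRC=", sites$source[j]),
            "GT:DP:GQ", cell[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Reads a VCF 4.2 file with GT (required) and optional DP/GQ FORMAT fields.
#' Non-biallelic records (multiple ALT alleles, or symbolic/indel alleles)
#' are skipped with a warning and counted in the `skipped_records` attribute.
#' Together with [write_vcf()] this forms an exact round trip on genotype
#' codes, depths and GQs.
#'
#' @param path path to a VCF file (plain text or gzip).
#' @return a `genotype_matrix` (sites in file order); attribute
#'   `skipped_records` carries the non-biallelic count.
#' @export
read_vcf <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  hdr_idx <- grep("^#CHROM\t", lines)
  if (length(hdr_idx) != 1L) stop("not a VCF: no #CHROM header line")
  hdr <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10L) stop("VCF has no sample columns")
  samples <- hdr[-(1:9)]
  body <- lines[-seq_len(hdr_idx)]
  body <- body[nzchar(body)]
  nt0 <- length(body)
  if (nt0 == 0L) stop("VCF has no data records")
  fields <- strsplit(body, "\t", fixed = TRUE)
  len_ok <- lengths(fields) == length(hdr)
  if (!all(len_ok))
    stop(sprintf("VCF record %d has %d fields, expected %d",
                 which(!len_ok)[1], lengths(fields)[which(!len_ok)[1]], length(hdr)))
  rec <- do.call(rbind, fields)
  biallelic <- !grepl(",", rec[, 5], fixed = TRUE) &
    nchar(rec[, 4]) == 1L & nchar(rec[, 5]) == 1L &
    rec[, 4] %in% c("A", "C", "G", "T") & rec[, 5] %in% c("A", "C", "G", "T")
  n_skip <- sum(!biallelic)
  if (n_skip > 0) {
    warning(sprintf("skipped %d non-biallelic VCF record(s)", n_skip))
    rec <- rec[biallelic, , drop = FALSE]
  }
  nt <- nrow(rec)
  if (nt == 0L) stop("no biallelic records in VCF")
  src <- ifelse(grepl("(^|;)SRC=denovo(;|$)", rec[, 8]), "denovo", "reference")
  sites <- data.frame(
    id = rec[, 3], contig = rec[, 1], pos = as.integer(rec[, 2]),
    ref = rec[, 4], alt = rec[, 5], source = src, stringsAsFactors = FALSE
  )
  blank <- sites$id == "."
  if (any(blank)) sites$id[blank] <- paste0(sites$contig[blank], "_", sites$pos[blank])

  ns <- length(samples)
  geno <- matrix(NA_integer_, ns, nt)
  depth <- matrix(NA_integer_, ns, nt)
  gq <- matrix(NA_real_, ns, nt)
  gt_code <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
               "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  for (j in seq_len(nt)) {
    fmt <- strsplit(rec[j, 9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    dp_i <- match("DP", fmt)
    gq_i <- match("GQ", fmt)
    if (is.na(gt_i)) stop(sprintf("VCF record %d lacks a GT field", j))
    parts <- strsplit(rec[j, 9 + seq_len(ns)], ":", fixed = TRUE)
    gt <- vapply(parts, `[`, character(1), gt_i)
    geno[, j] <- gt_code[gt]
    if (!is.na(dp_i)) {
      dp <- vapply(parts, function(p) if (length(p) >= dp_i) p[dp_i] else ".", character(1))
      depth[, j] <- suppressWarnings(as.integer(dp))
    }
    if (!is.na(gq_i)) {
      g <- vapply(parts, function(p) if (length(p) >= gq_i) p[gq_i] else ".", character(1))
      gq[, j] <- suppressWarnings(as.numeric(g))
    }
  }
  out <- genotype_matrix(geno, depth = depth, gq = gq, sites = sites,
                         samples = samples)
  attr(out, "skipped_records") <- n_skip
  out
}
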