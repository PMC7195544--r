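# IUPAC ambiguity code for an unordered base pair
iupac_het <- function(a, b) {
  key <- paste(pmin(a, b), pmax(a, b), sep = "")
  codes <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  out <- codes[key]
  if (anyNA(out)) stop("invalid base pair for IUPAC coding: ", key[is.na(out)][1])
  unname(out)
}

#' Export a genotype matrix as a concatenated SNP alignment
#'
#' Builds one sequence per sample by concatenating the per-site base calls
#' (the supermatrix used by external tree programs): homozygotes become the
#' corresponding allele, heterozygotes the IUPAC ambiguity code, and missing
#' calls `?` (PHYLIP/NEXUS) or `N` (FASTA). The PHYLIP output is relaxed
#' (full names, space-separated); the NEXUS output carries a TAXA block and a
#' DNA CHARACTERS block.
#'
#' @param m a `genotype_matrix` with at least one site.
#' @param path output path.
#' @param format one of `"phylip"`, `"nexus"`, `"fasta"`.
#' @return `path`, invisibly. Warns if any sample is entirely missing.
#' @export
export_alignment <- function(m, path, format = c("phylip", "nexus", "fasta")) {
  format <- match.arg(format)
  ns <- length(m$samples)
  nt <- nrow(m$sites)
  if (ns == 0L || nt == 0L) stop("cannot export an empty matrix")
  miss_char <- if (format == "fasta") "N" else "?"

  chars <- matrix(miss_char, ns, nt)
  het <- iupac_het(m$sites$ref, m$sites$alt)
  for (j in seq_len(nt)) {
    g <- m$geno[, j]
    chars[!is.na(g) & g == 0L, j] <- m$sites$ref[j]
    chars[!is.na(g) & g == 1L, j] <- het[j]
    chars[!is.na(g) & g == 2L, j] <- m$sites$alt[j]
  }
  seqs <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
  all_missing <- rowSums(!is.na(m$geno)) == 0L
  if (any(all_missing))
    warning("sample(s) with no called sites exported as all-missing: ",
            paste(m$samples[all_missing], collapse = ", "))

  lines <- switch(format,
    fasta = as.vector(rbind(paste0(">", m$samples), seqs)),
    phylip = c(sprintf("%d %d", ns, nt), paste(m$samples, seqs)),
    nexus = c(
      "#NEXUS",
      "BEGIN TAXA;",
      sprintf("  DIMENSIONS NTAX=%d;", ns),
      paste0("  TAXLABELS ", paste(m$samples, collapse = " "), ";"),
      "END;",
      "BEGIN CHARACTERS;",
      sprintf("  DIMENSIONS NCHAR=%d;", nt),
      "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
      "  MATRIX",
      paste("   ", m$samples, seqs),
      "  ;",
      "END;"
    )
  )
  writeLines(lines, path)
  invisible(path)
}
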