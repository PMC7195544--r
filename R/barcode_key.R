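#' Build or read a demultiplexing barcode key
#'
#' A barcode key maps in-line barcodes to sample ids. Barcodes must be
#' non-empty strings over A/C/G/T and mutually prefix-free (no barcode may be
#' a prefix of another), so that the longest-prefix match used by
#' [demultiplex_and_trim()] is unambiguous.
#'
#' @param sample_id character vector of unique sample ids.
#' @param barcode character vector of barcodes, one per sample.
#' @return data frame with columns `sample_id`, `barcode` and class
#'   `c("barcode_key", "data.frame")`.
#' @export
barcode_key <- function(sample_id, barcode) {
  sample_id <- as.character(sample_id)
  barcode <- toupper(as.character(barcode))
  if (length(sample_id) == 0L) stop("empty barcode key")
  if (length(sample_id) != length(barcode))
    stop("sample_id and barcode must have equal length")
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in barcode key")
  if (any(nchar(barcode) == 0L)) stop("empty barcode")
  if (any(grepl("[^ACGT]", barcode))) stop("barcodes must be over A/C/G/T")
  for (i in seq_along(barcode)) {
    pref <- startsWith(barcode, barcode[i])
    pref[i] <- FALSE
    if (any(pref))
      stop(sprintf("barcode '%s' (%s) is a prefix of barcode '%s' (%s)",
                   barcode[i], sample_id[i],
                   barcode[which(pref)[1]], sample_id[which(pref)[1]]))
  }
  out <- data.frame(sample_id = sample_id, barcode = barcode,
                    stringsAsFactors = FALSE)
  class(out) <- c("barcode_key", class(out))
  out
}

#' @rdname barcode_key
#' @param path path to a tab-separated file with columns sample_id, barcode
#'   (no header).
#' @export
read_barcode_key <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("sample_id", "barcode"))
  barcode_key(tab$sample_id, tab$barcode)
}

#' @rdname barcode_key
#' @param key a `barcode_key`.
#' @export
write_barcode_key <- function(key, path) {
  write.table(key[, c("sample_id", "barcode")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
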