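#' Fetch reference flanks around a variant
#'
#' Returns up to `window` reference bases on each side of a variant's
#' reference span (the `ref_len` bases starting at `pos`, 1-based VCF
#' convention), uppercased. At a contig boundary the flank is truncated, so
#' the left flank at position 1 is the empty string.
#'
#' @param reference Path to a FASTA file (read in full; intended for the
#'   small synthetic contigs this package generates) or a pre-loaded named
#'   character vector of sequences as returned by [read_reference()].
#' @param chrom Contig name.
#' @param pos 1-based start of the variant's reference span.
#' @param window Maximum flank length on each side.
#' @param ref_len Length of the reference span (1 for a SNV).
#' @return A list with `left` and `right` flank strings.
#' @export
fetch_flank <- function(reference, chrom, pos, window, ref_len = 1L) {
  seqs <- if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    read_reference(reference)
  } else {
    reference
  }
  if (!chrom %in% names(seqs)) {
    stop("Contig ", chrom, " not found in reference (has: ",
         paste(names(seqs), collapse = ", "), ")", call. = FALSE)
  }
  contig <- seqs[[chrom]]
  len <- nchar(contig)
  if (pos < 1 || pos + ref_len - 1 > len) {
    stop("Position ", pos, " (span ", ref_len, ") outside contig ", chrom,
         " of length ", len, call. = FALSE)
  }
  left_start <- max(1, pos - window)
  left <- if (pos == 1) "" else substr(contig, left_start, pos - 1)
  right_end <- min(len, pos + ref_len - 1 + window)
  right <- if (pos + ref_len - 1 == len) "" else substr(contig, pos + ref_len, right_end)
  list(left = toupper(left), right = toupper(right))
}

#' Read a FASTA reference into a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a named vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_reference <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
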