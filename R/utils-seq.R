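# Internal sequence helpers. DNA is handled as plain uppercase character
# strings over {A,C,G,T,N}; Biostrings does the heavy lifting for FASTA I/O
# and reverse complement.

BASES <- c("A", "C", "G", "T")

# Encode a DNA string as integer codes A=1, C=2, G=3, T=4, N=0.
# Any other character is an error (the scanner's alphabet contract).
encode_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  codes <- match(chars, BASES)
  codes[chars == "N"] <- 0L
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes) & chars != "N"])
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ", "))
  }
  as.integer(codes)
}

decode_seq <- function(codes) {
  paste(c("N", BASES)[codes + 1L], collapse = "")
}

#' Reverse complement of a DNA string
#' @param seq character string over {A,C,G,T,N}.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Read a genome FASTA into a named character vector of chromosome sequences.
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

write_genome <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

# 1-based substring extraction with clamping to the chromosome.
extract_window <- function(chrom_seq, center, flank) {
  n <- nchar(chrom_seq)
  lo <- max(1L, center - flank + 1L)
  hi <- min(n, center + flank)
  substr(chrom_seq, lo, hi)
}

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
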