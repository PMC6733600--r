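#' Read and write FASTQ read sets
#'
#' Read sets are plain data.frames with columns `id`, `seq` and `qual`
#' (Sanger Phred+33 quality string). Parsing and serialisation go through
#' Biostrings.
#'
#' @param path file path (".gz" handled transparently).
#' @return `read_fastq`: a read-set data.frame.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = sub(" .*", "", names(x)),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' @param reads a read-set data.frame (`id`, `seq`, `qual`).
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write a locus reference as FASTA plus a feature/annotation TSV
#'
#' @param ref a `locus_reference`.
#' @param fasta,features_tsv output paths.
#' @return invisibly, the paths written.
#' @export
write_reference <- function(ref, fasta, features_tsv = NULL) {
  dna <- Biostrings::DNAStringSet(ref$sequence)
  names(dna) <- ref$id
  Biostrings::writeXStringSet(dna, fasta)
  if (!is.null(features_tsv)) {
    f <- ref$features
    out <- data.frame(name = f$name, start = f$start, end = f$end,
                      strand = f$strand,
                      tss_offset = ref$tss_offset,
                      primer_margin = ref$primer_margin)
    write.table(out, features_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(fasta, features_tsv))
}

#' Convert Phred+33 quality strings to integer vectors (and back)
#' @param qual character vector of quality strings.
#' @return list of integer Phred vectors.
#' @export
qual_to_int <- function(qual) {
  lapply(qual, function(q) if (nchar(q)) utf8ToInt(q) - 33L else integer())
}

#' @param q list of integer Phred vectors.
#' @rdname qual_to_int
#' @export
int_to_qual <- function(q) {
  vapply(q, function(v) if (length(v)) intToUtf8(v + 33L) else "", "")
}
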