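#' Read genome sequences from FASTA
#'
#' Reads nucleotide FASTA into a [Biostrings::DNAStringSet]. Sequences are
#' upper-cased, record names are trimmed to the first whitespace-delimited
#' token of the header, and every record is checked against the IUPAC
#' nucleotide alphabet. Topology defaults to linear; set
#' `circular = TRUE` for genomes that should be treated as circles by the
#' downstream detectors (stored in the `circular` metadata column).
#'
#' @param file path to a FASTA file.
#' @param circular logical, recycled across records.
#' @return a `DNAStringSet` with a `circular` metadata column.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 demo", "acgt"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(file, circular = FALSE) {
  txt <- readLines(file, warn = FALSE)
  txt <- txt[nzchar(txt)]
  if (!length(txt) || !any(startsWith(txt, ">")))
    stop("empty FASTA stream: ", file)
  ## validate alphabet per record before handing to Biostrings, so the
  ## error can name the offending record
  hdr <- grep("^>", txt)
  ids <- sub("\\s.*$", "", sub("^>", "", txt[hdr]))
  bounds <- c(hdr[-1] - 1L, length(txt))
  for (i in seq_along(hdr)) {
    body <- if (hdr[i] + 1L > bounds[i]) "" else
      paste(txt[(hdr[i] + 1L):bounds[i]], collapse = "")
    if (!nzchar(body))
      stop("record '", ids[i], "' has an empty sequence")
    bad <- gsub("[ACGTURYSWKMBDHVN]", "", toupper(body))
    if (nzchar(bad))
      stop("record '", ids[i], "' contains non-nucleotide letter(s): ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  }
  dna <- Biostrings::readDNAStringSet(file)
  names(dna) <- sub("\\s.*$", "", names(dna))
  dna <- Biostrings::DNAStringSet(toupper(dna))
  mcols(dna) <- DataFrame(circular = rep_len(circular, length(dna)))
  dna
}

## coerce the genome argument of the various operations to a named
## DNAStringSet; accepts DNAStringSet, DNAString (needs a name), or a
## named character vector
.asGenome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    g <- genome
  } else if (methods::is(genome, "DNAString")) {
    g <- Biostrings::DNAStringSet(genome)
  } else if (is.character(genome)) {
    g <- Biostrings::DNAStringSet(toupper(genome))
  } else stop("cannot interpret 'genome' as nucleotide sequence(s)")
  if (is.null(names(g)) || any(!nzchar(names(g))))
    stop("genome sequences must be named")
  g
}

.genomeCircular <- function(genome) {
  mc <- mcols(genome)
  if (!is.null(mc) && "circular" %in% colnames(mc))
    as.logical(mc$circular) else rep(FALSE, length(genome))
}

.genomeSeqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome),
                        seqlengths = Biostrings::width(genome),
                        isCircular = .genomeCircular(genome))
}

#' Write genome sequences to FASTA
#'
#' @param genome a `DNAStringSet`.
#' @param file output path.
#' @param width line width.
#' @return `file`, invisibly.
#' @export
writeGenome <- function(genome, file, width = 70L) {
  Biostrings::writeXStringSet(.asGenome(genome), file, width = width)
  invisible(file)
}
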