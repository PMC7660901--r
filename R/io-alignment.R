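## Tabular alignment (BLAST outfmt-6 style) parsing. A "record" is the set
## of HSP rows sharing one (query, subject) pair; operations downstream
## group the tidy HSP table by that key.

.BLAST6_DEFAULT <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                     "gapopen", "qstart", "qend", "sstart", "send",
                     "evalue", "bitscore")

.BLAST6_NUMERIC <- c("pident", "length", "mismatch", "gapopen", "qstart",
                     "qend", "sstart", "send", "evalue", "bitscore",
                     "nident", "qlen", "slen", "staxids")

#' Read tabular alignment results
#'
#' Parses BLAST outfmt-6-style tab-separated text with a declared column
#' order (default: the standard 12 columns). Rows sharing a
#' (`qseqid`, `sseqid`) pair form one alignment record with one HSP per row.
#' An `identities` column is always present: taken from `nident` when
#' declared, otherwise reconstructed as `round(pident/100 * length)`.
#'
#' @param file path to the tabular file, or `NULL` when `text` is given.
#' @param text the document as a character vector of lines.
#' @param columns character vector naming each column in file order.
#'   Recognised names follow BLAST+ format specifiers (`qseqid`, `sseqid`,
#'   `pident`, `length`, `nident`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`, `qlen`, `slen`, `stitle`, `staxids`, ...).
#' @return a `data.frame` of HSPs with one row per alignment segment.
#' @export
readAlignmentTabular <- function(file = NULL, text = NULL,
                                 columns = .BLAST6_DEFAULT) {
  stopifnot(all(c("qseqid", "sseqid") %in% columns))
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else text
  body <- which(nzchar(lines) & !startsWith(lines, "#"))
  rows <- vector("list", length(body))
  for (k in seq_along(body)) {
    i <- body[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(columns))
      stop("alignment line ", i, ": expected ", length(columns),
           " columns, found ", length(f))
    rows[[k]] <- f
  }
  if (!length(rows)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character()), length(columns)), columns),
      stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, rows)
    out <- as.data.frame(m, stringsAsFactors = FALSE)
    names(out) <- columns
  }
  for (cn in intersect(names(out), .BLAST6_NUMERIC))
    out[[cn]] <- as.numeric(out[[cn]])
  if (!"identities" %in% names(out)) {
    out$identities <- if ("nident" %in% names(out)) out$nident
      else if (all(c("pident", "length") %in% names(out)))
        round(out$pident / 100 * out$length)
      else NA_real_
  }
  if (nrow(out) && "length" %in% names(out) && any(out$length < 1))
    stop("alignment length < 1 in record ",
         out$qseqid[which(out$length < 1)[1]], " vs ",
         out$sseqid[which(out$length < 1)[1]])
  out
}

#' Write HSP rows as tabular alignment text
#'
#' @param hits a data.frame of HSPs (as from [readAlignmentTabular()]).
#' @param file optional output path.
#' @param columns columns to emit, in order.
#' @return lines of text (invisibly when `file` is given).
#' @export
writeAlignmentTabular <- function(hits, file = NULL,
                                  columns = intersect(c(.BLAST6_DEFAULT,
                                                        "qlen", "slen"),
                                                      names(hits))) {
  fmt <- function(x) {
    if (is.numeric(x)) {
      out <- format(x, trim = TRUE, scientific = FALSE, digits = 15)
      whole <- !is.na(x) & x == round(x)
      out[whole] <- format(x[whole], trim = TRUE, scientific = FALSE,
                           nsmall = 0)
      out
    } else as.character(x)
  }
  cols <- lapply(hits[columns], fmt)
  lines <- do.call(paste, c(cols, sep = "\t"))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
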