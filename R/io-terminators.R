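## Rho-independent terminator prediction records (TransTermHP-style),
## exchanged as a simple tab-separated table:
## seq_id, start, end, strand, score, stem_matches, tail_seq

#' Read terminator prediction records
#'
#' @param file path to a tab-separated terminator table, or `NULL` when
#'   `text` is given.
#' @param text the document as a character vector of lines.
#' @return a `data.frame` with columns `seq_id`, `start`, `end`, `strand`,
#'   `score`, `stem_matches`, `tail_seq`.
#' @export
readTerminators <- function(file = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else text
  body <- which(nzchar(lines) & !startsWith(lines, "#"))
  cols <- c("seq_id", "start", "end", "strand", "score", "stem_matches",
            "tail_seq")
  rows <- vector("list", length(body))
  for (k in seq_along(body)) {
    f <- strsplit(lines[body[k]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 7L)
      stop("terminator line ", body[k], ": expected 7 columns, found ",
           length(f))
    rows[[k]] <- f
  }
  if (!length(rows))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), stem_matches = integer(),
                      tail_seq = character(), stringsAsFactors = FALSE))
  m <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(m) <- cols
  m$start <- as.integer(m$start); m$end <- as.integer(m$end)
  m$score <- as.numeric(m$score)
  m$stem_matches <- as.integer(m$stem_matches)
  if (any(!grepl("^[ACGT]*$", m$tail_seq)))
    stop("terminator tail sequence contains non-ACGT letters")
  m
}

#' Write terminator records
#'
#' @param term a terminator `data.frame` (see [readTerminators()]).
#' @param file optional output path.
#' @return lines of text (invisibly when `file` is given).
#' @export
writeTerminators <- function(term, file = NULL) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%d\t%s", term$seq_id, term$start,
                   term$end, term$strand,
                   format(term$score, trim = TRUE, scientific = FALSE),
                   term$stem_matches, term$tail_seq)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
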