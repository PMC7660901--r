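## XMFA (extended multi-FASTA alignment) parsing, as emitted by
## progressiveMauve: blocks of aligned rows with headers
## "> idx:start-end strand [comment]", blocks terminated by "=" lines.

#' Read an XMFA alignment
#'
#' @param file path to an XMFA file, or `NULL` when `text` is given.
#' @param text the document as a character vector of lines.
#' @return a list of blocks; each block is a `data.frame` with columns
#'   `index` (sequence index), `start`, `end`, `strand` and `seq` (the
#'   aligned text, gaps as `-`).
#' @examples
#' readXMFA(text = c("> 1:1-4 + a", "ACGT", "> 2:1-4 + b", "AC-T", "="))
#' @export
readXMFA <- function(file = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else text
  blocks <- list()
  rows <- list()
  cur <- NULL
  flushRow <- function() {
    if (!is.null(cur)) rows[[length(rows) + 1L]] <<- cur
    cur <<- NULL
  }
  flushBlock <- function() {
    flushRow()
    if (!length(rows)) return()
    df <- data.frame(
      index = vapply(rows, `[[`, integer(1), "index"),
      start = vapply(rows, `[[`, numeric(1), "start"),
      end = vapply(rows, `[[`, numeric(1), "end"),
      strand = vapply(rows, `[[`, character(1), "strand"),
      seq = vapply(rows, `[[`, character(1), "seq"),
      stringsAsFactors = FALSE)
    if (length(unique(nchar(df$seq))) > 1L)
      stop("XMFA block ", length(blocks) + 1L,
           ": rows have unequal aligned lengths")
    blocks[[length(blocks) + 1L]] <<- df
    rows <<- list()
  }
  for (ln in lines) {
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (startsWith(ln, "=")) { flushBlock(); next }
    if (startsWith(ln, ">")) {
      flushRow()
      m <- regmatches(ln, regexec(
        "^>\\s*([0-9]+):([0-9]+)-([0-9]+)\\s+([+-])", ln))[[1]]
      if (length(m) != 5L)
        stop("malformed XMFA header: ", ln)
      cur <- list(index = as.integer(m[2]), start = as.numeric(m[3]),
                  end = as.numeric(m[4]), strand = m[5], seq = "")
    } else {
      if (is.null(cur)) stop("XMFA sequence line outside any record: ", ln)
      cur$seq <- paste0(cur$seq, gsub("\\s", "", ln))
    }
  }
  flushBlock()  # tolerate a missing trailing "="
  blocks
}

#' Write XMFA blocks
#'
#' @param blocks a list of block data.frames as returned by [readXMFA()].
#' @param file optional output path.
#' @return lines of text (invisibly when `file` is given).
#' @export
writeXMFA <- function(blocks, file = NULL) {
  lines <- character()
  for (b in blocks) {
    for (i in seq_len(nrow(b)))
      lines <- c(lines,
                 sprintf("> %d:%d-%d %s", b$index[i], as.integer(b$start[i]),
                         as.integer(b$end[i]), b$strand[i]),
                 b$seq[i])
    lines <- c(lines, "=")
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
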