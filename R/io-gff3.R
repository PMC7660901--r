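## GFF3 reading/writing for the constrained dialect the pipeline exchanges:
## version-3, key=value;key=value attributes, 1-based inclusive coordinates.
## Written by hand so parse errors carry line numbers, unresolved Parents are
## flagged rather than dropped, and the writer is byte-deterministic.

.gffEncode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x <- gsub("\n", "%0A", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub("&", "%26", x, fixed = TRUE)
}

.gffDecode <- function(x) {
  vapply(x, function(s) {
    if (grepl("%", s, fixed = TRUE)) utils::URLdecode(s) else s
  }, character(1), USE.NAMES = FALSE)
}

#' Read a GFF3 document into a FeatureSet
#'
#' Parses the version-3 dialect (nine tab-separated columns,
#' `key=value;key=value` attributes). `ID` and `Parent` attributes populate
#' the feature hierarchy; all other attributes are preserved verbatim in the
#' `attrs` metadata column. Features whose `Parent` does not resolve within
#' the document are retained with `dangling = TRUE`. Feature order is
#' preserved.
#'
#' @param file path to a GFF3 file, or `NULL` when `text` is given.
#' @param text optionally, the document as a character vector of lines.
#' @return a [FeatureSet].
#' @examples
#' fs <- readGFF3(text = c("##gff-version 3",
#'   "g1\tx\tgene\t1\t9\t.\t+\t.\tID=gene1",
#'   "g1\tx\tCDS\t1\t9\t.\t+\t0\tID=cds1;Parent=gene1"))
#' featureParent(fs)
#' @export
readGFF3 <- function(file = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else text
  n <- length(lines)
  keep <- logical(n)
  for (i in seq_len(n)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (startsWith(ln, "##FASTA")) break
    if (startsWith(ln, "#")) next
    keep[i] <- TRUE
  }
  idx <- which(keep)
  recs <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("GFF3 line ", i, ": expected 9 tab-separated columns, found ",
           length(f))
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end))
      stop("GFF3 line ", i, ": non-numeric coordinates")
    if (end < start)
      stop("GFF3 line ", i, ": end (", end, ") < start (", start, ")")
    if (start < 1L)
      stop("GFF3 line ", i, ": start must be >= 1")
    atts <- character()
    id <- NA_character_; parent <- NA_character_
    if (f[9] != "." && nzchar(f[9])) {
      for (kv in strsplit(f[9], ";", fixed = TRUE)[[1]]) {
        if (!nzchar(kv)) next
        eq <- regexpr("=", kv, fixed = TRUE)
        if (eq < 0)
          stop("GFF3 line ", i, ": malformed attribute '", kv, "'")
        key <- substr(kv, 1L, eq - 1L)
        val <- .gffDecode(substr(kv, eq + 1L, nchar(kv)))
        if (key == "ID") id <- val
        else if (key == "Parent") parent <- strsplit(val, ",", fixed = TRUE)[[1]][1]
        else atts[key] <- val
      }
    }
    recs[[k]] <- list(seqid = f[1], source = f[2], type = f[3],
                      start = start, end = end,
                      score = if (f[6] == ".") NA_real_ else as.numeric(f[6]),
                      strand = if (f[7] %in% c("+", "-")) f[7] else "*",
                      phase = if (f[8] == ".") NA_integer_ else as.integer(f[8]),
                      ID = id, Parent = parent, attrs = atts)
  }
  if (!length(recs))
    return(FeatureSet())
  g <- function(fld, how) vapply(recs, function(r) how(r[[fld]]), how(NA))
  FeatureSet(seqid = g("seqid", as.character),
             start = g("start", as.integer), end = g("end", as.integer),
             strand = g("strand", as.character), type = g("type", as.character),
             ID = g("ID", as.character), Parent = g("Parent", as.character),
             source = g("source", as.character), score = g("score", as.numeric),
             phase = g("phase", as.integer),
             attrs = lapply(recs, `[[`, "attrs"))
}

## deterministic emission order: group features under their top-level
## ancestor, order groups by (seqid, root start, root end, root ID), then
## within a group by depth, start, ID
.gffOrder <- function(fs) {
  id <- featureID(fs)
  parent <- featureParent(fs)
  root <- seq_along(id)
  depth <- integer(length(id))
  for (i in seq_along(id)) {
    j <- i; d <- 0L
    while (!is.na(parent[j])) {
      j2 <- match(parent[j], id)
      if (is.na(j2)) break
      j <- j2; d <- d + 1L
    }
    root[i] <- j; depth[i] <- d
  }
  key_id <- ifelse(is.na(id), "", id)
  order(as.character(seqnames(fs))[root], start(fs)[root], end(fs)[root],
        key_id[root], depth, start(fs), end(fs), key_id)
}

#' Write a FeatureSet as GFF3
#'
#' Emits a `##gff-version 3` header and one line per feature with parents
#' preceding their children, in a deterministic order (by sequence, the span
#' of the top-level feature, then depth and start). Writing is a fixed point:
#' writing, re-reading and writing again reproduces the bytes.
#'
#' @param fs a [FeatureSet].
#' @param file optional output path; when `NULL` the lines are returned.
#' @return the GFF3 document as a character vector of lines (invisibly when
#'   `file` is given).
#' @export
writeGFF3 <- function(fs, file = NULL) {
  fs <- .flagDangling(fs)
  if (any(mcols(fs)$dangling)) {
    bad <- featureID(fs)[mcols(fs)$dangling]
    bad <- bad[!is.na(bad)]
    stop("cannot write FeatureSet with dangling Parent reference(s): ",
         paste(unique(featureParent(fs)[mcols(fs)$dangling]), collapse = ", "))
  }
  fs <- fs[.gffOrder(fs)]
  mc <- mcols(fs)
  lines <- "##gff-version 3"
  for (i in seq_along(fs)) {
    at <- character()
    if (!is.na(mc$ID[i])) at <- c(at, paste0("ID=", .gffEncode(mc$ID[i])))
    if (!is.na(mc$Parent[i]))
      at <- c(at, paste0("Parent=", .gffEncode(mc$Parent[i])))
    extra <- mc$attrs[[i]]
    if (length(extra))
      at <- c(at, paste0(.gffEncode(names(extra)), "=", .gffEncode(extra)))
    strand <- as.character(strand(fs)[i])
    lines <- c(lines, paste(
      as.character(seqnames(fs))[i], mc$source[i], mc$type[i],
      start(fs)[i], end(fs)[i],
      if (is.na(mc$score[i])) "." else as.character(mc$score[i]),
      if (strand == "*") "." else strand,
      if (is.na(mc$phase[i])) "." else as.character(mc$phase[i]),
      if (length(at)) paste(at, collapse = ";") else ".",
      sep = "\t"))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
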