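## Dice-coefficient similarity arithmetic and the comparative-genomics
## tables: alignment-record filtering, related-phage ranking, and
## XMFA -> pairwise percent-identity tables.

#' Dice coefficient
#'
#' The similarity of two sequences given the number of identical aligned
#' matches: `2 * m / (len_a + len_b)`.
#'
#' @param identicalMatches count of identical aligned positions.
#' @param lenA,lenB full lengths of the two compared sequences.
#' @return a fraction in `[0, 1]`.
#' @examples
#' diceCoefficient(300, 1000, 1000)  # 0.3
#' @export
diceCoefficient <- function(identicalMatches, lenA, lenB) {
  if (any(lenA + lenB == 0)) stop("sequence lengths sum to zero")
  stopifnot(all(identicalMatches >= 0),
            all(identicalMatches <= pmin(lenA, lenB)))
  2 * identicalMatches / (lenA + lenB)
}

## aggregate identities of one record's HSPs: greedy by bitscore, an HSP
## is dropped when its subject interval overlaps an already-kept HSP, so
## identity over a reused subject region is never counted twice
.aggregateIdentities <- function(h) {
  o <- order(-h$bitscore, h$sstart, h$send)
  kept_lo <- numeric(); kept_hi <- numeric()
  m <- 0
  for (i in o) {
    lo <- min(h$sstart[i], h$send[i]); hi <- max(h$sstart[i], h$send[i])
    if (any(lo <= kept_hi & hi >= kept_lo)) next
    kept_lo <- c(kept_lo, lo); kept_hi <- c(kept_hi, hi)
    m <- m + h$identities[i]
  }
  m
}

## per-(query, subject) Dice percent from an HSP table carrying qlen/slen
.recordDice <- function(hits) {
  need <- c("qlen", "slen")
  if (!all(need %in% names(hits)) ||
      any(is.na(hits$qlen)) || any(is.na(hits$slen)))
    stop("record ", hits$qseqid[1], " vs ", hits$sseqid[1],
         ": query/subject lengths (qlen, slen) are required")
  key <- paste(hits$qseqid, hits$sseqid, sep = "\r")
  parts <- split(hits, key)
  data.frame(
    qseqid = vapply(parts, function(h) h$qseqid[1], character(1)),
    sseqid = vapply(parts, function(h) h$sseqid[1], character(1)),
    dice_pct = vapply(parts, function(h)
      100 * diceCoefficient(.aggregateIdentities(h), h$qlen[1], h$slen[1]),
      numeric(1)),
    row.names = NULL)
}

#' Filter alignment records by Dice coefficient
#'
#' Computes each (query, subject) record's Dice percent — summing HSP
#' identities after discarding subject-interval overlaps (higher bitscore
#' wins) and applying `2m / (qlen + slen)` — and retains records whose
#' percent lies in the closed interval `[minPct, maxPct]`.
#'
#' @param hits an HSP `data.frame` with `qlen` and `slen` columns.
#' @param minPct,maxPct inclusive bounds in percent (defaults 50 and 100).
#' @return the retained subset of `hits` (all HSPs of passing records).
#' @export
diceFilter <- function(hits, minPct = 50, maxPct = 100) {
  if (!nrow(hits)) return(hits)
  d <- .recordDice(hits)
  ok <- d[d$dice_pct >= minPct & d$dice_pct <= maxPct, , drop = FALSE]
  key <- paste(hits$qseqid, hits$sseqid, sep = "\r")
  out <- hits[key %in% paste(ok$qseqid, ok$sseqid, sep = "\r"), ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank related organisms by unique protein hits
#'
#' For protein-level hits annotated with a subject organism, counts per
#' organism the number of distinct query proteins with at least one hit,
#' and returns the top `topN` organisms by that count (ties broken by
#' organism label).
#'
#' @param hits an HSP `data.frame`; the organism label is taken from the
#'   `organism` column when present, else `stitle`, else `sseqid`.
#' @param topN rows to return (default 20).
#' @return a `data.frame` with columns `name` and `unique_proteins`,
#'   sorted by decreasing count.
#' @export
rankByUniqueProteins <- function(hits, topN = 20L) {
  if (!nrow(hits))
    return(data.frame(name = character(), unique_proteins = integer()))
  org <- if ("organism" %in% names(hits)) hits$organism
         else if ("stitle" %in% names(hits)) hits$stitle
         else hits$sseqid
  tab <- tapply(hits$qseqid, org, function(q) length(unique(q)))
  df <- data.frame(name = names(tab),
                   unique_proteins = as.integer(tab))
  df <- df[order(-df$unique_proteins, df$name), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, topN)
}

#' Rank nucleotide hits by Dice percent identity
#'
#' For genome-level nucleotide hits, computes each subject genome's Dice
#' percent against the query (HSP aggregation as in [diceFilter()]) and
#' returns the top `topN` subjects (ties broken by subject identifier).
#'
#' @param hits an HSP `data.frame` with `qlen` and `slen` columns.
#' @param topN rows to return (default 10).
#' @return a `data.frame` with columns `name` and `dice_pct`, sorted by
#'   decreasing percent.
#' @export
rankNucleotideHits <- function(hits, topN = 10L) {
  if (!nrow(hits))
    return(data.frame(name = character(), dice_pct = numeric()))
  d <- .recordDice(hits)
  ## one row per subject genome (a genome-level search has one query)
  tab <- tapply(d$dice_pct, d$sseqid, max)
  df <- data.frame(name = names(tab), dice_pct = as.numeric(tab))
  df <- df[order(-df$dice_pct, df$name), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, topN)
}

#' Pairwise percent-identity table from an XMFA alignment
#'
#' For each pair of sequences, counts alignment columns where both rows are
#' present in a block, neither is gapped, and the letters agree
#' (case-insensitively), summed over all blocks; the cell value is the
#' Dice percent `100 * 2m / (len_a + len_b)`. The table is symmetric with
#' 100 on the diagonal.
#'
#' @param blocks a list of XMFA blocks (see [readXMFA()]).
#' @param seqLengths numeric vector of full sequence lengths, indexed by
#'   the XMFA sequence indices (names optional).
#' @return a symmetric numeric matrix of percent identities.
#' @export
xmfaIdentityTable <- function(blocks, seqLengths) {
  n <- length(seqLengths)
  m <- matrix(0, n, n)
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    if (any(b$index < 1 | b$index > n))
      stop("XMFA block ", bi, " references unknown sequence index ",
           paste(setdiff(b$index, seq_len(n)), collapse = ", "))
    if (nrow(b) < 2L) next
    chars <- lapply(toupper(b$seq), function(s) strsplit(s, "")[[1]])
    for (i in seq_len(nrow(b) - 1L)) for (j in (i + 1L):nrow(b)) {
      a <- chars[[i]]; c2 <- chars[[j]]
      ident <- sum(a == c2 & a != "-")
      ii <- b$index[i]; jj <- b$index[j]
      m[ii, jj] <- m[ii, jj] + ident
      m[jj, ii] <- m[jj, ii] + ident
    }
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- if (i == j) 100 else
      100 * 2 * m[i, j] / (seqLengths[i] + seqLengths[j])
  }
  nm <- if (!is.null(names(seqLengths))) names(seqLengths)
        else as.character(seq_len(n))
  dimnames(out) <- list(nm, nm)
  out
}
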