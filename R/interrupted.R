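## Interrupted-gene detection: a single database protein hit by multiple
## discrete query genes is the signature of a gene split by an intron, a
## programmed translational frameshift, a sequencing artifact, or the
## opening of a circular genome inside a gene.

#' Remove low-identity HSPs
#'
#' Discards every HSP whose `identities / align_len` falls strictly below
#' the threshold (high identity over a short part of a longer segment is
#' uninformative); rows at exactly the threshold are retained. Records left
#' with no HSPs disappear entirely. Idempotent and monotone in the
#' threshold.
#'
#' @param hits an HSP `data.frame` (see [readAlignmentTabular()]) with
#'   `identities` and `length` columns.
#' @param minIdentityFraction discard threshold (default 0.3).
#' @return the retained subset of `hits`.
#' @export
filterLowIdentityHsps <- function(hits, minIdentityFraction = 0.3) {
  if (!nrow(hits)) return(hits)
  if (any(hits$length == 0))
    stop("HSP with zero alignment length in record ",
         hits$qseqid[which(hits$length == 0)[1]])
  keep <- hits$identities / hits$length >= minIdentityFraction
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## nearest-end distance between two genomic intervals, optionally on a
## circle of length L; returns c(distance, wrapped)
.fragmentDistance <- function(s1, e1, s2, e2, L = NA, circular = FALSE) {
  inner <- max(0L, max(s1, s2) - min(e1, e2) - 1L)
  if (!circular || is.na(L)) return(c(inner, FALSE))
  ## gap the other way around the circle
  outer <- max(0L, L - max(e1, e2) + min(s1, s2) - 1L)
  if (max(s1, s2) <= min(e1, e2))  # overlapping intervals: distance 0
    return(c(0L, FALSE))
  if (outer < inner) c(outer, TRUE) else c(inner, FALSE)
}

#' Detect interrupted genes from alignment evidence
#'
#' For every subject (database) protein hit by at least two distinct query
#' features, reports an interrupted-gene candidate when: at least two
#' unique HSPs support it; the fragments' subject intervals are compatible
#' with `sepMin` (consecutive signed separation on the subject of at least
#' `sepMin`; negative values permit that much overlap, zero or positive
#' values require separation); all contributing query features lie on the
#' same genomic strand; and consecutive fragments (ordered along the
#' subject) sit within `maxSepNt` of each other on the genome — computed
#' around the circle for circular genomes, which also detects genes split
#' across the genome ends.
#'
#' Candidates are reported per subject for manual review; no intron /
#' frameshift / artifact class is assigned automatically.
#'
#' @param hits an HSP `data.frame`, already filtered with
#'   [filterLowIdentityHsps()] (applied again here defensively).
#' @param features a [FeatureSet] resolving each `qseqid` to genomic
#'   coordinates (feature `ID` match).
#' @param genome the genome (for length and circularity), or `NULL` when
#'   `genomeLength` is given.
#' @param params ignored placeholder for future options.
#' @param maxSepNt maximum genomic distance between consecutive fragments
#'   (default 10000).
#' @param sepMin minimum signed separation of fragment intervals on the
#'   subject (default 0: separation required, overlap disallowed).
#' @param minIdentityFraction HSP retention threshold (default 0.3).
#' @param circular treat the genome as circular; defaults to the genome's
#'   own flag.
#' @param genomeLength genome length in nt when `genome` is not supplied.
#' @return a `data.frame` with one row per candidate: `subject_id`,
#'   `n_fragments`, `fragments` (comma-joined query feature IDs in subject
#'   order), `genomic_gaps` (comma-joined nt gaps between consecutive
#'   fragments), `spans_origin`, plus a `subject_intervals` column
#'   (comma-joined `start-end` spans on the subject).
#' @export
detectInterrupted <- function(hits, features, genome = NULL, params = NULL,
                              maxSepNt = 10000L, sepMin = 0L,
                              minIdentityFraction = 0.3, circular = NULL,
                              genomeLength = NULL) {
  empty <- data.frame(subject_id = character(), n_fragments = integer(),
                      fragments = character(), genomic_gaps = character(),
                      spans_origin = logical(),
                      subject_intervals = character())
  hits <- filterLowIdentityHsps(hits, minIdentityFraction)
  if (!nrow(hits)) return(empty)
  if (!is.null(genome)) {
    genome <- .asGenome(genome)
    if (is.null(genomeLength)) genomeLength <- Biostrings::width(genome)[1]
    if (is.null(circular)) circular <- .genomeCircular(genome)[1]
  }
  if (is.null(circular)) circular <- FALSE
  if (is.null(genomeLength)) genomeLength <- NA_integer_
  ids <- featureID(features)
  miss <- setdiff(unique(hits$qseqid), ids)
  if (length(miss))
    stop("query id(s) not found among features: ",
         paste(miss, collapse = ", "))
  fi <- match(hits$qseqid, ids)
  hits$g_start <- start(features)[fi]
  hits$g_end <- end(features)[fi]
  hits$g_strand <- as.character(strand(features))[fi]
  out <- list()
  for (subj in sort(unique(hits$sseqid))) {
    h <- hits[hits$sseqid == subj, , drop = FALSE]
    if (length(unique(h$qseqid)) < 2L) next
    if (nrow(h) < 2L) next
    if (length(unique(h$g_strand)) != 1L) next
    ## one fragment per query: the union span of its HSPs on the subject
    frag <- do.call(rbind, lapply(split(h, h$qseqid), function(q) {
      data.frame(qseqid = q$qseqid[1],
                 s_lo = min(q$sstart, q$send), s_hi = max(q$sstart, q$send),
                 g_start = q$g_start[1], g_end = q$g_end[1])
    }))
    frag <- frag[order(frag$s_lo, frag$s_hi, frag$qseqid), , drop = FALSE]
    ## keep fragments whose subject intervals respect the separation
    ## minimum relative to the previously kept fragment
    kept <- 1L
    for (k in seq_len(nrow(frag))[-1]) {
      prev <- kept[length(kept)]
      sep <- frag$s_lo[k] - frag$s_hi[prev] - 1L
      if (sep >= sepMin) kept <- c(kept, k)
    }
    if (length(kept) < 2L) next
    frag <- frag[kept, , drop = FALSE]
    gaps <- integer(); wrapped <- logical()
    ok <- TRUE
    for (k in seq_len(nrow(frag))[-1]) {
      d <- .fragmentDistance(frag$g_start[k - 1], frag$g_end[k - 1],
                             frag$g_start[k], frag$g_end[k],
                             L = genomeLength, circular = circular)
      if (d[1] > maxSepNt) { ok <- FALSE; break }
      gaps <- c(gaps, d[1]); wrapped <- c(wrapped, as.logical(d[2]))
    }
    if (!ok) next
    out[[length(out) + 1L]] <- data.frame(
      subject_id = subj, n_fragments = nrow(frag),
      fragments = paste(frag$qseqid, collapse = ","),
      genomic_gaps = paste(gaps, collapse = ","),
      spans_origin = any(wrapped),
      subject_intervals = paste(sprintf("%d-%d", frag$s_lo, frag$s_hi),
                                collapse = ","))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
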