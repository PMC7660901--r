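## Candidate spanin discovery: i-spanins carry a transmembrane domain,
## o-spanins a lipobox; candidate gene pairs must sit within 50 nt of each
## other on the same strand, often with the o-spanin gene embedded in an
## alternate reading frame inside the i-spanin gene.

.KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2, X = 0)

.LIPOBOX_P1 <- "[ILMFTV][^REKDX][GAS]C"
.LIPOBOX_P2 <- "AW[AGS]C"

#' Find lipobox motifs in a protein
#'
#' Scans for the two four-residue lipobox patterns
#' `[ILMFTV]-[any residue except R/E/K/D]-[GAS]-C` and `A-W-[AGS]-C`
#' (the terminal Cys is the lipoylation site). All occurrences starting at
#' or before `regionEnd` are reported, including overlapping ones. `X`
#' residues never satisfy a constrained position.
#'
#' @param protein amino-acid string.
#' @param regionEnd last residue index at which a motif may start
#'   (default 40; lipoboxes terminate signal peptides, hence the
#'   N-terminal restriction).
#' @return a `data.frame` with columns `offset` (1-based residue index of
#'   the motif start), `motif` and `pattern` (1 or 2).
#' @examples
#' findLipoboxes("MKKLAGCDE")  # LAGC at offset 4, pattern 1
#' @export
findLipoboxes <- function(protein, regionEnd = 40L) {
  protein <- toupper(protein)
  hits <- list()
  for (p in 1:2) {
    pat <- paste0("(?=(", if (p == 1) .LIPOBOX_P1 else .LIPOBOX_P2, "))")
    m <- gregexpr(pat, protein, perl = TRUE)[[1]]
    if (m[1] < 0) next
    for (off in as.integer(m)) {
      if (off > regionEnd) next
      hits[[length(hits) + 1L]] <-
        data.frame(offset = off, motif = substr(protein, off, off + 3L),
                   pattern = p)
    }
  }
  if (!length(hits))
    return(data.frame(offset = integer(), motif = character(),
                      pattern = integer()))
  df <- do.call(rbind, hits)
  df <- df[order(df$offset, df$pattern), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Predict transmembrane segments by hydropathy
#'
#' A Kyte-Doolittle sliding-window hydropathy predictor: maximal runs of
#' window positions whose mean hydropathy meets the threshold are reported
#' as transmembrane segments with their peak window mean. This is the
#' package's built-in stand-in for a dedicated transmembrane topology
#' predictor; externally produced predictions can be supplied to
#' [findSpanins()] instead.
#'
#' @param protein amino-acid string (unknown residues score 0).
#' @param window window length in residues (default 19, the canonical
#'   length of a membrane-spanning helix).
#' @param threshold mean-hydropathy cutoff (default 1.6).
#' @return a `data.frame` with columns `start`, `end` (residue span of the
#'   segment) and `peak` (highest window mean within it); zero rows when
#'   the protein is shorter than `window` or nothing crosses the
#'   threshold.
#' @export
predictTmSegments <- function(protein, window = 19L, threshold = 1.6) {
  aa <- strsplit(toupper(protein), "")[[1]]
  n <- length(aa)
  empty <- data.frame(start = integer(), end = integer(), peak = numeric())
  if (n < window) return(empty)
  h <- .KD_SCALE[aa]
  h[is.na(h)] <- 0
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  hot <- means >= threshold
  if (!any(hot)) return(empty)
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- which(r$values)
  data.frame(start = starts[segs],
             end = ends[segs] + window - 1L,
             peak = vapply(segs, function(k)
               max(means[starts[k]:ends[k]]), numeric(1)))
}

## gap in nt between two 1-based inclusive intervals (0 when they touch,
## overlap or nest)
.intervalGap <- function(s1, e1, s2, e2) {
  max(0L, max(s1, s2) - min(e1, e2) - 1L)
}

.architecture <- function(s1, e1, s2, e2) {
  if ((s2 >= s1 && e2 <= e1) || (s1 >= s2 && e1 <= e2)) "embedded"
  else if (s2 <= e1 && s1 <= e2) "overlapping"
  else "separated"
}

#' Pair i-spanin and o-spanin candidates
#'
#' Emits every (i-spanin, o-spanin) candidate pair on the same strand whose
#' genomic intervals lie within `maxSep` nucleotides of each other
#' (interval gap; overlapping or embedded spans count as 0, so the embedded
#' architecture always passes). Pairs are classified `embedded`,
#' `overlapping` or `separated` and ordered by genomic position. A
#' candidate carrying both kinds of evidence may appear in both roles but
#' never pairs with itself.
#'
#' @param cands a candidate `data.frame` with columns `orf`, `seqid`,
#'   `start`, `end`, `strand`, `role` (`"i-spanin"`/`"o-spanin"`).
#' @param maxSep maximum separation in nt (default 50).
#' @return a `data.frame` with columns `i_orf`, `o_orf`, `seqid`, `strand`,
#'   `architecture`, `separation_nt`.
#' @export
pairSpaninCandidates <- function(cands, maxSep = 50L) {
  empty <- data.frame(i_orf = character(), o_orf = character(),
                      seqid = character(), strand = character(),
                      architecture = character(),
                      separation_nt = integer())
  ic <- cands[cands$role == "i-spanin", , drop = FALSE]
  oc <- cands[cands$role == "o-spanin", , drop = FALSE]
  if (!nrow(ic) || !nrow(oc)) return(empty)
  rows <- list()
  for (a in seq_len(nrow(ic))) for (b in seq_len(nrow(oc))) {
    if (ic$orf[a] == oc$orf[b]) next
    if (ic$seqid[a] != oc$seqid[b]) next
    if (ic$strand[a] != oc$strand[b]) next
    gap <- .intervalGap(ic$start[a], ic$end[a], oc$start[b], oc$end[b])
    if (gap > maxSep) next
    rows[[length(rows) + 1L]] <- data.frame(
      i_orf = ic$orf[a], o_orf = oc$orf[b], seqid = ic$seqid[a],
      strand = ic$strand[a],
      architecture = .architecture(ic$start[a], ic$end[a],
                                   oc$start[b], oc$end[b]),
      separation_nt = gap,
      key_start = min(ic$start[a], oc$start[b]),
      key_end = min(ic$end[a], oc$end[b]))
  }
  if (!length(rows)) return(empty)
  df <- do.call(rbind, rows)
  df <- df[order(df$seqid, df$key_start, df$key_end, df$i_orf, df$o_orf), ,
           drop = FALSE]
  rownames(df) <- NULL
  df[, setdiff(names(df), c("key_start", "key_end")), drop = FALSE]
}

#' SpaninReport: result of a spanin search
#'
#' @slot candidates data.frame of classified candidate ORFs.
#' @slot pairs data.frame of same-strand candidate pairs within the
#'   separation limit.
#' @slot unpaired data.frame of candidates that joined no pair.
#' @slot features the [FeatureSet] of filtered naive ORFs searched.
#' @export
setClass("SpaninReport",
         representation(candidates = "data.frame", pairs = "data.frame",
                        unpaired = "data.frame", features = "FeatureSet"))

#' @describeIn SpaninReport candidate pairs
#' @param x a `SpaninReport`.
#' @export
spaninPairs <- function(x) x@pairs

#' @describeIn SpaninReport classified candidates
#' @export
spaninCandidates <- function(x) x@candidates

#' @describeIn SpaninReport candidates in no pair
#' @export
spaninUnpaired <- function(x) x@unpaired

setMethod("show", "SpaninReport", function(object) {
  cat("SpaninReport:", nrow(object@candidates), "candidate ORF roles,",
      nrow(object@pairs), "pair(s),", nrow(object@unpaired),
      "unpaired candidate(s)\n")
  invisible(object)
})

#' Find candidate spanin gene pairs in a genome
#'
#' The full signature-based spanin search: naive six-frame ORF calling
#' (genetic code 11, 30 aa minimum), filtering to the common phage start
#' codons (ATG/GTG/TTG), Shine-Dalgarno annotation, translation, then
#' classification of each ORF: transmembrane evidence makes an i-spanin
#' candidate, a lipobox makes an o-spanin candidate. Candidate pairs must
#' lie within `maxSep` nt on the same strand. Optionally, hits from a
#' search against a curated spanin protein database are overlaid as
#' supporting evidence (expectation value at most `evalueCutoff`).
#'
#' The signature approach deliberately over-calls: false-positive pairs are
#' reported with their evidence for manual review rather than suppressed.
#'
#' @param genome a named `DNAStringSet` or named character vector.
#' @param minAaLen minimum ORF protein length (default 30).
#' @param startCodons accepted start codons after filtering.
#' @param maxSep maximum pair separation in nt (default 50).
#' @param lipoboxRegion last residue at which a lipobox may start
#'   (default 40).
#' @param tmWindow,tmThreshold hydropathy predictor settings (19, 1.6).
#' @param tmPredictions optional externally produced transmembrane
#'   segments: a `data.frame` with columns `orf` (ORF protein/feature id),
#'   `start`, `end`; bypasses the built-in predictor.
#' @param spaninDbHits optional HSP table (see [readAlignmentTabular()])
#'   from a search of the translated ORFs against a curated spanin
#'   database.
#' @param evalueCutoff e-value cutoff for the evidence overlay
#'   (default 0.001).
#' @param annotateSd add Shine-Dalgarno children to the ORF models.
#' @return a [SpaninReport-class] object.
#' @export
findSpanins <- function(genome, minAaLen = 30L,
                        startCodons = c("ATG", "GTG", "TTG"),
                        maxSep = 50L, lipoboxRegion = 40L,
                        tmWindow = 19L, tmThreshold = 1.6,
                        tmPredictions = NULL, spaninDbHits = NULL,
                        evalueCutoff = 0.001, annotateSd = TRUE) {
  genome <- .asGenome(genome)
  orfs <- callOrfs(genome, minAaLen = minAaLen)
  orfs <- filterByStartCodon(orfs, genome, allowed = startCodons)
  orfs <- ensureGeneParents(orfs)
  if (annotateSd) orfs <- annotateShineDalgarno(orfs, genome)
  prots <- translateCDS(orfs, genome)
  cds <- orfs[featureType(orfs) == "CDS"]
  support <- list()
  if (!is.null(spaninDbHits) && nrow(spaninDbHits)) {
    ok <- spaninDbHits[spaninDbHits$evalue <= evalueCutoff, , drop = FALSE]
    support <- split(ok$sseqid, ok$qseqid)
  }
  rows <- list()
  for (cid in names(prots)) {
    i <- match(cid, featureID(cds))
    if (is.na(i)) i <- which(vapply(mcols(cds)$attrs, function(a)
      identical(a[["joined"]], cid), logical(1)))[1]
    aa <- prots[[cid]]
    gid <- featureParent(cds)[i]
    sup <- paste(sort(unique(unlist(
      support[intersect(c(cid, gid), names(support))]))), collapse = ",")
    tm <- if (!is.null(tmPredictions)) {
      p <- tmPredictions[tmPredictions$orf %in% c(cid, gid), , drop = FALSE]
      if (nrow(p)) data.frame(start = p$start, end = p$end, peak = NA_real_)
      else data.frame(start = integer(), end = integer(), peak = numeric())
    } else predictTmSegments(aa, window = tmWindow, threshold = tmThreshold)
    lip <- findLipoboxes(aa, regionEnd = lipoboxRegion)
    base <- data.frame(orf = cid, seqid = as.character(seqnames(cds)[i]),
                       start = start(cds)[i], end = end(cds)[i],
                       strand = as.character(strand(cds)[i]),
                       blast_support = sup)
    if (nrow(tm)) {
      b <- base
      b$role <- "i-spanin"
      b$detail <- paste(sprintf("TM %d-%d", tm$start, tm$end),
                        collapse = ";")
      rows[[length(rows) + 1L]] <- b
    }
    if (nrow(lip)) {
      b <- base
      b$role <- "o-spanin"
      b$detail <- paste(sprintf("lipobox %s@%d", lip$motif, lip$offset),
                        collapse = ";")
      rows[[length(rows) + 1L]] <- b
    }
  }
  cands <- if (length(rows)) do.call(rbind, rows)
           else data.frame(orf = character(), seqid = character(),
                           start = integer(), end = integer(),
                           strand = character(), blast_support = character(),
                           role = character(), detail = character())
  cands <- cands[order(cands$seqid, cands$start, cands$end, cands$role), ,
                 drop = FALSE]
  rownames(cands) <- NULL
  pairs <- pairSpaninCandidates(cands, maxSep = maxSep)
  in_pair <- cands$orf %in% c(pairs$i_orf, pairs$o_orf)
  methods::new("SpaninReport", candidates = cands, pairs = pairs,
               unpaired = cands[!in_pair, , drop = FALSE], features = orfs)
}
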