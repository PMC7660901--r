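## Shine-Dalgarno detection: extract the upstream window of each CDS,
## search it for the consensus AGGAGGT or its sub-motifs, and attach the
## best match to the gene model as a Shine_Dalgarno_sequence child.

#' Default Shine-Dalgarno candidate motifs
#'
#' The E. coli consensus `AGGAGGT` plus all its contiguous substrings of
#' length >= 4, deduplicated and ordered by decreasing length (ties by
#' position within the consensus). The list is a plain character vector and
#' can be replaced wholesale by the caller.
#'
#' @return an ordered character vector of motifs.
#' @examples
#' defaultSdCandidates()[1]  # "AGGAGGT"
#' @export
defaultSdCandidates <- function() {
  consensus <- "AGGAGGT"
  n <- nchar(consensus)
  out <- character()
  for (len in n:4) {
    for (i in seq_len(n - len + 1L)) {
      m <- substr(consensus, i, i + len - 1L)
      if (!(m %in% out)) out <- c(out, m)
    }
  }
  out
}

#' Extract the upstream window of a feature
#'
#' Returns the coding-strand sequence covering offsets `far` down to `near`
#' nucleotides upstream of the first base of the feature's start codon
#' (reverse-complemented for minus-strand features). At a linear sequence
#' edge the window is truncated (possibly to an empty string) and flagged.
#'
#' @param feature a length-1 [FeatureSet] (the CDS, or the gene carrying
#'   its coordinates).
#' @param genome the genome the feature refers to.
#' @param near nearest upstream offset searched (default 3).
#' @param far farthest upstream offset (default 24).
#' @return the window as a single character string with attributes
#'   `gstart`, `gend` (genome span, `NA` when empty), `strand`,
#'   `nearOffset` (the offset of the window's 3'-most base) and
#'   `truncated`.
#' @export
upstreamWindow <- function(feature, genome, near = 3L, far = 24L) {
  stopifnot(length(feature) == 1L, near >= 1L, near < far)
  genome <- .asGenome(genome)
  sid <- as.character(seqnames(feature))
  s <- as.character(genome[[sid]])
  L <- nchar(s)
  strand <- as.character(strand(feature))
  if (strand == "-") {
    s0 <- end(feature)
    lo <- s0 + near; hi <- s0 + far
    truncated <- hi > L
    hi <- min(hi, L)
    if (lo > L) {
      w <- ""
      attr(w, "gstart") <- NA_integer_; attr(w, "gend") <- NA_integer_
    } else {
      w <- .revcomp(substr(s, lo, hi))
      attr(w, "gstart") <- lo; attr(w, "gend") <- hi
    }
  } else {
    s0 <- start(feature)
    lo <- s0 - far; hi <- s0 - near
    truncated <- lo < 1L
    lo <- max(lo, 1L)
    if (hi < 1L) {
      w <- ""
      attr(w, "gstart") <- NA_integer_; attr(w, "gend") <- NA_integer_
    } else {
      w <- substr(s, lo, hi)
      attr(w, "gstart") <- lo; attr(w, "gend") <- hi
    }
  }
  attr(w, "strand") <- strand
  attr(w, "nearOffset") <- near
  attr(w, "truncated") <- truncated
  w
}

#' Search a window for Shine-Dalgarno motifs
#'
#' Exact string matching of every candidate motif against the upstream
#' window. In `longest` mode the maximal-length match is returned, ties
#' broken in favour of the occurrence closest to the start codon (smallest
#' offset); in `all` mode every occurrence of every candidate is returned.
#' The offset is measured from the last base of the motif to the first base
#' of the start codon.
#'
#' @param window an upstream window string (see [upstreamWindow()]); plain
#'   strings are accepted, with `nearOffset` taken from the argument.
#' @param candidates ordered motif list (default [defaultSdCandidates()]).
#' @param nearOffset offset of the window's 3'-most base from the start
#'   codon; overridden by the window's own attribute when present.
#' @param mode `"longest"` or `"all"`.
#' @return a `data.frame` with columns `motif`, `offset`, `wstart`, `wend`
#'   (match position within the window); zero rows when nothing matches.
#'   In `longest` mode at most one row.
#' @examples
#' bestSdMatch("TTAGGAGGTCAATTCCAAGGAC")$motif  # "AGGAGGT"
#' @export
bestSdMatch <- function(window, candidates = defaultSdCandidates(),
                        nearOffset = 3L, mode = c("longest", "all")) {
  mode <- match.arg(mode)
  if (!is.null(attr(window, "nearOffset")))
    nearOffset <- attr(window, "nearOffset")
  w <- as.character(window)
  n <- nchar(w)
  hits <- list()
  if (n > 0) {
    for (m in candidates) {
      ml <- nchar(m)
      if (ml > n) next
      p <- 1L
      repeat {
        i <- regexpr(m, substr(w, p, n), fixed = TRUE)
        if (i < 0) break
        ws <- p + as.integer(i) - 1L
        we <- ws + ml - 1L
        hits[[length(hits) + 1L]] <-
          data.frame(motif = m, offset = nearOffset + (n - we),
                     wstart = ws, wend = we)
        p <- ws + 1L
        if (p > n) break
      }
    }
  }
  if (!length(hits))
    return(data.frame(motif = character(), offset = integer(),
                      wstart = integer(), wend = integer()))
  df <- do.call(rbind, hits)
  df <- df[order(-nchar(df$motif), df$offset), , drop = FALSE]
  df <- df[!duplicated(df[c("wstart", "wend")]), , drop = FALSE]
  rownames(df) <- NULL
  if (mode == "longest") df[1, , drop = FALSE] else df
}

## genomic span of a window-relative match
.sdGenomicSpan <- function(window, wstart, wend) {
  gs <- attr(window, "gstart"); ge <- attr(window, "gend")
  if (attr(window, "strand") == "-") {
    c(ge - wend + 1L, ge - wstart + 1L)
  } else {
    c(gs + wstart - 1L, gs + wend - 1L)
  }
}

#' Annotate Shine-Dalgarno sequences on gene models
#'
#' For every gene that owns a CDS child and does not already carry a
#' ribosome-binding-site child (`Shine_Dalgarno_sequence` or
#' `ribosome_entry_site`), searches the upstream window of its start codon
#' and, on a match, adds one `Shine_Dalgarno_sequence` child feature with
#' the genomic coordinates of the matched motif. All other features pass
#' through untouched; the operation is idempotent.
#'
#' @param fs a [FeatureSet] of gene -> CDS models.
#' @param genome the genome the features refer to.
#' @param near,far upstream window bounds in nt (defaults 3 and 24).
#' @param candidates motif list (default [defaultSdCandidates()]).
#' @return the annotated [FeatureSet].
#' @export
annotateShineDalgarno <- function(fs, genome, near = 3L, far = 24L,
                                  candidates = defaultSdCandidates()) {
  genome <- .asGenome(genome)
  if (!length(fs)) return(fs)
  id <- featureID(fs)
  parent <- featureParent(fs)
  type <- featureType(fs)
  rbs_types <- c("Shine_Dalgarno_sequence", "ribosome_entry_site")
  genes <- which(type == "gene" & !is.na(id))
  new_rows <- list()
  for (gi in genes) {
    kids <- which(!is.na(parent) & parent == id[gi])
    if (any(type[kids] %in% rbs_types)) next
    cds <- kids[type[kids] == "CDS"]
    if (!length(cds)) next
    strand <- as.character(strand(fs)[cds[1]])
    m5 <- if (strand == "-") cds[which.max(end(fs)[cds])]
          else cds[which.min(start(fs)[cds])]
    w <- upstreamWindow(fs[m5], genome, near = near, far = far)
    hit <- bestSdMatch(w, candidates = candidates, mode = "longest")
    if (!nrow(hit)) next
    span <- .sdGenomicSpan(w, hit$wstart, hit$wend)
    sd_id <- paste0(id[gi], ".sd")
    k <- 1L
    while (sd_id %in% c(id, vapply(new_rows, `[[`, "", "ID"))) {
      sd_id <- paste0(id[gi], ".sd.", k); k <- k + 1L
    }
    new_rows[[length(new_rows) + 1L]] <- list(
      seqid = as.character(seqnames(fs)[gi]), start = span[1],
      end = span[2], strand = strand, ID = sd_id, Parent = id[gi],
      motif = hit$motif, offset = hit$offset)
  }
  if (!length(new_rows)) return(fs)
  sd <- FeatureSet(
    seqid = vapply(new_rows, `[[`, "", "seqid"),
    start = vapply(new_rows, function(r) r$start, integer(1)),
    end = vapply(new_rows, function(r) r$end, integer(1)),
    strand = vapply(new_rows, `[[`, "", "strand"),
    type = "Shine_Dalgarno_sequence",
    ID = vapply(new_rows, `[[`, "", "ID"),
    Parent = vapply(new_rows, `[[`, "", "Parent"),
    attrs = lapply(new_rows, function(r)
      c(sd_motif = r$motif, sd_offset = as.character(r$offset))))
  GenomeInfoDb::seqlevels(sd) <- GenomeInfoDb::seqlevels(fs)
  out <- .asFeatureSet(c(methods::as(fs, "GRanges"),
                         methods::as(sd, "GRanges")))
  methods::validObject(out)
  out
}
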