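## Naive six-frame ORF calling and the bespoke filtering stages of the
## structural annotation workflow: phage start-codon filtering, feature-type
## filtering, gene-model parent correction, terminator promotion.

.stopCodons <- function(geneticCode = "11") {
  gc <- Biostrings::getGeneticCode(geneticCode)
  names(gc)[gc == "*"]
}

.initCodons <- function(geneticCode = "11") {
  gc <- Biostrings::getGeneticCode(geneticCode)
  alt <- attr(gc, "alt_init_codons")
  sort(unique(c("ATG", alt)))
}

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## scan one linear strand-oriented string; returns ORFs as 1-based
## [start, end] on that string, end inclusive of the stop codon
.scanStrand <- function(s, minAa, starts, stops, allStarts, requireStop) {
  L <- nchar(s)
  out <- list()
  for (off in 0:2) {
    nc <- (L - off) %/% 3L
    if (nc < 1L) next
    pos <- off + 3L * (seq_len(nc) - 1L) + 1L
    codons <- substring(s, pos, pos + 2L)
    is_stop <- codons %in% stops
    is_start <- codons %in% starts
    seg_from <- c(1L, which(is_stop) + 1L)
    seg_stop <- c(which(is_stop), NA_integer_)
    for (k in seq_along(seg_from)) {
      stop_i <- seg_stop[k]
      if (is.na(stop_i) && requireStop) next
      lo <- seg_from[k]
      hi <- if (is.na(stop_i)) nc else stop_i - 1L
      if (hi < lo) next
      cand <- lo + which(is_start[lo:hi]) - 1L
      if (!length(cand)) next
      last_coding <- if (is.na(stop_i)) nc else stop_i - 1L
      if (!allStarts) cand <- cand[1]
      for (st in cand) {
        aa <- last_coding - st + 1L
        if (aa < minAa) next
        nt_start <- pos[st]
        nt_end <- if (is.na(stop_i)) pos[last_coding] + 2L else pos[stop_i] + 2L
        out[[length(out) + 1L]] <- c(nt_start, nt_end)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Call ORFs naively on all six frames
#'
#' Finds open reading frames on both strands of each genome sequence: every
#' stop-to-stop segment contributes the ORF running from its first
#' initiation codon (under the chosen genetic code; all of them with
#' `allStarts = TRUE`) to the next in-frame stop, kept when the encoded
#' protein (excluding the stop) is at least `minAaLen` residues. The CDS
#' span includes the stop codon, following prokaryotic GFF3 convention.
#' Each ORF is emitted as a `gene` feature with a `CDS` child.
#'
#' Sequences flagged circular (or `circular = TRUE`) additionally yield
#' origin-spanning ORFs, represented as two joined parts sharing a
#' `joined` attribute.
#'
#' @param genome a named `DNAStringSet` (or named character vector).
#' @param minAaLen minimum protein length in residues, excluding the stop
#'   (default 30).
#' @param geneticCode NCBI genetic-code table identifier (default `"11"`,
#'   Bacteria/Archaea).
#' @param startCodons codons accepted as initiators at the calling stage;
#'   defaults to the declared initiation codons of `geneticCode`.
#' @param allStarts emit one ORF per in-frame start rather than only the
#'   longest variant per stop.
#' @param requireStop require a terminating stop codon (ORFs running off
#'   the sequence end are dropped).
#' @param circular override the genome's circularity flag(s).
#' @param idPrefix prefix for generated feature IDs.
#' @return a [FeatureSet] of gene + CDS pairs, ordered by sequence, start,
#'   end and strand.
#' @examples
#' g <- Biostrings::DNAStringSet(c(phage = paste0(
#'   "ATG", strrep("GCT", 32), "TAA")))
#' callOrfs(g, minAaLen = 30)
#' @export
callOrfs <- function(genome, minAaLen = 30L, geneticCode = "11",
                     startCodons = NULL, allStarts = FALSE,
                     requireStop = TRUE, circular = NULL,
                     idPrefix = "orf") {
  genome <- .asGenome(genome)
  stopifnot(minAaLen >= 1L)
  stops <- .stopCodons(geneticCode)
  if (is.null(startCodons)) startCodons <- .initCodons(geneticCode)
  circ <- if (is.null(circular)) .genomeCircular(genome)
          else rep_len(circular, length(genome))
  all_orfs <- list()
  for (si in seq_along(genome)) {
    s <- as.character(genome[[si]])
    L <- nchar(s)
    if (L < 3L) next
    sid <- names(genome)[si]
    fwd <- .scanStrand(s, minAaLen, startCodons, stops, allStarts,
                       requireStop)
    rc <- .revcomp(s)
    rev <- .scanStrand(rc, minAaLen, startCodons, stops, allStarts,
                       requireStop)
    orfs <- rbind(
      if (nrow(fwd)) data.frame(seqid = sid, start = fwd$start,
                                end = fwd$end, strand = "+", wrap = FALSE),
      if (nrow(rev)) data.frame(seqid = sid, start = L - rev$end + 1L,
                                end = L - rev$start + 1L, strand = "-",
                                wrap = FALSE))
    if (circ[si] && L >= 6L) {
      for (strand in c("+", "-")) {
        ss <- if (strand == "+") s else rc
        dbl <- paste0(ss, ss)
        hits <- .scanStrand(dbl, minAaLen, startCodons, stops, allStarts,
                            requireStop)
        hits <- hits[hits$start <= L & hits$end > L &
                     (hits$end - hits$start + 1L) <= L, , drop = FALSE]
        if (nrow(hits)) {
          st <- hits$start; en <- hits$end - L
          if (strand == "-") {
            ## map back from the reverse complement circle
            st2 <- L - (hits$end - L) + 1L  # genome start of 3' part
            en2 <- L - hits$start + 1L      # genome end of 5' part
            orfs <- rbind(orfs, data.frame(seqid = sid, start = st2,
                                           end = en2, strand = "-",
                                           wrap = TRUE))
          } else {
            orfs <- rbind(orfs, data.frame(seqid = sid, start = st,
                                           end = en, strand = "+",
                                           wrap = TRUE))
          }
        }
      }
    }
    all_orfs[[length(all_orfs) + 1L]] <- orfs
  }
  orfs <- if (length(all_orfs)) do.call(rbind, all_orfs)
          else data.frame(seqid = character(), start = integer(),
                          end = integer(), strand = character(),
                          wrap = logical())
  if (nrow(orfs)) {
    orfs <- orfs[order(orfs$seqid, orfs$start, orfs$end, orfs$strand), ,
                 drop = FALSE]
    rownames(orfs) <- NULL
  }
  si <- .genomeSeqinfo(genome)
  recs <- list()
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  for (i in seq_len(nrow(orfs))) {
    gid <- sprintf("%s%05d", idPrefix, i)
    cid <- paste0(gid, ".cds")
    if (!orfs$wrap[i]) {
      recs[[length(recs) + 1L]] <- data.frame(
        seqid = orfs$seqid[i], start = orfs$start[i], end = orfs$end[i],
        strand = orfs$strand[i], type = c("gene", "CDS"),
        ID = c(gid, cid), Parent = c(NA, gid), phase = c(NA, 0L),
        joined = NA_character_)
    } else {
      ## wraparound: 5' part runs to the sequence end (plus strand) or
      ## from the sequence start (minus strand)
      L <- lens[[orfs$seqid[i]]]
      p1 <- c(orfs$start[i], L)        # genomic right part
      p2 <- c(1L, orfs$end[i])         # genomic left part
      w5 <- if (orfs$strand[i] == "+") L - orfs$start[i] + 1L
            else orfs$end[i]
      ph2 <- as.integer((3L - (w5 %% 3L)) %% 3L)
      phases <- if (orfs$strand[i] == "+") c(0L, ph2) else c(ph2, 0L)
      recs[[length(recs) + 1L]] <- data.frame(
        seqid = orfs$seqid[i],
        start = c(p1[1], p1[1], p2[1], p2[1]),
        end = c(p1[2], p1[2], p2[2], p2[2]),
        strand = orfs$strand[i],
        type = c("gene", "CDS", "gene", "CDS"),
        ID = c(paste0(gid, ".p1"), paste0(cid, ".p1"),
               paste0(gid, ".p2"), paste0(cid, ".p2")),
        Parent = c(NA, paste0(gid, ".p1"), NA, paste0(gid, ".p2")),
        phase = c(NA, phases[1], NA, phases[2]),
        joined = gid)
    }
  }
  if (!length(recs))
    return(FeatureSet(seqinfo = si))
  df <- do.call(rbind, recs)
  FeatureSet(seqid = df$seqid, start = df$start, end = df$end,
             strand = df$strand, type = df$type, ID = df$ID,
             Parent = df$Parent, phase = df$phase,
             attrs = lapply(df$joined, function(j)
               if (is.na(j)) character() else c(joined = j)),
             seqinfo = si)
}

## strand-aware first codon of a CDS feature; handles circular wrap when
## the position arithmetic runs off either end
.firstCodon <- function(genome, seqid, start, end, strand) {
  s <- as.character(genome[[seqid]])
  if (strand == "-") {
    .revcomp(substr(s, end - 2L, end))
  } else {
    substr(s, start, start + 2L)
  }
}

#' Filter gene models by start codon
#'
#' Retains exactly the gene/CDS groups whose strand-aware first codon is in
#' `allowed` (default: the common phage start codons ATG, GTG, TTG). The
#' gene parent, its CDS and any other children are removed together when
#' the codon fails the filter; features outside gene/CDS groups pass
#' through. The result is a subset of the input.
#'
#' @param fs a [FeatureSet] of gene models.
#' @param genome the genome the features refer to.
#' @param allowed accepted start codons.
#' @return the filtered [FeatureSet].
#' @export
filterByStartCodon <- function(fs, genome, allowed = c("ATG", "GTG", "TTG")) {
  genome <- .asGenome(genome)
  allowed <- toupper(allowed)
  id <- featureID(fs)
  parent <- featureParent(fs)
  is_cds <- featureType(fs) == "CDS"
  keep <- rep(TRUE, length(fs))
  joined <- vapply(mcols(fs)$attrs, function(a)
    if ("joined" %in% names(a)) a[["joined"]] else NA_character_,
    character(1))
  ## group CDS by gene parent; joined wraparound parts group together;
  ## standalone CDS form their own group
  grp <- ifelse(is_cds & !is.na(joined), paste0(".join.", joined),
                ifelse(is.na(parent),
                       ifelse(is.na(id), paste0(".idx", seq_along(fs)), id),
                       parent))
  for (g in unique(grp[is_cds])) {
    members <- which(is_cds & grp == g)
    is_join <- startsWith(g, ".join.")
    if (!is_join && any(width(fs)[members] < 3L))
      stop("CDS shorter than one codon: ",
           paste(stats::na.omit(id[members]), collapse = ", "))
    ## 5'-most CDS part decides (strand-aware; wraparound parts straddle
    ## the origin, so the 5' part sits at the far end of the sequence)
    strand <- as.character(strand(fs)[members[1]])
    m5 <- if (is_join) {
      if (strand == "-") members[which.min(end(fs)[members])]
      else members[which.max(start(fs)[members])]
    } else {
      if (strand == "-") members[which.max(end(fs)[members])]
      else members[which.min(start(fs)[members])]
    }
    codon <- .firstCodon(genome, as.character(seqnames(fs)[m5]),
                         start(fs)[m5], end(fs)[m5], strand)
    if (!(codon %in% allowed)) {
      gene_ids <- unique(stats::na.omit(parent[members]))
      rm_set <- unique(c(stats::na.omit(id[members]),
                         if (length(gene_ids))
                           .withDescendants(fs, gene_ids)))
      keep[members] <- FALSE
      keep[!is.na(id) & id %in% rm_set] <- FALSE
    }
  }
  .asFeatureSet(fs[keep])
}

#' Keep or drop features by type
#'
#' In `drop` mode, features of the listed types are removed together with
#' all their descendants. In `keep` mode, only the listed types and their
#' ancestors are retained. The result is always a subset of the input and
#' the operation is idempotent.
#'
#' @param fs a [FeatureSet].
#' @param types Sequence Ontology terms.
#' @param mode `"keep"` or `"drop"`.
#' @return the filtered [FeatureSet].
#' @export
filterFeatureTypes <- function(fs, types, mode = c("drop", "keep")) {
  mode <- match.arg(mode)
  if (!length(fs)) return(fs)
  id <- featureID(fs)
  parent <- featureParent(fs)
  hit <- featureType(fs) %in% types
  if (mode == "drop") {
    if (!any(hit)) return(fs)
    rm_ids <- .withDescendants(fs, stats::na.omit(id[hit]))
    keep <- !hit & !(ifelse(is.na(id), "", id) %in% rm_ids)
  } else {
    keep_ids <- stats::na.omit(id[hit])
    ## add all ancestors of kept features
    anc <- character()
    for (i in which(hit)) {
      j <- i
      while (!is.na(parent[j])) {
        j2 <- match(parent[j], id)
        if (is.na(j2)) break
        anc <- c(anc, id[j2]); j <- j2
      }
    }
    keep <- hit | (ifelse(is.na(id), "", id) %in% c(keep_ids, anc))
  }
  .asFeatureSet(fs[keep])
}

#' Add gene parents to orphan CDS features
#'
#' Every CDS without a resolvable gene parent gains a `gene` parent feature
#' with identical span and strand; already-parented CDS are untouched. The
#' operation is idempotent.
#'
#' @param fs a [FeatureSet].
#' @return the corrected [FeatureSet].
#' @export
ensureGeneParents <- function(fs) {
  if (!length(fs)) return(fs)
  id <- featureID(fs)
  parent <- featureParent(fs)
  orphan <- which(featureType(fs) == "CDS" &
                  (is.na(parent) | !(parent %in% id)))
  if (!length(orphan)) return(fs)
  mc <- mcols(fs)
  new_rows <- list()
  for (k in seq_along(orphan)) {
    i <- orphan[k]
    base <- if (!is.na(id[i])) paste0("gene.", id[i])
            else sprintf("gene.orphan%03d", k)
    gid <- base
    j <- 1L
    while (gid %in% c(id, vapply(new_rows, `[[`, "", "ID"))) {
      gid <- paste0(base, ".", j); j <- j + 1L
    }
    new_rows[[k]] <- list(seqid = as.character(seqnames(fs)[i]),
                          start = start(fs)[i], end = end(fs)[i],
                          strand = as.character(strand(fs)[i]), ID = gid,
                          at = i)
  }
  mcols(fs)$Parent[orphan] <- vapply(new_rows, `[[`, "", "ID")
  genes <- FeatureSet(
    seqid = vapply(new_rows, `[[`, "", "seqid"),
    start = vapply(new_rows, function(r) r$start, integer(1)),
    end = vapply(new_rows, function(r) r$end, integer(1)),
    strand = vapply(new_rows, `[[`, "", "strand"),
    type = "gene", ID = vapply(new_rows, `[[`, "", "ID"),
    source = mc$source[orphan])
  GenomeInfoDb::seqlevels(genes) <- GenomeInfoDb::seqlevels(fs)
  out <- .asFeatureSet(c(methods::as(fs, "GRanges"),
                         methods::as(genes, "GRanges")))
  methods::validObject(out)
  out
}

#' Promote terminator predictions
#'
#' Applies the promotion criteria for rho-independent terminator
#' predictions: confidence score strictly greater than `minScore`, hairpin
#' stem with at least `minStem` paired matches, and a run of at least
#' `minTRun` consecutive T's anywhere in the T-tail. Order is preserved.
#'
#' @param term a terminator `data.frame` (see [readTerminators()]).
#' @param minScore exclusive score threshold (default 95).
#' @param minStem minimum stem matches (default 5).
#' @param minTRun minimum consecutive T's in the tail (default 4).
#' @return the subset of `term` meeting all three criteria.
#' @examples
#' term <- data.frame(seq_id = "g", start = 1, end = 30, strand = "+",
#'                    score = c(96, 95), stem_matches = c(5, 9),
#'                    tail_seq = c("ATTTTG", "TTTT"))
#' filterTerminators(term)  # keeps only the first row
#' @export
filterTerminators <- function(term, minScore = 95, minStem = 5L,
                              minTRun = 4L) {
  keep <- term$score > minScore &
    term$stem_matches >= minStem &
    grepl(strrep("T", minTRun), term$tail_seq, fixed = TRUE)
  term[keep, , drop = FALSE]
}

#' Extract and translate CDS features
#'
#' Strand-aware extraction of CDS nucleotide sequences and translation
#' under the given genetic code. Joined two-part CDS features (wraparound
#' genes) are concatenated in translation order. The trailing stop, when
#' present, is removed from the protein.
#'
#' @param fs a [FeatureSet] containing CDS features.
#' @param genome the genome the features refer to.
#' @param geneticCode NCBI genetic-code table identifier.
#' @return a named character vector of protein sequences, one per CDS
#'   (joined parts collapse onto the shared `joined` identifier).
#' @export
translateCDS <- function(fs, genome, geneticCode = "11") {
  genome <- .asGenome(genome)
  cds <- fs[featureType(fs) == "CDS"]
  if (!length(cds)) return(stats::setNames(character(), character()))
  joined <- vapply(mcols(cds)$attrs, function(a)
    if ("joined" %in% names(a)) a[["joined"]] else NA_character_,
    character(1))
  key <- ifelse(is.na(joined), ifelse(is.na(featureID(cds)),
                                      sprintf(".cds%d", seq_along(cds)),
                                      featureID(cds)), joined)
  out <- character(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    strand <- as.character(strand(cds)[idx[1]])
    if (length(idx) > 1L) {
      ## joined wraparound parts: the 5' part abuts the origin from the
      ## far side (plus strand: runs to the sequence end; minus strand:
      ## runs from the sequence start)
      idx <- if (strand == "-") idx[order(end(cds)[idx])]
             else idx[order(-start(cds)[idx])]
    }
    nt <- paste(vapply(idx, function(i) {
      s <- as.character(genome[[as.character(seqnames(cds)[i])]])
      part <- substr(s, start(cds)[i], end(cds)[i])
      if (strand == "-") .revcomp(part) else part
    }, character(1)), collapse = "")
    nt <- substr(nt, 1L, 3L * (nchar(nt) %/% 3L))
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(nt),
      genetic.code = Biostrings::getGeneticCode(geneticCode),
      if.fuzzy.codon = "X"))
    aa <- sub("\\*$", "", aa)
    out[k] <- aa
  }
  out
}
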