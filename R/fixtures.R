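## Seeded synthetic fixtures with known ground truth. Planted gene, SD and
## spanin constructs are assembled on an engineered inert background:
## cyclic "TAGT" spacers carry stop codons in all six frames but no
## initiation codon on either strand, so no ORF can begin in or survive
## across a spacer. Residual decoy ORFs arising inside planted cassettes
## (alternate reading frames of real coding sequence) are discovered by a
## six-frame sweep at build time and recorded in the truth, never ignored.

## inert spacer: stops in all six frames, no starts on either strand
.inertSpacer <- function(n) {
  if (n <= 0) return("")
  substr(strrep("TAGT", n %/% 4 + 1L), 1L, n)
}

## cytosine filler: no starts or stops on either strand, cannot form or
## extend any Shine-Dalgarno candidate motif, and creates no initiation
## codon at a junction with an upstream stop codon
.cfill <- function(n) {
  if (n <= 0) return("")
  strrep("C", n)
}

.SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

.randomCodons <- function(n) {
  paste(sample(.SENSE_CODONS, n, replace = TRUE), collapse = "")
}

## ---- cassette builders (relative 1-based coordinates) --------------------

## gene with an upstream Shine-Dalgarno motif at a chosen offset
.geneCassette <- function(sdOffset = 7L, aaLen = 32L, strand = "+",
                          sdMotif = "AGGAGGT") {
  ml <- nchar(sdMotif)
  stopifnot(sdOffset >= 3L, sdOffset + ml - 1L <= 24L, aaLen >= 2L)
  pad_before <- max(2L, 26L - ml - (sdOffset - 1L))
  up <- paste0(.cfill(pad_before), sdMotif, .cfill(sdOffset - 1L))
  gene <- paste0("ATG", .randomCodons(aaLen - 1L), "TAA")
  seqs <- paste0(up, gene)
  n <- nchar(seqs)
  u <- nchar(up)
  feat <- data.frame(type = c("gene", "CDS", "Shine_Dalgarno_sequence"),
                     start = c(u + 1L, u + 1L, pad_before + 1L),
                     end = c(n, n, pad_before + ml),
                     strand = "+", role = c("gene", "gene", "sd"),
                     sd_offset = c(NA, NA, sdOffset))
  if (strand == "-") {
    seqs <- .revcomp(seqs)
    feat[, c("start", "end")] <- cbind(n - feat$end + 1L,
                                       n - feat$start + 1L)
    feat$strand <- "-"
  }
  list(seq = seqs, features = feat, pairs = NULL)
}

## o-spanin ORF: M K L A G C S*26 — lipobox LAGC at residue 3, no
## transmembrane run; 32 aa
.O_CASSETTE <- paste0("ATGAAACTGGCTGGCTGC", strrep("AGC", 26), "TAA")

## i-spanin ORF: M L*29 — Leu run gives the TM signal; the CTC codon is
## pyrimidine-only, so alternate frames of the run contain no starts
.I_CASSETTE <- paste0("ATG", strrep("CTC", 29), "TAA")

.translateLocal <- function(nt) {
  sub("\\*$", "", as.character(Biostrings::translate(
    Biostrings::DNAString(nt))))
}

## spanin pair cassette for one architecture; returns relative CDS spans
.spaninCassette <- function(architecture = c("embedded", "overlapping",
                                             "separated"),
                            sep = 20L, oppositeStrand = FALSE) {
  architecture <- match.arg(architecture)
  o <- .O_CASSETTE
  if (architecture == "embedded") {
    pre <- paste0("ATG", strrep("CTC", 21), "CCCC")
    body <- paste0(pre, o)
    k <- (3L - nchar(body) %% 3L) %% 3L
    seqs <- paste0(body, strrep("C", k), "TAA")
    i_span <- c(1L, nchar(seqs))
    o_span <- c(nchar(pre) + 1L, nchar(pre) + nchar(o))
  } else if (architecture == "overlapping") {
    pre <- paste0("ATG", strrep("CTC", 28), "CC")
    seqs <- paste0(pre, o)
    i_span <- c(1L, nchar(pre) + 4L)   # i stops at the TGA inside o's start
    o_span <- c(nchar(pre) + 1L, nchar(pre) + nchar(o))
  } else {
    iseq <- .I_CASSETTE
    gap <- .cfill(sep)
    seqs <- paste0(iseq, gap, o)
    i_span <- c(1L, nchar(iseq))
    o_span <- c(nchar(iseq) + sep + 1L, nchar(seqs))
  }
  ## self-check the dual-frame construction
  i_nt <- substr(seqs, i_span[1], i_span[2])
  o_nt <- substr(seqs, o_span[1], o_span[2])
  i_aa <- .translateLocal(i_nt)
  o_aa <- .translateLocal(o_nt)
  stopifnot(!grepl("\\*", i_aa), !grepl("\\*", o_aa),
            nchar(i_aa) >= 30L, nchar(o_aa) >= 30L,
            nrow(predictTmSegments(i_aa)) >= 1L,
            nrow(findLipoboxes(o_aa)) >= 1L)
  n <- nchar(seqs)
  feat <- data.frame(type = "CDS",
                     start = c(i_span[1], o_span[1]),
                     end = c(i_span[2], o_span[2]),
                     strand = "+", role = c("i-spanin", "o-spanin"),
                     sd_offset = NA)
  expected <- !oppositeStrand
  if (oppositeStrand && architecture == "separated") {
    ## flip only the o-spanin ORF onto the minus strand
    o_rc <- .revcomp(o)
    seqs <- paste0(.I_CASSETTE, .cfill(sep), o_rc)
    feat$strand <- c("+", "-")
  }
  pairs <- data.frame(i_start = feat$start[1], i_end = feat$end[1],
                      o_start = feat$start[2], o_end = feat$end[2],
                      strand = "+", architecture = architecture,
                      separation_nt = if (architecture == "separated") sep
                                      else 0L,
                      expected = expected)
  list(seq = seqs, features = feat, pairs = pairs)
}

## lipobox-bearing decoy ORF with no nearby partner
.decoyCassette <- function() {
  list(seq = .O_CASSETTE,
       features = data.frame(type = "CDS", start = 1L,
                             end = nchar(.O_CASSETTE), strand = "+",
                             role = "decoy-lipobox", sd_offset = NA),
       pairs = NULL)
}

#' Build a synthetic genome with known ground truth
#'
#' Assembles planted elements — genes with Shine-Dalgarno motifs at chosen
#' offsets, i-spanin/o-spanin pair constructs in embedded, overlapping or
#' separated architectures, and decoy lipobox ORFs — on an inert background
#' that carries stop codons in all six frames but no initiation codons, so
#' planted ORFs are recovered exactly. A build-time six-frame sweep records
#' any decoy ORF arising inside planted cassettes in the truth.
#'
#' @param seed integer seed; identical seeds give identical bytes.
#' @param elements list of element descriptors, each a list with `kind`
#'   (`"gene"`, `"spanin_pair"`, `"decoy_lipobox"`) and kind-specific
#'   fields: genes take `sdOffset` (default 7), `aaLen` (default 32),
#'   `strand`, `sdMotif`; spanin pairs take `architecture`
#'   (`"embedded"`/`"overlapping"`/`"separated"`), `sep` (nt, default 20)
#'   and `oppositeStrand`; `gapBefore` overrides the spacer length ahead
#'   of any element.
#' @param minLen pad the genome with background up to this length.
#' @param name genome sequence name.
#' @return a list with `genome` (a one-sequence `DNAStringSet`) and
#'   `truth`: `features` (a [FeatureSet] of planted gene/CDS/SD features),
#'   `pairs` (expected spanin pairs with coordinates), `decoys`
#'   (data.frame of unplanned ORFs found by the sweep).
#' @export
makeGenomeFixture <- function(seed = 1L, elements = list(), minLen = 1000L,
                              name = "synthetic_genome") {
  set.seed(seed)
  parts <- character()
  pos <- 0L
  feats <- list(); pairs <- list()
  for (el in elements) {
    gap <- if (!is.null(el$gapBefore)) el$gapBefore
           else sample(30:60, 1L)
    parts <- c(parts, .inertSpacer(gap))
    pos <- pos + gap
    cas <- switch(el$kind,
      gene = .geneCassette(
        sdOffset = if (is.null(el$sdOffset)) 7L else el$sdOffset,
        aaLen = if (is.null(el$aaLen)) 32L else el$aaLen,
        strand = if (is.null(el$strand)) "+" else el$strand,
        sdMotif = if (is.null(el$sdMotif)) "AGGAGGT" else el$sdMotif),
      spanin_pair = .spaninCassette(
        architecture = if (is.null(el$architecture)) "embedded"
                       else el$architecture,
        sep = if (is.null(el$sep)) 20L else el$sep,
        oppositeStrand = isTRUE(el$oppositeStrand)),
      decoy_lipobox = .decoyCassette(),
      stop("unknown fixture element kind: ", el$kind))
    f <- cas$features
    f$start <- f$start + pos; f$end <- f$end + pos
    feats[[length(feats) + 1L]] <- f
    if (!is.null(cas$pairs)) {
      p <- cas$pairs
      p[, c("i_start", "i_end", "o_start", "o_end")] <-
        p[, c("i_start", "i_end", "o_start", "o_end")] + pos
      pairs[[length(pairs) + 1L]] <- p
    }
    parts <- c(parts, cas$seq)
    pos <- pos + nchar(cas$seq)
  }
  tail_gap <- max(40L, minLen - pos)
  parts <- c(parts, .inertSpacer(tail_gap))
  genome_seq <- paste(parts, collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(genome_seq, name))
  mcols(genome) <- DataFrame(circular = FALSE)
  truth_feats <- if (length(feats)) do.call(rbind, feats)
                 else data.frame(type = character(), start = integer(),
                                 end = integer(), strand = character(),
                                 role = character(), sd_offset = numeric())
  truth_pairs <- if (length(pairs)) do.call(rbind, pairs)
                 else data.frame(i_start = integer(), i_end = integer(),
                                 o_start = integer(), o_end = integer(),
                                 strand = character(),
                                 architecture = character(),
                                 separation_nt = integer(),
                                 expected = logical())
  rownames(truth_feats) <- NULL; rownames(truth_pairs) <- NULL
  ## build-time self-check: re-extract planted sequences
  for (i in seq_len(nrow(truth_feats))) {
    if (identical(truth_feats$type[i], "Shine_Dalgarno_sequence")) {
      got <- substr(genome_seq, truth_feats$start[i], truth_feats$end[i])
      if (truth_feats$strand[i] == "-") got <- .revcomp(got)
      stopifnot(grepl("^[ACGT]+$", got))
    }
    if (identical(truth_feats$type[i], "CDS")) {
      nt <- substr(genome_seq, truth_feats$start[i], truth_feats$end[i])
      if (truth_feats$strand[i] == "-") nt <- .revcomp(nt)
      stopifnot(substr(nt, 1, 3) == "ATG")
    }
  }
  ## sweep for decoy ORFs beyond the planted truth
  called <- callOrfs(genome, minAaLen = 30L)
  cds <- called[featureType(called) == "CDS"]
  key_called <- sprintf("%d-%d%s", start(cds), end(cds),
                        as.character(strand(cds)))
  tf_cds <- truth_feats[truth_feats$type %in% c("CDS", "gene") &
                        truth_feats$role != "sd", , drop = FALSE]
  tf_cds <- unique(tf_cds[, c("start", "end", "strand")])
  key_truth <- sprintf("%d-%d%s", tf_cds$start, tf_cds$end, tf_cds$strand)
  extra <- which(!(key_called %in% key_truth))
  decoys <- data.frame(start = start(cds)[extra], end = end(cds)[extra],
                       strand = as.character(strand(cds))[extra])
  fs <- .truthFeatureSet(truth_feats, name, nchar(genome_seq))
  list(genome = genome,
       truth = list(features = fs, feature_table = truth_feats,
                    pairs = truth_pairs, decoys = decoys))
}

## turn the flat truth table into a parented FeatureSet
.truthFeatureSet <- function(tf, seqname, seqlen) {
  rows <- list()
  gi <- 0L
  i <- 1L
  n <- nrow(tf)
  while (i <= n) {
    if (tf$type[i] == "gene") {
      gi <- gi + 1L
      gid <- sprintf("tgene%03d", gi)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "gene", start = tf$start[i], end = tf$end[i],
        strand = tf$strand[i], ID = gid, Parent = NA)
      i <- i + 1L
      while (i <= n && tf$type[i] != "gene" &&
             tf$role[i] %in% c("gene", "sd")) {
        sub_id <- if (tf$type[i] == "CDS") paste0(gid, ".cds")
                  else paste0(gid, ".sd")
        rows[[length(rows) + 1L]] <- data.frame(
          type = tf$type[i], start = tf$start[i], end = tf$end[i],
          strand = tf$strand[i], ID = sub_id, Parent = gid)
        i <- i + 1L
      }
    } else {
      gi <- gi + 1L
      gid <- sprintf("tgene%03d", gi)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "gene", start = tf$start[i], end = tf$end[i],
        strand = tf$strand[i], ID = gid, Parent = NA)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "CDS", start = tf$start[i], end = tf$end[i],
        strand = tf$strand[i], ID = paste0(gid, ".cds"), Parent = gid)
      i <- i + 1L
    }
  }
  if (!length(rows)) return(FeatureSet())
  df <- do.call(rbind, rows)
  FeatureSet(seqid = seqname, start = df$start, end = df$end,
             strand = df$strand, type = df$type, ID = df$ID,
             Parent = df$Parent,
             seqinfo = GenomeInfoDb::Seqinfo(seqname, seqlen))
}

#' Build alignment records exercising interrupted-gene detection
#'
#' Constructs a genome-feature set and an HSP table in which two query
#' genes hit complementary intervals of one synthetic subject protein (the
#' split-gene signature), plus optional noise: an HSP below the identity
#' threshold, a single-fragment subject, and an opposite-strand fragment
#' pair. With `acrossOrigin = TRUE` the two fragments sit at the genome
#' ends so the split spans the origin of a circular genome.
#'
#' @param seed integer seed.
#' @param genomeLength genome length in nt (default 40000).
#' @param fragmentGap genomic gap between the two fragments (default 2000;
#'   ignored when `acrossOrigin = TRUE`).
#' @param acrossOrigin place the fragments across the genome ends.
#' @param noise add the noise records.
#' @return a list with `hits` (HSP `data.frame`), `features` (a
#'   [FeatureSet] resolving the query ids), `genomeLength`, and `truth`
#'   (expected subject id(s) of the detected candidate and the noise
#'   subject ids that must not be detected).
#' @export
makeSplitGeneRecords <- function(seed = 1L, genomeLength = 40000L,
                                 fragmentGap = 2000L, acrossOrigin = FALSE,
                                 noise = TRUE) {
  set.seed(seed)
  hsp <- function(q, s, sstart, send, len, ident, bits)
    data.frame(qseqid = q, sseqid = s, pident = round(100 * ident / len, 2),
               length = len, mismatch = len - ident, gapopen = 0L,
               qstart = 1L, qend = len, sstart = sstart, send = send,
               evalue = 1e-30, bitscore = bits, identities = ident)
  feats <- list(); hits <- list()
  addFeat <- function(id, start, end, strand) {
    feats[[length(feats) + 1L]] <<- data.frame(ID = id, start = start,
                                               end = end, strand = strand)
  }
  if (acrossOrigin) {
    ## 5' portion of the split gene at the genome end, 3' at the start
    addFeat("q_splitA", genomeLength - 800L, genomeLength - 50L, "+")
    addFeat("q_splitB", 200L, 900L, "+")
    hits[[1]] <- hsp("q_splitA", "subj_split", 1L, 120L, 120L, 108L, 220)
    hits[[2]] <- hsp("q_splitB", "subj_split", 131L, 250L, 120L, 110L, 230)
  } else {
    s1 <- 2000L
    addFeat("q_splitA", s1, s1 + 360L, "+")
    addFeat("q_splitB", s1 + 360L + fragmentGap, s1 + 360L + fragmentGap + 390L,
            "+")
    hits[[1]] <- hsp("q_splitA", "subj_split", 1L, 120L, 120L, 108L, 220)
    hits[[2]] <- hsp("q_splitB", "subj_split", 131L, 250L, 120L, 110L, 230)
  }
  noise_subjects <- character()
  if (noise) {
    ## single-fragment subject: only one query, never a candidate
    addFeat("q_single", 12000L, 12900L, "+")
    hits[[length(hits) + 1L]] <- hsp("q_single", "subj_single", 1L, 280L,
                                     280L, 250L, 400)
    ## low-identity HSPs (below 0.3) on a second subject pair
    addFeat("q_lowA", 15000L, 15400L, "+")
    addFeat("q_lowB", 16000L, 16400L, "+")
    hits[[length(hits) + 1L]] <- hsp("q_lowA", "subj_low", 1L, 100L, 100L,
                                     20L, 40)
    hits[[length(hits) + 1L]] <- hsp("q_lowB", "subj_low", 121L, 220L, 100L,
                                     25L, 45)
    ## opposite-strand fragments on a third subject
    addFeat("q_oppA", 20000L, 20400L, "+")
    addFeat("q_oppB", 21000L, 21400L, "-")
    hits[[length(hits) + 1L]] <- hsp("q_oppA", "subj_opp", 1L, 110L, 110L,
                                     90L, 180)
    hits[[length(hits) + 1L]] <- hsp("q_oppB", "subj_opp", 121L, 230L, 110L,
                                     95L, 190)
    noise_subjects <- c("subj_single", "subj_low", "subj_opp")
  }
  fdf <- do.call(rbind, feats)
  fs <- FeatureSet(seqid = "synthetic_genome", start = fdf$start,
                   end = fdf$end, strand = fdf$strand, type = "CDS",
                   ID = fdf$ID)
  list(hits = do.call(rbind, hits), features = fs,
       genomeLength = genomeLength,
       truth = list(detected = "subj_split", rejected = noise_subjects,
                    spans_origin = acrossOrigin))
}

#' Boundary battery of terminator records
#'
#' The full 3x3x3 grid of scores \{94, 95, 96\}, stem matches \{4, 5, 6\}
#' and tail T-runs \{3, 4, 5\}; exactly the combinations with score > 95,
#' stem >= 5 and run >= 4 satisfy the promotion criteria.
#'
#' @param seed integer seed (records are deterministic; the seed fixes the
#'   record order contract).
#' @return a list with `records` (terminator `data.frame`) and `truth`
#'   (logical vector marking the records expected to survive
#'   [filterTerminators()] at its defaults).
#' @export
makeTerminatorRecords <- function(seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(score = c(94, 95, 96), stem = c(4L, 5L, 6L),
                      trun = c(3L, 4L, 5L))
  rec <- data.frame(
    seq_id = "synthetic_genome",
    start = 100L + 50L * (seq_len(nrow(grid)) - 1L),
    end = 130L + 50L * (seq_len(nrow(grid)) - 1L),
    strand = "+",
    score = grid$score,
    stem_matches = grid$stem,
    tail_seq = paste0("A", strrep("T", grid$trun), "GCA"))
  truth <- grid$score > 95 & grid$stem >= 5L & grid$trun >= 4L
  list(records = rec, truth = truth)
}
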