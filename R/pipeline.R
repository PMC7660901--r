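## Desk-scale convenience pipelines mirroring the structural -> functional
## annotation ordering: naive ORF models with SD annotation (structural),
## then evidence reports (spanins, interrupted genes, comparative tables).

#' Run the structural annotation pipeline
#'
#' Chains [callOrfs()] -> [filterByStartCodon()] -> [ensureGeneParents()]
#' -> [annotateShineDalgarno()] on a genome and writes a deterministic
#' GFF3 gene-model document. When a terminator prediction file is
#' supplied, predictions passing [filterTerminators()] are promoted to
#' `terminator` features in the output.
#'
#' @param genomeFile path to the genome FASTA.
#' @param outFile output GFF3 path.
#' @param minAaLen minimum ORF protein length (default 30).
#' @param startCodons accepted start codons (default ATG/GTG/TTG).
#' @param near,far Shine-Dalgarno window bounds (defaults 3, 24).
#' @param terminatorFile optional terminator prediction table.
#' @param minScore,minStem,minTRun terminator promotion thresholds.
#' @return the final [FeatureSet], invisibly; the GFF3 is written to
#'   `outFile`.
#' @export
runStructural <- function(genomeFile, outFile, minAaLen = 30L,
                          startCodons = c("ATG", "GTG", "TTG"),
                          near = 3L, far = 24L, terminatorFile = NULL,
                          minScore = 95, minStem = 5L, minTRun = 4L) {
  if (!file.exists(genomeFile))
    stop("genome file not found: ", genomeFile)
  genome <- readGenome(genomeFile)
  fs <- callOrfs(genome, minAaLen = minAaLen)
  fs <- filterByStartCodon(fs, genome, allowed = startCodons)
  fs <- ensureGeneParents(fs)
  fs <- annotateShineDalgarno(fs, genome, near = near, far = far)
  if (!is.null(terminatorFile)) {
    term <- readTerminators(terminatorFile)
    term <- filterTerminators(term, minScore = minScore, minStem = minStem,
                              minTRun = minTRun)
    if (nrow(term)) {
      tf <- FeatureSet(seqid = term$seq_id, start = term$start,
                       end = term$end, strand = term$strand,
                       type = "terminator",
                       ID = sprintf("terminator%03d", seq_len(nrow(term))),
                       score = term$score)
      GenomeInfoDb::seqlevels(tf) <- GenomeInfoDb::seqlevels(fs)
      fs <- .asFeatureSet(c(methods::as(fs, "GRanges"),
                            methods::as(tf, "GRanges")))
    }
  }
  writeGFF3(fs, outFile)
  invisible(fs)
}

.writeTsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  file
}

#' Run the evidence reports
#'
#' Produces the functional/comparative evidence tables on one genome: the
#' spanin candidate report, and — when an alignment hits file is supplied —
#' interrupted-gene candidates, Dice-filtered hits and the related-organism
#' ranking tables. Reports are TSV files with fixed column orders; missing
#' inputs skip the corresponding report with a notice.
#'
#' @param genomeFile path to the genome FASTA.
#' @param outDir output directory (created if needed).
#' @param gffFile optional GFF3 of gene models used to resolve alignment
#'   query ids for interrupted-gene detection.
#' @param proteinHitsFile optional protein-level tabular hits (with the
#'   default 12 columns) for interrupted-gene detection and the
#'   unique-protein ranking.
#' @param nucleotideHitsFile optional genome-level tabular hits carrying
#'   `qlen`/`slen` columns for the Dice filter and nucleotide ranking.
#' @param nucleotideHitsColumns column declaration for
#'   `nucleotideHitsFile` (default: the 12 standard columns plus
#'   `qlen`, `slen`).
#' @param maxSepNt,sepMin,minIdentityFraction interrupted-gene settings.
#' @param minPct,maxPct Dice filter bounds.
#' @param topProteins,topNucleotide ranking table sizes (20 and 10).
#' @param circular treat the genome as circular.
#' @return named character vector of written report paths, invisibly.
#' @export
runReports <- function(genomeFile, outDir, gffFile = NULL,
                       proteinHitsFile = NULL, nucleotideHitsFile = NULL,
                       nucleotideHitsColumns = c(.BLAST6_DEFAULT, "qlen",
                                                 "slen"),
                       maxSepNt = 10000L, sepMin = 0L,
                       minIdentityFraction = 0.3, minPct = 50,
                       maxPct = 100, topProteins = 20L,
                       topNucleotide = 10L, circular = FALSE) {
  if (!file.exists(genomeFile))
    stop("genome file not found: ", genomeFile)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  genome <- readGenome(genomeFile, circular = circular)
  out <- character()
  rep <- findSpanins(genome)
  out["spanin_pairs"] <- .writeTsv(spaninPairs(rep),
                                   file.path(outDir, "spanin_pairs.tsv"))
  out["spanin_candidates"] <- .writeTsv(
    spaninCandidates(rep), file.path(outDir, "spanin_candidates.tsv"))
  if (!is.null(proteinHitsFile)) {
    hits <- readAlignmentTabular(proteinHitsFile)
    if (!is.null(gffFile)) {
      feats <- readGFF3(gffFile)
      cand <- detectInterrupted(hits, feats, genome = genome,
                                maxSepNt = maxSepNt, sepMin = sepMin,
                                minIdentityFraction = minIdentityFraction,
                                circular = circular)
      out["interrupted"] <- .writeTsv(cand,
                                      file.path(outDir, "interrupted.tsv"))
    }
    out["rank_proteins"] <- .writeTsv(
      rankByUniqueProteins(hits, topN = topProteins),
      file.path(outDir, "rank_proteins.tsv"))
  } else {
    message("no protein hits file supplied; skipping interrupted-gene and ",
            "protein ranking reports")
  }
  if (!is.null(nucleotideHitsFile)) {
    nthits <- readAlignmentTabular(nucleotideHitsFile,
                                   columns = nucleotideHitsColumns)
    filtered <- diceFilter(nthits, minPct = minPct, maxPct = maxPct)
    out["dice_filtered"] <- .writeTsv(
      filtered, file.path(outDir, "dice_filtered.tsv"))
    out["rank_nt"] <- .writeTsv(
      rankNucleotideHits(nthits, topN = topNucleotide),
      file.path(outDir, "rank_nt.tsv"))
  } else {
    message("no nucleotide hits file supplied; skipping comparative reports")
  }
  invisible(out)
}
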