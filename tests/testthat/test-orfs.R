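test_that("a single plus-strand ORF is called with the stop codon included", {
  s <- paste0("ATG", strrep("GCT", 32), "TAA")   # 33 aa protein, 102 nt
  g <- asGenome(s)
  fs <- callOrfs(g, minAaLen = 30)
  expect_identical(orfTable(fs),
                   data.frame(start = 1L, end = 102L, strand = "+"))
  expect_identical(orfTable(fs), oracleOrfs(s, 30))
  ## every CDS has a gene parent
  cds <- fs[featureType(fs) == "CDS"]
  expect_true(all(featureParent(cds) %in% featureID(fs)))
  ## below the length cutoff nothing is called (protein is 33 aa)
  expect_equal(nrow(orfTable(callOrfs(g, minAaLen = 34))), 0)
})

test_that("ORF calling matches the six-frame brute-force oracle on random sequence", {
  set.seed(7)
  for (rep in 1:25) {
    s <- randDna(sample(500:2000, 1))
    expect_identical(orfTable(callOrfs(asGenome(s), minAaLen = 30)),
                     oracleOrfs(s, 30),
                     info = paste("genome", rep))
  }
})

test_that("allStarts emits one ORF per in-frame start and contains the default set", {
  set.seed(11)
  s <- randDna(1500)
  default <- orfTable(callOrfs(asGenome(s), minAaLen = 20))
  all_starts <- orfTable(callOrfs(asGenome(s), minAaLen = 20,
                                  allStarts = TRUE))
  expect_identical(all_starts, oracleOrfs(s, 20, allStarts = TRUE))
  expect_gte(nrow(all_starts), nrow(default))
  key <- function(d) paste(d$start, d$end, d$strand)
  expect_true(all(key(default) %in% key(all_starts)))
})

test_that("ORF calls mirror under reverse complement", {
  set.seed(13)
  s <- randDna(1200)
  L <- nchar(s)
  fwd <- orfTable(callOrfs(asGenome(s), minAaLen = 25))
  rev <- orfTable(callOrfs(asGenome(rcomp(s)), minAaLen = 25))
  mirrored <- data.frame(start = L - fwd$end + 1L, end = L - fwd$start + 1L,
                         strand = ifelse(fwd$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$start, mirrored$end,
                             mirrored$strand), ]
  rownames(mirrored) <- NULL
  expect_identical(rev, mirrored)
})

test_that("circular genomes yield origin-spanning ORFs as joined parts", {
  body <- paste0("ATG", strrep("CTC", 40), "TAA")  # 126 nt ORF
  ## place the ORF across the origin: last 60 nt at the sequence end,
  ## remainder at the sequence start; pad with stop-rich spacer
  orf_start_tail <- 60L
  spacer <- strrep("TAGT", 40)
  s <- paste0(substr(body, orf_start_tail + 1, nchar(body)), spacer,
              substr(body, 1, orf_start_tail))
  lin <- callOrfs(asGenome(s), minAaLen = 30)
  expect_false(any(orfTable(lin)$strand == "+"))
  circ <- callOrfs(asGenome(s, circular = TRUE), minAaLen = 30)
  cds <- circ[featureType(circ) == "CDS" &
              as.character(GenomicRanges::strand(circ)) == "+"]
  expect_equal(length(cds), 2)   # two joined parts
  joined <- vapply(S4Vectors::mcols(cds)$attrs, `[[`, "", "joined")
  expect_equal(length(unique(joined)), 1)
  ## translated joined CDS reproduces the planted protein
  prot <- translateCDS(circ, asGenome(s, circular = TRUE))
  expect_equal(unname(prot[[unique(joined)]]),
               paste0("M", strrep("L", 40)))
})

test_that("start-codon filtering keeps ATG/GTG/TTG groups and drops the rest", {
  s <- paste0(
    strrep("TAGT", 10),                               # 40 nt spacer
    "ATG", strrep("CTC", 32), "TAA",                  # ATG ORF at 41
    strrep("TAGT", 10),
    "CTG", strrep("CTC", 32), "TAA")                  # CTG ORF
  g <- asGenome(s)
  fs <- callOrfs(g, minAaLen = 30)
  planted <- data.frame(start = c(41L, 183L), end = c(142L, 284L),
                        strand = "+")
  tab_all <- orfTable(fs)
  expect_true(all(paste(planted$start, planted$end) %in%
                  paste(tab_all$start, tab_all$end)))
  kept <- filterByStartCodon(fs, g)
  tab <- orfTable(kept)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$start, 41L)
  ## the failing group's gene parent goes with its CDS
  expect_false(any(featureType(kept) == "gene" &
                   GenomicRanges::start(kept) == 183L))
  ## idempotent, subset of input
  expect_identical(orfTable(filterByStartCodon(kept, g)), tab)
})

test_that("minus-strand start codons are evaluated on the reverse complement", {
  ## GTG-started ORF on the minus strand
  fwd <- paste0("GTG", strrep("CTC", 32), "TAA")
  s <- paste0(strrep("TAGT", 10), rcomp(fwd), strrep("TAGT", 10))
  g <- asGenome(s)
  fs <- callOrfs(g, minAaLen = 30)
  tab <- orfTable(fs)
  expect_equal(tab$strand, "-")
  kept <- filterByStartCodon(fs, g, allowed = c("ATG", "GTG", "TTG"))
  expect_equal(nrow(orfTable(kept)), 1)
  none <- filterByStartCodon(fs, g, allowed = "ATG")
  expect_equal(nrow(orfTable(none)), 0)
})

test_that("a CDS shorter than one codon is rejected by the start filter", {
  fs <- FeatureSet(seqid = "g", start = c(1L, 1L), end = c(2L, 2L),
                   strand = "+", type = c("gene", "CDS"),
                   ID = c("g1", "c1"), Parent = c(NA, "g1"))
  expect_error(filterByStartCodon(fs, asGenome("ACGTACGT")), "c1")
})

test_that("feature-type filtering drops listed types with their children", {
  fs <- FeatureSet(
    seqid = "g", start = c(10L, 10L, 2L, 200L), end = c(90L, 90L, 7L, 240L),
    strand = "+",
    type = c("gene", "CDS", "Shine_Dalgarno_sequence", "terminator"),
    ID = c("gene1", "cds1", "sd1", "t1"),
    Parent = c(NA, "gene1", "gene1", NA))
  dropped <- filterFeatureTypes(fs, "Shine_Dalgarno_sequence", mode = "drop")
  expect_setequal(featureID(dropped), c("gene1", "cds1", "t1"))
  ## dropping a parent removes its children too
  no_gene <- filterFeatureTypes(fs, "gene", mode = "drop")
  expect_setequal(featureID(no_gene), "t1")
  ## empty drop list is the identity
  expect_equal(featureID(filterFeatureTypes(fs, character(), mode = "drop")),
               featureID(fs))
  ## keep mode retains listed types plus ancestors
  kept <- filterFeatureTypes(fs, c("gene", "CDS"), mode = "keep")
  expect_setequal(featureID(kept), c("gene1", "cds1"))
  kept_cds <- filterFeatureTypes(fs, "CDS", mode = "keep")
  expect_setequal(featureID(kept_cds), c("gene1", "cds1"))
  ## idempotent
  expect_equal(featureID(filterFeatureTypes(kept, c("gene", "CDS"),
                                            mode = "keep")),
               featureID(kept))
})

test_that("orphan CDS features gain unique gene parents, idempotently", {
  fs <- FeatureSet(seqid = "g", start = c(10L, 200L), end = c(108L, 298L),
                   strand = c("+", "-"), type = "CDS",
                   ID = c("c1", "c2"))
  fixed <- ensureGeneParents(fs)
  genes <- fixed[featureType(fixed) == "gene"]
  expect_equal(length(genes), 2)
  expect_equal(anyDuplicated(featureID(genes)), 0)
  cds <- fixed[featureType(fixed) == "CDS"]
  expect_true(all(featureParent(cds) %in% featureID(genes)))
  ## spans and strands match their CDS
  i <- match(featureParent(cds), featureID(genes))
  expect_equal(GenomicRanges::start(genes)[i], GenomicRanges::start(cds))
  expect_equal(as.character(GenomicRanges::strand(genes))[i],
               as.character(GenomicRanges::strand(cds)))
  ## idempotent
  again <- ensureGeneParents(fixed)
  expect_equal(length(again), length(fixed))
  expect_setequal(featureID(again), featureID(fixed))
})

test_that("terminator promotion applies the three criteria exactly", {
  term <- data.frame(
    seq_id = "g", start = 1L, end = 30L, strand = "+",
    score = c(96, 95, 99, 96),
    stem_matches = c(5L, 9L, 5L, 4L),
    tail_seq = c("ATTTTG", "TTTT", "TTTA", "TTTTT"))
  kept <- filterTerminators(term)
  ## row 1 passes; row 2 fails the exclusive score threshold; row 3 has a
  ## 3-T run; row 4 fails the stem minimum
  expect_equal(rownames(kept), "1")
  ## full boundary battery: 4 of 27 combinations survive
  bat <- makeTerminatorRecords(1)
  surv <- filterTerminators(bat$records)
  expect_equal(nrow(surv), 4)
  expect_equal(which(bat$truth), as.integer(rownames(surv)))
  ## order preserved, idempotent
  expect_identical(filterTerminators(surv), surv)
})
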