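test_that("default SD candidate list is the consensus and its >=4 nt substrings", {
  cands <- defaultSdCandidates()
  expect_equal(cands[1], "AGGAGGT")
  expect_true("GGAGG" %in% cands)
  expect_true(all(nchar(cands) >= 4))
  expect_equal(anyDuplicated(cands), 0)
  ## ordered by decreasing length
  expect_true(all(diff(nchar(cands)) <= 0))
  ## every candidate occurs in the consensus
  expect_true(all(vapply(cands, grepl, logical(1), x = "AGGAGGT",
                         fixed = TRUE)))
})

test_that("upstream windows use the documented coordinate arithmetic", {
  s <- randDna(200)
  g <- asGenome(s)
  plus <- FeatureSet(seqid = "g", start = 100L, end = 150L, strand = "+",
                     type = "CDS", ID = "c1")
  w <- upstreamWindow(plus, g, near = 3, far = 24)
  ## plus strand, start codon at 100: genome positions 76..97
  expect_equal(attr(w, "gstart"), 76L)
  expect_equal(attr(w, "gend"), 97L)
  expect_equal(as.character(w), substr(s, 76, 97))
  expect_false(attr(w, "truncated"))

  minus <- FeatureSet(seqid = "g", start = 10L, end = 50L, strand = "-",
                      type = "CDS", ID = "c2")
  w2 <- upstreamWindow(minus, g, near = 3, far = 24)
  ## minus strand, start codon first base at 50: rc of positions 53..74
  expect_equal(attr(w2, "gstart"), 53L)
  expect_equal(attr(w2, "gend"), 74L)
  expect_equal(as.character(w2), rcomp(substr(s, 53, 74)))

  edge <- FeatureSet(seqid = "g", start = 2L, end = 40L, strand = "+",
                     type = "CDS", ID = "c3")
  w3 <- upstreamWindow(edge, g, near = 3, far = 24)
  expect_true(attr(w3, "truncated"))
  expect_equal(nchar(w3), 0)
})

test_that("best match is the longest candidate, ties to the smallest offset", {
  hit <- bestSdMatch("TTAGGAGGTCAATTCCAAGGAC")
  expect_equal(hit$motif, "AGGAGGT")
  ## pyrimidine-only window has no match
  expect_equal(nrow(bestSdMatch("TTTCCCTTTCCC")), 0)
  ## two equal-length occurrences: the one closer to the start codon wins
  w <- "AGGATTTTAGGATTT"
  h <- bestSdMatch(w, nearOffset = 3)
  expect_equal(h$motif, "AGGA")
  expect_equal(h$wstart, 9L)
  expect_equal(h$offset, 3L + nchar(w) - 12L)
})

test_that("longest mode equals the maximum of all mode on random windows", {
  set.seed(21)
  for (i in 1:200) {
    w <- randDna(22)
    all_hits <- bestSdMatch(w, mode = "all")
    oracle <- oracleSdMatches(w)
    ## same occurrence set as the brute-force search
    key <- function(d) sort(paste(d$motif, d$wstart, d$wend))
    expect_equal(key(all_hits), key(oracle), info = w)
    top <- bestSdMatch(w, mode = "longest")
    if (!nrow(all_hits)) {
      expect_equal(nrow(top), 0, info = w)
    } else {
      expect_equal(nchar(top$motif), max(nchar(all_hits$motif)), info = w)
      best_len <- all_hits[nchar(all_hits$motif) == nchar(top$motif), ]
      expect_equal(top$offset, min(best_len$offset), info = w)
    }
  }
})

test_that("planted motifs are recovered at their planted offsets", {
  set.seed(22)
  for (i in 1:100) {
    motif <- sample(defaultSdCandidates(), 1)
    offset <- sample(3:(24 - nchar(motif) + 1), 1)
    fx <- makeGenomeFixture(seed = i, elements = list(
      list(kind = "gene", sdOffset = offset, sdMotif = motif)))
    fs <- callOrfs(fx$genome, minAaLen = 30)
    fs <- filterByStartCodon(fs, fx$genome)
    ann <- annotateShineDalgarno(fs, fx$genome)
    tt <- fx$truth$feature_table
    truth_cds <- tt[tt$type == "CDS", ]
    truth_sd <- tt[tt$type == "Shine_Dalgarno_sequence", ]
    ## find the planted gene's own SD child
    cds_i <- which(featureType(ann) == "CDS" &
                   GenomicRanges::start(ann) == truth_cds$start &
                   GenomicRanges::end(ann) == truth_cds$end)
    expect_length(cds_i, 1)
    gid <- featureParent(ann)[cds_i]
    sd <- childrenOf(ann, gid)
    sd <- sd[featureType(sd) == "Shine_Dalgarno_sequence"]
    expect_equal(length(sd), 1, info = paste(motif, offset, i))
    expect_equal(GenomicRanges::start(sd), truth_sd$start)
    expect_equal(GenomicRanges::end(sd), truth_sd$end)
    off_attr <- S4Vectors::mcols(sd)$attrs[[1]][["sd_offset"]]
    expect_equal(as.integer(off_attr), offset, info = paste(motif, i))
  }
})

test_that("SD child coordinates re-extract to the reported motif on both strands", {
  for (strand in c("+", "-")) {
    fx <- makeGenomeFixture(seed = 5, elements = list(
      list(kind = "gene", sdOffset = 8, strand = strand)))
    g <- fx$genome
    fs <- annotateShineDalgarno(
      filterByStartCodon(callOrfs(g, 30), g), g)
    tt <- fx$truth$feature_table
    truth_cds <- tt[tt$type == "CDS", ]
    cds_i <- which(featureType(fs) == "CDS" &
                   GenomicRanges::start(fs) == truth_cds$start &
                   GenomicRanges::end(fs) == truth_cds$end)
    sd <- childrenOf(fs, featureParent(fs)[cds_i])
    sd <- sd[featureType(sd) == "Shine_Dalgarno_sequence"]
    expect_equal(length(sd), 1, info = strand)
    seqtxt <- as.character(g[[1]])
    got <- substr(seqtxt, GenomicRanges::start(sd), GenomicRanges::end(sd))
    if (strand == "-") got <- rcomp(got)
    expect_equal(got, S4Vectors::mcols(sd)$attrs[[1]][["sd_motif"]],
                 info = strand)
    expect_equal(as.character(GenomicRanges::strand(sd)), strand)
  }
})

test_that("annotation skips genes that already own an RBS child and is idempotent", {
  fx <- makeGenomeFixture(seed = 9, elements = list(
    list(kind = "gene", sdOffset = 7)))
  g <- fx$genome
  fs <- filterByStartCodon(callOrfs(g, 30), g)
  once <- annotateShineDalgarno(fs, g)
  n_sd <- sum(featureType(once) == "Shine_Dalgarno_sequence")
  expect_gte(n_sd, 1)
  ## all original features pass through untouched
  expect_true(all(featureID(fs) %in% featureID(once)))
  expect_equal(length(once), length(fs) + n_sd)
  twice <- annotateShineDalgarno(once, g)
  expect_equal(length(twice), length(once))
  expect_setequal(featureID(twice), featureID(once))
  ## an existing ribosome_entry_site child also suppresses annotation
  gr <- methods::as(once, "GRanges")
  S4Vectors::mcols(gr)$type[S4Vectors::mcols(gr)$type ==
                            "Shine_Dalgarno_sequence"] <-
    "ribosome_entry_site"
  res <- annotateShineDalgarno(phannot:::.asFeatureSet(gr), g)
  expect_equal(sum(featureType(res) == "Shine_Dalgarno_sequence"), 0)
})
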