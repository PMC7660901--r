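test_that("lipobox patterns match their documented examples", {
  h1 <- findLipoboxes("MKKLAGCDE")
  expect_equal(h1$offset, 4L)
  expect_equal(h1$motif, "LAGC")
  expect_equal(h1$pattern, 1L)

  h2 <- findLipoboxes("MAWGC")
  expect_equal(h2$offset, 2L)
  expect_equal(h2$motif, "AWGC")
  expect_equal(h2$pattern, 2L)

  ## E is excluded at position 2 of pattern 1; pattern 2 needs W
  expect_equal(nrow(findLipoboxes("MLEGC")), 0)
  ## X never satisfies a constrained position
  expect_equal(nrow(findLipoboxes("MLXGC")), 0)
  ## region bound: motif starting after regionEnd is not reported
  far <- paste0(strrep("P", 50), "LAGC")
  expect_equal(nrow(findLipoboxes(far, regionEnd = 40)), 0)
  expect_equal(nrow(findLipoboxes(far, regionEnd = 51)), 1)
})

test_that("lipobox search equals the brute-force residue check on random proteins", {
  set.seed(31)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:100) {
    prot <- paste(sample(aa20, 60, replace = TRUE), collapse = "")
    expect_equal(findLipoboxes(prot), oracleLipobox(prot), info = prot)
  }
})

test_that("overlapping lipobox occurrences are all reported", {
  ## LLGC at 1 and LGCC? build LLAGC: L-L-A-G-C has LLAG? no —
  ## use 'ILSC' style chain: I L S C -> pattern1 at 1; L S C? S not in GAS
  prot <- "MLLGCGCAA"   # LLGC at 2? L,L,G,C: yes; LGCG? G,C not C-terminal
  hits <- findLipoboxes(prot)
  oracle <- oracleLipobox(prot)
  expect_equal(hits, oracle)
})

test_that("hydropathy windows find a planted leucine run and reject charged sequence", {
  prot <- paste0(strrep("D", 10), strrep("L", 19), strrep("E", 10))
  segs <- predictTmSegments(prot, window = 19, threshold = 1.6)
  expect_equal(nrow(segs), 1)
  ## the pure-L window is the only one reaching mean 3.8
  expect_lte(segs$start, 11)
  expect_gte(segs$end, 29)
  expect_equal(segs$peak, 3.8, tolerance = 1e-12)

  expect_equal(nrow(predictTmSegments(strrep("D", 40))), 0)
  ## shorter than the window: empty
  expect_equal(nrow(predictTmSegments("MKL")), 0)
})

test_that("hydropathy means agree with direct averaging on a mixed protein", {
  set.seed(33)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  prot <- paste(sample(aa20, 40, replace = TRUE), collapse = "")
  segs <- predictTmSegments(prot, window = 19, threshold = 0)
  ## oracle: compute each window mean directly
  kd <- phannot:::.KD_SCALE
  vals <- kd[strsplit(prot, "")[[1]]]
  wins <- vapply(1:(40 - 19 + 1), function(i) mean(vals[i:(i + 18)]),
                 numeric(1))
  hot <- which(wins >= 0)
  if (length(hot)) {
    expect_equal(min(segs$start), min(hot))
    expect_equal(max(segs$end), max(hot) + 18)
  } else {
    expect_equal(nrow(segs), 0)
  }
})

test_that("pairing applies the strand rule, the 50-nt limit, and classifies architecture", {
  cand <- function(orf, start, end, strand, role)
    data.frame(orf = orf, seqid = "g", start = start, end = end,
               strand = strand, role = role)
  ## embedded: o wholly inside i, same strand
  pairs <- pairSpaninCandidates(rbind(
    cand("i1", 100, 500, "+", "i-spanin"),
    cand("o1", 200, 400, "+", "o-spanin")))
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$architecture, "embedded")
  expect_equal(pairs$separation_nt, 0L)

  ## 60 nt apart: no pair at the default limit
  expect_equal(nrow(pairSpaninCandidates(rbind(
    cand("i1", 100, 200, "+", "i-spanin"),
    cand("o1", 261, 400, "+", "o-spanin")))), 0)
  ## exactly 50 nt apart: paired
  p50 <- pairSpaninCandidates(rbind(
    cand("i1", 100, 200, "+", "i-spanin"),
    cand("o1", 251, 400, "+", "o-spanin")))
  expect_equal(p50$separation_nt, 50L)
  expect_equal(p50$architecture, "separated")

  ## opposite strands never pair
  expect_equal(nrow(pairSpaninCandidates(rbind(
    cand("i1", 100, 200, "+", "i-spanin"),
    cand("o1", 211, 400, "-", "o-spanin")))), 0)

  ## partial overlap
  pov <- pairSpaninCandidates(rbind(
    cand("i1", 100, 300, "+", "i-spanin"),
    cand("o1", 290, 500, "+", "o-spanin")))
  expect_equal(pov$architecture, "overlapping")

  ## a dual-evidence ORF never pairs with itself
  expect_equal(nrow(pairSpaninCandidates(rbind(
    cand("b1", 100, 300, "+", "i-spanin"),
    cand("b1", 100, 300, "+", "o-spanin")))), 0)
})

test_that("planted spanin pairs are recovered in all three architectures", {
  for (arch in c("embedded", "overlapping", "separated")) {
    fx <- makeGenomeFixture(seed = 101, elements = list(
      list(kind = "spanin_pair", architecture = arch, sep = 35)))
    rep <- findSpanins(fx$genome)
    truth <- fx$truth$pairs
    pairs <- spaninPairs(rep)
    cands <- spaninCandidates(rep)
    found <- FALSE
    for (r in seq_len(nrow(pairs))) {
      ic <- cands[cands$orf == pairs$i_orf[r] & cands$role == "i-spanin", ][1, ]
      oc <- cands[cands$orf == pairs$o_orf[r] & cands$role == "o-spanin", ][1, ]
      if (ic$start == truth$i_start && ic$end == truth$i_end &&
          oc$start == truth$o_start && oc$end == truth$o_end)
        found <- TRUE
    }
    expect_true(found, info = arch)
    planted <- pairs[pairs$architecture == arch, ]
    expect_gte(nrow(planted), 1)
  }
})

test_that("a decoy lipobox ORF 300 nt away is reported only among unpaired candidates", {
  fx <- makeGenomeFixture(seed = 103, elements = list(
    list(kind = "spanin_pair", architecture = "embedded"),
    list(kind = "decoy_lipobox", gapBefore = 300)))
  rep <- findSpanins(fx$genome)
  tt <- fx$truth$feature_table
  decoy <- tt[tt$role == "decoy-lipobox", ]
  cands <- spaninCandidates(rep)
  dec_cand <- cands[cands$start == decoy$start & cands$end == decoy$end, ]
  expect_gte(nrow(dec_cand), 1)
  ## present among candidates but in no pair
  pairs <- spaninPairs(rep)
  pair_orfs <- c(pairs$i_orf, pairs$o_orf)
  expect_false(any(dec_cand$orf %in% pair_orfs))
  unp <- spaninUnpaired(rep)
  expect_true(any(unp$start == decoy$start & unp$end == decoy$end))
})

test_that("a background-only genome yields no spanin pairs", {
  fx <- makeGenomeFixture(seed = 104, elements = list(), minLen = 1500)
  rep <- findSpanins(fx$genome)
  expect_equal(nrow(spaninPairs(rep)), 0)
  expect_equal(nrow(spaninCandidates(rep)), 0)
})

test_that("every reported pair satisfies strand equality and the separation bound", {
  fx <- makeGenomeFixture(seed = 105, elements = list(
    list(kind = "spanin_pair", architecture = "separated", sep = 50),
    list(kind = "spanin_pair", architecture = "embedded")))
  rep <- findSpanins(fx$genome, maxSep = 50)
  pairs <- spaninPairs(rep)
  cands <- spaninCandidates(rep)
  for (r in seq_len(nrow(pairs))) {
    ic <- cands[cands$orf == pairs$i_orf[r] & cands$role == "i-spanin", ][1, ]
    oc <- cands[cands$orf == pairs$o_orf[r] & cands$role == "o-spanin", ][1, ]
    expect_equal(ic$strand, oc$strand)
    gap <- max(0, max(ic$start, oc$start) - min(ic$end, oc$end) - 1)
    expect_lte(gap, 50)
    expect_equal(pairs$separation_nt[r], gap)
  }
})

test_that("pair detection mirrors under reverse complement of the genome", {
  fx <- makeGenomeFixture(seed = 106, elements = list(
    list(kind = "spanin_pair", architecture = "separated", sep = 20)))
  g <- fx$genome
  L <- Biostrings::width(g)[1]
  grc <- asGenome(rcomp(as.character(g[[1]])), name = names(g))
  fwd <- spaninPairs(findSpanins(g))
  rev <- spaninPairs(findSpanins(grc))
  expect_equal(nrow(fwd), nrow(rev))
  ## the planted pair appears mirrored
  truth <- fx$truth$pairs
  cands_rev <- spaninCandidates(findSpanins(grc))
  mi <- c(L - truth$i_end + 1, L - truth$i_start + 1)
  mo <- c(L - truth$o_end + 1, L - truth$o_start + 1)
  found <- any(cands_rev$start == mi[1] & cands_rev$end == mi[2] &
               cands_rev$role == "i-spanin" & cands_rev$strand == "-") &&
           any(cands_rev$start == mo[1] & cands_rev$end == mo[2] &
               cands_rev$role == "o-spanin" & cands_rev$strand == "-")
  expect_true(found)
})

test_that("externally supplied TM predictions and BLAST support are honoured", {
  fx <- makeGenomeFixture(seed = 107, elements = list(
    list(kind = "spanin_pair", architecture = "separated", sep = 10)))
  g <- fx$genome
  base <- findSpanins(g)
  cands <- spaninCandidates(base)
  icand <- cands[cands$role == "i-spanin", ][1, ]
  ## external TM table naming a different ORF flips the i-candidate set
  oc_orf <- cands[cands$role == "o-spanin", ][1, "orf"]
  ext <- findSpanins(g, tmPredictions = data.frame(
    orf = oc_orf, start = 1, end = 19))
  ecands <- spaninCandidates(ext)
  expect_false(icand$orf %in% ecands$orf[ecands$role == "i-spanin"])
  expect_true(oc_orf %in% ecands$orf[ecands$role == "i-spanin"])
  ## spanin-database hits at e <= 0.001 annotate support; worse are ignored
  hits <- data.frame(qseqid = c(icand$orf, icand$orf),
                     sseqid = c("Rz_lambda", "weak_hit"),
                     evalue = c(1e-10, 0.5))
  wsup <- spaninCandidates(findSpanins(g, spaninDbHits = hits))
  row <- wsup[wsup$orf == icand$orf & wsup$role == "i-spanin", ]
  expect_equal(row$blast_support, "Rz_lambda")
})
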