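## Independent brute-force oracles, deliberately coded as plain state
## machines over the sequence so they share no logic with the package
## implementations they check.

TABLE11_STARTS <- c("ATG", "GTG", "TTG", "CTG", "ATT", "ATC", "ATA")
TABLE11_STOPS <- c("TAA", "TAG", "TGA")

randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")

rcomp <- function(x) {
  chartr_rev <- chartr("ACGT", "TGCA", x)
  paste(rev(strsplit(chartr_rev, "")[[1]]), collapse = "")
}

## six-frame ORF scan: walks each frame codon by codon, remembering the
## first start codon seen since the last stop; on a stop, emits the ORF
## when the protein (excluding the stop) reaches the minimum length
oracleOrfs <- function(s, minAa = 30, starts = TABLE11_STARTS,
                       allStarts = FALSE) {
  L <- nchar(s)
  res <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else rcomp(s)
    for (off in 0:2) {
      pending <- integer()   # nt positions of candidate starts
      p <- off + 1
      while (p + 2 <= L) {
        cod <- substr(ss, p, p + 2)
        if (cod %in% TABLE11_STOPS) {
          for (st in pending) {
            n_aa <- (p - st) / 3
            if (n_aa >= minAa) {
              a <- st; b <- p + 2
              if (strand == "-") { a2 <- L - b + 1; b <- L - a + 1; a <- a2 }
              res[[length(res) + 1]] <- c(a, b, strand == "-")
            }
            if (!allStarts) break
          }
          pending <- integer()
        } else if (cod %in% starts) {
          if (allStarts || !length(pending)) pending <- c(pending, p)
        }
        p <- p + 3
      }
      ## ORFs without a terminating stop are not emitted
    }
  }
  if (!length(res))
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  m <- do.call(rbind, res)
  df <- data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
                   strand = ifelse(m[, 3] == 1, "-", "+"))
  df <- df[order(df$start, df$end, df$strand), ]
  rownames(df) <- NULL
  df
}

## comparison helper: called ORF FeatureSet -> coordinate table
orfTable <- function(fs) {
  cds <- fs[featureType(fs) == "CDS"]
  df <- data.frame(start = GenomicRanges::start(cds),
                   end = GenomicRanges::end(cds),
                   strand = as.character(GenomicRanges::strand(cds)))
  df <- df[order(df$start, df$end, df$strand), ]
  rownames(df) <- NULL
  df
}

## brute-force SD search: every candidate against every window position
oracleSdMatches <- function(window, candidates = defaultSdCandidates(),
                            nearOffset = 3) {
  n <- nchar(window)
  hits <- list()
  for (m in candidates) {
    k <- nchar(m)
    if (k > n) next
    for (i in seq_len(n - k + 1)) {
      if (substr(window, i, i + k - 1) == m) {
        hits[[length(hits) + 1]] <-
          data.frame(motif = m, offset = nearOffset + (n - (i + k - 1)),
                     wstart = i, wend = i + k - 1)
      }
    }
  }
  if (!length(hits))
    return(data.frame(motif = character(), offset = integer(),
                      wstart = integer(), wend = integer()))
  do.call(rbind, hits)
}

## position-by-position lipobox check using explicit residue sets
oracleLipobox <- function(protein, regionEnd = 40) {
  aa <- strsplit(protein, "")[[1]]
  set1 <- c("I", "L", "M", "F", "T", "V")
  not2 <- c("R", "E", "K", "D", "X")
  set3 <- c("G", "A", "S")
  hits <- list()
  for (i in seq_len(max(0, length(aa) - 3))) {
    if (i > regionEnd) break
    p1 <- aa[i] %in% set1 && !(aa[i + 1] %in% not2) &&
      aa[i + 2] %in% set3 && aa[i + 3] == "C"
    p2 <- aa[i] == "A" && aa[i + 1] == "W" && aa[i + 2] %in% set3 &&
      aa[i + 3] == "C"
    if (p1) hits[[length(hits) + 1]] <-
        data.frame(offset = i, motif = paste(aa[i:(i + 3)], collapse = ""),
                   pattern = 1)
    if (p2) hits[[length(hits) + 1]] <-
        data.frame(offset = i, motif = paste(aa[i:(i + 3)], collapse = ""),
                   pattern = 2)
  }
  if (!length(hits))
    return(data.frame(offset = integer(), motif = character(),
                      pattern = integer()))
  df <- do.call(rbind, hits)
  df <- df[order(df$offset, df$pattern), ]
  rownames(df) <- NULL
  df
}

## genome with a named single sequence
asGenome <- function(s, name = "g", circular = FALSE) {
  g <- Biostrings::DNAStringSet(stats::setNames(s, name))
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(circular = circular)
  g
}
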