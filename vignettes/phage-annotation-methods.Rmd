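---
title: "Methods: phage annotation stages in phannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phage annotation stages in phannot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phannot)
```

`phannot` implements the bespoke filtering and detection stages of a
phage genome annotation pipeline. This vignette documents the models and
conventions behind each stage, the tunable parameters and their
defaults, what the synthetic fixtures do and do not emulate, and the
design choices made where a convention had to be fixed.

## Naive ORF calling

`callOrfs()` scans all six frames of a genome. Within each frame, every
stop-to-stop segment contributes one ORF running from its first
initiation codon to the next in-frame stop. Conventions:

- **Initiation codons** at the calling stage are the declared initiation
  codons of the genetic code (for table 11: ATG, GTG, TTG, CTG, ATT,
  ATC, ATA). The deliberate permissiveness mirrors a naive caller whose
  job is sensitivity; the explicit phage start-codon filter
  (`filterByStartCodon()`, default ATG/GTG/TTG) narrows the set
  afterwards. Emitting only the longest variant per stop (rather than
  one ORF per in-frame start) is the default because start-site
  refinement belongs to the downstream Shine-Dalgarno and spanin
  stages; `allStarts = TRUE` restores the exhaustive behaviour.
- **Length cutoff**: `minAaLen = 30` residues, counted excluding the
  stop codon. The CDS span *includes* the stop codon, the prokaryotic
  GFF3 convention, so a 30 aa ORF spans 93 nt.
- **ORFs without a terminating stop** (running off a linear sequence
  end) are dropped by default (`requireStop = TRUE`).
- **Circular genomes**: origin-spanning ORFs are only called when the
  genome is flagged circular, and are represented as two joined parts
  sharing a `joined` attribute rather than as coordinates beyond the
  sequence length; this keeps every feature's coordinates within the
  genome and start ≤ end, at the cost of a slightly unusual two-part
  gene model.

`ensureGeneParents()` gives every orphan CDS a `gene` parent with the
same span and strand (idempotently), because downstream tools expect the
gene → CDS → child hierarchy.

## Shine-Dalgarno annotation

`annotateShineDalgarno()` searches the upstream window of each gene's
start codon for the *E. coli* consensus `AGGAGGT` or smaller candidate
motifs. Fixed conventions, chosen once and used consistently:

- **Candidate set** (`defaultSdCandidates()`): the consensus plus all of
  its contiguous substrings of length ≥ 4, ordered by decreasing length
  — 10 motifs. The list is an ordinary character vector and can be
  replaced wholesale.
- **Window**: offsets 3–24 nt upstream of the first base of the start
  codon (`near = 3`, `far = 24`), reverse-complemented for minus-strand
  genes. The **offset** of a match is the distance from the last base of
  the motif to the first base of the start codon, and the motif must lie
  wholly inside the window. At a linear sequence edge the window is
  truncated and flagged.
- **Longest match wins**; among equal-length matches the one closest to
  the start codon is chosen, since canonical SD spacing is short.
  Matching is exact string matching — no mismatches, no IUPAC
  ambiguity expansion.
- Genes already owning a `Shine_Dalgarno_sequence` *or*
  `ribosome_entry_site` child are skipped, so re-annotation is
  idempotent and externally assigned RBS features are respected.

## Spanin candidate discovery

Spanins disrupt the outer membrane during lysis of Gram-negative hosts.
The two-component architecture — an inner-membrane i-spanin with a
transmembrane domain and an outer-membrane o-spanin lipoprotein, often
encoded in an alternate reading frame *inside* the i-spanin gene — is
the signature `findSpanins()` looks for:

1. naive ORF calling (table 11, ≥ 30 aa) → phage start filter →
   SD annotation → translation;
2. **i-spanin evidence**: `predictTmSegments()`, a Kyte–Doolittle
   sliding-window hydropathy scan (window 19 residues, the canonical
   membrane-spanning helix length; threshold 1.6 mean hydropathy).
   This is the package's own transmembrane stand-in; externally produced
   topology predictions can be passed via `tmPredictions` and bypass it.
3. **o-spanin evidence**: `findLipoboxes()`, the four-residue motifs
   `[ILMFTV]-[any but R/E/K/D]-[GAS]-C` and `A-W-[AGS]-C`, restricted to
   the first 40 residues because the lipobox terminates a signal
   peptide. `X` never satisfies a constrained position. All overlapping
   occurrences are reported.
4. **pairing** (`pairSpaninCandidates()`): every (i, o) candidate pair on
   the same strand within `maxSep = 50` nt. The separation is the
   *interval gap* — 0 for overlapping or embedded spans — so the
   embedded architecture always passes its own filter. Start-to-start
   distance was rejected as a convention precisely because it would fail
   embedded pairs. A dual-evidence ORF may appear in both roles but
   never pairs with itself.
5. optional overlay of curated-database protein hits at
   e-value ≤ 0.001 as `blast_support`.

The signature approach intentionally over-calls: false pairs are
reported with their evidence for manual review (and appear in the
package's own fixtures as recorded decoys), never silently suppressed.

## Interrupted genes

`detectInterrupted()` looks for one database protein hit by several
discrete query genes. Conventions:

- HSPs with identities/length strictly below 0.3 are discarded first
  (`filterLowIdentityHsps()`); exactly 0.3 is retained.
- One fragment per query = the union span of its retained HSPs on the
  subject. Fragments are ordered along the subject, and consecutive
  fragments must respect `sepMin` (signed separation on the subject:
  negative values permit that much overlap, the default 0 requires
  non-overlap — conservative, since overlap usually means two calls of
  the same gene rather than a split gene).
- All contributing query features must lie on the same genomic strand.
- Consecutive fragments must sit within `maxSepNt = 10000` nt of each
  other, measured between nearest interval ends — pairwise between
  consecutive fragments, not over the total span. On circular genomes
  the shorter way around the circle is used, which also detects genes
  split across the genome ends (`spans_origin`).
- No intron/frameshift/artifact class is assigned: fragment boundaries
  need manual inspection of the alignments, so the tool reports ordered
  fragments per subject and leaves interpretation to the annotator.

## Comparative genomics

`diceCoefficient()` is the closed form `2m/(lenA + lenB)`. For a
multi-HSP record the aggregated *m* sums HSP identities after discarding
subject-interval overlaps (higher bitscore wins), so identity over a
reused subject region is never counted twice. `diceFilter()` applies
closed bounds 50–100%. Rankings: `rankByUniqueProteins()` counts
distinct query proteins per subject organism (top 20);
`rankNucleotideHits()` ranks subject genomes by Dice percent (top 10);
ties break lexicographically for reproducibility.
`xmfaIdentityTable()` counts columns where both rows are present,
ungapped and equal (case-insensitively, since alignment tools emit mixed
case), summed over blocks; the diagonal is 100 by definition.

## Synthetic fixtures

`makeGenomeFixture()` assembles planted cassettes on an engineered
background: cyclic `TAGT` spacers, which carry stop codons in all six
frames but no initiation codon on either strand, and cytosine fillers
inside cassettes. No ORF can begin in or survive across a spacer, so an
element-free genome has *zero* callable ORFs and planted ORFs are
recovered at exactly their designed coordinates. Alternate reading
frames of real coding sequence (the random gene bodies, the spanin
cassettes) can still spawn decoy ORFs; a build-time six-frame sweep
records these in `truth$decoys` rather than ignoring them. Spanin
cassettes are hand-designed dual-frame constructs (the o-spanin ORF in
frame +2 inside the i-spanin ORF) verified at build time: the i-spanin
protein must contain a transmembrane run, the o-spanin a lipobox, and
neither frame a premature stop.

This background is deliberately *unlike* real phage DNA: real genomes
have realistic codon usage, GC skew, overlapping genes everywhere and no
ORF-free spacers. Passing the planted-recovery tests therefore
demonstrates correctness of the algorithms' logic and coordinate
arithmetic, not their specificity on real genomes — on real data the
spanin signature search in particular is expected to produce multiple
false-positive pairs per genome.

`makeSplitGeneRecords()` builds alignment records for the split-gene
signature (two fragments hitting complementary subject intervals at
~90% identity) plus noise: a sub-threshold identity pair, a
single-fragment subject, and an opposite-strand pair.
`makeTerminatorRecords()` is the full 3×3×3 boundary battery around the
terminator promotion criteria (scores 94/95/96 × stems 4/5/6 × T-runs
3/4/5), of which exactly 4 combinations pass.

All fixture randomness flows from the single `seed` argument; identical
seeds give identical bytes.

## Problem sizes and numerical notes

The test suite checks `callOrfs()` against an independently coded
brute-force six-frame oracle on 200 seeded random genomes of 1–5 kb,
Shine-Dalgarno recovery on 500 seeded windows, spanin planted-pair
recall on 51 seeded genomes across the three architectures (plus
negative constructs at 60 nt separation and on opposite strands), and
rotation invariance of circular interrupted-gene detection. These sizes
give full coverage of the discrete case space (every architecture,
every boundary of every filter) while keeping the default test run
fast.

Everything in the toolkit is exact integer/string computation except
the hydropathy means (plain floating-point averages) and the identity
reconstruction `round(pident/100 × length)` used when a tabular input
lacks an `nident` column — exact at the four-digit precision BLAST
prints. Deterministic orderings are fixed everywhere results are
emitted: features by (sequence, top-level span, depth, start, ID);
pairs by genomic position; rankings by metric then identifier.

## Known limitations

- The transmembrane stand-in is a hydropathy heuristic, not an HMM
  topology model; supply external predictions for serious use.
- Lipobox patterns are the permissive motif pair above; no
  signal-peptidase II cleavage model is applied.
- Wraparound (origin-spanning) start codons that themselves straddle
  the origin are not evaluated by the start-codon filter.
- Interrupted-gene detection reports candidates; it does not refine
  intron boundaries or identify slippery sites.
- GenBank I/O, five-column submission tables and the execution of
  external predictors (gene callers, BLAST, terminator or topology
  predictors) are out of scope; their outputs are consumed as files.
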