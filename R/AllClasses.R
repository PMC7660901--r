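#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges strand start end width seqnames
#' @importFrom IRanges IRanges
NULL

#' FeatureSet: hierarchical genome annotations
#'
#' A `FeatureSet` is a [GenomicRanges::GRanges] with the metadata columns a
#' GFF3 gene model needs: `source`, `type` (a Sequence Ontology term such as
#' `gene`, `CDS` or `Shine_Dalgarno_sequence`), `score`, `phase`, `ID`,
#' `Parent` (the ID of the enclosing feature, or `NA` for top-level
#' features), a list column `attrs` holding any further GFF3 attributes, and
#' a `dangling` flag set by the reader when a `Parent` does not resolve.
#' Coordinates are 1-based inclusive throughout, matching GFF3.
#'
#' @slot .  inherits all slots from `GRanges`.
#' @export
setClass("FeatureSet", contains = "GRanges")

.FS_MCOLS <- c("source", "type", "score", "phase", "ID", "Parent", "attrs",
               "dangling")

.validFeatureSet <- function(object) {
  msg <- character()
  mc <- mcols(object)
  missing <- setdiff(.FS_MCOLS, colnames(mc))
  if (length(missing))
    msg <- c(msg, paste0("missing metadata column(s): ",
                         paste(missing, collapse = ", ")))
  if (!length(msg)) {
    ids <- mc$ID[!is.na(mc$ID)]
    if (anyDuplicated(ids))
      msg <- c(msg, paste0("duplicate feature ID(s): ",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (!is.character(mc$type) || anyNA(mc$type))
      msg <- c(msg, "'type' must be character without NA")
  }
  if (length(msg)) msg else TRUE
}
setValidity("FeatureSet", .validFeatureSet)

#' Construct a FeatureSet
#'
#' @param seqid character vector of genome sequence names.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @param type Sequence Ontology feature type.
#' @param ID feature identifiers (unique; `NA` allowed).
#' @param Parent ID of the parent feature or `NA`.
#' @param source GFF3 source column.
#' @param score numeric score or `NA`.
#' @param phase CDS phase (0, 1, 2) or `NA`.
#' @param attrs list of named character vectors with extra GFF3 attributes.
#' @param seqinfo optional [GenomeInfoDb::Seqinfo] for the genome.
#' @return a `FeatureSet`.
#' @examples
#' FeatureSet(seqid = "g1", start = 1, end = 99, strand = "+",
#'            type = "gene", ID = "gene1")
#' @export
FeatureSet <- function(seqid = character(), start = integer(),
                       end = integer(), strand = "+", type = character(),
                       ID = NA_character_, Parent = NA_character_,
                       source = "phannot", score = NA_real_,
                       phase = NA_integer_, attrs = NULL, seqinfo = NULL) {
  n <- length(start)
  if (is.null(attrs)) attrs <- rep(list(character()), n)
  gr <- GRanges(seqnames = seqid, ranges = IRanges(start, end),
                strand = rep_len(as.character(strand), n))
  if (!is.null(seqinfo)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(seqinfo)
    GenomeInfoDb::seqinfo(gr) <- seqinfo
  }
  mcols(gr) <- DataFrame(
    source = rep_len(as.character(source), n),
    type = rep_len(as.character(type), n),
    score = rep_len(as.numeric(score), n),
    phase = rep_len(as.integer(phase), n),
    ID = rep_len(as.character(ID), n),
    Parent = rep_len(as.character(Parent), n),
    attrs = I(attrs),
    dangling = logical(n))
  fs <- methods::as(gr, "FeatureSet")
  fs <- .flagDangling(fs)
  methods::validObject(fs)
  fs
}

## recompute the dangling flag from the current ID/Parent columns
.flagDangling <- function(fs) {
  mc <- mcols(fs)
  mcols(fs)$dangling <- !is.na(mc$Parent) & !(mc$Parent %in% mc$ID)
  fs
}

.asFeatureSet <- function(gr) {
  fs <- methods::as(gr, "FeatureSet")
  .flagDangling(fs)
}

#' @describeIn FeatureSet feature types (SO terms)
#' @param fs a `FeatureSet`.
#' @export
featureType <- function(fs) mcols(fs)$type

#' @describeIn FeatureSet feature identifiers
#' @export
featureID <- function(fs) mcols(fs)$ID

#' @describeIn FeatureSet parent identifiers (`NA` for top-level features)
#' @export
featureParent <- function(fs) mcols(fs)$Parent

#' Children of given features
#'
#' @param fs a `FeatureSet`.
#' @param ids parent feature IDs.
#' @return the subset of `fs` whose `Parent` is in `ids`.
#' @export
childrenOf <- function(fs, ids) {
  fs[!is.na(featureParent(fs)) & featureParent(fs) %in% ids]
}

## ids plus all transitive descendants
.withDescendants <- function(fs, ids) {
  out <- ids
  repeat {
    kid <- featureID(childrenOf(fs, out))
    kid <- kid[!is.na(kid)]
    new <- setdiff(kid, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  out
}

setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet with", length(object), "features\n")
  if (length(object)) {
    tb <- table(featureType(object))
    cat("  types:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
        "\n")
    n_dang <- sum(mcols(object)$dangling)
    if (n_dang) cat("  dangling parents:", n_dang, "\n")
  }
  invisible(object)
})
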