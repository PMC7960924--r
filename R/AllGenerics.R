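#' Accessors for crypticSplice classes
#'
#' Small accessor generics so user code never reaches into slots:
#' \code{txId}, \code{geneSymbol}, \code{txStrand}, \code{txContig},
#' \code{exonRanges}, \code{cdsBounds}, \code{maxDelta}, \code{eventKind},
#' \code{insertedLength}, \code{frameClass}, \code{ptcCodon},
#' \code{nmdPredicted}, \code{wtProductSize}, \code{variantProductSizes}.
#'
#' @param x an object of the documented class.
#' @return The corresponding slot value; see each class's documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("txId", function(x) standardGeneric("txId"))
#' @rdname accessors
#' @export
setGeneric("geneSymbol", function(x) standardGeneric("geneSymbol"))
#' @rdname accessors
#' @export
setGeneric("txStrand", function(x) standardGeneric("txStrand"))
#' @rdname accessors
#' @export
setGeneric("txContig", function(x) standardGeneric("txContig"))
#' @rdname accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname accessors
#' @export
setGeneric("cdsBounds", function(x) standardGeneric("cdsBounds"))
#' @rdname accessors
#' @export
setGeneric("maxDelta", function(x) standardGeneric("maxDelta"))
#' @rdname accessors
#' @export
setGeneric("eventKind", function(x) standardGeneric("eventKind"))
#' @rdname accessors
#' @export
setGeneric("insertedLength", function(x) standardGeneric("insertedLength"))
#' @rdname accessors
#' @export
setGeneric("frameClass", function(x) standardGeneric("frameClass"))
#' @rdname accessors
#' @export
setGeneric("ptcCodon", function(x) standardGeneric("ptcCodon"))
#' @rdname accessors
#' @export
setGeneric("nmdPredicted", function(x) standardGeneric("nmdPredicted"))
#' @rdname accessors
#' @export
setGeneric("wtProductSize", function(x) standardGeneric("wtProductSize"))
#' @rdname accessors
#' @export
setGeneric("variantProductSizes",
           function(x) standardGeneric("variantProductSizes"))

#' @rdname accessors
setMethod("txId", "TranscriptModel", function(x) x@transcriptId)
#' @rdname accessors
setMethod("geneSymbol", "TranscriptModel", function(x) x@geneSymbol)
#' @rdname accessors
setMethod("geneSymbol", "SpliceAIRecord", function(x) x@gene)
#' @rdname accessors
setMethod("geneSymbol", "AnnotatedVariant", function(x) x@gene)
#' @rdname accessors
setMethod("txStrand", "TranscriptModel", function(x) x@strand)
#' @rdname accessors
setMethod("txContig", "TranscriptModel", function(x) x@contig)
#' @rdname accessors
setMethod("exonRanges", "TranscriptModel", function(x) x@exons)
#' @rdname accessors
setMethod("exonRanges", "TranscriptConsequence", function(x) x@mutantExons)
#' @rdname accessors
setMethod("cdsBounds", "TranscriptModel",
          function(x) c(start = x@cdsStart, end = x@cdsEnd))
#' @rdname accessors
setMethod("maxDelta", "SpliceAIRecord",
          function(x) max(x@dsAG, x@dsAL, x@dsDG, x@dsDL))
#' @rdname accessors
setMethod("maxDelta", "AnnotatedVariant", function(x)
    if (is.null(x@spliceai)) NA_real_ else maxDelta(x@spliceai))
#' @rdname accessors
setMethod("eventKind", "SpliceEvent", function(x) x@kind)
#' @rdname accessors
setMethod("insertedLength", "SpliceEvent", function(x) x@insertedLength)
#' @rdname accessors
setMethod("insertedLength", "TranscriptConsequence",
          function(x) x@insertedLength)
#' @rdname accessors
setMethod("frameClass", "TranscriptConsequence", function(x) x@frameClass)
#' @rdname accessors
setMethod("ptcCodon", "TranscriptConsequence", function(x) x@ptcCodon)
#' @rdname accessors
setMethod("nmdPredicted", "TranscriptConsequence", function(x) x@nmdPredicted)
#' @rdname accessors
setMethod("wtProductSize", "RtpcrPrediction", function(x) x@wtSize)
#' @rdname accessors
setMethod("variantProductSizes", "RtpcrPrediction", function(x) {
    stats::setNames(x@variantSizes, x@labels)
})

setMethod("show", "TranscriptModel", function(object) {
    nEx <- length(object@exons)
    cat(sprintf("TranscriptModel %s (%s) on %s(%s): %d exon%s, %d bp exonic\n",
                object@transcriptId, object@geneSymbol, object@contig,
                object@strand, nEx, if (nEx == 1L) "" else "s",
                sum(width(object@exons))))
    if (!is.na(object@cdsStart))
        cat(sprintf("  CDS %d-%d\n", object@cdsStart, object@cdsEnd))
})

setMethod("show", "SpliceAIRecord", function(object) {
    cat(sprintf(
        "SpliceAIRecord %s|%s AG %.2f@%+d AL %.2f@%+d DG %.2f@%+d DL %.2f@%+d\n",
        object@allele, object@gene,
        object@dsAG, object@dpAG, object@dsAL, object@dpAL,
        object@dsDG, object@dpDG, object@dsDL, object@dpDL))
})

setMethod("show", "AnnotatedVariant", function(object) {
    cat(sprintf("AnnotatedVariant %s:%d%s>%s [%s] %s gene=%s AF=%s\n",
                object@contig, object@pos, object@ref, object@alt,
                object@zygosity, object@probandId, object@gene,
                ifelse(is.na(object@alleleFrequency), "absent",
                       format(object@alleleFrequency))))
})

setMethod("show", "SpliceEvent", function(object) {
    if (object@kind == "none") {
        cat("SpliceEvent: none\n")
    } else {
        cat(sprintf(
            "SpliceEvent %s: +%d bp in intron %d (min gained score %.2f)\n",
            object@kind, object@insertedLength, object@hostIntron,
            object@minGainedScore))
    }
})

setMethod("show", "TranscriptConsequence", function(object) {
    cat(sprintf(
        "TranscriptConsequence: %d exons, +%d bp, %s, PTC %s, NMD %s\n",
        length(object@mutantExons), object@insertedLength, object@frameClass,
        ifelse(is.na(object@ptcCodon), "absent",
               sprintf("codon %d", object@ptcCodon)),
        ifelse(isTRUE(object@nmdPredicted), "predicted", "not predicted")))
})

setMethod("show", "MinigeneConstruct", function(object) {
    cat(sprintf(
        "MinigeneConstruct %s:%d-%d (%s): test exon %d bp%s, flank %d bp\n",
        object@contig, start(object@region), end(object@region),
        object@strand, width(object@testExon),
        if (length(object@crypticExon))
            sprintf(", cryptic exon %d bp", width(object@crypticExon)) else "",
        object@flank))
})

setMethod("show", "RtpcrPrediction", function(object) {
    cat(sprintf("RtpcrPrediction: WT %d bp; variant %s\n", object@wtSize,
                paste(sprintf("%d bp (%s)", object@variantSizes,
                              object@labels), collapse = ", ")))
})
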