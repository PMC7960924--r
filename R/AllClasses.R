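#' @import methods
#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors isSingleString
NULL

#' TranscriptModel: a strand-aware exon chain with CDS bounds
#'
#' A single transcript model on a named contig: an ordered, non-overlapping
#' exon chain plus optional CDS bounds. All coordinates are 1-based inclusive
#' genomic positions (the convention of GFF3/GTF/VCF and of
#' \link[IRanges]{IRanges}); readers convert at the boundary.
#'
#' @slot transcriptId character(1), transcript identifier.
#' @slot geneSymbol character(1), gene symbol.
#' @slot contig character(1), contig name.
#' @slot strand character(1), \code{"+"} or \code{"-"}.
#' @slot exons \link[IRanges]{IRanges} of exons in ascending genomic order.
#' @slot cdsStart,cdsEnd integer(1), genomic left/right bounds of the CDS
#'   (\code{cdsStart <= cdsEnd} regardless of strand), or \code{NA} for a
#'   non-coding transcript.
#'
#' @details Every intron must be at least 4 bases long, leaving room for the
#' canonical GT...AG dinucleotides. Intron \code{k} is the intron following
#' exon \code{k} in transcript (5' to 3') order, the convention used in
#' clinical reports such as "intron 43".
#'
#' @seealso [transcriptModel()] for the user-facing constructor.
#' @export
setClass("TranscriptModel",
    representation(
        transcriptId = "character",
        geneSymbol   = "character",
        contig       = "character",
        strand       = "character",
        exons        = "IRanges",
        cdsStart     = "integer",
        cdsEnd       = "integer"
    )
)

setValidity("TranscriptModel", function(object) {
    msg <- character()
    if (!isSingleString(object@transcriptId) || !nzchar(object@transcriptId))
        msg <- c(msg, "transcriptId must be a non-empty string")
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    ex <- object@exons
    if (length(ex) == 0L)
        msg <- c(msg, "at least one exon is required")
    if (length(ex) > 1L) {
        if (is.unsorted(start(ex), strictly = TRUE))
            msg <- c(msg, "exons must be sorted by ascending genomic start")
        gaps <- start(ex)[-1L] - end(ex)[-length(ex)] - 1L
        if (any(gaps < 4L))
            msg <- c(msg, sprintf(
                "exons overlap or leave an intron shorter than 4 bases in %s",
                object@transcriptId))
    }
    if (!is.na(object@cdsStart) || !is.na(object@cdsEnd)) {
        if (is.na(object@cdsStart) || is.na(object@cdsEnd))
            msg <- c(msg, "cdsStart and cdsEnd must both be set or both NA")
        else {
            if (object@cdsStart > object@cdsEnd)
                msg <- c(msg, "cdsStart must be <= cdsEnd")
            inExon <- function(p) any(p >= start(ex) & p <= end(ex))
            if (!inExon(object@cdsStart) || !inExon(object@cdsEnd))
                msg <- c(msg, "CDS bounds must lie inside the exon union")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TranscriptModel
#'
#' @param transcriptId,geneSymbol,contig,strand scalar metadata; see
#'   \linkS4class{TranscriptModel}.
#' @param exons an \link[IRanges]{IRanges} of exons (ascending genomic order),
#'   1-based inclusive.
#' @param cdsStart,cdsEnd genomic left/right CDS bounds, or \code{NA} for a
#'   non-coding transcript.
#' @return A \linkS4class{TranscriptModel}.
#' @examples
#' tx <- transcriptModel("tx1", "GENE1", "chrT", "+",
#'                       IRanges::IRanges(c(1, 201), c(100, 300)),
#'                       cdsStart = 1, cdsEnd = 300)
#' exonRanges(tx)
#' @export
transcriptModel <- function(transcriptId, geneSymbol, contig, strand, exons,
                            cdsStart = NA, cdsEnd = NA) {
    new("TranscriptModel",
        transcriptId = as.character(transcriptId),
        geneSymbol   = as.character(geneSymbol),
        contig       = as.character(contig),
        strand       = as.character(strand),
        exons        = exons,
        cdsStart     = as.integer(cdsStart),
        cdsEnd       = as.integer(cdsEnd))
}

#' SpliceAIRecord: one gene's SpliceAI annotation of a variant
#'
#' The four delta scores (acceptor gain/loss, donor gain/loss), each in
#' [0, 1], and the four corresponding delta positions, signed offsets from
#' the variant position on the reference strand (positive towards increasing
#' genomic coordinate).
#'
#' @slot allele character(1), the ALT allele the annotation refers to.
#' @slot gene character(1), gene symbol.
#' @slot dsAG,dsAL,dsDG,dsDL numeric(1) delta scores in [0, 1].
#' @slot dpAG,dpAL,dpDG,dpDL integer(1) signed positions relative to the
#'   variant.
#' @export
setClass("SpliceAIRecord",
    representation(
        allele = "character", gene = "character",
        dsAG = "numeric", dsAL = "numeric",
        dsDG = "numeric", dsDL = "numeric",
        dpAG = "integer", dpAL = "integer",
        dpDG = "integer", dpDL = "integer"
    )
)

setValidity("SpliceAIRecord", function(object) {
    sc <- c(object@dsAG, object@dsAL, object@dsDG, object@dsDL)
    if (any(is.na(sc)) || any(sc < 0) || any(sc > 1))
        return("delta scores must lie in [0, 1]")
    TRUE
})

setClassUnion("SpliceAIRecordOrNULL", members = c("SpliceAIRecord", "NULL"))

#' Construct a SpliceAIRecord
#'
#' @param allele,gene scalar strings.
#' @param dsAG,dsAL,dsDG,dsDL delta scores in [0, 1].
#' @param dpAG,dpAL,dpDG,dpDL signed delta positions (reference strand).
#' @return A \linkS4class{SpliceAIRecord}.
#' @export
spliceAIRecord <- function(allele, gene, dsAG = 0, dsAL = 0, dsDG = 0,
                           dsDL = 0, dpAG = 0L, dpAL = 0L, dpDG = 0L,
                           dpDL = 0L) {
    new("SpliceAIRecord", allele = allele, gene = gene,
        dsAG = as.numeric(dsAG), dsAL = as.numeric(dsAL),
        dsDG = as.numeric(dsDG), dsDL = as.numeric(dsDL),
        dpAG = as.integer(dpAG), dpAL = as.integer(dpAL),
        dpDG = as.integer(dpDG), dpDL = as.integer(dpDL))
}

#' AnnotatedVariant: one decomposed VCF allele with annotations
#'
#' @slot contig,ref,alt character(1) VCF fields (one ALT allele).
#' @slot pos integer(1), 1-based genomic position.
#' @slot probandId character(1).
#' @slot gene character(1), annotated gene symbol ("" if none).
#' @slot zygosity character(1): "het", "hom" or "hemi".
#' @slot alleleFrequency numeric(1) population allele frequency in [0, 1],
#'   or \code{NA} when the variant is absent from the population database.
#' @slot codingClass character(1): "none", "missense", "nonsense",
#'   "frameshift" or "other" (pass-through annotation, never computed here).
#' @slot rankScores named numeric, pass-through deleteriousness rank scores
#'   (e.g. CADD/VEST3/GERP ranks), each in [0, 1].
#' @slot spliceai a \linkS4class{SpliceAIRecord} or \code{NULL}.
#' @slot novel logical(1), whether the allele is absent from population
#'   databases (pass-through; \code{NA} if unannotated).
#' @slot cdnaLabel character(1), pass-through cDNA (HGVS c.) label, "" if
#'   unannotated.
#' @export
setClass("AnnotatedVariant",
    representation(
        contig = "character", pos = "integer",
        ref = "character", alt = "character",
        probandId = "character", gene = "character",
        zygosity = "character",
        alleleFrequency = "numeric",
        codingClass = "character",
        rankScores = "numeric",
        spliceai = "SpliceAIRecordOrNULL",
        novel = "logical",
        cdnaLabel = "character"
    )
)

setValidity("AnnotatedVariant", function(object) {
    msg <- character()
    if (!grepl("^[ACGT]+$", object@ref) || !grepl("^[ACGT]+$", object@alt))
        msg <- c(msg, "ref and alt must be non-empty strings over ACGT")
    if (!object@zygosity %in% c("het", "hom", "hemi"))
        msg <- c(msg, "zygosity must be het, hom or hemi")
    af <- object@alleleFrequency
    if (!is.na(af) && (af < 0 || af > 1))
        msg <- c(msg, "alleleFrequency must lie in [0, 1]")
    if (!object@codingClass %in%
            c("none", "missense", "nonsense", "frameshift", "other"))
        msg <- c(msg, "invalid codingClass")
    if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedVariant
#'
#' @param contig,pos,ref,alt core VCF fields (single ALT allele).
#' @param probandId sample identifier.
#' @param gene annotated gene symbol.
#' @param zygosity "het", "hom" or "hemi".
#' @param alleleFrequency population AF, or \code{NA} if unobserved.
#' @param codingClass pass-through coding consequence class.
#' @param rankScores named numeric of pass-through rank scores.
#' @param spliceai \linkS4class{SpliceAIRecord} or \code{NULL}.
#' @param novel logical novelty flag (pass-through).
#' @param cdnaLabel pass-through HGVS c. label.
#' @return An \linkS4class{AnnotatedVariant}.
#' @export
annotatedVariant <- function(contig, pos, ref, alt, probandId = "",
                             gene = "", zygosity = "het",
                             alleleFrequency = NA_real_,
                             codingClass = "none",
                             rankScores = numeric(),
                             spliceai = NULL, novel = NA,
                             cdnaLabel = "") {
    new("AnnotatedVariant", contig = as.character(contig),
        pos = as.integer(pos), ref = toupper(ref), alt = toupper(alt),
        probandId = as.character(probandId), gene = as.character(gene),
        zygosity = zygosity, alleleFrequency = as.numeric(alleleFrequency),
        codingClass = codingClass, rankScores = rankScores,
        spliceai = spliceai, novel = as.logical(novel),
        cdnaLabel = as.character(cdnaLabel))
}

#' SpliceEvent: a classified cryptic-splicing mechanism
#'
#' @slot kind character(1): "pseudo_exon" (a gained acceptor/donor pair
#'   inside one intron splices a new exon in), "exon_elongation" (a gained
#'   donor extends the upstream exon into its intron), "acceptor_shift"
#'   (a gained acceptor replaces the lost canonical acceptor, extending the
#'   downstream exon), or "none".
#' @slot gainedAcceptor,gainedDonor,lostSite integer(1) genomic positions,
#'   \code{NA} when not part of the mechanism.
#' @slot hostIntron integer(1) 1-based intron index (transcript order).
#' @slot insertedLength integer(1) bases added to the mature transcript,
#'   counting both boundary bases of a new exon inclusively.
#' @slot minGainedScore numeric(1), the minimum delta score over the gained
#'   sites the event relies on; low values flag likely partial splicing.
#' @export
setClass("SpliceEvent",
    representation(
        kind = "character",
        gainedAcceptor = "integer", gainedDonor = "integer",
        lostSite = "integer",
        hostIntron = "integer",
        insertedLength = "integer",
        minGainedScore = "numeric"
    )
)

setValidity("SpliceEvent", function(object) {
    msg <- character()
    if (!object@kind %in%
            c("pseudo_exon", "exon_elongation", "acceptor_shift", "none"))
        msg <- c(msg, "invalid event kind")
    if (object@kind != "none" &&
            (is.na(object@insertedLength) || object@insertedLength < 1L))
        msg <- c(msg, "insertedLength must be >= 1 for a non-none event")
    if (object@kind == "pseudo_exon" &&
            (is.na(object@gainedAcceptor) || is.na(object@gainedDonor)))
        msg <- c(msg, "pseudo_exon requires both gained sites")
    if (length(msg)) msg else TRUE
})

#' TranscriptConsequence: effect of a splice event on the mature transcript
#'
#' @slot mutantExons \link[IRanges]{IRanges}, the mutant exon chain
#'   (ascending genomic order).
#' @slot insertedLength integer(1) bases added.
#' @slot frameClass character(1): "in_frame" or "frameshift".
#' @slot ptcCodon integer(1) codon index (1 = initiator) of the first
#'   premature termination codon, \code{NA} if none.
#' @slot nmdPredicted logical(1), TRUE when the PTC is predicted to trigger
#'   nonsense-mediated decay under the last-junction rule.
#' @slot proteinEffect character(1): "insertion", "truncation" or "none".
#' @export
setClass("TranscriptConsequence",
    representation(
        mutantExons = "IRanges",
        insertedLength = "integer",
        frameClass = "character",
        ptcCodon = "integer",
        nmdPredicted = "logical",
        proteinEffect = "character"
    )
)

setValidity("TranscriptConsequence", function(object) {
    msg <- character()
    if (!object@frameClass %in% c("in_frame", "frameshift"))
        msg <- c(msg, "frameClass must be in_frame or frameshift")
    inFrame <- object@insertedLength %% 3L == 0L
    if ((object@frameClass == "in_frame") != inFrame)
        msg <- c(msg, "frameClass must equal in_frame iff insertedLength %% 3 == 0")
    if (isTRUE(object@nmdPredicted) && is.na(object@ptcCodon))
        msg <- c(msg, "nmdPredicted requires a PTC")
    if (length(msg)) msg else TRUE
})

#' MinigeneConstruct: a designed splicing-reporter insert
#'
#' The genomic fragment cloned between the two vector exons of a splicing
#' reporter: the test exon (the canonical exon closest to the candidate
#' variant), the predicted cryptic exon when there is one, and surrounding
#' intronic flanks.
#'
#' @slot contig character(1).
#' @slot region \link[IRanges]{IRanges}(1), the amplified insert region.
#' @slot testExon \link[IRanges]{IRanges}(1).
#' @slot crypticExon \link[IRanges]{IRanges}, length 1 or empty.
#' @slot strand character(1), transcript strand.
#' @slot flank integer(1) intronic flank size per side (bases).
#' @slot vectorExonBp integer(1) bases each vector exon contributes to an
#'   RT-PCR product.
#' @slot insertSeq character(1), insert sequence in transcript sense.
#' @export
setClass("MinigeneConstruct",
    representation(
        contig = "character",
        region = "IRanges",
        testExon = "IRanges",
        crypticExon = "IRanges",
        strand = "character",
        flank = "integer",
        vectorExonBp = "integer",
        insertSeq = "character"
    )
)

setValidity("MinigeneConstruct", function(object) {
    msg <- character()
    if (length(object@region) != 1L)
        msg <- c(msg, "region must be a single interval")
    else {
        covers <- function(iv) length(iv) == 0L ||
            (start(object@region) <= start(iv) && end(object@region) >= end(iv))
        if (!covers(object@testExon) || !covers(object@crypticExon))
            msg <- c(msg, "region must cover the test exon and cryptic exon")
        if (nchar(object@insertSeq) != width(object@region))
            msg <- c(msg, "insert sequence length must equal region width")
    }
    if (object@flank < 0L)
        msg <- c(msg, "flank must be >= 0")
    if (length(msg)) msg else TRUE
})

#' RtpcrPrediction: predicted RT-PCR product sizes for a minigene assay
#'
#' @slot wtSize integer(1), wild-type product size in bases
#'   (test exon + both vector-exon contributions).
#' @slot variantSizes integer, product sizes expected from the variant
#'   construct; partial splicing makes the wild-type-sized band possible
#'   alongside the aberrant one.
#' @slot labels character, one isoform label per variant size.
#' @export
setClass("RtpcrPrediction",
    representation(
        wtSize = "integer",
        variantSizes = "integer",
        labels = "character"
    )
)

setValidity("RtpcrPrediction", function(object) {
    if (length(object@variantSizes) != length(object@labels))
        return("one label per variant product size required")
    TRUE
})
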