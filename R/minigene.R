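#' Design a minigene splicing-reporter insert for a candidate event
#'
#' The insert is the genomic fragment a validation assay would clone
#' between the two vector exons of a splicing reporter: the test exon (the
#' canonical exon closest to the candidate variant), the predicted cryptic
#' exon when the event creates one, the intervening intron, and a symmetric
#' intronic flank on each side. For an elongation or acceptor-shift event
#' the extended exon itself is the region of interest, so the insert spans
#' the test exon out to the gained site.
#'
#' @param tx the canonical \linkS4class{TranscriptModel}.
#' @param event a \linkS4class{SpliceEvent} of kind other than "none".
#' @param genome named \link[Biostrings]{DNAStringSet}.
#' @param flank intronic flank per side in bases (default 150).
#' @param vectorExonBp bases each vector exon contributes to an RT-PCR
#'   product (default 92).
#' @return A \linkS4class{MinigeneConstruct}. The insert sequence is
#'   reported in transcript sense (reverse-complemented for minus-strand
#'   genes). A region running off the contig is clipped with a warning.
#' @export
designConstruct <- function(tx, event, genome, flank = 150,
                            vectorExonBp = 92) {
    if (eventKind(event) == "none")
        stop("cannot design a construct for an event of kind none")
    flank <- as.integer(flank)
    stopifnot(flank >= 0L)
    ex <- exonRanges(tx)
    plus <- txStrand(tx) == "+"
    intr <- intronRanges(tx)
    gi <- if (plus) event@hostIntron else
        length(intr) - event@hostIntron + 1L
    ## test exon: the canonical exon flanking the host intron nearest the
    ## event (upstream exon for donor-driven events, downstream for
    ## acceptor-driven ones, measured in transcript sense)
    upExon <- ex[gi]                     # transcript-upstream on + strand
    downExon <- ex[gi + 1L]
    if (!plus) { tmp <- upExon; upExon <- downExon; downExon <- tmp }
    testExon <- switch(eventKind(event),
        pseudo_exon = {
            ## nearer flanking exon in transcript sense
            dUp <- min(abs(c(event@gainedAcceptor, event@gainedDonor) -
                           c(IRanges::start(upExon), IRanges::end(upExon))))
            dDown <- min(abs(c(event@gainedAcceptor, event@gainedDonor) -
                             c(IRanges::start(downExon),
                               IRanges::end(downExon))))
            if (dUp <= dDown) upExon else downExon
        },
        exon_elongation = upExon,
        acceptor_shift = downExon)
    cryptic <- if (eventKind(event) == "pseudo_exon")
        IRanges::IRanges(min(event@gainedAcceptor, event@gainedDonor),
                         max(event@gainedAcceptor, event@gainedDonor))
    else IRanges::IRanges()
    feat <- c(testExon, cryptic)
    if (eventKind(event) != "pseudo_exon") {
        g <- if (eventKind(event) == "exon_elongation") event@gainedDonor
             else event@gainedAcceptor
        feat <- c(feat, IRanges::IRanges(g, g))
    }
    lo <- min(IRanges::start(feat)) - flank
    hi <- max(IRanges::end(feat)) + flank
    contig <- txContig(tx)
    contigLen <- Biostrings::width(genome)[match(contig, names(genome))]
    if (lo < 1L || hi > contigLen) {
        warning("minigene region clipped to contig bounds on ", contig)
        lo <- max(lo, 1L); hi <- min(hi, contigLen)
    }
    region <- IRanges::IRanges(lo, hi)
    seq <- as.character(Biostrings::subseq(genome[[contig]], lo, hi))
    if (!plus)
        seq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(seq)))
    new("MinigeneConstruct", contig = contig, region = region,
        testExon = testExon, crypticExon = cryptic,
        strand = txStrand(tx), flank = flank,
        vectorExonBp = as.integer(vectorExonBp), insertSeq = seq)
}

#' Predict RT-PCR product sizes for a minigene construct
#'
#' The wild-type product is the test exon plus the two vector-exon
#' contributions. The variant construct can yield the aberrant product
#' (wild-type size plus the inserted length) and, whenever splicing is
#' partial - always possible while any gained-site score is below 1 - the
#' wild-type-sized product as well, reproducing the two-band gel patterns
#' seen in validation assays.
#'
#' @param construct a \linkS4class{MinigeneConstruct}.
#' @param event the \linkS4class{SpliceEvent} the construct was designed
#'   for.
#' @return An \linkS4class{RtpcrPrediction}.
#' @examples
#' # test exon of 100 bp and a 129-bp pseudo-exon give bands of 284 and 413
#' @export
predictRtpcrProducts <- function(construct, event) {
    wt <- 2L * construct@vectorExonBp + IRanges::width(construct@testExon)
    if (eventKind(event) == "none")
        return(new("RtpcrPrediction", wtSize = wt,
                   variantSizes = wt, labels = "canonical"))
    aberrant <- wt + insertedLength(event)
    new("RtpcrPrediction", wtSize = wt,
        variantSizes = c(wt, aberrant),
        labels = c("canonical", "aberrant"))
}

#' In silico splicing check of a minigene construct
#'
#' Splices the construct insert at the canonical and gained sites and
#' verifies that the resulting product sizes match
#' [predictRtpcrProducts()]; used as an internal consistency check.
#'
#' @param construct a \linkS4class{MinigeneConstruct}.
#' @param event the designed \linkS4class{SpliceEvent}.
#' @return TRUE invisibly if consistent, otherwise an error.
#' @export
spliceConstructInSilico <- function(construct, event) {
    pred <- predictRtpcrProducts(construct, event)
    exonic <- IRanges::width(construct@testExon)
    pieces <- exonic
    if (eventKind(event) == "pseudo_exon")
        pieces <- c(pieces, IRanges::width(construct@crypticExon))
    else if (eventKind(event) != "none")
        pieces <- c(pieces, insertedLength(event))
    got <- sort(2L * construct@vectorExonBp + c(exonic, sum(pieces)))
    want <- sort(unique(c(pred@wtSize, pred@variantSizes)))
    if (!identical(as.integer(got), as.integer(want)))
        stop("in silico splicing of the construct does not reproduce the ",
             "predicted product sizes")
    invisible(TRUE)
}

#' Apply a list of substitutions to a minigene insert sequence
#'
#' Site-directed mutagenesis bookkeeping for constructs carrying more than
#' one variant: substitutions are applied in coordinate-descending order so
#' earlier edits never invalidate later coordinates.
#'
#' @param construct a \linkS4class{MinigeneConstruct}.
#' @param variants list of \linkS4class{AnnotatedVariant} whose positions
#'   fall inside the construct region (single-base substitutions only).
#' @return The construct with the edited insert sequence.
#' @export
mutageniseConstruct <- function(construct, variants) {
    if (!length(variants)) return(construct)
    pos <- vapply(variants, function(v) v@pos, integer(1))
    ord <- order(pos, decreasing = TRUE)
    seq <- construct@insertSeq
    lo <- IRanges::start(construct@region)
    hi <- IRanges::end(construct@region)
    for (v in variants[ord]) {
        if (nchar(v@ref) != 1L || nchar(v@alt) != 1L)
            stop("only single-base substitutions are supported")
        if (v@pos < lo || v@pos > hi)
            stop("variant ", variantKey(v), " outside the construct region")
        off <- if (construct@strand == "+") v@pos - lo + 1L
               else hi - v@pos + 1L
        ref <- if (construct@strand == "+") v@ref else complementBases(v@ref)
        alt <- if (construct@strand == "+") v@alt else complementBases(v@alt)
        if (substr(seq, off, off) != ref)
            stop("reference mismatch while editing construct at ",
                 variantKey(v))
        substr(seq, off, off) <- alt
    }
    construct@insertSeq <- seq
    construct
}
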