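#' Classify the cryptic-splicing mechanism of a variant
#'
#' Converts the SpliceAI delta positions (signed reference-strand offsets
#' from the variant) to genomic coordinates and classifies the mechanism:
#' \itemize{
#'   \item acceptor gain and donor gain both at or above the cutoff, with
#'     the acceptor 5' of the donor in transcript sense and both inside one
#'     intron: a \strong{pseudo_exon} whose inserted length counts both
#'     boundary bases inclusively (donor - acceptor + 1 in transcript
#'     sense);
#'   \item donor gain alone (with or without donor loss): an
#'     \strong{exon_elongation} of the upstream exon out to the new donor;
#'   \item acceptor gain together with acceptor loss: an
#'     \strong{acceptor_shift} moving the downstream exon's 5' edge;
#'   \item anything else: \strong{none}.
#' }
#' When both gains pass but the acceptor lies 3' of the donor no valid exon
#' can form and the event is classified "none" with a warning. When several
#' patterns pass, the most specific mechanism wins (pseudo-exon, then
#' acceptor shift, then elongation).
#'
#' @param variant an \linkS4class{AnnotatedVariant} (deep-intronic for
#'   \code{tx}).
#' @param rec a \linkS4class{SpliceAIRecord}; defaults to the variant's own.
#' @param tx the gene's canonical \linkS4class{TranscriptModel}.
#' @param cutoff per-site delta-score cutoff (default 0.5).
#' @return A \linkS4class{SpliceEvent}. Its \code{minGainedScore} slot
#'   carries the minimum delta score over the gained sites so that reports
#'   can relate prediction strength to the completeness of aberrant
#'   splicing seen in assays.
#' @export
inferSpliceEvent <- function(variant, rec = variant@spliceai, tx,
                             cutoff = 0.5) {
    if (is.null(rec)) stop("variant has no SpliceAI record")
    plus <- txStrand(tx) == "+"
    pos <- variant@pos
    gAG <- pos + rec@dpAG
    gDG <- pos + rec@dpDG
    gAL <- pos + rec@dpAL
    gDL <- pos + rec@dpDL
    intr <- intronRanges(tx)
    intronOf <- function(g) {
        hit <- which(g >= IRanges::start(intr) & g <= IRanges::end(intr))
        if (length(hit) != 1L) NA_integer_ else hit
    }
    noEvent <- new("SpliceEvent", kind = "none",
                   gainedAcceptor = NA_integer_, gainedDonor = NA_integer_,
                   lostSite = NA_integer_, hostIntron = NA_integer_,
                   insertedLength = NA_integer_,
                   minGainedScore = NA_real_)
    txIntron <- function(i)                      # genomic -> transcript order
        if (plus) i else length(intr) - i + 1L
    if (rec@dsAG >= cutoff && rec@dsDG >= cutoff) {
        okOrder <- if (plus) gAG <= gDG else gAG >= gDG
        if (!okOrder) {
            warning("gained acceptor lies 3' of gained donor; ",
                    "no valid exon can form")
            return(noEvent)
        }
        iA <- intronOf(gAG); iD <- intronOf(gDG)
        if (is.na(iA) || is.na(iD))
            stop("gained site outside any intron of ", txId(tx))
        if (iA != iD) stop("non-local event: gained sites in different introns")
        return(new("SpliceEvent", kind = "pseudo_exon",
                   gainedAcceptor = as.integer(gAG),
                   gainedDonor = as.integer(gDG),
                   lostSite = NA_integer_, hostIntron = txIntron(iA),
                   insertedLength = abs(gDG - gAG) + 1L,
                   minGainedScore = min(rec@dsAG, rec@dsDG)))
    }
    if (rec@dsAG >= cutoff && rec@dsAL >= cutoff) {
        i <- intronOf(gAG)
        if (is.na(i)) stop("gained acceptor outside any intron of ", txId(tx))
        ex <- exonRanges(tx)
        downEdge <- if (plus) IRanges::start(ex)[i + 1L]
                    else IRanges::end(ex)[i]
        len <- abs(downEdge - gAG)
        if (len < 1L) return(noEvent)
        return(new("SpliceEvent", kind = "acceptor_shift",
                   gainedAcceptor = as.integer(gAG),
                   gainedDonor = NA_integer_,
                   lostSite = as.integer(gAL), hostIntron = txIntron(i),
                   insertedLength = as.integer(len),
                   minGainedScore = rec@dsAG))
    }
    if (rec@dsDG >= cutoff) {
        i <- intronOf(gDG)
        if (is.na(i)) stop("gained donor outside any intron of ", txId(tx))
        ex <- exonRanges(tx)
        upEdge <- if (plus) IRanges::end(ex)[i] else IRanges::start(ex)[i + 1L]
        len <- abs(gDG - upEdge)
        if (len < 1L) return(noEvent)
        return(new("SpliceEvent", kind = "exon_elongation",
                   gainedAcceptor = NA_integer_,
                   gainedDonor = as.integer(gDG),
                   lostSite = if (rec@dsDL >= cutoff) as.integer(gDL)
                              else NA_integer_,
                   hostIntron = txIntron(i),
                   insertedLength = as.integer(len),
                   minGainedScore = rec@dsDG))
    }
    noEvent
}

#' Apply a splice event to a transcript's exon chain
#'
#' @param tx a \linkS4class{TranscriptModel}.
#' @param event a \linkS4class{SpliceEvent} of kind other than "none".
#' @return The mutant exon chain as an \link[IRanges]{IRanges} in ascending
#'   genomic order. A pseudo-exon adds one exon; elongation and acceptor
#'   shift keep the exon count and stretch one exon.
#' @export
applyEvent <- function(tx, event) {
    if (eventKind(event) == "none") stop("cannot apply an event of kind none")
    ex <- exonRanges(tx)
    plus <- txStrand(tx) == "+"
    intr <- intronRanges(tx)
    gi <- if (plus) event@hostIntron else length(intr) - event@hostIntron + 1L
    if (is.na(gi) || gi < 1L || gi > length(intr))
        stop("event lies outside transcript ", txId(tx))
    if (eventKind(event) == "pseudo_exon") {
        lo <- min(event@gainedAcceptor, event@gainedDonor)
        hi <- max(event@gainedAcceptor, event@gainedDonor)
        out <- c(ex, IRanges::IRanges(lo, hi))
        return(BiocGenerics::sort(out))
    }
    if (eventKind(event) == "exon_elongation") {
        if (plus) IRanges::end(ex)[gi] <- event@gainedDonor
        else IRanges::start(ex)[gi + 1L] <- event@gainedDonor
        return(ex)
    }
    ## acceptor_shift
    if (plus) IRanges::start(ex)[gi + 1L] <- event@gainedAcceptor
    else IRanges::end(ex)[gi] <- event@gainedAcceptor
    ex
}

#' Reading-frame consequence of an insertion
#'
#' @param insertedLength inserted bases (>= 1).
#' @return "in_frame" when the length is a multiple of 3, else
#'   "frameshift".
#' @examples
#' frameConsequence(129)  # in_frame
#' frameConsequence(29)   # frameshift
#' @export
frameConsequence <- function(insertedLength) {
    stopifnot(insertedLength >= 1L)
    if (insertedLength %% 3L == 0L) "in_frame" else "frameshift"
}

## Spliced mRNA of an exon chain (transcript sense); contigSeq is a plain
## character string.
splicedSequence <- function(chain, contigSeq, strand) {
    s <- paste(substring(contigSeq, IRanges::start(chain),
                         IRanges::end(chain)), collapse = "")
    if (strand == "-")
        s <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
    s
}

firstStopCodon <- function(cdsSeq) {
    n <- nchar(cdsSeq) %/% 3L
    if (n == 0L) return(NA_integer_)
    aa <- as.character(suppressWarnings(Biostrings::translate(
        Biostrings::DNAString(substr(cdsSeq, 1L, n * 3L)),
        if.fuzzy.codon = "X")))
    hit <- regexpr("*", aa, fixed = TRUE)
    if (hit < 0L) NA_integer_ else as.integer(hit)
}

#' Locate a premature termination codon in a mutant transcript
#'
#' Splices the mutant exon chain against the genome, translates from the
#' CDS start, and reports the first in-frame stop codon lying strictly 5'
#' of the wild-type stop. The variant's own substitution is applied to the
#' sequence when supplied, since a gained splice site often sits on the
#' variant base itself.
#'
#' @param tx the wild-type \linkS4class{TranscriptModel} (coding).
#' @param mutantChain exon chain from [applyEvent()].
#' @param genome named \link[Biostrings]{DNAStringSet}.
#' @param variant optional \linkS4class{AnnotatedVariant} whose single-base
#'   substitution is applied before translation.
#' @return 1-based codon index of the PTC (1 = initiator), or \code{NA}
#'   when the mutant stops no earlier than where the wild-type stop lands
#'   in the mutant transcript.
#' @export
findPtc <- function(tx, mutantChain, genome, variant = NULL) {
    if (is.na(tx@cdsStart)) stop("non-coding transcript: ", txId(tx))
    contig <- txContig(tx)
    contigSeq <- as.character(genome[[contig]])
    if (!is.null(variant) && nchar(variant@ref) == 1L &&
        nchar(variant@alt) == 1L) {
        have <- substr(contigSeq, variant@pos, variant@pos)
        if (have != variant@ref)
            stop("variant ref allele (", variant@ref,
                 ") does not match the genome (", have, ")")
        substr(contigSeq, variant@pos, variant@pos) <- variant@alt
    }
    cdsOffsetIn <- function(chain) {
        mockTx <- transcriptModel(txId(tx), geneSymbol(tx), contig,
                                  txStrand(tx), chain,
                                  cdsStart = tx@cdsStart,
                                  cdsEnd = tx@cdsEnd)
        txCoord(mockTx, cdsFirstBase(tx))
    }
    cdsFrom <- function(chain) {
        s <- splicedSequence(chain, contigSeq, txStrand(tx))
        substr(s, cdsOffsetIn(chain), nchar(s))
    }
    wtStop <- firstStopCodon(cdsFrom(exonRanges(tx)))
    mutStop <- firstStopCodon(cdsFrom(mutantChain))
    if (is.na(mutStop)) return(NA_integer_)
    if (!is.na(wtStop)) {
        ## the wild-type stop's 3' end shifts downstream by the inserted
        ## length; a stop is premature only if it ends strictly before that
        delta <- sum(IRanges::width(mutantChain)) -
            sum(IRanges::width(exonRanges(tx)))
        if (3L * mutStop >= 3L * wtStop + delta) return(NA_integer_)
    }
    mutStop
}

#' Predict nonsense-mediated decay under the last-junction rule
#'
#' A premature termination codon is predicted to trigger NMD when it ends
#' strictly more than \code{boundary} nucleotides upstream of the last
#' exon-exon junction of the mutant transcript (the standard 50-nt
#' heuristic). A single-exon chain has no junction and never triggers NMD.
#'
#' @param ptcCodon 1-based codon index of the PTC (from [findPtc()]).
#' @param mutantChain mutant exon chain (\link[IRanges]{IRanges}, ascending
#'   genomic order).
#' @param cdsStartCdna transcript-sense coordinate (1-based) of the first
#'   CDS base within the chain.
#' @param strand transcript strand (determines which exon is last).
#' @param boundary the NMD boundary in nucleotides (default 50; strict >).
#' @return TRUE when NMD is predicted.
#' @export
predictNmd <- function(ptcCodon, mutantChain, cdsStartCdna = 1L,
                       strand = "+", boundary = 50) {
    if (is.na(ptcCodon)) return(FALSE)
    if (length(mutantChain) < 2L) return(FALSE)
    w <- IRanges::width(mutantChain)
    lastW <- if (strand == "+") w[length(w)] else w[1L]
    lastJunction <- sum(w) - lastW
    ptcEnd <- cdsStartCdna - 1L + 3L * ptcCodon
    (lastJunction - ptcEnd) > boundary
}

#' Full transcript consequence of a splice event
#'
#' Applies the event, classifies the reading frame, scans for a premature
#' termination codon and applies the NMD rule.
#'
#' @param variant the \linkS4class{AnnotatedVariant}.
#' @param tx the canonical \linkS4class{TranscriptModel}.
#' @param genome named \link[Biostrings]{DNAStringSet}.
#' @param event optional pre-computed \linkS4class{SpliceEvent}; inferred
#'   from the variant's SpliceAI record when missing.
#' @param cutoff per-site delta-score cutoff for event inference.
#' @param nmdBoundary NMD last-junction boundary in nucleotides.
#' @return A \linkS4class{TranscriptConsequence}, or \code{NULL} when the
#'   event kind is "none".
#' @export
reconstructConsequence <- function(variant, tx, genome, event = NULL,
                                   cutoff = 0.5, nmdBoundary = 50) {
    if (is.null(event))
        event <- inferSpliceEvent(variant, tx = tx, cutoff = cutoff)
    if (eventKind(event) == "none") return(NULL)
    chain <- applyEvent(tx, event)
    fc <- frameConsequence(insertedLength(event))
    ptc <- findPtc(tx, chain, genome, variant = variant)
    cdsStartCdna <- {
        mockTx <- transcriptModel(txId(tx), geneSymbol(tx), txContig(tx),
                                  txStrand(tx), chain,
                                  cdsStart = tx@cdsStart, cdsEnd = tx@cdsEnd)
        txCoord(mockTx, cdsFirstBase(tx))
    }
    nmd <- predictNmd(ptc, chain, cdsStartCdna, strand = txStrand(tx),
                      boundary = nmdBoundary)
    effect <- if (!is.na(ptc)) "truncation"
              else if (fc == "in_frame") "insertion" else "none"
    new("TranscriptConsequence", mutantExons = chain,
        insertedLength = insertedLength(event), frameClass = fc,
        ptcCodon = as.integer(ptc),
        nmdPredicted = nmd, proteinEffect = effect)
}

#' One-row report of a variant's predicted consequence
#'
#' Assembles the narrative fields of a consequence report: event kind,
#' inserted length, frame class, PTC codon, NMD call, and the minimum
#' gained-site score (low values flag candidates likely to show partial
#' splicing in a validation assay).
#'
#' @param variant an \linkS4class{AnnotatedVariant}.
#' @param event a \linkS4class{SpliceEvent}.
#' @param consequence a \linkS4class{TranscriptConsequence} or \code{NULL}.
#' @return A one-row data.frame.
#' @export
summarizeConsequence <- function(variant, event, consequence) {
    if (eventKind(event) == "none" || is.null(consequence))
        return(data.frame(
            proband = variant@probandId, gene = variant@gene,
            key = variantKey(variant), zygosity = variant@zygosity,
            event = "none", inserted_length = NA_integer_,
            frame = NA_character_, ptc_codon = NA_integer_,
            nmd = NA, min_gained_score = NA_real_,
            note = "no predicted effect", stringsAsFactors = FALSE))
    data.frame(
        proband = variant@probandId, gene = variant@gene,
        key = variantKey(variant), zygosity = variant@zygosity,
        event = eventKind(event),
        inserted_length = insertedLength(event),
        frame = frameClass(consequence),
        ptc_codon = ptcCodon(consequence),
        nmd = nmdPredicted(consequence),
        min_gained_score = event@minGainedScore,
        note = if (variant@zygosity == "hom") "homozygous" else "",
        stringsAsFactors = FALSE)
}
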