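#' Read a reference genome FASTA
#'
#' Thin wrapper around \code{\link[Biostrings]{readDNAStringSet}} that keys
#' contigs by the first whitespace-delimited token of each header, uppercases
#' the sequence, and enforces a clean ACGTN alphabet.
#'
#' @param path path to a FASTA file.
#' @return A named \link[Biostrings]{DNAStringSet}, one element per contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrT toy", "acgtACGT"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
    seqs <- Biostrings::readDNAStringSet(path)
    if (length(seqs) == 0L)
        stop("FASTA file contains no sequences: ", path)
    nm <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(nm))
        stop("duplicate contig name in FASTA: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    if (any(Biostrings::width(seqs) == 0L))
        stop("empty contig in FASTA: ", paste(nm[Biostrings::width(seqs) == 0L],
                                              collapse = ", "))
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
    names(seqs) <- nm
    bad <- grepl("[^ACGTN]", as.character(seqs))
    if (any(bad))
        stop("contig contains characters outside ACGTN: ",
             paste(nm[bad], collapse = ", "))
    seqs
}

#' Read transcript models from GFF3 or GTF
#'
#' Imports exon and CDS features with \code{\link[rtracklayer]{import}},
#' groups them by transcript, and returns one
#' \linkS4class{TranscriptModel} per transcript. File coordinates (1-based
#' inclusive) are kept as-is, the convention used throughout the package.
#'
#' @param path path to a GFF3 or GTF file.
#' @param dialect "gff3" or "gtf"; default guesses from the file extension.
#' @param genome optional \link[Biostrings]{DNAStringSet}; when supplied,
#'   exons are checked against contig bounds.
#' @return A named list of \linkS4class{TranscriptModel} objects, keyed by
#'   transcript id.
#' @export
readGeneModels <- function(path, dialect = c("auto", "gff3", "gtf"),
                           genome = NULL) {
    dialect <- match.arg(dialect)
    if (dialect == "auto")
        dialect <- if (grepl("\\.gtf$", path, ignore.case = TRUE))
            "gtf" else "gff3"
    gr <- rtracklayer::import(path, format = dialect)
    md <- S4Vectors::mcols(gr)
    type <- as.character(md$type)
    keep <- type %in% c("exon", "CDS")
    gr <- gr[keep]; md <- md[keep, , drop = FALSE]; type <- type[keep]
    txOf <- function(md) {
        if (!is.null(md$transcript_id)) return(as.character(md$transcript_id))
        if (!is.null(md$Parent)) {
            p <- md$Parent
            if (is(p, "List")) p <- vapply(p, function(x)
                if (length(x)) x[[1L]] else NA_character_, character(1))
            return(sub("^transcript:", "", as.character(p)))
        }
        stop("cannot determine transcript id from ", path)
    }
    txid <- txOf(md)
    gene <- if (!is.null(md$gene_name)) as.character(md$gene_name)
            else if (!is.null(md$gene_id)) as.character(md$gene_id)
            else if (!is.null(md$gene)) as.character(md$gene)
            else rep("", length(gr))
    out <- list()
    for (id in unique(txid)) {
        sel <- txid == id
        ex <- gr[sel & type == "exon"]
        cds <- gr[sel & type == "CDS"]
        if (length(ex) == 0L)
            stop("transcript without exon rows: ", id)
        contig <- as.character(GenomicRanges::seqnames(ex))[1L]
        strand <- as.character(GenomicRanges::strand(ex))[1L]
        if (!strand %in% c("+", "-"))
            stop("transcript without declared strand: ", id)
        rng <- IRanges::IRanges(GenomicRanges::start(ex),
                                GenomicRanges::end(ex))
        rng <- BiocGenerics::sort(rng)
        if (length(rng) > 1L &&
            any(IRanges::start(rng)[-1L] <=
                IRanges::end(rng)[-length(rng)]))
            stop("overlapping exons in transcript ", id)
        if (!is.null(genome)) {
            if (!contig %in% names(genome))
                stop("transcript ", id, " on unknown contig ", contig)
            if (max(IRanges::end(rng)) > length(genome[[contig]]))
                stop("exon outside contig bounds in transcript ", id)
        }
        g <- gene[sel][1L]
        cs <- ce <- NA_integer_
        if (length(cds)) {
            cs <- min(GenomicRanges::start(cds))
            ce <- max(GenomicRanges::end(cds))
        }
        out[[id]] <- transcriptModel(id, g, contig, strand, rng,
                                     cdsStart = cs, cdsEnd = ce)
    }
    out
}

#' Intron ranges of a transcript
#'
#' @param tx a \linkS4class{TranscriptModel}.
#' @return An \link[IRanges]{IRanges} of introns in ascending genomic order
#'   (empty for a single-exon transcript). Intron k in transcript order is
#'   element k for a plus-strand gene and element
#'   \code{length(introns) - k + 1} for a minus-strand gene.
#' @export
intronRanges <- function(tx) {
    ex <- exonRanges(tx)
    if (length(ex) < 2L) return(IRanges::IRanges())
    IRanges::IRanges(IRanges::end(ex)[-length(ex)] + 1L,
                     IRanges::start(ex)[-1L] - 1L)
}

#' Distance of a genomic position from the nearest exon-intron junction
#'
#' For an intronic position the distance is the number of intronic bases
#' between the position and the closer flanking exon edge, counting the
#' position itself: the first intronic base next to an exon has distance 1,
#' matching the HGVS "+1"/"-1" offsets. Deep-intronic filtering keeps
#' positions with distance strictly greater than the chosen threshold.
#'
#' @param pos 1-based genomic position on the transcript's contig.
#' @param tx a \linkS4class{TranscriptModel}.
#' @return A list with \code{distance} (integer bases) and \code{location}
#'   ("exonic", "intronic" or "outside"). Exonic positions have distance 0;
#'   positions outside the transcript span report the distance to the nearer
#'   transcript end.
#' @examples
#' tx <- transcriptModel("t", "G", "c", "+",
#'                       IRanges::IRanges(c(1, 1102), c(100, 1300)))
#' junctionDistance(182, tx)  # intronic offset +82
#' @export
junctionDistance <- function(pos, tx) {
    pos <- as.integer(pos)
    ex <- exonRanges(tx)
    s <- min(IRanges::start(ex)); e <- max(IRanges::end(ex))
    if (pos < s || pos > e)
        return(list(distance = min(abs(pos - s), abs(pos - e)),
                    location = "outside"))
    if (any(pos >= IRanges::start(ex) & pos <= IRanges::end(ex)))
        return(list(distance = 0L, location = "exonic"))
    upEnd <- max(IRanges::end(ex)[IRanges::end(ex) < pos])
    downStart <- min(IRanges::start(ex)[IRanges::start(ex) > pos])
    list(distance = min(pos - upEnd, downStart - pos),
         location = "intronic")
}

## Transcript-sense coordinate of a genomic exonic base: 1 = transcript 5'
## end. Errors if pos is not exonic.
txCoord <- function(tx, pos) {
    ex <- exonRanges(tx)
    hit <- which(pos >= IRanges::start(ex) & pos <= IRanges::end(ex))
    if (length(hit) != 1L)
        stop("position ", pos, " is not exonic in ", txId(tx))
    w <- IRanges::width(ex)
    if (txStrand(tx) == "+") {
        before <- if (hit > 1L) sum(w[seq_len(hit - 1L)]) else 0L
        before + (pos - IRanges::start(ex)[hit]) + 1L
    } else {
        ord <- rev(seq_along(ex))               # transcript order
        idx <- match(hit, ord)
        before <- if (idx > 1L) sum(w[ord[seq_len(idx - 1L)]]) else 0L
        before + (IRanges::end(ex)[hit] - pos) + 1L
    }
}

## First CDS base in transcript sense (genomic position).
cdsFirstBase <- function(tx) {
    if (is.na(tx@cdsStart)) stop("non-coding transcript: ", txId(tx))
    if (txStrand(tx) == "+") tx@cdsStart else tx@cdsEnd
}

## cDNA (HGVS c.) coordinate of an exonic genomic base: 1 = A of the
## initiator ATG. Positions 5' of the CDS come out <= 0 and are rejected,
## full 5'-UTR notation being out of scope.
cdnaPosition <- function(tx, pos) {
    p <- txCoord(tx, pos) - txCoord(tx, cdsFirstBase(tx)) + 1L
    if (p < 1L)
        stop("position 5' of the CDS is not supported: ", pos)
    p
}

## Inverse of cdnaPosition: genomic base of cDNA coordinate n.
genomicPosition <- function(tx, n) {
    ex <- exonRanges(tx)
    offset <- txCoord(tx, cdsFirstBase(tx)) - 1L
    t <- n + offset                              # transcript-sense coordinate
    w <- IRanges::width(ex)
    ord <- if (txStrand(tx) == "+") seq_along(ex) else rev(seq_along(ex))
    cum <- cumsum(w[ord])
    i <- which(t <= cum)[1L]
    if (is.na(i)) stop("cDNA position ", n, " beyond transcript end")
    within <- t - (if (i > 1L) cum[i - 1L] else 0L)
    g <- ord[i]
    if (txStrand(tx) == "+") IRanges::start(ex)[g] + within - 1L
    else IRanges::end(ex)[g] - within + 1L
}
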