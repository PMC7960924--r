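#' Parse a cDNA (HGVS c.) variant label with intronic offsets
#'
#' Understands the substitution grammar \code{c.N<ref>><alt>} and its
#' intronic forms \code{c.N+M<ref>><alt>} / \code{c.N-M<ref>><alt>}, where N
#' is the cDNA anchor (the exon edge the offset counts from) and M the
#' intronic offset. Thousands separators and stray spaces inside the offset
#' are tolerated (\code{"c.3998+3,023 T>G"}). Other exonic descriptions
#' (\code{del}, \code{dup}, ...) are accepted as exonic anchors with
#' offset 0; their edit semantics are not interpreted.
#'
#' @param text a single HGVS c. label.
#' @return A list with \code{kind} ("intronic" or "exonic"), \code{anchor}
#'   (integer cDNA position), \code{offset} (integer, 0 for exonic),
#'   \code{side} ("donor_downstream" for +M, "acceptor_upstream" for -M,
#'   \code{NA} for exonic), \code{ref}, \code{alt} (\code{NA} for
#'   non-substitution labels) and the original \code{text}.
#' @examples
#' parseIntronicHgvs("c.2367+82A>G")
#' parseIntronicHgvs("c.8682-654C>G")
#' parseIntronicHgvs("c.1148delC")
#' @export
parseIntronicHgvs <- function(text) {
    stopifnot(length(text) == 1L)
    raw <- text
    s <- gsub("[ ,]", "", text)
    m <- regexec("^c\\.(\\d+)([+-])(\\d+)([ACGT])>([ACGT])$", s)[[1L]]
    if (m[1L] != -1L) {
        g <- regmatches(s, list(m))[[1L]]
        return(list(kind = "intronic", anchor = as.integer(g[2L]),
                    offset = as.integer(g[4L]),
                    side = if (g[3L] == "+") "donor_downstream"
                           else "acceptor_upstream",
                    ref = g[5L], alt = g[6L], text = raw))
    }
    m <- regexec("^c\\.(\\d+)([ACGT])>([ACGT])$", s)[[1L]]
    if (m[1L] != -1L) {
        g <- regmatches(s, list(m))[[1L]]
        return(list(kind = "exonic", anchor = as.integer(g[2L]),
                    offset = 0L, side = NA_character_,
                    ref = g[3L], alt = g[4L], text = raw))
    }
    m <- regexec("^c\\.(\\d+)(_\\d+)?(del|dup|ins)[ACGT]*$", s)[[1L]]
    if (m[1L] != -1L) {
        g <- regmatches(s, list(m))[[1L]]
        return(list(kind = "exonic", anchor = as.integer(g[2L]),
                    offset = 0L, side = NA_character_,
                    ref = NA_character_, alt = NA_character_, text = raw))
    }
    bad <- regexpr("[^c.0-9+_ ,>ACGTdelupins-]", s)
    stop("cannot parse HGVS c. label '", raw, "'",
         if (bad > 0L) sprintf(" (unexpected character at position %d)", bad)
         else " (grammar mismatch)")
}

complementBases <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Format a genomic substitution as a cDNA (HGVS c.) label
#'
#' The inverse of [parseIntronicHgvs()] on the same transcript: an exonic
#' position becomes \code{c.N<ref>><alt>}; an intronic position is anchored
#' at the nearer exon edge in transcript sense, \code{+M} downstream of a
#' donor, \code{-M} upstream of an acceptor (ties go to the donor side).
#' On minus-strand transcripts ref and alt are complemented to the coding
#' strand.
#'
#' @param tx a coding \linkS4class{TranscriptModel}.
#' @param pos 1-based genomic position within the transcript span.
#' @param ref,alt reference-strand alleles (single bases).
#' @return The HGVS c. label as a string.
#' @export
formatIntronicHgvs <- function(tx, pos, ref, alt) {
    pos <- as.integer(pos)
    loc <- junctionDistance(pos, tx)
    if (loc$location == "outside")
        stop("position ", pos, " lies outside transcript ", txId(tx))
    if (txStrand(tx) == "-") { ref <- complementBases(ref)
                               alt <- complementBases(alt) }
    if (loc$location == "exonic")
        return(sprintf("c.%d%s>%s", cdnaPosition(tx, pos), ref, alt))
    ex <- exonRanges(tx)
    upEnd <- max(IRanges::end(ex)[IRanges::end(ex) < pos])
    downStart <- min(IRanges::start(ex)[IRanges::start(ex) > pos])
    if (txStrand(tx) == "+") {
        dDonor <- pos - upEnd;        donorAnchor <- upEnd
        dAcc   <- downStart - pos;    accAnchor   <- downStart
    } else {
        dDonor <- downStart - pos;    donorAnchor <- downStart
        dAcc   <- pos - upEnd;        accAnchor   <- upEnd
    }
    if (dDonor <= dAcc)
        sprintf("c.%d+%d%s>%s", cdnaPosition(tx, donorAnchor), dDonor,
                ref, alt)
    else
        sprintf("c.%d-%d%s>%s", cdnaPosition(tx, accAnchor), dAcc, ref, alt)
}

#' Map a parsed cDNA label back to a genomic position
#'
#' @param tx a coding \linkS4class{TranscriptModel}.
#' @param label an HGVS c. label or the list returned by
#'   [parseIntronicHgvs()].
#' @return The 1-based genomic position of the variant.
#' @export
hgvsToGenomic <- function(tx, label) {
    p <- if (is.character(label)) parseIntronicHgvs(label) else label
    anchorG <- genomicPosition(tx, p$anchor)
    if (p$kind == "exonic") return(anchorG)
    plus <- txStrand(tx) == "+"
    if (p$side == "donor_downstream") {
        if (plus) anchorG + p$offset else anchorG - p$offset
    } else {
        if (plus) anchorG - p$offset else anchorG + p$offset
    }
}

#' Transcript-order index of the intron containing a position
#'
#' Intron k is the intron that follows exon k in transcript (5' to 3')
#' order, the numbering used in clinical reports.
#'
#' @param tx a \linkS4class{TranscriptModel}.
#' @param pos 1-based genomic position.
#' @return Integer intron index, or \code{NA} if the position is not
#'   intronic.
#' @export
intronNumber <- function(tx, pos) {
    intr <- intronRanges(tx)
    hit <- which(pos >= IRanges::start(intr) & pos <= IRanges::end(intr))
    if (length(hit) != 1L) return(NA_integer_)
    if (txStrand(tx) == "+") hit else length(intr) - hit + 1L
}
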