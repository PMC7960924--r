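#' Read a gene panel table
#'
#' The panel is a TSV with columns \code{gene}, \code{inheritance}
#' (AD / AR / XL) and \code{transcript_id} (the canonical transcript
#' evaluated for that gene). Gene symbols are matched case-sensitively
#' throughout the package.
#'
#' @param path path to the panel TSV.
#' @return A data.frame with one row per gene.
#' @export
readGenePanel <- function(path) {
    p <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "inheritance", "transcript_id")
    if (!all(need %in% colnames(p)))
        stop("panel must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(p$gene))
        stop("panel lists a gene more than once")
    if (!all(p$inheritance %in% c("AD", "AR", "XL")))
        stop("inheritance must be one of AD, AR, XL")
    p
}

dropReason <- function(variants, keep, reason) {
    removed <- variants[!keep]
    out <- variants[keep]
    rem <- attr(variants, "removed")
    if (is.null(rem)) rem <- data.frame(key = character(),
                                        reason = character())
    if (length(removed))
        rem <- rbind(rem, data.frame(
            key = vapply(removed, variantKey, character(1)),
            reason = reason))
    attr(out, "removed") <- rem
    out
}

#' Population-frequency filter
#'
#' Keeps variants rare enough to cause a rare Mendelian disease: allele
#' frequency strictly below \code{afMax}, or absent from the population
#' database altogether (an unobserved allele is by definition rare).
#' Removed variants are tagged "common" in the \code{removed} attribute of
#' the result.
#'
#' @param variants list of \linkS4class{AnnotatedVariant}.
#' @param afMax maximum allele frequency (default 0.005, i.e. 0.5\%).
#' @return The surviving variants (with a \code{removed} attribute
#'   accumulating \code{key}/\code{reason} rows).
#' @export
frequencyFilter <- function(variants, afMax = 0.005) {
    keep <- vapply(variants, function(v)
        is.na(v@alleleFrequency) || v@alleleFrequency < afMax, logical(1))
    dropReason(variants, keep, "common")
}

#' Splice-score filter
#'
#' Keeps variants whose maximum SpliceAI delta score (over acceptor
#' gain/loss and donor gain/loss) reaches the cutoff; variants without a
#' SpliceAI annotation fail. Removed variants are tagged "low_score".
#'
#' @inheritParams frequencyFilter
#' @param cutoff minimum max-delta score; the cutoff is inclusive
#'   (score >= cutoff passes). Default 0.5.
#' @return The surviving variants.
#' @export
spliceScoreFilter <- function(variants, cutoff = 0.5) {
    keep <- vapply(variants, function(v) {
        d <- maxDelta(v)
        !is.na(d) && d >= cutoff
    }, logical(1))
    dropReason(variants, keep, "low_score")
}

#' Gene-panel restriction
#'
#' Keeps variants annotated to a gene in the disease panel; others are
#' tagged "not_in_panel".
#'
#' @inheritParams frequencyFilter
#' @param panel data.frame from [readGenePanel()].
#' @return The surviving variants.
#' @export
panelRestrict <- function(variants, panel) {
    keep <- vapply(variants, function(v) v@gene %in% panel$gene, logical(1))
    dropReason(variants, keep, "not_in_panel")
}

#' Deep-intronic distance filter
#'
#' Keeps variants lying strictly more than \code{minDistance} intronic
#' bases from the nearest exon-intron junction of the gene's canonical
#' transcript, removing anything close enough to act through the canonical
#' splice sites. With the HGVS-aligned distance convention (the first
#' intronic base has distance 1), the default excludes offsets +1..+10 and
#' -1..-10. Exonic and near-junction variants are tagged "near_junction";
#' they remain eligible as coding second alleles, just not as deep-intronic
#' splice candidates.
#'
#' @inheritParams frequencyFilter
#' @param txLookup named list of \linkS4class{TranscriptModel}, keyed by
#'   gene symbol (the panel's canonical transcript per gene).
#' @param minDistance junction-distance threshold (default 10; strict >).
#' @return The surviving variants.
#' @export
deepIntronicFilter <- function(variants, txLookup, minDistance = 10) {
    keep <- vapply(variants, function(v) {
        tx <- txLookup[[v@gene]]
        if (is.null(tx))
            stop("no canonical transcript for gene ", v@gene)
        jd <- junctionDistance(v@pos, tx)
        jd$location == "intronic" && jd$distance > minDistance
    }, logical(1))
    dropReason(variants, keep, "near_junction")
}

#' Pair alleles of one gene under its inheritance model
#'
#' Dominant (AD) genes and X-linked (XL) hemizygous genotypes are solved by
#' a single qualifying splice variant. Recessive (AR) genes need a second
#' allele: a homozygous splice variant, a second qualifying splice variant,
#' or a rare coding hit in the same gene; a lone heterozygous splice
#' variant is reported as \code{needs_second_allele}. Heterozygous variants
#' under XL are likewise held for a second allele. Compound heterozygotes
#' are assumed in trans when phase is unknown and flagged
#' \code{phase_unconfirmed}.
#'
#' @param spliceVars qualifying splice candidates in the gene (list of
#'   \linkS4class{AnnotatedVariant}).
#' @param codingHits rare coding variants in the same gene (list).
#' @param mode "AD", "AR" or "XL".
#' @return A list with \code{status} ("solved_candidate",
#'   "needs_second_allele" or "rejected"), \code{reasons} (character),
#'   \code{paired} (list of the alleles supporting the call) and
#'   \code{phaseUnconfirmed} (logical).
#' @export
inheritancePairing <- function(spliceVars, codingHits = list(), mode) {
    if (!mode %in% c("AD", "AR", "XL"))
        stop("unknown inheritance mode: ", mode)
    if (length(spliceVars) == 0L)
        return(list(status = "rejected", reasons = "unpaired",
                    paired = list(), phaseUnconfirmed = FALSE))
    zyg <- vapply(spliceVars, function(v) v@zygosity, character(1))
    if (mode == "AD")
        return(list(status = "solved_candidate", reasons = character(),
                    paired = spliceVars[1L], phaseUnconfirmed = FALSE))
    if (mode == "XL") {
        hemi <- which(zyg %in% c("hemi", "hom"))
        if (length(hemi))
            return(list(status = "solved_candidate", reasons = character(),
                        paired = spliceVars[hemi[1L]],
                        phaseUnconfirmed = FALSE))
        return(list(status = "needs_second_allele", reasons = "unpaired",
                    paired = spliceVars, phaseUnconfirmed = FALSE))
    }
    ## AR
    hom <- which(zyg == "hom")
    if (length(hom))
        return(list(status = "solved_candidate", reasons = character(),
                    paired = spliceVars[hom[1L]], phaseUnconfirmed = FALSE))
    if (length(spliceVars) >= 2L)
        return(list(status = "solved_candidate", reasons = character(),
                    paired = spliceVars[1:2], phaseUnconfirmed = TRUE))
    if (length(codingHits) >= 1L)
        return(list(status = "solved_candidate", reasons = character(),
                    paired = c(spliceVars[1L], codingHits[1L]),
                    phaseUnconfirmed = TRUE))
    list(status = "needs_second_allele", reasons = "unpaired",
         paired = spliceVars, phaseUnconfirmed = FALSE)
}

#' Prioritize a cohort of probands
#'
#' Runs the full candidate-selection cascade for every proband in a
#' manifest: population-frequency filter, SpliceAI score filter, gene-panel
#' restriction, inheritance-aware allele pairing, and the deep-intronic
#' junction-distance filter. Coding variants are never splice candidates
#' but remain eligible as second alleles for recessive genes. The filters
#' are pure, so their order only affects which removal reason a multiply
#' failing variant is tagged with.
#'
#' @param manifest data.frame with columns \code{proband} and \code{vcf}
#'   (path to the proband's annotated VCF).
#' @param panel data.frame from [readGenePanel()].
#' @param models named list of \linkS4class{TranscriptModel} keyed by
#'   transcript id (must cover every panel transcript).
#' @param afMax,scoreCutoff,minJunctionDistance filter thresholds; defaults
#'   0.005, 0.5 and 10.
#' @param afKey INFO key holding the allele frequency.
#' @return A list with \code{reports} (per-proband list: \code{probandId},
#'   per-gene pairing \code{genes}, and the proband's candidate rows),
#'   \code{candidates} (data.frame of splice-candidate rows across solved
#'   probands), \code{funnel} (per-stage in/out counts), and \code{summary}
#'   (\code{nDistinctSplice}, \code{nSolvedProbands}, \code{nNovel}).
#' @export
prioritizeCohort <- function(manifest, panel, models, afMax = 0.005,
                             scoreCutoff = 0.5, minJunctionDistance = 10,
                             afKey = "AF") {
    txByGene <- list()
    for (i in seq_len(nrow(panel))) {
        tx <- models[[panel$transcript_id[i]]]
        if (is.null(tx))
            stop("panel transcript not found in models: ",
                 panel$transcript_id[i])
        txByGene[[panel$gene[i]]] <- tx
    }
    manifest <- manifest[order(manifest$proband), , drop = FALSE]
    reports <- list()
    candRows <- list()
    funnel <- c(input = 0L, rare = 0L, high_score = 0L, in_panel = 0L,
                deep_intronic = 0L, solved = 0L)
    for (i in seq_len(nrow(manifest))) {
        pid <- manifest$proband[i]
        if (!file.exists(manifest$vcf[i]))
            stop("VCF missing for proband ", pid, ": ", manifest$vcf[i])
        vars <- readAnnotatedVcf(manifest$vcf[i], probandId = pid,
                                 afKey = afKey)
        funnel["input"] <- funnel["input"] + length(vars)
        rare <- frequencyFilter(vars, afMax = afMax)
        funnel["rare"] <- funnel["rare"] + length(rare)
        scored <- spliceScoreFilter(rare, cutoff = scoreCutoff)
        funnel["high_score"] <- funnel["high_score"] + length(scored)
        inPanel <- panelRestrict(scored, panel)
        funnel["in_panel"] <- funnel["in_panel"] + length(inPanel)
        deep <- deepIntronicFilter(inPanel, txByGene,
                                   minDistance = minJunctionDistance)
        funnel["deep_intronic"] <- funnel["deep_intronic"] + length(deep)
        codingPool <- panelRestrict(frequencyFilter(vars, afMax = afMax),
                                    panel)
        codingPool <- codingPool[vapply(codingPool, function(v)
            v@codingClass != "none", logical(1))]
        genes <- unique(vapply(deep, geneSymbol, character(1)))
        geneStatus <- list()
        for (g in sort(genes)) {
            sv <- deep[vapply(deep, function(v) v@gene == g, logical(1))]
            ch <- codingPool[vapply(codingPool, function(v)
                v@gene == g, logical(1))]
            ## the same allele cannot pair with itself
            svKeys <- vapply(sv, variantKey, character(1))
            ch <- ch[!vapply(ch, variantKey, character(1)) %in% svKeys]
            mode <- panel$inheritance[panel$gene == g]
            geneStatus[[g]] <- inheritancePairing(sv, ch, mode)
        }
        solved <- any(vapply(geneStatus, function(s)
            s$status == "solved_candidate", logical(1)))
        if (solved) funnel["solved"] <- funnel["solved"] + 1L
        rows <- list()
        for (g in names(geneStatus)) {
            st <- geneStatus[[g]]
            if (st$status != "solved_candidate") next
            tx <- txByGene[[g]]
            for (v in st$paired) {
                isSplice <- !is.null(v@spliceai) &&
                    maxDelta(v) >= scoreCutoff &&
                    junctionDistance(v@pos, tx)$location == "intronic"
                jd <- junctionDistance(v@pos, tx)
                lab <- if (nchar(v@ref) == 1L && nchar(v@alt) == 1L)
                    formatIntronicHgvs(tx, v@pos, v@ref, v@alt)
                else if (nzchar(v@cdnaLabel)) v@cdnaLabel
                else ""
                rows[[length(rows) + 1L]] <- data.frame(
                    proband = pid, gene = g, contig = v@contig, pos = v@pos,
                    ref = v@ref, alt = v@alt, cdna = lab,
                    zygosity = v@zygosity,
                    type = if (isSplice) "splicing" else v@codingClass,
                    novel = v@novel,
                    max_delta = if (is.null(v@spliceai)) NA_real_
                                else maxDelta(v),
                    junction_distance = jd$distance,
                    phase_unconfirmed = st$phaseUnconfirmed,
                    key = variantKey(v),
                    stringsAsFactors = FALSE)
            }
        }
        probandRows <- if (length(rows)) do.call(rbind, rows) else
            data.frame()
        reports[[pid]] <- list(probandId = pid, genes = geneStatus,
                               candidates = probandRows)
        if (length(rows)) candRows <- c(candRows, rows)
    }
    candidates <- if (length(candRows)) do.call(rbind, candRows) else
        data.frame(proband = character(), gene = character(),
                   contig = character(), pos = integer(), ref = character(),
                   alt = character(), cdna = character(),
                   zygosity = character(), type = character(),
                   novel = logical(), max_delta = numeric(),
                   junction_distance = integer(),
                   phase_unconfirmed = logical(), key = character(),
                   stringsAsFactors = FALSE)
    spl <- candidates[candidates$type == "splicing", , drop = FALSE]
    distinct <- !duplicated(spl$key)
    summary <- list(
        nDistinctSplice = sum(distinct),
        nSolvedProbands = unname(funnel["solved"]),
        nNovel = sum(spl$novel[distinct], na.rm = TRUE))
    list(reports = reports, candidates = candidates,
         funnel = funnel, summary = summary)
}
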