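#' Parse a SpliceAI INFO field
#'
#' The published SpliceAI VCF convention packs one annotation per gene as
#' ten pipe-delimited tokens,
#' \code{ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL},
#' with several genes separated by commas. "." tokens are read as score 0
#' and position 0.
#'
#' @param text the raw INFO value (possibly comma-separated), or a character
#'   vector of already-split groups.
#' @return A list of \linkS4class{SpliceAIRecord}, one per gene annotation.
#' @examples
#' parseSpliceaiField("G|OPA1|0.02|0.01|0.91|0.63|-9|21|7|-38")
#' @export
parseSpliceaiField <- function(text) {
    groups <- unlist(strsplit(text, ",", fixed = TRUE), use.names = FALSE)
    lapply(groups, function(g) {
        tok <- strsplit(g, "|", fixed = TRUE)[[1L]]
        if (length(tok) != 10L)
            stop("malformed SpliceAI group (", length(tok),
                 " tokens, expected 10): '", g, "'")
        num <- function(x) {
            x[x %in% c(".", "")] <- "0"
            suppressWarnings(as.numeric(x))
        }
        sc <- num(tok[3:6])
        if (any(is.na(sc)) || any(sc < 0) || any(sc > 1))
            stop("SpliceAI delta score outside [0,1] in group '", g, "'")
        dp <- as.integer(num(tok[7:10]))
        spliceAIRecord(allele = tok[1L], gene = tok[2L],
                       dsAG = sc[1L], dsAL = sc[2L],
                       dsDG = sc[3L], dsDL = sc[4L],
                       dpAG = dp[1L], dpAL = dp[2L],
                       dpDG = dp[3L], dpDL = dp[4L])
    })
}

zygosityFromGT <- function(gt, altIdx) {
    if (is.na(gt) || gt %in% c(".", "./.", ".|."))
        stop("missing GT genotype")
    alleles <- strsplit(gt, "[/|]")[[1L]]
    hits <- sum(alleles == as.character(altIdx))
    if (length(alleles) == 1L)
        return(if (hits == 1L) "hemi" else NA_character_)
    if (hits == 2L) "hom" else if (hits == 1L) "het" else NA_character_
}

#' Read an annotated VCF into AnnotatedVariant objects
#'
#' Reads a VCF 4.x file with \code{\link[VariantAnnotation]{readVcf}} and
#' decomposes every record into one \linkS4class{AnnotatedVariant} per ALT
#' allele actually carried by the sample. Understands the INFO keys
#' \code{AF} (population allele frequency, Number=A), \code{SpliceAI}
#' (standard SpliceAI annotation), and the pass-through annotation keys
#' \code{GENE}, \code{CODING} (coding consequence class), \code{CDNA}
#' (HGVS c. label), \code{NOVEL} (absent from population databases) and any
#' of \code{CADD}/\code{VEST3}/\code{GERP} rank scores. The AF key name is
#' configurable because cohorts differ in which population database
#' supplies it.
#'
#' @param path path to a VCF file.
#' @param probandId sample identifier recorded on each variant; defaults to
#'   the VCF sample name.
#' @param afKey INFO key holding the population allele frequency.
#' @return A list of \linkS4class{AnnotatedVariant}.
#' @export
readAnnotatedVcf <- function(path, probandId = NULL, afKey = "AF") {
    vcf <- VariantAnnotation::readVcf(path)
    if (ncol(vcf) < 1L)
        stop("VCF has no sample column (GT required): ", path)
    if (is.null(probandId))
        probandId <- colnames(vcf)[1L]
    rr <- SummarizedExperiment::rowRanges(vcf)
    refs <- as.character(VariantAnnotation::ref(vcf))
    alts <- VariantAnnotation::alt(vcf)
    info <- VariantAnnotation::info(vcf)
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("VCF lacks the GT FORMAT field: ", path)
    getInfo1 <- function(key, i) {
        if (!key %in% colnames(info)) return(NA)
        v <- info[[key]][i]
        if (is(v, "List") || is.list(v)) v <- unlist(v)
        if (length(v) == 0L) NA else v[1L]
    }
    out <- list()
    for (i in seq_along(vcf)) {
        contig <- as.character(GenomicRanges::seqnames(rr))[i]
        pos <- GenomicRanges::start(rr)[i]
        altSet <- as.character(alts[[i]])
        afs <- if (afKey %in% colnames(info)) {
            v <- info[[afKey]][i]
            if (is(v, "List") || is.list(v)) unlist(v) else v
        } else rep(NA_real_, length(altSet))
        saiGroups <- if ("SpliceAI" %in% colnames(info)) {
            v <- info$SpliceAI[i]
            if (is(v, "List") || is.list(v)) unlist(v) else v
        } else character()
        saiGroups <- saiGroups[!is.na(saiGroups)]
        recs <- if (length(saiGroups))
            parseSpliceaiField(paste(saiGroups, collapse = ",")) else list()
        for (k in seq_along(altSet)) {
            a <- altSet[k]
            if (!grepl("^[ACGT]+$", a))
                stop("symbolic or non-ACGT ALT allele rejected: ", a)
            zyg <- zygosityFromGT(gt[i, 1L], k)
            if (is.na(zyg)) next                 # allele not carried
            sai <- NULL
            for (r in recs) if (r@allele == a) { sai <- r; break }
            rs <- c(CADD = suppressWarnings(as.numeric(getInfo1("CADD", i))),
                    VEST3 = suppressWarnings(as.numeric(getInfo1("VEST3", i))),
                    GERP = suppressWarnings(as.numeric(getInfo1("GERP", i))))
            rs <- rs[!is.na(rs)]
            af <- if (length(afs) >= k) as.numeric(afs[k]) else NA_real_
            nv <- getInfo1("NOVEL", i)
            out[[length(out) + 1L]] <- annotatedVariant(
                contig = contig, pos = pos, ref = refs[i], alt = a,
                probandId = probandId,
                gene = {g <- getInfo1("GENE", i); if (is.na(g)) "" else g},
                zygosity = zyg, alleleFrequency = af,
                codingClass = {cc <- getInfo1("CODING", i)
                               if (is.na(cc)) "none" else cc},
                rankScores = rs, spliceai = sai,
                novel = if (is.na(nv)) NA else as.logical(nv),
                cdnaLabel = {cd <- getInfo1("CDNA", i)
                             if (is.na(cd)) "" else cd})
        }
    }
    out
}

#' Unique key of a variant allele
#'
#' @param v an \linkS4class{AnnotatedVariant}.
#' @return "contig:pos:ref:alt" as a string.
#' @export
variantKey <- function(v)
    paste(v@contig, v@pos, v@ref, v@alt, sep = ":")

#' Write the candidate report TSV
#'
#' Writes finalized candidate rows with a deterministic column order and a
#' deterministic row order (proband id, then genomic position); coordinates
#' are 1-based. Running it twice on the same input yields byte-identical
#' files.
#'
#' @param candidates a data.frame of candidate rows as produced by
#'   [prioritizeCohort()] (columns proband, gene, contig, pos, ref, alt,
#'   cdna, zygosity, type, novel, and any extra measurement columns).
#' @param path output path.
#' @return Invisibly, the ordered data.frame that was written.
#' @export
writeCandidateTsv <- function(candidates, path) {
    cols <- c("proband", "gene", "contig", "pos", "ref", "alt", "cdna",
              "zygosity", "type", "novel")
    extra <- setdiff(colnames(candidates), cols)
    if (nrow(candidates)) {
        candidates <- candidates[order(candidates$proband, candidates$contig,
                                       candidates$pos), , drop = FALSE]
    }
    df <- candidates[, c(intersect(cols, colnames(candidates)), extra),
                     drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    invisible(df)
}
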