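## Geometry of the worked-example genes. Each gene-analog is a two-exon
## transcript on its own contig, laid out so that the published cDNA
## anchors of the case series are literally realizable: the first exon ends
## (or the second begins) at the printed anchor, and the intron is long
## enough both to host the printed intronic offset and to keep the variant
## on the anchored side of the intron midpoint so the formatted HGVS label
## reproduces the printed one.
exampleGeneGeometry <- function() {
    list(
        ADGRV1  = list(e1 = 14661L, ilen = 1600L, e2 = 1500L, inh = "AR"),
        USH2A   = list(e1 = 8681L,  ilen = 1400L, e2 = 3190L, inh = "AR"),
        OPA1    = list(e1 = 1608L,  ilen = 1400L, e2 = 402L,  inh = "AD"),
        RPGRIP1 = list(e1 = 2367L,  ilen = 400L,  e2 = 405L,  inh = "AR"),
        CNGB3   = list(e1 = 1662L,  ilen = 2600L, e2 = 501L,  inh = "AR"),
        PCDH15  = list(e1 = 3998L,  ilen = 6100L, e2 = 403L,  inh = "AR"))
}

patchStr <- function(s, at, value) {
    substr(s, at, at + nchar(value) - 1L) <- value
    s
}

patchCodon <- function(cds, codon, value) {
    stopifnot(nchar(value) == 3L)
    patchStr(cds, 3L * codon - 2L, value)
}

#' Build the bundled worked-example cohort
#'
#' Constructs, deterministically and entirely in code, a six-gene toy
#' genome and an eight-proband cohort reproducing a published case series
#' of deep-intronic splice variants in inherited-retinal-disease genes:
#' six distinct splice variants (five novel) across the six genes, each
#' paired with the reported coding second allele where the inheritance
#' model requires one. The gene models are synthetic stand-ins: exon sizes
#' are chosen so the published cDNA anchors and intronic offsets are
#' literally realizable, and each cryptic-exon insert carries (or omits) an
#' in-frame stop codon exactly as the reported transcript consequence
#' requires. SpliceAI delta scores and positions are encoded so the
#' reported event of each variant (pseudo-exon of 129, 54, 84, 34 or 29
#' bases; 81-base exon elongation) is recovered by event inference.
#'
#' @param dir directory the FASTA, GFF3, panel and per-proband VCFs are
#'   written to (created if missing).
#' @return A list with \code{genome}, \code{models}, \code{panel},
#'   \code{manifest} (proband/vcf data.frame), \code{cases} (the
#'   case-series variant table: patient, gene, cdna, zygosity, type,
#'   novel), \code{paths} (named vector of written files) and
#'   \code{expected} (headline accounting: 6 distinct splice variants, 8
#'   solved probands, 5 novel).
#' @export
exampleCohort <- function(dir = tempfile("ird_cohort_")) {
    set.seed(20210302L)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    geom <- exampleGeneGeometry()
    genome <- character(0)
    models <- list()
    for (g in names(geom)) {
        p <- geom[[g]]
        cds <- makeCds(p$e1 + p$e2)
        intron <- makeIntron(p$ilen)
        if (g == "ADGRV1") {
            cds <- patchCodon(cds, 1988L, "CTT")   # c.5964 = T (dup anchor)
            cds <- patchCodon(cds, 1989L, "ACC")   # c.5965 = A (the dup'd base)
            cont <- randNonStopCodons(28L)         # 84-base cryptic exon
            cont <- patchStr(cont, 1L, "ACT")      # acceptor base = ref A
            cont <- patchStr(cont, 49L, "TAA")     # stop 17 codons in
            intron <- patchStr(intron, 717L, cont)
        } else if (g == "USH2A") {
            cds <- patchCodon(cds, 2894L, "CAC")   # junction codon guard
            cds <- patchCodon(cds, 3358L, "TCT")   # c.10073 = C
            cds <- patchCodon(cds, 3955L, "TGG")   # c.11864 = G
            ## 129-base cryptic exon: acceptor base (ref C), an immediate
            ## in-frame stop, then open sequence
            cont <- paste0("C", "TAA", randNonStopCodons(41L), "CC")
            intron <- patchStr(intron, p$ilen - 654L + 1L, cont)
        } else if (g == "OPA1") {
            cont <- randNonStopCodons(18L)         # 54-base in-frame insert
            cont <- patchStr(cont, 52L, "GCA")     # donor base = ref A
            intron <- patchStr(intron, 569L, cont) # no stop: clean insertion
        } else if (g == "RPGRIP1") {
            cds <- patchCodon(cds, 705L, "CAG")    # c.2114 = A
            cont <- randNonStopCodons(27L)         # 81-base elongation
            cont <- patchStr(cont, 1L, "GTC")      # keep intron GT start
            cont <- patchStr(cont, 55L, "TAA")     # stop 19 codons in
            intron <- patchStr(intron, 1L, cont)
            intron <- patchStr(intron, 82L, "A")   # variant base
        } else if (g == "CNGB3") {
            cds <- patchCodon(cds, 383L, "ACA")    # c.1148 = C (del anchor)
            cont <- paste0("G", randBases(33L))    # 34-base cryptic exon
            intron <- patchStr(intron, p$ilen - 1205L + 1L, cont)
        } else if (g == "PCDH15") {
            cds <- patchCodon(cds, 388L, "GGC")    # c.1163 = G
            cont <- paste0("T", randBases(28L))    # 29-base cryptic exon
            intron <- patchStr(intron, 3023L, cont)
        }
        built <- assembleGene(g, paste0("TX_", g), paste0("chr_", g),
                              c(substr(cds, 1L, p$e1),
                                substr(cds, p$e1 + 1L, p$e1 + p$e2)),
                              intron, "+", pad = 300L)
        genome[paste0("chr_", g)] <- built$seq
        models[[paste0("TX_", g)]] <- built$tx
    }
    genome <- Biostrings::DNAStringSet(genome)
    panel <- data.frame(
        gene = names(geom),
        inheritance = vapply(geom, `[[`, character(1), "inh"),
        transcript_id = paste0("TX_", names(geom)),
        row.names = NULL, stringsAsFactors = FALSE)
    world <- list(genome = genome, models = models, panel = panel)
    paths <- writeWorld(world, dir)

    tx <- function(g) models[[paste0("TX_", g)]]
    gpos <- function(g, n) genomicPosition(tx(g), n)
    ipos <- function(g, intronOffset) {     # offset from the exon-1 donor
        IRanges::end(exonRanges(tx(g)))[1L] + intronOffset
    }
    sai <- list(
        ADGRV1  = spliceaiGroup("G", "ADGRV1", dsAG = 0.58, dsDG = 0.93,
                                dpAG = 0L, dpDG = 83L),
        USH2A   = spliceaiGroup("G", "USH2A", dsAG = 0.62, dsDG = 0.95,
                                dpAG = 0L, dpDG = 128L),
        OPA1    = spliceaiGroup("G", "OPA1", dsAG = 0.88, dsDG = 0.92,
                                dpAG = -53L, dpDG = 0L),
        RPGRIP1 = spliceaiGroup("G", "RPGRIP1", dsDG = 0.90, dsDL = 0.42,
                                dpDG = -1L, dpDL = -82L),
        CNGB3   = spliceaiGroup("A", "CNGB3", dsAG = 0.78, dsDG = 0.86,
                                dpAG = 0L, dpDG = 33L),
        PCDH15  = spliceaiGroup("G", "PCDH15", dsAG = 0.91, dsDG = 0.96,
                                dpAG = 0L, dpDG = 28L))
    spliceRow <- function(g, intronOffsetPos, ref, alt, af, novel, cdna) {
        data.frame(contig = paste0("chr_", g), pos = intronOffsetPos,
                   ref = ref, alt = alt, af = af, spliceai = sai[[g]],
                   gene = g, coding = "none", cdna = cdna, novel = novel,
                   gt = "0/1", stringsAsFactors = FALSE)
    }
    codingRow <- function(g, pos, ref, alt, af, coding, cdna, novel) {
        data.frame(contig = paste0("chr_", g), pos = pos, ref = ref,
                   alt = alt, af = af, spliceai = NA_character_, gene = g,
                   coding = coding, cdna = cdna, novel = novel, gt = "0/1",
                   stringsAsFactors = FALSE)
    }
    base <- function(g, pos) refBaseAt(genome, paste0("chr_", g), pos)

    splice <- list(
        ADGRV1  = spliceRow("ADGRV1", ipos("ADGRV1", 717L), "A", "G",
                            NA_real_, TRUE, "c.14661+717A>G"),
        USH2A   = spliceRow("USH2A", ipos("USH2A", 1400L - 654L + 1L),
                            "C", "G", NA_real_, TRUE, "c.8682-654C>G"),
        OPA1    = spliceRow("OPA1", ipos("OPA1", 622L), "A", "G",
                            NA_real_, TRUE, "c.1608+622A>G"),
        RPGRIP1 = spliceRow("RPGRIP1", ipos("RPGRIP1", 82L), "A", "G",
                            NA_real_, TRUE, "c.2367+82A>G"),
        CNGB3   = spliceRow("CNGB3", ipos("CNGB3", 2600L - 1205L + 1L),
                            "G", "A", 5e-5, FALSE, "c.1663-1205G>A"),
        PCDH15  = spliceRow("PCDH15", ipos("PCDH15", 3023L), "T", "G",
                            NA_real_, TRUE, "c.3998+3023T>G"))
    dupPos <- gpos("ADGRV1", 5964L)
    delPos <- gpos("CNGB3", 1147L)
    coding <- list(
        ADGRV1_dup = codingRow("ADGRV1", dupPos, base("ADGRV1", dupPos),
                               paste0(base("ADGRV1", dupPos), "A"),
                               1.43e-5, "frameshift", "c.5965dupA", FALSE),
        USH2A_mis  = codingRow("USH2A", gpos("USH2A", 10073L), "C", "T",
                               8e-4, "missense", "c.10073C>T", FALSE),
        USH2A_non  = codingRow("USH2A", gpos("USH2A", 11864L), "G", "A",
                               2e-4, "nonsense", "c.11864G>A", FALSE),
        RPGRIP1_mis = codingRow("RPGRIP1", gpos("RPGRIP1", 2114L), "A", "C",
                                NA_real_, "missense", "c.2114A>C", TRUE),
        CNGB3_del  = codingRow("CNGB3", delPos,
                               paste0(base("CNGB3", delPos),
                                      base("CNGB3", delPos + 1L)),
                               base("CNGB3", delPos),
                               1e-3, "frameshift", "c.1148delC", FALSE),
        PCDH15_mis = codingRow("PCDH15", gpos("PCDH15", 1163L), "G", "T",
                               NA_real_, "missense", "c.1163G>T", TRUE))

    probands <- list(
        DGB288  = rbind(coding$ADGRV1_dup, splice$ADGRV1),
        DGB289  = rbind(coding$USH2A_mis, splice$USH2A),
        MEP105  = rbind(coding$PCDH15_mis, splice$PCDH15),
        MEP129  = rbind(coding$CNGB3_del, splice$CNGB3),
        MEP130  = rbind(coding$CNGB3_del, splice$CNGB3),
        MEP337  = rbind(coding$USH2A_non, splice$USH2A),
        MEP344  = splice$OPA1,
        NEI4320 = rbind(coding$RPGRIP1_mis, splice$RPGRIP1))
    contigLengths <- stats::setNames(Biostrings::width(genome),
                                     names(genome))
    manifest <- data.frame(proband = names(probands),
                           vcf = file.path(dir,
                                           paste0(names(probands), ".vcf")),
                           stringsAsFactors = FALSE)
    for (i in seq_along(probands))
        writeProbandVcf(manifest$vcf[i], manifest$proband[i],
                        probands[[i]], contigLengths)
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    caseRow <- function(patient, gene, cdna, type, novel)
        data.frame(patient = patient, gene = gene, cdna = cdna,
                   zygosity = "heterozygous", type = type, novel = novel,
                   stringsAsFactors = FALSE)
    cases <- rbind(
        caseRow("DGB288", "ADGRV1", "c.5965dupA", "frameshift", FALSE),
        caseRow("DGB288", "ADGRV1", "c.14661+717A>G", "splicing", TRUE),
        caseRow("DGB289", "USH2A", "c.10073C>T", "missense", FALSE),
        caseRow("DGB289", "USH2A", "c.8682-654C>G", "splicing", TRUE),
        caseRow("MEP337", "USH2A", "c.11864G>A", "nonsense", FALSE),
        caseRow("MEP337", "USH2A", "c.8682-654C>G", "splicing", TRUE),
        caseRow("MEP344", "OPA1", "c.1608+622A>G", "splicing", TRUE),
        caseRow("NEI4320", "RPGRIP1", "c.2114A>C", "missense", TRUE),
        caseRow("NEI4320", "RPGRIP1", "c.2367+82A>G", "splicing", TRUE),
        caseRow("MEP129", "CNGB3", "c.1148delC", "frameshift", FALSE),
        caseRow("MEP129", "CNGB3", "c.1663-1205G>A", "splicing", FALSE),
        caseRow("MEP130", "CNGB3", "c.1148delC", "frameshift", FALSE),
        caseRow("MEP130", "CNGB3", "c.1663-1205G>A", "splicing", FALSE),
        caseRow("MEP105", "PCDH15", "c.1163G>T", "missense", TRUE),
        caseRow("MEP105", "PCDH15", "c.3998+3,023 T>G", "splicing", TRUE))
    utils::write.table(cases, file.path(dir, "cases.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    list(genome = genome, models = models, panel = panel,
         manifest = manifest, cases = cases,
         paths = c(paths, manifest = file.path(dir, "manifest.tsv"),
                   cases = file.path(dir, "cases.tsv")),
         expected = list(nDistinctSplice = 6L, nSolvedProbands = 8L,
                         nNovel = 5L))
}
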