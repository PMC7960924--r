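STOP_CODONS <- c("TAA", "TAG", "TGA")

allCodons <- function() {
    b <- c("A", "C", "G", "T")
    as.vector(outer(outer(b, b, paste0), b, paste0))
}

nonStopCodons <- function() setdiff(allCodons(), STOP_CODONS)

randBases <- function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

randNonStopCodons <- function(n)
    paste(sample(nonStopCodons(), n, replace = TRUE), collapse = "")

## ATG-initiated CDS of len bases (len %% 3 == 0) ending in a stop, with no
## internal in-frame stop.
makeCds <- function(len) {
    stopifnot(len %% 3L == 0L, len >= 9L)
    paste0("ATG", randNonStopCodons(len %/% 3L - 2L), "TAA")
}

## Canonical intron: GT ... AG.
makeIntron <- function(len) {
    stopifnot(len >= 4L)
    paste0("GT", if (len > 4L) randBases(len - 4L) else "", "AG")
}

## Assemble a single-transcript gene from exon/intron pieces laid out in
## transcript sense; returns the contig sequence (reference strand) and the
## TranscriptModel. For a minus-strand gene the sense layout is
## reverse-complemented onto the contig and exon coordinates mirrored.
assembleGene <- function(geneSymbol, transcriptId, contig, exonSeqs,
                         intronSeqs, strand = "+", pad = 0L) {
    stopifnot(length(intronSeqs) == length(exonSeqs) - 1L)
    pieces <- character(0)
    for (i in seq_along(exonSeqs)) {
        pieces <- c(pieces, exonSeqs[i])
        if (i < length(exonSeqs)) pieces <- c(pieces, intronSeqs[i])
    }
    if (pad > 0L)                       # intergenic padding on both sides
        pieces <- c(randBases(pad), pieces, randBases(pad))
    senseSeq <- paste(pieces, collapse = "")
    lens <- nchar(pieces)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    first <- if (pad > 0L) 2L else 1L
    exIdx <- seq(first, by = 2L, length.out = length(exonSeqs))
    exons <- IRanges::IRanges(starts[exIdx], ends[exIdx])
    L <- nchar(senseSeq)
    if (strand == "-") {
        contigSeq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(senseSeq)))
        exons <- IRanges::IRanges(L - IRanges::end(exons) + 1L,
                                  L - IRanges::start(exons) + 1L)
        exons <- BiocGenerics::sort(exons)
    } else {
        contigSeq <- senseSeq
    }
    tx <- transcriptModel(transcriptId, geneSymbol, contig, strand, exons,
                          cdsStart = min(IRanges::start(exons)),
                          cdsEnd = max(IRanges::end(exons)))
    list(seq = contigSeq, tx = tx)
}

#' Specification of a synthetic cohort
#'
#' Bundles the knobs of the synthetic test world: gene-model geometry,
#' the planted proband configurations, per-proband decoy counts and the
#' seed that fixes every random draw.
#'
#' @param nGenes number of genes (each on its own contig).
#' @param exonsPerGene exons per gene.
#' @param intronRange integer range (min, max) of intron lengths; the
#'   minimum must be at least 200 so deep-intronic variants fit.
#' @param probandConfigs character vector, one proband per element, each of
#'   "AD_single", "AR_splice_plus_coding", "AR_hom_splice", "XL_hemi" or
#'   "unsolved".
#' @param decoys named integer vector with elements \code{common},
#'   \code{low_score} and \code{near_junction}: decoy variants planted per
#'   proband.
#' @param seed integer seed fixing every downstream draw.
#' @return A list of class "cohortSpec".
#' @export
cohortSpec <- function(nGenes = 6L, exonsPerGene = 3L,
                       intronRange = c(400L, 1200L),
                       probandConfigs = c("AD_single",
                                          "AR_splice_plus_coding",
                                          "AR_hom_splice", "XL_hemi",
                                          "unsolved"),
                       decoys = c(common = 1L, low_score = 1L,
                                  near_junction = 1L),
                       seed = 1L) {
    stopifnot(nGenes >= 3L, exonsPerGene >= 2L,
              intronRange[1L] >= 200L, intronRange[1L] <= intronRange[2L],
              all(probandConfigs %in% c("AD_single", "AR_splice_plus_coding",
                                        "AR_hom_splice", "XL_hemi",
                                        "unsolved")),
              all(decoys >= 0L))
    structure(list(nGenes = as.integer(nGenes),
                   exonsPerGene = as.integer(exonsPerGene),
                   intronRange = as.integer(intronRange),
                   probandConfigs = probandConfigs,
                   decoys = decoys, seed = as.integer(seed)),
              class = "cohortSpec")
}

#' Simulate a toy genome, gene models and panel
#'
#' Builds one gene per contig: an ATG-initiated CDS split across exons with
#' canonical GT...AG introns, both strands represented, CDS free of
#' internal in-frame stops and terminated by a stop codon. Inheritance
#' modes cycle AR, AD, XL across genes so every planted configuration can
#' find a matching gene. Deterministic under the spec's seed.
#'
#' @param spec a [cohortSpec()].
#' @return A list with \code{genome} (named
#'   \link[Biostrings]{DNAStringSet}), \code{models} (named list of
#'   \linkS4class{TranscriptModel}) and \code{panel} (data.frame).
#' @export
simulateGenomeAndModels <- function(spec) {
    set.seed(spec$seed)
    genome <- character(0)
    models <- list()
    inh <- rep(c("AR", "AD", "XL"), length.out = spec$nGenes)
    panel <- data.frame(gene = character(), inheritance = character(),
                        transcript_id = character(),
                        stringsAsFactors = FALSE)
    for (i in seq_len(spec$nGenes)) {
        gene <- sprintf("GENE%d", i)
        txid <- sprintf("TX%d", i)
        contig <- sprintf("chrS%d", i)
        strand <- if (i %% 2L == 0L) "-" else "+"
        nEx <- spec$exonsPerGene
        exonLens <- sample(seq(90L, 180L, by = 3L), nEx, replace = TRUE)
        total <- sum(exonLens)
        exonLens[nEx] <- exonLens[nEx] + (3L - total %% 3L) %% 3L
        intronLens <- sample(seq(spec$intronRange[1L], spec$intronRange[2L]),
                             nEx - 1L, replace = TRUE)
        cds <- makeCds(sum(exonLens))
        cuts <- cumsum(exonLens)
        exonSeqs <- substring(cds, c(1L, cuts[-nEx] + 1L), cuts)
        intronSeqs <- vapply(intronLens, makeIntron, character(1))
        g <- assembleGene(gene, txid, contig, exonSeqs, intronSeqs, strand,
                          pad = 300L)
        genome[contig] <- g$seq
        models[[txid]] <- g$tx
        panel <- rbind(panel, data.frame(gene = gene, inheritance = inh[i],
                                         transcript_id = txid,
                                         stringsAsFactors = FALSE))
    }
    list(genome = Biostrings::DNAStringSet(genome), models = models,
         panel = panel)
}

#' Write a simulated world to disk
#'
#' Writes \code{genome.fa}, \code{models.gff3} and \code{panel.tsv} so the
#' file-based readers and the end-to-end pipeline can run on a simulated
#' cohort.
#'
#' @param world result of [simulateGenomeAndModels()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
writeWorld <- function(world, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(world$genome, fa)
    gff <- file.path(dir, "models.gff3")
    rows <- list()
    for (tx in world$models) {
        ex <- exonRanges(tx)
        n <- length(ex)
        gr <- GenomicRanges::GRanges(
            seqnames = rep(txContig(tx), 2L * n),
            ranges = IRanges::IRanges(rep(IRanges::start(ex), 2L),
                                      rep(IRanges::end(ex), 2L)),
            strand = txStrand(tx))
        S4Vectors::mcols(gr)$type <- rep(c("exon", "CDS"), each = n)
        S4Vectors::mcols(gr)$Parent <- rep(txId(tx), 2L * n)
        S4Vectors::mcols(gr)$gene_name <- rep(geneSymbol(tx), 2L * n)
        ## GFF3 phase of each CDS piece, in transcript order
        w <- IRanges::width(ex)
        ord <- if (txStrand(tx) == "+") seq_len(n) else rev(seq_len(n))
        cumBefore <- c(0L, cumsum(w[ord])[-n])
        phase <- integer(n)
        phase[ord] <- (3L - cumBefore %% 3L) %% 3L
        S4Vectors::mcols(gr)$phase <- c(rep(NA_integer_, n), phase)
        rows[[length(rows) + 1L]] <- gr
    }
    all <- suppressWarnings(do.call(c, rows))
    rtracklayer::export(all, gff, format = "gff3")
    panel <- file.path(dir, "panel.tsv")
    utils::write.table(world$panel, panel, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(genome = fa, models = gff, panel = panel))
}

## Render one SpliceAI INFO group.
spliceaiGroup <- function(alt, gene, dsAG = 0, dsAL = 0, dsDG = 0, dsDL = 0,
                          dpAG = 0L, dpAL = 0L, dpDG = 0L, dpDL = 0L) {
    sprintf("%s|%s|%.2f|%.2f|%.2f|%.2f|%d|%d|%d|%d",
            alt, gene, dsAG, dsAL, dsDG, dsDL,
            as.integer(dpAG), as.integer(dpAL), as.integer(dpDG),
            as.integer(dpDL))
}

## Write a single-sample VCF from a data.frame of rows with columns
## contig, pos, ref, alt, gt and optional af, spliceai, gene, coding, cdna,
## novel (logical).
writeProbandVcf <- function(path, probandId, rows, contigLengths) {
    hdr <- c(
        "##fileformat=VCFv4.2",
        sprintf("##contig=<ID=%s,length=%d>", names(contigLengths),
                as.integer(contigLengths)),
        "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
        "##INFO=<ID=SpliceAI,Number=.,Type=String,Description=\"SpliceAI annotation: ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL\">",
        "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Annotated gene symbol\">",
        "##INFO=<ID=CODING,Number=1,Type=String,Description=\"Coding consequence class\">",
        "##INFO=<ID=CDNA,Number=1,Type=String,Description=\"HGVS c. label\">",
        "##INFO=<ID=NOVEL,Number=0,Type=Flag,Description=\"Absent from population databases\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
               probandId))
    rows <- rows[order(rows$contig, rows$pos), , drop = FALSE]
    lines <- vapply(seq_len(nrow(rows)), function(i) {
        r <- rows[i, ]
        info <- character(0)
        if (!is.null(r$af) && !is.na(r$af))
            info <- c(info, sprintf("AF=%g", r$af))
        if (!is.null(r$spliceai) && !is.na(r$spliceai) && nzchar(r$spliceai))
            info <- c(info, paste0("SpliceAI=", r$spliceai))
        if (!is.null(r$gene) && !is.na(r$gene) && nzchar(r$gene))
            info <- c(info, paste0("GENE=", r$gene))
        if (!is.null(r$coding) && !is.na(r$coding) && r$coding != "none")
            info <- c(info, paste0("CODING=", r$coding))
        if (!is.null(r$cdna) && !is.na(r$cdna) && nzchar(r$cdna))
            info <- c(info, paste0("CDNA=", gsub("[ ,]", "", r$cdna)))
        if (!is.null(r$novel) && !is.na(r$novel) && r$novel)
            info <- c(info, "NOVEL")
        if (!length(info)) info <- "."
        sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT\t%s",
                r$contig, as.integer(r$pos), r$ref, r$alt,
                paste(info, collapse = ";"), r$gt)
    }, character(1))
    writeLines(c(hdr, lines), path)
    invisible(path)
}

refBaseAt <- function(genome, contig, pos)
    substr(as.character(genome[[contig]]), pos, pos)

otherBase <- function(b) {
    pool <- setdiff(c("A", "C", "G", "T"), b)
    pool[1L]
}

#' Plant causal and decoy variants into a simulated cohort
#'
#' For every proband configuration in the spec, plants the corresponding
#' causal alleles (deep-intronic splice variants with SpliceAI scores above
#' cutoff and delta positions consistent with the intended event, plus rare
#' coding second alleles where the configuration requires one) and the
#' requested decoys: common variants (AF above the frequency threshold),
#' low-score splice variants, and near-junction variants within 10 bases of
#' an exon. Writes one VCF per proband and a truth table.
#'
#' @param spec a [cohortSpec()].
#' @param world result of [simulateGenomeAndModels()] on the same spec.
#' @param dir output directory for the per-proband VCFs.
#' @return A list with \code{manifest} (data.frame proband/vcf),
#'   \code{truth} (data.frame: proband, gene, key, role, intended_status,
#'   event_kind, inserted_length) and \code{vcfDir}.
#' @export
plantCohort <- function(spec, world, dir) {
    set.seed(spec$seed + 1L)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    genome <- world$genome
    panel <- world$panel
    models <- world$models
    contigLengths <- stats::setNames(Biostrings::width(genome),
                                     names(genome))
    txByGene <- stats::setNames(
        lapply(panel$transcript_id, function(id) models[[id]]), panel$gene)
    genesByMode <- split(panel$gene, panel$inheritance)
    modeCounter <- c(AD = 0L, AR = 0L, XL = 0L)
    pickGene <- function(mode) {
        pool <- genesByMode[[mode]]
        if (is.null(pool) || !length(pool))
            stop("no ", mode, " gene in the panel for the requested config")
        modeCounter[mode] <<- modeCounter[mode] + 1L
        pool[(modeCounter[mode] - 1L) %% length(pool) + 1L]
    }
    ## deep-intronic pseudo-exon splice variant in intron 1 (genomic order)
    plantSplice <- function(tx, gt) {
        intr <- intronRanges(tx)
        iv <- intr[1L]
        len <- IRanges::width(iv)
        insLen <- sample(21L:90L, 1L)
        ## keep the whole insert > 10 bases clear of both junctions
        loOff <- 30L
        hiOff <- len - 30L - insLen
        off <- sample(loOff:hiOff, 1L)
        gA <- IRanges::start(iv) + off           # genomic-left site
        gB <- gA + insLen - 1L
        plus <- txStrand(tx) == "+"
        pos <- if (plus) gA else gB              # variant at the acceptor
        dpAG <- 0L
        dpDG <- if (plus) insLen - 1L else -(insLen - 1L)
        ref <- refBaseAt(genome, txContig(tx), pos)
        alt <- otherBase(ref)
        sai <- spliceaiGroup(alt, geneSymbol(tx),
                             dsAG = stats::runif(1, 0.5, 1),
                             dsDG = stats::runif(1, 0.5, 1),
                             dpAG = dpAG, dpDG = dpDG)
        list(row = data.frame(contig = txContig(tx), pos = pos, ref = ref,
                              alt = alt, af = NA_real_, spliceai = sai,
                              gene = geneSymbol(tx), coding = "none",
                              cdna = NA_character_, novel = TRUE, gt = gt,
                              stringsAsFactors = FALSE),
             insLen = insLen)
    }
    plantCoding <- function(tx, gt) {
        ## mid-exon-1 substitution annotated as a nonsense coding hit
        ex <- exonRanges(tx)
        i <- if (txStrand(tx) == "+") 1L else length(ex)
        pos <- IRanges::start(ex)[i] + IRanges::width(ex)[i] %/% 2L
        ref <- refBaseAt(genome, txContig(tx), pos)
        data.frame(contig = txContig(tx), pos = pos, ref = ref,
                   alt = otherBase(ref), af = 1e-4, spliceai = NA_character_,
                   gene = geneSymbol(tx), coding = "nonsense",
                   cdna = NA_character_, novel = FALSE, gt = gt,
                   stringsAsFactors = FALSE)
    }
    plantDecoys <- function(tx) {
        rows <- list()
        intr <- intronRanges(tx)
        iv <- intr[length(intr)]
        mk <- function(pos, af, sai) {
            ref <- refBaseAt(genome, txContig(tx), pos)
            data.frame(contig = txContig(tx), pos = pos, ref = ref,
                       alt = otherBase(ref), af = af, spliceai = sai,
                       gene = geneSymbol(tx), coding = "none",
                       cdna = NA_character_, novel = FALSE, gt = "0/1",
                       stringsAsFactors = FALSE)
        }
        mid <- IRanges::start(iv) + IRanges::width(iv) %/% 2L
        n <- spec$decoys
        if (n["common"] > 0L)
            for (k in seq_len(n["common"]))
                rows[[length(rows) + 1L]] <- mk(mid - k, af = 0.02,
                    sai = spliceaiGroup("A", geneSymbol(tx), dsAG = 0.9,
                                        dsDG = 0.9, dpDG = 30L))
        if (n["low_score"] > 0L)
            for (k in seq_len(n["low_score"]))
                rows[[length(rows) + 1L]] <- mk(mid + k, af = NA_real_,
                    sai = spliceaiGroup("A", geneSymbol(tx), dsAG = 0.2,
                                        dsDG = 0.3, dpDG = 30L))
        if (n["near_junction"] > 0L)
            for (k in seq_len(n["near_junction"]))
                rows[[length(rows) + 1L]] <- mk(IRanges::start(iv) + 4L + k,
                    af = NA_real_,
                    sai = spliceaiGroup("A", geneSymbol(tx), dsAG = 0.9,
                                        dsDG = 0.9, dpDG = 20L))
        rows
    }
    manifest <- data.frame(proband = character(), vcf = character(),
                           stringsAsFactors = FALSE)
    truth <- list()
    addTruth <- function(pid, gene, key, role, status, kind, insLen)
        truth[[length(truth) + 1L]] <<- data.frame(
            proband = pid, gene = gene, key = key, role = role,
            intended_status = status, event_kind = kind,
            inserted_length = insLen, stringsAsFactors = FALSE)
    vkey <- function(r) paste(r$contig, r$pos, r$ref, r$alt, sep = ":")
    for (p in seq_along(spec$probandConfigs)) {
        cfg <- spec$probandConfigs[p]
        pid <- sprintf("SIM%03d", p)
        rows <- list()
        if (cfg != "unsolved") {
            mode <- switch(cfg, AD_single = "AD", XL_hemi = "XL", "AR")
            gene <- pickGene(mode)
            tx <- txByGene[[gene]]
            gt <- switch(cfg, AR_hom_splice = "1/1", XL_hemi = "1", "0/1")
            sp <- plantSplice(tx, gt)
            rows[[length(rows) + 1L]] <- sp$row
            addTruth(pid, gene, vkey(sp$row), "causal_splice",
                     "solved_candidate", "pseudo_exon", sp$insLen)
            if (cfg == "AR_splice_plus_coding") {
                cd <- plantCoding(tx, "0/1")
                rows[[length(rows) + 1L]] <- cd
                addTruth(pid, gene, vkey(cd), "causal_coding",
                         "solved_candidate", NA_character_, NA_integer_)
            }
            decoyTx <- txByGene[[pickGene(mode)]]
        } else {
            decoyTx <- txByGene[[panel$gene[1L]]]
        }
        for (d in plantDecoys(decoyTx)) {
            rows[[length(rows) + 1L]] <- d
            addTruth(pid, geneSymbol(decoyTx), vkey(d), "decoy", "rejected",
                     NA_character_, NA_integer_)
        }
        df <- do.call(rbind, rows)
        path <- file.path(dir, paste0(pid, ".vcf"))
        writeProbandVcf(path, pid, df, contigLengths)
        manifest <- rbind(manifest, data.frame(proband = pid, vcf = path,
                                               stringsAsFactors = FALSE))
    }
    list(manifest = manifest, truth = do.call(rbind, truth), vcfDir = dir)
}
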