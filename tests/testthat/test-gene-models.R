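test_that("readFasta keys contigs by first header token and uppercases", {
    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">chrT toy contig", "acgt", "ACGT", ">b", "GGGG"), fa)
    g <- readFasta(fa)
    expect_identical(names(g), c("chrT", "b"))
    expect_identical(as.character(g[["chrT"]]), "ACGTACGT")
    expect_identical(as.character(g[["b"]]), "GGGG")

    dup <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
    expect_error(readFasta(dup), "duplicate")
    empty <- withr::local_tempfile(fileext = ".fa")
    writeLines(character(0), empty)
    expect_error(readFasta(empty))
})

test_that("GFF3 and GTF dialects yield the same transcript model", {
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "chrT\ttoy\texon\t11\t40\t.\t+\t.\tID=e2;Parent=tx1;gene_name=G1",
        "chrT\ttoy\texon\t51\t80\t.\t+\t.\tID=e1;Parent=tx1;gene_name=G1",
        "chrT\ttoy\tCDS\t11\t40\t.\t+\t0\tID=c1;Parent=tx1;gene_name=G1",
        "chrT\ttoy\tCDS\t51\t80\t.\t+\t0\tID=c2;Parent=tx1;gene_name=G1"),
        gff)
    gtf <- withr::local_tempfile(fileext = ".gtf")
    writeLines(c(
        paste0("chrT\ttoy\texon\t51\t80\t.\t+\t.\t",
               "gene_id \"G1\"; transcript_id \"tx1\"; gene_name \"G1\";"),
        paste0("chrT\ttoy\texon\t11\t40\t.\t+\t.\t",
               "gene_id \"G1\"; transcript_id \"tx1\"; gene_name \"G1\";"),
        paste0("chrT\ttoy\tCDS\t11\t40\t.\t+\t0\t",
               "gene_id \"G1\"; transcript_id \"tx1\"; gene_name \"G1\";"),
        paste0("chrT\ttoy\tCDS\t51\t80\t.\t+\t0\t",
               "gene_id \"G1\"; transcript_id \"tx1\"; gene_name \"G1\";")),
        gtf)
    a <- readGeneModels(gff)[["tx1"]]
    b <- readGeneModels(gtf)[["tx1"]]
    ## unordered exon rows come back as a sorted chain in both dialects
    expect_identical(IRanges::start(exonRanges(a)), c(11L, 51L))
    expect_identical(IRanges::end(exonRanges(a)), c(40L, 80L))
    expect_identical(exonRanges(a), exonRanges(b))
    expect_identical(geneSymbol(a), geneSymbol(b))
    expect_identical(cdsBounds(a), cdsBounds(b))
    expect_identical(length(intronRanges(a)), 1L)
})

test_that("overlapping exons and invalid models are rejected", {
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "chrT\ttoy\texon\t11\t40\t.\t+\t.\tParent=txbad",
        "chrT\ttoy\texon\t35\t80\t.\t+\t.\tParent=txbad"), gff)
    expect_error(readGeneModels(gff), "txbad")
    expect_error(transcriptModel("t", "g", "c", "+",
                                 IRanges::IRanges(c(1, 103), c(100, 200)),
                                 NA, NA),
                 "intron")
})

test_that("junctionDistance matches HGVS offsets and a brute-force scan", {
    set.seed(11)
    ## published-style case: offset +82 in a long intron is 82 bases deep
    tx <- transcriptModel("t", "G", "c", "+",
                          IRanges::IRanges(c(1L, 1102L), c(100L, 1300L)))
    expect_identical(junctionDistance(182L, tx),
                     list(distance = 82L, location = "intronic"))
    expect_identical(junctionDistance(50L, tx),
                     list(distance = 0L, location = "exonic"))
    expect_identical(junctionDistance(1400L, tx)$location, "outside")

    ## middle base of a 21-base intron is 11 deep from either side
    tx21 <- transcriptModel("t21", "G", "c", "+",
                            IRanges::IRanges(c(1L, 32L), c(10L, 60L)))
    expect_identical(junctionDistance(21L, tx21)$distance, 11L)

    ## exhaustive agreement with the brute-force oracle on random models
    for (rep in 1:5) {
        nEx <- sample(2:5, 1)
        wds <- sample(20:60, 2 * nEx - 1, TRUE)   # exon/intron widths
        bounds <- cumsum(wds)
        exStarts <- c(1L, bounds[seq(2, length(bounds) - 1, by = 2)] + 1L)
        exEnds <- bounds[seq(1, length(bounds), by = 2)]
        ex <- IRanges::IRanges(exStarts, exEnds)
        txr <- transcriptModel("r", "G", "c", "+", ex)
        for (pos in seq_len(max(IRanges::end(ex)) + 10L)) {
            got <- junctionDistance(pos, txr)
            want <- bruteJunctionDistance(pos, ex)
            expect_identical(got$location, want$location)
            expect_identical(as.integer(got$distance),
                             as.integer(want$distance))
        }
    }
})

test_that("junctionDistance is invariant under strand mirroring", {
    set.seed(12)
    w <- toyWorld(exonLens = c(60L, 60L, 60L), intronLens = c(300L, 500L))
    wm <- {
        set.seed(12)
        toyWorld(exonLens = c(60L, 60L, 60L), intronLens = c(300L, 500L),
                 strand = "-")
    }
    L <- length(w$genome[["chrT"]])
    span <- range(c(IRanges::start(exonRanges(w$tx)),
                    IRanges::end(exonRanges(w$tx))))
    for (pos in seq(span[1], span[2], by = 7L)) {
        a <- junctionDistance(pos, w$tx)
        b <- junctionDistance(L - pos + 1L, wm$tx)
        expect_identical(a, b)
    }
})

test_that("intron numbering follows transcript order", {
    w <- toyWorld(exonLens = c(60L, 60L, 60L), intronLens = c(300L, 500L),
                  strand = "-")
    intr <- intronRanges(w$tx)
    ## genomic-leftmost intron is the transcript-last one on minus strand
    expect_identical(intronNumber(w$tx, IRanges::start(intr)[1L] + 5L), 2L)
    expect_identical(intronNumber(w$tx, IRanges::start(intr)[2L] + 5L), 1L)
})
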