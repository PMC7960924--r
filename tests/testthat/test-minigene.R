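test_that("construct region covers exons, insert and symmetric flanks", {
    set.seed(71)
    ## test exon 100, intervening intron portion 400, cryptic exon 129:
    ## region length 100 + 400 + 129 + 2 x 150 = 929
    w <- toyWorld(exonLens = c(100L, 110L), intronLens = c(1500L))
    tx <- w$tx
    intr <- intronRanges(tx)[1L]
    accPos <- IRanges::end(exonRanges(tx))[1L] + 401L
    contig <- as.character(w$genome[["chrT"]])
    rec <- spliceAIRecord("G", "TOY", dsAG = 0.9, dsDG = 0.9,
                          dpAG = 0L, dpDG = 128L)
    v <- annotatedVariant("chrT", accPos,
                          substr(contig, accPos, accPos), "G",
                          gene = "TOY", spliceai = rec)
    ev <- inferSpliceEvent(v, tx = tx)
    mg <- designConstruct(tx, ev, w$genome, flank = 150)
    expect_identical(IRanges::width(mg@region), 929L)
    expect_identical(nchar(mg@insertSeq), 929L)
    expect_identical(IRanges::width(mg@crypticExon), 129L)

    ## flank 0: exactly the exon span
    mg0 <- designConstruct(tx, ev, w$genome, flank = 0)
    expect_identical(IRanges::width(mg0@region), 629L)
    expect_identical(IRanges::start(mg0@region),
                     IRanges::start(exonRanges(tx))[1L])
})

test_that("RT-PCR products are test exon + 2x92, aberrant band exceeds WT by the insert", {
    set.seed(72)
    w <- toyWorld(exonLens = c(100L, 110L), intronLens = c(1500L))
    tx <- w$tx
    mkEvent <- function(insLen) {
        accPos <- IRanges::end(exonRanges(tx))[1L] + 401L
        contig <- as.character(w$genome[["chrT"]])
        rec <- spliceAIRecord("G", "TOY", dsAG = 0.9, dsDG = 0.9,
                              dpAG = 0L, dpDG = insLen - 1L)
        v <- annotatedVariant("chrT", accPos,
                              substr(contig, accPos, accPos), "G",
                              gene = "TOY", spliceai = rec)
        inferSpliceEvent(v, tx = tx)
    }
    for (insLen in c(29L, 54L, 81L, 129L)) {
        ev <- mkEvent(insLen)
        mg <- designConstruct(tx, ev, w$genome)
        pred <- predictRtpcrProducts(mg, ev)
        expect_identical(wtProductSize(pred), 2L * 92L + 100L)
        ## partial splicing always possible: both bands listed
        expect_identical(sort(pred@variantSizes),
                         c(284L, 284L + insLen))
        expect_true(all(pred@variantSizes >= 2L * 92L))
        expect_silent(spliceConstructInSilico(mg, ev))
    }
})

test_that("mutagenesis edits apply in coordinate-descending order", {
    set.seed(73)
    w <- toyWorld(exonLens = c(100L, 110L), intronLens = c(800L))
    tx <- w$tx
    accPos <- IRanges::end(exonRanges(tx))[1L] + 301L
    contig <- as.character(w$genome[["chrT"]])
    rec <- spliceAIRecord("G", "TOY", dsAG = 0.9, dsDG = 0.9,
                          dpAG = 0L, dpDG = 28L)
    v <- annotatedVariant("chrT", accPos,
                          substr(contig, accPos, accPos), "G",
                          gene = "TOY", spliceai = rec)
    ev <- inferSpliceEvent(v, tx = tx)
    mg <- designConstruct(tx, ev, w$genome)
    p2 <- accPos + 5L
    v2 <- annotatedVariant("chrT", p2, substr(contig, p2, p2),
                           setdiff(c("A", "C", "G", "T"),
                                   substr(contig, p2, p2))[1L],
                           gene = "TOY")
    edited <- mutageniseConstruct(mg, list(v, v2))
    offs <- c(v@pos, v2@pos) - IRanges::start(mg@region) + 1L
    expect_identical(substr(edited@insertSeq, offs[1L], offs[1L]), v@alt)
    expect_identical(substr(edited@insertSeq, offs[2L], offs[2L]), v2@alt)
    expect_identical(nchar(edited@insertSeq), nchar(mg@insertSeq))
    vOut <- annotatedVariant("chrT", 1L, "A", "G", gene = "TOY")
    expect_error(mutageniseConstruct(mg, list(vOut)), "outside")
})
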