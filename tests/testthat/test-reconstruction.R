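## build a deep-intronic variant carrying a SpliceAI record describing an
## acceptor-gain/donor-gain pair spanning insLen bases
spliceVariant <- function(w, insLen, offset = 200L, ag = 0.9, dg = 0.9,
                          al = 0, dl = 0) {
    tx <- w$tx
    intr <- intronRanges(tx)[1L]
    plus <- txStrand(tx) == "+"
    pos <- if (plus) IRanges::start(intr) + offset
           else IRanges::end(intr) - offset
    contig <- as.character(w$genome[["chrT"]])
    ref <- substr(contig, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
    rec <- spliceAIRecord(alt, "TOY", dsAG = ag, dsAL = al, dsDG = dg,
                          dsDL = dl, dpAG = 0L,
                          dpDG = if (plus) insLen - 1L else -(insLen - 1L))
    annotatedVariant("chrT", pos, ref, alt, probandId = "P",
                     gene = "TOY", spliceai = rec)
}

test_that("event inference recovers pseudo-exons, elongation and none", {
    set.seed(51)
    w <- toyWorld(exonLens = c(99L, 120L), intronLens = c(1001L))
    ## 129-base acceptor/donor pair -> pseudo-exon of 129
    v <- spliceVariant(w, 129L)
    ev <- inferSpliceEvent(v, tx = w$tx)
    expect_identical(eventKind(ev), "pseudo_exon")
    expect_identical(insertedLength(ev), 129L)
    expect_identical(ev@gainedDonor - ev@gainedAcceptor + 1L, 129L)
    expect_equal(ev@minGainedScore, 0.9)
    expect_identical(ev@hostIntron, 1L)

    ## 29-base pair (acceptor at the variant, donor 28 downstream)
    ev29 <- inferSpliceEvent(spliceVariant(w, 29L), tx = w$tx)
    expect_identical(insertedLength(ev29), 29L)

    ## donor gain 81 bases past the canonical donor -> elongation of 81
    intr <- intronRanges(w$tx)[1L]
    pos <- IRanges::start(intr) + 81L
    contig <- as.character(w$genome[["chrT"]])
    ref <- substr(contig, pos, pos)
    rec <- spliceAIRecord("G", "TOY", dsDG = 0.9, dpDG = -1L)
    vEl <- annotatedVariant("chrT", pos, ref, "G", gene = "TOY",
                            spliceai = rec)
    evEl <- inferSpliceEvent(vEl, tx = w$tx)
    expect_identical(eventKind(evEl), "exon_elongation")
    expect_identical(insertedLength(evEl), 81L)

    ## all scores below cutoff -> none
    evNone <- inferSpliceEvent(spliceVariant(w, 50L, ag = 0.2, dg = 0.3),
                               tx = w$tx)
    expect_identical(eventKind(evNone), "none")

    ## acceptor 3' of donor cannot form an exon -> none with warning
    recBad <- spliceAIRecord("G", "TOY", dsAG = 0.9, dsDG = 0.9,
                             dpAG = 50L, dpDG = 0L)
    vBad <- annotatedVariant("chrT", pos, ref, "G", gene = "TOY",
                             spliceai = recBad)
    expect_warning(evBad <- inferSpliceEvent(vBad, tx = w$tx), "3'")
    expect_identical(eventKind(evBad), "none")

    ## acceptor gain + acceptor loss -> acceptor shift
    recShift <- spliceAIRecord("G", "TOY", dsAG = 0.9, dsAL = 0.8,
                               dpAG = 0L, dpAL = 100L)
    vSh <- spliceVariant(w, 29L)
    vSh@spliceai <- recShift
    evSh <- inferSpliceEvent(vSh, tx = w$tx)
    expect_identical(eventKind(evSh), "acceptor_shift")
})

test_that("applying an event conserves exonic length plus the insert", {
    set.seed(52)
    w <- toyWorld(exonLens = c(99L, 120L, 90L), intronLens = c(600L, 400L))
    wtLen <- sum(IRanges::width(exonRanges(w$tx)))
    ev <- inferSpliceEvent(spliceVariant(w, 63L), tx = w$tx)
    chain <- applyEvent(w$tx, ev)
    expect_length(chain, 4L)
    expect_identical(sum(IRanges::width(chain)), wtLen + 63L)
    ## removing the inserted interval restores the original chain
    restored <- chain[!(IRanges::start(chain) == ev@gainedAcceptor &
                        IRanges::end(chain) == ev@gainedDonor)]
    expect_identical(restored, exonRanges(w$tx))

    ## elongation keeps the exon count
    rec <- spliceAIRecord("G", "TOY", dsDG = 0.9, dpDG = 0L)
    intr <- intronRanges(w$tx)[1L]
    pos <- IRanges::start(intr) + 44L
    v <- annotatedVariant("chrT", pos,
                          substr(as.character(w$genome[["chrT"]]), pos, pos),
                          "G", gene = "TOY", spliceai = rec)
    evEl <- inferSpliceEvent(v, tx = w$tx)
    chainEl <- applyEvent(w$tx, evEl)
    expect_length(chainEl, 3L)
    expect_identical(sum(IRanges::width(chainEl)),
                     wtLen + insertedLength(evEl))
})

test_that("frame consequence equals length mod 3 for all lengths 1-300", {
    for (len in 1:300)
        expect_identical(frameConsequence(len),
                         if (len %% 3L == 0L) "in_frame" else "frameshift")
})

test_that("findPtc agrees with a brute-force codon scan on random inserts", {
    set.seed(53)
    for (i in 1:200) {
        nCodons <- sample(30:80, 1)
        e1 <- sample(seq(30L, 3L * nCodons - 30L, by = 1L), 1)
        insLen <- sample(10:60, 1)
        w <- toyWorld(exonLens = c(e1, 3L * nCodons - e1),
                      intronLens = c(max(200L, insLen + 100L)))
        v <- spliceVariant(w, insLen, offset = 20L)
        ev <- inferSpliceEvent(v, tx = w$tx)
        chain <- applyEvent(w$tx, ev)
        got <- findPtc(w$tx, chain, w$genome, variant = v)

        ## oracle: splice by hand, apply the substitution, scan codons
        contig <- as.character(w$genome[["chrT"]])
        substr(contig, v@pos, v@pos) <- v@alt
        mrna <- paste(substring(contig, IRanges::start(chain),
                                IRanges::end(chain)), collapse = "")
        stopIdx <- bruteFirstStop(mrna)
        wtStop <- nchar(w$cds) / 3L
        want <- if (!is.na(stopIdx) &&
                    3L * stopIdx < 3L * wtStop + insLen) stopIdx
                else NA_integer_
        expect_identical(got, want)
    }
})

test_that("NMD follows the 50-nt last-junction rule with a strict boundary", {
    chain <- IRanges::IRanges(c(1L, 1001L, 2001L), c(300L, 1300L, 2300L))
    ## junction at 600 in spliced coordinates; codon ending at 400 is 200 nt
    ## upstream
    expect_true(predictNmd(ptcCodon = 133L, chain, cdsStartCdna = 1L))
    ## PTC in the last exon
    expect_false(predictNmd(ptcCodon = 250L, chain, cdsStartCdna = 1L))
    ## exactly 50 nt upstream of the junction: strict > means no NMD
    expect_false(predictNmd(ptcCodon = 183L, chain, cdsStartCdna = 2L))
    expect_true(predictNmd(ptcCodon = 183L, chain, cdsStartCdna = 1L))
    ## a single-exon chain has no junction
    expect_false(predictNmd(10L, IRanges::IRanges(1L, 3000L)))
    expect_false(predictNmd(NA_integer_, chain))
})

test_that("events and consequences are invariant under strand mirroring", {
    for (seed in c(61L, 62L, 63L)) {
        set.seed(seed)
        wp <- toyWorld(exonLens = c(99L, 120L), intronLens = c(1001L))
        set.seed(seed)
        wm <- toyWorld(exonLens = c(99L, 120L), intronLens = c(1001L),
                       strand = "-")
        insLen <- sample(c(29L, 54L, 81L, 129L), 1)
        vp <- spliceVariant(wp, insLen)
        vm <- spliceVariant(wm, insLen)
        evp <- inferSpliceEvent(vp, tx = wp$tx)
        evm <- inferSpliceEvent(vm, tx = wm$tx)
        expect_identical(eventKind(evp), eventKind(evm))
        expect_identical(insertedLength(evp), insertedLength(evm))
        expect_identical(evp@hostIntron, evm@hostIntron)
        cp <- reconstructConsequence(vp, wp$tx, wp$genome, event = evp)
        cm <- reconstructConsequence(vm, wm$tx, wm$genome, event = evm)
        expect_identical(frameClass(cp), frameClass(cm))
        expect_identical(ptcCodon(cp), ptcCodon(cm))
        expect_identical(nmdPredicted(cp), nmdPredicted(cm))
        expect_identical(sum(IRanges::width(exonRanges(cp))),
                         sum(IRanges::width(exonRanges(cm))))
    }
})

test_that("consequence summaries carry the minimum gained-site score", {
    set.seed(54)
    w <- toyWorld()
    v <- spliceVariant(w, 30L, ag = 0.58, dg = 0.93)
    ev <- inferSpliceEvent(v, tx = w$tx)
    cons <- reconstructConsequence(v, w$tx, w$genome, event = ev)
    row <- summarizeConsequence(v, ev, cons)
    expect_equal(row$min_gained_score, 0.58)
    noneRow <- summarizeConsequence(
        v, inferSpliceEvent(spliceVariant(w, 30L, ag = 0.1, dg = 0.1),
                            tx = w$tx), NULL)
    expect_identical(noneRow$event, "none")
    expect_identical(noneRow$note, "no predicted effect")
})
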