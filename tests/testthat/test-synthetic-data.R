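test_that("simulated worlds are deterministic and splice-canonical", {
    spec <- cohortSpec(seed = 5L)
    w1 <- simulateGenomeAndModels(spec)
    w2 <- simulateGenomeAndModels(spec)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    p1 <- writeWorld(w1, d1); p2 <- writeWorld(w2, d2)
    for (f in names(p1))
        expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))

    ## every intron starts GT and ends AG on the transcript strand
    for (tx in w1$models) {
        contig <- as.character(w1$genome[[txContig(tx)]])
        intr <- intronRanges(tx)
        for (k in seq_along(intr)) {
            s <- substr(contig, IRanges::start(intr)[k],
                        IRanges::end(intr)[k])
            if (txStrand(tx) == "-")
                s <- as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(s)))
            expect_identical(substr(s, 1L, 2L), "GT")
            expect_identical(substr(s, nchar(s) - 1L, nchar(s)), "AG")
        }
    }
})

test_that("simulated CDS of both strands translates without internal stops", {
    spec <- cohortSpec(seed = 6L)
    w <- simulateGenomeAndModels(spec)
    strands <- vapply(w$models, txStrand, character(1))
    expect_setequal(unique(strands), c("+", "-"))
    for (tx in w$models) {
        contig <- as.character(w$genome[[txContig(tx)]])
        ex <- exonRanges(tx)
        mrna <- paste(substring(contig, IRanges::start(ex),
                                IRanges::end(ex)), collapse = "")
        if (txStrand(tx) == "-")
            mrna <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(mrna)))
        expect_identical(substr(mrna, 1L, 3L), "ATG")
        expect_identical(bruteFirstStop(mrna), nchar(mrna) %/% 3L)
    }
})

test_that("planted cohorts are recovered exactly, decoys rejected", {
    spec <- cohortSpec(seed = 9L)
    world <- simulateGenomeAndModels(spec)
    pl <- plantCohort(spec, world, withr::local_tempdir())
    pri <- prioritizeCohort(pl$manifest, world$panel, world$models)
    causal <- pl$truth[pl$truth$role == "causal_splice", ]
    expect_true(all(causal$key %in% pri$candidates$key))
    decoys <- pl$truth[pl$truth$role == "decoy", ]
    expect_identical(sum(decoys$key %in% pri$candidates$key), 0L)
    ## the unsolved proband stays unsolved
    solved <- vapply(pri$reports, function(r)
        any(vapply(r$genes, function(s)
            s$status == "solved_candidate", logical(1))), logical(1))
    cfgByPid <- setNames(spec$probandConfigs,
                         sprintf("SIM%03d", seq_along(spec$probandConfigs)))
    for (pid in names(solved))
        expect_identical(unname(solved[pid]),
                         cfgByPid[[pid]] != "unsolved")

    ## planted event reconstruction matches the truth record
    for (i in seq_len(nrow(causal))) {
        r <- causal[i, ]
        tx <- world$models[[
            world$panel$transcript_id[world$panel$gene == r$gene]]]
        vars <- readAnnotatedVcf(
            pl$manifest$vcf[pl$manifest$proband == r$proband], r$proband)
        v <- vars[vapply(vars, variantKey, character(1)) == r$key][[1L]]
        ev <- inferSpliceEvent(v, tx = tx)
        expect_identical(eventKind(ev), r$event_kind)
        expect_identical(insertedLength(ev), r$inserted_length)
        cons <- reconstructConsequence(v, tx, world$genome, event = ev)
        expect_identical(frameClass(cons),
                         frameConsequence(r$inserted_length))
    }
})

test_that("the worked-example cohort encodes the reported case series", {
    fx <- exampleCohort(withr::local_tempdir())
    expect_identical(nrow(fx$manifest), 8L)
    expect_identical(nrow(fx$panel), 6L)
    expect_identical(nrow(fx$cases), 15L)

    ## every case label parses; splice offsets all clear the 10-bp filter
    for (i in seq_len(nrow(fx$cases))) {
        p <- parseIntronicHgvs(fx$cases$cdna[i])
        if (fx$cases$type[i] == "splicing") {
            expect_identical(p$kind, "intronic")
            expect_gt(p$offset, 10L)
        }
    }

    ## the case series' single-variant proband sits on the dominant gene
    mep344 <- readAnnotatedVcf(
        fx$manifest$vcf[fx$manifest$proband == "MEP344"], "MEP344")
    expect_length(mep344, 1L)
    expect_identical(geneSymbol(mep344[[1L]]), "OPA1")
    expect_identical(fx$panel$inheritance[fx$panel$gene == "OPA1"], "AD")

    ## the two siblings share both alleles of the recessive gene
    k129 <- vapply(readAnnotatedVcf(
        fx$manifest$vcf[fx$manifest$proband == "MEP129"], "MEP129"),
        variantKey, character(1))
    k130 <- vapply(readAnnotatedVcf(
        fx$manifest$vcf[fx$manifest$proband == "MEP130"], "MEP130"),
        variantKey, character(1))
    expect_setequal(k129, k130)
    expect_length(k129, 2L)

    ## two runs produce byte-identical cohort files
    fx2 <- exampleCohort(withr::local_tempdir())
    for (p in fx$manifest$proband)
        expect_identical(
            readLines(fx$manifest$vcf[fx$manifest$proband == p]),
            readLines(fx2$manifest$vcf[fx2$manifest$proband == p]))
    expect_identical(readLines(fx$paths["genome"]),
                     readLines(fx2$paths["genome"]))
})
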