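mkVar <- function(pos = 500L, af = NA_real_, gene = "G1",
                  zygosity = "het", coding = "none", sai = NULL,
                  ref = "A", alt = "G", proband = "P1") {
    annotatedVariant("chrT", pos, ref, alt, probandId = proband,
                     gene = gene, zygosity = zygosity,
                     alleleFrequency = af, codingClass = coding,
                     spliceai = sai)
}

sai <- function(ag = 0, al = 0, dg = 0, dl = 0, dpag = 0, dpdg = 0)
    spliceAIRecord("G", "G1", dsAG = ag, dsAL = al, dsDG = dg, dsDL = dl,
                   dpAG = dpag, dpDG = dpdg)

test_that("frequency filter keeps rare and absent-AF variants", {
    vs <- list(mkVar(af = 0.004), mkVar(af = 0.006), mkVar(af = NA_real_),
               mkVar(af = 1.43e-5), mkVar(af = 0.005))
    out <- frequencyFilter(vs)
    expect_length(out, 3L)              # 0.004, absent, 1.43e-5
    rem <- attr(out, "removed")
    expect_identical(unique(rem$reason), "common")
    expect_identical(nrow(rem), 2L)     # 0.006 and the boundary 0.005
})

test_that("splice-score filter applies an inclusive 0.5 cutoff to max delta", {
    expect_equal(maxDelta(sai(ag = 0.8, dg = 0.7)), 0.8)
    vs <- list(mkVar(sai = sai(ag = 0.49)), mkVar(sai = sai(ag = 0.5)),
               mkVar(sai = NULL), mkVar(sai = sai(dl = 0.51)))
    out <- spliceScoreFilter(vs)
    expect_length(out, 2L)              # 0.5 passes, 0.51 passes
    expect_identical(unique(attr(out, "removed")$reason), "low_score")
})

test_that("panel restriction matches gene symbols case-sensitively", {
    panel <- data.frame(gene = "G1", inheritance = "AR",
                        transcript_id = "t1")
    vs <- list(mkVar(gene = "G1"), mkVar(gene = "g1"), mkVar(gene = "G2"))
    out <- panelRestrict(vs, panel)
    expect_length(out, 1L)
    expect_identical(geneSymbol(out[[1L]]), "G1")
})

test_that("deep-intronic filter excludes offsets 1-10 and exonic positions", {
    tx <- transcriptModel("t1", "G1", "chrT", "+",
                          IRanges::IRanges(c(1L, 1102L), c(100L, 1300L)))
    lookup <- list(G1 = tx)
    vs <- list(mkVar(pos = 182L),   # offset +82: kept
               mkVar(pos = 110L),   # offset +10: removed (strict >)
               mkVar(pos = 111L),   # offset +11: kept
               mkVar(pos = 448L),   # offset -654 analog deep: kept
               mkVar(pos = 50L))    # exonic: removed
    out <- deepIntronicFilter(vs, lookup)
    expect_identical(vapply(out, function(v) v@pos, integer(1)),
                     c(182L, 111L, 448L))
    expect_identical(unique(attr(out, "removed")$reason), "near_junction")
    expect_error(deepIntronicFilter(list(mkVar(gene = "GX")), lookup),
                 "no canonical transcript")
})

test_that("inheritance pairing follows gene mode and zygosity", {
    sv <- mkVar(sai = sai(ag = 0.9))
    svHom <- mkVar(sai = sai(ag = 0.9), zygosity = "hom")
    svHemi <- mkVar(sai = sai(ag = 0.9), zygosity = "hemi")
    cd <- mkVar(pos = 60L, coding = "frameshift", af = 1e-3)

    expect_identical(inheritancePairing(list(sv), list(), "AD")$status,
                     "solved_candidate")
    ar1 <- inheritancePairing(list(sv), list(), "AR")
    expect_identical(ar1$status, "needs_second_allele")
    ar2 <- inheritancePairing(list(sv), list(cd), "AR")
    expect_identical(ar2$status, "solved_candidate")
    expect_length(ar2$paired, 2L)
    expect_true(ar2$phaseUnconfirmed)
    expect_identical(inheritancePairing(list(svHom), list(), "AR")$status,
                     "solved_candidate")
    sv2 <- mkVar(pos = 700L, sai = sai(dg = 0.8))
    expect_identical(inheritancePairing(list(sv, sv2), list(),
                                        "AR")$status, "solved_candidate")
    expect_identical(inheritancePairing(list(svHemi), list(), "XL")$status,
                     "solved_candidate")
    expect_identical(inheritancePairing(list(sv), list(), "XL")$status,
                     "needs_second_allele")
    expect_error(inheritancePairing(list(sv), list(), "AQ"), "unknown")
    expect_identical(inheritancePairing(list(), list(cd), "AR")$status,
                     "rejected")
})

test_that("relaxing thresholds never shrinks the candidate set", {
    for (seed in c(101L, 202L)) {
        spec <- cohortSpec(seed = seed)
        world <- simulateGenomeAndModels(spec)
        pl <- plantCohort(spec, world, withr::local_tempdir())
        strict <- prioritizeCohort(pl$manifest, world$panel, world$models,
                                   afMax = 0.005, scoreCutoff = 0.5)
        looseScore <- prioritizeCohort(pl$manifest, world$panel,
                                       world$models, afMax = 0.005,
                                       scoreCutoff = 0.3)
        looseAf <- prioritizeCohort(pl$manifest, world$panel, world$models,
                                    afMax = 0.05, scoreCutoff = 0.5)
        expect_true(all(strict$candidates$key %in%
                        looseScore$candidates$key))
        expect_true(all(strict$candidates$key %in% looseAf$candidates$key))
    }
})

test_that("pure filters commute on the final candidate set", {
    set.seed(41)
    panel <- data.frame(gene = "G1", inheritance = "AR",
                        transcript_id = "t1")
    vs <- lapply(1:30, function(i)
        mkVar(pos = sample(200:900, 1) + i,
              af = sample(c(NA, 1e-4, 0.02), 1),
              gene = sample(c("G1", "GX"), 1),
              sai = sai(ag = runif(1))))
    f <- list(function(x) frequencyFilter(x),
              function(x) spliceScoreFilter(x),
              function(x) panelRestrict(x, panel))
    keysOf <- function(vars) sort(vapply(vars, variantKey, character(1)))
    ref <- keysOf(f[[3]](f[[2]](f[[1]](vs))))
    for (perm in list(c(1, 3, 2), c(2, 1, 3), c(3, 2, 1))) {
        got <- keysOf(f[[perm[3]]](f[[perm[2]]](f[[perm[1]]](vs))))
        expect_identical(got, ref)
    }
})
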