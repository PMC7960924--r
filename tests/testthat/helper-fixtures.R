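## Shared builders and independent oracles for the test suite. The oracles
## deliberately avoid the package's own coordinate and translation code:
## brute-force scans and plain character loops only.

STOPS <- c("TAA", "TAG", "TGA")

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

## random codon string with no stop codon, plain implementation
randOpenCodons <- function(n) {
    out <- character(n)
    for (i in seq_len(n)) {
        repeat {
            c3 <- randSeq(3)
            if (!c3 %in% STOPS) break
        }
        out[i] <- c3
    }
    paste(out, collapse = "")
}

## Simple two/three-exon plus-strand transcript with its contig sequence.
## Exons carry an ATG-initiated open CDS ending in TAA.
toyWorld <- function(exonLens = c(99L, 120L), intronLens = c(1001L),
                     pad = 200L, strand = "+") {
    total <- sum(exonLens)
    stopifnot(total %% 3L == 0L)
    cds <- paste0("ATG", randOpenCodons(total / 3L - 2L), "TAA")
    cuts <- cumsum(exonLens)
    exonSeqs <- substring(cds, c(1L, cuts[-length(cuts)] + 1L), cuts)
    intronSeqs <- vapply(intronLens, function(n)
        paste0("GT", randSeq(n - 4L), "AG"), character(1))
    g <- crypticSplice:::assembleGene("TOY", "TXTOY", "chrT", exonSeqs,
                                      intronSeqs, strand, pad = pad)
    genome <- Biostrings::DNAStringSet(setNames(g$seq, "chrT"))
    list(genome = genome, tx = g$tx, cds = cds)
}

## Brute-force junction distance: min |pos - e| over every exonic base e,
## computed by scanning, plus the exonic / outside classification.
bruteJunctionDistance <- function(pos, exons) {
    exonic <- unlist(lapply(seq_along(exons), function(i)
        seq(IRanges::start(exons)[i], IRanges::end(exons)[i])))
    lo <- min(exonic); hi <- max(exonic)
    if (pos >= lo && pos <= hi && pos %in% exonic)
        return(list(distance = 0L, location = "exonic"))
    d <- min(abs(pos - exonic))
    if (pos < lo || pos > hi)
        list(distance = min(abs(pos - lo), abs(pos - hi)),
             location = "outside")
    else list(distance = d, location = "intronic")
}

## Independent codon scanner: index of the first stop codon in a cDNA
## string read from position 1, or NA.
bruteFirstStop <- function(cdna) {
    n <- nchar(cdna) %/% 3L
    for (i in seq_len(n)) {
        if (substr(cdna, 3L * i - 2L, 3L * i) %in% STOPS) return(i)
    }
    NA_integer_
}

## Minimal single-sample VCF writer used by variant-io tests (independent
## of the package's own writer).
writeTinyVcf <- function(path, lines, sample = "S1",
                         contig = "chrT", len = 10000L) {
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", contig, len),
             "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
             "##INFO=<ID=SpliceAI,Number=.,Type=String,Description=\"sai\">",
             "##INFO=<ID=GENE,Number=1,Type=String,Description=\"gene\">",
             "##INFO=<ID=CODING,Number=1,Type=String,Description=\"class\">",
             "##INFO=<ID=NOVEL,Number=0,Type=Flag,Description=\"novel\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
             paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                    sample))
    writeLines(c(hdr, lines), path)
    path
}
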