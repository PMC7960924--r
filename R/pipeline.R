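#' Assemble a pipeline configuration
#'
#' Collects the thresholds of the prioritization cascade and the
#' reconstruction/minigene design parameters, with the defaults used
#' throughout the package: variants rarer than 0.5\% population frequency,
#' SpliceAI max-delta at least 0.5, junction distance strictly greater than
#' 10 bases, a 50-nt NMD last-junction boundary, 150-base minigene flanks
#' and 92 bases of vector exon on each side of an RT-PCR product.
#'
#' @param fasta,gff,panel,manifest input paths (reference FASTA, transcript
#'   models, gene panel TSV, proband manifest TSV with columns
#'   proband/vcf).
#' @param afMax,scoreCutoff,minJunctionDistance,nmdBoundary,flank,vectorExonBp
#'   numeric thresholds; see Details above for defaults and meaning.
#' @param afKey INFO key holding the population allele frequency.
#' @param outDir directory the pipeline writes its outputs into.
#' @return A list of class "pipelineConfig".
#' @export
pipelineConfig <- function(fasta = NULL, gff = NULL, panel = NULL,
                           manifest = NULL, afMax = 0.005,
                           scoreCutoff = 0.5, minJunctionDistance = 10,
                           nmdBoundary = 50, flank = 150, vectorExonBp = 92,
                           afKey = "AF", outDir = ".") {
    structure(list(fasta = fasta, gff = gff, panel = panel,
                   manifest = manifest, afMax = afMax,
                   scoreCutoff = scoreCutoff,
                   minJunctionDistance = minJunctionDistance,
                   nmdBoundary = nmdBoundary, flank = flank,
                   vectorExonBp = vectorExonBp, afKey = afKey,
                   outDir = outDir),
              class = "pipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipelineConfig()]; unknown keys are warned about and dropped.
#' @return A "pipelineConfig" list.
#' @export
readPipelineConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    known <- names(formals(pipelineConfig))
    unknown <- setdiff(names(raw), known)
    if (length(unknown))
        warning("unknown configuration keys ignored: ",
                paste(unknown, collapse = ", "))
    do.call(pipelineConfig, raw[intersect(names(raw), known)])
}

#' Validate a pipeline configuration
#'
#' @param config a "pipelineConfig" list.
#' @return A list with \code{errors} and \code{warnings} (character
#'   vectors); errors block a run.
#' @export
validateConfig <- function(config) {
    errors <- character(); warnings <- character()
    inRange <- function(x, lo, hi) is.numeric(x) && !is.na(x) &&
        x >= lo && x <= hi
    if (!inRange(config$afMax, 0, 1))
        errors <- c(errors, "afMax must lie in [0, 1]")
    if (!inRange(config$scoreCutoff, 0, 1))
        errors <- c(errors, "scoreCutoff must lie in [0, 1]")
    else if (config$scoreCutoff == 0)
        warnings <- c(warnings,
                      "scoreCutoff of 0 lets every annotated variant pass")
    if (!inRange(config$minJunctionDistance, 0, Inf))
        errors <- c(errors, "minJunctionDistance must be >= 0")
    if (!inRange(config$nmdBoundary, 0, Inf))
        errors <- c(errors, "nmdBoundary must be >= 0")
    if (!inRange(config$flank, 0, Inf))
        errors <- c(errors, "flank must be >= 0")
    if (!inRange(config$vectorExonBp, 0, Inf))
        errors <- c(errors, "vectorExonBp must be >= 0")
    list(errors = errors, warnings = warnings)
}

#' Run the full candidate pipeline
#'
#' End-to-end orchestration: load the reference and models, prioritize the
#' cohort, reconstruct the predicted transcript consequence of every
#' candidate splice variant, design its minigene construct, and write the
#' candidate TSV, consequence TSV, construct FASTA plus predicted product
#' sizes, and a summary JSON. One log line per filter stage reports the
#' in/out counts of the cascade. All outputs are deterministic for fixed
#' inputs; partial outputs are removed if any stage fails.
#'
#' @param config a "pipelineConfig" list (see [pipelineConfig()]).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with \code{summary}, \code{candidates},
#'   \code{consequences} (data.frames) and the written \code{paths}.
#' @export
runPipeline <- function(config, quiet = FALSE) {
    chk <- validateConfig(config)
    for (w in chk$warnings) warning(w, call. = FALSE)
    if (length(chk$errors))
        stop("invalid configuration: ", paste(chk$errors, collapse = "; "))
    say <- function(...) if (!quiet) message(sprintf(...))
    outDir <- config$outDir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(candidates = file.path(outDir, "candidates.tsv"),
               consequences = file.path(outDir, "consequences.tsv"),
               constructs = file.path(outDir, "constructs.fa"),
               products = file.path(outDir, "products.tsv"),
               summary = file.path(outDir, "summary.json"))
    cleanup <- function() unlink(paths[file.exists(paths)])
    runStage <- function(stage, expr) {
        tryCatch(expr, error = function(e) {
            cleanup()
            stop("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e), call. = FALSE)
        })
    }
    genome <- runStage("load_reference", readFasta(config$fasta))
    models <- runStage("load_models",
                       readGeneModels(config$gff, genome = genome))
    panel <- runStage("load_panel", readGenePanel(config$panel))
    manifest <- runStage("load_manifest",
        utils::read.delim(config$manifest, stringsAsFactors = FALSE))
    pri <- runStage("prioritize", prioritizeCohort(
        manifest, panel, models, afMax = config$afMax,
        scoreCutoff = config$scoreCutoff,
        minJunctionDistance = config$minJunctionDistance,
        afKey = config$afKey))
    f <- pri$funnel
    say("variants in: %d", f["input"])
    say("  pass frequency (< %g): %d", config$afMax, f["rare"])
    say("  pass splice score (>= %g): %d", config$scoreCutoff,
        f["high_score"])
    say("  in panel: %d", f["in_panel"])
    say("  deep intronic (> %g bp): %d", config$minJunctionDistance,
        f["deep_intronic"])
    say("solved probands: %d", f["solved"])
    runStage("write_candidates",
             writeCandidateTsv(pri$candidates, paths["candidates"]))

    txByGene <- stats::setNames(
        lapply(panel$transcript_id, function(id) models[[id]]), panel$gene)
    cand <- pri$candidates
    spl <- cand[cand$type == "splicing", , drop = FALSE]
    spl <- spl[!duplicated(spl$key), , drop = FALSE]
    spl <- spl[order(spl$contig, spl$pos), , drop = FALSE]
    consequences <- list()
    constructs <- character(0)
    products <- list()
    runStage("reconstruct", for (i in seq_len(nrow(spl))) {
        r <- spl[i, ]
        tx <- txByGene[[r$gene]]
        vars <- readAnnotatedVcf(
            manifest$vcf[match(r$proband, manifest$proband)],
            probandId = r$proband, afKey = config$afKey)
        v <- vars[vapply(vars, variantKey, character(1)) == r$key][[1L]]
        ev <- inferSpliceEvent(v, tx = tx, cutoff = config$scoreCutoff)
        cons <- reconstructConsequence(v, tx, genome, event = ev,
                                       cutoff = config$scoreCutoff,
                                       nmdBoundary = config$nmdBoundary)
        row <- summarizeConsequence(v, ev, cons)
        row$cdna <- r$cdna
        consequences[[length(consequences) + 1L]] <- row
        if (eventKind(ev) != "none") {
            mg <- designConstruct(tx, ev, genome, flank = config$flank,
                                  vectorExonBp = config$vectorExonBp)
            pred <- predictRtpcrProducts(mg, ev)
            constructs[sprintf("%s_%s", r$gene, r$cdna)] <- mg@insertSeq
            products[[length(products) + 1L]] <- data.frame(
                gene = r$gene, cdna = r$cdna,
                wt_product = wtProductSize(pred),
                variant_products = paste(pred@variantSizes, collapse = ","),
                stringsAsFactors = FALSE)
        }
    })
    consequences <- if (length(consequences)) do.call(rbind, consequences)
                    else data.frame()
    runStage("write_consequences", utils::write.table(
        consequences, paths["consequences"], sep = "\t", quote = FALSE,
        row.names = FALSE))
    runStage("write_constructs", {
        ins <- Biostrings::DNAStringSet(constructs)
        Biostrings::writeXStringSet(ins, paths["constructs"])
        utils::write.table(
            if (length(products)) do.call(rbind, products)
            else data.frame(), paths["products"], sep = "\t",
            quote = FALSE, row.names = FALSE)
    })
    summary <- c(pri$summary,
                 list(funnel = as.list(f),
                      probands = nrow(manifest),
                      parameters = list(
                          afMax = config$afMax,
                          scoreCutoff = config$scoreCutoff,
                          minJunctionDistance = config$minJunctionDistance,
                          nmdBoundary = config$nmdBoundary,
                          flank = config$flank,
                          vectorExonBp = config$vectorExonBp)))
    runStage("write_summary", jsonlite::write_json(
        summary, paths["summary"], auto_unbox = TRUE, pretty = TRUE,
        digits = NA))
    invisible(list(summary = summary, candidates = pri$candidates,
                   consequences = consequences, paths = paths,
                   reports = pri$reports))
}
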