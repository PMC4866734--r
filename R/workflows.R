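#' @include evaluation.R
NULL

## End-to-end orchestration: simulate, benchmark and classify runs that
## read/write TSV tables, log their full configuration and seed, and
## derive every stage seed from one master seed so classifier arms share
## splits. A thin command-line wrapper over these functions ships in
## inst/scripts/sptl.R.

.runLog <- function(outputDir, what, config, inputs = character(0)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    lines <- c(
        sprintf("tool: spatialTL %s",
                as.character(utils::packageVersion("spatialTL"))),
        sprintf("command: %s", what),
        sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
        "config:",
        vapply(names(config), function(k)
            sprintf("  %s: %s", k,
                    paste(format(config[[k]]), collapse = " ")),
            character(1L)))
    if (length(inputs)) {
        sums <- tools::md5sum(inputs)
        lines <- c(lines, "inputs:",
                   sprintf("  %s: %s", basename(inputs), unname(sums)))
    }
    writeLines(lines, file.path(outputDir, paste0(what, ".log")))
    message(paste(lines, collapse = "\n"))
    invisible(lines)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a run configuration file
#'
#' Plain YAML key-value file mirroring the arguments of the run functions.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
}

#' Save / load a trained classifier archive
#'
#' Serialises a trained model (coefficients, kernel or neighbourhood
#' parameters, class set and training data references) into a single
#' self-describing archive so classification runs can be reproduced
#' without retraining.
#'
#' @param model a [KnnTlModel] or [SvmTlModel].
#' @param path archive path (`.rds`).
#' @return `saveModel` the path, invisibly; `loadModel` the model.
#' @export
saveModel <- function(model, path) {
    saveRDS(list(format = "spatialTL-model", version = "1",
                 class = class(model), model = model), path)
    invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
    obj <- readRDS(path)
    if (!identical(obj$format, "spatialTL-model"))
        stop("not a spatialTL model archive: ", path)
    obj$model
}

#' Simulate a paired dataset and write it as TSV files
#'
#' Wraps the synthetic generator and emits the same TSV formats the
#' readers consume: `primary.tsv`, `auxiliary.tsv`, `markers.tsv` (pool
#' proteins labelled `"unknown"`) and `truth.tsv` (the pool's hidden
#' classes).
#'
#' @param outputDir output directory (created if needed).
#' @param config a `"SimConfig"`; by default a two-source scenario from
#'   [makeTwoSourceScenario()] with the given seed.
#' @param seed integer seed (used only when `config` is `NULL`).
#' @return invisibly, the list of written file paths.
#' @export
runSimulate <- function(outputDir, config = NULL, seed = 1L) {
    if (is.null(config)) config <- makeTwoSourceScenario(seed = seed)
    .runLog(outputDir, "simulate",
            config[setdiff(names(config),
                           c("confusablePrimary", "confusableAuxiliary",
                             "primaryCentres"))])
    gen <- generatePairedData(config)
    ds <- gen$dataset
    paths <- list(
        primary = file.path(outputDir, "primary.tsv"),
        auxiliary = file.path(outputDir, "auxiliary.tsv"),
        markers = file.path(outputDir, "markers.tsv"),
        truth = file.path(outputDir, "truth.tsv"))
    writeFeatureMatrix(primaryData(ds), paths$primary)
    writeFeatureMatrix(auxiliaryData(ds), paths$auxiliary)
    .writeTsv(data.frame(accession = proteinIds(ds),
                         class = ds@labels), paths$markers)
    .writeTsv(data.frame(accession = names(gen$truth),
                         class = unname(gen$truth)), paths$truth)
    invisible(paths)
}

## Load the three input files into a PairedDataset.
.loadPaired <- function(primaryFile, auxiliaryFile, markerFile) {
    alignDatasets(readFeatureMatrix(primaryFile),
                  readFeatureMatrix(auxiliaryFile),
                  readMarkerFile(markerFile))
}

#' Run the benchmark workflow
#'
#' Loads the paired data, benchmarks the requested classifier arms on
#' shared stratified splits, and writes per-arm macro and class F1 tables
#' plus the pairwise Welch significance table.
#'
#' @param primaryFile,auxiliaryFile,markerFile input TSV/CSV paths.
#' @param outputDir output directory.
#' @param classifiers arms to run (see [benchmarkClassifiers()]).
#' @param rounds benchmark rounds; `fullScale = TRUE` restores the
#'   canonical 100 rounds and full parameter grids.
#' @param seed master seed.
#' @param control tuning overrides, see [benchmarkClassifiers()].
#' @param fullScale logical; use the full canonical grids and 100 rounds.
#' @return invisibly, the list of [BenchmarkResult] objects.
#' @export
runBenchmark <- function(primaryFile, auxiliaryFile, markerFile, outputDir,
                         classifiers = c("knn_primary", "knn_auxiliary",
                                         "knn_tl"),
                         rounds = 10L, seed = 1L, control = list(),
                         fullScale = FALSE) {
    if (fullScale) {
        rounds <- 100L
        control <- utils::modifyList(list(
            Cgrid = c(0.125, 0.25, 0.5, 1, 2, 4, 8, 16),
            gammaPgrid = c(0.01, 0.1, 1, 10, 100, 1000),
            gammaAgrid = c(0.01, 0.1, 1, 10, 100, 1000),
            knnInnerRounds = 100L, thetaInnerRounds = 100L), control)
    }
    .runLog(outputDir, "benchmark",
            list(classifiers = classifiers, rounds = rounds, seed = seed,
                 fullScale = fullScale),
            c(primaryFile, auxiliaryFile, markerFile))
    ds <- .loadPaired(primaryFile, auxiliaryFile, markerFile)
    L <- splitLabelled(ds)$L
    res <- benchmarkClassifiers(L, classifiers, rounds = rounds,
                                seed = seed, control = control)
    macro <- data.frame(round = seq_len(rounds),
                        lapply(res, function(r) r@macroF1),
                        check.names = FALSE)
    .writeTsv(macro, file.path(outputDir, "macro_f1.tsv"))
    for (arm in names(res)) {
        cf <- data.frame(round = seq_len(rounds), res[[arm]]@classF1,
                         check.names = FALSE)
        .writeTsv(cf, file.path(outputDir,
                                paste0("class_f1_", arm, ".tsv")))
    }
    .writeTsv(compareArms(res), file.path(outputDir, "welch_tests.tsv"))
    invisible(res)
}

#' Run the classification workflow
#'
#' Trains the requested transfer-learning classifier on the marker
#' proteins (optimising its free parameters on the labelled data), scores
#' every unlabelled protein, optionally calibrates a score threshold at a
#' target FDR against a supplied gold-standard reference (also writing ROC
#' points and AUC), and writes the assignment table and a reusable model
#' archive.
#'
#' @param primaryFile,auxiliaryFile,markerFile input paths.
#' @param outputDir output directory.
#' @param classifier `"knn_tl"` or `"svm_tl"`.
#' @param goldFile optional two-column TSV (accession, reference class)
#'   of high-confidence localisations used for FDR calibration and ROC.
#' @param targetFdr target false discovery rate (default 0.05).
#' @param threshold explicit score threshold; overrides FDR calibration.
#' @param seed master seed.
#' @param control tuning overrides as in [benchmarkClassifiers()].
#' @return invisibly, a list with the trained model, assignments, and any
#'   threshold/ROC results.
#' @export
runClassify <- function(primaryFile, auxiliaryFile, markerFile, outputDir,
                        classifier = c("knn_tl", "svm_tl"),
                        goldFile = NULL, targetFdr = 0.05,
                        threshold = NULL, seed = 1L, control = list()) {
    classifier <- match.arg(classifier)
    .runLog(outputDir, "classify",
            list(classifier = classifier, targetFdr = targetFdr,
                 threshold = if (is.null(threshold)) "auto" else threshold,
                 seed = seed),
            c(primaryFile, auxiliaryFile, markerFile,
              if (!is.null(goldFile)) goldFile))
    ctl <- utils::modifyList(list(
        knnGrid = c(3L, 5L, 7L, 9L, 11L, 13L, 15L),
        knnInnerRounds = 5L, thetaCandidates = 256L,
        thetaInnerRounds = 5L,
        Cgrid = c(1, 8), gammaPgrid = c(0.1, 1), gammaAgrid = c(0.1, 1),
        svmInnerRounds = 1L), control)
    ds <- .loadPaired(primaryFile, auxiliaryFile, markerFile)
    parts <- splitLabelled(ds)
    L <- parts$L; U <- parts$U
    if (nrow(U@primary) == 0L) stop("no unlabelled proteins to classify")
    if (classifier == "knn_tl") {
        kP <- optimiseK(L@primary, L@labels, grid = ctl$knnGrid,
                        rounds = ctl$knnInnerRounds,
                        seed = .deriveSeed(seed, 11L),
                        classSet = L@classSet)$bestK
        kA <- optimiseK(L@auxiliary, L@labels, grid = ctl$knnGrid,
                        rounds = ctl$knnInnerRounds,
                        seed = .deriveSeed(seed, 12L),
                        classSet = L@classSet)$bestK
        opt <- optimiseTheta(L, kP, kA,
                             candidateCount = ctl$thetaCandidates,
                             rounds = ctl$thetaInnerRounds,
                             seed = .deriveSeed(seed, 13L))
        model <- trainKnnTl(L, kP, kA, opt$consensus)
        .writeTsv(data.frame(class = L@classSet,
                             opt$weightDistribution, check.names = FALSE),
                  file.path(outputDir, "theta_weight_distribution.tsv"))
    } else {
        gs <- gridSearchSvmTl(L, ctl$Cgrid, ctl$gammaPgrid, ctl$gammaAgrid,
                              rounds = ctl$svmInnerRounds,
                              seed = .deriveSeed(seed, 23L))
        model <- trainSvmTl(L, gs$best[["C"]], gs$best[["gammaP"]],
                            gs$best[["gammaA"]])
    }
    saveModel(model, file.path(outputDir, "model.rds"))
    scored <- suppressWarnings(predict(model, U))
    extras <- list()
    if (is.null(threshold) && !is.null(goldFile)) {
        ref <- readMarkerFile(goldFile)
        gold <- makeGoldStandard(scored, ref)
        scores <- stats::setNames(scored$score, scored$accession)
        roc <- tryCatch(rocAnalysis(scores, gold), error = function(e) {
            .logInfo("ROC skipped: %s", conditionMessage(e))
            NULL
        })
        if (!is.null(roc)) {
            .writeTsv(roc$points, file.path(outputDir, "roc_points.tsv"))
            .logInfo("AUC %.3f", roc$auc)
        }
        fdr <- fdrThreshold(scores, gold, targetFdr)
        extras <- list(gold = gold, roc = roc, fdr = fdr)
        threshold <- if (fdr$attained) fdr$threshold else {
            .logInfo("target FDR %.3g unattainable (min %.3g); using strictest threshold",
                     targetFdr, fdr$minFdr)
            fdr$threshold
        }
        .logInfo("threshold %.4g", threshold)
    } else if (is.null(threshold)) {
        threshold <- 0
    }
    assignments <- classifyUnknowns(model, U, threshold)
    .writeTsv(assignments, file.path(outputDir, "assignments.tsv"))
    invisible(c(list(model = model, assignments = assignments,
                     threshold = threshold), extras))
}
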