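#' @include svm-tl.R
NULL

#' Per-class and macro F1 scores
#'
#' Computes precision `tp/(tp+fp)`, recall `tp/(tp+fn)` and their harmonic
#' mean F1 for every class, plus the unweighted macro average. When a class
#' has `tp = 0` the affected ratios (and hence its F1) are 0 — never
#' predicting a class scores zero for it.
#'
#' @param truth character vector of true class labels.
#' @param predicted character vector of predicted labels, same length.
#' @param classSet ordered class names; a prediction or truth label outside
#'   this set is an error.
#' @return list with `perClassF1` (named numeric), `macroF1`, and `counts`
#'   (data frame of tp/fp/fn per class).
#' @examples
#' f1Scores(c("a", "a", "b"), c("a", "b", "b"), c("a", "b"))
#' @export
f1Scores <- function(truth, predicted, classSet) {
    if (length(truth) != length(predicted))
        stop("truth and predicted must have equal length")
    bad <- setdiff(unique(c(truth, predicted)), classSet)
    if (length(bad))
        stop("label(s) absent from classSet: ", paste(bad, collapse = ", "))
    f1 <- numeric(length(classSet))
    tp <- fp <- fn <- integer(length(classSet))
    for (i in seq_along(classSet)) {
        cl <- classSet[i]
        tp[i] <- sum(truth == cl & predicted == cl)
        fp[i] <- sum(truth != cl & predicted == cl)
        fn[i] <- sum(truth == cl & predicted != cl)
        if (tp[i] > 0L) {
            prec <- tp[i] / (tp[i] + fp[i])
            rec <- tp[i] / (tp[i] + fn[i])
            f1[i] <- 2 * prec * rec / (prec + rec)
        }                                    # else F1 = 0 by convention
    }
    names(f1) <- classSet
    list(perClassF1 = f1, macroF1 = mean(f1),
         counts = data.frame(class = classSet, tp = tp, fp = fp, fn = fn,
                             stringsAsFactors = FALSE))
}

#' Welch two-sample t-test
#'
#' Two-tailed two-sample t-test assuming unequal variances
#' (Welch-Satterthwaite degrees of freedom), with a significance flag at
#' the 0.01 threshold used for classifier comparisons.
#'
#' @param a,b numeric score samples (each of size >= 2).
#' @param alpha significance threshold (default 0.01).
#' @return list with `p`, `statistic`, `df` and logical `significant`.
#' @export
welchTTest <- function(a, b, alpha = 0.01) {
    if (length(a) < 2L || length(b) < 2L)
        stop("each sample needs at least two values")
    if (stats::var(a) == 0 && stats::var(b) == 0)
        stop("both samples have zero variance")
    tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
    list(p = tt$p.value, statistic = unname(tt$statistic),
         df = unname(tt$parameter), significant = tt$p.value < alpha)
}

## --- internal benchmark helpers -------------------------------------------

## Score candidate theta matrices (rows) by rounds x nfold CV; shared by
## the per-class optimiser and the Wu source-weight comparator.
.scoreThetaRounds <- function(L, kP, kA, cand, rounds, nfold, seed) {
    classes <- L@classSet
    labels <- L@labels
    best <- matrix(NA_real_, rounds, ncol(cand))
    roundScores <- numeric(rounds)
    for (r in seq_len(rounds)) {
        fold <- .withSeed(.deriveSeed(seed, 1000L + r),
                          .assignFolds(labels, classes, nfold))
        scores <- numeric(nrow(cand))
        for (f in seq_len(nfold)) {
            tr <- fold != f
            P <- .voteMatrix(L@primary[tr, , drop = FALSE], labels[tr],
                             L@primary[!tr, , drop = FALSE], kP, classes)
            Q <- .voteMatrix(L@auxiliary[tr, , drop = FALSE], labels[tr],
                             L@auxiliary[!tr, , drop = FALSE], kA, classes)
            truth <- labels[!tr]
            for (ci in seq_len(nrow(cand))) {
                th <- cand[ci, ]
                V <- sweep(P, 2L, th, "*") + sweep(Q, 2L, 1 - th, "*")
                pred <- .argmaxClass(V, classes, warnTies = FALSE)
                scores[ci] <- scores[ci] +
                    f1Scores(truth, pred, classes)$macroF1
            }
        }
        bi <- .pickTheta(scores, cand)
        best[r, ] <- cand[bi, ]
        roundScores[r] <- scores[bi] / nfold
    }
    list(best = best, roundScores = roundScores)
}

## e1071 (LIBSVM) RBF baseline: small grid search then a final fit.
## Scores are vote shares from the one-vs-one decomposition (deterministic).
.libsvmArm <- function(xtr, ytr, xte, Cgrid, gammaGrid, nfold, seed,
                       classes) {
    combos <- expand.grid(C = Cgrid, gamma = gammaGrid,
                          KEEP.OUT.ATTRS = FALSE)
    total <- numeric(nrow(combos))
    fold <- .withSeed(.deriveSeed(seed, 31L),
                      .assignFolds(ytr, classes, nfold))
    for (f in seq_len(nfold)) {
        tr <- fold != f
        for (ci in seq_len(nrow(combos))) {
            fit <- e1071::svm(xtr[tr, , drop = FALSE],
                              factor(ytr[tr], levels = classes),
                              kernel = "radial", cost = combos$C[ci],
                              gamma = combos$gamma[ci], scale = FALSE)
            pred <- as.character(predict(fit, xtr[!tr, , drop = FALSE]))
            total[ci] <- total[ci] +
                f1Scores(ytr[!tr], pred, classes)$macroF1
        }
    }
    bi <- which.max(total)
    fit <- e1071::svm(xtr, factor(ytr, levels = classes),
                      kernel = "radial", cost = combos$C[bi],
                      gamma = combos$gamma[bi], scale = FALSE)
    pred <- predict(fit, xte, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    ## vote share per class from pairwise decision values
    votes <- matrix(0, nrow(xte), length(classes),
                    dimnames = list(NULL, classes))
    for (cn in colnames(dv)) {
        pair <- strsplit(cn, "/", fixed = TRUE)[[1L]]
        pos <- dv[, cn] >= 0
        votes[, pair[1L]] <- votes[, pair[1L]] + pos
        votes[, pair[2L]] <- votes[, pair[2L]] + !pos
    }
    npairs <- ncol(dv)
    list(class = as.character(pred),
         score = apply(votes, 1L, max) / npairs,
         params = c(C = combos$C[bi], gamma = combos$gamma[bi]))
}

## One benchmark round for one classifier arm; returns list(class, score)
## over the test rows plus the tuned parameters.
.benchmarkArm <- function(kind, Ltr, Lte, roundSeed, ctl) {
    classes <- Ltr@classSet
    kOpt <- function(x, tag) {
        optimiseK(x, Ltr@labels, grid = ctl$knnGrid,
                  rounds = ctl$knnInnerRounds, seed = .deriveSeed(roundSeed, tag),
                  classSet = classes)$bestK
    }
    switch(kind,
        knn_primary = {
            kP <- kOpt(Ltr@primary, 11L)
            mod <- trainKnnTl(Ltr, kP, kP, rep(1, length(classes)))
            p <- suppressWarnings(predict(mod, Lte))
            list(class = p$class, score = p$score, params = c(k = kP))
        },
        knn_auxiliary = {
            kA <- kOpt(Ltr@auxiliary, 12L)
            mod <- trainKnnTl(Ltr, kA, kA, rep(0, length(classes)))
            p <- suppressWarnings(predict(mod, Lte))
            list(class = p$class, score = p$score, params = c(k = kA))
        },
        knn_tl = {
            kP <- kOpt(Ltr@primary, 11L)
            kA <- kOpt(Ltr@auxiliary, 12L)
            theta <- ctl$fixedTheta
            if (is.null(theta)) {
                cand <- .thetaCandidates(length(classes),
                                         ctl$thetaCandidates,
                                         ctl$thetaGrid,
                                         .deriveSeed(roundSeed, 13L))
                sc <- .scoreThetaRounds(Ltr, kP, kA, cand,
                                        ctl$thetaInnerRounds, 5L,
                                        .deriveSeed(roundSeed, 13L))
                ## per-round winners pooled: take the winner of the last
                ## inner round scored best on average
                theta <- sc$best[which.max(sc$roundScores), ]
            }
            mod <- trainKnnTl(Ltr, kP, kA, theta)
            p <- suppressWarnings(predict(mod, Lte))
            list(class = p$class, score = p$score,
                 params = c(kP = kP, kA = kA, theta))
        },
        knn_tl_wu = {
            kP <- kOpt(Ltr@primary, 11L)
            kA <- kOpt(Ltr@auxiliary, 12L)
            cand <- matrix(rep(ctl$lambdaGrid, length(classes)),
                           ncol = length(classes))
            sc <- .scoreThetaRounds(Ltr, kP, kA, cand,
                                    ctl$thetaInnerRounds, 5L,
                                    .deriveSeed(roundSeed, 14L))
            lambda <- sc$best[which.max(sc$roundScores), 1L]
            mod <- trainKnnTl(Ltr, kP, kA, rep(lambda, length(classes)))
            p <- suppressWarnings(predict(mod, Lte))
            list(class = p$class, score = p$score,
                 params = c(kP = kP, kA = kA, lambda = lambda))
        },
        svm_primary = .libsvmArm(Ltr@primary, Ltr@labels, Lte@primary,
                                 ctl$Cgrid, ctl$gammaPgrid, 5L,
                                 .deriveSeed(roundSeed, 21L), classes),
        svm_auxiliary = .libsvmArm(Ltr@auxiliary, Ltr@labels, Lte@auxiliary,
                                   ctl$Cgrid, ctl$gammaAgrid, 5L,
                                   .deriveSeed(roundSeed, 22L), classes),
        svm_tl = {
            gs <- gridSearchSvmTl(Ltr, ctl$Cgrid, ctl$gammaPgrid,
                                  ctl$gammaAgrid, rounds = 1L, nfold = 5L,
                                  seed = .deriveSeed(roundSeed, 23L))
            mod <- trainSvmTl(Ltr, gs$best[["C"]], gs$best[["gammaP"]],
                              gs$best[["gammaA"]])
            p <- suppressWarnings(predict(mod, Lte))
            list(class = p$class, score = p$score, params = gs$best)
        },
        stop("unknown classifier kind: ", kind))
}

#' Benchmark classifier arms by repeated stratified 80/20 rounds
#'
#' The generalisation-assessment schema: in every round the labelled data
#' are split into stratified training (`fraction`) and test partitions, the
#' free parameters of each classifier arm are tuned on the training
#' partition by stratified 5-fold cross-validated grid search, the tuned
#' classifier is refitted and scored on the withheld test partition, and
#' the macro and class-specific F1 scores are recorded. All arms share the
#' per-round splits (identical derived seeds), so paired comparisons across
#' arms are meaningful.
#'
#' @param L a fully labelled [PairedDataset] (use [splitLabelled()] first).
#' @param classifiers character vector of arms among `knn_primary`,
#'   `knn_auxiliary`, `knn_tl`, `knn_tl_wu`, `svm_primary`,
#'   `svm_auxiliary`, `svm_tl`.
#' @param rounds number of 80/20 rounds.
#' @param seed integer master seed; every round seed derives from it.
#' @param fraction training fraction.
#' @param control list overriding tuning settings: `knnGrid`,
#'   `knnInnerRounds`, `thetaCandidates`, `thetaInnerRounds`, `thetaGrid`,
#'   `lambdaGrid`, `Cgrid`, `gammaPgrid`, `gammaAgrid`, `fixedTheta`.
#'   Defaults are desk-scale reductions of the canonical grids; see the
#'   package vignette.
#' @return named list of [BenchmarkResult], one per arm.
#' @export
benchmarkClassifiers <- function(L,
                                 classifiers = c("knn_primary",
                                                 "knn_auxiliary", "knn_tl"),
                                 rounds = 100L, seed = 1L, fraction = 0.8,
                                 control = list()) {
    stopifnot(methods::is(L, "PairedDataset"))
    ctl <- utils::modifyList(list(
        knnGrid = c(3L, 5L, 7L, 9L, 11L, 13L, 15L),
        knnInnerRounds = 2L,
        thetaCandidates = 256L,
        thetaInnerRounds = 2L,
        thetaGrid = c(0, 1 / 3, 2 / 3, 1),
        lambdaGrid = c(0, 1 / 3, 2 / 3, 1),
        Cgrid = c(1, 8),
        gammaPgrid = c(0.1, 1, 10),
        gammaAgrid = c(0.1, 1),
        fixedTheta = NULL), control)
    classes <- L@classSet
    out <- list()
    for (kind in classifiers) {
        macro <- numeric(rounds)
        classF1 <- matrix(NA_real_, rounds, length(classes),
                          dimnames = list(NULL, classes))
        seeds <- integer(rounds)
        for (r in seq_len(rounds)) {
            roundSeed <- .deriveSeed(seed, r)
            seeds[r] <- roundSeed
            plan <- stratifiedHoldout(L, fraction, roundSeed)
            Ltr <- .subsetPaired(L, plan@train)
            Lte <- .subsetPaired(L, plan@test)
            arm <- .benchmarkArm(kind, Ltr, Lte, roundSeed, ctl)
            rep_ <- f1Scores(Lte@labels, arm$class, classes)
            macro[r] <- rep_$macroF1
            classF1[r, ] <- rep_$perClassF1
        }
        out[[kind]] <- methods::new("BenchmarkResult", classifier = kind,
                                    macroF1 = macro, classF1 = classF1,
                                    seeds = seeds, config = ctl)
        .logInfo("benchmark %s: median macro F1 %.3f over %d rounds",
                 kind, stats::median(macro), rounds)
    }
    out
}

#' Pairwise Welch tests between benchmark arms
#'
#' @param results named list of [BenchmarkResult] (shared seeds).
#' @param alpha significance threshold (default 0.01).
#' @return data frame of arm pairs with p-values and significance flags.
#' @export
compareArms <- function(results, alpha = 0.01) {
    arms <- names(results)
    rows <- list()
    for (i in seq_along(arms)) {
        for (j in seq_along(arms)) {
            if (i >= j) next
            wt <- welchTTest(results[[i]]@macroF1, results[[j]]@macroF1,
                             alpha)
            rows[[length(rows) + 1L]] <- data.frame(
                armA = arms[i], armB = arms[j],
                medianA = stats::median(results[[i]]@macroF1),
                medianB = stats::median(results[[j]]@macroF1),
                p = wt$p, significant = wt$significant,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

#' Build a gold standard from an external high-confidence reference
#'
#' Flags each scored protein as correct or incorrect by comparing its
#' predicted class with a high-confidence reference localisation (e.g. a
#' high-resolution map of the same system), after an optional explicit
#' class-name mapping between the two nomenclatures.
#'
#' @param predictions data frame with columns `accession` and `class` (as
#'   returned by the predict methods).
#' @param reference named character vector: accession -> reference class.
#' @param classMap optional named character vector translating prediction
#'   class names to reference class names.
#' @return data frame with `accession`, `predictedClass`, `referenceClass`
#'   and logical `correct`, restricted to proteins present in the
#'   reference.
#' @export
makeGoldStandard <- function(predictions, reference, classMap = NULL) {
    hit <- predictions$accession %in% names(reference)
    if (!any(hit)) stop("no scored protein appears in the reference")
    pred <- predictions[hit, , drop = FALSE]
    mapped <- pred$class
    if (!is.null(classMap)) {
        tr <- classMap[mapped]
        mapped <- ifelse(is.na(tr), mapped, tr)
    }
    data.frame(accession = pred$accession,
               predictedClass = pred$class,
               referenceClass = unname(reference[pred$accession]),
               correct = mapped == unname(reference[pred$accession]),
               stringsAsFactors = FALSE)
}

#' ROC curve and AUC for classifier scores against a gold standard
#'
#' At each unique score threshold `t`, true positives are correctly
#' assigned proteins with score >= t and false positives incorrectly
#' assigned ones with score >= t; TPR and FPR normalise by the total
#' correct and incorrect counts. The AUC is the trapezoid area over the
#' distinct thresholds.
#'
#' @param scores named numeric classifier scores covering the gold
#'   proteins.
#' @param gold data frame as from [makeGoldStandard()] (columns
#'   `accession`, `correct`).
#' @return list with `points` (data frame threshold/tpr/fpr) and `auc`.
#' @export
rocAnalysis <- function(scores, gold) {
    s <- scores[gold$accession]
    if (anyNA(s)) stop("scores must cover every gold-standard protein")
    correct <- gold$correct
    npos <- sum(correct); nneg <- sum(!correct)
    if (npos == 0L || nneg == 0L)
        stop("degenerate gold standard: needs at least one correct and one incorrect assignment")
    thr <- sort(unique(s), decreasing = TRUE)
    tpr <- vapply(thr, function(t) sum(correct & s >= t) / npos, numeric(1L))
    fpr <- vapply(thr, function(t) sum(!correct & s >= t) / nneg, numeric(1L))
    pts <- data.frame(threshold = c(Inf, thr), tpr = c(0, tpr),
                      fpr = c(0, fpr))
    auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1L) +
                                utils::tail(pts$tpr, -1L)) / 2)
    list(points = pts, auc = auc)
}

#' FDR-calibrated classifier score threshold
#'
#' Finds the smallest score threshold at which the false discovery rate —
#' the fraction of incorrect assignments among proteins scoring at or
#' above the threshold — does not exceed `targetFdr`. When no threshold
#' attains the target (as can happen for weakly separating score
#' distributions) a failure object is returned carrying the minimum
#' achievable FDR and the strictest threshold attaining it.
#'
#' @param scores named numeric classifier scores covering the gold
#'   proteins.
#' @param gold data frame with `accession` and logical `correct`.
#' @param targetFdr target false discovery rate in (0, 1) (5% in typical
#'   use).
#' @return list of class `"fdrThreshold"` with elements `attained`,
#'   `threshold`, `fdr`, `nAssigned`, and for failures `minFdr` plus its
#'   `threshold`.
#' @export
fdrThreshold <- function(scores, gold, targetFdr = 0.05) {
    if (nrow(gold) == 0L) stop("empty gold standard")
    if (targetFdr <= 0 || targetFdr >= 1)
        stop("targetFdr must lie in (0, 1)")
    s <- scores[gold$accession]
    if (anyNA(s)) stop("scores must cover every gold-standard protein")
    correct <- gold$correct
    thr <- sort(unique(s))
    fdrAt <- vapply(thr, function(t) {
        sel <- s >= t
        sum(!correct & sel) / sum(sel)
    }, numeric(1L))
    ok <- which(fdrAt <= targetFdr)
    if (length(ok)) {
        t <- thr[ok[1L]]
        structure(list(attained = TRUE, threshold = t, fdr = fdrAt[ok[1L]],
                       nAssigned = sum(s >= t), targetFdr = targetFdr),
                  class = "fdrThreshold")
    } else {
        best <- max(which(fdrAt == min(fdrAt)))   # strictest threshold
        structure(list(attained = FALSE, threshold = thr[best],
                       fdr = fdrAt[best], minFdr = fdrAt[best],
                       nAssigned = sum(s >= thr[best]),
                       targetFdr = targetFdr),
                  class = "fdrThreshold")
    }
}

#' @export
print.fdrThreshold <- function(x, ...) {
    if (x$attained)
        cat(sprintf("FDR threshold: %.4g (achieved FDR %.3f <= target %.3f, %d assigned)\n",
                    x$threshold, x$fdr, x$targetFdr, x$nAssigned))
    else
        cat(sprintf("target FDR %.3f unattainable; minimum achievable FDR %.3f at strictest threshold %.4g\n",
                    x$targetFdr, x$minFdr, x$threshold))
    invisible(x)
}

#' Assign unlabelled proteins with a score threshold
#'
#' Predicts every unlabelled protein and sets predictions scoring below
#' `threshold` to `"unassigned"`.
#'
#' @param model a [KnnTlModel] or [SvmTlModel].
#' @param U a [PairedDataset] of unlabelled (or any query) proteins.
#' @param threshold score cutoff in \[0, 1\] (0 assigns everything).
#' @return data frame with `accession`, `class`, `score` and logical
#'   `assigned`; a per-class summary table is attached as attribute
#'   `"summary"`.
#' @export
classifyUnknowns <- function(model, U, threshold = 0) {
    p <- predict(model, U)
    assigned <- p$score >= threshold
    out <- data.frame(accession = p$accession,
                      class = ifelse(assigned, p$class, "unassigned"),
                      score = p$score, assigned = assigned,
                      stringsAsFactors = FALSE)
    attr(out, "summary") <- table(out$class)
    .logInfo("assigned %d / %d proteins at threshold %.3g",
             sum(assigned), nrow(out), threshold)
    out
}
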