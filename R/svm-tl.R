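#' @include lp.R
NULL

## Two-kernel 1-norm linear-programming SVM transfer learning.
##
## Each binary problem solves
##   min |alphaP|_1 + |alphaA|_1 + C+ sum_{i in S+} xi_i + C- sum_{i in S-} xi_i
##   s.t. y_i f(x_i, v_i) + xi_i >= 1,  alphaP, alphaA, xi >= 0,
## with latent function
##   f(x, v) = sum_l y_l [alphaP_l K_P(x_l, x) + alphaA_l K_A(v_l, v)] + b,
## the class-imbalance weights being C+ = C n-/n+ and C- = C n+/n-. The
## 1-norm objective promotes sparse coefficient vectors. Multiclass
## prediction is one-vs-one with Platt sigmoid probabilities coupled into a
## single class distribution.

#' Gaussian (RBF) kernel matrix
#'
#' `K(x1, x2) = exp(-gamma * ||x1 - x2||^2)`.
#'
#' @param X1,X2 numeric matrices with matching feature dimension (`X2`
#'   defaults to `X1`).
#' @param gamma positive kernel width parameter.
#' @return `nrow(X1) x nrow(X2)` kernel matrix with entries in (0, 1\].
#' @examples
#' gaussianKernel(rbind(c(0, 0)), rbind(c(1, 1)), gamma = 0.5)  # exp(-1)
#' @export
gaussianKernel <- function(X1, X2 = X1, gamma) {
    if (gamma <= 0) stop("gamma must be positive")
    X1 <- as.matrix(X1); X2 <- as.matrix(X2)
    if (ncol(X1) != ncol(X2)) stop("feature dimensions differ")
    exp(-gamma * .crossDist2(X1, X2))
}

## Morik cost-sensitive slack weights.
.morikWeights <- function(y, C) {
    npos <- sum(y > 0); nneg <- sum(y < 0)
    ifelse(y > 0, C * nneg / npos, C * npos / nneg)
}

## Assemble and solve the LP shared by the one- and two-kernel variants.
## Variable layout: [alphaP (m) | alphaA (m, optional) | xi (m) | b+ | b-].
.trainBinaryLP <- function(KP, KA, y, C, classPos, classNeg, trainIds) {
    m <- length(y)
    if (length(unique(sign(y))) < 2L)
        stop("both classes must be present in the training labels")
    YY <- tcrossprod(y)
    blocks <- list(YY * KP)
    if (!is.null(KA)) blocks <- c(blocks, list(YY * KA))
    A <- do.call(cbind, c(blocks, list(diag(m), y, -y)))
    nAlpha <- m * length(blocks)
    Cvec <- .morikWeights(y, C)
    obj <- c(rep(1, nAlpha), Cvec, 0, 0)
    sol <- .lpSimplex(obj, A, rep(1, m),
                      basis = (nAlpha + 1L):(nAlpha + m))
    if (identical(sol$status, "infeasible")) {
        tab <- table(factor(ifelse(y > 0, classPos, classNeg),
                            levels = c(classPos, classNeg)))
        fb <- names(tab)[which.max(tab)]   # ties: first class in order
        .logInfo("LP infeasible for pair %s|%s; falling back to majority class %s",
                 classPos, classNeg, fb)
        return(methods::new("BinaryLPModel", alphaP = numeric(0),
                            alphaA = numeric(0), b = 0, y = y,
                            trainIds = trainIds, classPos = classPos,
                            classNeg = classNeg, objective = NA_real_,
                            fallbackClass = fb))
    }
    if (!identical(sol$status, "optimal"))
        stop("LP solver failure (status: ", sol$status, ")")
    alphaP <- pmax(sol$x[seq_len(m)], 0)
    alphaA <- if (is.null(KA)) numeric(m) else
        pmax(sol$x[m + seq_len(m)], 0)
    b <- sol$x[nAlpha + m + 1L] - sol$x[nAlpha + m + 2L]
    methods::new("BinaryLPModel", alphaP = alphaP, alphaA = alphaA, b = b,
                 y = y, trainIds = trainIds, classPos = classPos,
                 classNeg = classNeg, objective = sol$objective,
                 fallbackClass = character(0))
}

#' Train one binary two-kernel 1-norm LP-SVM
#'
#' Solves the sparse linear programme for a single pair of classes given
#' precomputed kernel matrices for both sources, applying the Morik
#' class-imbalance weights `C+ = C n-/n+`, `C- = C n+/n-` to the slack
#' penalties. When the solver reports the programme infeasible the returned
#' model records the majority class of the labelled pair and predicts it
#' unconditionally.
#'
#' @param KP,KA m x m kernel matrices for the primary and auxiliary source
#'   over the same m training proteins.
#' @param y numeric +1/-1 labels of the m rows.
#' @param C positive slack penalty before imbalance adjustment.
#' @param classPos,classNeg class names encoded +1 and -1.
#' @param trainIds accessions of the m rows.
#' @return a [BinaryLPModel].
#' @export
trainBinaryTL <- function(KP, KA, y, C,
                          classPos = "+1", classNeg = "-1",
                          trainIds = paste0("row", seq_along(y))) {
    if (C <= 0) stop("C must be positive")
    stopifnot(nrow(KP) == length(y), ncol(KP) == length(y),
              nrow(KA) == length(y), ncol(KA) == length(y))
    .trainBinaryLP(KP, KA, y, C, classPos, classNeg, trainIds)
}

#' Train one binary single-kernel 1-norm LP-SVM
#'
#' The single-source counterpart: same linear programme with one kernel
#' expansion only (used for single-source lpSVM comparisons).
#'
#' @param K m x m kernel matrix.
#' @inheritParams trainBinaryTL
#' @return a [BinaryLPModel] (its `alphaA` slot is all zeros).
#' @export
trainBinarySingle <- function(K, y, C,
                              classPos = "+1", classNeg = "-1",
                              trainIds = paste0("row", seq_along(y))) {
    if (C <= 0) stop("C must be positive")
    stopifnot(nrow(K) == length(y), ncol(K) == length(y))
    .trainBinaryLP(K, NULL, y, C, classPos, classNeg, trainIds)
}

#' Latent decision values of a binary LP-SVM
#'
#' Evaluates `f(x, v) = sum_l y_l [alphaP_l KP(x_l, x) + alphaA_l
#' KA(v_l, v)] + b` for query proteins given rows of kernel evaluations
#' against the model's training set; thresholding the sign at 0 gives the
#' binary class. For fallback models the value is `+Inf` when the fallback
#' class is the positive class and `-Inf` otherwise, so downstream
#' sign-thresholding and voting honour the unconditional prediction.
#'
#' @param model a [BinaryLPModel].
#' @param kPRows queries x m matrix of primary-kernel evaluations
#'   `KP(x_l, x)` (ignored by fallback models).
#' @param kARows queries x m matrix of auxiliary-kernel evaluations; omit
#'   (or `NULL`) for single-kernel models.
#' @return numeric vector of latent values.
#' @export
decisionValue <- function(model, kPRows, kARows = NULL) {
    stopifnot(methods::is(model, "BinaryLPModel"))
    kPRows <- rbind(kPRows)
    if (length(model@fallbackClass)) {
        v <- if (model@fallbackClass == model@classPos) Inf else -Inf
        return(rep(v, nrow(kPRows)))
    }
    f <- as.vector(kPRows %*% (model@y * model@alphaP)) + model@b
    if (any(model@alphaA > 0)) {
        if (is.null(kARows))
            stop("model uses the auxiliary kernel; kARows is required")
        f <- f + as.vector(rbind(kARows) %*% (model@y * model@alphaA))
    }
    f
}

## Pair key helper ("i|j" with i before j in classSet order).
.pairKey <- function(a, b) paste(a, b, sep = "|")

#' Train the one-vs-one multiclass two-kernel LP-SVM
#'
#' Fits one binary LP-SVM per unordered pair of classes (the first class of
#' each pair coded +1), applying the Morik imbalance weights, and fits a
#' Platt sigmoid to each pair's training decision values for probabilistic
#' prediction.
#'
#' @param L a fully labelled [PairedDataset].
#' @param C positive slack penalty.
#' @param gammaP,gammaA Gaussian kernel widths for the two sources.
#' @param sources `"both"` (transfer learning, default), `"primary"` or
#'   `"auxiliary"` (single-source lpSVM).
#' @return an [SvmTlModel].
#' @seealso [gridSearchSvmTl()], [predict,SvmTlModel-method]
#' @export
trainSvmTl <- function(L, C, gammaP, gammaA,
                       sources = c("both", "primary", "auxiliary")) {
    stopifnot(methods::is(L, "PairedDataset"))
    sources <- match.arg(sources)
    if (any(L@labels == UNKNOWN_LABEL))
        stop("training data must be fully labelled")
    classes <- L@classSet
    if (length(classes) < 2L) stop("at least two classes are required")
    labels <- L@labels
    ids <- rownames(L@primary)
    KPfull <- if (sources != "auxiliary")
        gaussianKernel(L@primary, gamma = gammaP) else NULL
    KAfull <- if (sources != "primary")
        gaussianKernel(L@auxiliary, gamma = gammaA) else NULL
    models <- list()
    platt <- list()
    for (i in seq_len(length(classes) - 1L)) {
        for (j in seq((i + 1L), length(classes))) {
            sel <- labels %in% classes[c(i, j)]
            y <- ifelse(labels[sel] == classes[i], 1, -1)
            key <- .pairKey(classes[i], classes[j])
            mod <- if (sources == "both") {
                trainBinaryTL(KPfull[sel, sel], KAfull[sel, sel], y, C,
                              classes[i], classes[j], ids[sel])
            } else if (sources == "primary") {
                trainBinarySingle(KPfull[sel, sel], y, C,
                                  classes[i], classes[j], ids[sel])
            } else {
                trainBinarySingle(KAfull[sel, sel], y, C,
                                  classes[i], classes[j], ids[sel])
            }
            models[[key]] <- mod
            if (length(mod@fallbackClass)) {
                platt[[key]] <- c(A = NA_real_, B = NA_real_)
            } else {
                kP <- if (sources == "auxiliary") KAfull[sel, sel]
                      else KPfull[sel, sel]
                kA <- if (sources == "both") KAfull[sel, sel] else NULL
                f <- decisionValue(mod, kP, kA)
                platt[[key]] <- fitPlatt(f, y)
            }
        }
    }
    methods::new(Class = "SvmTlModel", models = models, platt = platt,
                 classSet = classes, C = C,
                 gammaP = if (sources == "auxiliary") NA_real_ else gammaP,
                 gammaA = if (sources == "primary") NA_real_ else gammaA,
                 sources = sources,
                 trainPrimary = L@primary, trainAuxiliary = L@auxiliary,
                 trainLabels = labels)
}

#' Predict sub-cellular classes with the multiclass LP-SVM
#'
#' For each query the pairwise decision values are turned into pairwise
#' probabilities by the fitted Platt sigmoids and coupled into a single
#' class distribution (`method = "probability"`, the default); the
#' predicted class maximises the coupled probability and the classifier
#' score is that maximum. `method = "votes"` instead counts sign votes
#' among the pairwise classifiers, ties broken by summed decision values
#' and then class order.
#'
#' @param object an [SvmTlModel].
#' @param newdata a [PairedDataset] of query proteins.
#' @param method `"probability"` or `"votes"`.
#' @param ... ignored.
#' @return data frame with columns `accession`, `class`, `score`; for the
#'   probability path the full coupled probability matrix is attached as
#'   attribute `"probabilities"`.
#' @export
setMethod("predict", "SvmTlModel", function(object, newdata,
                                            method = c("probability",
                                                       "votes"), ...) {
    method <- match.arg(method)
    stopifnot(methods::is(newdata, "PairedDataset"))
    classes <- object@classSet
    nc <- length(classes)
    nq <- nrow(newdata@primary)
    KPq <- if (object@sources != "auxiliary")
        gaussianKernel(newdata@primary, object@trainPrimary,
                       object@gammaP) else NULL
    KAq <- if (object@sources != "primary")
        gaussianKernel(newdata@auxiliary, object@trainAuxiliary,
                       object@gammaA) else NULL
    ids <- rownames(object@trainPrimary)
    ## per-pair decision values for all queries
    fvals <- list()
    for (key in names(object@models)) {
        mod <- object@models[[key]]
        sel <- match(mod@trainIds, ids)
        kP <- if (object@sources == "auxiliary")
            KAq[, sel, drop = FALSE] else KPq[, sel, drop = FALSE]
        kA <- if (object@sources == "both")
            KAq[, sel, drop = FALSE] else NULL
        fvals[[key]] <- decisionValue(mod, kP, kA)
    }
    if (method == "votes") {
        votes <- matrix(0, nq, nc, dimnames = list(NULL, classes))
        sumdec <- matrix(0, nq, nc, dimnames = list(NULL, classes))
        for (key in names(object@models)) {
            mod <- object@models[[key]]
            f <- fvals[[key]]
            pos <- f >= 0
            votes[, mod@classPos] <- votes[, mod@classPos] + pos
            votes[, mod@classNeg] <- votes[, mod@classNeg] + !pos
            fin <- ifelse(is.finite(f), f, sign(f) * 1e6)
            sumdec[, mod@classPos] <- sumdec[, mod@classPos] + fin
            sumdec[, mod@classNeg] <- sumdec[, mod@classNeg] - fin
        }
        ## primary criterion votes, ties by summed decision values, then
        ## class order (handled by .argmaxClass on the composite score)
        comp <- votes + 1e-9 * tanh(sumdec / 1e3)
        cls <- .argmaxClass(comp, classes, warnTies = FALSE)
        res <- data.frame(accession = rownames(newdata@primary),
                          class = cls,
                          score = apply(votes, 1L, max) /
                              length(object@models),
                          stringsAsFactors = FALSE, row.names = NULL)
        return(res)
    }
    probs <- matrix(NA_real_, nq, nc, dimnames = list(NULL, classes))
    R <- matrix(0.5, nc, nc, dimnames = list(classes, classes))
    for (q in seq_len(nq)) {
        for (key in names(object@models)) {
            mod <- object@models[[key]]
            f <- fvals[[key]][q]
            if (length(mod@fallbackClass)) {
                r <- if (is.infinite(f) && f > 0) 1 - 1e-7 else 1e-7
            } else {
                ab <- object@platt[[key]]
                r <- .plattProb(f, ab[["A"]], ab[["B"]])
                r <- min(max(r, 1e-7), 1 - 1e-7)
            }
            R[mod@classPos, mod@classNeg] <- r
            R[mod@classNeg, mod@classPos] <- 1 - r
        }
        probs[q, ] <- pairwiseCoupling(R)
    }
    cls <- .argmaxClass(probs, classes, warnTies = FALSE)
    res <- data.frame(accession = rownames(newdata@primary),
                      class = cls,
                      score = apply(probs, 1L, max),
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(res, "probabilities") <- probs
    res
})

#' Grid search for the LP-SVM transfer-learning parameters
#'
#' Scores every (C, gammaP, gammaA) combination by repeated rounds of
#' stratified `nfold` cross-validation on the labelled data, using mean
#' macro F1 of the probabilistic predictions, and returns the best
#' combination (first in grid order on ties). Kernel matrices are computed
#' once per gamma and re-used across the C grid.
#'
#' @param L a fully labelled [PairedDataset].
#' @param Cgrid candidate slack penalties (default the canonical
#'   `{0.125, 0.25, 0.5, 1, 2, 4, 8, 16}`).
#' @param gammaPgrid,gammaAgrid candidate kernel widths (default the
#'   canonical `{0.01, 0.1, 1, 10, 100, 1000}`).
#' @param rounds cross-validation rounds.
#' @param nfold folds per round.
#' @param seed integer seed.
#' @param sources as in [trainSvmTl()]; for single-source fits the unused
#'   gamma grid collapses to `NA`.
#' @return list with `best` (named vector C, gammaP, gammaA) and `scores`
#'   (data frame of all combinations and their mean macro F1).
#' @export
gridSearchSvmTl <- function(L,
                            Cgrid = c(0.125, 0.25, 0.5, 1, 2, 4, 8, 16),
                            gammaPgrid = c(0.01, 0.1, 1, 10, 100, 1000),
                            gammaAgrid = c(0.01, 0.1, 1, 10, 100, 1000),
                            rounds = 1L, nfold = 5L, seed = 1L,
                            sources = "both") {
    stopifnot(methods::is(L, "PairedDataset"))
    if (!length(Cgrid) || !length(gammaPgrid) || !length(gammaAgrid))
        stop("parameter grids must be non-empty")
    if (sources == "primary") gammaAgrid <- NA_real_
    if (sources == "auxiliary") gammaPgrid <- NA_real_
    combos <- expand.grid(C = Cgrid, gammaP = gammaPgrid,
                          gammaA = gammaAgrid, KEEP.OUT.ATTRS = FALSE)
    labels <- L@labels
    classes <- L@classSet
    total <- numeric(nrow(combos))
    nscored <- 0L
    for (r in seq_len(rounds)) {
        fold <- .withSeed(.deriveSeed(seed, 5000L + r),
                          .assignFolds(labels, classes, nfold))
        for (f in seq_len(nfold)) {
            tr <- fold != f
            Ltr <- .subsetPaired(L, rownames(L@primary)[tr])
            Lval <- .subsetPaired(L, rownames(L@primary)[!tr])
            truth <- labels[!tr]
            for (ci in seq_len(nrow(combos))) {
                mod <- trainSvmTl(Ltr, combos$C[ci],
                                  combos$gammaP[ci], combos$gammaA[ci],
                                  sources = sources)
                pred <- predict(mod, Lval)
                total[ci] <- total[ci] +
                    f1Scores(truth, pred$class, classes)$macroF1
            }
            nscored <- nscored + 1L
        }
    }
    scores <- cbind(combos, meanMacroF1 = total / nscored)
    bi <- which.max(scores$meanMacroF1)
    list(best = c(C = combos$C[bi], gammaP = combos$gammaP[bi],
                  gammaA = combos$gammaA[bi]),
         scores = scores)
}
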