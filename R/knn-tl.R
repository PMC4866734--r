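#' @include data-model.R
NULL

## Class-weighted k-NN transfer learning.
##
## For a query protein (x, v) the kP nearest labelled neighbours of x in the
## primary source and the kA nearest labelled neighbours of v in the
## auxiliary source are found (Euclidean distance in both spaces; on a
## binary auxiliary matrix squared Euclidean distance is the Hamming
## distance, so one code path serves both). The per-source class-count
## vectors are normalised to vote distributions p-hat and q-hat, and the
## per-class voting score is the convex combination
##     V(i) = theta_i * pHat_i + (1 - theta_i) * qHat_i,
## the query being assigned to the class maximising V.

## Assign fold numbers per class; caller must have seeded the RNG.
.assignFolds <- function(labels, classSet, k) {
    fold <- integer(length(labels))
    for (cl in classSet) {
        idx <- which(labels == cl)
        idx <- .shuffle(idx)
        fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
}

## Indices (into the training rows) of the k nearest neighbours of each
## query, distance ties at the k-th position resolved by including the
## lexicographically smallest accession(s).
.neighbourIdx <- function(train, query, k) {
    d2 <- .crossDist2(query, train)
    acc <- rownames(train)
    res <- apply(d2, 1L, function(d) order(d, acc)[seq_len(k)])
    if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

## Vote matrix (queries x classes) from the k nearest labelled neighbours.
.voteMatrix <- function(train, trainLabels, query, k, classSet) {
    idx <- .neighbourIdx(train, query, k)
    lab <- matrix(trainLabels[idx], nrow = nrow(query))
    votes <- vapply(classSet,
                    function(cl) rowSums(lab == cl) / k,
                    numeric(nrow(query)))
    if (nrow(query) == 1L) votes <- matrix(votes, nrow = 1L,
                                           dimnames = list(NULL, classSet))
    rownames(votes) <- rownames(query)
    votes
}

#' Class-vote distribution among the k nearest labelled neighbours
#'
#' Finds the `k` nearest labelled rows of one source (Euclidean distance,
#' distance ties at the k-th neighbour broken towards the lexicographically
#' smallest accession) and returns the per-class neighbour counts divided by
#' `k` — a vote distribution summing to one.
#'
#' @param train labelled feature matrix (rows named by accession).
#' @param trainLabels class labels of the training rows.
#' @param query a single query row (vector or 1-row matrix).
#' @param k neighbourhood size, `1 <= k <= nrow(train)`.
#' @param classSet ordered class names.
#' @return named numeric vote vector over `classSet`, summing to 1.
#' @examples
#' train <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1,
#'                 dimnames = list(paste0("P", 1:6), NULL))
#' neighbourVotes(train, rep(c("a", "b"), each = 3), 0.5, k = 3,
#'                classSet = c("a", "b"))
#' @export
neighbourVotes <- function(train, trainLabels, query, k, classSet) {
    if (k <= 0) stop("k must be positive")
    if (k > nrow(train)) stop("k exceeds the number of labelled rows")
    query <- matrix(as.numeric(query), nrow = 1L)
    drop(.voteMatrix(train, trainLabels, query, as.integer(k), classSet))
}

#' Combine primary and auxiliary vote vectors with per-class weights
#'
#' The transfer-learning voting rule: for each class i,
#' `V(i) = theta[i] * pHat[i] + (1 - theta[i]) * qHat[i]`. A weight of 1
#' uses only primary neighbours for that class, a weight of 0 only
#' auxiliary neighbours.
#'
#' @param pHat primary vote vector (one entry per class).
#' @param qHat auxiliary vote vector, same length.
#' @param theta per-class weights in \[0, 1\], same length.
#' @return numeric vector of per-class voting scores, each in \[0, 1\].
#' @examples
#' combineVotes(c(0.6, 0.4), c(0.3, 0.7), c(1 / 3, 1 / 3))
#' @export
combineVotes <- function(pHat, qHat, theta) {
    n <- length(pHat)
    if (length(qHat) != n || length(theta) != n)
        stop("pHat, qHat and theta must have one entry per class")
    if (any(theta < 0 | theta > 1))
        stop("theta weights must lie in [0, 1]")
    theta * pHat + (1 - theta) * qHat
}

#' Optimise the neighbourhood size k for one data source
#'
#' Evaluates each candidate `k` by repeated rounds of stratified `nfold`
#' cross-validation on the labelled data of a single source, scoring by
#' mean macro F1, and returns the best `k` (smallest on ties). Candidates
#' exceeding the smallest training-fold size are skipped with a warning.
#'
#' @param x labelled feature matrix of one source.
#' @param labels class labels of its rows.
#' @param grid candidate neighbourhood sizes; the default is the odd grid
#'   3-15. Even values are accepted with a warning.
#' @param rounds number of cross-validation rounds.
#' @param nfold folds per round (default 5).
#' @param seed integer seed; results are deterministic given the seed.
#' @param classSet ordered class names (default: sorted observed labels).
#' @return list with `bestK`, a `scores` data frame (k, meanMacroF1) and
#'   the `skipped` candidates.
#' @export
optimiseK <- function(x, labels, grid = c(3L, 5L, 7L, 9L, 11L, 13L, 15L),
                      rounds = 100L, nfold = 5L, seed = 1L,
                      classSet = sort(unique(labels))) {
    if (length(grid) == 0L) stop("the k grid is empty")
    grid <- sort(unique(as.integer(grid)))
    if (any(grid %% 2L == 0L))
        warning("even k value(s) supplied; the canonical grid is odd",
                call. = FALSE)
    counts <- table(factor(labels, levels = classSet))
    if (any(counts < nfold))
        stop("stratification error: class(es) smaller than nfold: ",
             paste(names(counts)[counts < nfold], collapse = ", "))
    n <- length(labels)
    ## training-fold size is n minus the largest fold
    maxFold <- sum(ceiling(as.integer(counts) / nfold))
    minTrain <- n - maxFold
    usable <- grid[grid <= minTrain]
    skipped <- setdiff(grid, usable)
    if (length(skipped))
        warning("skipping k value(s) exceeding the smallest training fold: ",
                paste(skipped, collapse = ", "), call. = FALSE)
    if (length(usable) == 0L)
        stop("no usable k values in the grid")
    kmax <- max(usable)
    f1sum <- stats::setNames(numeric(length(usable)), usable)
    nscored <- 0L
    for (r in seq_len(rounds)) {
        fold <- .withSeed(.deriveSeed(seed, r),
                          .assignFolds(labels, classSet, nfold))
        for (f in seq_len(nfold)) {
            tr <- fold != f
            idx <- .neighbourIdx(x[tr, , drop = FALSE],
                                 x[!tr, , drop = FALSE], kmax)
            labs <- matrix(labels[tr][idx], nrow = sum(!tr))
            truth <- labels[!tr]
            for (j in seq_along(usable)) {
                k <- usable[j]
                cnt <- vapply(classSet, function(cl)
                    rowSums(labs[, seq_len(k), drop = FALSE] == cl),
                    numeric(sum(!tr)))
                if (sum(!tr) == 1L) cnt <- matrix(cnt, nrow = 1L)
                pred <- .argmaxClass(cnt, classSet, warnTies = FALSE)
                f1sum[j] <- f1sum[j] +
                    f1Scores(truth, pred, classSet)$macroF1
            }
            nscored <- nscored + 1L
        }
    }
    scores <- data.frame(k = usable, meanMacroF1 = unname(f1sum) / nscored)
    list(bestK = usable[which.max(scores$meanMacroF1)],
         scores = scores, skipped = skipped)
}

## Candidate theta matrix: the full grid^|C| lattice when small enough,
## otherwise a seeded uniform sample that always contains the all-ones and
## all-zeros corners (so the degenerate single-source reductions remain
## reachable).
.thetaCandidates <- function(nClass, candidateCount, grid, seed) {
    full <- length(grid)^nClass
    if (full <= candidateCount) {
        m <- as.matrix(expand.grid(rep(list(grid), nClass),
                                   KEEP.OUT.ATTRS = FALSE))
    } else {
        m <- .withSeed(.deriveSeed(seed, 777L), {
            matrix(sample(grid, candidateCount * nClass, replace = TRUE),
                   ncol = nClass)
        })
        m <- rbind(rep(1, nClass), rep(0, nClass), m)
        m <- m[!duplicated(m), , drop = FALSE]
        m <- m[seq_len(min(nrow(m), candidateCount)), , drop = FALSE]
    }
    dimnames(m) <- NULL
    m
}

## Winner selection among candidate theta vectors: maximal CV score, with
## exact ties broken first towards the most decisive weights (largest
## total distance from 1/2 — on equal evidence, commit to whichever source
## carries the signal), then towards the larger total weight (prefer the
## primary experiment, guarding against needless dilution of the primary
## signal), then by candidate order.
.pickTheta <- function(scores, cand) {
    mx <- which(scores >= max(scores) - 1e-12)
    if (length(mx) == 1L) return(mx)
    dec <- rowSums(abs(cand[mx, , drop = FALSE] - 0.5))
    mx <- mx[dec >= max(dec) - 1e-12]
    tot <- rowSums(cand[mx, , drop = FALSE])
    mx[which.max(tot)]
}

#' Optimise the per-class transfer weights theta
#'
#' Searches the per-class weight lattice `{0, 1/3, 2/3, 1}^|C|` by repeated
#' rounds of stratified `nfold` cross-validation: in each round every
#' candidate theta vector is scored by mean macro F1 over the folds
#' (neighbour votes are computed once per fold and re-combined per
#' candidate) and the best vector is recorded. The consensus theta is the
#' most frequent per-round winner (ties towards the higher mean score).
#'
#' @param L a fully labelled [PairedDataset].
#' @param kP,kA fixed neighbourhood sizes for the two sources (chosen
#'   beforehand with [optimiseK()]).
#' @param candidateCount maximum number of candidate vectors; the full
#'   lattice is enumerated when it fits (`4^|C| <= candidateCount`),
#'   otherwise a seeded sample including both corners is drawn.
#' @param rounds optimisation rounds.
#' @param nfold folds per round.
#' @param seed integer seed.
#' @param grid candidate weight values (default `{0, 1/3, 2/3, 1}`).
#' @return list with `bestPerRound` (rounds x classes matrix of per-round
#'   winning weights), `consensus` (named numeric theta), `roundScores`
#'   (mean macro F1 of each round's winner) and `weightDistribution`
#'   (classes x grid counts of the per-round winners — the data behind the
#'   usual bubble plot).
#' @export
optimiseTheta <- function(L, kP, kA, candidateCount = 256L, rounds = 100L,
                          nfold = 5L, seed = 1L,
                          grid = c(0, 1 / 3, 2 / 3, 1)) {
    stopifnot(methods::is(L, "PairedDataset"))
    if (candidateCount < 2L)
        stop("candidateCount must be at least 2")
    classes <- L@classSet
    nc <- length(classes)
    cand <- .thetaCandidates(nc, candidateCount, grid, seed)
    labels <- L@labels
    best <- matrix(NA_real_, rounds, nc,
                   dimnames = list(NULL, classes))
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
                scores[ci] <- scores[ci] + f1Scores(truth, pred, classes)$macroF1
            }
        }
        bi <- .pickTheta(scores, cand)
        best[r, ] <- cand[bi, ]
        roundScores[r] <- scores[bi] / nfold
    }
    keys <- apply(best, 1L, paste, collapse = "|")
    freq <- table(keys)
    top <- names(freq)[freq == max(freq)]
    if (length(top) > 1L) {
        keyScore <- vapply(top, function(kk) mean(roundScores[keys == kk]),
                           numeric(1L))
        top <- top[which.max(keyScore)]
    }
    consensus <- best[match(top, keys), ]
    dist <- t(vapply(seq_len(nc), function(i)
        vapply(grid, function(g) sum(abs(best[, i] - g) < 1e-9), numeric(1L)),
        numeric(length(grid))))
    dimnames(dist) <- list(classes, format(grid, digits = 3L))
    list(bestPerRound = best,
         consensus = stats::setNames(consensus, classes),
         roundScores = roundScores,
         weightDistribution = dist)
}

#' Train the class-weighted k-NN transfer-learning classifier
#'
#' @param L a fully labelled [PairedDataset].
#' @param kP,kA neighbourhood sizes for the primary and auxiliary source.
#' @param theta per-class weights in \[0, 1\] (any real values are allowed;
#'   the optimiser searches the canonical lattice).
#' @return a [KnnTlModel].
#' @seealso [optimiseK()], [optimiseTheta()], [predict,KnnTlModel-method]
#' @export
trainKnnTl <- function(L, kP, kA, theta) {
    stopifnot(methods::is(L, "PairedDataset"))
    if (any(L@labels == UNKNOWN_LABEL))
        stop("training data must be fully labelled")
    if (!is.null(names(theta)))
        theta <- theta[L@classSet]
    methods::new("KnnTlModel", kP = as.integer(kP), kA = as.integer(kA),
                 theta = as.numeric(theta),
                 trainPrimary = L@primary, trainAuxiliary = L@auxiliary,
                 trainLabels = L@labels, classSet = L@classSet)
}

## Shared prediction core; theta may be any per-class weight vector.
.predictKnn <- function(model, newdata, theta, warnTies = TRUE) {
    stopifnot(methods::is(newdata, "PairedDataset"))
    P <- .voteMatrix(model@trainPrimary, model@trainLabels,
                     newdata@primary, model@kP, model@classSet)
    Q <- .voteMatrix(model@trainAuxiliary, model@trainLabels,
                     newdata@auxiliary, model@kA, model@classSet)
    V <- sweep(P, 2L, theta, "*") + sweep(Q, 2L, 1 - theta, "*")
    cls <- .argmaxClass(V, model@classSet, warnTies = warnTies)
    res <- data.frame(accession = rownames(newdata@primary),
                      class = cls,
                      score = apply(V, 1L, max),
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(res, "votes") <- V
    res
}

#' Predict sub-cellular classes with the k-NN transfer-learning model
#'
#' Combines the per-source neighbour vote distributions with the model's
#' per-class weights and assigns each query to the class maximising the
#' voting score; the classifier score is that maximal voting score (in
#' \[0, 1\]). Exact score ties are broken towards the first class in
#' `classSet` order, with a warning.
#'
#' @param object a [KnnTlModel].
#' @param newdata a [PairedDataset] of query proteins (aligned sources).
#' @param ... ignored.
#' @return data frame with columns `accession`, `class`, `score`; the full
#'   voting-score matrix is attached as attribute `"votes"`.
#' @export
setMethod("predict", "KnnTlModel", function(object, newdata, ...) {
    .predictKnn(object, newdata, object@theta)
})

#' Predict with a single source-level weight (Wu-style comparator)
#'
#' The source-weighted variant used as a comparator: a single scalar
#' `lambda` replaces every per-class weight, weighting the data sources but
#' not the classes.
#'
#' @param model a [KnnTlModel].
#' @param newdata a [PairedDataset] of query proteins.
#' @param lambda scalar source weight in \[0, 1\].
#' @return as [predict,KnnTlModel-method].
#' @export
predictSourceWeighted <- function(model, newdata, lambda) {
    if (length(lambda) != 1L || lambda < 0 || lambda > 1)
        stop("lambda must be a single value in [0, 1]")
    .predictKnn(model, newdata, rep(lambda, length(model@classSet)))
}
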