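#' @include data-model.R
NULL

## Synthetic paired-data generator. Primary profiles live on the
## probability simplex and are drawn per class from a Dirichlet
## distribution around a class centre — mimicking sum-normalised
## iTRAQ/TMT gradient-occupancy profiles. Auxiliary profiles are sparse
## binary vectors with a class-enriched block of informative terms —
## mimicking GO CC incidence. Per-class, per-source resolution is
## controlled by letting chosen class pairs share a primary centre or an
## auxiliary term block.

#' Configuration for the synthetic paired-data generator
#'
#' @param classSizes named integer vector of labelled proteins per class
#'   (names become the class set; >= 2 classes).
#' @param unlabelledCount size of the unlabelled pool, drawn from the same
#'   class mixture with hidden truth.
#' @param S primary dimension (number of gradient fractions).
#' @param T_ auxiliary dimension (number of annotation terms).
#' @param primaryConcentration Dirichlet concentration governing primary
#'   cluster tightness (larger = tighter).
#' @param primaryCentres `"auto"` (centres placed towards distinct simplex
#'   vertices with mixing controlled by `separation`) or a classes x S
#'   matrix of simplex points.
#' @param separation for `"auto"` centres: weight in (0, 1\] on the class's
#'   own vertex versus the uniform profile.
#' @param auxInformativeTerms number of enriched terms per class block.
#' @param auxOnProb Bernoulli rate of informative terms in their own class.
#' @param auxBackgroundProb background Bernoulli rate of all other terms.
#' @param confusablePrimary,confusableAuxiliary lists of class-name pairs
#'   forced to share a primary centre / an auxiliary term block,
#'   making them unresolvable in that source.
#' @param seed integer seed governing the whole generation.
#' @return a validated list of class `"SimConfig"`.
#' @export
simConfig <- function(classSizes, unlabelledCount = 0L, S = 8L, T_ = 40L,
                      primaryConcentration = 20, primaryCentres = "auto",
                      separation = 0.6,
                      auxInformativeTerms = 6L, auxOnProb = 0.75,
                      auxBackgroundProb = 0.08,
                      confusablePrimary = list(),
                      confusableAuxiliary = list(),
                      seed = 1L) {
    if (is.null(names(classSizes)))
        names(classSizes) <- paste0("class", seq_along(classSizes))
    cfg <- list(classSizes = classSizes,
                unlabelledCount = as.integer(unlabelledCount),
                S = as.integer(S), T_ = as.integer(T_),
                primaryConcentration = primaryConcentration,
                primaryCentres = primaryCentres,
                separation = separation,
                auxInformativeTerms = as.integer(auxInformativeTerms),
                auxOnProb = auxOnProb,
                auxBackgroundProb = auxBackgroundProb,
                confusablePrimary = confusablePrimary,
                confusableAuxiliary = confusableAuxiliary,
                seed = as.integer(seed))
    class(cfg) <- "SimConfig"
    .validateSimConfig(cfg)
    cfg
}

.validateSimConfig <- function(cfg) {
    nc <- length(cfg$classSizes)
    if (nc < 2L) stop("at least two classes are required")
    if (any(cfg$classSizes < 1L)) stop("class sizes must be positive")
    if (cfg$S < 2L || cfg$T_ < 1L) stop("dimensions must be positive")
    probs <- c(cfg$auxOnProb, cfg$auxBackgroundProb, cfg$separation)
    if (any(probs < 0 | probs > 1))
        stop("probabilities must lie in [0, 1]")
    ## auxiliary blocks: one per group of auxiliary-confusable classes
    nBlocks <- nc - sum(lengths(cfg$confusableAuxiliary) - 1L)
    if (nBlocks * cfg$auxInformativeTerms > cfg$T_)
        stop("infeasible config: informative term blocks exceed T")
    classes <- names(cfg$classSizes)
    for (p in c(cfg$confusablePrimary, cfg$confusableAuxiliary))
        if (!all(p %in% classes))
            stop("confusable pair names unknown class(es): ",
                 paste(setdiff(p, classes), collapse = ", "))
    invisible(cfg)
}

## Group classes into sharing groups given a list of confusable pairs.
.shareGroups <- function(classes, pairs) {
    group <- stats::setNames(seq_along(classes), classes)
    for (p in pairs) group[group == group[p[2L]]] <- group[p[1L]]
    group
}

.rdirichlet <- function(n, alpha) {
    g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
                nrow = n, byrow = TRUE)
    g / rowSums(g)
}

#' Generate a synthetic paired dataset
#'
#' Draws labelled primary/auxiliary profiles per class and an unlabelled
#' pool from the same class mixture. Primary rows are non-negative and sum
#' to one; auxiliary rows are binary. The unlabelled pool's hidden class
#' membership is returned separately as the ground truth.
#'
#' @param config a [simConfig()] object.
#' @return list with `dataset` (a [PairedDataset] whose pool proteins are
#'   labelled `"unknown"`) and `truth` (named character: pool accession ->
#'   true class).
#' @export
generatePairedData <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    classes <- names(config$classSizes)
    nc <- length(classes)
    ## class centres on the simplex
    if (identical(config$primaryCentres, "auto")) {
        vert <- diag(config$S)[rep_len(seq_len(config$S), nc), ,
                               drop = FALSE]
        centres <- config$separation * vert +
            (1 - config$separation) / config$S
    } else {
        centres <- as.matrix(config$primaryCentres)
        stopifnot(nrow(centres) == nc, ncol(centres) == config$S)
    }
    rownames(centres) <- classes
    ## classes sharing a primary group inherit the representative's centre
    pGroup <- .shareGroups(classes, config$confusablePrimary)
    centres <- centres[unname(pGroup), , drop = FALSE]
    rownames(centres) <- classes
    ## auxiliary informative term blocks, shared within auxiliary groups
    aGroup <- .shareGroups(classes, config$confusableAuxiliary)
    uniqueGroups <- unique(aGroup)
    blockOf <- stats::setNames(match(aGroup, uniqueGroups), classes)
    blocks <- lapply(seq_along(uniqueGroups), function(g)
        ((g - 1L) * config$auxInformativeTerms + 1L):
        (g * config$auxInformativeTerms))
    drawClass <- function(cl, n, tagOffset) {
        prim <- .withSeed(.deriveSeed(config$seed,
                                      tagOffset + match(cl, classes)), {
            .rdirichlet(n, config$primaryConcentration * centres[cl, ])
        })
        aux <- .withSeed(.deriveSeed(config$seed,
                                     tagOffset + 100L + match(cl, classes)), {
            p <- rep(config$auxBackgroundProb, config$T_)
            p[blocks[[blockOf[cl]]]] <- config$auxOnProb
            matrix(stats::rbinom(n * config$T_, 1L,
                                 rep(p, each = n)), nrow = n)
        })
        list(prim = prim, aux = aux)
    }
    prim <- NULL; aux <- NULL; labels <- character(0)
    for (cl in classes) {
        d <- drawClass(cl, config$classSizes[[cl]], 0L)
        prim <- rbind(prim, d$prim)
        aux <- rbind(aux, d$aux)
        labels <- c(labels, rep(cl, config$classSizes[[cl]]))
    }
    truth <- character(0)
    if (config$unlabelledCount > 0L) {
        poolClasses <- .withSeed(.deriveSeed(config$seed, 900L), {
            sample(classes, config$unlabelledCount, replace = TRUE,
                   prob = config$classSizes / sum(config$classSizes))
        })
        for (cl in classes) {
            n <- sum(poolClasses == cl)
            if (n == 0L) next
            d <- drawClass(cl, n, 300L)
            prim <- rbind(prim, d$prim)
            aux <- rbind(aux, d$aux)
        }
        ## pool rows were appended grouped by class; record truth in order
        truth <- unlist(lapply(classes, function(cl)
            rep(cl, sum(poolClasses == cl))), use.names = FALSE)
        labels <- c(labels, rep(UNKNOWN_LABEL, length(truth)))
    }
    ids <- sprintf("prot%04d", seq_len(nrow(prim)))
    rownames(prim) <- ids
    rownames(aux) <- ids
    colnames(prim) <- sprintf("fraction%02d", seq_len(config$S))
    colnames(aux) <- sprintf("term%03d", seq_len(config$T_))
    ds <- pairedDataset(prim, aux, labels, classSet = classes)
    names(truth) <- ids[labels == UNKNOWN_LABEL]
    list(dataset = ds, truth = truth)
}

#' Two-source benchmark scenario configuration
#'
#' Builds a [simConfig()] in which the first half of the classes share
#' primary centres in consecutive pairs (so they are unresolvable in the
#' primary source but carry disjoint auxiliary term blocks) while the
#' second half share auxiliary term blocks in consecutive pairs (resolved
#' in primary only). Neither single source can classify all classes, so
#' transfer learning has headroom in both directions — the canonical
#' test-bed for the class-weight optimiser and the benchmark harness.
#'
#' @param nClasses even number of classes, >= 4.
#' @param classSize labelled proteins per class (default 40).
#' @param unlabelledCount unlabelled pool size (default 100).
#' @param seed integer seed.
#' @param ... further arguments passed to [simConfig()].
#' @return a `"SimConfig"` object.
#' @export
makeTwoSourceScenario <- function(nClasses = 4L, classSize = 40L,
                                  unlabelledCount = 100L, seed = 1L, ...) {
    if (nClasses %% 2L != 0L) stop("nClasses must be even")
    if (nClasses < 4L) stop("nClasses must be at least 4")
    classes <- paste0("class", seq_len(nClasses))
    half <- nClasses / 2L
    pairUp <- function(idx) {
        lapply(seq(1L, length(idx) - 1L, by = 2L),
               function(i) classes[idx[c(i, i + 1L)]])
    }
    simConfig(classSizes = stats::setNames(rep(classSize, nClasses),
                                           classes),
              unlabelledCount = unlabelledCount,
              confusablePrimary = pairUp(seq_len(half)),
              confusableAuxiliary = pairUp((half + 1L):nClasses),
              seed = seed, ...)
}
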