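#' @include AllGenerics.R
NULL

## Internal helpers: seeding, logging, small shared utilities.

## Derive a reproducible sub-seed from a base seed and an integer tag, kept
## inside the 32-bit signed range R requires for set.seed().
.deriveSeed <- function(seed, tag) {
    as.integer((as.numeric(seed) * 7919 + as.numeric(tag) * 104729) %%
               2147483647)
}

## Run `expr` under a local RNG state seeded with `seed`.
.withSeed <- function(seed, expr) {
    withr::with_seed(as.integer(seed), expr)
}

.logInfo <- function(fmt, ...) {
    message(sprintf("[spatialTL] %s", sprintf(fmt, ...)))
}

## Squared Euclidean cross-distances between the rows of two matrices.
.crossDist2 <- function(query, ref) {
    d2 <- outer(rowSums(query^2), rowSums(ref^2), "+") -
        2 * tcrossprod(query, ref)
    d2[d2 < 0] <- 0
    d2
}

## Labelled (non-"unknown") row indices of a PairedDataset.
.labelledIdx <- function(ds) which(ds@labels != UNKNOWN_LABEL)

## Argmax over the rows of a score matrix with deterministic tie-breaking:
## the first class in classSet order wins; ties are reported via a single
## warning naming how many rows were affected.
.argmaxClass <- function(scores, classes, warnTies = TRUE) {
    stopifnot(ncol(scores) == length(classes))
    best <- max.col(scores, ties.method = "first")
    if (warnTies) {
        nties <- sum(apply(scores, 1L, function(r) sum(r == max(r)) > 1L))
        if (nties > 0L)
            warning(sprintf("%d prediction(s) had tied top scores; assigned the first class in classSet order", nties),
                    call. = FALSE)
    }
    classes[best]
}

## Deterministic per-class shuffle used by the stratified partitioners.
.shuffle <- function(x) if (length(x) == 1L) x else sample(x)
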