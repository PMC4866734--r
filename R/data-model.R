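#' @include utils.R
NULL

#' Construct a PairedDataset
#'
#' Builds a validated [PairedDataset] from two feature matrices sharing the
#' same ordered row names and a label vector. Labels may be supplied as a
#' named vector (matched by accession) or positionally.
#'
#' @param primary numeric matrix with unique accession row names.
#' @param auxiliary numeric matrix, identical ordered row names.
#' @param labels character vector of class labels, `"unknown"` allowed;
#'   if named, matched against accessions (missing accessions become
#'   `"unknown"`).
#' @param classSet ordered class names; defaults to the sorted set of
#'   non-`"unknown"` labels observed.
#' @return a [PairedDataset].
#' @examples
#' p <- matrix(runif(12), 4, 3, dimnames = list(paste0("P", 1:4), NULL))
#' a <- matrix(rbinom(8, 1, .5), 4, 2, dimnames = list(paste0("P", 1:4), NULL))
#' pairedDataset(p, a, c("er", "er", "unknown", "golgi"))
#' @export
pairedDataset <- function(primary, auxiliary, labels,
                          classSet = NULL) {
    primary <- as.matrix(primary)
    auxiliary <- as.matrix(auxiliary)
    if (!is.null(names(labels))) {
        labels <- unname(labels[rownames(primary)])
        labels[is.na(labels)] <- UNKNOWN_LABEL
    }
    labels <- as.character(labels)
    if (is.null(classSet))
        classSet <- sort(setdiff(unique(labels), UNKNOWN_LABEL))
    methods::new("PairedDataset", primary = primary, auxiliary = auxiliary,
                 labels = labels, classSet = classSet)
}

## Row-subset of a PairedDataset by accession, preserving classSet.
.subsetPaired <- function(ds, ids) {
    idx <- match(ids, rownames(ds@primary))
    if (anyNA(idx))
        stop("unknown accessions requested: ",
             paste(utils::head(ids[is.na(idx)], 5L), collapse = ", "))
    methods::new("PairedDataset",
                 primary = ds@primary[idx, , drop = FALSE],
                 auxiliary = ds@auxiliary[idx, , drop = FALSE],
                 labels = ds@labels[idx],
                 classSet = ds@classSet)
}

#' Align a primary and an auxiliary matrix into a PairedDataset
#'
#' Restricts both matrices to the intersection of their accessions (kept in
#' primary row order), reports the number of rows dropped from each source,
#' and attaches labels; accessions absent from `labels` become `"unknown"`.
#'
#' @param primary numeric matrix, rows named by accession.
#' @param auxiliary numeric matrix, rows named by accession.
#' @param labels named character vector (accession -> class or `"unknown"`).
#' @param classSet optional ordered class names.
#' @return a [PairedDataset] over the shared accessions.
#' @details Accession matching is exact string equality; identifiers needing
#'   normalisation (e.g. isoform suffixes) must be cleaned upstream.
#' @examples
#' p <- matrix(1:6, 3, 2, dimnames = list(c("P1", "P2", "P3"), NULL))
#' a <- matrix(1:6, 3, 2, dimnames = list(c("P2", "P3", "P4"), NULL))
#' alignDatasets(p, a, c(P2 = "er", P3 = "unknown"))
#' @export
alignDatasets <- function(primary, auxiliary, labels, classSet = NULL) {
    primary <- as.matrix(primary)
    auxiliary <- as.matrix(auxiliary)
    if (nrow(primary) == 0L || nrow(auxiliary) == 0L)
        stop("both matrices must be non-empty")
    if (anyDuplicated(rownames(primary)) || anyDuplicated(rownames(auxiliary)))
        stop("duplicate accessions in input matrices")
    if (is.null(rownames(primary)) || is.null(rownames(auxiliary)))
        stop("both matrices must carry accession row names")
    shared <- rownames(primary)[rownames(primary) %in% rownames(auxiliary)]
    if (length(shared) == 0L)
        stop("alignment error: the primary and auxiliary accession sets are disjoint")
    dropP <- nrow(primary) - length(shared)
    dropA <- nrow(auxiliary) - length(shared)
    .logInfo("aligned %d shared proteins (dropped %d primary-only, %d auxiliary-only)",
             length(shared), dropP, dropA)
    lab <- stats::setNames(rep(UNKNOWN_LABEL, length(shared)), shared)
    if (!is.null(names(labels))) {
        hit <- intersect(shared, names(labels))
        lab[hit] <- labels[hit]
    } else stop("labels must be a named character vector")
    pairedDataset(primary[shared, , drop = FALSE],
                  auxiliary[shared, , drop = FALSE],
                  lab, classSet = classSet)
}

#' Partition a PairedDataset into labelled and unlabelled sections
#'
#' @param ds a [PairedDataset].
#' @return a list with elements `L` (proteins carrying a class label) and
#'   `U` (proteins labelled `"unknown"`); `U` may have zero rows.
#' @examples
#' ds <- pairedDataset(
#'   matrix(runif(8), 4, 2, dimnames = list(paste0("P", 1:4), NULL)),
#'   matrix(runif(8), 4, 2, dimnames = list(paste0("P", 1:4), NULL)),
#'   c("er", "golgi", "unknown", "er"))
#' str(splitLabelled(ds), max.level = 1)
#' @export
splitLabelled <- function(ds) {
    stopifnot(methods::is(ds, "PairedDataset"))
    lab <- .labelledIdx(ds)
    if (length(lab) == 0L)
        stop("no labelled proteins in the dataset")
    ids <- rownames(ds@primary)
    list(L = .subsetPaired(ds, ids[lab]),
         U = .subsetPaired(ds, ids[-lab]))
}

## Per-class training counts: floor(fraction * N_i) plus one extra for the
## classes with the largest fractional remainders until the rounded total
## train size is reached; remainder ties broken by class order.
.stratifiedCounts <- function(counts, fraction) {
    exact <- fraction * counts
    base <- floor(exact)
    slots <- round(fraction * sum(counts)) - sum(base)
    if (slots > 0) {
        rem <- exact - base
        extra <- order(-rem, seq_along(counts))[seq_len(slots)]
        base[extra] <- base[extra] + 1L
    }
    as.integer(base)
}

#' Stratified holdout split of the labelled proteins
#'
#' Draws a stratified train/test partition of the labelled section of a
#' paired dataset: each class contributes `fraction` of its members to the
#' training set (within one protein, by largest-remainder rounding), so the
#' relative class proportions of the full labelled set are preserved in both
#' partitions.
#'
#' @param L a [PairedDataset] whose proteins are all labelled.
#' @param fraction training fraction in (0, 1); 0.8 gives the usual 80/20
#'   generalisation-assessment split.
#' @param seed integer seed; the plan is deterministic given the seed.
#' @return a [SplitPlan].
#' @export
stratifiedHoldout <- function(L, fraction = 0.8, seed = 1L) {
    stopifnot(methods::is(L, "PairedDataset"))
    if (fraction <= 0 || fraction >= 1)
        stop("fraction must lie in (0, 1)")
    labels <- L@labels
    if (any(labels == UNKNOWN_LABEL))
        stop("stratifiedHoldout expects a fully labelled dataset; use splitLabelled() first")
    counts <- table(factor(labels, levels = L@classSet))
    if (any(counts < 2L))
        stop("stratification error: class(es) with fewer than 2 members: ",
             paste(names(counts)[counts < 2L], collapse = ", "))
    ntrain <- .stratifiedCounts(as.integer(counts), fraction)
    ids <- rownames(L@primary)
    .withSeed(seed, {
        train <- unlist(lapply(seq_along(L@classSet), function(i) {
            members <- ids[labels == L@classSet[i]]
            .shuffle(members)[seq_len(ntrain[i])]
        }), use.names = FALSE)
    })
    methods::new("SplitPlan", train = train, test = setdiff(ids, train),
                 fraction = fraction, seed = as.integer(seed))
}

#' Stratified k-fold partition of the labelled proteins
#'
#' @param L a fully labelled [PairedDataset].
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return a list of `k` [SplitPlan] objects; each plan's test set is one
#'   fold, its training set the remaining folds. Folds are disjoint, cover
#'   the dataset, and per-class fold counts differ by at most one.
#' @export
stratifiedKfold <- function(L, k = 5L, seed = 1L) {
    stopifnot(methods::is(L, "PairedDataset"))
    labels <- L@labels
    if (any(labels == UNKNOWN_LABEL))
        stop("stratifiedKfold expects a fully labelled dataset")
    counts <- table(factor(labels, levels = L@classSet))
    small <- names(counts)[counts < k]
    if (length(small))
        stop("stratification error: class(es) smaller than k = ", k, ": ",
             paste(small, collapse = ", "))
    ids <- rownames(L@primary)
    fold <- integer(length(ids))
    .withSeed(seed, {
        for (cl in L@classSet) {
            idx <- which(labels == cl)
            idx <- .shuffle(idx)
            fold[idx] <- rep_len(seq_len(k), length(idx))
        }
    })
    lapply(seq_len(k), function(f) {
        methods::new("SplitPlan",
                     train = ids[fold != f], test = ids[fold == f],
                     fraction = (k - 1) / k, seed = as.integer(seed))
    })
}

#' Read a feature matrix from a delimited file
#'
#' Expects a header row of feature names and a first column of protein
#' accessions. The delimiter is inferred from the extension (`.csv` comma,
#' otherwise tab).
#'
#' @param path file path.
#' @param sep optional explicit field separator.
#' @return numeric matrix with accession row names.
#' @export
readFeatureMatrix <- function(path, sep = NULL) {
    if (is.null(sep))
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             comment.char = "")
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids))
        stop("format error: duplicate accessions in ", path)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (anyNA(m))
        stop("missing values in ", path, "; profiles must be complete")
    .logInfo("read %s: %d proteins x %d features", basename(path),
             nrow(m), ncol(m))
    m
}

#' Write a feature matrix as TSV
#'
#' Inverse of [readFeatureMatrix()]; the first column is the accession.
#'
#' @param m numeric matrix with row names.
#' @param path output file path.
#' @param idColumn name for the accession column.
#' @export
writeFeatureMatrix <- function(m, path, idColumn = "accession") {
    if (is.null(colnames(m)))
        colnames(m) <- paste0("feature", seq_len(ncol(m)))
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c(idColumn, colnames(m))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a marker file
#'
#' Two-column delimited file: accession, class label (`"unknown"` allowed).
#'
#' @param path file path.
#' @param sep optional field separator (default inferred as in
#'   [readFeatureMatrix()]).
#' @param header whether the file carries a header row (default `TRUE`).
#' @return named character vector accession -> label.
#' @export
readMarkerFile <- function(path, sep = NULL, header = TRUE) {
    if (is.null(sep))
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = header, sep = sep,
                             stringsAsFactors = FALSE, comment.char = "")
    if (ncol(tab) < 2L)
        stop("marker file must have two columns: accession, class")
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids))
        stop("format error: duplicate accessions in marker file")
    lab <- stats::setNames(as.character(tab[[2L]]), ids)
    .logInfo("read %s: %d proteins, %d labelled", basename(path),
             length(lab), sum(lab != UNKNOWN_LABEL))
    lab
}
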