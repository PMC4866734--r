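## Central S4 classes. The data model mirrors the paired-source notation used
## throughout spatial proteomics transfer learning: a primary quantitative
## matrix (proteins x S gradient-occupancy features) and an auxiliary matrix
## (proteins x T heterogeneous features, typically binary GO CC terms) over
## one shared, ordered protein set, plus a marker map assigning each protein
## either a sub-cellular class or the distinguished token "unknown".

#' Token marking proteins of unknown localisation
#'
#' @keywords internal
UNKNOWN_LABEL <- "unknown"

.validFeatureMatrix <- function(x, what) {
    msg <- NULL
    if (!is.matrix(x) || !is.numeric(x))
        msg <- c(msg, sprintf("%s must be a numeric matrix", what))
    else {
        if (nrow(x) > 0L &&
            (is.null(rownames(x)) || anyDuplicated(rownames(x))))
            msg <- c(msg, sprintf("%s must have unique row names (accessions)",
                                  what))
        if (ncol(x) < 1L)
            msg <- c(msg, sprintf("%s must have at least one feature", what))
        if (anyNA(x))
            msg <- c(msg, sprintf("%s contains missing values; impute or drop upstream", what))
    }
    msg
}

#' PairedDataset: aligned primary/auxiliary data over one protein set
#'
#' Holds a primary feature matrix (e.g. LOPIT density-gradient profiles,
#' proteins x S fractions) and an auxiliary feature matrix (e.g. a binary
#' GO CC term incidence matrix, proteins x T terms) whose rows refer to the
#' same proteins in the same order, together with a label vector over the
#' shared accessions. Proteins labelled `"unknown"` form the unlabelled
#' pool; all other labels must belong to `classSet`.
#'
#' @slot primary numeric matrix, rows named by protein accession.
#' @slot auxiliary numeric matrix, same row names and order as `primary`.
#' @slot labels character vector, one label per row (`"unknown"` allowed).
#' @slot classSet ordered character vector of sub-cellular class names.
#'
#' @seealso [pairedDataset()], [alignDatasets()], [splitLabelled()]
#' @exportClass PairedDataset
setClass("PairedDataset",
    representation(primary = "matrix",
                   auxiliary = "matrix",
                   labels = "character",
                   classSet = "character"),
    validity = function(object) {
        msg <- c(.validFeatureMatrix(object@primary, "primary"),
                 .validFeatureMatrix(object@auxiliary, "auxiliary"))
        if (is.null(msg)) {
            if (!identical(rownames(object@primary), rownames(object@auxiliary)))
                msg <- c(msg, "primary and auxiliary must share identical ordered row names")
            if (length(object@labels) != nrow(object@primary))
                msg <- c(msg, "labels length must equal the number of proteins")
            known <- setdiff(unique(object@labels), UNKNOWN_LABEL)
            if (!all(known %in% object@classSet))
                msg <- c(msg, sprintf("labels outside classSet: %s",
                                      paste(setdiff(known, object@classSet),
                                            collapse = ", ")))
            if (anyDuplicated(object@classSet))
                msg <- c(msg, "classSet contains duplicated class names")
        }
        if (is.null(msg)) TRUE else msg
    })

#' SplitPlan: a stratified train/test partition of labelled proteins
#'
#' @slot train,test disjoint character vectors of accessions whose union is
#'   the labelled protein set the plan was built from.
#' @slot fraction training fraction in (0, 1).
#' @slot seed integer seed the plan was drawn with.
#'
#' @seealso [stratifiedHoldout()], [stratifiedKfold()]
#' @exportClass SplitPlan
setClass("SplitPlan",
    representation(train = "character", test = "character",
                   fraction = "numeric", seed = "integer"),
    validity = function(object) {
        msg <- NULL
        if (length(intersect(object@train, object@test)) > 0L)
            msg <- c(msg, "train and test overlap")
        if (length(object@fraction) != 1L ||
            object@fraction <= 0 || object@fraction >= 1)
            msg <- c(msg, "fraction must lie in (0, 1)")
        if (is.null(msg)) TRUE else msg
    })

#' KnnTlModel: the class-weighted k-NN transfer-learning classifier
#'
#' Stores the per-source neighbourhood sizes `kP` and `kA`, the per-class
#' weight vector theta (theta[i] = 1 uses only primary neighbours for class
#' i, theta[i] = 0 only auxiliary neighbours) and references to the labelled
#' training data from both sources.
#'
#' @slot kP,kA positive integer neighbourhood sizes for the primary and
#'   auxiliary source.
#' @slot theta numeric vector of per-class weights in \[0, 1\], named by class.
#' @slot trainPrimary,trainAuxiliary labelled training matrices.
#' @slot trainLabels class labels of the training rows.
#' @slot classSet ordered class names.
#'
#' @seealso [trainKnnTl()], [optimiseK()], [optimiseTheta()]
#' @exportClass KnnTlModel
setClass("KnnTlModel",
    representation(kP = "integer", kA = "integer", theta = "numeric",
                   trainPrimary = "matrix", trainAuxiliary = "matrix",
                   trainLabels = "character", classSet = "character"),
    validity = function(object) {
        msg <- NULL
        if (object@kP < 1L || object@kA < 1L)
            msg <- c(msg, "kP and kA must be positive")
        if (length(object@theta) != length(object@classSet))
            msg <- c(msg, "theta must have one weight per class")
        if (any(object@theta < 0 | object@theta > 1))
            msg <- c(msg, "theta weights must lie in [0, 1]")
        if (object@kP > nrow(object@trainPrimary) ||
            object@kA > nrow(object@trainAuxiliary))
            msg <- c(msg, "k exceeds the number of labelled training rows")
        if (is.null(msg)) TRUE else msg
    })

#' BinaryLPModel: one pairwise two-kernel 1-norm LP-SVM
#'
#' The solution of the sparse linear-programming SVM separating one pair of
#' classes: non-negative kernel expansion coefficients for each source and a
#' free offset. When the linear programme reported no solution the model
#' instead records a fallback class (the most common class in its labelled
#' data) and predicts it unconditionally.
#'
#' @slot alphaP,alphaA non-negative coefficient vectors (length m); empty for
#'   fallback models.
#' @slot b real offset.
#' @slot y numeric +1/-1 training labels.
#' @slot trainIds accessions of the m training rows, in order.
#' @slot classPos,classNeg class names encoded as +1 and -1.
#' @slot objective optimal LP objective value (NA for fallback models).
#' @slot fallbackClass length-zero, or the class predicted unconditionally.
#'
#' @seealso [trainBinaryTL()], [trainBinarySingle()], [decisionValue()]
#' @exportClass BinaryLPModel
setClass("BinaryLPModel",
    representation(alphaP = "numeric", alphaA = "numeric", b = "numeric",
                   y = "numeric", trainIds = "character",
                   classPos = "character", classNeg = "character",
                   objective = "numeric", fallbackClass = "character"),
    validity = function(object) {
        msg <- NULL
        fallback <- length(object@fallbackClass) == 1L
        if (fallback && (length(object@alphaP) || length(object@alphaA)))
            msg <- c(msg, "fallback models must carry empty coefficient vectors")
        if (!fallback) {
            if (any(object@alphaP < -1e-9) || any(object@alphaA < -1e-9))
                msg <- c(msg, "alpha coefficients must be non-negative")
            if (length(object@alphaP) != length(object@y))
                msg <- c(msg, "alphaP length must match the training labels")
        }
        if (!all(object@y %in% c(-1, 1)))
            msg <- c(msg, "y must be coded +1/-1")
        if (is.null(msg)) TRUE else msg
    })

#' SvmTlModel: one-vs-one multiclass two-kernel LP-SVM
#'
#' A pairwise decomposition of the multiclass problem: one [BinaryLPModel]
#' and one Platt sigmoid per unordered class pair, plus the Gaussian kernel
#' parameters and the labelled training data needed to evaluate kernels at
#' prediction time. `sources` records whether both kernels ("both") or a
#' single source ("primary"/"auxiliary") entered the latent function.
#'
#' @slot models named list of [BinaryLPModel], one per class pair "i|j".
#' @slot platt named list of c(A, B) sigmoid parameters per pair.
#' @slot classSet ordered class names.
#' @slot C,gammaP,gammaA kernel/regularisation parameters.
#' @slot sources "both", "primary" or "auxiliary".
#' @slot trainPrimary,trainAuxiliary labelled training matrices.
#' @slot trainLabels training class labels.
#'
#' @seealso [trainSvmTl()], [gridSearchSvmTl()]
#' @exportClass SvmTlModel
setClass("SvmTlModel",
    representation(models = "list", platt = "list", classSet = "character",
                   C = "numeric", gammaP = "numeric", gammaA = "numeric",
                   sources = "character",
                   trainPrimary = "matrix", trainAuxiliary = "matrix",
                   trainLabels = "character"),
    validity = function(object) {
        msg <- NULL
        nc <- length(object@classSet)
        if (length(object@models) != nc * (nc - 1L) / 2L)
            msg <- c(msg, "expected one binary model per unordered class pair")
        if (!object@sources %in% c("both", "primary", "auxiliary"))
            msg <- c(msg, "sources must be 'both', 'primary' or 'auxiliary'")
        if (is.null(msg)) TRUE else msg
    })

#' BenchmarkResult: per-round generalisation scores for one classifier arm
#'
#' Macro F1 and class-specific F1 scores across repeated stratified 80/20
#' rounds, for one classifier configuration.
#'
#' @slot classifier descriptor, e.g. "knn_tl" or "svm_primary".
#' @slot macroF1 numeric vector, one macro F1 per round.
#' @slot classF1 matrix rounds x classes of class-specific F1 scores.
#' @slot seeds integer per-round seeds (shared across arms for pairing).
#' @slot config list of the configuration the arm ran with.
#'
#' @seealso [benchmarkClassifiers()]
#' @exportClass BenchmarkResult
setClass("BenchmarkResult",
    representation(classifier = "character", macroF1 = "numeric",
                   classF1 = "matrix", seeds = "integer", config = "list"),
    validity = function(object) {
        msg <- NULL
        if (length(object@macroF1) != nrow(object@classF1))
            msg <- c(msg, "macroF1 length must equal the classF1 row count")
        if (is.null(msg)) TRUE else msg
    })
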