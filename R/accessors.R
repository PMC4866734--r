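#' @include utils.R
NULL

#' @rdname accessors
#' @export
setMethod("primaryData", "PairedDataset", function(object) object@primary)

#' @rdname accessors
#' @export
setMethod("auxiliaryData", "PairedDataset", function(object) object@auxiliary)

#' @rdname accessors
#' @export
setMethod("markerLabels", "PairedDataset", function(object) {
    stats::setNames(object@labels, rownames(object@primary))
})

#' @rdname accessors
#' @export
setMethod("classSet", "PairedDataset", function(object) object@classSet)

#' @rdname accessors
#' @export
setMethod("classSet", "KnnTlModel", function(object) object@classSet)

#' @rdname accessors
#' @export
setMethod("classSet", "SvmTlModel", function(object) object@classSet)

#' @rdname accessors
#' @export
setMethod("proteinIds", "PairedDataset", function(object) {
    rownames(object@primary)
})

#' @rdname accessors
#' @export
setMethod("trainIds", "SplitPlan", function(plan) plan@train)

#' @rdname accessors
#' @export
setMethod("testIds", "SplitPlan", function(plan) plan@test)

#' @export
setMethod("show", "PairedDataset", function(object) {
    lab <- .labelledIdx(object)
    cat("PairedDataset with", nrow(object@primary), "proteins\n")
    cat(" primary  :", ncol(object@primary), "features\n")
    cat(" auxiliary:", ncol(object@auxiliary), "features\n")
    cat(" labelled :", length(lab), " unlabelled:",
        nrow(object@primary) - length(lab), "\n")
    cat(" classes  :", paste(object@classSet, collapse = ", "), "\n")
    invisible(NULL)
})

#' @export
setMethod("show", "SplitPlan", function(object) {
    cat("SplitPlan:", length(object@train), "train /",
        length(object@test), "test (fraction",
        object@fraction, ", seed", object@seed, ")\n")
    invisible(NULL)
})

#' @export
setMethod("show", "KnnTlModel", function(object) {
    cat("KnnTlModel (class-weighted k-NN transfer learning)\n")
    cat(" kP =", object@kP, " kA =", object@kA, "\n")
    cat(" theta:", paste(sprintf("%s=%.3g", object@classSet, object@theta),
                         collapse = ", "), "\n")
    cat(" trained on", nrow(object@trainPrimary), "labelled proteins\n")
    invisible(NULL)
})

#' @export
setMethod("show", "BinaryLPModel", function(object) {
    if (length(object@fallbackClass)) {
        cat("BinaryLPModel [fallback]: predicts", object@fallbackClass, "\n")
    } else {
        cat("BinaryLPModel:", object@classPos, "(+1) vs",
            object@classNeg, "(-1)\n")
        cat(sprintf(" m = %d, nonzero alphaP = %d, nonzero alphaA = %d, b = %.4g\n",
                    length(object@y), sum(object@alphaP > 1e-8),
                    sum(object@alphaA > 1e-8), object@b))
    }
    invisible(NULL)
})

#' @export
setMethod("show", "SvmTlModel", function(object) {
    cat("SvmTlModel (one-vs-one two-kernel 1-norm LP-SVM)\n")
    cat(" sources:", object@sources, "\n")
    cat(sprintf(" C = %g, gammaP = %g, gammaA = %g\n",
                object@C, object@gammaP, object@gammaA))
    cat(" classes:", paste(object@classSet, collapse = ", "), "\n")
    cat(" pairwise models:", length(object@models), "\n")
    invisible(NULL)
})

#' @export
setMethod("show", "BenchmarkResult", function(object) {
    cat("BenchmarkResult:", object@classifier, "over",
        length(object@macroF1), "rounds\n")
    cat(sprintf(" macro F1 median %.3f (IQR %.3f-%.3f)\n",
                stats::median(object@macroF1),
                stats::quantile(object@macroF1, 0.25),
                stats::quantile(object@macroF1, 0.75)))
    invisible(NULL)
})
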