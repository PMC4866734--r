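## Shared in-code fixtures for the test suite.

## A tiny deterministic paired dataset: `sizes` labelled proteins per class,
## Gaussian primary clusters at the given 2-D centres, binary auxiliary with
## one informative term block per class.
makeToyPaired <- function(sizes = c(a = 10, b = 10),
                          centres = rbind(c(0, 0), c(4, 4)),
                          sdev = 0.3, nTerms = 6, seed = 1) {
    classes <- names(sizes)
    withr::with_seed(seed, {
        prim <- NULL; aux <- NULL; labels <- character(0)
        for (i in seq_along(classes)) {
            n <- sizes[[i]]
            prim <- rbind(prim, cbind(rnorm(n, centres[i, 1], sdev),
                                      rnorm(n, centres[i, 2], sdev)))
            block <- matrix(rbinom(n * nTerms, 1, 0.1), n, nTerms)
            block[, seq(2 * i - 1, 2 * i)] <- rbinom(n * 2, 1, 0.9)
            aux <- rbind(aux, block)
            labels <- c(labels, rep(classes[i], n))
        }
        ids <- sprintf("P%03d", seq_len(nrow(prim)))
        rownames(prim) <- ids; rownames(aux) <- ids
        pairedDataset(prim, aux, labels, classSet = classes)
    })
}

## Separable two-class toy with both sources informative; returns kernels
## and +1/-1 labels ready for the binary LP trainers.
makeSeparableKernels <- function(m = 20, gamma = 1, seed = 5) {
    withr::with_seed(seed, {
        x <- rbind(matrix(rnorm(m, 0, 0.4), m / 2, 2),
                   matrix(rnorm(m, 3, 0.4), m / 2, 2))
        v <- rbind(matrix(rnorm(m, 1, 0.4), m / 2, 2),
                   matrix(rnorm(m, -2, 0.4), m / 2, 2))
        rownames(x) <- rownames(v) <- sprintf("P%02d", seq_len(m))
        y <- rep(c(1, -1), each = m / 2)
        list(x = x, v = v, y = y,
             KP = gaussianKernel(x, gamma = gamma),
             KA = gaussianKernel(v, gamma = gamma))
    })
}

## Independent LP oracle: solve min obj'x s.t. Ax >= rhs, x >= 0 with an
## unrelated solver (SciPy's HiGHS interior-point/simplex via the system
## python), exchanging the problem as JSON.
oracleLpObjective <- function(obj, A, rhs) {
    infile <- tempfile(fileext = ".json")
    outfile <- tempfile(fileext = ".json")
    writeLines(jsonlite::toJSON(list(obj = obj, A = A, rhs = rhs),
                                digits = NA), infile)
    code <- paste(
        "import json, sys",
        "from scipy.optimize import linprog",
        "d = json.load(open(sys.argv[1]))",
        "res = linprog(d['obj'], A_ub=[[-a for a in row] for row in d['A']],",
        "              b_ub=[-b for b in d['rhs']], method='highs')",
        "json.dump({'status': int(res.status),",
        "           'objective': res.fun if res.fun is not None else None},",
        "          open(sys.argv[2], 'w'))", sep = "\n")
    status <- system2("python", c("-c", shQuote(code), infile, outfile))
    stopifnot(status == 0)
    res <- jsonlite::fromJSON(outfile)
    stopifnot(res$status == 0)
    res$objective
}

## Assemble the two-kernel 1-norm SVM linear programme from scratch
## (independently of the package internals) as (obj, A, rhs).
assembleSvmLp <- function(KP, KA, y, C) {
    m <- length(y)
    npos <- sum(y > 0); nneg <- sum(y < 0)
    Cvec <- ifelse(y > 0, C * nneg / npos, C * npos / nneg)
    YY <- outer(y, y)
    A <- cbind(YY * KP, YY * KA, diag(m), y, -y)
    list(obj = c(rep(1, 2 * m), Cvec, 0, 0), A = A, rhs = rep(1, m))
}
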