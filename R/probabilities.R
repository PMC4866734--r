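#' @include utils.R
NULL

## Probabilistic outputs for the binary and multiclass LP-SVM: a Platt
## sigmoid fitted to decision values by regularised maximum likelihood
## (with the Lin et al. target-value correction and their robust Newton
## iteration), and the iterative pairwise-coupling fixed point that turns
## one-vs-one pairwise probabilities into a single multiclass distribution.

## Sigmoid evaluated stably: P(y = +1 | f) = 1 / (1 + exp(A f + B)).
.plattProb <- function(f, A, B) {
    fApB <- A * f + B
    ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

#' Fit a Platt sigmoid to decision values
#'
#' Fits `P(y = +1 | f) = 1 / (1 + exp(A f + B))` by regularised maximum
#' likelihood with the corrected target values `t+ = (n+ + 1)/(n+ + 2)`
#' and `t- = 1/(n- + 2)`, using the damped Newton iteration of Lin et al.
#'
#' @param f numeric decision values.
#' @param y labels; +1/-1 (anything positive is treated as +1).
#' @return named numeric vector `c(A, B)`.
#' @export
fitPlatt <- function(f, y) {
    if (any(!is.finite(f)))
        stop("decision values must be finite")
    pos <- y > 0
    if (!any(pos) || all(pos))
        stop("both classes must be present")
    prior1 <- sum(pos); prior0 <- sum(!pos)
    hiTarget <- (prior1 + 1) / (prior1 + 2)
    loTarget <- 1 / (prior0 + 2)
    t <- ifelse(pos, hiTarget, loTarget)
    A <- 0
    B <- log((prior0 + 1) / (prior1 + 1))
    sigma <- 1e-12      # Hessian ridge
    eps <- 1e-5
    fval <- function(A, B) {
        fApB <- A * f + B
        sum(ifelse(fApB >= 0,
                   t * fApB + log1p(exp(-fApB)),
                   (t - 1) * fApB + log1p(exp(fApB))))
    }
    Fv <- fval(A, B)
    for (it in seq_len(100L)) {
        fApB <- A * f + B
        p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                    1 / (1 + exp(fApB)))
        q <- 1 - p
        d2 <- p * q
        h11 <- sigma + sum(f * f * d2)
        h22 <- sigma + sum(d2)
        h21 <- sum(f * d2)
        d1 <- t - p
        g1 <- sum(f * d1)
        g2 <- sum(d1)
        if (abs(g1) < eps && abs(g2) < eps) break
        det <- h11 * h22 - h21 * h21
        dA <- -(h22 * g1 - h21 * g2) / det
        dB <- -(-h21 * g1 + h11 * g2) / det
        gd <- g1 * dA + g2 * dB
        step <- 1
        repeat {
            newA <- A + step * dA
            newB <- B + step * dB
            newF <- fval(newA, newB)
            if (newF < Fv + 1e-4 * step * gd) {
                A <- newA; B <- newB; Fv <- newF
                break
            }
            step <- step / 2
            if (step < 1e-10) {
                warning("Platt fit line search failed; returning current estimate",
                        call. = FALSE)
                return(c(A = A, B = B))
            }
        }
    }
    c(A = A, B = B)
}

#' Couple pairwise probabilities into a multiclass distribution
#'
#' Solves the pairwise-coupling fixed point (the second method of Wu, Lin
#' and Weng, as used by LIBSVM): given `r[i, j] = P(class i | i vs j)` for
#' all class pairs, finds the probability vector `p` minimising the coupled
#' inconsistency, by the sequential iterative update.
#'
#' @param R square matrix of pairwise probabilities with
#'   `R[j, i] = 1 - R[i, j]` and entries in (0, 1); the diagonal is
#'   ignored.
#' @param tol fixed-point tolerance (default 1e-10).
#' @param maxIter iteration cap; non-convergence is an error reporting the
#'   final iterate.
#' @return probability vector over the classes (sums to 1).
#' @examples
#' p <- c(0.5, 0.3, 0.2)
#' R <- outer(p, p, function(a, b) a / (a + b))
#' pairwiseCoupling(R)  # recovers p
#' @export
pairwiseCoupling <- function(R, tol = 1e-10, maxIter = 1000L) {
    k <- nrow(R)
    stopifnot(ncol(R) == k, k >= 2L)
    off <- row(R) != col(R)
    if (any(R[off] <= 0 | R[off] >= 1))
        stop("pairwise probabilities must lie strictly in (0, 1)")
    if (max(abs((R + t(R))[off] - 1)) > 1e-6)
        stop("R[j, i] must equal 1 - R[i, j]")
    Q <- matrix(0, k, k)
    for (i in seq_len(k)) {
        for (j in seq_len(k)) {
            if (i == j) {
                Q[i, i] <- sum(R[setdiff(seq_len(k), i), i]^2)
            } else {
                Q[i, j] <- -R[j, i] * R[i, j]
            }
        }
    }
    p <- rep(1 / k, k)
    for (it in seq_len(maxIter)) {
        Qp <- as.vector(Q %*% p)
        pQp <- sum(p * Qp)
        if (max(abs(Qp - pQp)) < tol) {
            names(p) <- rownames(R)
            return(p / sum(p))
        }
        for (i in seq_len(k)) {
            diff <- (-Qp[i] + pQp) / Q[i, i]
            p[i] <- p[i] + diff
            pQp <- (pQp + diff * (diff * Q[i, i] + 2 * Qp[i])) /
                (1 + diff)^2
            Qp <- (Qp + diff * Q[, i]) / (1 + diff)
            p <- p / (1 + diff)
        }
    }
    stop("pairwise coupling did not converge; final iterate: ",
         paste(sprintf("%.6g", p), collapse = ", "))
}
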