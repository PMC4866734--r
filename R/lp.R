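#' @include utils.R
NULL

## Dense two-phase primal simplex for linear programmes of the form
##
##     min  c'x   subject to  A x >= b,  x >= 0.
##
## This is all the 1-norm SVM training needs: the m margin constraints with
## explicit slack variables, non-negative kernel coefficients and the offset
## encoded as the difference of two non-negative variables. For that
## programme the slack columns form an identity block with positive
## right-hand side, so the caller can pass them as a starting `basis` and
## skip phase 1 entirely; generic calls without a basis run a phase-1
## artificial-variable feasibility search, which is also what detects
## genuinely infeasible programmes.
##
## Pivoting uses Dantzig's rule with a switch to Bland's rule (finite
## termination) once the iteration count passes a degeneracy guard.

.simplexIterate <- function(Tm, b, cost, basis, tol = 1e-9,
                            maxit = 20000L) {
    m <- nrow(Tm)
    bland <- FALSE
    guard <- 20L * (m + ncol(Tm))
    for (it in seq_len(maxit)) {
        if (it > guard) bland <- TRUE
        red <- cost - as.vector(crossprod(cost[basis], Tm))
        red[basis] <- 0
        if (bland) {
            ent <- which(red < -tol)
            if (length(ent) == 0L)
                return(list(status = "optimal", T = Tm, b = b, basis = basis))
            j <- ent[1L]
        } else {
            j <- which.min(red)
            if (red[j] >= -tol)
                return(list(status = "optimal", T = Tm, b = b, basis = basis))
        }
        col <- Tm[, j]
        pos <- which(col > tol)
        if (length(pos) == 0L)
            return(list(status = "unbounded"))
        ratio <- b[pos] / col[pos]
        leave <- pos[ratio == min(ratio)]
        ## ties towards the smallest basis index (anti-cycling friendly)
        i <- leave[which.min(basis[leave])]
        piv <- Tm[i, j]
        Tm[i, ] <- Tm[i, ] / piv
        b[i] <- b[i] / piv
        other <- setdiff(seq_len(m), i)
        fac <- Tm[other, j]
        Tm[other, ] <- Tm[other, , drop = FALSE] -
            tcrossprod(fac, Tm[i, ])
        b[other] <- b[other] - fac * b[i]
        b[b < 0 & b > -tol] <- 0
        basis[i] <- j
    }
    list(status = "maxit")
}

## Solve min c'x s.t. Ax >= b, x >= 0. `basis`, when given, must index
## columns of A forming an identity block with b >= 0 on those rows.
## Returns list(status, x, objective); status is one of "optimal",
## "infeasible", "unbounded", "maxit".
.lpSimplex <- function(obj, A, rhs, basis = NULL, tol = 1e-9,
                       maxit = 20000L) {
    m <- nrow(A)
    n <- ncol(A)
    Tm <- cbind(A, -diag(m))
    b <- as.numeric(rhs)
    neg <- b < 0
    if (any(neg)) {
        Tm[neg, ] <- -Tm[neg, , drop = FALSE]
        b[neg] <- -b[neg]
    }
    ncols <- n + m
    cost <- c(as.numeric(obj), rep(0, m))
    if (is.null(basis)) {
        basis <- integer(m)
        basis[neg] <- n + which(neg)      # surplus entered with +1 sign
        needArt <- which(!neg)
        if (length(needArt)) {
            Art <- matrix(0, m, length(needArt))
            Art[cbind(needArt, seq_along(needArt))] <- 1
            Tm <- cbind(Tm, Art)
            basis[needArt] <- ncols + seq_along(needArt)
            c1 <- c(rep(0, ncols), rep(1, length(needArt)))
            ph1 <- .simplexIterate(Tm, b, c1, basis, tol, maxit)
            if (ph1$status != "optimal")
                return(list(status = ph1$status))
            if (sum(c1[ph1$basis] * ph1$b) > 1e-7)
                return(list(status = "infeasible"))
            Tm <- ph1$T; b <- ph1$b; basis <- ph1$basis
            ## drive any residual zero-valued artificials out of the basis
            artRows <- which(basis > ncols)
            dropRows <- integer(0)
            for (i in artRows) {
                cand <- which(abs(Tm[i, seq_len(ncols)]) > tol)
                cand <- setdiff(cand, basis)
                if (length(cand)) {
                    j <- cand[1L]
                    piv <- Tm[i, j]
                    Tm[i, ] <- Tm[i, ] / piv
                    b[i] <- b[i] / piv
                    other <- setdiff(seq_len(nrow(Tm)), i)
                    fac <- Tm[other, j]
                    Tm[other, ] <- Tm[other, , drop = FALSE] -
                        tcrossprod(fac, Tm[i, ])
                    b[other] <- b[other] - fac * b[i]
                    basis[i] <- j
                } else dropRows <- c(dropRows, i)   # redundant constraint
            }
            if (length(dropRows)) {
                keep <- setdiff(seq_len(nrow(Tm)), dropRows)
                Tm <- Tm[keep, , drop = FALSE]
                b <- b[keep]
                basis <- basis[keep]
            }
            Tm <- Tm[, seq_len(ncols), drop = FALSE]
        }
    }
    res <- .simplexIterate(Tm, b, cost, basis, tol, maxit)
    if (res$status != "optimal")
        return(list(status = res$status))
    x <- numeric(ncols)
    x[res$basis] <- res$b
    list(status = "optimal",
         x = x[seq_len(n)],
         objective = sum(cost[seq_len(ncols)] * x))
}
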