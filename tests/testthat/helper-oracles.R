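## Independent reference implementations used as test oracles.

## Platt sigmoid: minimise the same regularised maximum-likelihood
## objective (corrected targets) with a generic quasi-Newton optimiser
## instead of the package's damped Newton iteration.
refPlatt <- function(f, y) {
    pos <- y > 0
    hi <- (sum(pos) + 1) / (sum(pos) + 2)
    lo <- 1 / (sum(!pos) + 2)
    t <- ifelse(pos, hi, lo)
    nll <- function(par) {
        fApB <- par[1] * f + par[2]
        sum(ifelse(fApB >= 0,
                   t * fApB + log1p(exp(-fApB)),
                   (t - 1) * fApB + log1p(exp(fApB))))
    }
    stats::optim(c(0, 0), nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))$par
}

## Brute-force F1 from first-principles confusion counts.
bruteF1 <- function(truth, predicted, classes) {
    f1 <- vapply(classes, function(cl) {
        tp <- sum(truth == cl & predicted == cl)
        fp <- sum(truth != cl & predicted == cl)
        fn <- sum(truth == cl & predicted != cl)
        if (tp == 0) return(0)
        prec <- tp / (tp + fp); rec <- tp / (tp + fn)
        2 * prec * rec / (prec + rec)
    }, numeric(1))
    list(perClassF1 = f1, macroF1 = mean(f1))
}
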