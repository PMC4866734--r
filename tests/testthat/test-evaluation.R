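test_that("f1Scores follows the precision/recall definitions", {
    expect_equal(f1Scores(c("a", "b"), c("a", "b"), c("a", "b"))$macroF1, 1)

    ## a class with tp = 8, fp = 2, fn = 4: F1 = 8/11
    truth <- c(rep("a", 12), rep("b", 10))
    pred <- c(rep("a", 8), rep("b", 4), rep("a", 2), rep("b", 8))
    rep_ <- f1Scores(truth, pred, c("a", "b"))
    expect_equal(rep_$perClassF1[["a"]], 8 / 11)
    expect_equal(rep_$counts$tp[1], 8)
    expect_equal(rep_$counts$fp[1], 2)
    expect_equal(rep_$counts$fn[1], 4)

    ## never-predicted class scores zero
    rep0 <- f1Scores(c("a", "a", "b"), c("b", "b", "b"), c("a", "b"))
    expect_equal(rep0$perClassF1[["a"]], 0)

    expect_error(f1Scores(c("a"), c("z"), c("a", "b")), "absent")
    expect_error(f1Scores(c("a", "b"), "a", c("a", "b")), "equal length")
})

test_that("f1Scores agrees with the brute-force oracle on random vectors", {
    withr::with_seed(14, {
        classes <- c("er", "golgi", "pm", "mito")
        for (i in 1:40) {
            n <- sample(10:60, 1)
            truth <- sample(classes, n, replace = TRUE)
            pred <- sample(classes, n, replace = TRUE)
            mine <- f1Scores(truth, pred, classes)
            oracle <- bruteF1(truth, pred, classes)
            expect_equal(mine$perClassF1, oracle$perClassF1)
            expect_equal(mine$macroF1, oracle$macroF1)
        }
    })
})

test_that("welchTTest reproduces the Welch formulas and flags significance", {
    a <- c(1.2, 1.5, 1.9, 2.0, 2.4)
    b <- c(0.8, 1.0, 1.1, 1.6, 1.7, 2.2)
    res <- welchTTest(a, b)
    ## independent hand computation of the Welch statistic
    se2 <- var(a) / 5 + var(b) / 6
    tstat <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((var(a) / 5)^2 / 4 + (var(b) / 6)^2 / 5)
    expect_equal(res$statistic, tstat, tolerance = 1e-10)
    expect_equal(res$p, 2 * stats::pt(-abs(tstat), df), tolerance = 1e-10)

    expect_equal(welchTTest(a, a)$p, 1)
    withr::with_seed(4, {
        res2 <- welchTTest(rnorm(100), rnorm(100, 5))
        expect_lt(res2$p, 0.01)
        expect_true(res2$significant)
    })
    expect_error(welchTTest(rep(1, 5), rep(2, 5)), "zero variance")
    expect_error(welchTTest(1, c(1, 2)), "at least two")
})

test_that("rocAnalysis handles perfect, flat and hand-checkable score sets", {
    gold <- data.frame(accession = paste0("p", 1:6),
                       correct = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
    sep <- stats::setNames(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), gold$accession)
    expect_equal(rocAnalysis(sep, gold)$auc, 1)

    flat <- stats::setNames(rep(0.5, 6), gold$accession)
    expect_equal(rocAnalysis(flat, gold)$auc, 0.5)

    ## AUC equals concordant pairs / (n+ * n-) for tie-free scores
    s <- stats::setNames(c(0.9, 0.4, 0.75, 0.6, 0.55, 0.2), gold$accession)
    conc <- 0
    for (i in which(gold$correct)) for (j in which(!gold$correct))
        conc <- conc + unname(s[i] > s[j])
    expect_equal(rocAnalysis(s, gold)$auc, conc / 9)

    allc <- data.frame(accession = gold$accession, correct = rep(TRUE, 6))
    expect_error(rocAnalysis(sep, allc), "degenerate")
})

test_that("rocAnalysis AUC matches the Mann-Whitney identity on random sets", {
    withr::with_seed(19, {
        for (i in 1:10) {
            n <- 20
            correct <- sample(c(TRUE, FALSE), n, replace = TRUE)
            if (all(correct) || !any(correct)) correct[1:2] <- c(TRUE, FALSE)
            s <- sample(seq(0.01, 0.99, by = 0.01), n)   # tie-free
            gold <- data.frame(accession = paste0("q", 1:n),
                               correct = correct)
            names(s) <- gold$accession
            U <- sum(outer(s[correct], s[!correct], ">"))
            expect_equal(rocAnalysis(s, gold)$auc,
                         U / (sum(correct) * sum(!correct)),
                         tolerance = 1e-12)
        }
    })
})

test_that("fdrThreshold equals an exhaustive scan and reports failures", {
    gold <- data.frame(accession = paste0("p", 1:10),
                       correct = c(FALSE, FALSE, TRUE, FALSE, TRUE,
                                   TRUE, TRUE, TRUE, TRUE, TRUE))
    s <- stats::setNames(seq(0.05, 0.95, by = 0.1), gold$accession)
    res <- fdrThreshold(s, gold, 0.2)
    ## exhaustive scan over every candidate threshold
    cand <- sort(unique(s))
    fdrs <- vapply(cand, function(t) {
        sel <- s >= t; sum(!gold$correct & sel) / sum(sel)
    }, numeric(1))
    expect_true(res$attained)
    expect_equal(res$threshold, cand[which(fdrs <= 0.2)[1]])

    ## all correct: lowest score, FDR 0
    allc <- data.frame(accession = gold$accession, correct = rep(TRUE, 10))
    res2 <- fdrThreshold(s, allc, 0.05)
    expect_equal(res2$threshold, min(s))
    expect_equal(res2$fdr, 0)

    ## top-scoring protein incorrect: unattainable strict target
    bad <- gold; bad$correct[which.max(s)] <- FALSE
    res3 <- fdrThreshold(s, bad, 0.01)
    expect_false(res3$attained)
    expect_equal(res3$minFdr, min(vapply(cand, function(t) {
        sel <- s >= t; sum(!bad$correct & sel) / sum(sel)
    }, numeric(1))))
    expect_output(print(res3), "unattainable")
    expect_error(fdrThreshold(s, gold[0, ], 0.05), "empty")
})

test_that("fdrThreshold is monotone in the target rate", {
    withr::with_seed(27, {
        for (i in 1:10) {
            n <- 30
            gold <- data.frame(accession = paste0("p", 1:n),
                               correct = sample(c(TRUE, FALSE), n, TRUE,
                                                prob = c(0.7, 0.3)))
            if (all(gold$correct) || !any(gold$correct))
                gold$correct[1:2] <- c(TRUE, FALSE)
            s <- stats::setNames(runif(n), gold$accession)
            prev <- Inf
            for (target in c(0.05, 0.1, 0.2, 0.4)) {
                r <- fdrThreshold(s, gold, target)
                if (r$attained) {
                    expect_lte(r$threshold, prev)
                    prev <- r$threshold
                }
            }
        }
    })
})

test_that("classifyUnknowns applies the score threshold", {
    cfg <- simConfig(c(a = 15, b = 15), unlabelledCount = 30, seed = 5)
    gen <- generatePairedData(cfg)
    parts <- splitLabelled(gen$dataset)
    mod <- trainKnnTl(parts$L, 5, 5, c(0.5, 0.5))
    suppressMessages({
        all_ <- classifyUnknowns(mod, parts$U, threshold = 0)
        none <- classifyUnknowns(mod, parts$U, threshold = 1.01)
        mid <- classifyUnknowns(mod, parts$U, threshold = 0.7)
    })
    expect_true(all(all_$assigned))
    expect_true(all(!none$assigned))
    expect_true(all(none$class == "unassigned"))
    raw <- suppressWarnings(predict(mod, parts$U))
    expect_equal(sum(mid$assigned), sum(raw$score >= 0.7))
})

test_that("benchmark rounds are reproducible and reduce under forced theta", {
    ds <- makeToyPaired(sizes = c(a = 12, b = 12),
                        centres = rbind(c(0, 0), c(2, 2)), sdev = 0.7)
    ctl <- list(knnGrid = c(3, 5), knnInnerRounds = 1,
                thetaCandidates = 16, thetaInnerRounds = 1)
    suppressMessages({
        r1 <- benchmarkClassifiers(ds, c("knn_primary", "knn_tl"),
                                   rounds = 2, seed = 3, control = ctl)
        r2 <- benchmarkClassifiers(ds, c("knn_primary", "knn_tl"),
                                   rounds = 2, seed = 3, control = ctl)
    })
    expect_equal(r1$knn_tl@macroF1, r2$knn_tl@macroF1)
    expect_identical(r1$knn_primary@classF1, r2$knn_primary@classF1)

    ## theta forced to all-ones reproduces the primary-only arm exactly
    ctl$fixedTheta <- c(1, 1)
    suppressMessages(
        r3 <- benchmarkClassifiers(ds, c("knn_primary", "knn_tl"),
                                   rounds = 2, seed = 3, control = ctl))
    expect_equal(r3$knn_tl@macroF1, r3$knn_primary@macroF1)
    expect_equal(r3$knn_tl@classF1, r3$knn_primary@classF1)
})

test_that("compareArms reports symmetric pairwise Welch results", {
    a <- methods::new("BenchmarkResult", classifier = "x",
                      macroF1 = c(0.9, 0.92, 0.91, 0.95),
                      classF1 = matrix(0.9, 4, 2), seeds = 1:4,
                      config = list())
    b <- methods::new("BenchmarkResult", classifier = "y",
                      macroF1 = c(0.7, 0.72, 0.69, 0.75),
                      classF1 = matrix(0.7, 4, 2), seeds = 1:4,
                      config = list())
    tab <- compareArms(list(x = a, y = b))
    expect_equal(nrow(tab), 1)
    expect_equal(tab$p, welchTTest(a@macroF1, b@macroF1)$p)
    tab2 <- compareArms(list(y = b, x = a))
    expect_equal(tab$p, tab2$p)
})
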