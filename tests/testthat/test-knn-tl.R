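test_that("neighbourVotes counts classes among the k nearest rows", {
    train <- matrix(c(0, 1, 2, 10, 11), ncol = 1,
                    dimnames = list(paste0("P", 1:5), NULL))
    labs <- c("A", "A", "A", "B", "B")
    ## all five neighbours: 3 A, 2 B
    expect_equal(unname(neighbourVotes(train, labs, 5, k = 5,
                                       classSet = c("A", "B"))),
                 c(0.6, 0.4))
    ## query inside a pure class-A neighbourhood
    expect_equal(neighbourVotes(train, labs, 1, k = 3,
                                classSet = c("A", "B"))[["A"]], 1)
    expect_error(neighbourVotes(train, labs, 1, k = 0, c("A", "B")),
                 "positive")
    expect_error(neighbourVotes(train, labs, 1, k = 9, c("A", "B")),
                 "exceeds")
})

test_that("neighbourVotes matches a brute-force distance sort in 1-D", {
    pts <- c(0.0, 0.9, 2.1, 3.0, 5.2, 6.0)
    train <- matrix(pts, ncol = 1, dimnames = list(paste0("P", 1:6), NULL))
    labs <- c("A", "B", "A", "B", "A", "B")
    for (q in c(-1, 0.5, 2.5, 10)) {
        ord <- order(abs(pts - q))           # brute force, no tie cases
        for (k in c(1, 3, 5)) {
            expected <- table(factor(labs[ord[1:k]], levels = c("A", "B"))) / k
            got <- neighbourVotes(train, labs, q, k, c("A", "B"))
            expect_equal(unname(got), unname(as.numeric(expected)))
        }
    }
})

test_that("neighbour distance ties resolve towards the smallest accession", {
    ## P1 and P3 are equidistant from the query; k = 2 must take P1
    train <- matrix(c(-1, 0, 1), ncol = 1,
                    dimnames = list(c("P3", "P2", "P1"), NULL))
    labs <- c("A", "B", "C")
    v <- neighbourVotes(train, labs, 0, k = 2, classSet = c("A", "B", "C"))
    expect_equal(unname(v), c(0, 0.5, 0.5))  # P2 (B) and P1 (C), not P3
})

test_that("combineVotes implements the weighted voting rule", {
    ## theta = 1 reduces to the primary votes, theta = 0 to the auxiliary
    p <- c(0.6, 0.4); q <- c(0.1, 0.9)
    expect_equal(combineVotes(p, q, c(1, 1)), p)
    expect_equal(combineVotes(p, q, c(0, 0)), q)
    expect_equal(combineVotes(0.6, 0.3, 1 / 3), 0.4)
    expect_error(combineVotes(p, q, 1), "one entry per class")
    expect_error(combineVotes(p, q, c(2, 0)), "\\[0, 1\\]")
})

test_that("combineVotes output is a convex combination per class", {
    withr::with_seed(11, {
        for (i in 1:25) {
            nc <- sample(2:6, 1)
            p <- runif(nc); q <- runif(nc); th <- runif(nc)
            V <- combineVotes(p, q, th)
            expect_true(all(V >= pmin(p, q) - 1e-12))
            expect_true(all(V <= pmax(p, q) + 1e-12))
        }
    })
})

test_that("optimiseK selects the smallest k on score ties and is deterministic", {
    ## tight, widely separated clusters: every k scores macro F1 = 1
    ds <- makeToyPaired(sizes = c(a = 12, b = 12),
                        centres = rbind(c(0, 0), c(50, 50)), sdev = 0.05)
    res <- optimiseK(primaryData(ds), markerLabels(ds),
                     grid = c(3, 5, 7), rounds = 2, seed = 4,
                     classSet = classSet(ds))
    expect_equal(res$scores$meanMacroF1, rep(1, 3))
    expect_equal(res$bestK, 3)

    res2 <- optimiseK(primaryData(ds), markerLabels(ds),
                      grid = c(3, 5, 7), rounds = 2, seed = 4,
                      classSet = classSet(ds))
    expect_identical(res, res2)
})

test_that("optimiseK skips k values larger than the smallest training fold", {
    ds <- makeToyPaired(sizes = c(a = 6, b = 6),
                        centres = rbind(c(0, 0), c(10, 10)))
    expect_warning(
        res <- optimiseK(primaryData(ds), markerLabels(ds),
                         grid = c(3, 15), rounds = 1, seed = 1,
                         classSet = classSet(ds)),
        "skipping")
    expect_equal(res$skipped, 15)
    expect_error(
        suppressWarnings(optimiseK(primaryData(ds), markerLabels(ds),
                                   grid = 15, rounds = 1, seed = 1,
                                   classSet = classSet(ds))),
        "no usable")
})

test_that("predict assigns the argmax class with deterministic tie-breaking", {
    ds <- makeToyPaired()
    model <- trainKnnTl(ds, 3, 3, c(0.5, 0.5))
    p <- suppressWarnings(predict(model, ds))
    V <- attr(p, "votes")
    expect_equal(p$class, classSet(ds)[max.col(V, "first")])
    expect_equal(p$score, unname(apply(V, 1, max)))
    expect_true(all(p$score >= 0 & p$score <= 1))

    ## constructed exact tie: lambda = 0.5 with opposing pure votes
    train <- matrix(c(0, 10), 2, 1, dimnames = list(c("P1", "P2"), NULL))
    aux <- matrix(c(10, 0), 2, 1, dimnames = list(c("P1", "P2"), NULL))
    tiny <- pairedDataset(train, aux, c("A", "B"))
    m <- trainKnnTl(tiny, 1, 1, c(0.5, 0.5))
    q <- pairedDataset(matrix(0, 1, 1, dimnames = list("Q", NULL)),
                       matrix(0, 1, 1, dimnames = list("Q", NULL)),
                       "unknown", classSet = c("A", "B"))
    expect_warning(res <- predict(m, q), "tied")
    expect_equal(res$class, "A")            # first class in classSet order
})

test_that("degenerate theta reduces exactly to single-source k-NN", {
    ds <- makeToyPaired(sizes = c(a = 15, b = 12, c = 9),
                        centres = rbind(c(0, 0), c(2, 2), c(-2, 2)),
                        sdev = 0.8, seed = 3)
    L <- ds
    q <- makeToyPaired(sizes = c(a = 5, b = 5, c = 5),
                       centres = rbind(c(0, 0), c(2, 2), c(-2, 2)),
                       sdev = 0.8, seed = 9)
    tl <- trainKnnTl(L, 5, 3, rep(1, 3))
    primOnly <- suppressWarnings(
        predict(trainKnnTl(L, 5, 5, rep(1, 3)), q))
    expect_identical(suppressWarnings(predict(tl, q))$class, primOnly$class)

    tl0 <- trainKnnTl(L, 5, 3, rep(0, 3))
    auxVotes <- spatialTL:::.voteMatrix(auxiliaryData(L), markerLabels(L),
                                        auxiliaryData(q), 3, classSet(L))
    expect_equal(attr(suppressWarnings(predict(tl0, q)), "votes"),
                 auxVotes)
})

test_that("predict is invariant to a common permutation of training rows", {
    ds <- makeToyPaired(sizes = c(a = 10, b = 10), seed = 6)
    q <- makeToyPaired(sizes = c(a = 4, b = 4), seed = 8)
    perm <- withr::with_seed(2, sample(proteinIds(ds)))
    dsPerm <- spatialTL:::.subsetPaired(ds, perm)
    m1 <- trainKnnTl(ds, 3, 3, c(0.5, 0.5))
    m2 <- trainKnnTl(dsPerm, 3, 3, c(0.5, 0.5))
    expect_equal(suppressWarnings(predict(m1, q)),
                 suppressWarnings(predict(m2, q)),
                 ignore_attr = TRUE)
})

test_that("predictSourceWeighted equals predict with a constant theta", {
    ds <- makeToyPaired(seed = 4)
    q <- makeToyPaired(seed = 12)
    m <- trainKnnTl(ds, 3, 3, c(0.7, 0.2))
    expect_error(predictSourceWeighted(m, q, 1.2), "\\[0, 1\\]")
    for (lam in c(0, 0.5, 1)) {
        viaTheta <- suppressWarnings(
            predict(trainKnnTl(ds, 3, 3, rep(lam, 2)), q))
        expect_equal(suppressWarnings(predictSourceWeighted(m, q, lam)),
                     viaTheta, ignore_attr = TRUE)
    }
})

test_that("theta candidate generation enumerates or samples with corners", {
    full <- spatialTL:::.thetaCandidates(2, 256, c(0, 1/3, 2/3, 1), 1)
    expect_equal(nrow(full), 16)             # 4^2 full lattice
    expect_equal(nrow(unique(full)), 16)

    sampled <- spatialTL:::.thetaCandidates(10, 64, c(0, 1/3, 2/3, 1), 1)
    expect_lte(nrow(sampled), 64)
    expect_true(any(apply(sampled, 1, function(r) all(r == 1))))
    expect_true(any(apply(sampled, 1, function(r) all(r == 0))))
})

test_that("optimiseTheta skews weights towards the informative source", {
    ## class a separable only in the primary source (shared auxiliary
    ## block), class b/c separable in both; a's weights should skew high
    cfg <- simConfig(c(a = 20, b = 20, c = 20),
                     confusableAuxiliary = list(c("a", "b")), seed = 5)
    L <- generatePairedData(cfg)$dataset
    opt <- optimiseTheta(L, 5, 5, rounds = 5, seed = 2)
    expect_equal(dim(opt$bestPerRound), c(5, 3))
    expect_gte(mean(opt$bestPerRound[, "a"]), 2 / 3)
    expect_equal(rowSums(opt$weightDistribution),
                 stats::setNames(rep(5, 3), c("a", "b", "c")))
    expect_error(optimiseTheta(L, 5, 5, candidateCount = 1), "at least 2")
})
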