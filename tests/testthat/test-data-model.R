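test_that("alignDatasets restricts to the shared accessions and reports drops", {
    p <- matrix(1:6, 3, 2, dimnames = list(c("p1", "p2", "p3"), c("f1", "f2")))
    a <- matrix(1:6, 3, 2, dimnames = list(c("p2", "p3", "p4"), c("t1", "t2")))
    expect_message(ds <- alignDatasets(p, a, c(p2 = "er")),
                   "dropped 1 primary-only, 1 auxiliary-only")
    expect_identical(proteinIds(ds), c("p2", "p3"))
    expect_identical(unname(markerLabels(ds)), c("er", "unknown"))

    ## identical id lists: zero drops, order preserved
    expect_message(ds2 <- alignDatasets(p, p, c(p3 = "er", p1 = "golgi")),
                   "dropped 0 primary-only, 0 auxiliary-only")
    expect_identical(proteinIds(ds2), c("p1", "p2", "p3"))

    ## disjoint sets are an alignment error, duplicates a format error
    b <- matrix(1:2, 1, 2, dimnames = list("zz", NULL))
    expect_error(alignDatasets(p, b, c(p1 = "er")), "disjoint")
    pdup <- rbind(p, p1 = c(9, 9))
    expect_error(alignDatasets(pdup, a, c(p2 = "er")), "duplicate")
})

test_that("PairedDataset validity rejects malformed inputs", {
    p <- matrix(runif(6), 3, 2, dimnames = list(paste0("p", 1:3), NULL))
    expect_error(pairedDataset(p, p, c("a", NA, "b")))
    pna <- p; pna[1, 1] <- NA
    expect_error(pairedDataset(pna, p, rep("a", 3)), "missing")
    a <- p; rownames(a) <- c("p1", "p3", "p2")
    expect_error(pairedDataset(p, a, rep("a", 3)), "row names")
    expect_error(pairedDataset(p, p, c("a", "b", "c"), classSet = c("a", "b")),
                 "outside classSet")
})

test_that("splitLabelled partitions labelled and unknown proteins", {
    ds <- makeToyPaired()
    lab <- markerLabels(ds)
    lab[c(3, 7, 15)] <- "unknown"
    ds2 <- pairedDataset(primaryData(ds), auxiliaryData(ds), lab,
                         classSet = classSet(ds))
    parts <- splitLabelled(ds2)
    expect_equal(nrow(primaryData(parts$L)), 17)
    expect_equal(nrow(primaryData(parts$U)), 3)
    expect_setequal(c(proteinIds(parts$L), proteinIds(parts$U)),
                    proteinIds(ds2))

    ## all labelled: empty unlabelled section
    parts <- splitLabelled(ds)
    expect_equal(nrow(primaryData(parts$U)), 0)

    ## labels permuted relative to ids give the same partition
    perm <- sample(names(lab))
    ds3 <- pairedDataset(primaryData(ds), auxiliaryData(ds), lab[perm],
                         classSet = classSet(ds))
    expect_setequal(proteinIds(splitLabelled(ds3)$L), proteinIds(parts2 <- splitLabelled(ds2)$L))

    ds4 <- pairedDataset(primaryData(ds), auxiliaryData(ds),
                         rep("unknown", 20), classSet = classSet(ds))
    expect_error(splitLabelled(ds4), "no labelled")
})

test_that("stratifiedHoldout preserves class proportions and is deterministic", {
    ds <- makeToyPaired(sizes = c(a = 50, b = 50),
                        centres = rbind(c(0, 0), c(3, 3)))
    plan <- stratifiedHoldout(ds, 0.8, seed = 7)
    lab <- markerLabels(ds)
    expect_equal(as.vector(table(lab[trainIds(plan)])), c(40L, 40L))
    expect_equal(as.vector(table(lab[testIds(plan)])), c(10L, 10L))

    plan2 <- stratifiedHoldout(ds, 0.8, seed = 7)
    expect_identical(trainIds(plan), trainIds(plan2))

    ## uneven class sizes: per-class train counts within one of 0.8 * N_i
    ds2 <- makeToyPaired(sizes = c(a = 7, b = 13),
                         centres = rbind(c(0, 0), c(3, 3)))
    plan3 <- stratifiedHoldout(ds2, 0.8, seed = 3)
    cnt <- table(markerLabels(ds2)[trainIds(plan3)])
    expect_true(cnt[["a"]] %in% 5:6)
    expect_true(cnt[["b"]] %in% 10:11)
    expect_equal(sum(cnt), 16)
})

test_that("stratifiedHoldout over many seeds always satisfies the within-one bound", {
    ds <- makeToyPaired(sizes = c(a = 9, b = 14, c = 23),
                        centres = rbind(c(0, 0), c(3, 3), c(-3, 3)))
    lab <- markerLabels(ds)
    keys <- character(50)
    for (s in 1:50) {
        plan <- stratifiedHoldout(ds, 0.8, seed = s)
        cnt <- table(factor(lab[trainIds(plan)], levels = c("a", "b", "c")))
        expect_true(all(abs(cnt - 0.8 * c(9, 14, 23)) <= 1))
        keys[s] <- paste(sort(trainIds(plan)), collapse = ",")
    }
    expect_gt(length(unique(keys)), 45)   # distinct plans across seeds
})

test_that("stratifiedHoldout and kfold reject too-small classes", {
    ds <- makeToyPaired(sizes = c(solo = 1, b = 10),
                        centres = rbind(c(0, 0), c(3, 3)))
    expect_error(stratifiedHoldout(ds, 0.8, 1), "solo")
    ds2 <- makeToyPaired(sizes = c(tiny = 4, b = 10),
                         centres = rbind(c(0, 0), c(3, 3)))
    expect_error(stratifiedKfold(ds2, k = 5), "tiny")
})

test_that("stratifiedKfold folds are disjoint, covering and balanced", {
    ds <- makeToyPaired(sizes = c(a = 10, b = 10))
    folds <- stratifiedKfold(ds, k = 5, seed = 2)
    expect_length(folds, 5)
    lab <- markerLabels(ds)
    testSets <- lapply(folds, testIds)
    expect_setequal(unlist(testSets), proteinIds(ds))
    expect_equal(sum(lengths(testSets)), 20)
    for (f in folds) {
        expect_equal(as.vector(table(lab[testIds(f)])), c(2L, 2L))
        expect_setequal(c(trainIds(f), testIds(f)), proteinIds(ds))
    }
})

test_that("feature matrix and marker files round-trip through TSV", {
    ds <- makeToyPaired()
    tmp <- withr::local_tempdir()
    pPath <- file.path(tmp, "prim.tsv")
    writeFeatureMatrix(primaryData(ds), pPath)
    suppressMessages(back <- readFeatureMatrix(pPath))
    expect_equal(unname(back), unname(primaryData(ds)), tolerance = 1e-12)
    expect_identical(rownames(back), proteinIds(ds))

    mPath <- file.path(tmp, "markers.tsv")
    utils::write.table(data.frame(accession = proteinIds(ds),
                                  class = markerLabels(ds)),
                       mPath, sep = "\t", quote = FALSE, row.names = FALSE)
    suppressMessages(lab <- readMarkerFile(mPath))
    expect_identical(unname(lab[proteinIds(ds)]),
                     unname(markerLabels(ds)))
})
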