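test_that("gaussianKernel follows the RBF definition", {
    x <- matrix(rnorm(10), 5, 2)
    K <- gaussianKernel(x, gamma = 2)
    expect_equal(unname(diag(K)), rep(1, 5))
    expect_true(all(K > 0 & K <= 1))
    ## direct formula evaluation
    expect_equal(gaussianKernel(rbind(c(0, 0)), rbind(c(1, 1)), 0.5)[1, 1],
                 exp(-1))
    ## gamma -> 0 limit saturates at 1
    expect_equal(max(abs(gaussianKernel(x, gamma = 1e-12) - 1)), 0,
                 tolerance = 1e-9)
    expect_error(gaussianKernel(x, gamma = 0), "positive")
})

test_that("the simplex solver handles optimal, infeasible and generic LPs", {
    ## min x1 + 2 x2 s.t. x1 + x2 >= 1, x2 >= 0.2 -> x = (0.8, 0.2)
    sol <- spatialTL:::.lpSimplex(c(1, 2), rbind(c(1, 1), c(0, 1)),
                                  c(1, 0.2))
    expect_equal(sol$status, "optimal")
    expect_equal(sol$objective, 1.2, tolerance = 1e-9)
    expect_equal(sol$x, c(0.8, 0.2), tolerance = 1e-9)

    ## infeasible: x1 >= 1 and -x1 >= 0
    bad <- spatialTL:::.lpSimplex(c(1), rbind(1, -1), c(1, 0))
    expect_equal(bad$status, "infeasible")

    ## random feasible programmes agree with the boot::simplex oracle
    withr::with_seed(10, {
        for (i in 1:10) {
            n <- sample(3:6, 1); m <- sample(2:4, 1)
            A <- matrix(runif(m * n, 0.1, 1), m, n)
            obj <- runif(n, 0.5, 2)
            rhs <- runif(m, 0.5, 2)
            mine <- spatialTL:::.lpSimplex(obj, A, rhs)
            expect_equal(mine$status, "optimal")
            expect_equal(mine$objective, oracleLpObjective(obj, A, rhs),
                         tolerance = 1e-8)
        }
    })
})

test_that("Morik imbalance weights follow C+ = C n-/n+ and C- = C n+/n-", {
    y <- c(rep(1, 10), rep(-1, 40))
    w <- spatialTL:::.morikWeights(y, 1)
    expect_equal(unique(w[y > 0]), 4)
    expect_equal(unique(w[y < 0]), 0.25)
    w2 <- spatialTL:::.morikWeights(y, 2.5)
    expect_equal(unique(w2[y > 0]), 2.5 * 40 / 10)
    expect_equal(unique(w2[y < 0]), 2.5 * 10 / 40)
})

test_that("the separable toy is fit with zero training errors and unit margins", {
    sk <- makeSeparableKernels()
    mod <- trainBinaryTL(sk$KP, sk$KA, sk$y, C = 1,
                         classPos = "pos", classNeg = "neg",
                         trainIds = rownames(sk$x))
    expect_length(mod@fallbackClass, 0)
    f <- decisionValue(mod, sk$KP, sk$KA)
    expect_true(all(sign(f) == sk$y))                  # zero training errors
    expect_true(all(sk$y * f >= 1 - 1e-8))             # margin constraints
    expect_true(all(mod@alphaP >= 0 & mod@alphaA >= 0))

    ## single-kernel variant on the same primary data
    mod1 <- trainBinarySingle(sk$KP, sk$y, C = 1)
    f1 <- decisionValue(mod1, sk$KP)
    expect_true(all(sk$y * f1 >= 1 - 1e-8))
    expect_error(trainBinarySingle(sk$KP, rep(1, length(sk$y)), 1),
                 "both classes")
})

test_that("LP training matches an independently assembled generic LP oracle", {
    withr::with_seed(42, {
        for (i in 1:8) {
            m <- sample(c(10, 16, 20), 1)
            x <- matrix(rnorm(m * 2, sd = 1.5), m, 2)
            v <- matrix(rnorm(m * 2, sd = 1.5), m, 2)
            rownames(x) <- rownames(v) <- sprintf("r%02d", 1:m)
            y <- sample(c(1, -1), m, replace = TRUE)
            if (length(unique(y)) < 2) y[1:2] <- c(1, -1)
            C <- sample(c(0.5, 1, 4), 1)
            KP <- gaussianKernel(x, gamma = 1)
            KA <- gaussianKernel(v, gamma = 0.5)
            mod <- trainBinaryTL(KP, KA, y, C)
            lp <- assembleSvmLp(KP, KA, y, C)
            expect_equal(mod@objective,
                         oracleLpObjective(lp$obj, lp$A, lp$rhs),
                         tolerance = 1e-6)
        }
    })
})

test_that("TL feasible set nests the single-source one when sources coincide", {
    sk <- makeSeparableKernels(m = 16)
    modS <- trainBinarySingle(sk$KP, sk$y, C = 2)
    modT <- trainBinaryTL(sk$KP, sk$KP, sk$y, C = 2)
    expect_lte(modT@objective, modS@objective + 1e-8)
})

test_that("decisionValue evaluates the latent function and fallback sentinels", {
    ## all alphas zero, b = 0.5 -> f = 0.5 everywhere
    m <- methods::new("BinaryLPModel", alphaP = rep(0, 3), alphaA = rep(0, 3),
                      b = 0.5, y = c(1, 1, -1), trainIds = c("a", "b", "c"),
                      classPos = "A", classNeg = "B", objective = 0,
                      fallbackClass = character(0))
    expect_equal(decisionValue(m, matrix(runif(6), 2, 3),
                               matrix(runif(6), 2, 3)), c(0.5, 0.5))

    fb <- methods::new("BinaryLPModel", alphaP = numeric(0),
                       alphaA = numeric(0), b = 0, y = c(1, -1, -1),
                       trainIds = c("a", "b", "c"), classPos = "A",
                       classNeg = "B", objective = NA_real_,
                       fallbackClass = "B")
    expect_equal(decisionValue(fb, matrix(0, 2, 3)), c(-Inf, -Inf))
    fbA <- methods::new("BinaryLPModel", alphaP = numeric(0),
                        alphaA = numeric(0), b = 0, y = c(1, 1, -1),
                        trainIds = c("a", "b", "c"), classPos = "A",
                        classNeg = "B", objective = NA_real_,
                        fallbackClass = "A")
    expect_equal(decisionValue(fbA, matrix(0, 1, 3)), Inf)
})

test_that("sign of the latent function reproduces the binary decision rule", {
    sk <- makeSeparableKernels(m = 12)
    mod <- trainBinaryTL(sk$KP, sk$KA, sk$y, C = 1)
    grid <- withr::with_seed(3, matrix(rnorm(20), 10, 2))
    kP <- gaussianKernel(grid, sk$x, 1)
    kA <- gaussianKernel(grid, sk$v, 1)
    f <- decisionValue(mod, kP, kA)
    h <- ifelse(f >= 0, 1, -1)
    expect_identical(h, sign(f + (f == 0)))
})
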