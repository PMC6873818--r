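scoredFixture <- function(n = 12, seed = 1) {
    set.seed(seed)
    ids <- sprintf("P%02d", seq_len(n))
    ctl <- matrix(rpois(n * 4, 20), n, 4,
                  dimnames = list(ids, sprintf("f%d", 1:4)))
    trt <- matrix(rpois(n * 4, 20), n, 4, dimnames = dimnames(ctl))
    scoreExperiment(alignPair(ElutionMatrix(ctl, "control"),
                              ElutionMatrix(trt, "treated")))
}

test_that("the background pool sorts by abundance with ID tie-breaks and
           excludes annotated or undefined proteins", {
    ctl <- makeElut(rbind(A = c(9, 1), B = c(5, 5), C = c(5, 5),
                          D = c(1, 1), Z = c(0, 0)))
    trt <- makeElut(rbind(A = c(9, 1), B = c(5, 5), C = c(5, 5),
                          D = c(1, 1), Z = c(0, 0)), condition = "treated")
    de <- scoreExperiment(alignPair(ctl, trt))
    pool <- orderBackgroundPool(de)
    expect_identical(pool$id, c("A", "B", "C", "D"))  # B before C on tie
    pool2 <- orderBackgroundPool(de, annotated = "B")
    expect_identical(pool2$id, c("A", "C", "D"))
    expect_error(orderBackgroundPool(de, annotated = c("A", "B", "C", "D")),
                 "fewer than 3")
})

test_that("window indices follow the half-width rule with inward-extending
           edge clamps", {
    pool <- data.frame(id = sprintf("P%04d", 1:1000),
                       Dnorm = runif(1000),
                       meanAbundance = seq(1000, 1, by = -1))
    mid <- backgroundWindow(pool, "P0500", pool$meanAbundance[500], s = 100)
    expect_identical(c(mid$lo, mid$hi), c(400L, 600L))
    expect_length(mid$scores, 200)          # 201 positions minus self
    edge <- backgroundWindow(pool, "P0001", pool$meanAbundance[1], s = 100)
    expect_identical(c(edge$lo, edge$hi), c(1L, 201L))
    expect_length(edge$scores, 200)
    tail <- backgroundWindow(pool, "P1000", pool$meanAbundance[1000],
                             s = 100)
    expect_identical(c(tail$lo, tail$hi), c(800L, 1000L))
    # a query that is not a pool member keeps all window positions
    out <- backgroundWindow(pool, "QUERY", pool$meanAbundance[500] + 0.5,
                            s = 100)
    expect_length(out$scores, 201)
    small <- backgroundWindow(pool[1:50, ], "P0010",
                              pool$meanAbundance[10], s = 100)
    expect_length(small$scores, 49)         # whole pool minus self
})

test_that("an annotated query is placed at the abundance rank it would
           occupy in the pool", {
    pool <- data.frame(id = sprintf("P%03d", 1:10),
                       Dnorm = runif(10),
                       meanAbundance = seq(100, 10, by = -10))
    w <- backgroundWindow(pool, "ANNOT", 55, s = 2)
    # abundance 55 would sit at rank 6 (after 100..60): window ranks 4-8
    expect_identical(c(w$lo, w$hi), c(4L, 8L))
    expect_length(w$scores, 5)
})

test_that("BH correction matches the hand example and the brute-force
           step-up oracle", {
    expect_equal(fdrCorrect(0.03), 0.03)
    expect_equal(fdrCorrect(c(0.01, 0.02, 0.03, 0.5)),
                 c(0.04, 0.04, 0.04, 0.5))
    expect_equal(fdrCorrect(rep(0.2, 5)), rep(0.2, 5))
    set.seed(11)
    for (i in 1:200) {
        p <- runif(sample(1:40, 1))
        expect_equal(fdrCorrect(p), bruteBH(p), tolerance = 1e-12)
    }
    expect_error(fdrCorrect(c(0.1, 1.2)), "\\[0, 1\\]")
    q <- fdrCorrect(c(0.01, NA, 0.04))
    expect_true(is.na(q[2]))
    expect_equal(q[c(1, 3)], bruteBH(c(0.01, 0.04)))
})

test_that("q values dominate p values and significance uses a strict
           threshold", {
    set.seed(3)
    p <- runif(30)
    q <- fdrCorrect(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(callRnaAssociated(0.049, alpha = 0.05))
    expect_false(callRnaAssociated(0.05, alpha = 0.05))
    expect_identical(sum(callRnaAssociated(rep(1, 10))), 0L)
})

test_that("assignSignificance adds calibrated columns and preserves score
           ranking within a shared window fit", {
    de <- scoredFixture(n = 40, seed = 5)
    de <- assignSignificance(de, s = 100, seed = 5)
    rd <- SummarizedExperiment::rowData(de)
    expect_true(all(rd$p >= 0 & rd$p <= 1, na.rm = TRUE))
    expect_true(all(rd$q >= rd$p - 1e-12, na.rm = TRUE))
    expect_identical(rd$significant, callRnaAssociated(rd$q, 0.05))
    cfg <- S4Vectors::metadata(de)$significance
    expect_identical(cfg$s, 100)
    # ranking by p equals ranking by score among proteins sharing one
    # window fit (pool smaller than the window: all share the whole pool,
    # up to self-exclusion differences; check monotone trend)
    ok <- !is.na(rd$p)
    expect_gt(cor(rd$Dnorm[ok], -rd$p[ok], method = "spearman"), 0.95)
})

test_that("undefined scores propagate as undefined significance", {
    ctl <- makeElut(rbind(A = c(5, 1), B = c(4, 2), C = c(3, 3),
                          D = c(2, 4), Z = c(0, 0)))
    trt <- makeElut(rbind(A = c(5, 1), B = c(4, 2), C = c(3, 3),
                          D = c(2, 4), Z = c(0, 0)), condition = "treated")
    de <- assignSignificance(scoreExperiment(alignPair(ctl, trt)))
    rd <- SummarizedExperiment::rowData(de)
    expect_true(is.na(rd$p[rownames(de) == "Z"]))
    expect_true(is.na(rd$q[rownames(de) == "Z"]))
    expect_false(rd$significant[rownames(de) == "Z"])
})

test_that("annotated proteins are scored against, but excluded from, the
           background", {
    set.seed(9)
    n <- 30
    ids <- sprintf("P%02d", 1:n)
    ctl <- matrix(rpois(n * 6, 15), n, 6,
                  dimnames = list(ids, sprintf("f%d", 1:6)))
    trt <- matrix(rpois(n * 6, 15), n, 6, dimnames = dimnames(ctl))
    de <- scoreExperiment(alignPair(ElutionMatrix(ctl, "control"),
                                    ElutionMatrix(trt, "treated")))
    de <- assignSignificance(de, annotated = c("P01", "P02"), seed = 9)
    rd <- SummarizedExperiment::rowData(de)
    expect_false(anyNA(rd$p))   # annotated proteins still get p values
    expect_identical(S4Vectors::metadata(de)$significance$poolSize, 28L)
})
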