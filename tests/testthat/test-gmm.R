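# The windowed background model: 1- vs 2-component Gaussian mixtures with
# BIC selection and the weight criteria.

# the accept scenario keeps the background weight (0.8) clearly above the
# acceptance threshold (0.7): at the threshold itself the estimated weight
# straddles it and selection is a coin flip by construction
drawBimodal <- function(n = 201, wLow = 0.8, muLow = 0.2, sdLow = 0.05,
                        muHigh = 1.2, sdHigh = 0.1) {
    nLow <- round(n * wLow)
    c(rnorm(nLow, muLow, sdLow), rnorm(n - nLow, muHigh, sdHigh))
}

test_that("a clearly bimodal window selects two components and recovers the
           background mean", {
    set.seed(101)
    w <- drawBimodal()
    fit <- fitBackground(w, seed = 101)
    expect_identical(fit@nComponents, 2L)
    expect_true(all(fit@criteria))
    # recovered background mean within 3 standard errors of truth
    se <- 0.05 / sqrt(round(201 * 0.8))
    expect_lt(abs(fit@mu - 0.2), 3 * se)
    expect_equal(sum(fit@weights), 1)
    expect_true(all(fit@sds > 0))
})

test_that("a unimodal window falls back to one component via BIC", {
    set.seed(202)
    w <- rnorm(201, 0.3, 0.05)
    fit <- fitBackground(w, seed = 202)
    expect_identical(fit@nComponents, 1L)
    expect_false(fit@criteria[["bic"]] && fit@criteria[["low_mean_heaviest"]]
                 && fit@criteria[["weight_threshold"]])
    expect_equal(fit@mu, mean(w), tolerance = 1e-12)
})

test_that("a window whose low-mean component is the minority is rejected by
           the weight criteria", {
    set.seed(303)
    w <- drawBimodal(wLow = 0.3)   # 30% low / 70% high
    fit <- fitBackground(w, seed = 303)
    expect_identical(fit@nComponents, 1L)
    # BIC clearly favours two components here; the weight rules veto it
    expect_true(fit@criteria[["bic"]])
    expect_false(fit@criteria[["low_mean_heaviest"]] &&
                 fit@criteria[["weight_threshold"]])
})

test_that("the weight threshold vetoes an accepted majority that is not
           heavy enough", {
    set.seed(404)
    w <- drawBimodal(wLow = 0.55)
    fit <- fitBackground(w, tWeight = 0.7, seed = 404)
    expect_identical(fit@nComponents, 1L)
    fitLoose <- fitBackground(w, tWeight = 0.5, seed = 404)
    expect_identical(fitLoose@nComponents, 2L)
})

test_that("the EM fit agrees with mclust as an independent oracle", {
    suppressMessages(library(mclust))
    set.seed(505)
    for (rep in 1:5) {
        w <- drawBimodal()
        fit <- fitBackground(w, seed = rep)
        mc <- mclust::Mclust(w, G = 2, modelNames = "V", verbose = FALSE)
        # same optimum: log-likelihoods match closely and component means
        # agree after sorting
        expect_equal(
            sum(log(fit@weights[1] * dnorm(w, fit@means[1], fit@sds[1]) +
                    fit@weights[2] * dnorm(w, fit@means[2], fit@sds[2]))),
            mc$loglik, tolerance = 1e-3)
        expect_equal(sort(fit@means), sort(as.numeric(mc$parameters$mean)),
                     tolerance = 0.02)
    }
})

test_that("degenerate windows are flagged and sigma is floored", {
    fit <- fitBackground(rep(0.4, 50), seed = 1)
    expect_true(fit@degenerate)
    expect_identical(fit@sigma, 1e-6)
    zp <- gmmZP(0.5, fit)
    expect_true(is.finite(zp$z))
    expect_true(is.na(zp$p))
})

test_that("fitBackground validates its inputs", {
    expect_error(fitBackground(numeric(0)), "empty")
    expect_error(fitBackground(c(0.1, NA)), "NA")
    expect_error(fitBackground(rnorm(10), tWeight = 1.2), "tWeight")
})

test_that("Z-scores and upper-tail p values follow the standard normal", {
    fit <- new("GmmFit", nComponents = 1L, weights = 1, means = 0.2,
               sds = 0.1, bic = c(bic1 = 0, bic2 = 0),
               criteria = c(bic = FALSE, low_mean_heaviest = FALSE,
                            weight_threshold = FALSE),
               mu = 0.2, sigma = 0.1, tWeight = 0.7, degenerate = FALSE,
               n = 100L)
    atMu <- gmmZP(0.2, fit)
    expect_equal(atMu$z, 0)
    expect_equal(atMu$p, 0.5)
    z2 <- gmmZP(0.4, fit)
    expect_equal(z2$z, 2)
    expect_equal(z2$p, 0.02275, tolerance = 1e-4)  # upper-tail table value
    below <- gmmZP(0.1, fit)
    expect_lt(below$z, 0)
    expect_gt(below$p, 0.5)
    # p is strictly decreasing in the score for a fixed fit
    ds <- seq(0, 2, by = 0.05)
    expect_true(all(diff(gmmZP(ds, fit)$p) < 0))
})

test_that("fitting is deterministic under a fixed seed and leaves the
           caller's RNG alone", {
    set.seed(606)
    w <- drawBimodal()
    before <- .Random.seed
    f1 <- fitBackground(w, seed = 9)
    expect_identical(.Random.seed, before)
    f2 <- fitBackground(w, seed = 9)
    expect_identical(f1@means, f2@means)
    expect_identical(f1@mu, f2@mu)
})
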