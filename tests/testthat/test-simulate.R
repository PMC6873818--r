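test_that("the generator is bit-deterministic under a seed and leaves the
           caller's RNG alone", {
    set.seed(77)
    before <- .Random.seed
    s1 <- simulateDiffrac(nProteins = 100, seed = 5)
    expect_identical(.Random.seed, before)
    s2 <- simulateDiffrac(nProteins = 100, seed = 5)
    expect_identical(psmCounts(s1$control), psmCounts(s2$control))
    expect_identical(psmCounts(s1$treated), psmCounts(s2$treated))
    expect_identical(s1$truth, s2$truth)
    s3 <- simulateDiffrac(nProteins = 100, seed = 6)
    expect_false(identical(psmCounts(s1$control), psmCounts(s3$control)))
})

test_that("config invariants are checked before sampling", {
    expect_error(simulateDiffrac(nFractions = 1), "at least 2")
    expect_error(simulateDiffrac(rnaFraction = 1.5), "rnaFraction")
    expect_error(simulateDiffrac(abundanceMeanlog = Inf), "finite")
})

test_that("expected PSM mass matches the drawn abundance and truth
           proportions match the config", {
    sim <- simulateDiffrac(nProteins = 1500, rnaFraction = 0.25, seed = 8)
    tot <- rowSums(psmCounts(sim$control))
    # Poisson totals concentrate on the drawn abundance
    expect_equal(mean(tot / sim$truth$abundance), 1, tolerance = 0.02)
    expect_equal(mean(sim$truth$is_rna_associated), 0.25, tolerance = 0.01)
    # null proteins carry no effect
    nulls <- !sim$truth$is_rna_associated
    expect_true(all(sim$truth$true_shift[nulls] == 0))
    expect_true(all(sim$truth$abundance_multiplier[nulls] == 1))
})

test_that("true responders separate from nulls in the normalized score", {
    gaps <- vapply(1:5, function(seed) {
        sim <- simulateDiffrac(nProteins = 300, rnaFraction = 0.1,
                               shiftRange = c(12, 12), seed = seed)
        de <- scoreExperiment(alignPair(sim$control, sim$treated))
        rd <- SummarizedExperiment::rowData(de)
        isTrue <- sim$truth$is_rna_associated[match(rownames(de),
            sim$truth$protein_id)]
        mean(rd$Dnorm[isTrue], na.rm = TRUE) -
            mean(rd$Dnorm[!isTrue], na.rm = TRUE)
    }, numeric(1))
    expect_true(all(gaps > 0))
})

test_that("a null-only simulation has no systematic control/treated
           difference", {
    sim <- simulateDiffrac(nProteins = 400, rnaFraction = 0, seed = 9)
    expect_false(any(sim$truth$is_rna_associated))
    de <- scoreExperiment(alignPair(sim$control, sim$treated))
    de <- classifySignals(de, significantOnly = FALSE)
    sh <- SummarizedExperiment::rowData(de)$shift
    expect_lt(abs(mean(sh, na.rm = TRUE)), 0.2)
})

test_that("planted complexes share templates and coherent effects", {
    sim <- simulateDiffrac(nProteins = 300,
        complexes = data.frame(size = c(5, 5),
                               shared = c(TRUE, TRUE),
                               rnp = c(TRUE, FALSE),
                               meanlog = log(150)),
        seed = 10)
    expect_s4_class(sim$complexes, "ComplexSet")
    expect_identical(sim$complexTruth$is_rnp, c(TRUE, FALSE))
    members <- complexMembers(sim$complexes)
    truth <- sim$truth
    rnpIds <- members[[sim$complexTruth$complex_id[1]]]
    nonIds <- members[[sim$complexTruth$complex_id[2]]]
    expect_true(all(truth$is_rna_associated[truth$protein_id %in% rnpIds]))
    expect_false(any(truth$is_rna_associated[truth$protein_id %in% nonIds]))
    # coherent shift: all members of the true RNP share one shift value
    shifts <- truth$true_shift[truth$protein_id %in% rnpIds]
    expect_equal(length(unique(shifts)), 1L)
    # shared template: subunits co-elute tightly in the control
    expect_gt(coelution(nonIds, sim$control), 0.75)
})

test_that("negative-binomial counts are overdispersed relative to Poisson", {
    pois <- simulateDiffrac(nProteins = 400, rnaFraction = 0, seed = 11)
    nb <- simulateDiffrac(nProteins = 400, rnaFraction = 0,
                          dispersion = 2, seed = 11)
    vmrOf <- function(s) {
        tot <- rowSums(psmCounts(s$control))
        mean((tot - s$truth$abundance)^2 / s$truth$abundance)
    }
    expect_gt(vmrOf(nb), 2 * vmrOf(pois))
})

test_that("evaluateRecovery computes confusion metrics and validates IDs", {
    sim <- simulateDiffrac(nProteins = 200, rnaFraction = 0.15,
                           shiftRange = c(12, 14), seed = 12)
    de <- scoreExperiment(alignPair(sim$control, sim$treated))
    de <- assignSignificance(de, seed = 12)
    ev <- evaluateRecovery(de, sim$truth)
    expect_true(all(c("tp", "fp", "tn", "fn", "fdp", "sensitivity",
                      "specificity") %in% names(ev$protein)))
    expect_equal(ev$protein$tp + ev$protein$fn,
                 sum(sim$truth$is_rna_associated))
    bad <- sim$truth
    bad$protein_id[1] <- "WRONG"
    expect_error(evaluateRecovery(de, bad), "do not match")
})
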