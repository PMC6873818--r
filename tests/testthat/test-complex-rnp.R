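toyComplexes <- function() {
    ComplexSet(list(cpxA = c("P1", "P2", "P3", "P4", "P5"),
                    cpxB = c("P6", "P7", "P8", "P9"),
                    cpxC = c("P2", "P3", "P10")),
               source = "CORUM")
}

test_that("Jaccard similarity matches hand counts", {
    expect_equal(jaccardIndex(c("A", "B"), c("A", "B")), 1)
    expect_equal(jaccardIndex(c("A", "B"), c("C", "D")), 0)
    expect_equal(jaccardIndex(c("A", "B", "C"), c("B", "C", "D")), 0.5)
    expect_error(jaccardIndex(character(), "A"), "empty")
})

test_that("merging collapses only identical-membership complexes, with
           first-set precedence", {
    corum <- ComplexSet(list(c1 = c("A", "B", "C", "D", "E"),
                             c2 = c("X", "Y")), source = "CORUM")
    humap <- ComplexSet(list(h1 = c("E", "D", "C", "B", "A"),  # same set
                             h2 = c("X", "Y", "Z")),           # J = 2/3
                        source = "huMAP")
    merged <- mergeComplexSets(corum, humap)
    expect_identical(length(complexMembers(merged)), 3L)
    info <- complexInfo(merged)
    dupSrc <- info$source[vapply(complexMembers(merged), setequal,
                                 logical(1), c("A", "B", "C", "D", "E"))]
    expect_identical(dupSrc, "CORUM")
    # near-duplicates (Jaccard 0.9 < 1) both survive
    expect_true(any(vapply(complexMembers(merged), setequal, logical(1),
                           c("X", "Y"))))
    expect_true(any(vapply(complexMembers(merged), setequal, logical(1),
                           c("X", "Y", "Z"))))
})

test_that("merging is idempotent and membership-order-insensitive", {
    a <- toyComplexes()
    b <- ComplexSet(list(b1 = c("P1", "P2")), source = "huMAP")
    m1 <- mergeComplexSets(a, b)
    m2 <- mergeComplexSets(m1, b)
    expect_identical(complexMembers(m2), complexMembers(m1))
    mSwap <- mergeComplexSets(b, a)
    key <- function(cs) sort(vapply(complexMembers(cs), paste,
                                    character(1), collapse = "|"))
    expect_identical(key(mSwap), key(m1))
    empty <- ComplexSet(list(), source = "huMAP")
    expect_identical(complexMembers(mergeComplexSets(a, empty)),
                     complexMembers(a))
})

test_that("complex files round-trip in both accepted layouts", {
    simple <- withr::local_tempfile()
    writeLines(c("cpx1:\tP1\tP2\tP3", "P4\tP5"), simple)
    cs <- readComplexSet(simple, source = "CORUM")
    expect_identical(complexMembers(cs)$cpx1, c("P1", "P2", "P3"))
    expect_identical(length(complexMembers(cs)), 2L)
    corumStyle <- withr::local_tempfile()
    writeLines(c("complex_id\tname\tsubunits",
                 "1\tribosome-like\tP1;P2;P3",
                 "2\tsolo\tP9"), corumStyle)
    expect_warning(cs2 <- readComplexSet(corumStyle, source = "CORUM"),
                   "fewer than 2")
    expect_identical(complexMembers(cs2)[["1"]], c("P1", "P2", "P3"))
    expect_identical(complexInfo(cs2)$name, "ribosome-like")
})

test_that("co-elution averages pairwise Pearson correlations of detected
           subunits", {
    prof <- rbind(P1 = c(1, 4, 9, 4, 1),
                  P2 = c(2, 8, 18, 8, 2),    # same shape as P1
                  P3 = c(9, 4, 1, 4, 9))
    colnames(prof) <- sprintf("f%d", 1:5)
    expect_equal(coelution(c("P1", "P2"), prof), 1)
    expect_lt(coelution(c("P1", "P3"), prof), 0)
    # brute-force mean of the three pairwise correlations
    expected <- mean(c(cor(prof["P1", ], prof["P2", ]),
                       cor(prof["P1", ], prof["P3", ]),
                       cor(prof["P2", ], prof["P3", ])))
    expect_equal(coelution(c("P1", "P2", "P3"), prof), expected)
    expect_true(is.na(coelution(c("P1", "MISSING"), prof)))
})

test_that("RNP calls require a strict subunit majority over the evidence
           union", {
    cs <- toyComplexes()
    calls <- callRnp(cs, diffracSignificant = c("P1", "P2"),
                     htAnnotated = "P3", ltAnnotated = character())
    a <- calls[calls$complex_id == "cpxA", ]
    expect_equal(a$frac_union, 3 / 5)
    expect_true(a$is_rnp)            # 3 of 5: strict majority
    b <- calls[calls$complex_id == "cpxB", ]
    expect_false(b$is_rnp)           # 0 of 4
    half <- callRnp(ComplexSet(list(h = c("P1", "P2", "P3", "P4")),
                               source = "x"),
                    diffracSignificant = c("P1", "P2"))
    expect_false(half$is_rnp)        # exactly half fails
    none <- callRnp(cs)
    expect_false(any(none$is_rnp))   # empty evidence: no RNPs
    # annotation-only evidence suffices even with no elution detection
    annOnly <- callRnp(ComplexSet(list(k = c("Q1", "Q2", "Q3")),
                                  source = "x"),
                       htAnnotated = c("Q1", "Q2", "Q3"))
    expect_true(annOnly$is_rnp)
})

test_that("RNP Select gates on co-elution and a relaxed majority", {
    shape <- c(1, 5, 12, 5, 1)
    ctrl <- rbind(P1 = shape * 2, P2 = shape * 3, P3 = shape,
                  P4 = c(10, 2, 1, 2, 10),   # anticorrelated with `shape`
                  Q1 = shape, Q2 = shape * 2)
    colnames(ctrl) <- sprintf("f%d", 1:5)
    cs <- ComplexSet(list(good = c("P1", "P2", "P3"),
                          anti = c("P3", "P4"),
                          qq = c("Q1", "Q2")), source = "x")
    pv <- c(P1 = 0.2, P2 = 0.2, P3 = 0.9, P4 = 0.001,
            Q1 = 0.9, Q2 = 0.9)
    sel <- callRnpSelect(cs, ctrl, pv)
    g <- sel[sel$complex_id == "good", ]
    expect_true(g$is_rnp_select)        # r = 1, 2/3 below 0.5
    a <- sel[sel$complex_id == "anti", ]
    expect_false(a$is_rnp_select)       # anticorrelated: co-elution gate
    expect_match(a$select_reason, "co-elution")
    q <- sel[sel$complex_id == "qq", ]
    expect_false(q$is_rnp_select)       # co-elutes but no relaxed majority
    expect_match(q$select_reason, "majority")
    # inverted threshold direction flips the qq call
    selInv <- callRnpSelect(cs, ctrl, pv, direction = "greater")
    expect_true(selInv$is_rnp_select[selInv$complex_id == "qq"])
})

test_that("subunits missing from the elution data stay in the majority
           denominator but not the co-elution mean", {
    shape <- c(1, 5, 12, 5, 1)
    ctrl <- rbind(P1 = shape, P2 = shape * 2)
    colnames(ctrl) <- sprintf("f%d", 1:5)
    cs <- ComplexSet(list(c1 = c("P1", "P2", "M1", "M2")), source = "x")
    pv <- c(P1 = 0.01, P2 = 0.01)
    sel <- callRnpSelect(cs, ctrl, pv)
    expect_equal(sel$mean_pairwise_r, 1)
    expect_equal(sel$frac_relaxed, 0.5)   # 2 of 4: not a strict majority
    expect_false(sel$is_rnp_select)
})
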