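# Shared fixtures and independent oracles used across test files.

makeElut <- function(mat, ids = NULL, condition = "control") {
    if (is.null(rownames(mat)))
        rownames(mat) <- ids %||% sprintf("P%d", seq_len(nrow(mat)))
    if (is.null(colnames(mat)))
        colnames(mat) <- sprintf("f%d", seq_len(ncol(mat)))
    ElutionMatrix(mat, condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# three proteins x four fractions; P2's profile moves between conditions
smallPair <- function() {
    ctl <- makeElut(rbind(P1 = c(5, 5, 0, 0),
                          P2 = c(8, 2, 0, 0),
                          P3 = c(0, 0, 3, 3)), condition = "control")
    trt <- makeElut(rbind(P1 = c(5, 5, 0, 0),
                          P2 = c(0, 0, 2, 8),
                          P3 = c(0, 0, 3, 3)), condition = "treated")
    alignPair(ctl, trt)
}

# independent elementwise L1 oracle (explicit loop, no vectorized reuse)
bruteL1 <- function(x, y) {
    total <- 0
    for (i in seq_along(x)) total <- total + abs(x[i] - y[i])
    total
}

# independent Benjamini-Hochberg step-up oracle
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (i in seq_len(m)) q[i] <- min(ps[i:m] * m / (i:m))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

# write a wide TSV elution file from a matrix
writeElutTsv <- function(mat, path) {
    df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}
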