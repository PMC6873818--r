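# Abundance-windowed significance: every protein's normalized score is
# compared against an empirical null built from proteins of similar
# abundance, because the normalized L1 score is biased by abundance (low
# counts -> noisier profiles -> larger scores under the null).

#' Order the background pool by abundance
#'
#' The background pool contains proteins eligible to serve as empirical-null
#' members: those with a defined score and no prior literature annotation as
#' RNA-associated. The pool is sorted by mean abundance, descending, with
#' ties broken lexicographically by protein identifier so window membership
#' is deterministic.
#'
#' @param de a scored [DiffracExperiment-class].
#' @param annotated character vector of literature-annotated RNA-associated
#'   protein identifiers to exclude from the pool (they would contaminate
#'   the null); may be empty.
#' @return data.frame with columns \code{id}, \code{Dnorm},
#'   \code{meanAbundance}, one row per pool member in abundance order.
#' @export
orderBackgroundPool <- function(de, annotated = character()) {
    rd <- rowData(de)
    if (is.null(rd$Dnorm))
        stop("experiment has not been scored; run scoreExperiment() first")
    keep <- rd$scoreDefined & !(rownames(de) %in% annotated)
    pool <- data.frame(id = rownames(de)[keep], Dnorm = rd$Dnorm[keep],
                       meanAbundance = rd$meanAbundance[keep],
                       stringsAsFactors = FALSE)
    if (nrow(pool) < 3L)
        stop("background pool has fewer than 3 proteins; ",
             "cannot fit an empirical null")
    pool[order(-pool$meanAbundance, pool$id), , drop = FALSE]
}

# Rank a query would occupy in the (abundance-desc, id-asc) ordered pool.
.poolRank <- function(pool, id, meanAbundance) {
    hit <- match(id, pool$id)
    if (!is.na(hit))
        return(list(rank = hit, inPool = TRUE))
    before <- pool$meanAbundance > meanAbundance |
        (pool$meanAbundance == meanAbundance & pool$id < id)
    list(rank = sum(before) + 1L, inPool = FALSE)
}

#' Extract a protein's abundance window from the background pool
#'
#' The window spans pool positions \eqn{[r - s, r + s]} around the rank
#' \eqn{r} the query protein occupies (or would occupy) in the
#' abundance-ordered pool — 2s+1 members for an interior protein. At the
#' pool edges the window is clamped and extended inward so the full width is
#' preserved whenever the pool allows; a pool smaller than 2s+1 degenerates
#' to the whole pool. The query's own score is never part of its window,
#' preventing extreme scorers from inflating their own null.
#'
#' @param pool ordered pool from [orderBackgroundPool()].
#' @param id query protein identifier.
#' @param meanAbundance the query's mean abundance (used to place proteins
#'   that are not pool members, e.g. annotated ones).
#' @param s half-width: the window covers \code{s} pool neighbours on each
#'   side (default 100).
#' @return list with \code{scores} (window member Dnorm values), \code{lo},
#'   \code{hi} (pool index range) and \code{selfIndex} (the query's pool
#'   index, NA when not a member).
#' @export
backgroundWindow <- function(pool, id, meanAbundance, s = 100L) {
    s <- as.integer(s)
    if (is.na(s) || s < 1L)
        stop("window half-width s must be >= 1")
    n <- nrow(pool)
    r <- .poolRank(pool, id, meanAbundance)
    width <- 2L * s + 1L
    lo <- r$rank - s
    hi <- r$rank + s
    if (lo < 1L) {
        lo <- 1L
        hi <- min(n, width)
    } else if (hi > n) {
        hi <- n
        lo <- max(1L, n - width + 1L)
    }
    idx <- lo:hi
    selfIndex <- if (r$inPool) r$rank else NA_integer_
    if (!is.na(selfIndex))
        idx <- idx[idx != selfIndex]
    list(scores = pool$Dnorm[idx], lo = lo, hi = hi, selfIndex = selfIndex)
}

#' Benjamini-Hochberg FDR correction
#'
#' Standard step-up adjusted p values with enforced monotonicity, preserving
#' input order. Undefined (NA) p values are excluded from the correction —
#' they do not count toward the number of tests — and come back as NA.
#'
#' @param p numeric vector of p values in [0, 1] (NAs allowed).
#' @return numeric vector of q values, same length and order.
#' @export
fdrCorrect <- function(p) {
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1))
        stop("p values must lie in [0, 1]")
    q <- rep(NA_real_, length(p))
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    q
}

#' Flag significant RNA-associated proteins
#'
#' @param q numeric vector of FDR-adjusted p values.
#' @param alpha FDR level; a protein is called significant when
#'   \code{q < alpha} (strict: q exactly at the level is not called).
#' @return logical vector (FALSE for NA q).
#' @export
callRnaAssociated <- function(q, alpha = 0.05) {
    !is.na(q) & q < alpha
}

#' Assign windowed-background significance to every protein
#'
#' For each protein with a defined score, takes its abundance window from
#' the annotation-free background pool, fits the one/two-component Gaussian
#' mixture ([fitBackground()]), computes the Z-score and upper-tail p value
#' of the protein's normalized score against the background component
#' ([gmmZP()]), then applies Benjamini-Hochberg correction across all
#' proteins and calls significance at \code{alpha}.
#'
#' Annotated proteins are excluded from window membership but are still
#' scored, placed at the abundance rank they would occupy in the pool.
#' Identical windows (common near the pool edges and for small pools) are
#' fitted once and cached.
#'
#' @param de a scored [DiffracExperiment-class].
#' @param annotated character vector of literature-annotated RNA-associated
#'   identifiers (excluded from the null; default none).
#' @param s window half-width in pool ranks (default 100).
#' @param tWeight two-component acceptance weight threshold (default 0.7,
#'   the midpoint of the 0.6-0.75 range that works in practice).
#' @param alpha FDR level for the significance call (default 0.05).
#' @param seed integer seed controlling EM restarts; fixed seed gives
#'   bit-identical results.
#' @param nRestarts,tol,maxIter,sigmaFloor passed to [fitBackground()].
#' @return \code{de} with rowData columns \code{Z}, \code{p}, \code{q},
#'   \code{significant}, plus \code{gmmComponents} (1/2, NA for undefined
#'   scores). Parameters are echoed in \code{metadata(de)$significance}.
#' @export
assignSignificance <- function(de, annotated = character(), s = 100L,
                               tWeight = 0.7, alpha = 0.05, seed = 1L,
                               nRestarts = 10L, tol = 1e-6, maxIter = 500L,
                               sigmaFloor = 1e-6) {
    stopifnot(is(de, "DiffracExperiment"))
    rd <- rowData(de)
    if (is.null(rd$Dnorm))
        stop("experiment has not been scored; run scoreExperiment() first")
    pool <- orderBackgroundPool(de, annotated)
    n <- nrow(de)
    ids <- rownames(de)
    Z <- p <- rep(NA_real_, n)
    comps <- rep(NA_integer_, n)
    cache <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
        if (!rd$scoreDefined[i])
            next
        w <- backgroundWindow(pool, ids[i], rd$meanAbundance[i], s = s)
        key <- paste(w$lo, w$hi, w$selfIndex, sep = ":")
        fit <- cache[[key]]
        if (is.null(fit)) {
            fit <- fitBackground(w$scores, tWeight = tWeight, seed = seed,
                                 nRestarts = nRestarts, tol = tol,
                                 maxIter = maxIter, sigmaFloor = sigmaFloor)
            cache[[key]] <- fit
        }
        zp <- gmmZP(rd$Dnorm[i], fit)
        Z[i] <- zp$z
        p[i] <- zp$p
        comps[i] <- fit@nComponents
    }
    q <- fdrCorrect(p)
    rowData(de)$Z <- Z
    rowData(de)$p <- p
    rowData(de)$q <- q
    rowData(de)$significant <- callRnaAssociated(q, alpha)
    rowData(de)$gmmComponents <- comps
    metadata(de)$significance <- list(s = s, tWeight = tWeight,
        alpha = alpha, seed = seed, nRestarts = nRestarts,
        nAnnotated = length(annotated), poolSize = nrow(pool))
    de
}

#' Export per-protein significance results as a data.frame
#'
#' @param de a [DiffracExperiment-class] after [assignSignificance()].
#' @return data.frame with columns \code{id, D_norm, mean_abundance, Z, p,
#'   q, significant}.
#' @export
significanceTable <- function(de) {
    rd <- rowData(de)
    if (is.null(rd$q))
        stop("run assignSignificance() first")
    data.frame(id = rownames(de), D_norm = rd$Dnorm,
               mean_abundance = rd$meanAbundance, Z = rd$Z, p = rd$p,
               q = rd$q, significant = rd$significant,
               stringsAsFactors = FALSE)
}
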