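# Synthetic paired CF-MS experiments with known ground truth. The generator
# emulates a ~50-fraction SEC separation: log-normal protein abundances,
# Gaussian elution peaks discretized onto the fraction grid, and Poisson
# (optionally negative-binomial) PSM sampling. A configurable subset of
# "RNA-associated" proteins gets a shifted and/or abundance-scaled treated
# profile; planted complexes share an elution template and, when true RNPs,
# shift coherently.

.discretePeak <- function(center, width, nFractions) {
    d <- stats::dnorm(seq_len(nFractions), mean = center, sd = width)
    s <- sum(d)
    if (s == 0) {   # peak fell far off the grid; park mass at nearest edge
        d <- numeric(nFractions)
        d[max(1L, min(nFractions, round(center)))] <- 1
        return(d)
    }
    d / s   # truncation at the edges renormalized: drawn abundance is kept
}

#' Simulate a paired control/treated elution experiment
#'
#' Generates a control and a treated [ElutionMatrix-class] plus per-protein
#' (and optionally per-complex) ground truth. Each protein draws a total
#' abundance from a log-normal, an elution peak center uniform over the
#' fraction grid and a peak width uniform over \code{peakWidthRange}; its
#' expected profile is the discretized, renormalized Gaussian times the
#' abundance, and observed PSM counts are Poisson (negative-binomial when
#' \code{dispersion} is finite) draws from it. True RNA-associated proteins
#' change between conditions: their treated peak center moves by a drawn
#' shift (by default toward later fractions, i.e. lower apparent molecular
#' weight — the dominant response to RNA removal) and their treated
#' abundance is scaled by a log-normal multiplier. Null proteins keep an
#' identical expected profile in both conditions; only counting noise
#' differs.
#'
#' @param nProteins number of simulated proteins (default 2000).
#' @param nFractions fractions in the separation (default 50).
#' @param abundanceMeanlog,abundanceSdlog log-normal parameters of the
#'   per-condition total PSM abundance (defaults \code{log(30)} and 1:
#'   median 30 PSMs, a realistic spectral-counting depth where the bulk of
#'   the proteome sits between a few and a few hundred PSMs).
#' @param peakWidthRange uniform range of the Gaussian peak SD in fractions
#'   (default c(1.5, 4)).
#' @param rnaFraction proportion of proteins that truly respond to
#'   treatment (default 0.1).
#' @param shiftRange uniform range of the peak-shift magnitude in fractions
#'   for true proteins (default c(8, 16)).
#' @param shiftTowardLowMwProb probability that a true protein's peak moves
#'   toward later fractions / lower apparent MW (default 0.8, mirroring the
#'   predominance of complex disassembly over gain of mass).
#' @param multiplierSdlog log-normal sdlog of the treated-abundance
#'   multiplier for true proteins (meanlog 0; default 0.25).
#' @param jitterScale abundance-variance coupling knob: each condition's
#'   peak center is jittered by N(0, jitterScale/sqrt(abundance)),
#'   adding extra profile variability for low-abundance proteins beyond
#'   counting noise. Default 0 (off), so null proteins have exactly equal
#'   expected profiles in both conditions.
#' @param dispersion negative-binomial size parameter; \code{Inf} (default)
#'   means Poisson counts. Real PSM counts are overdispersed, so finite
#'   values (e.g. 10) are useful for robustness checks.
#' @param complexes optional data.frame with columns \code{size},
#'   \code{shared} (logical: subunits share an elution template) and
#'   \code{rnp} (logical: subunits are true responders with a coherent
#'   shift), plus an optional \code{meanlog} column overriding the
#'   abundance log-mean for that complex's members — stable complexes
#'   recovered from CF-MS data sit in the well-detected part of the
#'   proteome, so planting them at a higher abundance than the proteome
#'   bulk is the realistic regime. Members are assigned to disjoint
#'   protein sets.
#' @param seed integer seed; a fixed seed gives bit-identical output. The
#'   caller's RNG state is left untouched.
#' @return list with elements \code{control}, \code{treated}
#'   ([ElutionMatrix-class]), \code{truth} (data.frame: \code{protein_id},
#'   \code{is_rna_associated}, \code{true_shift} — signed in fraction
#'   indices, positive toward later fractions —, \code{abundance},
#'   \code{abundance_multiplier}, \code{complex_id}), \code{complexes}
#'   (a [ComplexSet-class] or NULL) and \code{complexTruth} (data.frame:
#'   \code{complex_id}, \code{is_rnp}, or NULL).
#' @examples
#' sim <- simulateDiffrac(nProteins = 50, rnaFraction = 0.2, seed = 3)
#' sim$control
#' @export
simulateDiffrac <- function(nProteins = 2000L, nFractions = 50L,
                            abundanceMeanlog = log(30), abundanceSdlog = 1,
                            peakWidthRange = c(1.5, 4), rnaFraction = 0.1,
                            shiftRange = c(8, 16),
                            shiftTowardLowMwProb = 0.8,
                            multiplierSdlog = 0.25, jitterScale = 0,
                            dispersion = Inf, complexes = NULL, seed = 1L) {
    if (nFractions < 2L)
        stop("need at least 2 fractions")
    if (rnaFraction < 0 || rnaFraction > 1)
        stop("rnaFraction must be in [0, 1]")
    if (!all(is.finite(c(abundanceMeanlog, abundanceSdlog, peakWidthRange,
                         shiftRange, multiplierSdlog, jitterScale))))
        stop("distribution parameters must be finite")
    if (exists(".Random.seed", envir = globalenv())) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()),
                add = TRUE)
    }
    set.seed(seed)
    n <- as.integer(nProteins)
    ids <- sprintf("SIM%05d", seq_len(n))
    abundance <- stats::rlnorm(n, abundanceMeanlog, abundanceSdlog)
    center <- stats::runif(n, 1, nFractions)
    width <- stats::runif(n, peakWidthRange[1L], peakWidthRange[2L])
    isRna <- rep(FALSE, n)
    nTrue <- round(n * rnaFraction)
    if (nTrue > 0)
        isRna[sample.int(n, nTrue)] <- TRUE
    shift <- numeric(n)
    mult <- rep(1, n)
    mag <- stats::runif(n, shiftRange[1L], shiftRange[2L])
    sgn <- ifelse(stats::runif(n) < shiftTowardLowMwProb, 1, -1)
    shift[isRna] <- (mag * sgn)[isRna]
    mult[isRna] <- stats::rlnorm(sum(isRna), 0, multiplierSdlog)

    complexId <- rep(NA_character_, n)
    complexMembersList <- list()
    complexTruth <- NULL
    if (!is.null(complexes)) {
        complexes <- as.data.frame(complexes)
        need <- sum(complexes$size)
        if (need > n)
            stop("planted complexes need more proteins than simulated")
        free <- seq_len(n)
        for (k in seq_len(nrow(complexes))) {
            take <- free[seq_len(complexes$size[k])]
            free <- setdiff(free, take)
            cid <- sprintf("SIMCPX%03d", k)
            complexId[take] <- cid
            complexMembersList[[cid]] <- ids[take]
            if (!is.null(complexes$meanlog) &&
                is.finite(complexes$meanlog[k]))
                abundance[take] <- stats::rlnorm(length(take),
                    complexes$meanlog[k], abundanceSdlog)
            if (isTRUE(complexes$shared[k])) {
                tmpl <- stats::runif(1, 5, nFractions - 5)
                center[take] <- tmpl + stats::rnorm(length(take), 0, 0.5)
            }
            if (isTRUE(complexes$rnp[k])) {
                isRna[take] <- TRUE
                cShift <- stats::runif(1, shiftRange[1L], shiftRange[2L])
                shift[take] <- cShift
                mult[take] <- stats::rlnorm(length(take), 0, multiplierSdlog)
            } else {
                isRna[take] <- FALSE
                shift[take] <- 0
                mult[take] <- 1
            }
        }
        complexTruth <- data.frame(complex_id = names(complexMembersList),
                                   is_rnp = as.logical(complexes$rnp),
                                   stringsAsFactors = FALSE)
    }

    jitter <- function() if (jitterScale > 0)
        stats::rnorm(n, 0, jitterScale / sqrt(abundance)) else numeric(n)
    drawCounts <- function(mu) {
        v <- if (is.finite(dispersion))
            stats::rnbinom(length(mu), size = dispersion, mu = mu)
        else stats::rpois(length(mu), mu)
        v
    }
    ctl <- trt <- matrix(0, n, nFractions,
        dimnames = list(ids, sprintf("f%d", seq_len(nFractions))))
    jC <- jitter()
    jT <- jitter()
    for (i in seq_len(n)) {
        pC <- .discretePeak(center[i] + jC[i], width[i], nFractions)
        ctl[i, ] <- drawCounts(abundance[i] * pC)
        pT <- .discretePeak(center[i] + jT[i] + shift[i], width[i],
                            nFractions)
        trt[i, ] <- drawCounts(abundance[i] * mult[i] * pT)
    }
    truth <- data.frame(protein_id = ids, is_rna_associated = isRna,
                        true_shift = shift, abundance = abundance,
                        abundance_multiplier = mult, complex_id = complexId,
                        stringsAsFactors = FALSE)
    list(control = ElutionMatrix(ctl, "control"),
         treated = ElutionMatrix(trt, "treated"),
         truth = truth,
         complexes = if (length(complexMembersList))
             ComplexSet(complexMembersList, source = "simulated") else NULL,
         complexTruth = complexTruth)
}

#' Compare calls against simulation ground truth
#'
#' Confusion-table metrics at the protein level (significant calls vs true
#' RNA-associated status) and optionally at the complex level (RNP Select
#' calls vs planted-RNP status).
#'
#' @param de a [DiffracExperiment-class] after [assignSignificance()].
#' @param truth the per-protein truth data.frame from [simulateDiffrac()].
#' @param complexCalls optional data.frame with \code{complex_id} and a
#'   logical call column (default \code{is_rnp_select}).
#' @param complexTruth optional data.frame with \code{complex_id},
#'   \code{is_rnp}.
#' @param callColumn name of the logical column in \code{complexCalls} to
#'   evaluate.
#' @return list with \code{protein} (data.frame: tp, fp, tn, fn, fdp,
#'   sensitivity, specificity) and, when complex inputs are given,
#'   \code{complexes} (same columns). The realized false-discovery
#'   proportion (fdp) is 0 when nothing is called.
#' @export
evaluateRecovery <- function(de, truth, complexCalls = NULL,
                             complexTruth = NULL,
                             callColumn = "is_rnp_select") {
    stopifnot(is(de, "DiffracExperiment"))
    rd <- rowData(de)
    if (is.null(rd$significant))
        stop("run assignSignificance() first")
    if (!setequal(rownames(de), truth$protein_id))
        stop("protein identifiers in results and truth do not match")
    isTrue <- truth$is_rna_associated[match(rownames(de),
                                            truth$protein_id)]
    called <- rd$significant
    conf <- function(called, isTrue) {
        tp <- sum(called & isTrue)
        fp <- sum(called & !isTrue)
        fn <- sum(!called & isTrue)
        tn <- sum(!called & !isTrue)
        data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
            fdp = if (tp + fp > 0) fp / (tp + fp) else 0,
            sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
            specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
    }
    out <- list(protein = conf(called, isTrue))
    if (!is.null(complexCalls) && !is.null(complexTruth)) {
        if (!all(complexTruth$complex_id %in% complexCalls$complex_id))
            stop("complex identifiers in calls and truth do not match")
        m <- match(complexTruth$complex_id, complexCalls$complex_id)
        out$complexes <- conf(as.logical(complexCalls[[callColumn]][m]),
                              as.logical(complexTruth$is_rnp))
    }
    out
}
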