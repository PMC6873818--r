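# 1-D Gaussian mixture machinery for the abundance-windowed empirical null.
# Hand-written EM (inner loop in C++, src/gmm_em.cpp): one fit per protein
# across the whole proteome, so it has to be fast and bit-reproducible
# under a seed.

#' @useDynLib diffrac, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.gmm1 <- function(x) {
    n <- length(x)
    mu <- mean(x)
    sigma <- sqrt(sum((x - mu)^2) / n)   # MLE, consistent with EM loglik
    ll <- sum(stats::dnorm(x, mu, max(sigma, 1e-12), log = TRUE))
    list(weights = 1, means = mu, sds = sigma, loglik = ll,
         bic = -2 * ll + 2 * log(n))
}

.gmm2 <- function(x, nRestarts, tol, maxIter) {
    n <- length(x)
    nStarts <- max(1L, as.integer(nRestarts))
    mu0 <- matrix(0, 2L, nStarts)
    sd0 <- matrix(0, 2L, nStarts)
    w0 <- matrix(0.5, 2L, nStarts)
    # deterministic first start: split at the median
    xs <- sort(x)
    lo <- xs[seq_len(floor(n / 2))]
    hi <- xs[(floor(n / 2) + 1L):n]
    s0 <- stats::sd(x)
    mu0[, 1L] <- c(mean(lo), mean(hi))
    sd0[, 1L] <- pmax(c(stats::sd(lo), stats::sd(hi)), s0 / 10, 1e-6)
    for (r in seq_len(nStarts - 1L)) {
        m <- sort(sample(x, 2L))
        if (m[1L] == m[2L]) m <- m + c(-s0 / 4, s0 / 4)
        mu0[, r + 1L] <- m
        sd0[, r + 1L] <- max(s0 / 2, 1e-6)
    }
    fit <- .em2Best(x, mu0, sd0, w0, tol, maxIter)
    if (!isTRUE(fit$ok))
        return(NULL)
    fit$bic <- -2 * fit$loglik + 5 * log(n)
    fit
}

#' Fit the windowed Gaussian-mixture background and select a model
#'
#' Fits one- and two-component Gaussian mixtures (EM with a deterministic
#' median-split start plus seeded random restarts) to the differential
#' scores of an abundance window, then accepts the two-component model only
#' if all three criteria hold:
#' \enumerate{
#'   \item \eqn{BIC_2 \le BIC_1} (BIC computed as \eqn{-2\log L + k\log n});
#'   \item the component with the lowest mean — interpreted as the
#'     non-RNA-associated background — carries the largest weight;
#'   \item that largest weight is at least \code{tWeight}.
#' }
#' Otherwise the one-component fit is used. The returned \code{mu} and
#' \code{sigma} come from the lowest-mean component of the chosen model and
#' define the null for [gmmZP()].
#'
#' The two-component alternative exists because the window itself is
#' contaminated: proteins not yet annotated as RNA-associated can still be
#' true responders, inflating the upper tail. \code{tWeight} encodes the
#' expected proportion of non-responders; values between 0.6 and 0.75 work
#' well in practice and 0.7 is the default.
#'
#' @param scores numeric vector of window member scores (no NAs).
#' @param tWeight weight threshold in (0, 1) for criterion 3.
#' @param seed integer seed for the random restarts (the first start is
#'   deterministic); the caller's RNG state is left untouched.
#' @param nRestarts number of EM starts for the two-component fit.
#' @param tol EM log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations per start.
#' @param sigmaFloor lower bound for \code{sigma} so Z-scores stay finite on
#'   degenerate windows.
#' @return A [GmmFit-class].
#' @examples
#' set.seed(7)
#' w <- c(rnorm(140, 0.2, 0.05), rnorm(61, 1.2, 0.1))
#' fitBackground(w)   # two components accepted; mu ~ 0.2
#' @export
fitBackground <- function(scores, tWeight = 0.7, seed = 1L, nRestarts = 10L,
                          tol = 1e-6, maxIter = 500L, sigmaFloor = 1e-6) {
    if (!length(scores))
        stop("empty background window")
    if (anyNA(scores))
        stop("window scores must not contain NA")
    if (tWeight <= 0 || tWeight >= 1)
        stop("tWeight must be in (0, 1)")
    n <- length(scores)
    if (n < 4L || stats::sd(scores) < sigmaFloor) {
        mu <- mean(scores)
        return(new("GmmFit", nComponents = 1L, weights = 1, means = mu,
            sds = max(stats::sd(scores), 0, na.rm = TRUE),
            bic = c(bic1 = NA_real_, bic2 = NA_real_),
            criteria = c(bic = FALSE, low_mean_heaviest = FALSE,
                         weight_threshold = FALSE),
            mu = mu, sigma = max(stats::sd(scores), sigmaFloor, na.rm = TRUE),
            tWeight = tWeight, degenerate = TRUE, n = n))
    }
    f1 <- .gmm1(scores)
    if (!is.null(seed)) {
        if (exists(".Random.seed", envir = globalenv())) {
            oldSeed <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", oldSeed, envir = globalenv()),
                    add = TRUE)
        } else {
            on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
        }
        set.seed(seed)
    }
    f2 <- .gmm2(scores, nRestarts, tol, maxIter)
    if (is.null(f2)) {   # every EM start collapsed: no usable 2-component fit
        return(new("GmmFit", nComponents = 1L, weights = 1, means = f1$means,
            sds = f1$sds, bic = c(bic1 = f1$bic, bic2 = NA_real_),
            criteria = c(bic = FALSE, low_mean_heaviest = FALSE,
                         weight_threshold = FALSE),
            mu = f1$means, sigma = max(f1$sds, sigmaFloor),
            tWeight = tWeight, degenerate = FALSE, n = n))
    }
    lowIdx <- which.min(f2$means)
    crit <- c(bic = f2$bic <= f1$bic,
              low_mean_heaviest = which.max(f2$weights) == lowIdx,
              weight_threshold = max(f2$weights) >= tWeight)
    use2 <- all(crit)
    chosen <- if (use2) f2 else f1
    ci <- if (use2) lowIdx else 1L
    new("GmmFit", nComponents = if (use2) 2L else 1L,
        weights = chosen$weights, means = chosen$means, sds = chosen$sds,
        bic = c(bic1 = f1$bic, bic2 = f2$bic), criteria = crit,
        mu = chosen$means[ci], sigma = max(chosen$sds[ci], sigmaFloor),
        tWeight = tWeight, degenerate = FALSE, n = n)
}

#' Z-score and upper-tail p value against a fitted background
#'
#' \deqn{Z = (D^{norm} - \mu) / \sigma}{Z = (Dnorm - mu) / sigma}
#' with \eqn{\mu}, \eqn{\sigma} from the background component of the chosen
#' mixture; the p value is the standard-normal survival function of Z
#' (one-sided: only scores larger than the background are evidence of RNase
#' sensitivity).
#'
#' @param Dnorm numeric vector of normalized differential scores.
#' @param fit a [GmmFit-class].
#' @return list with numeric vectors \code{z} and \code{p}. For a
#'   degenerate (zero-variance) window the Z-score is still finite thanks to
#'   the sigma floor, but \code{p} is reported NA: a normal tail probability
#'   from a collapsed background is meaningless.
#' @export
gmmZP <- function(Dnorm, fit) {
    stopifnot(is(fit, "GmmFit"))
    z <- (Dnorm - fit@mu) / fit@sigma
    p <- if (fit@degenerate) rep(NA_real_, length(Dnorm))
         else stats::pnorm(z, lower.tail = FALSE)
    list(z = z, p = p)
}

setMethod("show", "GmmFit", function(object) {
    cat(sprintf(
        "GmmFit: %d component(s) over %d scores; mu = %.4g, sigma = %.4g\n",
        object@nComponents, object@n, object@mu, object@sigma))
    if (!object@degenerate)
        cat(sprintf("  BIC1 = %.2f, BIC2 = %.2f; criteria passed: %s\n",
            object@bic[["bic1"]], object@bic[["bic2"]],
            paste(names(object@criteria)[object@criteria], collapse = ", ")))
})
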