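# Elution-shift classification: where did the protein's mass go upon
# treatment (apparent molecular weight axis) and how much of it survived
# (abundance axis)?

#' PSM-weighted mean elution fraction
#'
#' The centroid of an elution profile: the average (1-based) fraction index
#' weighted by the PSMs observed in each fraction,
#' \eqn{\sum_i i\,x_i / \sum_i x_i}. Scale-invariant.
#'
#' @param x numeric elution profile.
#' @return weighted mean fraction, or NA for an all-zero profile.
#' @examples
#' weightedFraction(c(1, 0, 3))   # 2.5
#' @export
weightedFraction <- function(x) {
    tot <- sum(x)
    if (tot == 0)
        return(NA_real_)
    sum(seq_along(x) * x) / tot
}

#' Signed elution shift between control and treated profiles
#'
#' \code{weightedFraction(control) - weightedFraction(treated)}. In SEC,
#' later fractions hold smaller species, so a protein moving from high to
#' low apparent molecular weight (its complex disassembling) moves to later
#' fractions and gets a negative shift; a positive shift is an apparent
#' molecular-weight increase.
#'
#' @param x control profile.
#' @param y treated profile.
#' @return signed shift in fractions; NA when either profile is all zero.
#' @export
elutionShift <- function(x, y) {
    wx <- weightedFraction(x)
    wy <- weightedFraction(y)
    if (is.na(wx) || is.na(wy))
        return(NA_real_)
    wx - wy
}

#' Normalized abundance change upon treatment
#'
#' \eqn{(\sum y - \sum x) / (\sum y + \sum x)}: the difference of the
#' protein's total PSMs, normalized by their sum. Bounded in [-1, 1];
#' positive means the protein became more abundant (more soluble) after
#' treatment, -1 means it vanished.
#'
#' @param x control profile.
#' @param y treated profile.
#' @return value in [-1, 1]; NA when both totals are zero.
#' @export
abundanceChange <- function(x, y) {
    tx <- sum(x)
    ty <- sum(y)
    if (tx + ty == 0)
        return(NA_real_)
    (ty - tx) / (ty + tx)
}

#' Compute and classify elution shifts for an experiment
#'
#' Adds per-protein shift metrics to \code{rowData}: the control/treated
#' weighted mean fractions, the signed shift, the normalized abundance
#' change, and two independent class labels:
#' \describe{
#'   \item{mwClass}{\code{decrease_mw} (shift < 0), \code{increase_mw}
#'     (shift > 0) or \code{none} (shift exactly 0). Exact zeros are a real,
#'     trackable class, not a rounding artifact.}
#'   \item{solubilityClass}{\code{increase_abundance},
#'     \code{decrease_abundance} or \code{none} from the sign of the
#'     abundance change.}
#' }
#' By default only significant (RNase-sensitive) proteins receive class
#' labels — the class percentages are meant to describe identified
#' RNA-associated proteins — while the numeric metrics are computed for all.
#'
#' @param de a [DiffracExperiment-class]; needs [assignSignificance()]
#'   first unless \code{significantOnly = FALSE}.
#' @param significantOnly classify only significant proteins (default TRUE).
#' @return \code{de} with rowData columns \code{wControl}, \code{wTreated},
#'   \code{shift}, \code{dAbundance}, \code{mwClass}, \code{solubilityClass}.
#' @seealso [signalClassSummary()]
#' @export
classifySignals <- function(de, significantOnly = TRUE) {
    stopifnot(is(de, "DiffracExperiment"))
    rd <- rowData(de)
    x <- controlCounts(de)
    y <- treatedCounts(de)
    tx <- rowSums(x)
    ty <- rowSums(y)
    idx <- seq_len(ncol(x))
    wC <- ifelse(tx > 0, as.vector(x %*% idx) / tx, NA_real_)
    wT <- ifelse(ty > 0, as.vector(y %*% idx) / ty, NA_real_)
    shift <- wC - wT
    dAb <- ifelse(tx + ty > 0, (ty - tx) / (ty + tx), NA_real_)
    inScope <- if (significantOnly) {
        if (is.null(rd$significant))
            stop("run assignSignificance() first, or set ",
                 "significantOnly = FALSE")
        rd$significant
    } else rep(TRUE, nrow(de))
    mwClass <- rep(NA_character_, nrow(de))
    solClass <- rep(NA_character_, nrow(de))
    def <- inScope & !is.na(shift)
    mwClass[def] <- ifelse(shift[def] < 0, "decrease_mw",
                    ifelse(shift[def] > 0, "increase_mw", "none"))
    defA <- inScope & !is.na(dAb)
    solClass[defA] <- ifelse(dAb[defA] > 0, "increase_abundance",
                      ifelse(dAb[defA] < 0, "decrease_abundance", "none"))
    rowData(de)$wControl <- unname(wC)
    rowData(de)$wTreated <- unname(wT)
    rowData(de)$shift <- unname(shift)
    rowData(de)$dAbundance <- unname(dAb)
    rowData(de)$mwClass <- mwClass
    rowData(de)$solubilityClass <- solClass
    de
}

#' Summarize signal classes
#'
#' Counts and percentages per molecular-weight class and per
#' abundance (solubility) class among classified proteins.
#'
#' @param de a [DiffracExperiment-class] after [classifySignals()].
#' @return data.frame with columns \code{axis}, \code{class}, \code{n},
#'   \code{percent}.
#' @export
signalClassSummary <- function(de) {
    rd <- rowData(de)
    if (is.null(rd$mwClass))
        stop("run classifySignals() first")
    one <- function(axis, v) {
        v <- v[!is.na(v)]
        if (!length(v))
            return(data.frame(axis = character(), class = character(),
                              n = integer(), percent = numeric()))
        tab <- table(v)
        data.frame(axis = axis, class = names(tab), n = as.integer(tab),
                   percent = 100 * as.integer(tab) / length(v),
                   stringsAsFactors = FALSE, row.names = NULL)
    }
    rbind(one("mw", rd$mwClass), one("solubility", rd$solubilityClass))
}

#' Export shift metrics as a data.frame
#'
#' @param de a [DiffracExperiment-class] after [classifySignals()].
#' @return data.frame with columns \code{id, w_control, w_treated, shift,
#'   d_abundance, mw_class, solubility_class}.
#' @export
shiftTable <- function(de) {
    rd <- rowData(de)
    if (is.null(rd$mwClass))
        stop("run classifySignals() first")
    data.frame(id = rownames(de), w_control = rd$wControl,
               w_treated = rd$wTreated, shift = rd$shift,
               d_abundance = rd$dAbundance, mw_class = rd$mwClass,
               solubility_class = rd$solubilityClass,
               stringsAsFactors = FALSE)
}
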