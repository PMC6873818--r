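#' @describeIn diffrac-accessors PSM count matrix.
#' @export
setMethod("psmCounts", "ElutionMatrix", function(object) object@counts)

#' @describeIn diffrac-accessors condition label.
#' @export
setMethod("conditionLabel", "ElutionMatrix",
    function(object) object@condition)

#' @describeIn diffrac-accessors protein identifiers.
#' @export
setMethod("proteinIds", "ElutionMatrix",
    function(object) rownames(object@counts))

#' @describeIn diffrac-accessors protein identifiers.
#' @export
setMethod("proteinIds", "DiffracExperiment", function(object) rownames(object))

#' @describeIn diffrac-accessors fraction labels.
#' @export
setMethod("fractionLabels", "ElutionMatrix",
    function(object) colnames(object@counts))

#' @describeIn diffrac-accessors fraction labels.
#' @export
setMethod("fractionLabels", "DiffracExperiment",
    function(object) colnames(object))

#' @describeIn diffrac-accessors control PSM counts.
#' @export
setMethod("controlCounts", "DiffracExperiment",
    function(object) assay(object, "control"))

#' @describeIn diffrac-accessors treated PSM counts.
#' @export
setMethod("treatedCounts", "DiffracExperiment",
    function(object) assay(object, "treated"))

setMethod("show", "ElutionMatrix", function(object) {
    cat(sprintf("ElutionMatrix '%s': %d proteins x %d fractions (%.0f PSMs)\n",
        object@condition, nrow(object@counts), ncol(object@counts),
        sum(object@counts)))
})

setMethod("show", "DiffracExperiment", function(object) {
    cat(sprintf("DiffracExperiment: %d proteins x %d fractions\n",
        nrow(object), ncol(object)))
    cat(sprintf("  assays: %s\n", paste(assayNames(object), collapse = ", ")))
    rd <- names(rowData(object))
    if (length(rd))
        cat(sprintf("  rowData: %s\n", paste(rd, collapse = ", ")))
})

#' Read an elution matrix from a wide TSV (.elut) file
#'
#' The expected layout is one header row \code{id<TAB>f1<TAB>f2...} followed
#' by one row per protein: first column the protein identifier, remaining
#' columns PSM counts in elution (column) order. Blank cells mean 0 — a
#' protein not identified in a fraction contributes no spectral matches.
#'
#' @param path path to a tab-separated file.
#' @param condition condition label to attach (e.g. \code{"control"}).
#' @return An [ElutionMatrix-class].
#' @details Duplicate protein identifiers, negative counts, or fewer than
#'   two fraction columns are hard errors: each silently corrupts every
#'   downstream score.
#' @seealso [writeElutionMatrix()], [alignPair()]
#' @export
readElutionMatrix <- function(path, condition = "unnamed") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
        check.names = FALSE, colClasses = NA, stringsAsFactors = FALSE)
    if (ncol(df) < 3L)
        stop("elution matrix needs an id column plus at least 2 fractions: ",
             path)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate protein identifier(s) in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    m[is.na(m)] <- 0
    if (any(m < 0))
        stop("negative count(s) in ", path)
    rownames(m) <- ids
    ElutionMatrix(m, condition)
}

#' Write an elution matrix as a wide TSV (.elut) file
#'
#' Inverse of [readElutionMatrix()]: round-trips losslessly for integer
#' counts.
#'
#' @param x an [ElutionMatrix-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeElutionMatrix <- function(x, path) {
    stopifnot(is(x, "ElutionMatrix"))
    m <- psmCounts(x)
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Align a control/treated pair onto a shared protein universe
#'
#' Builds a [DiffracExperiment-class] whose row space is the union of the
#' two conditions' proteins, sorted by identifier for determinism. A protein
#' observed in only one condition gets an all-zero profile in the other and
#' stays in the analysis: complete loss (or gain) of a protein upon
#' treatment is itself a maximal differential-elution signal.
#'
#' Fraction grids must match exactly by index — profiles are compared
#' fraction-by-fraction and no cross-grid interpolation is defined (any
#' resampling would silently change the score), so unequal fraction counts
#' are a hard error.
#'
#' @param control,treated [ElutionMatrix-class] objects with the same number
#'   of fractions.
#' @return A [DiffracExperiment-class] with assays \code{control} and
#'   \code{treated}.
#' @examples
#' ctl <- ElutionMatrix(matrix(1:4, 2, dimnames = list(c("A", "B"),
#'     c("f1", "f2"))), "control")
#' trt <- ElutionMatrix(matrix(1:4, 2, dimnames = list(c("B", "C"),
#'     c("f1", "f2"))), "rnase")
#' alignPair(ctl, trt)   # universe {A, B, C}; A all-zero in treated
#' @export
alignPair <- function(control, treated) {
    stopifnot(is(control, "ElutionMatrix"), is(treated, "ElutionMatrix"))
    mc <- psmCounts(control)
    mt <- psmCounts(treated)
    if (ncol(mc) != ncol(mt))
        stop("fraction grids differ: control has ", ncol(mc),
             " fractions, treated has ", ncol(mt))
    ids <- sort(union(rownames(mc), rownames(mt)))
    expand <- function(m) {
        out <- matrix(0, nrow = length(ids), ncol = ncol(m),
                      dimnames = list(ids, colnames(mc)))
        out[rownames(m), ] <- m
        out
    }
    se <- SummarizedExperiment(
        assays = list(control = expand(mc), treated = expand(mt)),
        rowData = DataFrame(row.names = ids))
    de <- new("DiffracExperiment", se)
    metadata(de)$condition_labels <- c(control = conditionLabel(control),
                                       treated = conditionLabel(treated))
    de
}

#' Calibrate fraction position against molecular weight
#'
#' Fits \code{log10(kDa) ~ fraction} by least squares to size standards
#' (e.g. thyroglobulin 669 kDa, apoferritin 443 kDa, albumin 66 kDa,
#' carbonic anhydrase 29 kDa run on the same column). In SEC, apparent
#' molecular weight falls roughly log-linearly with elution fraction, so a
#' two-point calibration passes exactly through both anchors.
#'
#' @param standards data.frame (or 2-column matrix) with columns
#'   \code{fraction} and \code{kda}; at least two rows.
#' @return An [MwCalibration-class].
#' @details Non-monotonic standards (molecular weight not strictly
#'   decreasing with fraction) produce a warning, not an error: the fit is
#'   still returned but predictions should be treated with suspicion.
#' @seealso [predictMw()]
#' @export
calibrateMw <- function(standards) {
    standards <- as.data.frame(standards)
    if (ncol(standards) < 2L)
        stop("standards need columns (fraction, kda)")
    colnames(standards)[1:2] <- c("fraction", "kda")
    if (nrow(standards) < 2L)
        stop("need at least 2 molecular-weight standards")
    if (any(standards$kda <= 0))
        stop("molecular weights must be positive")
    o <- order(standards$fraction)
    mono <- all(diff(standards$kda[o]) < 0)
    if (!mono)
        warning("standards are not strictly decreasing in molecular weight ",
                "with fraction position; calibration may be unreliable")
    fit <- stats::lm(log10(kda) ~ fraction, data = standards)
    new("MwCalibration", standards = standards,
        coefficients = unname(stats::coef(fit)), monotonic = mono)
}

#' Predict apparent molecular weight (kDa) at fraction positions
#'
#' @param calibration an [MwCalibration-class].
#' @param fraction numeric vector of fraction positions.
#' @return Numeric vector of predicted kDa.
#' @export
predictMw <- function(calibration, fraction) {
    stopifnot(is(calibration, "MwCalibration"))
    b <- calibration@coefficients
    10^(b[1L] + b[2L] * fraction)
}

setMethod("show", "MwCalibration", function(object) {
    b <- object@coefficients
    cat(sprintf(
        "MwCalibration: log10(kDa) = %.4f %+.4f * fraction (%d standards%s)\n",
        b[1L], b[2L], nrow(object@standards),
        if (object@monotonic) "" else ", non-monotonic"))
})
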