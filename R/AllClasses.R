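#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData rowData<-
NULL

#' ElutionMatrix: one condition's protein-by-fraction spectral-count table
#'
#' A minimal container for a co-fractionation mass spectrometry (CF-MS)
#' elution experiment: a numeric matrix of peptide-spectral-match (PSM)
#' counts with proteins as rows and chromatographic fractions as columns,
#' plus a condition label (e.g. \code{"control"} or \code{"rnase"}).
#' Fraction order is the elution order; for size-exclusion chromatography
#' (SEC) earlier fractions hold larger assemblies.
#'
#' Counts are non-negative reals (not just integers) so normalized or
#' rescaled matrices flow through the same code path. Missing cells are not
#' permitted: absence of evidence is encoded as 0 at load time.
#'
#' @slot counts numeric matrix, proteins x fractions; non-negative, no NAs;
#'   rownames are unique protein identifiers, colnames are fraction labels.
#' @slot condition single character condition label.
#'
#' @seealso [readElutionMatrix()], [alignPair()]
#' @export
setClass("ElutionMatrix",
    representation(counts = "matrix", condition = "character"))

setValidity("ElutionMatrix", function(object) {
    m <- object@counts
    if (!is.numeric(m))
        return("counts must be numeric")
    if (length(object@condition) != 1L || is.na(object@condition))
        return("condition must be a single non-NA string")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("counts must have protein rownames and fraction colnames")
    if (anyDuplicated(rownames(m)))
        return(sprintf("duplicate protein identifier(s): %s",
            paste(unique(rownames(m)[duplicated(rownames(m))]),
                  collapse = ", ")))
    if (ncol(m) < 2L)
        return("an elution matrix needs at least 2 fractions")
    if (anyNA(m))
        return("counts must not contain NA (missing cells are 0)")
    if (any(m < 0))
        return("counts must be non-negative")
    TRUE
})

#' Construct an ElutionMatrix
#'
#' @param counts numeric matrix (proteins x fractions) with rownames and
#'   colnames.
#' @param condition condition label.
#' @return An [ElutionMatrix-class] object.
#' @examples
#' m <- matrix(c(0, 3, 1, 0, 2, 5), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("P1", "P2"), c("f1", "f2", "f3")))
#' ElutionMatrix(m, "control")
#' @export
ElutionMatrix <- function(counts, condition = "unnamed") {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    new("ElutionMatrix", counts = counts, condition = as.character(condition))
}

#' DiffracExperiment: an aligned control/treated pair
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are proteins (the union
#' of the two conditions' protein universes, zero-filled where a protein was
#' not observed), columns are fractions, and the two assays are
#' \code{"control"} and \code{"treated"}. Per-protein results (scores,
#' significance, shift metrics) accumulate in \code{rowData}.
#'
#' @seealso [alignPair()], [scoreExperiment()], [assignSignificance()]
#' @export
setClass("DiffracExperiment", contains = "SummarizedExperiment")

setValidity("DiffracExperiment", function(object) {
    an <- assayNames(object)
    if (!all(c("control", "treated") %in% an))
        return("assays must include 'control' and 'treated'")
    for (nm in c("control", "treated")) {
        a <- assay(object, nm)
        if (anyNA(a) || any(a < 0))
            return(sprintf("assay '%s' must be non-negative with no NAs", nm))
    }
    if (ncol(object) < 2L)
        return("need at least 2 fractions")
    if (anyDuplicated(rownames(object)))
        return("duplicate protein identifiers")
    TRUE
})

#' MwCalibration: fraction-to-molecular-weight mapping
#'
#' Log-linear calibration of a size-exclusion column from protein standards
#' of known molecular weight: \code{log10(kDa) ~ fraction}. Apparent
#' molecular weight decreases with fraction number in SEC, so a valid
#' calibration has a negative slope.
#'
#' @slot standards data.frame with columns \code{fraction} and \code{kda}.
#' @slot coefficients numeric length-2 (intercept, slope) of the
#'   \code{log10(kda) ~ fraction} least-squares fit.
#' @slot monotonic logical; TRUE when the standards' molecular weights are
#'   strictly decreasing in fraction position.
#' @seealso [calibrateMw()], [predictMw()]
#' @export
setClass("MwCalibration",
    representation(standards = "data.frame", coefficients = "numeric",
                   monotonic = "logical"))

setValidity("MwCalibration", function(object) {
    if (nrow(object@standards) < 2L)
        return("need at least 2 molecular-weight standards")
    if (length(object@coefficients) != 2L)
        return("coefficients must be (intercept, slope)")
    TRUE
})

#' ComplexSet: named protein complexes
#'
#' Protein-complex definitions in the CORUM / hu.MAP style: each complex is
#' a set of subunit protein identifiers with a name and a provenance label.
#'
#' @slot members named list of character vectors (subunit IDs per complex).
#' @slot info DataFrame with one row per complex: \code{complex_id},
#'   \code{name}, \code{source}.
#' @seealso [readComplexSet()], [mergeComplexSets()], [callRnp()]
#' @export
setClass("ComplexSet",
    representation(members = "list", info = "DataFrame"))

setValidity("ComplexSet", function(object) {
    if (length(object@members) != nrow(object@info))
        return("members and info must describe the same complexes")
    if (length(object@members)) {
        if (is.null(names(object@members)) ||
            anyDuplicated(names(object@members)))
            return("complex ids must be unique and non-empty")
        sizes <- lengths(object@members)
        if (any(sizes < 2L))
            return(sprintf("complex(es) with fewer than 2 subunits: %s",
                paste(names(object@members)[sizes < 2L], collapse = ", ")))
    }
    TRUE
})

#' AnnotationSet: literature RNA-binding annotations
#'
#' Protein identifiers annotated as RNA-binding, split into low-throughput
#' (curated GO evidence codes / UniProt keywords) and high-throughput
#' (interactome-capture style studies) sets. The two sets may overlap.
#'
#' @slot lt character vector of low-throughput-annotated protein IDs.
#' @slot ht character vector of high-throughput-annotated protein IDs.
#' @slot sources DataFrame mapping \code{protein_id} to \code{set}
#'   (\code{"lt"}/\code{"ht"}) and a free-text \code{source} tag.
#' @seealso [loadAnnotations()]
#' @export
setClass("AnnotationSet",
    representation(lt = "character", ht = "character", sources = "DataFrame"))

#' GmmFit: fitted background mixture for one abundance window
#'
#' Result of fitting one- and two-component Gaussian mixtures to a window of
#' normalized differential-elution scores and selecting between them. The
#' two-component model is accepted only when (a) its BIC is no worse than
#' the one-component BIC, (b) the lowest-mean component carries the largest
#' weight, and (c) that weight reaches \code{tWeight}; otherwise the
#' one-component fit is used. \code{mu}/\code{sigma} are taken from the
#' lowest-mean (putatively non-RNA-associated) component of the chosen model
#' and feed the Z-score.
#'
#' @slot nComponents 1L or 2L, the chosen model.
#' @slot weights,means,sds parameters of the chosen model's components.
#' @slot bic named numeric: BICs of the 1- and 2-component fits
#'   (\code{-2 logLik + k log n}; smaller is better).
#' @slot criteria named logical: the three selection criteria for the
#'   two-component model (\code{bic}, \code{low_mean_heaviest},
#'   \code{weight_threshold}).
#' @slot mu,sigma background mean and standard deviation used for Z-scores
#'   (sigma floored at \code{sigmaFloor}).
#' @slot tWeight the weight threshold used.
#' @slot degenerate TRUE when the window had (near-)zero variance.
#' @slot n number of window member scores fitted.
#' @seealso [fitBackground()], [gmmZP()]
#' @export
setClass("GmmFit",
    representation(nComponents = "integer", weights = "numeric",
                   means = "numeric", sds = "numeric", bic = "numeric",
                   criteria = "logical", mu = "numeric", sigma = "numeric",
                   tWeight = "numeric", degenerate = "logical", n = "integer"))
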