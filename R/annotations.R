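#' @describeIn diffrac-accessors low-throughput annotated IDs.
#' @export
setMethod("ltAnnotated", "AnnotationSet", function(object) object@lt)

#' @describeIn diffrac-accessors high-throughput annotated IDs.
#' @export
setMethod("htAnnotated", "AnnotationSet", function(object) object@ht)

setMethod("show", "AnnotationSet", function(object) {
    cat(sprintf(
        "AnnotationSet: %d low-throughput, %d high-throughput (%d shared)\n",
        length(object@lt), length(object@ht),
        length(intersect(object@lt, object@ht))))
})

.readAnnotationFile <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) {
        warning("annotation file is empty: ", path)
        return(data.frame(protein_id = character(), source = character(),
                          stringsAsFactors = FALSE))
    }
    parts <- strsplit(lines, "\t")
    data.frame(protein_id = vapply(parts, `[`, character(1), 1L),
               source = vapply(parts, function(p)
                   if (length(p) > 1L) p[2L] else basename(path),
                   character(1)),
               stringsAsFactors = FALSE)
}

#' Load RNA-binding annotation sets
#'
#' Reads plain-text annotation files (one protein ID per line, \code{#}
#' comments allowed, optional second TAB column with a source tag) into an
#' [AnnotationSet-class]. Low-throughput files typically come from curated
#' GO "RNA binding" terms restricted to experimental/curated evidence codes
#' plus UniProt ribonucleoprotein keywords; high-throughput files from
#' interactome-capture style studies. Building those files is upstream of
#' this package — no live database queries are performed, keeping runs
#' reproducible and offline.
#'
#' @param ltFiles,htFiles character vectors of file paths (either may be
#'   empty).
#' @param idMap optional path to a two-column TSV \code{from<TAB>to}
#'   translating annotation IDs into the elution-matrix namespace; annotated
#'   IDs absent from the map are dropped with a warning.
#' @return An [AnnotationSet-class].
#' @export
loadAnnotations <- function(ltFiles = character(), htFiles = character(),
                            idMap = NULL) {
    readSet <- function(files) {
        if (!length(files))
            return(data.frame(protein_id = character(),
                              source = character()))
        do.call(rbind, lapply(files, .readAnnotationFile))
    }
    lt <- readSet(ltFiles)
    ht <- readSet(htFiles)
    if (!is.null(idMap)) {
        mapDf <- utils::read.delim(idMap, header = FALSE, sep = "\t",
                                   stringsAsFactors = FALSE)
        map <- stats::setNames(as.character(mapDf[[2L]]),
                               as.character(mapDf[[1L]]))
        translate <- function(df) {
            hit <- df$protein_id %in% names(map)
            if (any(!hit))
                warning(sum(!hit), " annotated ID(s) absent from id map ",
                        "dropped: ",
                        paste(utils::head(df$protein_id[!hit], 5L),
                              collapse = ", "))
            df <- df[hit, , drop = FALSE]
            df$protein_id <- unname(map[df$protein_id])
            df
        }
        lt <- translate(lt)
        ht <- translate(ht)
    }
    sources <- rbind(
        if (nrow(lt)) cbind(lt, set = "lt") else NULL,
        if (nrow(ht)) cbind(ht, set = "ht") else NULL)
    if (is.null(sources))
        sources <- data.frame(protein_id = character(), source = character(),
                              set = character())
    new("AnnotationSet", lt = unique(lt$protein_id),
        ht = unique(ht$protein_id), sources = DataFrame(sources))
}

#' Negative log-transformed p values for ranking
#'
#' \code{-ln(p + 1e-308)}: a monotone transform placing the most significant
#' proteins at the top. The pseudocount keeps exact zeros finite
#' (\eqn{-\ln(10^{-308}) \approx 709.2}).
#'
#' @param p numeric p values in [0, 1] (NAs pass through).
#' @return numeric vector of the same length.
#' @export
negLnP <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p values must lie in [0, 1]")
    -log(p + 1e-308)
}

#' Precision along a score threshold sweep
#'
#' For each threshold \eqn{t}, precision is TP/AP where TP is the number of
#' annotated (positive) proteins with score strictly greater than \eqn{t}
#' and AP is the number of all proteins above \eqn{t}. Thresholds with no
#' protein above them are omitted (precision undefined).
#'
#' @param scores named numeric vector (typically [negLnP()] values).
#' @param positives character vector of annotated protein IDs.
#' @param thresholds numeric thresholds to evaluate; defaults to the sorted
#'   unique scores (so every attainable prediction set appears once).
#' @return data.frame with columns \code{threshold, tp, ap, precision}.
#' @export
precisionCurve <- function(scores, positives, thresholds = NULL) {
    if (is.null(names(scores)))
        stop("scores must be named by protein ID")
    if (is.null(thresholds))
        thresholds <- sort(unique(scores))
    isPos <- names(scores) %in% positives
    rows <- lapply(thresholds, function(t) {
        above <- scores > t
        ap <- sum(above)
        if (ap == 0)
            return(NULL)
        data.frame(threshold = t, tp = sum(above & isPos), ap = ap,
                   precision = sum(above & isPos) / ap)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(threshold = numeric(), tp = integer(),
                          ap = integer(), precision = numeric())
    rownames(out) <- NULL
    out
}

#' Precision-recall curve against an annotation set
#'
#' As [precisionCurve()], adding recall = TP/AKP where AKP (all known
#' positives) is the number of annotated proteins among the scored set.
#'
#' @inheritParams precisionCurve
#' @return data.frame with columns \code{threshold, tp, ap, precision,
#'   recall}.
#' @export
precisionRecall <- function(scores, positives, thresholds = NULL) {
    akp <- sum(names(scores) %in% positives)
    if (akp == 0)
        stop("no annotated positives among the scored proteins; ",
             "recall is undefined")
    out <- precisionCurve(scores, positives, thresholds)
    out$recall <- out$tp / akp
    out
}

#' Three-set overlap (Venn region) counts
#'
#' Counts the seven regions of a three-set Venn diagram, optionally
#' restricted to proteins whose mean abundance reaches a floor — overlap
#' comparisons between detection-limited methods are only fair among
#' proteins each method had a chance to see (default floor 10 mean PSMs).
#'
#' @param a,b,c character vectors of protein IDs.
#' @param de optional scored [DiffracExperiment-class] supplying
#'   \code{meanAbundance} for the filter; when NULL no filter is applied.
#' @param minMeanAbundance abundance floor (applied only when \code{de} is
#'   given; proteins absent from \code{de} are dropped by the filter).
#' @return named integer vector with regions \code{a_only, b_only, c_only,
#'   ab, ac, bc, abc}; the values sum to the size of the filtered union.
#' @export
overlapSummary <- function(a, b, c, de = NULL, minMeanAbundance = 10) {
    a <- unique(a); b <- unique(b); c <- unique(c)
    if (!is.null(de)) {
        rd <- rowData(de)
        if (is.null(rd$meanAbundance))
            stop("experiment has not been scored")
        keep <- rownames(de)[rd$meanAbundance >= minMeanAbundance]
        a <- intersect(a, keep)
        b <- intersect(b, keep)
        c <- intersect(c, keep)
    }
    ids <- union(a, union(b, c))
    inA <- ids %in% a; inB <- ids %in% b; inC <- ids %in% c
    c(a_only = sum(inA & !inB & !inC),
      b_only = sum(!inA & inB & !inC),
      c_only = sum(!inA & !inB & inC),
      ab = sum(inA & inB & !inC),
      ac = sum(inA & !inB & inC),
      bc = sum(!inA & inB & inC),
      abc = sum(inA & inB & inC))
}
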