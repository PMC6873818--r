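# End-to-end orchestration: align -> score -> significance -> shift
# classification -> complex calling -> (optional) recovery evaluation, with
# every stage's table written to disk and a manifest echoing the full
# configuration. Outputs are deterministic for a fixed config + seed: no
# timestamps or machine state enter any written file.

#' Default pipeline configuration
#'
#' @return named list of every tunable with its default: window half-width
#'   \code{s} (100 pool ranks), GMM weight threshold \code{tWeight} (0.7),
#'   FDR level \code{alpha} (0.05), co-elution gate \code{rMin} (0.75),
#'   relaxed complex-level threshold \code{pRelaxed} (0.5) with
#'   \code{pDirection} ("less"), abundance floor for overlap comparisons
#'   \code{minMeanAbundance} (10), \code{seed}, \code{nRestarts}, and
#'   \code{classifySignificantOnly}.
#' @export
diffracDefaults <- function() {
    list(s = 100L, tWeight = 0.7, alpha = 0.05, rMin = 0.75,
         pRelaxed = 0.5, pDirection = "less", minMeanAbundance = 10,
         seed = 1L, nRestarts = 10L, classifySignificantOnly = TRUE)
}

.mergeConfig <- function(config) {
    defaults <- diffracDefaults()
    bad <- setdiff(names(config),
                   c(names(defaults), "control", "treated", "corum",
                     "humap", "complexes", "ltAnnotations", "htAnnotations",
                     "idMap", "outdir"))
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
    utils::modifyList(defaults, config)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    path
}

#' Run the full differential-fractionation pipeline
#'
#' @param config named list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{control, treated}{paths to the two wide-TSV elution matrices
#'       (required).}
#'     \item{corum, humap, complexes}{optional complex-definition files; the
#'       first two are merged non-redundantly (CORUM precedence),
#'       \code{complexes} is a single pre-merged file.}
#'     \item{ltAnnotations, htAnnotations}{optional annotation file paths
#'       (character vectors).}
#'     \item{idMap}{optional annotation ID-mapping TSV.}
#'     \item{outdir}{output directory (required; created if absent).}
#'     \item{...}{any tunable from [diffracDefaults()].}
#'   }
#' @return invisibly, a list with the final [DiffracExperiment-class]
#'   (\code{de}), the complex calls (\code{complexes}, or NULL), and the
#'   paths of all written files. Stage tables land in \code{outdir}:
#'   \code{scores.tsv}, \code{significance.tsv}, \code{shifts.tsv},
#'   \code{class_summary.tsv}, \code{complexes.tsv} (when complex input is
#'   given) and \code{manifest.yaml}.
#' @details Literature annotations play two roles when given: the union of
#'   low- and high-throughput IDs is excluded from the background pool, and
#'   the per-evidence fractions enter the complex calls. A missing complex
#'   file skips the complex stage with a message rather than failing the
#'   protein-level analysis.
#' @export
runDiffrac <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    cfg <- .mergeConfig(config)
    for (key in c("control", "treated", "outdir"))
        if (is.null(cfg[[key]]))
            stop("config is missing required key '", key, "'")
    for (key in intersect(c("control", "treated", "corum", "humap",
                            "complexes", "idMap"), names(cfg)))
        if (is.character(cfg[[key]]) && !all(file.exists(cfg[[key]])))
            stop("config path does not exist: ", cfg[[key]])
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()
    # on stage failure: keep whatever was already written, renamed *.partial,
    # and abort naming the stage
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            for (pth in unlist(paths))
                if (file.exists(pth))
                    file.rename(pth, paste0(pth, ".partial"))
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE)
        })
    }

    control <- stage("read", readElutionMatrix(cfg$control, "control"))
    treated <- stage("read", readElutionMatrix(cfg$treated, "treated"))
    de <- stage("align", alignPair(control, treated))

    ann <- NULL
    annotatedIds <- character()
    if (length(cfg$ltAnnotations) || length(cfg$htAnnotations)) {
        ann <- stage("annotations",
            loadAnnotations(cfg$ltAnnotations %||% character(),
                            cfg$htAnnotations %||% character(),
                            idMap = cfg$idMap))
        annotatedIds <- union(ltAnnotated(ann), htAnnotated(ann))
    }

    de <- stage("score", scoreExperiment(de))
    paths$scores <- .writeTsv(scoreTable(de),
                              file.path(cfg$outdir, "scores.tsv"))
    de <- stage("significance",
        assignSignificance(de, annotated = annotatedIds, s = cfg$s,
            tWeight = cfg$tWeight, alpha = cfg$alpha, seed = cfg$seed,
            nRestarts = cfg$nRestarts))
    paths$significance <- .writeTsv(significanceTable(de),
        file.path(cfg$outdir, "significance.tsv"))
    de <- stage("classify", classifySignals(de,
        significantOnly = isTRUE(cfg$classifySignificantOnly)))
    paths$shifts <- .writeTsv(shiftTable(de),
                              file.path(cfg$outdir, "shifts.tsv"))
    paths$classSummary <- .writeTsv(signalClassSummary(de),
        file.path(cfg$outdir, "class_summary.tsv"))

    cpx <- NULL
    calls <- NULL
    if (!is.null(cfg$complexes) || !is.null(cfg$corum) ||
        !is.null(cfg$humap)) {
        calls <- stage("complexes", {
            if (!is.null(cfg$complexes)) {
                cpx <- readComplexSet(cfg$complexes, source = "other")
            } else {
                corum <- if (!is.null(cfg$corum))
                    readComplexSet(cfg$corum, "CORUM")
                humap <- if (!is.null(cfg$humap))
                    readComplexSet(cfg$humap, "huMAP")
                cpx <- if (is.null(corum)) humap
                       else if (is.null(humap)) corum
                       else mergeComplexSets(corum, humap)
            }
            complexCalls(cpx, de,
                htAnnotated = if (is.null(ann)) character()
                              else htAnnotated(ann),
                ltAnnotated = if (is.null(ann)) character()
                              else ltAnnotated(ann),
                rMin = cfg$rMin, pRelaxed = cfg$pRelaxed,
                direction = cfg$pDirection)
        })
        paths$complexes <- .writeTsv(calls,
            file.path(cfg$outdir, "complexes.tsv"))
    } else {
        message("no complex definitions given; complex stage skipped")
    }

    manifest <- list(
        package = "diffrac",
        version = as.character(utils::packageVersion("diffrac")),
        config = cfg[order(names(cfg))],
        rows = list(proteins = nrow(de),
                    fractions = ncol(de),
                    significant = sum(rowData(de)$significant),
                    complexes = if (is.null(calls)) 0L else nrow(calls)))
    paths$manifest <- file.path(cfg$outdir, "manifest.yaml")
    yaml::write_yaml(manifest, paths$manifest)
    invisible(list(de = de, complexes = calls, annotations = ann,
                   paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
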