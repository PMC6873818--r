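#' @describeIn diffrac-accessors subunit membership list.
#' @export
setMethod("complexMembers", "ComplexSet", function(object) object@members)

#' @describeIn diffrac-accessors per-complex metadata.
#' @export
setMethod("complexInfo", "ComplexSet", function(object) object@info)

setMethod("show", "ComplexSet", function(object) {
    cat(sprintf("ComplexSet: %d complexes (%s)\n", length(object@members),
        paste(sprintf("%s: %d", names(table(object@info$source)),
                      table(object@info$source)), collapse = ", ")))
})

#' Construct a ComplexSet
#'
#' @param members named list of character vectors of subunit protein IDs
#'   (each complex needs at least 2 subunits; duplicates within a complex
#'   are collapsed).
#' @param name optional character vector of complex names (defaults to the
#'   ids).
#' @param source provenance label(s), e.g. \code{"CORUM"} or \code{"huMAP"}.
#' @return A [ComplexSet-class].
#' @export
ComplexSet <- function(members, name = names(members), source = "other") {
    if (is.null(names(members)))
        names(members) <- sprintf("complex_%d", seq_along(members))
    members <- lapply(members, function(m) sort(unique(as.character(m))))
    info <- DataFrame(complex_id = names(members),
                      name = as.character(name),
                      source = rep_len(as.character(source),
                                       length(members)),
                      row.names = names(members))
    new("ComplexSet", members = members, info = info)
}

#' Jaccard similarity of two subunit sets
#'
#' \eqn{|a \cap b| / |a \cup b|}; 1 exactly when the two complexes have
#' identical membership.
#'
#' @param a,b non-empty character vectors (treated as sets).
#' @return value in [0, 1].
#' @export
jaccardIndex <- function(a, b) {
    if (!length(a) || !length(b))
        stop("Jaccard index of an empty set is undefined")
    length(intersect(a, b)) / length(union(a, b))
}

#' Read complex definitions from a file
#'
#' Two layouts are accepted:
#' \itemize{
#'   \item simple: one complex per line, TAB-separated subunit IDs, with an
#'     optional leading \code{complex_id:} token;
#'   \item CORUM-style TSV: a header naming a column that contains
#'     \code{subunits} (semicolon-separated IDs) and optionally
#'     \code{complex_name}/\code{name} and \code{complex_id}/\code{id}.
#' }
#' Complexes with fewer than two distinct subunits are dropped with a
#' warning — a "complex" of one protein cannot be scored for co-elution or
#' majority rules.
#'
#' @param path input file.
#' @param source provenance label attached to every complex.
#' @return A [ComplexSet-class].
#' @export
readComplexSet <- function(path, source = "other") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        return(ComplexSet(list(), source = source))
    header <- strsplit(tolower(lines[[1L]]), "\t")[[1L]]
    if (any(grepl("subunit", header))) {
        df <- utils::read.delim(text = paste(lines, collapse = "\n"),
            sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
        subCol <- grep("subunit", tolower(colnames(df)))[1L]
        idCol <- grep("^(complex_)?id$", tolower(colnames(df)))
        nameCol <- grep("name", tolower(colnames(df)))
        members <- strsplit(as.character(df[[subCol]]), ";", fixed = TRUE)
        members <- lapply(members, trimws)
        ids <- if (length(idCol)) as.character(df[[idCol[1L]]])
               else sprintf("%s_%d", source, seq_along(members))
        nms <- if (length(nameCol)) as.character(df[[nameCol[1L]]]) else ids
    } else {
        fields <- strsplit(lines, "\t")
        ids <- character(length(fields))
        members <- vector("list", length(fields))
        for (i in seq_along(fields)) {
            f <- fields[[i]]
            if (grepl(":$", f[1L])) {
                ids[i] <- sub(":$", "", f[1L])
                members[[i]] <- f[-1L]
            } else {
                ids[i] <- sprintf("%s_%d", source, i)
                members[[i]] <- f
            }
        }
        nms <- ids
    }
    members <- lapply(members, function(m) sort(unique(m[nzchar(m)])))
    ok <- lengths(members) >= 2L
    if (any(!ok))
        warning(sum(!ok), " complex(es) with fewer than 2 subunits dropped")
    names(members) <- ids
    ComplexSet(members[ok], name = nms[ok], source = source)
}

#' Merge complex sets into a non-redundant union
#'
#' Combines two sources (typically CORUM and hu.MAP) keeping every complex
#' whose membership is not an exact duplicate: only pairs with Jaccard
#' coefficient equal to 1.0 (identical subunit sets) are collapsed, with the
#' first argument taking precedence; near-duplicates (Jaccard < 1) are all
#' kept, however similar. Merging is idempotent and, up to the source label
#' of exact duplicates, order-insensitive.
#'
#' @param x,y [ComplexSet-class] objects; \code{x} has precedence on exact
#'   duplicates.
#' @return A merged [ComplexSet-class].
#' @export
mergeComplexSets <- function(x, y) {
    stopifnot(is(x, "ComplexSet"), is(y, "ComplexSet"))
    keyOf <- function(m) vapply(m, function(s)
        paste(sort(s), collapse = "\r"), character(1))
    kx <- keyOf(complexMembers(x))
    ky <- keyOf(complexMembers(y))
    keepY <- !(ky %in% kx) & !duplicated(ky)
    keepX <- !duplicated(kx)
    members <- c(complexMembers(x)[keepX], complexMembers(y)[keepY])
    info <- rbind(complexInfo(x)[keepX, , drop = FALSE],
                  complexInfo(y)[keepY, , drop = FALSE])
    ids <- make.unique(info$complex_id, sep = "_dup")
    names(members) <- ids
    info$complex_id <- ids
    rownames(info) <- ids
    new("ComplexSet", members = members, info = info)
}

#' Mean pairwise co-elution of a complex in the control separation
#'
#' Average Pearson correlation over all unordered pairs of detected subunit
#' control profiles. Subunits absent from the matrix or with an all-zero
#' (or constant) profile cannot contribute a correlation.
#'
#' @param subunits character vector of subunit IDs.
#' @param control an [ElutionMatrix-class] or a numeric matrix of control
#'   profiles.
#' @return mean pairwise r in [-1, 1], or NA when fewer than two subunits
#'   are detected (the complex is then ineligible for RNP Select).
#' @export
coelution <- function(subunits, control) {
    m <- if (is(control, "ElutionMatrix")) psmCounts(control)
         else as.matrix(control)
    hit <- intersect(subunits, rownames(m))
    prof <- m[hit, , drop = FALSE]
    prof <- prof[rowSums(prof) > 0 & apply(prof, 1L, stats::sd) > 0, ,
                 drop = FALSE]
    if (nrow(prof) < 2L)
        return(NA_real_)
    r <- stats::cor(t(prof))
    mean(r[upper.tri(r)])
}

#' Call RNP complexes by majority subunit evidence
#'
#' A complex is called an RNP when strictly more than half of its subunits
#' carry RNA-association evidence from any of three sources: (1) a
#' significant differential-elution call, (2) high-throughput literature
#' annotation, (3) low-throughput literature annotation. Per-source subunit
#' fractions are reported for transparency. The denominator is always the
#' complex's full subunit list — subunits never detected in the elution data
#' still count against the majority.
#'
#' @param complexes a [ComplexSet-class].
#' @param diffracSignificant character vector of significant protein IDs.
#' @param htAnnotated,ltAnnotated character vectors of high-/low-throughput
#'   annotated IDs (may be empty).
#' @return data.frame with one row per complex: subunit counts, per-evidence
#'   fractions, union fraction, and \code{is_rnp}.
#' @export
callRnp <- function(complexes, diffracSignificant = character(),
                    htAnnotated = character(), ltAnnotated = character()) {
    stopifnot(is(complexes, "ComplexSet"))
    members <- complexMembers(complexes)
    info <- complexInfo(complexes)
    evidence <- union(diffracSignificant, union(htAnnotated, ltAnnotated))
    frac <- function(m, set) length(intersect(m, set)) / length(m)
    data.frame(
        complex_id = info$complex_id,
        name = info$name,
        source = info$source,
        n_subunits = lengths(members),
        frac_diffrac = vapply(members, frac, numeric(1),
                              set = diffracSignificant),
        frac_ht = vapply(members, frac, numeric(1), set = htAnnotated),
        frac_lt = vapply(members, frac, numeric(1), set = ltAnnotated),
        frac_union = vapply(members, frac, numeric(1), set = evidence),
        is_rnp = vapply(members, frac, numeric(1), set = evidence) > 0.5,
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Call the high-confidence "RNP Select" complex set
#'
#' A complex is RNP Select when (a) its detected subunits co-elute in the
#' control separation with mean pairwise Pearson correlation above
#' \code{rMin}, and (b) strictly more than half of all its subunits pass a
#' relaxed per-protein differential-elution threshold. The rationale for the
#' relaxed threshold is that several co-complex subunits jointly passing it
#' is stronger evidence than any one protein's p value alone. By default the
#' relaxed rule is FDR-corrected p < \code{pRelaxed}; \code{direction =
#' "greater"} inverts the comparison for compatibility with pipelines that
#' phrase the rule the other way around.
#'
#' @param complexes a [ComplexSet-class].
#' @param control control [ElutionMatrix-class] (or matrix) for co-elution.
#' @param proteinP named numeric vector of per-protein (FDR-corrected)
#'   p values; subunits without a value never pass the relaxed rule.
#' @param rMin co-elution gate (default 0.75).
#' @param pRelaxed relaxed per-protein threshold (default 0.5).
#' @param direction \code{"less"} (default; pass = p < pRelaxed) or
#'   \code{"greater"}.
#' @return data.frame with \code{complex_id}, \code{mean_pairwise_r},
#'   \code{frac_relaxed}, \code{is_rnp_select}, and \code{select_reason}
#'   explaining failures (e.g. undefined co-elution).
#' @export
callRnpSelect <- function(complexes, control, proteinP, rMin = 0.75,
                          pRelaxed = 0.5,
                          direction = c("less", "greater")) {
    stopifnot(is(complexes, "ComplexSet"))
    direction <- match.arg(direction)
    members <- complexMembers(complexes)
    info <- complexInfo(complexes)
    n <- length(members)
    r <- vapply(members, coelution, numeric(1), control = control)
    fracRelaxed <- vapply(members, function(m) {
        pv <- proteinP[m]
        pass <- !is.na(pv) & if (direction == "less") pv < pRelaxed
                             else pv > pRelaxed
        sum(pass) / length(m)
    }, numeric(1))
    sel <- !is.na(r) & r > rMin & fracRelaxed > 0.5
    reason <- rep("", n)
    reason[is.na(r)] <- "coelution undefined (<2 detected subunits)"
    reason[!is.na(r) & r <= rMin] <- "co-elution below gate"
    reason[!is.na(r) & r > rMin & fracRelaxed <= 0.5] <-
        "no subunit majority at relaxed threshold"
    data.frame(complex_id = info$complex_id,
               mean_pairwise_r = unname(r),
               frac_relaxed = unname(fracRelaxed),
               is_rnp_select = unname(sel),
               select_reason = reason,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Combined complex-level calls
#'
#' Runs [callRnp()] and [callRnpSelect()] and joins them into the standard
#' complex output table.
#'
#' @inheritParams callRnp
#' @inheritParams callRnpSelect
#' @param de a [DiffracExperiment-class] after [assignSignificance()]; used
#'   for the significant set, the per-protein q values, the control matrix
#'   and detection counts.
#' @return data.frame with columns \code{complex_id, name, source,
#'   n_subunits, n_detected, frac_diffrac, frac_ht, frac_lt, frac_union,
#'   mean_pairwise_r, is_rnp, is_rnp_select}.
#' @export
complexCalls <- function(complexes, de, htAnnotated = character(),
                         ltAnnotated = character(), rMin = 0.75,
                         pRelaxed = 0.5, direction = c("less", "greater")) {
    stopifnot(is(complexes, "ComplexSet"), is(de, "DiffracExperiment"))
    if (!length(complexMembers(complexes)))
        stop("complex set is empty; nothing to call")
    rd <- rowData(de)
    if (is.null(rd$q))
        stop("run assignSignificance() first")
    sig <- rownames(de)[rd$significant]
    q <- stats::setNames(rd$q, rownames(de))
    ctrl <- controlCounts(de)
    base <- callRnp(complexes, sig, htAnnotated, ltAnnotated)
    sel <- callRnpSelect(complexes, ctrl, q, rMin = rMin,
                         pRelaxed = pRelaxed, direction = direction)
    detected <- vapply(complexMembers(complexes), function(m) {
        hit <- intersect(m, rownames(ctrl))
        sum(rowSums(ctrl[hit, , drop = FALSE]) > 0)
    }, integer(1))
    out <- cbind(base[, c("complex_id", "name", "source", "n_subunits")],
                 n_detected = unname(detected),
                 base[, c("frac_diffrac", "frac_ht", "frac_lt",
                          "frac_union")],
                 mean_pairwise_r = sel$mean_pairwise_r,
                 is_rnp = base$is_rnp,
                 is_rnp_select = sel$is_rnp_select)
    rownames(out) <- NULL
    out
}
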