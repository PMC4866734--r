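#' @include data-model.R
NULL

## Builders for auxiliary feature matrices from offline annotation files:
## binary GO Cellular Component term incidence, binary Human Protein Atlas
## localisations filtered by annotation reliability, and a STRING
## interaction contingency matrix of combined scores. All builders read
## local files only; no network access.

#' Read a GAF 2.x annotation file
#'
#' Parses a tab-separated Gene Association File (17 columns, comment lines
#' starting with `!` skipped) into an annotation table of (accession, term)
#' records, optionally filtered by ontology aspect (column 9; `"C"` keeps
#' the Cellular Component namespace).
#'
#' @param path GAF file path.
#' @param aspect single-letter aspect filter (default `"C"`); `NULL` keeps
#'   all aspects.
#' @return data frame with columns `accession`, `term`, `aspect`,
#'   `evidence`, deduplicated on (accession, term).
#' @export
readGaf <- function(path, aspect = "C") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    if (length(lines) == 0L) stop("no annotation records in ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(fields, length, integer(1L)) < 9L
    if (any(bad))
        stop("format error: GAF records with fewer than 9 columns in ", path)
    tab <- data.frame(
        accession = vapply(fields, `[`, character(1L), 2L),
        term = vapply(fields, `[`, character(1L), 5L),
        aspect = vapply(fields, `[`, character(1L), 9L),
        evidence = vapply(fields, `[`, character(1L), 7L),
        stringsAsFactors = FALSE)
    if (!is.null(aspect))
        tab <- tab[tab$aspect == aspect, , drop = FALSE]
    tab <- tab[!duplicated(tab[, c("accession", "term")]), , drop = FALSE]
    .logInfo("read %s: %d (accession, term) records", basename(path),
             nrow(tab))
    tab
}

#' Binary GO CC term matrix
#'
#' Builds a proteins x terms presence/absence matrix from an annotation
#' table: entry 1 when the protein carries the term. Proteins without any
#' term are dropped with a warning (an all-zero row is equidistant to
#' everything and would poison neighbour voting), and constant columns are
#' removed.
#'
#' @param annotations data frame with columns `accession` and `term`
#'   (e.g. from [readGaf()]).
#' @param proteinIds optional accession universe to restrict to.
#' @return binary numeric matrix, rows named by accession, columns by term.
#' @export
buildGOCCMatrix <- function(annotations, proteinIds = NULL) {
    stopifnot(all(c("accession", "term") %in% colnames(annotations)))
    if (!is.null(proteinIds))
        annotations <- annotations[annotations$accession %in% proteinIds, ,
                                   drop = FALSE]
    if (nrow(annotations) == 0L)
        stop("no CC annotations available")
    annotations <-
        annotations[!duplicated(annotations[, c("accession", "term")]), ,
                    drop = FALSE]
    prots <- unique(annotations$accession)
    terms <- sort(unique(annotations$term))
    m <- matrix(0, length(prots), length(terms),
                dimnames = list(prots, terms))
    m[cbind(match(annotations$accession, prots),
            match(annotations$term, terms))] <- 1
    if (!is.null(proteinIds)) {
        missing <- setdiff(proteinIds, prots)
        if (length(missing))
            warning(length(missing),
                    " protein(s) without any CC term dropped",
                    call. = FALSE)
    }
    keep <- apply(m, 2L, function(col) length(unique(col)) > 1L)
    if (any(!keep) && sum(keep) >= 1L)
        m <- m[, keep, drop = FALSE]
    .logInfo("GO CC matrix: %d proteins x %d terms", nrow(m), ncol(m))
    m
}

#' Binary Human Protein Atlas localisation matrix
#'
#' Builds a proteins x localisations presence/absence matrix from an HPA
#' export, keeping only records whose reliability passes the filter
#' (default: `"supportive"`); records with reliability values outside the
#' known set trigger a warning and are treated as not passing.
#'
#' @param hpaTable data frame with columns `accession`, `localisation`,
#'   `reliability`.
#' @param reliabilityFilter reliability value(s) accepted (matched
#'   case-insensitively).
#' @param knownValues reliability vocabulary (default
#'   `c("supportive", "uncertain")`).
#' @return binary numeric matrix over the proteins with at least one
#'   passing record.
#' @export
buildHPAMatrix <- function(hpaTable, reliabilityFilter = "supportive",
                           knownValues = c("supportive", "uncertain")) {
    stopifnot(all(c("accession", "localisation", "reliability") %in%
                  colnames(hpaTable)))
    rel <- tolower(hpaTable$reliability)
    unknown <- setdiff(unique(rel), tolower(knownValues))
    if (length(unknown))
        warning("unknown reliability value(s) treated as not passing: ",
                paste(unknown, collapse = ", "), call. = FALSE)
    keep <- rel %in% tolower(reliabilityFilter)
    tab <- hpaTable[keep, , drop = FALSE]
    if (nrow(tab) == 0L)
        stop("no records pass the reliability filter")
    tab <- tab[!duplicated(tab[, c("accession", "localisation")]), ,
               drop = FALSE]
    prots <- unique(tab$accession)
    locs <- sort(unique(tab$localisation))
    m <- matrix(0, length(prots), length(locs),
                dimnames = list(prots, locs))
    m[cbind(match(tab$accession, prots),
            match(tab$localisation, locs))] <- 1
    .logInfo("HPA matrix: %d proteins x %d localisations", nrow(m), ncol(m))
    m
}

#' STRING interaction contingency matrix
#'
#' Builds a proteins x interaction-partners matrix of STRING combined
#' scores scaled to \[0, 1\] (raw score / 1000); absent interactions are 0.
#' Query proteins with no interaction at all are dropped with a warning.
#'
#' @param links data frame with columns `accession`, `partner`, `score`
#'   (raw combined scores in \[0, 1000\]).
#' @param proteinIds optional accession universe to restrict the rows to.
#' @return numeric matrix with entries in \[0, 1\].
#' @export
buildStringMatrix <- function(links, proteinIds = NULL) {
    stopifnot(all(c("accession", "partner", "score") %in% colnames(links)))
    if (any(links$score < 0))
        stop("format error: negative combined scores")
    if (any(links$score > 1000))
        stop("format error: combined scores above 1000")
    if (!is.null(proteinIds))
        links <- links[links$accession %in% proteinIds, , drop = FALSE]
    links <- links[!duplicated(links[, c("accession", "partner")]), ,
                   drop = FALSE]
    if (nrow(links) == 0L) stop("no interactions available")
    prots <- unique(links$accession)
    partners <- sort(unique(links$partner))
    m <- matrix(0, length(prots), length(partners),
                dimnames = list(prots, partners))
    m[cbind(match(links$accession, prots),
            match(links$partner, partners))] <- links$score / 1000
    if (!is.null(proteinIds)) {
        missing <- setdiff(proteinIds, prots)
        if (length(missing))
            warning(length(missing),
                    " protein(s) without any interaction dropped",
                    call. = FALSE)
    }
    .logInfo("STRING matrix: %d proteins x %d partners", nrow(m), ncol(m))
    m
}
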