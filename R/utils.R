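## Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so generators are reproducible without clobbering
#' the session stream.
#' @noRd
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer")
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Extract the genes x samples numeric matrix from a SummarizedExperiment
## or pass a plain matrix through, validating labels.
.exprMatrix <- function(x) {
    if (is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, 1L)
    if (!is.matrix(x) || !is.numeric(x))
        stop("expression input must be a numeric matrix or a SummarizedExperiment")
    if (is.null(rownames(x)) || is.null(colnames(x)))
        stop("expression matrix must carry gene (row) and sample (column) names")
    if (anyDuplicated(rownames(x)))
        stop("duplicate gene id: ", rownames(x)[duplicated(rownames(x))][1L])
    if (anyDuplicated(colnames(x)))
        stop("duplicate sample id: ", colnames(x)[duplicated(colnames(x))][1L])
    if (!all(is.finite(x)))
        stop("expression matrix contains non-finite values")
    x
}

## Wrap a genes x samples matrix as a one-assay SummarizedExperiment.
.asSE <- function(m) {
    SummarizedExperiment::SummarizedExperiment(assays = list(expr = m))
}

#' Tokenize free text for thesaurus matching
#'
#' Splits on any character that is not alphanumeric, keeping internal
#' hyphens (so "EWI-2" and "Tspan12" survive as single tokens).
#' @noRd
tokenize <- function(text) {
    m <- gregexpr("[A-Za-z0-9]+(?:-[A-Za-z0-9]+)*", text)
    regmatches(text, m)[[1L]]
}

## Canonical key for a surface form: lower-cased tokens joined by a space.
.surfaceKey <- function(surface) {
    vapply(surface, function(s) paste(tolower(tokenize(s)), collapse = " "),
           character(1L), USE.NAMES = FALSE)
}
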