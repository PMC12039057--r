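#' Serialize a skeleton query as a MassQL statement
#'
#' Emits `QUERY scaninfo(MS2DATA) WHERE` followed by AND-joined
#' `MS2PROD=<mz>:TOLERANCEMZ=<tol>` clauses for fragment signals and
#' `MS2NL=<mz>:TOLERANCEMZ=<tol>` clauses for neutral-loss signals, m/z at 4
#' decimals, fragments (ascending m/z) before losses (ascending m/z). Only
#' the absolute tolerance component is emitted; clause-level ppm qualifiers
#' vary across MassQL engine versions, and [run_query()] remains the ground
#' truth for matching semantics.
#'
#' @param query a `SkeletonQuery` (or a data.frame of `kind`/`mz` signals).
#' @param tol a [tolerance()].
#' @return an object of class `MassQLQuery`: list with `text`, `source`,
#'   `tolerance`.
#' @examples
#' q <- data.frame(kind = "fragment", mz = 144.0808)
#' to_massql(q)$text
#' @export
to_massql <- function(query, tol = tolerance()) {
  signals <- if (inherits(query, "SkeletonQuery")) query$signals else query
  stopifnot(is.data.frame(signals))
  if (nrow(signals) == 0L) stop("query must contain at least one signal")
  signals <- signals[order(match(signals$kind, c("fragment", "loss")),
                           signals$mz), , drop = FALSE]
  clauses <- sprintf("%s=%.4f:TOLERANCEMZ=%g",
                     ifelse(signals$kind == "fragment", "MS2PROD", "MS2NL"),
                     signals$mz, tol$absolute)
  structure(list(
    text = paste("QUERY scaninfo(MS2DATA) WHERE",
                 paste(clauses, collapse = " AND ")),
    source = if (inherits(query, "SkeletonQuery")) query else NULL,
    signals = signals,
    tolerance = tol
  ), class = "MassQLQuery")
}

#' @export
print.MassQLQuery <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' Run a MassQL query against a feature-level MGF dataset
#'
#' Native interpreter for the MS2PROD/MS2NL conjunctions emitted by
#' [to_massql()]; by contract its result is identical to applying
#' [match_query()] with the source signal set to every spectrum.
#'
#' @param query a `MassQLQuery` or `SkeletonQuery`.
#' @param dataset a [spectral_library()] (e.g. read from an extract-level
#'   feature MGF).
#' @param tol a [tolerance()]; defaults to the query's own tolerance when it
#'   carries one.
#' @return character vector of matching spectrum ids.
#' @export
run_query <- function(query, dataset, tol = NULL) {
  stopifnot(inherits(dataset, "SpectralLibrary"))
  if (inherits(query, "MassQLQuery")) {
    signals <- query$signals
    if (is.null(tol)) tol <- query$tolerance
  } else if (inherits(query, "SkeletonQuery")) {
    signals <- query$signals
  } else {
    signals <- query
  }
  if (is.null(tol)) tol <- tolerance()
  hit <- vapply(dataset$spectra, function(s) match_query(signals, s, tol),
                logical(1))
  names(dataset$spectra)[hit]
}

#' Write MassQL statements, one file per skeleton
#'
#' @param results output of [extract_signatures()].
#' @param dir output directory (created if needed).
#' @param tol a [tolerance()].
#' @return invisibly, the written paths.
#' @export
write_massql <- function(results, dir, tol = tolerance()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (skel in names(results)) {
    if (!length(results[[skel]])) next
    txt <- vapply(results[[skel]], function(q) to_massql(q, tol)$text,
                  character(1))
    p <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", skel), ".massql"))
    writeLines(txt, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
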