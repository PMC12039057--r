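#' @name spectral_similarity
#' @title Cosine-type spectral similarity
#' @description
#' Classic cosine and modified cosine scores between MS/MS spectra. Both use
#' a one-to-one peak matching built greedily by descending intensity product
#' (the common construction in molecular-networking tools); the modified
#' cosine additionally allows matches offset by the precursor mass
#' difference, so it can recognize analogues differing by one substituent.
NULL

# candidate peak pairs within tolerance, optionally shifted by delta
candidate_pairs <- function(a, b, tol, delta = NULL) {
  na <- nrow(a$peaks); nb <- nrow(b$peaks)
  if (na == 0L || nb == 0L) {
    return(data.frame(i = integer(0), j = integer(0), product = numeric(0),
                      type = character(0)))
  }
  d <- outer(a$peaks$mz, b$peaks$mz, `-`)
  win <- matrix(tol_window(tol, outer(a$peaks$mz, b$peaks$mz, pmax)),
                nrow = na)
  hit <- abs(d) <= win
  type <- matrix("direct", na, nb)
  if (!is.null(delta) && abs(delta) > 0) {
    shifted <- abs(d - delta) <= win
    type[shifted & !hit] <- "shifted"
    hit <- hit | shifted
  }
  idx <- which(hit, arr.ind = TRUE)
  data.frame(
    i = idx[, 1L], j = idx[, 2L],
    product = a$peaks$intensity[idx[, 1L]] * b$peaks$intensity[idx[, 2L]],
    type = type[idx]
  )
}

greedy_cosine <- function(a, b, tol, delta = NULL) {
  pairs <- candidate_pairs(a, b, tol, delta)
  norm <- sqrt(sum(a$peaks$intensity^2)) * sqrt(sum(b$peaks$intensity^2))
  if (nrow(pairs) == 0L || norm == 0) {
    return(list(score = 0, n_matched = 0L))
  }
  pairs <- pairs[order(-pairs$product, pairs$i, pairs$j), , drop = FALSE]
  used_i <- logical(nrow(a$peaks)); used_j <- logical(nrow(b$peaks))
  total <- 0; n <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    total <- total + pairs$product[k]
    n <- n + 1L
  }
  list(score = min(total / norm, 1), n_matched = n)
}

#' Classic cosine score between two spectra
#'
#' Direct m/z matching only; peaks are paired one-to-one, greedily by
#' descending intensity product, and the score is the matched dot product
#' over the product of intensity norms.
#'
#' @param a,b [spectrum()] objects (normalized intensities recommended).
#' @param tol a [tolerance()]; cosine-type heatmaps conventionally use a
#'   wider 0.02 Da window than signature extraction.
#' @return list with `score` in `[0, 1]` and `n_matched`.
#' @export
cosine_score <- function(a, b, tol = tolerance(absolute = 0.02)) {
  greedy_cosine(a, b, tol, delta = NULL)
}

#' Modified cosine score between two spectra
#'
#' Like [cosine_score()], but a peak pair may also match when offset by the
#' precursor mass difference `precursor_a - precursor_b`, so shared
#' fragmentation shifted by one structural modification still contributes.
#'
#' @inheritParams cosine_score
#' @return list with `score` in `[0, 1]` and `n_matched`.
#' @export
modified_cosine <- function(a, b, tol = tolerance(absolute = 0.02)) {
  greedy_cosine(a, b, tol, delta = a$precursor_mz - b$precursor_mz)
}

#' Pairwise similarity matrix over a library, ordered for heatmaps
#'
#' Rows and columns are sorted by the skeleton dendrogram leaf order, then
#' by spectrum id; spectra whose skeleton is absent from the leaf order (or
#' ungrouped) are placed in a trailing block.
#'
#' @param library a [spectral_library()] (intensities should be normalized;
#'   see [normalize_spectrum()]).
#' @param method `"modified_cosine"` or `"cosine"`.
#' @param leaf_order character vector of skeleton labels (from
#'   [build_dendrogram()]); `NULL` keeps library order.
#' @param tol a [tolerance()].
#' @param floor optional masking threshold: values below it are set to 0 in
#'   the returned matrix (thresholded heatmap view).
#' @return a `SimilarityMatrix` whose `labels` are spectrum ids in heatmap
#'   order and with attribute `skeletons` giving each spectrum's label.
#' @export
similarity_heatmap <- function(library, method = c("modified_cosine", "cosine"),
                               leaf_order = NULL,
                               tol = tolerance(absolute = 0.02),
                               floor = NULL) {
  stopifnot(inherits(library, "SpectralLibrary"))
  method <- match.arg(method)
  score_fun <- if (method == "modified_cosine") modified_cosine else cosine_score
  skel <- vapply(library$spectra, function(s) s$skeleton %||% NA_character_,
                 character(1))
  ids <- names(library$spectra)
  if (is.null(leaf_order)) leaf_order <- unique(skel[!is.na(skel)])
  pos <- match(skel, leaf_order)
  unknown <- is.na(pos)
  if (any(unknown & !is.na(skel))) {
    message("spectra with skeletons outside the leaf order placed last: ",
            paste(ids[unknown & !is.na(skel)], collapse = ", "))
  }
  pos[unknown] <- length(leaf_order) + 1L
  ord <- order(pos, ids)
  ids <- ids[ord]
  spectra <- library$spectra[ord]
  n <- length(spectra)
  vals <- diag(1, n)
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- score_fun(spectra[[i]], spectra[[j]], tol)$score
        vals[i, j] <- s
        vals[j, i] <- s
      }
    }
  }
  if (!is.null(floor)) vals[vals < floor] <- 0
  dimnames(vals) <- list(ids, ids)
  structure(list(labels = ids, values = vals, leaf_order = ids),
            class = "SimilarityMatrix",
            skeletons = skel[ord], method = method)
}

#' Export a similarity matrix as TSV
#'
#' @param sim a `SimilarityMatrix`.
#' @param path output path.
#' @export
write_similarity_tsv <- function(sim, path) {
  df <- data.frame(label = rownames(sim$values), sim$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
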