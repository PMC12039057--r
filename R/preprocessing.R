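#' @name preprocessing
#' @title Spectrum conditioning chain
#' @description
#' The conditioning chain applied before signature extraction, in fixed
#' order: [deisotope()] -> [reduce_concurrent()] ->
#' [remove_precursor_region()] -> [normalize_spectrum()] ->
#' [compute_losses()] -> [harmonize()]. All steps share one [tolerance()].
#' The chain is idempotent: applying it twice equals applying it once.
NULL

C13_SPACING <- 1.00336

#' Remove carbon-isotopologue peaks
#'
#' Single low-to-high m/z pass: a peak is dropped when another peak sits one
#' or two 13C spacings (1.00336 / 2.00671 Da) below it, within tolerance, with
#' strictly higher intensity. Charge 1 only (positive-mode, singly charged
#' alkaloid library); the putative monoisotopic peak must be the more intense
#' one, otherwise both are kept.
#'
#' @param spectrum a [spectrum()] (peaks sorted by m/z).
#' @param tol a [tolerance()].
#' @return the deisotoped `Spectrum`.
#' @export
deisotope <- function(spectrum, tol = tolerance()) {
  pk <- spectrum$peaks
  n <- nrow(pk)
  if (n < 2L) return(spectrum)
  keep <- rep(TRUE, n)
  for (j in 2L:n) {
    win <- tol_window(tol, pk$mz[j])
    for (i in which(keep[1:(j - 1L)])) {
      d <- pk$mz[j] - pk$mz[i]
      if ((abs(d - C13_SPACING) <= win || abs(d - 2 * C13_SPACING) <= win) &&
          pk$intensity[i] > pk$intensity[j]) {
        keep[j] <- FALSE
        break
      }
    }
  }
  spectrum$peaks <- pk[keep, , drop = FALSE]
  rownames(spectrum$peaks) <- NULL
  spectrum
}

#' Reduce concurrent fragments within tolerance
#'
#' Peaks pairwise linked by the tolerance window (single-linkage chains over
#' the sorted m/z list) are collapsed to their single most intense member. At
#' equal intensity the lower m/z survives, making the result deterministic.
#'
#' @inheritParams deisotope
#' @return the reduced `Spectrum`; no two surviving peaks lie within the
#'   tolerance window of one another.
#' @export
reduce_concurrent <- function(spectrum, tol = tolerance()) {
  pk <- spectrum$peaks
  n <- nrow(pk)
  if (n < 2L) return(spectrum)
  gap <- diff(pk$mz)
  win <- tol_window(tol, pk$mz[-n])
  cluster <- cumsum(c(1L, as.integer(gap > win)))
  best <- vapply(split(seq_len(n), cluster), function(idx) {
    idx[which.max(pk$intensity[idx])] # which.max -> first max = lower m/z
  }, integer(1))
  spectrum$peaks <- pk[sort(best), , drop = FALSE]
  rownames(spectrum$peaks) <- NULL
  spectrum
}

#' Remove the precursor region
#'
#' Drops every fragment with m/z at or above the precursor m/z (the boundary
#' itself is removed). A spectrum emptied by this filter is flagged with
#' attribute `empty_after_filtering = TRUE` so the pipeline can exclude it
#' from the occurrence matrices.
#'
#' @inheritParams deisotope
#' @return the filtered `Spectrum`.
#' @export
remove_precursor_region <- function(spectrum) {
  keep <- spectrum$peaks$mz < spectrum$precursor_mz
  spectrum$peaks <- spectrum$peaks[keep, , drop = FALSE]
  rownames(spectrum$peaks) <- NULL
  if (nrow(spectrum$peaks) == 0L) {
    attr(spectrum, "empty_after_filtering") <- TRUE
  }
  spectrum
}

#' Normalize intensities to the base peak
#'
#' @inheritParams deisotope
#' @return the `Spectrum` with maximum intensity 1.0.
#' @export
normalize_spectrum <- function(spectrum) {
  if (nrow(spectrum$peaks) == 0L) return(spectrum)
  m <- max(spectrum$peaks$intensity)
  if (m <= 0) stop("cannot normalize: all intensities are zero")
  spectrum$peaks$intensity <- spectrum$peaks$intensity / m
  spectrum
}

#' Neutral losses of a spectrum
#'
#' One loss per fragment: `precursor_mz - fragment mz`, restricted to
#' fragments below the precursor, each inheriting its parent fragment's
#' (normalized) intensity.
#'
#' @inheritParams deisotope
#' @return data.frame with columns `mz` (loss value, Da) and `intensity`.
#' @export
compute_losses <- function(spectrum) {
  pk <- spectrum$peaks[spectrum$peaks$mz < spectrum$precursor_mz, , drop = FALSE]
  data.frame(mz = spectrum$precursor_mz - pk$mz, intensity = pk$intensity)
}

#' Run the conditioning chain on every spectrum
#'
#' @param library a [spectral_library()].
#' @param tol a [tolerance()].
#' @param deisotope_enabled run the deisotoping step (default TRUE).
#' @return list with `library` (preprocessed spectra; spectra emptied by the
#'   precursor filter removed) and `dropped` (their ids).
#' @export
preprocess_library <- function(library, tol = tolerance(),
                               deisotope_enabled = TRUE) {
  stopifnot(inherits(library, "SpectralLibrary"))
  out <- list(); dropped <- character(0)
  for (s in library$spectra) {
    if (deisotope_enabled) s <- deisotope(s, tol)
    s <- reduce_concurrent(s, tol)
    s <- remove_precursor_region(s)
    if (isTRUE(attr(s, "empty_after_filtering"))) {
      dropped <- c(dropped, s$spectrum_id)
      next
    }
    s <- normalize_spectrum(s)
    out[[length(out) + 1L]] <- s
  }
  if (length(dropped)) {
    message("excluded ", length(dropped),
            " spectra emptied by filtering: ", paste(dropped, collapse = ", "))
  }
  list(library = spectral_library(out), dropped = dropped)
}

#' Harmonize m/z values across a library into a binned signal matrix
#'
#' Pools all values of one kind (fragment m/z or neutral-loss values) across
#' the preprocessed library, clusters the sorted pool by a greedy
#' single-linkage scan under the tolerance window, and represents each
#' cluster by the intensity-weighted mean of its members, rounded
#' half-away-from-zero to 4 decimals. If one spectrum contributes several
#' members to a cluster, its most intense member is kept.
#'
#' @param library a preprocessed [spectral_library()].
#' @param tol a [tolerance()].
#' @param kind `"fragment"` or `"loss"`.
#' @return an object of class `BinnedSignalMatrix`: list with `matrix`
#'   (spectra x signals, normalized intensities, 0 = absent), `signals`
#'   (data.frame `kind`, `mz`) and `kind`.
#' @export
harmonize <- function(library, tol = tolerance(),
                      kind = c("fragment", "loss")) {
  stopifnot(inherits(library, "SpectralLibrary"))
  kind <- match.arg(kind)
  ids <- names(library$spectra)
  rows <- lapply(library$spectra, function(s) {
    if (kind == "fragment") s$peaks else compute_losses(s)
  })
  pool <- data.frame(
    mz = unlist(lapply(rows, `[[`, "mz"), use.names = FALSE),
    intensity = unlist(lapply(rows, `[[`, "intensity"), use.names = FALSE),
    spectrum = rep(ids, vapply(rows, nrow, integer(1)))
  )
  if (nrow(pool) == 0L) {
    return(structure(list(
      matrix = matrix(0, nrow = length(ids), ncol = 0L,
                      dimnames = list(ids, NULL)),
      signals = data.frame(kind = character(0), mz = numeric(0)),
      kind = kind), class = "BinnedSignalMatrix"))
  }
  pool <- pool[order(pool$mz), ]
  gap <- diff(pool$mz)
  win <- tol_window(tol, pool$mz[-nrow(pool)])
  cluster <- cumsum(c(1L, as.integer(gap > win)))
  reps <- vapply(split(seq_len(nrow(pool)), cluster), function(idx) {
    round_half_up(stats::weighted.mean(pool$mz[idx], pool$intensity[idx]), 4L)
  }, numeric(1))
  mat <- matrix(0, nrow = length(ids), ncol = length(reps),
                dimnames = list(ids, sprintf("%s%.4f",
                                             if (kind == "fragment") "F:" else "L:",
                                             reps)))
  for (k in seq_along(reps)) {
    idx <- which(cluster == k)
    for (i in idx) {
      r <- pool$spectrum[i]
      mat[r, k] <- max(mat[r, k], pool$intensity[i])
    }
  }
  structure(list(matrix = mat,
                 signals = data.frame(kind = kind, mz = unname(reps)),
                 kind = kind),
            class = "BinnedSignalMatrix")
}

#' @export
print.BinnedSignalMatrix <- function(x, ...) {
  cat(sprintf("<BinnedSignalMatrix:%s> %d spectra x %d signals\n",
              x$kind, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Combine fragment and loss matrices into one candidate matrix
#'
#' @param frag,loss `BinnedSignalMatrix` objects over the same spectra.
#' @return a combined `BinnedSignalMatrix` with `kind = "combined"`.
#' @export
combine_matrices <- function(frag, loss) {
  stopifnot(identical(rownames(frag$matrix), rownames(loss$matrix)))
  structure(list(matrix = cbind(frag$matrix, loss$matrix),
                 signals = rbind(frag$signals, loss$signals),
                 kind = "combined"),
            class = "BinnedSignalMatrix")
}

#' Export a binned signal matrix as TSV
#'
#' Rows are spectrum ids; column headers are `F:<mz>` / `L:<mz>` at 4
#' decimals.
#'
#' @param x a `BinnedSignalMatrix`.
#' @param path output path.
#' @export
write_signal_matrix <- function(x, path) {
  df <- data.frame(spectrum_id = rownames(x$matrix), x$matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
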