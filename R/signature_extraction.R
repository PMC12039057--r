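#' F-beta score
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`, with the convention that the
#' score is 0 when both precision and recall are 0. `beta = 2` weights recall
#' over precision (candidate signal scoring: combining signals later can only
#' lower recall and raise precision); `beta = 0.5` weights precision (final
#' query scoring).
#'
#' @param precision,recall values in `[0, 1]` (vectorized).
#' @param beta positive weighting exponent.
#' @return F-beta score(s) in `[0, 1]`.
#' @examples
#' fbeta(11 / 16, 11 / 12, beta = 2) # 0.859375
#' @export
fbeta <- function(precision, recall, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop("beta must be a single positive number")
  }
  denom <- beta^2 * precision + recall
  ifelse(denom == 0, 0, (1 + beta^2) * precision * recall / denom)
}

#' Score candidate signals per skeleton group
#'
#' Implements the candidate filter: a signal must occur (cell > 0) in at
#' least `min_occurrence` spectra library-wide to be a candidate. Per
#' skeleton, signals present in every group member are retained
#' unconditionally; the remaining candidates are ranked by F-beta
#' (precision = tp / occurrences, recall = tp / group size) and the
#' `max_rank` highest scores kept. Candidates scoring below `min_score` are
#' dropped. Signals with precision 1 (specificity-1: absent from every
#' out-group spectrum) are always retained — those outside the top ranks are
#' flagged `singleton_only` and later used as standalone queries rather than
#' combination members.
#'
#' @param matrix a combined `BinnedSignalMatrix` (see [combine_matrices()]).
#' @param groups named list: skeleton label -> character vector of spectrum
#'   ids (rows of the matrix). Spectra in no group count as negatives only.
#' @param min_occurrence minimum library-wide occurrence count (default 3).
#' @param min_score minimum F-beta score for non-universal candidates
#'   (default 0).
#' @param max_rank number of top-scoring non-universal candidates kept per
#'   skeleton (default 10).
#' @param beta F-beta weighting for candidate ranking (default 2).
#' @return named list: skeleton -> data.frame with columns `kind`, `mz`,
#'   `tp`, `occurrence`, `precision`, `recall`, `fscore`, `universal`,
#'   `specificity_one`, `singleton_only`; ordered by (fscore desc, mz asc,
#'   fragments before losses).
#' @export
score_candidates <- function(matrix, groups, min_occurrence = 3L,
                             min_score = 0, max_rank = 10L, beta = 2) {
  stopifnot(inherits(matrix, "BinnedSignalMatrix"))
  ids <- rownames(matrix$matrix)
  bad <- vapply(groups, function(g) any(!g %in% ids), logical(1))
  if (any(bad)) {
    stop("groups reference spectra absent from the matrix: ",
         paste(names(groups)[bad], collapse = ", "))
  }
  present <- matrix$matrix > 0
  occ <- colSums(present)
  is_cand <- occ >= min_occurrence
  out <- list()
  for (skel in names(groups)) {
    gids <- groups[[skel]]
    gs <- length(gids)
    tp <- colSums(present[gids, , drop = FALSE])
    keep <- is_cand & tp > 0
    if (!any(keep)) {
      out[[skel]] <- empty_candidates()
      next
    }
    prec <- tp[keep] / occ[keep]
    rec <- tp[keep] / gs
    f <- fbeta(prec, rec, beta)
    df <- data.frame(
      kind = matrix$signals$kind[keep],
      mz = matrix$signals$mz[keep],
      tp = unname(tp[keep]),
      occurrence = unname(occ[keep]),
      precision = unname(prec),
      recall = unname(rec),
      fscore = unname(f)
    )
    df$universal <- df$tp == gs
    df$specificity_one <- df$precision == 1
    # rank the non-universal remainder; universal signals do not consume slots
    rest <- which(!df$universal)
    rest <- rest[order(-df$fscore[rest], df$mz[rest],
                       match(df$kind[rest], c("fragment", "loss")))]
    ranked <- rest[seq_len(min(max_rank, length(rest)))]
    retained <- df$universal | seq_len(nrow(df)) %in% ranked |
      df$specificity_one
    df$singleton_only <- df$specificity_one & !df$universal &
      !(seq_len(nrow(df)) %in% ranked)
    df <- df[retained & df$fscore >= min_score, , drop = FALSE]
    df <- df[order(-df$fscore, df$mz,
                   match(df$kind, c("fragment", "loss"))), , drop = FALSE]
    rownames(df) <- NULL
    out[[skel]] <- df
  }
  out
}

empty_candidates <- function() {
  data.frame(kind = character(0), mz = numeric(0), tp = integer(0),
             occurrence = integer(0), precision = numeric(0),
             recall = numeric(0), fscore = numeric(0), universal = logical(0),
             specificity_one = logical(0), singleton_only = logical(0))
}

#' Match a conjunctive signal query against a raw spectrum
#'
#' TRUE iff every signal is found: a fragment signal must match some peak
#' m/z within the effective tolerance window at the signal m/z; a loss
#' signal must match `precursor_mz - peak mz` for some peak below the
#' precursor. Queries are conjunctive (AND semantics) and are evaluated on
#' raw, non-preprocessed spectra.
#'
#' @param signals data.frame with columns `kind` ("fragment"/"loss") and
#'   `mz`; must have at least one row.
#' @param spectrum a raw [spectrum()].
#' @param tol a [tolerance()].
#' @return logical scalar.
#' @export
match_query <- function(signals, spectrum, tol = tolerance()) {
  if (inherits(signals, "SkeletonQuery")) signals <- signals$signals
  if (nrow(signals) == 0L) stop("query must contain at least one signal")
  mzs <- spectrum$peaks$mz
  losses <- spectrum$precursor_mz - mzs[mzs < spectrum$precursor_mz]
  for (i in seq_len(nrow(signals))) {
    s <- signals$mz[i]
    w <- tol_window(tol, s)
    pool <- if (signals$kind[i] == "fragment") mzs else losses
    if (!length(pool) || min(abs(pool - s)) > w) return(FALSE)
  }
  TRUE
}

new_skeleton_query <- function(skeleton, signals, counts, n_library) {
  precision <- if ((counts$tp + counts$fp) > 0) {
    counts$tp / (counts$tp + counts$fp)
  } else 0
  recall <- if ((counts$tp + counts$fn) > 0) {
    counts$tp / (counts$tp + counts$fn)
  } else 0
  structure(list(
    skeleton = skeleton,
    signals = signals[order(match(signals$kind, c("fragment", "loss")),
                            signals$mz), , drop = FALSE],
    counts = counts,
    precision = precision,
    recall = recall,
    f05 = fbeta(precision, recall, 0.5),
    n_library = n_library
  ), class = "SkeletonQuery")
}

#' @export
print.SkeletonQuery <- function(x, ...) {
  sig <- paste(sprintf("%s:%.4f",
                       ifelse(x$signals$kind == "fragment", "F", "L"),
                       x$signals$mz), collapse = " AND ")
  cat(sprintf("<SkeletonQuery %s> {%s}\n  F0.5 = %.4f (P = %.4f, R = %.4f; tp=%d fp=%d fn=%d tn=%d)\n",
              x$skeleton, sig, x$f05, x$precision, x$recall,
              x$counts$tp, x$counts$fp, x$counts$fn, x$counts$tn))
  invisible(x)
}

signal_key <- function(signals) {
  paste(sprintf("%s:%.4f", ifelse(signals$kind == "fragment", "F", "L"),
                signals$mz)[order(match(signals$kind, c("fragment", "loss")),
                                  signals$mz)],
        collapse = "&")
}

#' Enumerate additive signal combinations and keep the best queries
#'
#' Every non-empty subset of the combinable candidates, up to `max_signals`
#' signals, is evaluated via [match_query()] against the whole raw library;
#' in addition, each specificity-1 candidate is always evaluated as a
#' standalone query. Positives are the skeleton's group members; negatives
#' are all other library spectra, grouped or not. Each query is scored with
#' F-beta (`beta_query`, default 0.5) and all queries tied at the maximum
#' score are returned, sorted by size then by signal m/z.
#'
#' Supersets of a query retrieving nothing also retrieve nothing, so the
#' enumeration prunes them; queries with an empty retrieved set score 0 and
#' are never reported.
#'
#' @param candidates candidate data.frame for one skeleton (see
#'   [score_candidates()]).
#' @param skeleton skeleton label.
#' @param library the raw [spectral_library()].
#' @param tol a [tolerance()].
#' @param max_signals maximum query size (default 10).
#' @param min_group minimum group size to attempt query generation
#'   (default 5); smaller groups are skipped with a message.
#' @param beta_query F-beta weighting for query scoring (default 0.5).
#' @return list of `SkeletonQuery` objects (empty if the group is too small
#'   or nothing scores above 0).
#' @export
enumerate_and_score <- function(candidates, skeleton, library,
                                tol = tolerance(), max_signals = 10L,
                                min_group = 5L, beta_query = 0.5) {
  stopifnot(inherits(library, "SpectralLibrary"))
  gids <- library$groups[[skeleton]]
  if (is.null(gids)) stop("unknown skeleton label: ", skeleton)
  gs <- length(gids)
  if (gs < min_group) {
    message("skipping '", skeleton, "': group size ", gs, " < ", min_group)
    return(list())
  }
  if (nrow(candidates) == 0L) return(list())
  ids <- names(library$spectra)
  n <- length(ids)
  in_group <- ids %in% gids

  # per-candidate retrieved sets over the raw library
  retrieved <- vapply(seq_len(nrow(candidates)), function(i) {
    vapply(library$spectra, function(s) {
      match_query(candidates[i, c("kind", "mz"), drop = FALSE], s, tol)
    }, logical(1))
  }, logical(n))
  if (is.null(dim(retrieved))) retrieved <- matrix(retrieved, nrow = n)

  score_set <- function(rset) {
    tp <- sum(rset & in_group)
    fp <- sum(rset & !in_group)
    fn <- gs - tp
    list(counts = list(tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn),
         f = fbeta(if (tp + fp > 0) tp / (tp + fp) else 0, tp / gs,
                   beta_query))
  }

  best <- -Inf
  hits <- list() # list of list(idx, counts, f)
  record <- function(idx, rset) {
    if (!any(rset)) return(invisible(FALSE))
    sc <- score_set(rset)
    if (sc$f > best + 1e-12) {
      best <<- sc$f
      hits <<- list(list(idx = idx, counts = sc$counts, f = sc$f))
    } else if (abs(sc$f - best) <= 1e-12) {
      hits[[length(hits) + 1L]] <<- list(idx = idx, counts = sc$counts,
                                         f = sc$f)
    }
    invisible(TRUE)
  }

  combinable <- which(!candidates$singleton_only)
  recurse <- function(start, idx, rset) {
    if (length(idx) >= max_signals || start > length(combinable)) return()
    for (pos in start:length(combinable)) {
      j <- combinable[pos]
      nset <- rset & retrieved[, j]
      if (!any(nset)) next # supersets are empty too: loss-free prune
      record(c(idx, j), nset)
      recurse(pos + 1L, c(idx, j), nset)
    }
  }
  recurse(1L, integer(0), rep(TRUE, n))

  for (j in which(candidates$singleton_only)) {
    record(j, retrieved[, j])
  }

  if (!length(hits) || best <= 0) {
    message("no query with a positive score for '", skeleton, "'")
    return(list())
  }
  queries <- lapply(hits, function(h) {
    new_skeleton_query(skeleton,
                       candidates[h$idx, c("kind", "mz"), drop = FALSE],
                       h$counts, n)
  })
  keys <- vapply(queries, function(q) signal_key(q$signals), character(1))
  sizes <- vapply(queries, function(q) nrow(q$signals), integer(1))
  queries <- queries[order(sizes, keys)]
  # identical signal sets can be recorded once via enumeration and once as a
  # specificity-1 singleton
  queries[!duplicated(vapply(queries, function(q) signal_key(q$signals),
                             character(1)))]
}

#' Extract skeleton-specific spectrometric signatures
#'
#' The full chain: condition every spectrum ([preprocess_library()]),
#' harmonize fragment and neutral-loss m/z values across the library
#' ([harmonize()]), score candidate signals per skeleton group
#' ([score_candidates()]), then enumerate and evaluate signal combinations
#' against the raw library ([enumerate_and_score()]). Only groups with at
#' least `min_group` members (after exclusion of spectra emptied by
#' filtering) produce queries.
#'
#' @param library a [spectral_library()] with skeleton groups.
#' @param tol a [tolerance()].
#' @param min_occurrence,min_score,max_rank,beta_candidates passed to
#'   [score_candidates()].
#' @param max_signals,min_group,beta_query passed to
#'   [enumerate_and_score()].
#' @param deisotope_enabled passed to [preprocess_library()].
#' @return named list: skeleton -> list of best `SkeletonQuery` objects
#'   (ties kept). Attribute `candidates` carries the per-skeleton candidate
#'   tables for provenance.
#' @export
extract_signatures <- function(library, tol = tolerance(),
                               min_occurrence = 3L, min_score = 0,
                               max_rank = 10L, beta_candidates = 2,
                               max_signals = 10L, min_group = 5L,
                               beta_query = 0.5, deisotope_enabled = TRUE) {
  stopifnot(inherits(library, "SpectralLibrary"))
  if (!length(library$groups)) {
    message("no skeleton groups in library; nothing to extract")
    return(structure(list(), candidates = list()))
  }
  pre <- preprocess_library(library, tol, deisotope_enabled)
  surviving <- names(pre$library$spectra)
  groups <- lapply(library$groups, intersect, surviving)
  groups <- groups[vapply(groups, length, integer(1)) > 0L]

  frag <- harmonize(pre$library, tol, "fragment")
  loss <- harmonize(pre$library, tol, "loss")
  comb <- combine_matrices(frag, loss)
  cands <- score_candidates(comb, groups, min_occurrence, min_score,
                            max_rank, beta_candidates)
  eligible <- names(groups)[vapply(groups, length, integer(1)) >= min_group]
  if (!length(eligible)) {
    message("no skeleton group reaches the minimum size of ", min_group)
    return(structure(list(), candidates = cands))
  }
  res <- lapply(eligible, function(skel) {
    enumerate_and_score(cands[[skel]], skel, library, tol,
                        max_signals, min_group, beta_query)
  })
  names(res) <- eligible
  structure(res, candidates = cands)
}

#' Write extracted queries as a TSV table
#'
#' One row per (skeleton, query): signals as a `&`-joined `F:<mz>`/`L:<mz>`
#' list plus confusion counts and scores.
#'
#' @param results output of [extract_signatures()].
#' @param path output path.
#' @export
write_queries_tsv <- function(results, path) {
  rows <- list()
  for (skel in names(results)) {
    for (q in results[[skel]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        skeleton = skel, signals = signal_key(q$signals),
        tp = q$counts$tp, fp = q$counts$fp, fn = q$counts$fn,
        tn = q$counts$tn, precision = q$precision, recall = q$recall,
        f05 = q$f05)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(skeleton = character(0), signals = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
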