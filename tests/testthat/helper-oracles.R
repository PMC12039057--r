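# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: the F-beta oracle is coded from the formula, the
# subset enumerator matches spectra with its own scan loop, and the
# clustering oracle merges by brute force.

# ---- F-beta oracle (direct arithmetic) -------------------------------------
oracle_fbeta <- function(p, r, beta) {
  num <- (1 + beta^2) * p * r
  den <- beta^2 * p + r
  if (den == 0) 0 else num / den
}

# ---- independent conjunctive matcher ---------------------------------------
oracle_match <- function(signals, spec, tol_abs = 0.010, tol_ppm = 25) {
  for (i in seq_len(nrow(signals))) {
    target <- signals$mz[i]
    w <- max(tol_abs, tol_ppm * target * 1e-6)
    found <- FALSE
    for (k in seq_len(nrow(spec$peaks))) {
      mz <- spec$peaks$mz[k]
      v <- if (signals$kind[i] == "fragment") mz else {
        if (mz >= spec$precursor_mz) next
        spec$precursor_mz - mz
      }
      if (abs(v - target) <= w) { found <- TRUE; break }
    }
    if (!found) return(FALSE)
  }
  TRUE
}

# ---- brute-force subset enumerator -----------------------------------------
# returns best F0.5 and the set of tied signal-key strings; subsets whose
# retrieved set is empty score 0 and are excluded (shared convention)
oracle_enumerate <- function(candidates, library, group_ids,
                             max_signals = 10L) {
  ids <- names(library$spectra)
  n <- length(ids)
  gs <- length(group_ids)
  nc <- nrow(candidates)
  key_of <- function(idx) {
    sig <- candidates[idx, , drop = FALSE]
    paste(sort(sprintf("%s:%.4f",
                       ifelse(sig$kind == "fragment", "F", "L"), sig$mz)),
          collapse = "&")
  }
  best <- -Inf; keys <- character(0)
  for (size in seq_len(min(max_signals, nc))) {
    combos <- utils::combn(nc, size, simplify = FALSE)
    for (idx in combos) {
      hit <- vapply(library$spectra, function(s) {
        oracle_match(candidates[idx, , drop = FALSE], s)
      }, logical(1))
      if (!any(hit)) next
      tp <- sum(ids[hit] %in% group_ids)
      p <- tp / sum(hit)
      r <- tp / gs
      f <- oracle_fbeta(p, r, 0.5)
      if (f > best + 1e-12) {
        best <- f; keys <- key_of(idx)
      } else if (abs(f - best) <= 1e-12) {
        keys <- c(keys, key_of(idx))
      }
    }
  }
  list(best = best, keys = sort(unique(keys)))
}

# ---- brute-force single-linkage clustering over a sorted pool --------------
oracle_cluster <- function(values, tol_abs = 0.010, tol_ppm = 25) {
  values <- sort(values)
  groups <- list(values[1])
  if (length(values) > 1) {
    for (v in values[-1]) {
      last <- groups[[length(groups)]]
      w <- max(tol_abs, tol_ppm * last[length(last)] * 1e-6)
      if (v - last[length(last)] <= w) {
        groups[[length(groups)]] <- c(last, v)
      } else {
        groups[[length(groups) + 1L]] <- v
      }
    }
  }
  groups
}

# ---- fixture builders ------------------------------------------------------
make_spectrum <- function(id, precursor, mz, intensity = NULL,
                          skeleton = NA_character_, ...) {
  if (is.null(intensity)) intensity <- rep(1, length(mz))
  spectrum(id, precursor, mz, intensity, skeleton = skeleton, ...)
}

# a BinnedSignalMatrix built directly from its parts
make_signal_matrix <- function(mat, kinds, mzs) {
  structure(list(matrix = mat,
                 signals = data.frame(kind = kinds, mz = mzs),
                 kind = "combined"),
            class = "BinnedSignalMatrix")
}

# random small library for oracle-equivalence checks: peaks drawn from a
# discrete m/z alphabet so signals recur across spectra
random_instance <- function(n_spectra = 12L, n_candidates = 6L) {
  alphabet <- round(runif(10, 100, 400), 4)
  spectra <- lapply(seq_len(n_spectra), function(i) {
    k <- sample(3:7, 1)
    make_spectrum(sprintf("S%02d", i), precursor = round(runif(1, 450, 600), 4),
                  mz = sample(alphabet, k),
                  intensity = runif(k, 10, 100),
                  skeleton = if (i <= 6) "grp" else NA_character_)
  })
  lib <- spectral_library(spectra)
  cand_mz <- sample(alphabet, min(n_candidates, length(alphabet)))
  candidates <- data.frame(kind = "fragment", mz = cand_mz,
                           singleton_only = FALSE)
  list(library = lib, candidates = candidates,
       group_ids = lib$groups[["grp"]])
}

# tiny MGF text written to a temp file
write_mgf_text <- function(lines) {
  path <- tempfile(fileext = ".mgf")
  writeLines(lines, path)
  path
}

toy_smiles_20 <- c(
  methane = "C", ethane = "CC", propane = "CCC", ethanol = "CCO",
  ethylamine = "CCN", benzene = "c1ccccc1", pyridine = "c1ccncc1",
  cyclohexane = "C1CCCCC1", piperidine = "C1CCNCC1", isobutane = "CC(C)C",
  alanine = "CC(N)C(=O)O", indole = "c1ccc2[nH]ccc2c1",
  ether = "CCOC", acetaldehyde = "CC=O", aceticacid = "CC(=O)O",
  thf = "C1CCOC1", phenol = "c1ccc(O)cc1", propylamine = "CCCN",
  toluene = "Cc1ccccc1", acetonitrile = "CC#N")
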