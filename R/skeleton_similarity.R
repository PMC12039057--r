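#' @name skeleton_similarity
#' @title Structural similarity between skeleton scaffolds
#' @description
#' Skeleton SMILES are converted to Morgan (ECFP-like circular) fingerprints
#' (radius 2, 2048 bits) and compared pairwise with the Tanimoto
#' coefficient; agglomerative clustering on `1 - similarity` yields the
#' dendrogram whose leaf order arranges spectra on heatmap axes.
#' Fingerprinting, SMARTS generation and substructure matching are delegated
#' to the RDKit toolkit through the `python` interpreter on the PATH (no
#' RDKit binding exists for R); all similarity and clustering arithmetic is
#' done in R.
NULL

run_chem_tool <- function(mode, input, args = character(0)) {
  py <- Sys.which("python")
  if (!nzchar(py)) stop("no 'python' interpreter on PATH (required for RDKit)")
  script <- system.file("python", "fp_tool.py", package = "spectrasig")
  if (!nzchar(script)) stop("bundled fp_tool.py not found")
  out <- suppressWarnings(
    system2(py, c(shQuote(script), mode, args), input = input,
            stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("chemistry helper failed (mode '", mode, "', exit ", status, ")")
  }
  if (length(out) != length(input)) {
    stop("chemistry helper returned ", length(out), " lines for ",
         length(input), " inputs")
  }
  out
}

#' Morgan fingerprints from SMILES
#'
#' @param smiles character vector of SMILES strings.
#' @param radius Morgan radius (default 2; "size = 2" in common parameter
#'   reporting, equivalent to ECFP4).
#' @param n_bits fingerprint length (default 2048).
#' @return logical matrix, one row per SMILES, `n_bits` columns.
#' @export
fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  stopifnot(is.character(smiles), length(smiles) > 0, radius >= 1,
            n_bits >= 8)
  out <- run_chem_tool("fp", smiles, c(radius, n_bits))
  bad <- grepl("^ERROR", out)
  if (any(bad)) {
    stop("unparsable SMILES at record(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(smiles[bad], collapse = ", "))
  }
  fp <- matrix(FALSE, nrow = length(smiles), ncol = n_bits)
  for (i in seq_along(out)) {
    if (nzchar(out[i])) {
      fp[i, as.integer(strsplit(out[i], " ")[[1]]) + 1L] <- TRUE
    }
  }
  rownames(fp) <- names(smiles)
  fp
}

#' SMILES to SMARTS conversion
#'
#' The generated SMARTS pattern always matches its own source structure
#' (self-match property, checkable with [smarts_self_match()]).
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of SMARTS patterns.
#' @export
smiles_to_smarts <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  out <- run_chem_tool("smarts", smiles)
  bad <- grepl("^ERROR", out)
  if (any(bad)) {
    stop("unparsable SMILES at record(s) ",
         paste(which(bad), collapse = ", "))
  }
  stats::setNames(out, names(smiles))
}

#' Check that SMARTS patterns match given structures
#'
#' @param smiles character vector of SMILES.
#' @param smarts character vector of SMARTS, same length.
#' @return logical vector.
#' @export
smarts_self_match <- function(smiles, smarts) {
  stopifnot(length(smiles) == length(smarts))
  out <- run_chem_tool("match", paste(smiles, smarts, sep = "\t"))
  if (any(grepl("^ERROR", out))) stop("invalid SMILES/SMARTS pair")
  out == "1"
}

#' Tanimoto coefficient between two bit vectors
#'
#' `|a AND b| / |a OR b|`; defined as 1.0 when both vectors are empty
#' (identical objects).
#'
#' @param a,b logical (or 0/1) vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(1.0)
  sum(a & b) / u
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fp logical fingerprint matrix (rows = structures); rownames become
#'   the labels.
#' @return an object of class `SimilarityMatrix`: list with `labels`,
#'   `values` (symmetric, unit diagonal) and `leaf_order` (initially the
#'   label order; see [build_dendrogram()]).
#' @export
tanimoto_matrix <- function(fp) {
  stopifnot(is.matrix(fp))
  m <- fp * 1L
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  un <- outer(ones, ones, `+`) - inter
  vals <- ifelse(un == 0, 1, inter / un)
  labels <- rownames(fp) %||% as.character(seq_len(nrow(fp)))
  dimnames(vals) <- list(labels, labels)
  structure(list(labels = labels, values = vals, leaf_order = labels),
            class = "SimilarityMatrix")
}

#' @export
print.SimilarityMatrix <- function(x, ...) {
  cat(sprintf("<SimilarityMatrix> %d x %d\n", nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Hierarchical clustering of a similarity matrix
#'
#' Agglomerative clustering on distance `1 - similarity`. The leaf order is
#' made canonical by a deterministic flip rule — at every merge the lighter
#' subtree (fewer leaves; ties broken by the lexicographically smallest
#' label) comes first — so the order is reproducible up to branch flips
#' under any permutation of the input labels.
#'
#' @param sim a `SimilarityMatrix` (at least 2 labels).
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`, i.e. UPGMA).
#' @return list with `hclust` (the tree), `leaf_order` (character vector)
#'   and `newick` (Newick serialization, via ape).
#' @export
build_dendrogram <- function(sim, linkage = "average") {
  stopifnot(inherits(sim, "SimilarityMatrix"))
  if (length(sim$labels) < 2L) stop("need at least 2 labels to cluster")
  d <- stats::as.dist(1 - sim$values)
  hc <- stats::hclust(d, method = linkage)
  leaf_order <- canonical_leaf_order(hc)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, leaf_order = leaf_order,
       newick = ape::write.tree(phy))
}

canonical_leaf_order <- function(hc) {
  labels <- hc$labels
  walk <- function(node) {
    if (node < 0) {
      return(list(leaves = labels[-node], size = 1L, minlab = labels[-node]))
    }
    a <- walk(hc$merge[node, 1L])
    b <- walk(hc$merge[node, 2L])
    if (a$size > b$size ||
        (a$size == b$size && a$minlab > b$minlab)) {
      tmp <- a; a <- b; b <- tmp
    }
    list(leaves = c(a$leaves, b$leaves), size = a$size + b$size,
         minlab = min(a$minlab, b$minlab))
  }
  walk(nrow(hc$merge))$leaves
}

#' Build skeleton records from a name/SMILES table
#'
#' Derives SMARTS and Morgan fingerprints for every skeleton and the
#' pairwise Tanimoto matrix.
#'
#' @param name character vector of skeleton labels.
#' @param smiles character vector of SMILES, same length.
#' @param radius,n_bits fingerprint parameters.
#' @return list with `table` (data.frame `name`, `smiles`, `smarts`),
#'   `fingerprints` (logical matrix) and `similarity` (`SimilarityMatrix`).
#' @export
skeleton_records <- function(name, smiles, radius = 2L, n_bits = 2048L) {
  stopifnot(length(name) == length(smiles), !anyDuplicated(name))
  fp <- fingerprint(stats::setNames(smiles, name), radius, n_bits)
  list(table = data.frame(name = name, smiles = smiles,
                          smarts = unname(smiles_to_smarts(smiles))),
       fingerprints = fp,
       similarity = tanimoto_matrix(fp))
}
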