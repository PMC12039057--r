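#' Construct a single MS/MS spectrum
#'
#' @param spectrum_id opaque identifier, unique within a library.
#' @param precursor_mz precursor ion m/z (Th, > 0).
#' @param mz fragment m/z values (Th).
#' @param intensity fragment intensities (non-negative).
#' @param charge precursor charge (positive-mode library, default 1).
#' @param compound_name compound name or `NA`.
#' @param smiles SMILES string or `NA`.
#' @param skeleton expert skeleton label or `NA` (ungrouped).
#' @param metadata named list of additional MGF header fields, kept verbatim.
#' @return an object of class `Spectrum`. Peaks are stored sorted by
#'   ascending m/z.
#' @export
spectrum <- function(spectrum_id, precursor_mz, mz, intensity,
                     charge = 1L, compound_name = NA_character_,
                     smiles = NA_character_, skeleton = NA_character_,
                     metadata = list()) {
  stopifnot(length(spectrum_id) == 1L,
            is.numeric(precursor_mz), length(precursor_mz) == 1L,
            precursor_mz > 0,
            length(mz) == length(intensity))
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) && (any(mz <= 0) || any(intensity < 0))) {
    stop("peaks must have mz > 0 and intensity >= 0")
  }
  o <- order(mz)
  structure(list(
    spectrum_id = as.character(spectrum_id),
    precursor_mz = precursor_mz,
    charge = as.integer(charge),
    peaks = data.frame(mz = mz[o], intensity = intensity[o]),
    compound_name = compound_name,
    smiles = smiles,
    skeleton = skeleton,
    metadata = metadata
  ), class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("<Spectrum %s> precursor %.4f, %d peaks%s\n",
              x$spectrum_id, x$precursor_mz, nrow(x$peaks),
              if (!is.na(x$skeleton)) paste0(", skeleton: ", x$skeleton) else ""))
  invisible(x)
}

#' Construct a spectral library
#'
#' Bundles a list of [spectrum()] objects and derives the skeleton group
#' mapping from their `skeleton` fields. Spectra without a skeleton label are
#' kept but assigned to no group; each spectrum belongs to at most one group.
#'
#' @param spectra list of `Spectrum` objects with unique ids.
#' @return an object of class `SpectralLibrary` with elements `spectra`
#'   (named list) and `groups` (named list: skeleton label -> character vector
#'   of spectrum ids).
#' @export
spectral_library <- function(spectra) {
  stopifnot(is.list(spectra))
  ids <- vapply(spectra, function(s) s$spectrum_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate spectrum ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(spectra) <- ids
  skel <- vapply(spectra, function(s) s$skeleton %||% NA_character_, character(1))
  grouped <- !is.na(skel) & nzchar(skel)
  groups <- split(unname(ids[grouped]), skel[grouped])
  structure(list(spectra = spectra, groups = groups),
            class = "SpectralLibrary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.SpectralLibrary <- function(x, ...) {
  cat(sprintf("<SpectralLibrary> %d spectra, %d skeleton groups\n",
              length(x$spectra), length(x$groups)))
  if (length(x$groups)) {
    sizes <- vapply(x$groups, length, integer(1))
    cat("  groups: ",
        paste(sprintf("%s (%d)", names(sizes), sizes), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.SpectralLibrary <- function(x) length(x$spectra)

#' Read an MGF spectral library
#'
#' Parses a Mascot Generic Format file (BEGIN IONS / END IONS blocks). Both
#' `PEPMASS=mz` and `PEPMASS=mz intensity` are accepted; unknown headers are
#' retained in each spectrum's `metadata`; charge defaults to 1+ when absent.
#' The skeleton label is read from a configurable header key because deposited
#' libraries differ in their metadata vocabulary.
#'
#' @param path path to an MGF file.
#' @param metadata_keys named character vector mapping the fields `id`,
#'   `name`, `smiles`, `skeleton` to MGF header keys.
#' @return a [spectral_library()].
#' @export
read_mgf <- function(path,
                     metadata_keys = c(id = "SCANS", name = "NAME",
                                       smiles = "SMILES",
                                       skeleton = "SKELETON")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) == 0L) stop("empty library: no BEGIN IONS block in ", path)
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  }
  defaults <- c(id = "SCANS", name = "NAME", smiles = "SMILES",
                skeleton = "SKELETON")
  mk <- defaults
  mk[names(metadata_keys)] <- metadata_keys

  spectra <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    block <- block[nzchar(block)]
    is_header <- grepl("=", block, fixed = TRUE) &
      !grepl("^[0-9.+-]", block)
    headers <- block[is_header]
    peak_rows <- block[!is_header]
    kv <- regmatches(headers, regexpr("=", headers, fixed = TRUE),
                     invert = TRUE)
    keys <- toupper(vapply(kv, `[`, character(1), 1L))
    vals <- vapply(kv, `[`, character(1), 2L)
    meta <- stats::setNames(as.list(vals), keys)

    if (is.null(meta$PEPMASS)) stop("block ", b, ": missing PEPMASS")
    pep <- suppressWarnings(as.numeric(strsplit(meta$PEPMASS, "[ \t]+")[[1]][1]))
    if (is.na(pep)) stop("block ", b, ": non-numeric PEPMASS")

    pk <- strsplit(peak_rows, "[ \t]+")
    mzs <- suppressWarnings(as.numeric(vapply(pk, `[`, character(1), 1L)))
    ints <- suppressWarnings(as.numeric(vapply(pk, function(p) {
      if (length(p) >= 2L) p[2L] else NA_character_
    }, character(1))))
    if (length(peak_rows) && (anyNA(mzs) || anyNA(ints))) {
      stop("block ", b, ": non-numeric peak row")
    }

    charge <- 1L
    if (!is.null(meta$CHARGE)) {
      ch <- suppressWarnings(as.integer(gsub("[^0-9]", "", meta$CHARGE)))
      if (!is.na(ch) && ch > 0L) charge <- ch
    }
    getf <- function(field) {
      v <- meta[[toupper(mk[[field]])]]
      if (is.null(v) || !nzchar(v)) NA_character_ else v
    }
    id <- getf("id")
    if (is.na(id)) id <- meta$TITLE %||% sprintf("spectrum_%d", b)
    known <- unique(c("PEPMASS", "CHARGE", "TITLE", toupper(mk)))
    extra <- meta[setdiff(names(meta), known)]
    spectra[[b]] <- spectrum(
      spectrum_id = id, precursor_mz = pep, mz = mzs, intensity = ints,
      charge = charge, compound_name = getf("name"),
      smiles = getf("smiles"), skeleton = getf("skeleton"),
      metadata = extra
    )
  }
  spectral_library(spectra)
}

#' Write a spectral library as MGF
#'
#' Round-trip contract: [read_mgf()] on the written file reproduces precursor
#' m/z and peak m/z to 4 decimals, peak counts exactly, and the metadata
#' fields. m/z values are serialized at 4 decimal places, matching the
#' harmonized signal representation.
#'
#' @param library a [spectral_library()]; must be non-empty.
#' @param path output path.
#' @param skeleton_key MGF header key used for the skeleton label.
#' @return invisibly, `path`.
#' @export
write_mgf <- function(library, path, skeleton_key = "SKELETON") {
  stopifnot(inherits(library, "SpectralLibrary"))
  if (length(library$spectra) == 0L) stop("refusing to write an empty library")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (s in library$spectra) {
    out <- c("BEGIN IONS",
             sprintf("PEPMASS=%.4f", s$precursor_mz),
             sprintf("CHARGE=%d+", s$charge),
             sprintf("SCANS=%s", s$spectrum_id))
    if (!is.na(s$compound_name)) out <- c(out, sprintf("NAME=%s", s$compound_name))
    if (!is.na(s$smiles)) out <- c(out, sprintf("SMILES=%s", s$smiles))
    if (!is.na(s$skeleton)) out <- c(out, sprintf("%s=%s", skeleton_key, s$skeleton))
    for (k in names(s$metadata)) {
      out <- c(out, sprintf("%s=%s", k, s$metadata[[k]]))
    }
    if (nrow(s$peaks)) {
      out <- c(out, sprintf("%.4f %.8g", s$peaks$mz, s$peaks$intensity))
    }
    out <- c(out, "END IONS", "")
    writeLines(out, con)
  }
  invisible(path)
}

#' Attach or replace skeleton labels from an assignment table
#'
#' Keys are resolved first against spectrum ids, then against compound names.
#' A compound name matching several spectra is ambiguous and raises an error;
#' unmatched keys are reported as a warning and otherwise ignored.
#'
#' @param library a [spectral_library()].
#' @param table named character vector: spectrum id or compound name ->
#'   skeleton label.
#' @return a new `SpectralLibrary` with groups rebuilt.
#' @export
attach_skeletons <- function(library, table) {
  stopifnot(inherits(library, "SpectralLibrary"),
            is.character(table), !is.null(names(table)))
  ids <- names(library$spectra)
  cnames <- vapply(library$spectra, function(s) s$compound_name %||% NA_character_,
                   character(1))
  spectra <- library$spectra
  unmatched <- character(0)
  for (key in names(table)) {
    if (key %in% ids) {
      spectra[[key]]$skeleton <- unname(table[[key]])
    } else {
      hit <- which(!is.na(cnames) & cnames == key)
      if (length(hit) > 1L) {
        stop("ambiguous compound name '", key, "' matches spectra: ",
             paste(ids[hit], collapse = ", "))
      } else if (length(hit) == 1L) {
        spectra[[hit]]$skeleton <- unname(table[[key]])
      } else {
        unmatched <- c(unmatched, key)
      }
    }
  }
  if (length(unmatched)) {
    warning("unmatched skeleton-table keys: ", paste(unmatched, collapse = ", "))
  }
  spectral_library(spectra)
}
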