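#' Precision and recall of an annotated retrieval
#'
#' Evaluation arithmetic for queries run on an independently annotated
#' dataset: precision is computed over the retrieved features that carry a
#' reference annotation (this quantity is reported as "accuracy" in some
#' sources — its arithmetic, true positives over annotated retrieved items,
#' is a precision); recall is computed over all reference-annotated features
#' of the target skeleton(s) in the dataset, not over all features.
#'
#' @param true_positive retrieved, annotated features whose annotation
#'   matches the target skeleton(s).
#' @param retrieved_annotated retrieved features carrying any reference
#'   annotation.
#' @param relevant_total reference-annotated features of the target
#'   skeleton(s) in the whole dataset.
#' @return list with `precision_pct` and `recall_pct`, percentages rounded
#'   to 2 decimals. A zero denominator yields `NA` (undefined), never 0.
#' @examples
#' retrieval_metrics(7, 16, 7) # precision 43.75, recall 100
#' @export
retrieval_metrics <- function(true_positive, retrieved_annotated,
                              relevant_total) {
  stopifnot(true_positive >= 0, retrieved_annotated >= 0, relevant_total >= 0,
            true_positive <= max(retrieved_annotated, 0))
  precision <- if (retrieved_annotated > 0) {
    round(100 * true_positive / retrieved_annotated, 2)
  } else NA_real_
  recall <- if (relevant_total > 0) {
    round(100 * true_positive / relevant_total, 2)
  } else NA_real_
  list(precision_pct = precision, recall_pct = recall)
}

#' Feature-by-sample intensity table
#'
#' @param intensity numeric matrix, rows = feature ids (rownames), columns =
#'   samples; non-negative ion intensities.
#' @param plant character vector of plant names, one per column.
#' @param genus character vector of genera, one per column.
#' @return an object of class `SourceTable`.
#' @export
source_table <- function(intensity, plant, genus) {
  stopifnot(is.matrix(intensity), !is.null(rownames(intensity)),
            length(plant) == ncol(intensity),
            length(genus) == ncol(intensity),
            all(intensity >= 0))
  structure(list(intensity = intensity, plant = as.character(plant),
                 genus = as.character(genus)), class = "SourceTable")
}

#' Merge duplicate plant columns by averaging
#'
#' When the same plant appears in several sample columns, the columns are
#' merged and the mean ion intensity per feature is retained.
#'
#' @param table a [source_table()].
#' @return a `SourceTable` with unique plant columns.
#' @export
merge_duplicate_plants <- function(table) {
  stopifnot(inherits(table, "SourceTable"))
  plants <- unique(table$plant)
  merged <- vapply(plants, function(p) {
    cols <- which(table$plant == p)
    rowMeans(table$intensity[, cols, drop = FALSE])
  }, numeric(nrow(table$intensity)))
  if (is.null(dim(merged))) {
    merged <- matrix(merged, nrow = nrow(table$intensity),
                     dimnames = list(rownames(table$intensity), plants))
  }
  genus <- vapply(plants, function(p) table$genus[table$plant == p][1],
                  character(1))
  source_table(merged, plants, genus)
}

#' Genus-level intensity share of tagged features
#'
#' Duplicate plant columns are first merged by mean; each genus' share is
#' then 100 times the summed intensity of the tagged features in that genus
#' divided by their total summed intensity. Shares sum to 100.
#'
#' @param table a [source_table()].
#' @param tagged character vector of feature ids (query hits); all must be
#'   present in the table.
#' @return named numeric vector: genus -> percentage, decreasing.
#' @export
genus_attribution <- function(table, tagged) {
  stopifnot(inherits(table, "SourceTable"), length(tagged) > 0)
  missing <- setdiff(tagged, rownames(table$intensity))
  if (length(missing)) {
    stop("tagged features absent from the table: ",
         paste(missing, collapse = ", "))
  }
  table <- merge_duplicate_plants(table)
  sub <- table$intensity[tagged, , drop = FALSE]
  by_genus <- tapply(colSums(sub), table$genus, sum)
  total <- sum(by_genus)
  if (total <= 0) stop("tagged features have zero total intensity")
  sort(100 * by_genus / total, decreasing = TRUE)
}
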