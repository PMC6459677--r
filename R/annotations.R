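#' Construct a cell annotation table
#'
#' A cell annotation table is the central input of differential proportion
#' analysis: one row per cell carrying an opaque cell identifier, the
#' experimental condition (group) label and the cluster (cell-type) label
#' the cell was assigned by upstream clustering. Labels are consumed as
#' given; no clustering is performed here.
#'
#' @param cell_id character vector of unique cell identifiers.
#' @param condition character vector of condition/group labels.
#' @param cluster character vector of cluster labels.
#' @return A `data.frame` with columns `cell_id`, `condition`, `cluster`.
#' @examples
#' ann <- cell_annotations(c("c1", "c2", "c3"), c("A", "A", "B"),
#'                         c("X", "Y", "X"))
#' build_count_table(ann)
#' @export
cell_annotations <- function(cell_id, condition, cluster) {
  ann <- data.frame(cell_id = as.character(cell_id),
                    condition = as.character(condition),
                    cluster = as.character(cluster),
                    stringsAsFactors = FALSE)
  validate_annotations(ann)
  ann
}

#' Validate a cell annotation table
#'
#' Checks the invariants every downstream operation relies on: presence of
#' the three required columns, at least one cell, unique cell identifiers,
#' and non-empty condition and cluster labels.
#'
#' @param annotations data.frame as produced by [cell_annotations()] or
#'   [read_annotations()].
#' @return The validated annotation table, invisibly.
#' @export
validate_annotations <- function(annotations) {
  if (!is.data.frame(annotations)) {
    stop("annotations must be a data.frame")
  }
  required <- c("cell_id", "condition", "cluster")
  missing <- setdiff(required, names(annotations))
  if (length(missing) > 0) {
    stop("annotations are missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(annotations) == 0) {
    stop("no cells: annotation table is empty")
  }
  if (anyDuplicated(annotations$cell_id)) {
    dup <- unique(annotations$cell_id[duplicated(annotations$cell_id)])
    stop("duplicate cell_id: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  bad <- is.na(annotations$condition) | annotations$condition == "" |
    is.na(annotations$cluster) | annotations$cluster == ""
  if (any(bad)) {
    stop(sum(bad), " cell(s) have empty condition or cluster labels")
  }
  invisible(annotations)
}

#' Tally cells per cluster and condition
#'
#' Builds the clusters-by-conditions count table underlying the proportion
#' test. Every (cluster, condition) combination is present, with explicit
#' zeros for clusters absent from a condition. Cluster and condition order
#' is the lexicographic sort of the labels, fixed here so that all
#' downstream vectors and permutation outputs align deterministically.
#'
#' @inheritParams validate_annotations
#' @return Integer matrix, clusters as rows, conditions as columns.
#' @export
build_count_table <- function(annotations) {
  validate_annotations(annotations)
  clusters <- sort(unique(annotations$cluster))
  conditions <- sort(unique(annotations$condition))
  tab <- table(factor(annotations$cluster, levels = clusters),
               factor(annotations$condition, levels = conditions))
  counts <- matrix(as.integer(tab), nrow = length(clusters),
                   dimnames = list(cluster = clusters, condition = conditions))
  counts
}

#' Convert a count table to per-condition proportions
#'
#' @param counts clusters-by-conditions integer matrix from
#'   [build_count_table()].
#' @return Numeric matrix of the same shape; each column sums to 1.
#' @export
to_proportions <- function(counts) {
  if (!is.matrix(counts) || is.null(colnames(counts))) {
    stop("counts must be a clusters-by-conditions matrix with dimnames")
  }
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("condition(s) with zero cells: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  sweep(counts, 2, totals, `/`)
}

#' Per-cluster difference in proportions between two conditions
#'
#' The observed statistic of differential proportion analysis: for each
#' cluster j, the difference in that cluster's share of cells between the
#' two conditions, `p_1j - p_2j`.
#'
#' @param proportions clusters-by-conditions matrix from [to_proportions()].
#' @param cond1,cond2 condition labels (columns of `proportions`).
#' @return Named numeric vector over clusters, in table row order.
#' @export
delta_proportions <- function(proportions, cond1, cond2) {
  for (cond in c(cond1, cond2)) {
    if (!cond %in% colnames(proportions)) {
      stop("unknown condition label: ", cond)
    }
  }
  proportions[, cond1] - proportions[, cond2]
}
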