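#' Counts-per-ten-thousand log normalization
#'
#' Scales each cell's UMI counts to sum to 10,000 and applies the natural
#' log with a pseudo-count of 1: a raw value `v` in a cell with total `s`
#' becomes `log(1 + 10000 * v / s)`. This is the normalization convention
#' all downstream fold-change and network weights assume.
#'
#' @param counts genes-by-cells matrix of raw UMI counts (base matrix or
#'   a `Matrix` sparse matrix); all values must be non-negative and every
#'   cell must have a positive total.
#' @return Matrix of the same class and dimnames holding normalized
#'   log-scale values.
#' @export
normalize_cptt <- function(counts) {
  if (min(counts) < 0) stop("raw counts must be non-negative")
  s <- Matrix::colSums(counts)
  if (any(s == 0)) {
    bad <- if (is.null(colnames(counts))) which(s == 0) else
      colnames(counts)[s == 0]
    stop("cell(s) with zero total counts: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (inherits(counts, "sparseMatrix")) {
    out <- counts %*% Matrix::Diagonal(x = 10000 / s)
    out <- methods::as(out, "CsparseMatrix")
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(counts)
  } else {
    out <- log1p(sweep(counts, 2, 10000 / s, `*`))
  }
  out
}

#' Fraction of a cell population expressing a gene
#'
#' @param expr genes-by-cells matrix (raw or normalized; detection only
#'   asks whether a value is nonzero, so any monotone positive transform
#'   of the counts gives the same answer).
#' @param cells logical mask, integer indices or cell names selecting the
#'   population's cells.
#' @param gene gene name or row index.
#' @return Detection rate in `[0, 1]`.
#' @export
detection_rate <- function(expr, cells, gene) {
  v <- expr[gene, cells]
  if (length(v) == 0) stop("empty population")
  mean(v > 0)
}

#' Log2 fold-change of a gene in one population versus all remaining cells
#'
#' Computes `log2((mean_in + pc) / (mean_rest + pc))` where the means are
#' taken over the population's cells and over all other cells. With
#' `fc_scale = "log"` (default) the means are taken over the normalized
#' log-scale values as given; with `"linear"` the values are first mapped
#' back to the linear normalized scale via `expm1`.
#'
#' @param expr normalized genes-by-cells matrix ([normalize_cptt()]).
#' @param clusters population label per cell (length `ncol(expr)`).
#' @param population the population of interest.
#' @param gene gene name or row index.
#' @param pseudocount added to both means before the ratio (default 1).
#' @param fc_scale `"log"` or `"linear"`; see Details in the methods
#'   vignette for why this choice matters for network weights.
#' @return A single log2 fold-change.
#' @export
log2fc_vs_rest <- function(expr, clusters, population, gene,
                           pseudocount = 1, fc_scale = c("log", "linear")) {
  fc_scale <- match.arg(fc_scale)
  inside <- clusters == population
  if (!any(inside)) stop("empty population: ", population)
  if (all(inside)) stop("population equals the entire cohort; no remaining cells")
  v <- as.numeric(expr[gene, ])
  if (fc_scale == "linear") v <- expm1(v)
  log2((mean(v[inside]) + pseudocount) / (mean(v[!inside]) + pseudocount))
}

#' Per-population detection rates and fold-changes for all genes
#'
#' Bulk version of [detection_rate()] and [log2fc_vs_rest()] used by the
#' ligand-receptor network: for every (gene, population) pair, the
#' fraction of the population's cells expressing the gene and the log2
#' fold-change of the gene in the population versus all remaining cells
#' (all conditions pooled).
#'
#' @inheritParams log2fc_vs_rest
#' @return List of class `"population_profiles"` with `populations`
#'   (sorted labels), `genes`, `sizes` (cells per population),
#'   `detection` and `log2fc` (genes-by-populations matrices),
#'   `pseudocount` and `fc_scale`.
#' @export
population_profiles <- function(expr, clusters, pseudocount = 1,
                                fc_scale = c("log", "linear")) {
  fc_scale <- match.arg(fc_scale)
  if (length(clusters) != ncol(expr)) {
    stop("clusters must have one label per cell (column of expr)")
  }
  pops <- sort(unique(as.character(clusters)))
  if (length(pops) < 2) stop("at least two populations are required")
  f <- factor(as.character(clusters), levels = pops)
  sizes <- as.integer(table(f))
  ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                              dims = c(length(f), length(pops)))
  vals <- if (fc_scale == "linear") {
    if (inherits(expr, "sparseMatrix")) {
      v <- methods::as(expr, "CsparseMatrix")
      v@x <- expm1(v@x)
      v
    } else expm1(expr)
  } else expr
  pop_sums <- as.matrix(vals %*% ind)
  det <- as.matrix((expr > 0) %*% ind)
  det <- sweep(det, 2, sizes, `/`)
  tot <- Matrix::rowSums(vals)
  mean_in <- sweep(pop_sums, 2, sizes, `/`)
  mean_rest <- sweep(-pop_sums, 1, tot, `+`)
  mean_rest <- sweep(mean_rest, 2, length(f) - sizes, `/`)
  fc <- log2((mean_in + pseudocount) / (mean_rest + pseudocount))
  dimnames(det) <- dimnames(fc) <- list(rownames(expr), pops)
  structure(list(populations = pops,
                 genes = rownames(expr),
                 sizes = stats::setNames(sizes, pops),
                 detection = det,
                 log2fc = fc,
                 pseudocount = pseudocount,
                 fc_scale = fc_scale),
            class = "population_profiles")
}

#' @export
print.population_profiles <- function(x, ...) {
  cat("Population expression profiles\n")
  cat("  populations:", length(x$populations),
      " genes:", length(x$genes), "\n")
  cat("  cells per population:",
      paste(sprintf("%s=%d", x$populations, x$sizes), collapse = ", "), "\n")
  cat("  fold-change scale:", x$fc_scale,
      " pseudocount:", x$pseudocount, "\n")
  invisible(x)
}
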