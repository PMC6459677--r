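#' Validate a ligand-receptor pair map
#'
#' The map is an input table of signaling pairs: one row per
#' (ligand, receptor) gene pair with a protein-association confidence
#' weight in `[0, 1]` (e.g. a STRING combined score rescaled to unit
#' range). The package does not curate or query any database; the map
#' must carry its weights.
#'
#' @param lr_map data.frame with columns `ligand`, `receptor`,
#'   `ppi_weight`.
#' @return The validated map, invisibly.
#' @export
validate_lr_map <- function(lr_map) {
  required <- c("ligand", "receptor", "ppi_weight")
  missing <- setdiff(required, names(lr_map))
  if (length(missing) > 0) {
    stop("ligand-receptor map is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(lr_map) == 0) stop("ligand-receptor map is empty")
  if (anyDuplicated(lr_map[, c("ligand", "receptor")])) {
    stop("duplicate (ligand, receptor) pairs in map")
  }
  if (any(lr_map$ppi_weight < 0 | lr_map$ppi_weight > 1)) {
    stop("ppi_weight values must lie in [0, 1]")
  }
  invisible(lr_map)
}

#' Enumerate candidate source-ligand-receptor-target paths
#'
#' The communication network has four layers: source populations,
#' ligands, receptors, target populations. For every ordered (source,
#' target) population pair and every mapped ligand-receptor pair, a
#' candidate path is emitted when the ligand is expressed in at least
#' `min_detection` of the source's cells and the receptor in at least
#' `min_detection` of the target's cells (boundary inclusive). Each path
#' carries three weights: the ligand's log2 fold-change in the source,
#' the pair's protein-association weight, and the receptor's log2
#' fold-change in the target; the path weight is their raw sum, never
#' rescaled, so that expression provides the greatest weighting.
#'
#' Map rows whose ligand or receptor gene is absent from the expression
#' data are skipped with a warning (gene-symbol mismatches are a data
#' issue, not an error).
#'
#' @param profiles [population_profiles()] of the cohort.
#' @param lr_map ligand-receptor pair map ([validate_lr_map()]).
#' @param min_detection minimum detection rate for a ligand in the source
#'   and a receptor in the target (default 0.10, compared with `>=`).
#' @param include_self also emit autocrine (source == target) paths
#'   (default `TRUE`).
#' @return `data.frame` of paths: `source`, `ligand`, `receptor`,
#'   `target`, `w_source_ligand`, `w_lr`, `w_receptor_target`,
#'   `path_weight`.
#' @export
enumerate_candidate_paths <- function(profiles, lr_map, min_detection = 0.10,
                                      include_self = TRUE) {
  validate_lr_map(lr_map)
  genes <- profiles$genes
  known <- lr_map$ligand %in% genes & lr_map$receptor %in% genes
  if (!all(known)) {
    absent <- unique(c(lr_map$ligand[!lr_map$ligand %in% genes],
                       lr_map$receptor[!lr_map$receptor %in% genes]))
    warning("skipping ", sum(!known), " map pair(s) with gene(s) absent ",
            "from the expression data: ",
            paste(utils::head(absent, 5), collapse = ", "))
    lr_map <- lr_map[known, , drop = FALSE]
  }
  if (nrow(lr_map) == 0) stop("no usable ligand-receptor pairs")
  li <- match(lr_map$ligand, genes)
  ri <- match(lr_map$receptor, genes)
  pops <- profiles$populations
  det_l <- profiles$detection[li, , drop = FALSE] >= min_detection
  det_r <- profiles$detection[ri, , drop = FALSE] >= min_detection
  out <- list()
  for (s in pops) {
    for (tg in pops) {
      if (!include_self && s == tg) next
      sel <- det_l[, s] & det_r[, tg]
      if (!any(sel)) next
      w_sl <- profiles$log2fc[li[sel], s]
      w_lr <- lr_map$ppi_weight[sel]
      w_rt <- profiles$log2fc[ri[sel], tg]
      out[[length(out) + 1L]] <- data.frame(
        source = s, ligand = lr_map$ligand[sel],
        receptor = lr_map$receptor[sel], target = tg,
        w_source_ligand = unname(w_sl), w_lr = w_lr,
        w_receptor_target = unname(w_rt),
        path_weight = unname(w_sl + w_lr + w_rt),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(source = character(), ligand = character(),
                      receptor = character(), target = character(),
                      w_source_ligand = numeric(), w_lr = numeric(),
                      w_receptor_target = numeric(),
                      path_weight = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Filter candidate paths by minimum path weight
#'
#' Removes down-regulated ligand-receptor connections by requiring
#' `path_weight >= min_path_weight` (default 1.5, boundary inclusive).
#'
#' @param paths path table from [enumerate_candidate_paths()].
#' @param min_path_weight minimum retained path weight.
#' @return The retained subset of `paths`.
#' @export
filter_paths <- function(paths, min_path_weight = 1.5) {
  paths[paths$path_weight >= min_path_weight, , drop = FALSE]
}

#' Summed path weight of one source-target connection
#'
#' @param paths path table whose rows all share one (source, target)
#'   population pair.
#' @return Sum of `path_weight` over the rows; 0 for an empty table.
#' @export
summed_weight <- function(paths) {
  if (nrow(paths) == 0) return(0)
  if (length(unique(paths$source)) > 1 || length(unique(paths$target)) > 1) {
    stop("paths mix more than one (source, target) pair")
  }
  sum(paths$path_weight)
}

#' Permutation p-value for one source-target connection
#'
#' Randomized-network null: the ligand-receptor (PPI) edges of the
#' connection's `T` candidate paths are retained, while the `T`
#' source-ligand and `T` receptor-target fold-change edges are re-drawn
#' (with replacement) from the supplied pools. For each of `m` random
#' networks, the re-drawn paths are filtered at `min_path_weight` and
#' summed; the p-value is the fraction of random networks whose summed
#' weight reaches the observed one (ties count, so the p-value of a
#' degenerate null equals 1).
#'
#' Randomness contract: all `m * T` ligand fold-changes are drawn in one
#' `sample()` call, then all `m * T` receptor fold-changes in a second;
#' permutation i occupies row i of the resulting `m`-by-`T` matrices. For
#' very large `m * T` the arithmetic (not the draws) is chunked.
#'
#' @param w_st observed summed filtered path weight.
#' @param lr_weights PPI weights of the connection's `T` candidate
#'   (unfiltered) paths.
#' @param ligand_pool,receptor_pool fold-change pools to resample from.
#' @param m number of random networks.
#' @param min_path_weight filter applied inside each random network.
#' @return Empirical p-value in `{0, 1/m, ..., 1}`; 1 by convention when
#'   `T = 0` (no candidate communication to assess).
#' @export
lrnet_null <- function(w_st, lr_weights, ligand_pool, receptor_pool,
                       m = 100000, min_path_weight = 1.5) {
  T_paths <- length(lr_weights)
  if (T_paths == 0) return(1)
  if (m < 1) stop("m must be >= 1")
  if (length(ligand_pool) == 0 || length(receptor_pool) == 0) {
    stop("fold-change pools must be non-empty")
  }
  lig <- matrix(sample(ligand_pool, m * T_paths, replace = TRUE),
                nrow = m, ncol = T_paths)
  rec <- matrix(sample(receptor_pool, m * T_paths, replace = TRUE),
                nrow = m, ncol = T_paths)
  chunk <- max(1L, as.integer(floor(4e6 / T_paths)))
  hits <- 0L
  start <- 1L
  while (start <= m) {
    end <- min(m, start + chunk - 1L)
    pw <- lig[start:end, , drop = FALSE] + rec[start:end, , drop = FALSE] +
      matrix(lr_weights, nrow = end - start + 1L, ncol = T_paths,
             byrow = TRUE)
    wi <- rowSums(pw * (pw >= min_path_weight))
    hits <- hits + sum(wi >= w_st)
    start <- end + 1L
  }
  hits / m
}

#' Benjamini-Hochberg adjustment of a p-value vector
#'
#' Step-up false-discovery-rate control across the family of tested
#' source-target connections.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, each at least its raw value and at most 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

## Fold-change pools for the randomized-network null: every (population,
## gene) source-side fold-change over genes appearing as ligands in the
## map and detected in that population, pooled across all populations;
## receptor pool analogous.
.lrnet_pools <- function(profiles, lr_map, min_detection) {
  genes <- profiles$genes
  lig_genes <- unique(lr_map$ligand[lr_map$ligand %in% genes])
  rec_genes <- unique(lr_map$receptor[lr_map$receptor %in% genes])
  li <- match(lig_genes, genes)
  ri <- match(rec_genes, genes)
  lig_ok <- profiles$detection[li, , drop = FALSE] >= min_detection
  rec_ok <- profiles$detection[ri, , drop = FALSE] >= min_detection
  list(ligand = profiles$log2fc[li, , drop = FALSE][lig_ok],
       receptor = profiles$log2fc[ri, , drop = FALSE][rec_ok])
}

#' Score all source-target connections of a profiled cohort
#'
#' Core of the communication-network test, operating on precomputed
#' [population_profiles()]: enumerates candidate paths, filters them,
#' sums per-connection weights, assigns each connection a
#' randomized-network p-value ([lrnet_null()]) and applies
#' Benjamini-Hochberg correction across all connections with at least one
#' candidate path. Connections with no candidate path are dropped from
#' testing and from the correction family. Connections are processed in
#' sorted (source, target) order so results are reproducible under a
#' fixed seed.
#'
#' @inheritParams enumerate_candidate_paths
#' @param min_path_weight minimum retained path weight (default 1.5).
#' @param m random networks per connection.
#' @param alpha significance threshold applied to adjusted p-values
#'   (default 0.01).
#' @param seed optional integer seed.
#' @return List of class `"lrnet_result"`: `results` (one row per tested
#'   connection: `source`, `target`, `n_candidate`, `n_filtered`, `w_st`,
#'   `p_w`, `p_adj`, `significant`), `paths` (the filtered path table)
#'   and `params`.
#' @export
lrnet_score <- function(profiles, lr_map, min_detection = 0.10,
                        min_path_weight = 1.5, m = 100000, alpha = 0.01,
                        include_self = TRUE, seed = NULL) {
  cand <- enumerate_candidate_paths(profiles, lr_map,
                                    min_detection = min_detection,
                                    include_self = include_self)
  if (nrow(cand) == 0) stop("no candidate paths in any connection")
  kept <- filter_paths(cand, min_path_weight)
  pools <- .lrnet_pools(profiles, lr_map, min_detection)
  key <- paste(cand$source, cand$target, sep = "\r")
  pair_keys <- sort(unique(key))
  if (!is.null(seed)) set.seed(seed)
  res <- vector("list", length(pair_keys))
  for (i in seq_along(pair_keys)) {
    pk <- pair_keys[i]
    sel <- key == pk
    st <- strsplit(pk, "\r", fixed = TRUE)[[1]]
    sub_kept <- kept[paste(kept$source, kept$target, sep = "\r") == pk, ,
                     drop = FALSE]
    w_st <- if (nrow(sub_kept) == 0) 0 else sum(sub_kept$path_weight)
    p_w <- lrnet_null(w_st, cand$w_lr[sel], pools$ligand, pools$receptor,
                      m = m, min_path_weight = min_path_weight)
    res[[i]] <- data.frame(source = st[1], target = st[2],
                           n_candidate = sum(sel),
                           n_filtered = nrow(sub_kept),
                           w_st = w_st, p_w = p_w,
                           stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  results$p_adj <- bh_adjust(results$p_w)
  results$significant <- results$p_adj < alpha
  structure(list(results = results, paths = kept,
                 params = list(min_detection = min_detection,
                               min_path_weight = min_path_weight,
                               m = m, alpha = alpha,
                               include_self = include_self, seed = seed,
                               fc_scale = profiles$fc_scale,
                               pseudocount = profiles$pseudocount)),
            class = "lrnet_result")
}

#' Ligand-receptor communication network test
#'
#' Full pipeline from a raw count matrix: counts-per-ten-thousand log
#' normalization, per-population detection rates and fold-changes versus
#' the remaining populations (all conditions pooled), four-layer path
#' enumeration with the detection filter, path-weight filtering,
#' per-connection summed weights, randomized-network empirical p-values
#' and Benjamini-Hochberg correction.
#'
#' @param counts genes-by-cells raw UMI count matrix with gene row names
#'   and cell column names.
#' @param annotations cell annotation table ([cell_annotations()]); its
#'   `cell_id` order must match the matrix columns.
#' @param lr_map ligand-receptor pair map ([validate_lr_map()]).
#' @inheritParams lrnet_score
#' @inheritParams population_profiles
#' @param normalized set `TRUE` when `counts` already holds
#'   counts-per-ten-thousand log-normalized values.
#' @return See [lrnet_score()].
#' @examples
#' set.seed(1)
#' sim <- generate_dataset(synthetic_design(n_genes = 120, n_decoy_pairs = 10,
#'                                          cells_per_condition = 400))
#' net <- lrnet_test(sim$counts, sim$annotations, sim$lr_map,
#'                   m = 200, seed = 1)
#' head(net$results)
#' @export
lrnet_test <- function(counts, annotations, lr_map, min_detection = 0.10,
                       min_path_weight = 1.5, m = 100000, alpha = 0.01,
                       include_self = TRUE, pseudocount = 1,
                       fc_scale = c("log", "linear"), normalized = FALSE,
                       seed = NULL) {
  validate_annotations(annotations)
  if (ncol(counts) != nrow(annotations)) {
    stop("matrix has ", ncol(counts), " cells but annotations have ",
         nrow(annotations), " rows")
  }
  if (!is.null(colnames(counts)) &&
      !identical(colnames(counts), annotations$cell_id)) {
    if (!setequal(colnames(counts), annotations$cell_id)) {
      stop("matrix cell ids do not match annotation cell ids")
    }
    counts <- counts[, annotations$cell_id, drop = FALSE]
  }
  norm <- if (normalized) counts else normalize_cptt(counts)
  profiles <- population_profiles(norm, annotations$cluster,
                                  pseudocount = pseudocount,
                                  fc_scale = fc_scale)
  lrnet_score(profiles, lr_map, min_detection = min_detection,
              min_path_weight = min_path_weight, m = m, alpha = alpha,
              include_self = include_self, seed = seed)
}

#' @export
print.lrnet_result <- function(x, ...) {
  cat("Ligand-receptor communication network\n")
  cat("  tested connections:", nrow(x$results),
      " significant (p_adj <", x$params$alpha, "):",
      sum(x$results$significant), "\n")
  cat("  filtered paths:", nrow(x$paths),
      " (min path weight ", x$params$min_path_weight, ")\n", sep = "")
  invisible(x)
}

#' Export a communication network as edge-list files
#'
#' Writes two tab-separated files importable by generic graph tools
#' (e.g. Cytoscape): `<prefix>.edges.tsv` with one row per source-target
#' connection (`source`, `target`, `n_candidate`, `n_filtered`, `w_st`,
#' `p_w`, `p_adj`, `significant`) and `<prefix>.paths.tsv` with the full
#' four-layer paths and their three edge weights. Floats are written with
#' 17 significant digits so re-reading reproduces them bit-exactly.
#'
#' @param net [lrnet_test()] / [lrnet_score()] result.
#' @param out_prefix output path prefix.
#' @param significant_only restrict both files to significant connections.
#' @return Invisibly, the two file paths.
#' @export
export_network <- function(net, out_prefix, significant_only = FALSE) {
  results <- net$results
  paths <- net$paths
  if (significant_only) {
    results <- results[results$significant, , drop = FALSE]
    keep <- paste(paths$source, paths$target) %in%
      paste(results$source, results$target)
    paths <- paths[keep, , drop = FALSE]
  }
  edge_file <- paste0(out_prefix, ".edges.tsv")
  path_file <- paste0(out_prefix, ".paths.tsv")
  write_tsv(results, edge_file)
  write_tsv(paths, path_file)
  invisible(c(edges = edge_file, paths = path_file))
}
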