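#' Partially relabel a cohort's cluster assignments
#'
#' One step of the differential-proportion-analysis null: `round(w * n)`
#' cells are selected uniformly at random and their cluster labels are
#' replaced by a random sub-sample (without replacement) of the pooled
#' cluster labels of all `n` cells. Condition labels and the number of
#' cells are untouched. Selected cells may receive their own original
#' label back, since the pooled draw ranges over all `n` labels.
#'
#' Randomness contract: exactly two draws from the current RNG stream per
#' call, in order `sample.int(n, k)` for the selected cells and
#' `sample.int(n, k)` for the positions of the replacement labels. The
#' fast null builder ([dpa_null()]) consumes the stream identically, one
#' call pair per permutation, so a fixed seed makes the two routes
#' comparable permutation by permutation.
#'
#' @inheritParams validate_annotations
#' @param w fraction of cells to relabel, in `[0, 1]`. The count of
#'   relabeled cells is `round(w * n)` (round-half-to-even).
#' @return Annotation table of identical shape with some cluster labels
#'   replaced.
#' @export
permute_labels <- function(annotations, w) {
  validate_annotations(annotations)
  if (!is.numeric(w) || length(w) != 1 || w < 0 || w > 1) {
    stop("w must be a single number in [0, 1]")
  }
  n <- nrow(annotations)
  k <- as.integer(round(w * n))
  sel <- sample.int(n, k)
  pool <- sample.int(n, k)
  out <- annotations
  out$cluster[sel] <- annotations$cluster[pool]
  out
}

## Internal permutation engine on integer-coded labels.
## clus: integer cluster codes in 1..J for all n cells (the label pool);
## mask1/mask2: logical membership of the two compared conditions.
## Returns a t x J matrix of null delta-p vectors. Counts are updated
## incrementally (only relabeled cells can change a tally), which keeps
## each permutation O(k) rather than O(n).
.dpa_null_core <- function(clus, mask1, mask2, J, w, t) {
  n <- length(clus)
  n1 <- sum(mask1)
  n2 <- sum(mask2)
  k <- as.integer(round(w * n))
  base1 <- tabulate(clus[mask1], J)
  base2 <- tabulate(clus[mask2], J)
  out <- matrix(0, nrow = t, ncol = J)
  for (i in seq_len(t)) {
    sel <- sample.int(n, k)
    pool <- sample.int(n, k)
    old <- clus[sel]
    new <- clus[pool]
    s1 <- mask1[sel]
    s2 <- mask2[sel]
    c1 <- base1 - tabulate(old[s1], J) + tabulate(new[s1], J)
    c2 <- base2 - tabulate(old[s2], J) + tabulate(new[s2], J)
    out[i, ] <- c1 / n1 - c2 / n2
  }
  out
}

## Encode an annotation table for the permutation engine. Cluster order is
## the lexicographic sort of labels across the whole cohort (all cells take
## part in the label pool, including cells from conditions other than the
## two compared).
.dpa_encode <- function(annotations, cond1, cond2) {
  validate_annotations(annotations)
  conds <- unique(annotations$condition)
  for (cond in c(cond1, cond2)) {
    if (!cond %in% conds) stop("unknown condition label: ", cond)
  }
  clusters <- sort(unique(annotations$cluster))
  list(clus = match(annotations$cluster, clusters),
       mask1 = annotations$condition == cond1,
       mask2 = annotations$condition == cond2,
       clusters = clusters)
}

#' Null distribution of the proportion-difference statistic
#'
#' Repeats the partial relabeling of [permute_labels()] `t` times; after
#' each relabeling the cluster proportions of the two conditions are
#' recomputed and their difference recorded. The resulting matrix is the
#' permutation null of the per-cluster statistic. Condition labels are
#' never permuted, so no permutation can empty a condition.
#'
#' @inheritParams permute_labels
#' @param cond1,cond2 the two condition labels being compared.
#' @param t number of permutations.
#' @param seed optional integer seed; when supplied, `set.seed(seed)` is
#'   called before the first permutation.
#' @return Numeric matrix with `t` rows and one column per cluster
#'   (lexicographic cluster order, as column names).
#' @export
dpa_null <- function(annotations, cond1, cond2, w = 0.1, t = 1000,
                     seed = NULL) {
  if (!is.numeric(w) || length(w) != 1 || w < 0 || w > 1) {
    stop("w must be a single number in [0, 1]")
  }
  if (t < 1) stop("t must be >= 1")
  enc <- .dpa_encode(annotations, cond1, cond2)
  if (!is.null(seed)) set.seed(seed)
  null <- .dpa_null_core(enc$clus, enc$mask1, enc$mask2,
                         length(enc$clusters), w, as.integer(t))
  colnames(null) <- enc$clusters
  null
}

## p-values from an observed delta vector and a null matrix; ties count in
## both tails, so p_increase + p_decrease >= 1 always.
.dpa_pvalues <- function(obs, null) {
  t <- nrow(null)
  obs_mat <- matrix(obs, nrow = t, ncol = length(obs), byrow = TRUE)
  p_inc <- colSums(null >= obs_mat) / t
  p_dec <- colSums(null <= obs_mat) / t
  list(p_increase = p_inc, p_decrease = p_dec, p = pmin(p_inc, p_dec))
}

#' Differential proportion analysis (DPA)
#'
#' Permutation test for whether each cluster's share of cells differs
#' between two conditions more than expected under partial random
#' relabeling of cluster assignments. The statistic per cluster is the
#' observed proportion difference; its null distribution is obtained by
#' relabeling a fraction `w` of all cells `t` times ([dpa_null()]).
#' Empirical one-sided p-values are the fractions of null statistics at
#' least as extreme as the observed one (ties counted in both tails):
#' `p_increase` for exceedances upward, `p_decrease` downward; the final
#' p-value is their minimum. No smoothing is applied, so `p = 0` is
#' possible and means "below 1/t".
#'
#' `w` is the key tuning parameter: smaller values give a stricter test
#' (fewer significant clusters), larger values a more permissive one. The
#' working default is `w = 0.1`. No multiple-testing correction is applied
#' across clusters; callers typically use a conservative fixed cutoff such
#' as 0.01.
#'
#' @inheritParams dpa_null
#' @return A `data.frame` with one row per cluster: `cluster`, per-condition
#'   cell counts (`n_cond1`, `n_cond2`) and proportions (`p_cond1`,
#'   `p_cond2`), `delta_p`, `p_increase`, `p_decrease`, `p_final`, and
#'   logical `below_resolution` flagging clusters where no null value
#'   reached the observed statistic (p reported as 0, i.e. < 1/t). The
#'   test configuration is attached as attribute `"params"`.
#' @examples
#' ann <- cell_annotations(
#'   paste0("c", 1:40),
#'   rep(c("sham", "MI"), each = 20),
#'   c(rep("F1", 14), rep("F2", 6), rep("F1", 6), rep("F2", 14)))
#' dpa_test(ann, "sham", "MI", w = 0.1, t = 200, seed = 1)
#' @export
dpa_test <- function(annotations, cond1, cond2, w = 0.1, t = 1000,
                     seed = NULL) {
  if (t < 1) stop("t must be >= 1")
  enc <- .dpa_encode(annotations, cond1, cond2)
  J <- length(enc$clusters)
  n1 <- sum(enc$mask1)
  n2 <- sum(enc$mask2)
  c1 <- tabulate(enc$clus[enc$mask1], J)
  c2 <- tabulate(enc$clus[enc$mask2], J)
  obs <- c1 / n1 - c2 / n2
  if (!is.null(seed)) set.seed(seed)
  null <- .dpa_null_core(enc$clus, enc$mask1, enc$mask2, J, w,
                         as.integer(t))
  pv <- .dpa_pvalues(obs, null)
  res <- data.frame(cluster = enc$clusters,
                    n_cond1 = c1, n_cond2 = c2,
                    p_cond1 = c1 / n1, p_cond2 = c2 / n2,
                    delta_p = obs,
                    p_increase = pv$p_increase,
                    p_decrease = pv$p_decrease,
                    p_final = pv$p,
                    below_resolution = pv$p == 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "params") <- list(cond1 = cond1, cond2 = cond2, w = w, t = t,
                              seed = seed, n_total = length(enc$clus))
  res
}
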