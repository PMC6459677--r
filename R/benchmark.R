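#' Default cell-type proportions for the simulation benchmarks
#'
#' Ten populations spanning abundant (30%) to rare (1%), the composition
#' used by the packaged simulation experiments.
#'
#' @return Numeric vector of length 10 summing to 1.
#' @export
default_base_proportions <- function() {
  c(0.30, 0.20, 0.15, 0.10, 0.08, 0.06, 0.05, 0.03, 0.02, 0.01)
}

#' Default truly-changed populations and their fold changes
#'
#' The control-vs-condition simulation plants proportion changes in six of
#' the ten populations and leaves four untouched. Effects are chosen by a
#' power rule (see the methods vignette): after renormalization and under
#' the worst-case +/-20% error-rate perturbation, every planted shift must
#' clear the permutation-null detection threshold of DPA (the stricter of
#' the two benchmarked tests) with a wide margin, so that a sensitivity of
#' 1 is the expected outcome for both tests at all benchmarked error rates.
#' Decreases sit on abundant populations (a proportion cannot fall below
#' zero, which bounds the attainable effect on rare ones); increases on
#' rare populations use large factors for the same reason.
#'
#' @return List with integer `populations` (indices into the base
#'   proportion vector) and numeric `factors` (multiplicative, applied
#'   before renormalization).
#' @export
default_changed_populations <- function() {
  list(populations = c(2L, 4L, 5L, 7L, 8L, 9L),
       factors = c(0.05, 0.05, 0.05, 5.0, 6.0, 8.0))
}

#' Apply multiplicative changes to a proportion vector
#'
#' @param p proportion vector summing to 1.
#' @param populations indices of the changed entries.
#' @param factors positive multiplicative factors, one per changed entry.
#' @return Renormalized proportion vector (sums to 1).
#' @export
apply_change_factors <- function(p, populations, factors) {
  if (length(populations) != length(factors)) {
    stop("populations and factors must have equal length")
  }
  if (any(factors <= 0)) stop("change factors must be > 0")
  q <- p
  q[populations] <- q[populations] * factors
  q / sum(q)
}

#' Randomly perturb a proportion vector by a relative error rate
#'
#' Emulates run-to-run compositional noise: each proportion is
#' independently multiplied by `(1 + e)` or `(1 - e)` with probability 1/2
#' and the vector is renormalized to sum to 1.
#'
#' @param p proportion vector summing to 1.
#' @param e relative error rate, `0 <= e < 1` (values >= 1 could produce
#'   non-positive proportions and are rejected).
#' @return Perturbed proportion vector summing to 1.
#' @export
perturb_proportions <- function(p, e) {
  if (e < 0) stop("error rate e must be >= 0")
  if (e >= 1) stop("error rate e must be < 1")
  if (e == 0) return(p)
  signs <- ifelse(stats::runif(length(p)) < 0.5, 1, -1)
  q <- p * (1 + signs * e)
  q / sum(q)
}

## Draw a two-condition cohort as integer cluster codes. Returns the code
## vector (condition 1 cells first), the two condition masks, and the
## per-condition count matrix.
.draw_cohort <- function(props1, props2, n1, n2) {
  J <- length(props1)
  c1 <- as.integer(stats::rmultinom(1, n1, props1))
  c2 <- as.integer(stats::rmultinom(1, n2, props2))
  clus <- c(rep.int(seq_len(J), c1), rep.int(seq_len(J), c2))
  mask1 <- c(rep(TRUE, n1), rep(FALSE, n2))
  list(clus = clus, mask1 = mask1, mask2 = !mask1,
       counts = cbind(c1, c2))
}

.codes_to_annotations <- function(drawn, cond_names, cluster_names) {
  n <- length(drawn$clus)
  data.frame(cell_id = sprintf("cell%06d", seq_len(n)),
             condition = ifelse(drawn$mask1, cond_names[1], cond_names[2]),
             cluster = cluster_names[drawn$clus],
             stringsAsFactors = FALSE)
}

#' Simulate two replicate experiments with no true composition change
#'
#' Both conditions are multinomial draws from the same base composition,
#' each arm first distorted by an independent error-rate perturbation
#' ([perturb_proportions()]). Ground truth: no population changed.
#'
#' @param base_proportions population proportions shared by both arms.
#' @param e relative error rate applied independently to each arm.
#' @param n1,n2 cells drawn for the two replicates.
#' @param cond_names labels for the two conditions.
#' @param seed optional integer seed.
#' @return Annotation `data.frame` (see [cell_annotations()]) with
#'   populations labelled `"pop01"`, `"pop02"`, ...
#' @export
simulate_replicate_pair <- function(base_proportions = default_base_proportions(),
                                    e = 0, n1 = 5000, n2 = 3000,
                                    cond_names = c("rep1", "rep2"),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p1 <- perturb_proportions(base_proportions, e)
  p2 <- perturb_proportions(base_proportions, e)
  drawn <- .draw_cohort(p1, p2, n1, n2)
  .codes_to_annotations(drawn, cond_names,
                        sprintf("pop%02d", seq_along(base_proportions)))
}

#' Simulate a control-vs-condition experiment with planted changes
#'
#' The control arm is drawn from the base composition; the condition arm
#' from the base with multiplicative factors applied to the changed
#' populations and renormalized. Both arms are then distorted by
#' independent error-rate perturbations (the noise is applied after the
#' true changes). "Changed" is defined by generative intent: the
#' populations whose pre-normalization proportions were deliberately
#' multiplied are positives, the remainder negatives, even though
#' renormalization shifts the latter slightly.
#'
#' @inheritParams simulate_replicate_pair
#' @param changed_populations,change_factors indices and multiplicative
#'   factors of the truly changed populations (defaults from
#'   [default_changed_populations()]).
#' @param n1,n2 cells drawn for control and condition.
#' @return List with `annotations` (control condition first) and logical
#'   `truth` marking the changed populations.
#' @export
simulate_control_condition <- function(base_proportions = default_base_proportions(),
                                       changed_populations = default_changed_populations()$populations,
                                       change_factors = default_changed_populations()$factors,
                                       e = 0, n1 = 4000, n2 = 6000,
                                       cond_names = c("control", "condition"),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cond_base <- apply_change_factors(base_proportions, changed_populations,
                                    change_factors)
  p1 <- perturb_proportions(base_proportions, e)
  p2 <- perturb_proportions(cond_base, e)
  drawn <- .draw_cohort(p1, p2, n1, n2)
  truth <- seq_along(base_proportions) %in% changed_populations
  list(annotations = .codes_to_annotations(
         drawn, cond_names, sprintf("pop%02d", seq_along(base_proportions))),
       truth = truth)
}

#' Per-cluster two-sided Fisher's exact tests
#'
#' For every cluster j, tests the 2x2 table of (cells in j, cells not in
#' j) by condition.
#'
#' @param counts clusters-by-conditions count matrix
#'   ([build_count_table()]).
#' @param cond1,cond2 condition labels (columns of `counts`).
#' @return Named numeric vector of two-sided p-values over clusters.
#' @export
fisher_per_cluster <- function(counts, cond1, cond2) {
  for (cond in c(cond1, cond2)) {
    if (!cond %in% colnames(counts)) stop("unknown condition label: ", cond)
  }
  x1 <- counts[, cond1]
  x2 <- counts[, cond2]
  n1 <- sum(x1)
  n2 <- sum(x2)
  if (n1 == 0 || n2 == 0) stop("condition with zero cells")
  p <- vapply(seq_along(x1), function(j) {
    stats::fisher.test(matrix(c(x1[j], n1 - x1[j], x2[j], n2 - x2[j]),
                              nrow = 2, byrow = TRUE))$p.value
  }, numeric(1))
  names(p) <- rownames(counts)
  p
}

#' Classification metrics of significance calls against ground truth
#'
#' @param calls logical vector of significance calls.
#' @param truth logical vector of true changes, same length.
#' @return Named numeric vector `sensitivity` (TP/(TP+FN); `NA` when there
#'   are no positives), `specificity` (TN/(TN+FP); `NA` when there are no
#'   negatives) and `precision` (TP/(TP+FP); 1 by convention when nothing
#'   is called).
#' @export
benchmark_metrics <- function(calls, truth) {
  if (length(calls) != length(truth)) {
    stop("calls and truth must have equal length")
  }
  calls <- as.logical(calls)
  truth <- as.logical(truth)
  tp <- sum(calls & truth)
  fp <- sum(calls & !truth)
  fn <- sum(!calls & truth)
  tn <- sum(!calls & !truth)
  c(sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    precision = if (tp + fp == 0) 1 else tp / (tp + fp))
}

#' Simulation benchmark of DPA against per-cluster Fisher's exact tests
#'
#' Runs one of the two packaged simulation designs over a grid of error
#' rates. `"replicate"`: two draws from one composition, no true changes
#' (5000 and 3000 cells by default) -- only specificity and precision are
#' meaningful. `"condition"`: control vs condition with six truly changed
#' populations (4000 and 6000 cells by default) -- sensitivity,
#' specificity and precision are all evaluated. For each repetition both
#' tests are run on the same simulated cohort and called at `alpha`;
#' metrics are averaged over repetitions.
#'
#' @param design `"replicate"` or `"condition"`.
#' @param base_proportions population composition of the base system.
#' @param changed_populations,change_factors planted changes (condition
#'   design only).
#' @param error_rates error rates to sweep.
#' @param reps repetitions per error rate.
#' @param n1,n2 cells per arm; defaults depend on the design (5000/3000
#'   for replicate, 4000/6000 for condition).
#' @param w,t DPA relabeling fraction and permutation count per simulated
#'   test.
#' @param alpha decision threshold applied to both tests' raw p-values.
#' @param seed optional integer seed for the whole sweep.
#' @return Tidy `data.frame`: `design`, `error_rate`, `method`,
#'   `sensitivity`, `specificity`, `precision` (means over repetitions).
#' @export
run_benchmark <- function(design = c("condition", "replicate"),
                          base_proportions = default_base_proportions(),
                          changed_populations = default_changed_populations()$populations,
                          change_factors = default_changed_populations()$factors,
                          error_rates = c(0.01, 0.05, 0.1, 0.15, 0.2),
                          reps = 100, n1 = NULL, n2 = NULL,
                          w = 0.1, t = 1000, alpha = 0.05, seed = NULL) {
  design <- match.arg(design)
  if (reps < 1) stop("reps must be >= 1")
  if (is.null(n1)) n1 <- if (design == "replicate") 5000 else 4000
  if (is.null(n2)) n2 <- if (design == "replicate") 3000 else 6000
  if (!is.null(seed)) set.seed(seed)
  J <- length(base_proportions)
  if (design == "condition") {
    cond_base <- apply_change_factors(base_proportions, changed_populations,
                                      change_factors)
    truth <- seq_len(J) %in% changed_populations
  } else {
    cond_base <- base_proportions
    truth <- rep(FALSE, J)
  }
  rows <- vector("list", length(error_rates))
  for (ei in seq_along(error_rates)) {
    e <- error_rates[ei]
    acc <- matrix(0, nrow = 2, ncol = 3,
                  dimnames = list(c("DPA", "Fisher"),
                                  c("sensitivity", "specificity", "precision")))
    cnt <- matrix(0L, nrow = 2, ncol = 3)
    for (r in seq_len(reps)) {
      p1 <- perturb_proportions(base_proportions, e)
      p2 <- perturb_proportions(cond_base, e)
      drawn <- .draw_cohort(p1, p2, n1, n2)
      obs <- drawn$counts[, 1] / n1 - drawn$counts[, 2] / n2
      null <- .dpa_null_core(drawn$clus, drawn$mask1, drawn$mask2, J, w, t)
      p_dpa <- .dpa_pvalues(obs, null)$p
      counts <- drawn$counts
      dimnames(counts) <- list(sprintf("pop%02d", seq_len(J)), c("c1", "c2"))
      p_fisher <- fisher_per_cluster(counts, "c1", "c2")
      for (mi in 1:2) {
        calls <- (if (mi == 1) p_dpa else p_fisher) < alpha
        m <- benchmark_metrics(calls, truth)
        ok <- !is.na(m)
        acc[mi, ok] <- acc[mi, ok] + m[ok]
        cnt[mi, ok] <- cnt[mi, ok] + 1L
      }
    }
    means <- acc / ifelse(cnt == 0, NA, cnt)
    rows[[ei]] <- data.frame(design = design, error_rate = e,
                             method = rownames(acc),
                             sensitivity = means[, 1],
                             specificity = means[, 2],
                             precision = means[, 3],
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, rows)
}
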