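#' Describe a synthetic single-cell cohort with planted ground truth
#'
#' The generator emulates the statistical structure the package's two
#' tests assume: multinomially sampled cluster memberships per condition
#' (with optional planted proportion changes for the proportion test) and
#' overdispersed negative-binomial expression with planted ligand and
#' receptor up-regulation defining known communication channels. It makes
#' no attempt to emulate doublets, ambient RNA, batch effects or QC
#' artifacts.
#'
#' Genes are assigned roles deterministically from the front of the gene
#' list: each planted channel takes `n_pairs` ligand genes then `n_pairs`
#' receptor genes, decoy pairs take two fresh genes each (so no gene is
#' shared between paths), and the remainder are background. Ligand and
#' receptor map genes share a common baseline mean so the detection
#' filter treats planted and decoy pairs alike.
#'
#' @param n_populations number of cell populations (labelled `"P1"`,
#'   `"P2"`, ...).
#' @param base_proportions population composition (defaults uniform).
#' @param cells_per_condition cells drawn per condition; a named vector
#'   defines the condition labels (default `control` and `condition`,
#'   1400 cells each).
#' @param changed_populations,change_factors optional planted proportion
#'   changes in the non-first condition (indices into the population
#'   list; factors applied before renormalization).
#' @param n_genes total genes.
#' @param lr_gene_mean baseline negative-binomial mean of ligand/receptor
#'   map genes (chosen so such genes pass a 10% detection filter in
#'   unperturbed populations).
#' @param bg_mean_meanlog,bg_mean_sdlog log-normal hyper-parameters of
#'   background gene means.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion);
#'   the default 0.5 gives the overdispersion typical of UMI counts.
#' @param channels list of planted communication channels, each a list
#'   with `source`, `target` (population labels), `n_pairs`,
#'   `ligand_effect`, `receptor_effect` (log2 mean shifts) and
#'   `ppi_weight`.
#' @param n_decoy_pairs ligand-receptor map pairs among non-planted genes
#'   (default 5x the planted count so the correction family is
#'   non-trivial); decoy association weights are uniform on `[0, 1]`.
#' @return List of class `"synthetic_design"`.
#' @export
synthetic_design <- function(n_populations = 4,
                             base_proportions = NULL,
                             cells_per_condition = c(control = 1400,
                                                     condition = 1400),
                             changed_populations = integer(0),
                             change_factors = numeric(0),
                             n_genes = 300,
                             lr_gene_mean = 0.5,
                             bg_mean_meanlog = log(0.3),
                             bg_mean_sdlog = 1,
                             dispersion = 0.5,
                             channels = list(list(source = "P1",
                                                  target = "P2",
                                                  n_pairs = 10,
                                                  ligand_effect = 2.0,
                                                  receptor_effect = 2.0,
                                                  ppi_weight = 0.9)),
                             n_decoy_pairs = 50) {
  if (is.null(base_proportions)) {
    base_proportions <- rep(1 / n_populations, n_populations)
  }
  if (length(base_proportions) != n_populations) {
    stop("base_proportions must have one entry per population")
  }
  if (abs(sum(base_proportions) - 1) > 1e-9) {
    stop("base_proportions must sum to 1")
  }
  if (n_populations < 1 || any(cells_per_condition < 1) || n_genes < 1) {
    stop("degenerate design: need at least one population, cell and gene")
  }
  if (length(changed_populations) != length(change_factors)) {
    stop("changed_populations and change_factors must have equal length")
  }
  if (is.null(names(cells_per_condition))) {
    names(cells_per_condition) <- paste0("cond", seq_along(cells_per_condition))
  }
  pops <- paste0("P", seq_len(n_populations))
  n_planted <- 0L
  for (ch in channels) {
    if (!all(c(ch$source, ch$target) %in% pops)) {
      stop("channel source/target must be population labels: ",
           paste(pops, collapse = ", "))
    }
    if (ch$n_pairs < 1) stop("each planted channel needs n_pairs >= 1")
    n_planted <- n_planted + as.integer(ch$n_pairs)
  }
  if (2L * n_planted + 2L * n_decoy_pairs > n_genes) {
    stop("n_genes too small for the requested map (need at least ",
         2L * n_planted + 2L * n_decoy_pairs, ")")
  }
  structure(list(n_populations = n_populations,
                 populations = pops,
                 base_proportions = base_proportions,
                 cells_per_condition = cells_per_condition,
                 changed_populations = as.integer(changed_populations),
                 change_factors = change_factors,
                 n_genes = as.integer(n_genes),
                 lr_gene_mean = lr_gene_mean,
                 bg_mean_meanlog = bg_mean_meanlog,
                 bg_mean_sdlog = bg_mean_sdlog,
                 dispersion = dispersion,
                 channels = channels,
                 n_decoy_pairs = as.integer(n_decoy_pairs)),
            class = "synthetic_design")
}

#' Generate a synthetic cohort from a design
#'
#' Draws per-condition population memberships from a multinomial (with
#' any planted proportion changes applied, renormalized, to the second
#' and later conditions), assigns gene roles, and draws UMI counts per
#' cell from negative binomials whose means are multiplied by
#' `2^effect` for planted ligand genes in their source population and
#' receptor genes in their target population. The returned truth record
#' lists the planted channels (per ligand-receptor pair) and the true
#' per-condition compositions.
#'
#' @param design a [synthetic_design()].
#' @param seed optional integer seed; a fixed seed makes the whole output
#'   bit-identical across runs.
#' @return List: `counts` (genes-by-cells integer matrix), `annotations`
#'   (cell annotation table), `lr_map` (planted pairs first, then
#'   decoys), `truth` (list with `channels` table, `changed_populations`,
#'   `proportions` per condition), and the `design`.
#' @export
generate_dataset <- function(design, seed = NULL) {
  if (!inherits(design, "synthetic_design")) {
    stop("design must be a synthetic_design object")
  }
  if (!is.null(seed)) set.seed(seed)
  pops <- design$populations
  J <- design$n_populations
  conds <- names(design$cells_per_condition)
  genes <- sprintf("g%04d", seq_len(design$n_genes))

  ## per-condition compositions: planted changes hit every condition
  ## after the first (the first is the reference arm)
  props <- list()
  props[[conds[1]]] <- design$base_proportions
  altered <- if (length(design$changed_populations) > 0) {
    apply_change_factors(design$base_proportions,
                         design$changed_populations, design$change_factors)
  } else design$base_proportions
  for (cond in conds[-1]) props[[cond]] <- altered

  ## gene roles and the ligand-receptor map
  next_gene <- 1L
  take <- function(k) {
    idx <- next_gene:(next_gene + k - 1L)
    next_gene <<- next_gene + k
    idx
  }
  channel_rows <- list()
  for (ci in seq_along(design$channels)) {
    ch <- design$channels[[ci]]
    li <- take(ch$n_pairs)
    ri <- take(ch$n_pairs)
    channel_rows[[ci]] <- data.frame(
      channel = ci, source = ch$source, target = ch$target,
      ligand = genes[li], receptor = genes[ri],
      ligand_effect = ch$ligand_effect,
      receptor_effect = ch$receptor_effect,
      ppi_weight = ch$ppi_weight, stringsAsFactors = FALSE)
  }
  channels <- if (length(channel_rows) > 0) do.call(rbind, channel_rows) else
    data.frame(channel = integer(), source = character(),
               target = character(), ligand = character(),
               receptor = character(), ligand_effect = numeric(),
               receptor_effect = numeric(), ppi_weight = numeric(),
               stringsAsFactors = FALSE)
  decoy_lig <- genes[take(design$n_decoy_pairs)]
  decoy_rec <- genes[take(design$n_decoy_pairs)]
  lr_map <- rbind(
    data.frame(ligand = channels$ligand, receptor = channels$receptor,
               ppi_weight = channels$ppi_weight, stringsAsFactors = FALSE),
    data.frame(ligand = decoy_lig, receptor = decoy_rec,
               ppi_weight = stats::runif(design$n_decoy_pairs),
               stringsAsFactors = FALSE))

  ## baseline gene means: map genes share a fixed mean, background genes
  ## draw from a log-normal
  mu <- numeric(design$n_genes)
  n_map_genes <- next_gene - 1L
  mu[seq_len(n_map_genes)] <- design$lr_gene_mean
  if (next_gene <= design$n_genes) {
    mu[next_gene:design$n_genes] <- stats::rlnorm(
      design$n_genes - n_map_genes,
      meanlog = design$bg_mean_meanlog, sdlog = design$bg_mean_sdlog)
  }

  ## population-specific mean multipliers from the planted channels
  mult <- matrix(1, nrow = design$n_genes, ncol = J,
                 dimnames = list(genes, pops))
  for (i in seq_len(nrow(channels))) {
    mult[channels$ligand[i], channels$source[i]] <-
      mult[channels$ligand[i], channels$source[i]] *
      2^channels$ligand_effect[i]
    mult[channels$receptor[i], channels$target[i]] <-
      mult[channels$receptor[i], channels$target[i]] *
      2^channels$receptor_effect[i]
  }

  ## cluster memberships, then counts, drawn condition by condition and
  ## population by population (fixed order => reproducible under seed)
  size <- 1 / design$dispersion
  ann_cond <- character(0)
  ann_clus <- character(0)
  blocks <- list()
  for (cond in conds) {
    ncells <- design$cells_per_condition[[cond]]
    tally <- as.integer(stats::rmultinom(1, ncells, props[[cond]]))
    ann_cond <- c(ann_cond, rep(cond, ncells))
    ann_clus <- c(ann_clus, rep.int(pops, tally))
    for (j in seq_len(J)) {
      if (tally[j] == 0) next
      mu_j <- mu * mult[, j]
      blocks[[length(blocks) + 1L]] <-
        matrix(stats::rnbinom(design$n_genes * tally[j], mu = mu_j,
                              size = size),
               nrow = design$n_genes, ncol = tally[j])
    }
  }
  counts <- do.call(cbind, blocks)
  cell_ids <- sprintf("cell%06d", seq_len(ncol(counts)))
  dimnames(counts) <- list(genes, cell_ids)
  annotations <- data.frame(cell_id = cell_ids, condition = ann_cond,
                            cluster = ann_clus, stringsAsFactors = FALSE)
  list(counts = counts,
       annotations = annotations,
       lr_map = lr_map,
       truth = list(channels = channels,
                    changed_populations = design$changed_populations,
                    proportions = props),
       design = design)
}
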