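test_that("generated datasets have consistent shapes and bookkeeping", {
  design <- small_design()
  sim <- generate_dataset(design, seed = 61)
  n_cells <- as.integer(sum(design$cells_per_condition))
  expect_identical(dim(sim$counts), c(150L, n_cells))
  expect_identical(nrow(sim$annotations), n_cells)
  expect_identical(sim$annotations$cell_id, colnames(sim$counts))
  expect_identical(nrow(sim$lr_map), 10L + 20L)  # planted + decoys
  expect_identical(nrow(sim$truth$channels), 10L)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_identical(sort(unique(sim$annotations$condition)),
                   c("condition", "control"))
  # no gene serves two roles in the map
  genes_used <- c(sim$lr_map$ligand, sim$lr_map$receptor)
  expect_false(anyDuplicated(genes_used) > 0)
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_dataset(small_design(), seed = 62)
  b <- generate_dataset(small_design(), seed = 62)
  expect_identical(a$counts, b$counts)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$lr_map, b$lr_map)
})

test_that("planted proportion changes land in the condition arm", {
  design <- synthetic_design(n_populations = 4,
                             base_proportions = c(0.4, 0.3, 0.2, 0.1),
                             cells_per_condition = c(control = 2000,
                                                     condition = 2000),
                             changed_populations = 2L,
                             change_factors = 3,
                             n_genes = 150, n_decoy_pairs = 20)
  sim <- generate_dataset(design, seed = 63)
  pr <- to_proportions(build_count_table(sim$annotations))
  want <- apply_change_factors(c(0.4, 0.3, 0.2, 0.1), 2L, 3)
  se <- sqrt(want * (1 - want) / 2000)
  expect_true(all(abs(pr[, "condition"] - want) < 4 * se))
  expect_true(all(abs(pr[, "control"] - c(0.4, 0.3, 0.2, 0.1)) < 4 *
                    sqrt(0.4 * 0.6 / 2000)))
  expect_identical(sim$truth$changed_populations, 2L)
})

test_that("planted ligand effects are recovered from the generated matrix", {
  design <- synthetic_design(cells_per_condition = c(control = 1000,
                                                     condition = 1000))
  sim <- generate_dataset(design, seed = 64)
  norm <- normalize_cptt(sim$counts)
  prof <- population_profiles(norm, sim$annotations$cluster,
                              fc_scale = "linear")
  lig <- sim$truth$channels$ligand
  rec <- sim$truth$channels$receptor
  # linear-scale fold-changes of planted genes sit near the planted
  # log2 effect of 2 (500 cells per population)
  expect_true(all(abs(prof$log2fc[lig, "P1"] - 2) < 0.5))
  expect_true(all(abs(prof$log2fc[rec, "P2"] - 2) < 0.5))
  # and show no up-regulation elsewhere (the rest includes the source
  # population, so off-source fold-changes sit at or below zero)
  expect_true(all(prof$log2fc[lig, "P3"] < 0.5))
})

test_that("degenerate designs are rejected", {
  expect_error(synthetic_design(n_genes = 0), "degenerate")
  expect_error(synthetic_design(n_genes = 50), "too small")
  expect_error(synthetic_design(base_proportions = c(0.5, 0.6)),
               "one entry per population|sum to 1")
  expect_error(synthetic_design(channels = list(list(source = "P9",
                                                     target = "P1",
                                                     n_pairs = 1,
                                                     ligand_effect = 1,
                                                     receptor_effect = 1,
                                                     ppi_weight = 0.5))),
               "population labels")
  expect_error(generate_dataset(list()), "synthetic_design")
})
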