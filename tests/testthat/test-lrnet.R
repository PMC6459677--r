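# Hand-built profile object: two populations, four genes, with chosen
# detection rates and fold-changes so path arithmetic is checkable by hand.
fake_profiles <- function(det, fc, pops = c("S", "T")) {
  structure(list(populations = pops,
                 genes = rownames(det),
                 sizes = stats::setNames(rep(10L, length(pops)), pops),
                 detection = det, log2fc = fc,
                 pseudocount = 1, fc_scale = "log"),
            class = "population_profiles")
}

test_that("candidate paths honor the detection filter at the boundary", {
  det <- matrix(c(0.5, 0.05, 0.10, 0.9,
                  0.2, 0.50, 0.80, 0.10),
                nrow = 4,
                dimnames = list(c("lig1", "lig2", "rec1", "rec2"),
                                c("S", "T")))
  fc <- matrix(c(2.0, 1.0, 0.5, 1.5,
                 0.1, 0.2, 0.3, 0.4),
               nrow = 4, dimnames = dimnames(det))
  map <- data.frame(ligand = c("lig1", "lig2"),
                    receptor = c("rec1", "rec2"),
                    ppi_weight = c(0.9, 0.8))
  paths <- enumerate_candidate_paths(fake_profiles(det, fc), map)
  # lig2 never reaches 10% detection in S, so no S-sourced lig2 path;
  # rec2 detection in T is exactly 0.10 and must be included
  s_to_t <- paths[paths$source == "S" & paths$target == "T", ]
  expect_identical(sort(s_to_t$ligand), c("lig1", "lig1")[1:2 <= 1])
  expect_true(all(s_to_t$ligand == "lig1"))
  expect_identical(s_to_t$receptor, "rec1")
  expect_equal(s_to_t$path_weight, 2.0 + 0.9 + 0.3)
  # detection exactly at the threshold counts (>= comparison)
  t_self <- paths[paths$source == "T" & paths$target == "T", ]
  expect_true("rec2" %in% t_self$receptor)

  # weights add up: (2.0 + 0.9 + 1.5) = 4.4
  det2 <- matrix(1, nrow = 2, ncol = 2,
                 dimnames = list(c("L", "R"), c("S", "T")))
  fc2 <- matrix(c(2.0, 9, 9, 1.5), nrow = 2, dimnames = dimnames(det2))
  p2 <- enumerate_candidate_paths(
    fake_profiles(det2, fc2),
    data.frame(ligand = "L", receptor = "R", ppi_weight = 0.9))
  expect_equal(p2$path_weight[p2$source == "S" & p2$target == "T"], 4.4)
  expect_equal(p2$path_weight,
               p2$w_source_ligand + p2$w_lr + p2$w_receptor_target)

  # unknown genes are skipped with a warning; fully absent map errors
  map_absent <- rbind(map, data.frame(ligand = "nope", receptor = "rec1",
                                      ppi_weight = 0.5))
  expect_warning(enumerate_candidate_paths(fake_profiles(det, fc),
                                           map_absent),
                 "absent")
  expect_error(
    suppressWarnings(enumerate_candidate_paths(
      fake_profiles(det, fc),
      data.frame(ligand = "nope", receptor = "nah", ppi_weight = 0.5))),
    "no usable")
  expect_error(enumerate_candidate_paths(
    fake_profiles(det, fc),
    data.frame(ligand = character(), receptor = character(),
               ppi_weight = numeric())), "empty")
})

test_that("path filtering and summed weights behave at the 1.5 boundary", {
  paths <- data.frame(source = "S", ligand = c("a", "b", "c"),
                      receptor = c("x", "y", "z"), target = "T",
                      w_source_ligand = 0, w_lr = 0,
                      w_receptor_target = 0,
                      path_weight = c(1.4, 1.5, 4.4))
  kept <- filter_paths(paths)
  expect_identical(kept$ligand, c("b", "c"))
  expect_identical(nrow(filter_paths(paths[0, ])), 0L)

  expect_equal(summed_weight(kept), 5.9)
  expect_equal(summed_weight(paths[0, ]), 0)
  expect_equal(summed_weight(paths[3, ]), 4.4)
  mixed <- paths
  mixed$target <- c("T", "T", "U")
  expect_error(summed_weight(mixed), "mix")
})

test_that("randomized-network p-values match a brute-force loop", {
  lr_w <- c(0.9, 0.4)
  lig_pool <- c(2.0, 0.1, -0.5)
  rec_pool <- c(1.5, 0.0, 0.3)
  for (seed in c(2, 3)) {
    for (w_st in c(0, 3.0, 8.0)) {
      set.seed(seed)
      got <- lrnet_null(w_st, lr_w, lig_pool, rec_pool, m = 400,
                        min_path_weight = 1.5)
      want <- oracle_lrnet_null(w_st, lr_w, lig_pool, rec_pool, m = 400,
                                min_path_weight = 1.5, seed = seed)
      expect_identical(got, want)
    }
  }

  # boundaries: no candidate paths, degenerate pools, unbeatable observation
  expect_identical(lrnet_null(5, numeric(0), 1, 1, m = 10), 1)
  expect_identical(lrnet_null(2.9, c(0.9), 1.0, 1.0, m = 50), 1)  # all ties
  set.seed(1)
  expect_identical(lrnet_null(1e6, c(0.9), c(0, 1), c(0, 1), m = 100), 0)
})

test_that("BH adjustment matches the textbook step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p & adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("raising thresholds never enlarges the network", {
  sim <- generate_dataset(small_design(), seed = 41)
  norm <- normalize_cptt(sim$counts)
  prof <- population_profiles(norm, sim$annotations$cluster)
  loose <- enumerate_candidate_paths(prof, sim$lr_map, min_detection = 0.05)
  tight <- enumerate_candidate_paths(prof, sim$lr_map, min_detection = 0.3)
  expect_lte(nrow(tight), nrow(loose))

  cand <- enumerate_candidate_paths(prof, sim$lr_map)
  for (mpw in c(0.5, 1.5, 3)) {
    kept <- filter_paths(cand, mpw)
    expect_true(all(kept$path_weight >= mpw))
  }
  n_kept <- vapply(c(0.5, 1.5, 3), function(mpw)
    nrow(filter_paths(cand, mpw)), integer(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("the end-to-end network test recovers a planted channel", {
  sim <- generate_dataset(small_design(), seed = 47)
  net <- lrnet_test(sim$counts, sim$annotations, sim$lr_map, m = 2000,
                    seed = 48)
  res <- net$results
  planted <- res$source == "P1" & res$target == "P2"
  expect_true(res$significant[planted])
  expect_equal(res$p_w[planted], 0)
  expect_true(all(res$n_filtered <= res$n_candidate))
  expect_true(all(res$p_adj >= res$p_w))
  expect_true(all(res$w_st >= 1.5 * res$n_filtered - 1e-9))

  # per-connection summed weights equal an independent recomputation
  norm <- normalize_cptt(sim$counts)
  prof <- population_profiles(norm, sim$annotations$cluster)
  cand <- enumerate_candidate_paths(prof, sim$lr_map)
  kept <- filter_paths(cand)
  for (i in seq_len(nrow(res))) {
    sub <- kept[kept$source == res$source[i] & kept$target == res$target[i], ]
    expect_equal(res$w_st[i], if (nrow(sub)) sum(sub$path_weight) else 0)
  }

  # determinism under a fixed seed
  net2 <- lrnet_test(sim$counts, sim$annotations, sim$lr_map, m = 2000,
                     seed = 48)
  expect_identical(net$results, net2$results)
})

test_that("network export round-trips weights bit-exactly", {
  sim <- generate_dataset(small_design(), seed = 51)
  net <- lrnet_test(sim$counts, sim$annotations, sim$lr_map, m = 200,
                    seed = 52)
  prefix <- file.path(tempdir(), "net_export")
  files <- export_network(net, prefix)
  edges <- utils::read.delim(files["edges"])
  paths <- utils::read.delim(files["paths"])
  expect_identical(edges$w_st, net$results$w_st)
  expect_identical(edges$p_w, net$results$p_w)
  expect_identical(nrow(paths), nrow(net$paths))
  expect_identical(paths$path_weight, net$paths$path_weight)

  # significant-only export of an all-null network gives header-only files
  none <- net
  none$results$significant <- FALSE
  files2 <- export_network(none, file.path(tempdir(), "net_empty"),
                           significant_only = TRUE)
  expect_identical(nrow(utils::read.delim(files2["edges"])), 0L)
  expect_identical(nrow(utils::read.delim(files2["paths"])), 0L)
  unlink(c(files, files2))
})
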