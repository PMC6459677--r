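# Small in-code fixtures shared across test files.

toy_annotations <- function() {
  cell_annotations(paste0("c", 1:4),
                   c("sham", "sham", "sham", "MI"),
                   c("F1", "F1", "F2", "F2"))
}

# 20-cell two-condition cohort with an imbalanced cluster.
toy_cohort <- function() {
  cell_annotations(paste0("c", 1:20),
                   rep(c("A", "B"), each = 10),
                   c(rep("X", 6), rep("Y", 4), rep("X", 2), rep("Y", 8)))
}

# Tiny expression fixture: 4 genes x 6 cells in two populations.
toy_expression <- function() {
  m <- matrix(c(4, 0, 1, 0,
                2, 1, 0, 0,
                3, 0, 2, 1,
                0, 2, 0, 1,
                1, 3, 0, 0,
                0, 1, 1, 2),
              nrow = 4, ncol = 6,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:6)))
  list(counts = m,
       clusters = c("A", "A", "A", "B", "B", "B"))
}

small_design <- function(...) {
  synthetic_design(n_genes = 150, n_decoy_pairs = 20,
                   cells_per_condition = c(control = 300, condition = 300),
                   ...)
}
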