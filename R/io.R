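## Atomic write helper: data land in a temp file in the destination
## directory, renamed into place only on success, so an interrupted run
## never leaves a partial output behind.
.write_atomic <- function(writer, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(pattern = paste0(".", basename(path), "."),
                  tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("failed to write ", path)
  invisible(path)
}

#' Write a data.frame as a tab-separated file
#'
#' Floats are serialized with 17 significant digits so a round-trip
#' through [utils::read.delim()] reproduces them bit-exactly. The file is
#' written atomically (temp-and-rename).
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
    }
  }
  .write_atomic(function(tmp) {
    utils::write.table(out, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }, path)
}

.read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop(what, " file is empty: ", path)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Read a cell annotation table
#'
#' Expects a UTF-8 tab-separated file with header columns `cell_id`,
#' `condition`, `cluster` (extra columns are ignored; CRLF line endings
#' are accepted). Duplicate cell identifiers and empty labels are
#' rejected.
#'
#' @param path annotation TSV path.
#' @return Validated annotation `data.frame`.
#' @export
read_annotations <- function(path) {
  df <- .read_table_checked(path, c("cell_id", "condition", "cluster"),
                            "annotation")
  ann <- cell_annotations(df$cell_id, df$condition, df$cluster)
  ann
}

#' Write a cell annotation table
#'
#' @inheritParams validate_annotations
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  write_tsv(annotations[, c("cell_id", "condition", "cluster")], path)
}

#' Read a ligand-receptor pair map
#'
#' Tab-separated file with header `ligand`, `receptor`, `ppi_weight`
#' (weights in `[0, 1]`).
#'
#' @param path map TSV path.
#' @return Validated map `data.frame`.
#' @export
read_lr_map <- function(path) {
  df <- .read_table_checked(path, c("ligand", "receptor", "ppi_weight"),
                            "ligand-receptor map")
  df$ppi_weight <- as.numeric(df$ppi_weight)
  validate_lr_map(df)
  df[, c("ligand", "receptor", "ppi_weight")]
}

#' Write a ligand-receptor pair map
#'
#' @param lr_map validated map ([validate_lr_map()]).
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_lr_map <- function(lr_map, path) {
  validate_lr_map(lr_map)
  write_tsv(lr_map[, c("ligand", "receptor", "ppi_weight")], path)
}

.read_sidecar_ids <- function(path, what) {
  ids <- utils::read.delim(path, header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
  if (anyDuplicated(ids)) stop("duplicate ", what, " identifiers in ", path)
  as.character(ids)
}

.find_sidecar <- function(dir, candidates) {
  for (base in candidates) {
    for (p in file.path(dir, c(base, paste0(base, ".gz")))) {
      if (file.exists(p)) return(p)
    }
  }
  stop("no ", candidates[1], " sidecar found in ", dir)
}

#' Read a genes-by-cells expression matrix
#'
#' Accepts either a Matrix Market triplet layout -- a directory (or a
#' `.mtx`/`.mtx.gz` file whose directory) containing `matrix.mtx`,
#' a gene sidecar (`genes.tsv` or `features.tsv`, first column = gene
#' id) and `barcodes.tsv`, any of them optionally gzipped -- or a dense
#' delimited text file (first column gene ids, header cell ids; tab or
#' comma separated). Integer counts are preserved exactly and dimensions
#' are checked against the sidecars.
#'
#' @param path directory or file path.
#' @return Genes-by-cells matrix with gene/cell dimnames (sparse
#'   `dgCMatrix` for Matrix Market input, base matrix for dense input).
#' @export
read_expression_matrix <- function(path) {
  if (dir.exists(path) || grepl("\\.mtx(\\.gz)?$", path)) {
    dir <- if (dir.exists(path)) path else dirname(path)
    mtx <- if (dir.exists(path)) .find_sidecar(dir, "matrix.mtx") else path
    m <- if (grepl("\\.gz$", mtx)) {
      con <- gzfile(mtx)
      on.exit(close(con), add = TRUE)
      Matrix::readMM(con)
    } else Matrix::readMM(mtx)
    m <- methods::as(m, "CsparseMatrix")
    genes <- .read_sidecar_ids(.find_sidecar(dir, c("genes.tsv", "features.tsv")),
                               "gene")
    cells <- .read_sidecar_ids(.find_sidecar(dir, "barcodes.tsv"), "barcode")
    if (length(genes) != nrow(m)) {
      stop("gene sidecar has ", length(genes), " entries but matrix has ",
           nrow(m), " rows")
    }
    if (length(cells) != ncol(m)) {
      stop("barcode sidecar has ", length(cells), " entries but matrix has ",
           ncol(m), " columns")
    }
    dimnames(m) <- list(genes, cells)
    m
  } else {
    if (!file.exists(path)) stop("matrix file not found: ", path)
    sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
    df <- utils::read.delim(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    genes <- as.character(df[[1]])
    if (anyDuplicated(genes)) stop("duplicate gene identifiers in ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (anyDuplicated(colnames(m))) {
      stop("duplicate cell identifiers in ", path)
    }
    storage.mode(m) <- "double"
    rownames(m) <- genes
    m
  }
}

#' Write a count matrix as a Matrix Market triplet directory
#'
#' Writes `matrix.mtx`, `genes.tsv` and `barcodes.tsv` under `dir`, the
#' layout [read_expression_matrix()] reads back.
#'
#' @param counts genes-by-cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_expression_matrix <- function(counts, dir) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene and cell dimnames")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  .write_atomic(function(tmp) Matrix::writeMM(sp, tmp),
                file.path(dir, "matrix.mtx"))
  .write_atomic(function(tmp) {
    writeLines(rownames(counts), tmp)
  }, file.path(dir, "genes.tsv"))
  .write_atomic(function(tmp) {
    writeLines(colnames(counts), tmp)
  }, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
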