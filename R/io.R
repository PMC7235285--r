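#' Read a cell matrix from disk
#'
#' Reads either a dense numeric table (TSV/CSV, no header: one cell per row
#' by default) or a sparse Matrix Market triplet file with companion
#' `barcodes.tsv` / `features.tsv` files (CellRanger dialect: features as
#' rows, cells as columns, 1-based indices per the Matrix Market standard).
#' Optionally applies the default preprocessing for raw counts
#' ([preprocess_lognorm_pca()]); users supplying a ready-made embedding keep
#' `preprocess = "none"`.
#'
#' @param path input file (`.tsv`, `.csv` or `.mtx`; `format = "auto"` picks
#'   by extension).
#' @param format `"auto"`, `"tsv"`, `"csv"` or `"mtx"`.
#' @param orientation `"cells_rows"` or `"cells_cols"`; defaults to
#'   `cells_rows` for dense tables and `cells_cols` for MTX.
#' @param preprocess `"none"` or `"lognorm_pca"`.
#' @param n_components number of principal components when preprocessing.
#' @param barcodes,features companion files for MTX input; default to
#'   `barcodes.tsv` and `features.tsv` (or `genes.tsv`) next to the matrix.
#' @return a tibble with a `cell_id` column followed by numeric coordinate
#'   columns.
#' @export
read_cells <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                       orientation = NULL,
                       preprocess = c("none", "lognorm_pca"),
                       n_components = 100,
                       barcodes = NULL, features = NULL) {
  format <- match.arg(format)
  preprocess <- match.arg(preprocess)
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", "tsv")
  }

  if (format == "mtx") {
    orientation <- orientation %||% "cells_cols"
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    barcodes <- barcodes %||% file.path(dir, "barcodes.tsv")
    if (is.null(features)) {
      features <- file.path(dir, "features.tsv")
      if (!file.exists(features)) features <- file.path(dir, "genes.tsv")
    }
    ids <- if (file.exists(barcodes)) readLines(barcodes) else NULL
    feat <- if (file.exists(features)) readLines(features) else NULL
    if (orientation == "cells_cols") m <- t(m)
    if (!is.null(ids)) {
      ids <- vapply(strsplit(ids, "\t"), `[`, character(1), 1L)
      if (length(ids) != nrow(m))
        abort(sprintf("barcodes file has %d entries but the matrix has %d cells",
                      length(ids), nrow(m)))
      rownames(m) <- ids
    }
    if (!is.null(feat)) {
      feat <- vapply(strsplit(feat, "\t"), `[`, character(1), 1L)
      if (length(feat) != ncol(m))
        abort(sprintf("features file has %d entries but the matrix has %d features",
                      length(feat), ncol(m)))
      colnames(m) <- feat
    }
  } else {
    orientation <- orientation %||% "cells_rows"
    sep <- if (format == "csv") "," else "\t"
    # base strtod parsing: bitwise round trip with the writer
    df <- tryCatch(
      utils::read.table(path, sep = sep, header = FALSE, colClasses = "numeric"),
      error = function(e) locate_bad_cell(path, sep)
    )
    m <- unname(as.matrix(df))
    if (orientation == "cells_cols") m <- t(m)
  }

  if (is.null(rownames(m))) rownames(m) <- paste0("cell_", seq_len(nrow(m)) - 1L)
  if (preprocess == "lognorm_pca") {
    m <- preprocess_lognorm_pca(m, n_components)
  } else if (is.null(colnames(m))) {
    colnames(m) <- paste0("dim_", seq_len(ncol(m)))
  }
  dplyr::bind_cols(tibble(cell_id = rownames(m)), as_tibble(m))
}

# pinpoint the first non-numeric cell for the error message
locate_bad_cell <- function(path, sep) {
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character")
  for (j in seq_along(raw)) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw[[j]]))) & !is.na(raw[[j]]))
    if (length(bad))
      abort(sprintf("non-numeric value '%s' at line %d, column %d of %s",
                    raw[[j]][bad[1]], bad[1], j, path))
  }
  abort(paste0("failed to parse ", path))
}

#' Library-size normalization, log transform and PCA
#'
#' The documented default preprocessing for raw count input: each cell's
#' counts are scaled to the median total count, `log1p`-transformed, and
#' reduced by PCA (centered, unscaled) to `n_components` dimensions. Signs
#' are fixed deterministically: within each component the loading of largest
#' magnitude is made positive, so identical inputs give identical embeddings
#' across runs and platforms.
#'
#' @param data nonnegative count matrix or data frame, cells as rows.
#' @param n_components number of principal components to keep (capped at
#'   what the data supports).
#' @return numeric score matrix, cells x components.
#' @export
preprocess_lognorm_pca <- function(data, n_components = 100) {
  X <- as_coord_matrix(data)
  if (any(X < 0)) abort("lognorm_pca preprocessing expects nonnegative counts")
  totals <- rowSums(X)
  bad <- which(totals == 0)
  if (length(bad))
    abort(paste0("all-zero cell(s): ", paste(rownames(X)[bad], collapse = ", ")))
  Xn <- X / totals * median(totals)
  L <- log1p(Xn)
  rank <- min(n_components, nrow(L) - 1L, ncol(L))
  if (rank < 1L) rank <- 1L
  pc <- prcomp(L, center = TRUE, scale. = FALSE, rank. = rank)
  scores <- pc$x
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Write a dense embedding fixture
#'
#' Writes the coordinates as a headerless TSV (one cell per row) that
#' round-trips bitwise through [read_cells()], plus an optional plain-text
#' label file (one label per line, aligned to cell order).
#'
#' @param data cells-by-dimensions input; a `label` column, if present, is
#'   used for `labels_path`.
#' @param path output TSV path.
#' @param labels_path optional output path for the label file.
#' @export
write_cells_tsv <- function(data, path, labels_path = NULL) {
  X <- as_coord_matrix(data)
  readr::write_tsv(as.data.frame(X), path, col_names = FALSE, progress = FALSE)
  if (!is.null(labels_path)) {
    if (!is.data.frame(data) || !"label" %in% names(data))
      abort("`labels_path` given but `data` has no `label` column")
    writeLines(as.character(data$label), labels_path)
  }
  invisible(path)
}

#' Write a sparse Matrix Market fixture
#'
#' Writes a CellRanger-style trio (`matrix.mtx`, `barcodes.tsv`,
#' `features.tsv`; features as rows, cells as columns, 1-based indices) to
#' exercise the sparse reader end-to-end. With `round_counts = TRUE` the
#' coordinates are shifted to be nonnegative and rounded to integers, turning
#' an embedding into count-like data.
#'
#' @param data cells-by-dimensions input.
#' @param dir output directory (created if needed).
#' @param round_counts shift-and-round coordinates to nonnegative integers.
#' @return invisibly, the matrix that was written (cells as rows).
#' @export
write_cells_mtx <- function(data, dir, round_counts = TRUE) {
  X <- as_coord_matrix(data)
  if (round_counts) X <- round(X - min(X, 0))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(X), sparse = TRUE)  # features x cells
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(X), file.path(dir, "barcodes.tsv"))
  feat <- colnames(X) %||% paste0("dim_", seq_len(ncol(X)))
  writeLines(feat, file.path(dir, "features.tsv"))
  invisible(X)
}
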