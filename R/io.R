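#' Read an expression matrix
#'
#' TSV layout: genes as rows (first column holds the gene identifier),
#' header line with sample/cell identifiers. MTX layout: a MatrixMarket
#' coordinate file accompanied by `<path>.genes.tsv` and `<path>.cells.tsv`
#' identifier sidecars; entries absent from the coordinate list are zeros.
#' Duplicate gene or sample identifiers are rejected.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"`, or `"mtx"`.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(paste0(path, ".genes.tsv"), warn = FALSE)
    cells <- readLines(paste0(path, ".cells.tsv"), warn = FALSE)
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      stop("parse error: MTX id sidecars do not match matrix dimensions")
    }
    dimnames(m) <- list(genes, cells)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("parse error: expression TSV needs id + value columns")
    ids <- as.character(df[[1]])
    vals <- df[, -1, drop = FALSE]
    non_num <- !vapply(vals, is.numeric, logical(1))
    if (any(non_num)) {
      for (j in which(non_num)) {
        bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                       !is.na(vals[[j]]))
        stop("parse error: non-numeric value in column '", names(vals)[j],
             "' at data line ", if (length(bad)) bad[1] else NA)
      }
    }
    m <- as.matrix(vals)
    rownames(m) <- ids
  }
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample identifier(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  m
}

#' Write an expression matrix
#'
#' TSV values are written with 6 significant digits (compare round-trips
#' numerically, not textually). MTX output writes the coordinate file plus
#' `<path>.genes.tsv` / `<path>.cells.tsv` identifier sidecars.
#'
#' @param matrix Genes x samples matrix with dimnames.
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(matrix, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  m <- as.matrix(matrix)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), paste0(path, ".genes.tsv"))
    writeLines(colnames(m), paste0(path, ".cells.tsv"))
  } else {
    df <- data.frame(gene = rownames(m), signif(m, 6), check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write an IHC score table (CSV)
#'
#' Columns: `sample_id`, `compartment`, `pct_negative`, `pct_low`,
#' `pct_medium`, `pct_high`, plus optional `pct_positive_cells` and
#' `indication`. Rows are validated on read (categories sum to 100).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_ihc_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ihc_rows(df)
  df
}

#' @rdname read_ihc_table
#' @param table IHC score table.
#' @export
write_ihc_table <- function(table, path) {
  validate_ihc_rows(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Merges the file's fields over [default_run_config()].
#'
#' @param path YAML or JSON configuration file.
#' @return Run-configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(default_run_config(), cfg)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Default pipeline run configuration
#'
#' @return Nested list with `seed` and per-stage sub-configurations
#'   (`simulate_sc`, `simulate_ihc`, `markers`, `pseudobulk`, `scoring`,
#'   `ihc_cutoffs`).
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    simulate_sc = list(n_cells_per_type = 500L, use_real_symbols = TRUE),
    simulate_ihc = list(n_samples = 60L,
                        indications = c("HNSCC", "BC", "CRC")),
    markers = list(target = "Mac_SPP1",
                   max_nonmac_fraction = 0.1,
                   max_other_mac_fraction = 0.5,
                   top_k = 5L),
    pseudobulk = list(cells_per_sample = 1000L, replicates = 10L),
    scoring = list(log_transform = TRUE, quantile_normalize = FALSE),
    ihc_cutoffs = c(1, 5, 10, 25, 50))
}
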