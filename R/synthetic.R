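#' Configuration for the synthetic single-cell generator
#'
#' Describes a multi-cell-type single-cell expression profile with planted
#' marker structure: subset-specific markers for the two TAM subsets and for
#' T cells, markers shared by all macrophage labels, and "broad" decoy genes
#' expressed by tumor and stromal cells. Counts are drawn from a gamma-Poisson
#' (negative-binomial-like) model on a linear TPM-like scale.
#'
#' Marker tables are two-column data frames `(gene, fc)` giving the 1-based
#' gene index and the fold-change multiplier applied to `baseline_mean` in the
#' marked cell type(s). Subset-specific markers planted for a macrophage label
#' are additionally elevated `other_mac_fc`-fold in the *other* macrophage
#' labels, emulating markers that are modestly expressed across the macrophage
#' compartment but minimal elsewhere.
#'
#' @param n_genes Number of genes.
#' @param cell_types Cell-type labels.
#' @param n_cells_per_type Cells per label (scalar, or named vector over
#'   `cell_types`); at least 2 per label.
#' @param planted_markers Named list (by label) of marker data frames.
#' @param macrophage_shared_markers Marker data frame elevated in every label
#'   in `mac_labels`.
#' @param broad_markers Marker data frame elevated in every label in
#'   `broad_labels` (tumor/stroma decoys).
#' @param mac_labels Labels counted as macrophages.
#' @param broad_labels Labels in which `broad_markers` are elevated.
#' @param other_mac_fc Fold change of a TAM-subset marker in the other
#'   macrophage labels (1 disables cross-expression).
#' @param baseline_mean Baseline expression mean (linear scale).
#' @param dispersion Gamma-Poisson dispersion; 0 gives pure Poisson noise.
#' @param library_scale Optional target column sum for TPM-like library
#'   scaling; `NULL` (default) keeps the linear gamma-Poisson scale so that
#'   planted means equal `baseline_mean * fc` in expectation.
#' @param use_real_symbols If `TRUE`, planted marker genes are named with the
#'   field's marker symbols (e.g. the SPP1 TAM markers PLAUR, SLC11A1, BRI3,
#'   FBP1, C15orf48) instead of synthetic `G0001`-style identifiers, for
#'   end-to-end demonstrations with the built-in signatures.
#' @param seed Integer seed; the generator uses a single RNG stream seeded
#'   from it, so identical configs give bitwise-identical output.
#' @return A validated `tam_sc_config` list.
#' @export
synthetic_sc_config <- function(
    n_genes = 200L,
    cell_types = c("Tumor", "Stroma", "Tcell",
                   "Mac_general", "Mac_C1QC", "Mac_SPP1"),
    n_cells_per_type = 500L,
    planted_markers = list(
      Mac_SPP1 = data.frame(gene = 1:5,   fc = 16),
      Mac_C1QC = data.frame(gene = 6:13,  fc = 16),
      Tcell    = data.frame(gene = 14:19, fc = 16)
    ),
    macrophage_shared_markers = data.frame(gene = 21:25, fc = 6),
    broad_markers = data.frame(gene = 31:38, fc = 6),
    mac_labels = c("Mac_general", "Mac_C1QC", "Mac_SPP1"),
    broad_labels = c("Tumor", "Stroma"),
    other_mac_fc = 3,
    baseline_mean = 5,
    dispersion = 0.4,
    library_scale = NULL,
    use_real_symbols = FALSE,
    seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), cell_types = as.character(cell_types),
    n_cells_per_type = n_cells_per_type, planted_markers = planted_markers,
    macrophage_shared_markers = macrophage_shared_markers,
    broad_markers = broad_markers, mac_labels = mac_labels,
    broad_labels = broad_labels, other_mac_fc = other_mac_fc,
    baseline_mean = baseline_mean, dispersion = dispersion,
    library_scale = library_scale, use_real_symbols = isTRUE(use_real_symbols),
    seed = as.integer(seed))
  class(cfg) <- "tam_sc_config"
  validate_sc_config(cfg)
  cfg
}

normalize_marker_table <- function(m, what) {
  if (is.null(m) || NROW(m) == 0L) {
    return(data.frame(gene = integer(0), fc = numeric(0)))
  }
  m <- as.data.frame(m)
  if (!all(c("gene", "fc") %in% names(m))) {
    stop("configuration error: ", what, " must have columns 'gene' and 'fc'")
  }
  data.frame(gene = as.integer(m$gene), fc = as.numeric(m$fc))
}

validate_sc_config <- function(cfg) {
  if (cfg$n_genes < 1L) stop("configuration error: n_genes must be positive")
  if (length(cfg$cell_types) < 1L || anyDuplicated(cfg$cell_types)) {
    stop("configuration error: cell_types must be non-empty and unique")
  }
  ncells <- cells_per_type(cfg)
  if (any(ncells < 2L)) {
    stop("configuration error: n_cells_per_type must be >= 2 for every label")
  }
  if (cfg$baseline_mean <= 0) stop("configuration error: baseline_mean must be positive")
  if (cfg$dispersion < 0) stop("configuration error: dispersion must be non-negative")
  if (cfg$other_mac_fc < 1) stop("configuration error: other_mac_fc must be >= 1")
  unknown <- setdiff(names(cfg$planted_markers), cfg$cell_types)
  if (length(unknown)) {
    stop("configuration error: planted markers for unknown labels: ",
         paste(unknown, collapse = ", "))
  }
  all_sets <- c(
    lapply(cfg$planted_markers, function(m) normalize_marker_table(m, "planted_markers")$gene),
    list(shared = normalize_marker_table(cfg$macrophage_shared_markers, "macrophage_shared_markers")$gene,
         broad = normalize_marker_table(cfg$broad_markers, "broad_markers")$gene))
  idx <- unlist(all_sets, use.names = FALSE)
  if (length(idx) && (min(idx) < 1L || max(idx) > cfg$n_genes)) {
    stop("configuration error: marker gene index outside 1..n_genes")
  }
  tam <- intersect(names(cfg$planted_markers), cfg$mac_labels)
  tam_idx <- unlist(all_sets[tam], use.names = FALSE)
  if (anyDuplicated(tam_idx)) {
    stop("configuration error: overlapping TAM marker sets")
  }
  if (anyDuplicated(idx)) {
    stop("configuration error: marker gene sets must be disjoint across roles")
  }
  fcs <- unlist(lapply(all_sets_fc(cfg), function(m) m$fc), use.names = FALSE)
  if (any(fcs < 1)) stop("configuration error: fold-change multipliers must be >= 1")
  invisible(cfg)
}

all_sets_fc <- function(cfg) {
  c(lapply(cfg$planted_markers, normalize_marker_table, what = "planted_markers"),
    list(normalize_marker_table(cfg$macrophage_shared_markers, "shared"),
         normalize_marker_table(cfg$broad_markers, "broad")))
}

cells_per_type <- function(cfg) {
  n <- cfg$n_cells_per_type
  if (length(n) == 1L) n <- rep(n, length(cfg$cell_types))
  if (is.null(names(n))) names(n) <- cfg$cell_types
  as.integer(n[cfg$cell_types])
}

real_symbol_map <- list(
  Mac_SPP1 = c("PLAUR", "SLC11A1", "BRI3", "FBP1", "C15orf48"),
  Mac_C1QC = c("APOE", "C1QC", "C1QB", "C1QA", "TREM2", "MRC1", "CD163", "MERTK"),
  Tcell    = c("CD3E", "CD8A", "CD8B", "GZMB", "ITGAE", "ZNF683"),
  shared   = c("CD68", "CD14", "LYZ", "AIF1", "TYROBP"),
  broad    = c("SPP1", "PPARG", "ADM", "MARCO", "VEGFA", "VCAN", "CXCL8", "ANGPTL4"))

sc_gene_ids <- function(cfg) {
  ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  if (!cfg$use_real_symbols) return(ids)
  assign_symbols <- function(ids, idx, symbols) {
    k <- min(length(idx), length(symbols))
    ids[idx[seq_len(k)]] <- symbols[seq_len(k)]
    ids
  }
  for (lab in intersect(names(cfg$planted_markers), names(real_symbol_map))) {
    ids <- assign_symbols(ids, normalize_marker_table(cfg$planted_markers[[lab]], lab)$gene,
                          real_symbol_map[[lab]])
  }
  ids <- assign_symbols(ids, normalize_marker_table(cfg$macrophage_shared_markers, "shared")$gene,
                        real_symbol_map$shared)
  ids <- assign_symbols(ids, normalize_marker_table(cfg$broad_markers, "broad")$gene,
                        real_symbol_map$broad)
  ids
}

# Expected mean matrix (genes x cell types) implied by a config.
sc_mean_matrix <- function(cfg) {
  mu <- matrix(cfg$baseline_mean, nrow = cfg$n_genes, ncol = length(cfg$cell_types),
               dimnames = list(NULL, cfg$cell_types))
  for (lab in names(cfg$planted_markers)) {
    m <- normalize_marker_table(cfg$planted_markers[[lab]], lab)
    mu[m$gene, lab] <- cfg$baseline_mean * m$fc
    if (lab %in% cfg$mac_labels && cfg$other_mac_fc > 1) {
      other <- setdiff(cfg$mac_labels, lab)
      # modest cross-expression in the rest of the macrophage compartment,
      # only where the subset fold change itself is active
      cross <- m$gene[m$fc > 1]
      mu[cross, other] <- cfg$baseline_mean * cfg$other_mac_fc
    }
  }
  sh <- normalize_marker_table(cfg$macrophage_shared_markers, "shared")
  for (lab in intersect(cfg$mac_labels, cfg$cell_types)) {
    mu[sh$gene, lab] <- cfg$baseline_mean * sh$fc
  }
  br <- normalize_marker_table(cfg$broad_markers, "broad")
  for (lab in intersect(cfg$broad_labels, cfg$cell_types)) {
    mu[br$gene, lab] <- cfg$baseline_mean * br$fc
  }
  mu
}

#' Generate a synthetic single-cell expression matrix with planted markers
#'
#' Draws gamma-Poisson counts around the per-type mean structure implied by
#' the configuration. Identical config and seed give bitwise-identical output.
#'
#' @param config A [synthetic_sc_config()].
#' @return List with `matrix` (genes x cells, dimnames set) and `annotation`
#'   (data frame with `cell_id`, `cell_type`).
#' @export
#' @examples
#' sim <- generate_single_cell(synthetic_sc_config(n_genes = 50,
#'   n_cells_per_type = 20, seed = 1))
#' dim(sim$matrix)
generate_single_cell <- function(config) {
  validate_sc_config(config)
  mu <- sc_mean_matrix(config)
  ncells <- cells_per_type(config)
  d <- config$dispersion
  withr::with_seed(config$seed, {
    blocks <- lapply(seq_along(config$cell_types), function(i) {
      n <- ncells[i]
      m <- rep(mu[, i], times = n)
      lambda <- if (d > 0) rgamma(length(m), shape = 1 / d, scale = d * m) else m
      matrix(rpois(length(m), lambda), nrow = config$n_genes, ncol = n)
    })
  })
  mat <- do.call(cbind, blocks)
  cell_type <- rep(config$cell_types, times = ncells)
  cell_id <- paste0(cell_type, "_",
                    unlist(lapply(ncells, seq_len), use.names = FALSE))
  dimnames(mat) <- list(sc_gene_ids(config), cell_id)
  if (!is.null(config$library_scale)) {
    cs <- colSums(mat)
    cs[cs == 0] <- 1
    mat <- sweep(mat, 2, config$library_scale / cs, `*`)
  }
  list(matrix = mat,
       annotation = data.frame(cell_id = cell_id, cell_type = cell_type,
                               stringsAsFactors = FALSE))
}

#' Configuration for the synthetic IHC score-table generator
#'
#' Emulates digital image-analysis output: per sample and compartment, the
#' percentage of cells in the four staining-intensity categories (negative,
#' low, medium, high). The percent-positive value is drawn from a truncated
#' normal around the compartment mean; positive cells are distributed over
#' low/medium/high by `category_split`.
#'
#' @param n_samples Number of samples (> 0).
#' @param compartments Compartment labels (default tumor and stroma).
#' @param tumor_positive_mean,stroma_positive_mean Mean percent-positive per
#'   compartment; the defaults (40 vs 10) mimic tumors expressing more of the
#'   analyte than the surrounding stroma.
#' @param category_split Nonnegative weights over `c(low, medium, high)`
#'   summing to 1.
#' @param noise_sd Standard deviation of the percent-positive noise.
#' @param indications Optional indication labels recycled over samples.
#' @param seed Integer seed.
#' @return A validated `tam_ihc_config` list.
#' @export
synthetic_ihc_config <- function(
    n_samples = 60L,
    compartments = c("tumor", "stroma"),
    tumor_positive_mean = 40,
    stroma_positive_mean = 10,
    category_split = c(low = 0.5, medium = 0.3, high = 0.2),
    noise_sd = 8,
    indications = NULL,
    seed = 1L) {
  if (n_samples < 1L) stop("configuration error: n_samples must be positive")
  if (any(category_split < 0) || abs(sum(category_split) - 1) > 1e-9) {
    stop("configuration error: category_split must be nonnegative and sum to 1")
  }
  if (noise_sd < 0) stop("configuration error: noise_sd must be non-negative")
  structure(list(
    n_samples = as.integer(n_samples), compartments = compartments,
    tumor_positive_mean = tumor_positive_mean,
    stroma_positive_mean = stroma_positive_mean,
    category_split = category_split, noise_sd = noise_sd,
    indications = indications, seed = as.integer(seed)),
    class = "tam_ihc_config")
}

#' Generate a synthetic IHC score table
#'
#' @param config A [synthetic_ihc_config()].
#' @return Data frame with one row per sample x compartment and columns
#'   `sample_id`, `compartment`, `pct_negative`, `pct_low`, `pct_medium`,
#'   `pct_high`, `pct_positive_cells`, and `indication` when configured.
#'   Category percentages sum to 100 per row.
#' @export
generate_ihc_table <- function(config) {
  if (!inherits(config, "tam_ihc_config")) stop("expected a tam_ihc_config")
  n <- config$n_samples
  comp_means <- c(tumor = config$tumor_positive_mean,
                  stroma = config$stroma_positive_mean)
  grid <- expand.grid(sample_id = sprintf("S%03d", seq_len(n)),
                      compartment = config$compartments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$sample_id, grid$compartment), , drop = FALSE]
  mu <- comp_means[grid$compartment]
  mu[is.na(mu)] <- config$tumor_positive_mean
  pos <- withr::with_seed(config$seed,
                          rnorm(nrow(grid), mean = mu, sd = config$noise_sd))
  pos <- pmin(pmax(pos, 0), 100)
  s <- config$category_split
  out <- data.frame(
    sample_id = grid$sample_id, compartment = grid$compartment,
    pct_negative = 100 - pos,
    pct_low = pos * s[[1]], pct_medium = pos * s[[2]], pct_high = pos * s[[3]],
    pct_positive_cells = pos, stringsAsFactors = FALSE)
  if (!is.null(config$indications)) {
    ind <- rep_len(config$indications, n)
    names(ind) <- sprintf("S%03d", seq_len(n))
    out$indication <- ind[out$sample_id]
  }
  rownames(out) <- NULL
  out
}

#' Write a synthetic fixture bundle to disk
#'
#' Writes the expression matrix (TSV, optionally also MatrixMarket MTX with
#' gene/cell id sidecars), the cell annotation TSV, the IHC score CSV, and a
#' `manifest.json` recording files, seed and a configuration hash. The bundle
#' round-trips losslessly through [read_expression()] and [read_ihc_table()].
#'
#' @param path Output directory (created if needed).
#' @param matrix Genes x cells expression matrix.
#' @param annotation Cell annotation data frame.
#' @param ihc_table IHC score table.
#' @param config Optional configuration object(s) to hash into the manifest.
#' @param seed Seed recorded in the manifest.
#' @param write_mtx Also write an MTX triplet of the expression matrix.
#' @return The manifest (list), invisibly.
#' @export
write_fixture_bundle <- function(path, matrix, annotation, ihc_table,
                                 config = NULL, seed = NULL,
                                 write_mtx = FALSE) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(path)) stop("I/O error: cannot create directory ", path)
  }
  files <- character(0)
  write_expression(matrix, file.path(path, "expression.tsv"))
  files <- c(files, "expression.tsv")
  if (write_mtx) {
    write_expression(matrix, file.path(path, "expression.mtx"), format = "mtx")
    files <- c(files, "expression.mtx", "expression.mtx.genes.tsv",
               "expression.mtx.cells.tsv")
  }
  write.table(annotation, file.path(path, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(files, "annotation.tsv")
  write_ihc_table(ihc_table, file.path(path, "ihc.csv"))
  files <- c(files, "ihc.csv")
  manifest <- list(files = files, seed = seed,
                   config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("tamsig")))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
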