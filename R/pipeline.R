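file_hash <- function(path) {
  rlang::hash(readBin(path, "raw", n = file.size(path)))
}

sc_config_from_run <- function(config, seed) {
  args <- config$simulate_sc %||% list()
  args$seed <- seed
  do.call(synthetic_sc_config, args)
}

#' Run the full TAM-signature workflow
#'
#' Executes the configured stages in order — simulate synthetic single-cell
#' and IHC data, select SPP1 TAM markers (differential expression +
#' specificity filter against an independently simulated reference), validate
#' signatures by pseudo-bulk spike-in, score the pseudo-bulk cohort and
#' assign the four C1QC x SPP1 TAM bins, and summarize the IHC table — and
#' writes per-stage outputs plus a `manifest.json` (inputs, outputs with
#' content hashes, seeds, configuration hash, package version). Rerunning
#' with the same configuration reproduces every output bitwise; only the
#' manifest timestamp differs.
#'
#' @param config Run configuration (see [default_run_config()] /
#'   [read_run_config()]).
#' @param out_dir Output directory, created if needed.
#' @return The manifest (list), invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (missing(out_dir)) stop("out_dir is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  outputs <- character(0)
  emit <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    outputs <<- c(outputs, name)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## stage 1: simulate
  sim <- stage("simulate_sc", {
    generate_single_cell(sc_config_from_run(config,
                                            derive_seed(seed, "simulate_sc")))
  })
  emit(sim$matrix, "expression.tsv", write_expression)
  emit(sim$annotation, "annotation.tsv", function(x, p) {
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  ihc <- stage("simulate_ihc", {
    args <- config$simulate_ihc %||% list()
    args$seed <- derive_seed(seed, "simulate_ihc")
    generate_ihc_table(do.call(synthetic_ihc_config, args))
  })
  emit(ihc, "ihc.csv", function(x, p) write_ihc_table(x, p))

  ## stage 2: marker selection (reference = independent simulation)
  mk_cfg <- config$markers %||% list()
  target <- mk_cfg$target %||% "Mac_SPP1"
  markers <- stage("markers", {
    differential_markers(sim$matrix, sim$annotation, target)
  })
  ref_sim <- stage("reference", {
    generate_single_cell(sc_config_from_run(config,
                                            derive_seed(seed, "reference")))
  })
  filtered <- stage("specificity_filter", {
    specificity_filter(
      markers,
      references = list(
        discovery = reference_profile(sim$matrix, sim$annotation),
        heldout = reference_profile(ref_sim$matrix, ref_sim$annotation)),
      target = target,
      max_nonmac_fraction = mk_cfg$max_nonmac_fraction %||% 0.1,
      max_other_mac_fraction = mk_cfg$max_other_mac_fraction %||% 0.5)
  })
  tsv_writer <- function(x, p) write.table(
    format(x, digits = 6, scientific = FALSE, trim = TRUE),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  emit(markers, "markers.tsv", tsv_writer)
  emit(filtered, "markers_filtered.tsv", tsv_writer)
  top_k <- mk_cfg$top_k %||% 5L
  recovered <- gene_signature("SPP1_recovered",
                              utils::head(filtered$gene, top_k))

  ## stage 3: pseudo-bulk spike-in validation
  sigs <- builtin_signatures()[c("C1QC", "SPP1_new", "SPP1_Zhang")]
  sigs$SPP1_recovered <- recovered
  pb_args <- config$pseudobulk %||% list()
  pb_args$seed <- derive_seed(seed, "pseudobulk")
  design <- do.call(pseudobulk_design, pb_args)
  val <- stage("pseudobulk_validation", {
    run_validation(sim$matrix, sim$annotation, sigs, design,
                   log_transform = config$scoring$log_transform %||% TRUE)
  })
  emit(val$scores, "pseudobulk_scores.tsv", tsv_writer)
  emit(val$report, "validation_report.tsv", tsv_writer)

  ## stage 4: cohort scoring and TAM bins on the pseudo-bulk cohort
  bins <- stage("tam_bins", {
    wide <- merge(
      stats::setNames(val$scores[val$scores$signature == "C1QC",
                                 c("sample_id", "score")],
                      c("sample_id", "c1qc_score")),
      stats::setNames(val$scores[val$scores$signature == "SPP1_new",
                                 c("sample_id", "score")],
                      c("sample_id", "spp1_score")),
      by = "sample_id")
    assign_tam_bins(wide, scope = "pooled")
  })
  emit(bins, "tam_bins.tsv", tsv_writer)
  emit(attr(bins, "prevalence"), "tam_bin_prevalence.tsv", tsv_writer)

  ## stage 5: IHC cohort summary
  ihc_summary <- stage("ihc_summary", {
    tum <- ihc[ihc$compartment == "tumor", , drop = FALSE]
    prev <- prevalence_at_cutoffs(ihc_pct_positive(tum),
                                  config$ihc_cutoffs %||% c(1, 5, 10, 25, 50))
    contrast <- compartment_contrast(ihc)
    list(prevalence = prev, tests = contrast$tests)
  })
  emit(ihc_summary$prevalence, "ihc_prevalence.tsv", tsv_writer)
  emit(ihc_summary$tests, "ihc_compartment_tests.tsv", tsv_writer)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tamsig")),
    seed = seed,
    config_hash = config_hash(config),
    recovered_signature = recovered$genes,
    outputs = lapply(stats::setNames(outputs, outputs), function(f) {
      list(file = f, hash = file_hash(file.path(out_dir, f)))
    }),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
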