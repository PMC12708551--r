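# Tiny deterministic cell universe with a sentinel gene expressed only by
# macrophages, so spiked-cell content is directly readable off the profile.
sentinel_universe <- function(n_per_type = 40) {
  types <- rep(c("Tumor", "Stroma", "Tcell", "Mac_general", "Mac_C1QC",
                 "Mac_SPP1"), each = n_per_type)
  n <- length(types)
  mac <- grepl("^Mac", types)
  m <- rbind(mac_sentinel = as.numeric(mac),
             tumor_gene = as.numeric(types == "Tumor"),
             flat = rep(1, n))
  colnames(m) <- paste0("c", seq_len(n))
  list(matrix = m,
       annotation = data.frame(cell_id = colnames(m), cell_type = types))
}

test_that("design validation catches malformed spike-in designs", {
  expect_error(pseudobulk_design(background_composition = c(Tumor = 0.7)),
               "sum to 1")
  expect_error(pseudobulk_design(
    background_composition = c(Tumor = 0.5, Mac_SPP1 = 0.5)),
    "macrophage labels")
  expect_error(pseudobulk_design(spike_fractions = c(0.01, 0.02)),
               "include 0")
  expect_error(pseudobulk_design(spike_fractions = c(0, 1.5)), "\\[0, 1\\]")
})

test_that("fraction-0 pseudo-bulk samples contain no macrophage cells", {
  u <- sentinel_universe()
  pb <- make_pseudobulk(u$matrix, u$annotation,
                        pseudobulk_design(cells_per_sample = 400,
                                          replicates = 3, seed = 1,
                                          include_control = FALSE))
  zero <- pb$metadata$fraction == 0
  expect_true(all(pb$matrix["mac_sentinel", pb$metadata$sample_id[zero]] == 0))
  expect_true(all(pb$metadata$n_spiked[zero] == 0))
})

test_that("a full-fraction sample is a pure profile of the spiked type", {
  u <- sentinel_universe()
  d <- pseudobulk_design(spike_fractions = c(0, 1), spiked_types = "Mac_SPP1",
                         cells_per_sample = 30, replicates = 2,
                         include_control = FALSE, seed = 2)
  pb <- make_pseudobulk(u$matrix, u$annotation, d)
  full <- pb$metadata$sample_id[pb$metadata$fraction == 1]
  expect_true(all(pb$matrix["mac_sentinel", full] == 1))
  expect_true(all(pb$matrix["tumor_gene", full] == 0))
})

test_that("realized spike counts equal round(fraction x cells_per_sample)", {
  u <- sentinel_universe()
  d <- pseudobulk_design(cells_per_sample = 1000, replicates = 2, seed = 1)
  pb <- make_pseudobulk(u$matrix, u$annotation, d)
  md <- pb$metadata
  spiked_arms <- !md$spiked_type %in% c("none", "Background")
  expect_equal(md$n_spiked[spiked_arms],
               as.integer(round(md$fraction[spiked_arms] * 1000)))
  expect_equal(md$n_spiked[md$fraction == 0.025 & spiked_arms][1], 25L)
  # mass conservation: spiked + background always sums to cells_per_sample
  expect_true(all(md$n_spiked + md$n_background == 1000))
})

test_that("pseudo-bulk generation is bitwise reproducible under a seed", {
  u <- sentinel_universe()
  d <- pseudobulk_design(cells_per_sample = 400, replicates = 2, seed = 7)
  a <- make_pseudobulk(u$matrix, u$annotation, d)
  b <- make_pseudobulk(u$matrix, u$annotation, d)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$metadata, b$metadata)
})

test_that("rounding a positive fraction to zero spiked cells warns", {
  u <- sentinel_universe()
  d <- pseudobulk_design(spike_fractions = c(0, 0.004),
                         spiked_types = "Mac_SPP1", cells_per_sample = 100,
                         replicates = 1, include_control = FALSE, seed = 1)
  expect_warning(pb <- make_pseudobulk(u$matrix, u$annotation, d),
                 "rounds to 0")
  expect_true(all(pb$metadata$n_spiked == 0))
})

test_that("monotone scores give rho 1; shuffled scores give no trend", {
  md <- data.frame(sample_id = paste0("s", 1:12),
                   spiked_type = "Mac_SPP1",
                   fraction = rep(c(0, 0.01, 0.02), each = 4),
                   replicate = rep(1:4, 3))
  sc <- data.frame(sample_id = md$sample_id, signature = "sig",
                   score = md$fraction * 10 + rep(c(0, 1e-4, 2e-4, 3e-4), 3))
  rep1 <- evaluate_signature(sc, md)
  expect_equal(rep1$rho, 1.0)
  expect_gt(rep1$slope_per_pct, 0)
  sc$score <- withr::with_seed(1, sample(sc$score))
  rep2 <- evaluate_signature(sc, md)
  expect_lt(abs(rep2$slope_per_pct), abs(rep1$slope_per_pct))
  # single fraction: no trend estimable
  expect_error(evaluate_signature(sc[1:4, ], md[1:4, ]), "fraction")
})

test_that("the SPP1 signature responds most to SPP1 TAM spiking", {
  sim <- generate_single_cell(synthetic_sc_config(seed = 1,
                                                  use_real_symbols = TRUE))
  val <- run_validation(sim$matrix, sim$annotation,
                        builtin_signatures()["SPP1_new"],
                        pseudobulk_design(replicates = 4, seed = 1))
  rep <- val$report
  slope <- function(arm) rep$slope_per_pct[rep$spiked_type == arm]
  expect_gt(slope("Mac_SPP1"), slope("Mac_C1QC"))
  expect_gt(slope("Mac_C1QC"), slope("Background"))
  expect_true(rep$specific[rep$spiked_type == "Mac_SPP1"])
  expect_gte(rep$rho[rep$spiked_type == "Mac_SPP1"], 0.9)
})

test_that("tumor/stroma decoy signatures react to background composition", {
  sim <- generate_single_cell(synthetic_sc_config(seed = 1,
                                                  use_real_symbols = TRUE))
  sigs <- builtin_signatures()[c("SPP1_new", "SPP1_Zhang")]
  mk_bg <- function(comp) {
    d <- pseudobulk_design(spike_fractions = c(0, 0.005),
                           spiked_types = "Mac_SPP1",
                           background_composition = comp,
                           cells_per_sample = 400, replicates = 6,
                           include_control = FALSE, seed = 3)
    pb <- make_pseudobulk(sim$matrix, sim$annotation, d)
    pb$matrix[, pb$metadata$sample_id[pb$metadata$fraction == 0]]
  }
  a <- mk_bg(c(Tumor = 0.70, Stroma = 0.25, Tcell = 0.05))
  b <- mk_bg(c(Tumor = 0.40, Stroma = 0.20, Tcell = 0.40))
  pooled <- cbind(a, b)
  colnames(pooled) <- paste0("s", seq_len(ncol(pooled)))
  sc <- score_signatures(pooled, sigs)
  shift <- vapply(c("SPP1_new", "SPP1_Zhang"), function(s) {
    v <- sc$score[sc$signature == s]
    mean(v[seq_len(ncol(a))]) - mean(v[-seq_len(ncol(a))])
  }, numeric(1))
  # Zhang genes live on tumor/stroma cells: composition moves the score.
  # The macrophage-specific signature stays put.
  expect_gt(abs(shift["SPP1_Zhang"]), 4 * abs(shift["SPP1_new"]))
})

test_that("an empty signature list is rejected", {
  u <- sentinel_universe()
  expect_error(run_validation(u$matrix, u$annotation, list(),
                              pseudobulk_design(cells_per_sample = 20,
                                                replicates = 1, seed = 1)),
               "empty signature list")
})
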