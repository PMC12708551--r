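ihc_row <- function(neg, low, med, high, ...) {
  data.frame(sample_id = "s1", compartment = "tumor", pct_negative = neg,
             pct_low = low, pct_medium = med, pct_high = high, ...)
}

test_that("H-score matches the weighted category sum", {
  expect_equal(h_score(ihc_row(100, 0, 0, 0)), 0)
  expect_equal(h_score(ihc_row(0, 0, 0, 100)), 300)
  expect_equal(h_score(ihc_row(40, 10, 20, 30)), 140)
  expect_error(h_score(ihc_row(50, 10, 20, 30)), "sum to 100")
  expect_error(h_score(ihc_row(110, -10, 0, 0)), "non-negative")
})

test_that("H-score stays within bounds and collapses when all-high", {
  tab <- generate_ihc_table(synthetic_ihc_config(n_samples = 50, seed = 2))
  h <- h_score(tab)
  expect_true(all(h >= 0 & h <= 300))
  allhigh <- generate_ihc_table(synthetic_ihc_config(
    n_samples = 20, category_split = c(low = 0, medium = 0, high = 1),
    seed = 3))
  expect_equal(h_score(allhigh), 3 * allhigh$pct_positive_cells)
})

test_that("prevalence uses strict inequality and decreases with cutoff", {
  prev <- prevalence_at_cutoffs(c(0, 0.5, 2, 50, 90), 1)
  expect_equal(prev$prevalence, 60)
  # boundary: a sample exactly at the cutoff is not positive
  expect_equal(prevalence_at_cutoffs(c(0, 5, 10), 0)$prevalence, 100 * 2 / 3)
  expect_equal(prevalence_at_cutoffs(rep(100, 4), c(1, 50, 99))$prevalence,
               rep(100, 3))
  tab <- prevalence_at_cutoffs(runif(200, 0, 100), c(1, 5, 10, 25, 50))
  expect_true(all(diff(tab$prevalence) <= 0))
  expect_error(prevalence_at_cutoffs(numeric(0), 1), "empty")
  expect_error(prevalence_at_cutoffs(c(10, 120), 1), "\\[0, 100\\]")
})

test_that("identical compartments give null differences and p near 1", {
  tab <- do.call(rbind, lapply(1:6, function(i) {
    rbind(data.frame(sample_id = paste0("s", i), compartment = "tumor",
                     pct_negative = 50, pct_low = 20, pct_medium = 20,
                     pct_high = 10),
          data.frame(sample_id = paste0("s", i), compartment = "stroma",
                     pct_negative = 50, pct_low = 20, pct_medium = 20,
                     pct_high = 10))
  }))
  cc <- compartment_contrast(tab)
  expect_true(all(cc$differences$h_score_diff == 0))
  expect_true(all(cc$tests$p_value > 0.99))
})

test_that("a uniform tumor excess is recovered with a significant pair test", {
  set.seed(1)
  n <- 20
  mk <- function(comp, pos) data.frame(
    sample_id = sprintf("s%02d", 1:n), compartment = comp,
    pct_negative = 100 - pos, pct_low = pos, pct_medium = 0, pct_high = 0)
  tab <- rbind(mk("tumor", 30 + (1:n) %% 5), mk("stroma", 20 + (1:n) %% 5))
  cc <- compartment_contrast(tab)
  expect_equal(mean(cc$differences$pct_positive_diff), 10)
  p_sr <- cc$tests$p_value[cc$tests$measure == "pct_positive" &
                             cc$tests$method == "wilcoxon_signed_rank"]
  expect_lt(p_sr, 0.01)
})

test_that("incomplete samples are excluded and a lone pair reports NA tests", {
  tab <- rbind(ihc_row(40, 30, 20, 10),
               data.frame(sample_id = "s1", compartment = "stroma",
                          pct_negative = 80, pct_low = 10, pct_medium = 5,
                          pct_high = 5),
               data.frame(sample_id = "s2", compartment = "tumor",
                          pct_negative = 70, pct_low = 10, pct_medium = 10,
                          pct_high = 10))
  expect_warning(cc <- compartment_contrast(tab), "s2")
  expect_equal(nrow(cc$differences), 1)
  expect_true(all(is.na(cc$tests$p_value)))
})

test_that("median split uses the strict-greater rule with ties going low", {
  sp <- median_split(c(1, 2, 3, 4))
  expect_equal(as.character(sp), c("low", "low", "high", "high"))
  # odd n: the median observation itself goes low
  sp3 <- median_split(c(10, 20, 30))
  expect_equal(as.character(sp3), c("low", "low", "high"))
  expect_error(median_split(c(5, 5, 5)), "no stratification")
  expect_error(median_split(7), ">= 2")
  # negating values swaps the groups up to median-tied samples
  v <- c(3, 8, 1, 9, 4, 7)
  expect_equal(as.character(median_split(-v)),
               rev(levels(median_split(v)))[as.integer(median_split(v))])
})

test_that("four score quadrants map to the four TAM bins", {
  sc <- data.frame(sample_id = paste0("s", 1:4),
                   c1qc_score = c(1, 1, -1, -1),
                   spp1_score = c(-1, 1, 1, -1))
  bins <- assign_tam_bins(sc)
  expect_equal(as.character(bins$bin),
               c("C1QChi_SPP1lo", "C1QChi_SPP1hi", "C1QClo_SPP1hi",
                 "C1QClo_SPP1lo"))
  expect_equal(sort(as.vector(table(bins$bin))), rep(1L, 4))
})

test_that("TAM bins partition the samples and swap under score exchange", {
  set.seed(8)
  sc <- data.frame(sample_id = paste0("s", 1:101),
                   c1qc_score = rnorm(101), spp1_score = rnorm(101))
  bins <- assign_tam_bins(sc)
  expect_equal(sum(table(bins$bin)), 101)
  expect_false(anyNA(bins$bin))
  swapped <- assign_tam_bins(data.frame(sample_id = sc$sample_id,
                                        c1qc_score = sc$spp1_score,
                                        spp1_score = sc$c1qc_score))
  map <- c(C1QChi_SPP1lo = "C1QClo_SPP1hi", C1QClo_SPP1hi = "C1QChi_SPP1lo",
           C1QChi_SPP1hi = "C1QChi_SPP1hi", C1QClo_SPP1lo = "C1QClo_SPP1lo")
  expect_equal(as.character(swapped$bin),
               unname(map[as.character(bins$bin)]))
})

test_that("per-indication binning on one indication equals pooled binning", {
  set.seed(12)
  sc <- data.frame(sample_id = paste0("s", 1:40), c1qc_score = rnorm(40),
                   spp1_score = rnorm(40), indication = "HNSCC")
  pooled <- assign_tam_bins(sc, scope = "pooled")
  per <- assign_tam_bins(sc, scope = "per_indication")
  expect_equal(as.character(per$bin), as.character(pooled$bin))
  sc$spp1_score[3] <- NA
  expect_error(assign_tam_bins(sc), "s3")
})

test_that("group-comparison wrappers reproduce the standard tests", {
  # Mann-Whitney on fully separated triples: U = 0, exact p = 2 * 1/20
  r <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                      test = "mannwhitney")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  same <- suppressWarnings(
    compare_groups(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3),
                   test = "mannwhitney"))
  expect_gt(same$p_value, 0.99)
  set.seed(2)
  far <- compare_groups(c(rnorm(30), rnorm(30) + 10),
                        rep(c("a", "b"), each = 30), test = "t")
  expect_lt(far$p_value, 1e-6)
  expect_error(compare_groups(1:3, c("a", "b", "c")), "two groups")
  expect_error(compare_groups(1:3, c("a", "b", "b"), test = "t"), ">= 2")
  expect_error(compare_groups(1:5, c("a", "a", "a", "b", "b"),
                              test = "paired_t"), "equal group lengths")
})
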