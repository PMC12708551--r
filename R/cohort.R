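ihc_category_cols <- c("pct_negative", "pct_low", "pct_medium", "pct_high")

validate_ihc_rows <- function(table, tol = 1e-6) {
  miss <- setdiff(ihc_category_cols, names(table))
  if (length(miss)) stop("IHC table lacks column(s): ", paste(miss, collapse = ", "))
  pct <- as.matrix(table[, ihc_category_cols, drop = FALSE])
  if (any(pct < -tol)) stop("IHC category percentages must be non-negative")
  bad <- abs(rowSums(pct) - 100) > tol
  if (any(bad)) {
    stop("IHC category percentages must sum to 100; offending row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  invisible(table)
}

#' IHC H-score
#'
#' The standard pathology summary of staining-intensity categories:
#' `H = 0*pct_negative + 1*pct_low + 2*pct_medium + 3*pct_high`, ranging 0
#' (all negative) to 300 (all high).
#'
#' @param table IHC score table (rows validated: the four category
#'   percentages must be non-negative and sum to 100).
#' @return Numeric vector of H-scores, one per row.
#' @export
#' @examples
#' h_score(data.frame(pct_negative = 40, pct_low = 10,
#'                    pct_medium = 20, pct_high = 30))  # 140
h_score <- function(table) {
  validate_ihc_rows(table)
  as.numeric(1 * table$pct_low + 2 * table$pct_medium + 3 * table$pct_high)
}

#' Prevalence of positivity above cutoffs
#'
#' For each cutoff c, the percentage of samples whose percent-positive value
#' is *strictly* greater than c (matching the ">1%" convention for calling a
#' sample positive).
#'
#' @param pct_positive Per-sample percent-positive values in \[0, 100\].
#' @param cutoffs Cutoffs in \[0, 100).
#' @return Data frame with `cutoff` and `prevalence` (percentage).
#' @export
#' @examples
#' prevalence_at_cutoffs(c(0, 0.5, 2, 50, 90), 1)  # 60
prevalence_at_cutoffs <- function(pct_positive, cutoffs = c(1, 5, 10, 25, 50)) {
  if (length(pct_positive) == 0L) stop("empty sample set")
  if (any(pct_positive < 0 | pct_positive > 100)) {
    stop("pct_positive values must lie in [0, 100]")
  }
  if (any(cutoffs < 0 | cutoffs >= 100)) stop("cutoffs must lie in [0, 100)")
  data.frame(
    cutoff = cutoffs,
    prevalence = vapply(cutoffs,
                        function(co) 100 * mean(pct_positive > co),
                        numeric(1)))
}

ihc_pct_positive <- function(table) {
  if ("pct_positive_cells" %in% names(table)) {
    as.numeric(table$pct_positive_cells)
  } else {
    100 - as.numeric(table$pct_negative)
  }
}

#' Tumor-versus-stroma compartment contrast
#'
#' Computes per-sample tumor-minus-stroma differences of the H-score and the
#' percent-positive value, plus paired two-sided tests (t and Wilcoxon
#' signed-rank). Samples missing either compartment are excluded with a
#' warning; with fewer than two complete samples the tests are reported as
#' not applicable (NA p-values).
#'
#' @param table IHC score table with a `compartment` column containing
#'   `"tumor"` and `"stroma"` rows per sample.
#' @return List with `differences` (per-sample data frame) and `tests`
#'   (method, statistic, p_value).
#' @export
compartment_contrast <- function(table) {
  validate_ihc_rows(table)
  tab <- table
  tab$h_score <- h_score(tab)
  tab$pct_positive <- ihc_pct_positive(tab)
  tum <- tab[tab$compartment == "tumor", , drop = FALSE]
  str <- tab[tab$compartment == "stroma", , drop = FALSE]
  common <- intersect(tum$sample_id, str$sample_id)
  incomplete <- setdiff(unique(tab$sample_id), common)
  if (length(incomplete)) {
    warning("sample(s) missing a compartment, excluded: ",
            paste(incomplete, collapse = ", "))
  }
  if (length(common) == 0L) stop("no sample has both compartments")
  it <- match(common, tum$sample_id)
  is <- match(common, str$sample_id)
  diffs <- data.frame(
    sample_id = common,
    h_score_diff = tum$h_score[it] - str$h_score[is],
    pct_positive_diff = tum$pct_positive[it] - str$pct_positive[is],
    stringsAsFactors = FALSE)
  run_pair <- function(x, y, what) {
    d <- x - y
    tt <- wt <- list(statistic = NA_real_, p.value = NA_real_)
    if (length(d) >= 2L) {
      if (all(d == 0)) {
        # identical compartments: both tests exactly uninformative
        tt$p.value <- 1
        wt$p.value <- 1
      } else {
        # constant nonzero differences leave the t-test undefined (sd = 0)
        # but the signed-rank test well-defined
        if (sd(d) > 0) tt <- t.test(x, y, paired = TRUE)
        wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                           exact = FALSE))
      }
    }
    data.frame(measure = what,
               method = c("paired_t", "wilcoxon_signed_rank"),
               statistic = c(unname(tt$statistic) %||% NA_real_,
                             unname(wt$statistic) %||% NA_real_),
               p_value = c(tt$p.value, wt$p.value),
               stringsAsFactors = FALSE)
  }
  tests <- rbind(
    run_pair(tum$h_score[it], str$h_score[is], "h_score"),
    run_pair(tum$pct_positive[it], str$pct_positive[is], "pct_positive"))
  rownames(tests) <- NULL
  list(differences = diffs, tests = tests)
}

#' Median split into high and low groups
#'
#' `high` if and only if the value is strictly greater than the median;
#' values equal to the median go to `low` (fixed, documented tie rule), so
#' the group sizes can differ by at most the number of median-tied samples.
#'
#' @param values Numeric vector (>= 2 values, not all identical).
#' @param labels Optional sample labels used as names of the result.
#' @return Factor with levels `low`, `high`.
#' @export
#' @examples
#' median_split(c(1, 2, 3, 4))  # low low high high
median_split <- function(values, labels = NULL) {
  if (length(values) < 2L) stop("median split needs >= 2 samples")
  if (length(unique(values)) == 1L) {
    stop("all values identical: no stratification possible")
  }
  out <- factor(ifelse(values > median(values), "high", "low"),
                levels = c("low", "high"))
  if (!is.null(labels)) names(out) <- labels else names(out) <- names(values)
  out
}

tam_bin_levels <- c("C1QChi_SPP1lo", "C1QChi_SPP1hi", "C1QClo_SPP1hi",
                    "C1QClo_SPP1lo")

#' Assign samples to the four C1QC x SPP1 TAM bins
#'
#' Median splits of the C1QC and SPP1 signature scores define four bins
#' (C1QC-high:SPP1-low, C1QC-high:SPP1-high, C1QC-low:SPP1-high,
#' C1QC-low:SPP1-low) that partition the sample set. Medians are computed
#' over the pooled cohort or within each indication, per `scope`.
#'
#' @param scores Data frame with `sample_id`, `c1qc_score`, `spp1_score`,
#'   and (for per-indication scope) `indication`.
#' @param scope `"pooled"` or `"per_indication"`.
#' @return The input with a `bin` factor column and a `binning_scope`
#'   column; attribute `prevalence` holds the per-indication bin prevalence
#'   table (percentages).
#' @export
assign_tam_bins <- function(scores, scope = c("pooled", "per_indication")) {
  scope <- match.arg(scope)
  need <- c("sample_id", "c1qc_score", "spp1_score")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stop("scores table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(scores$c1qc_score) || anyNA(scores$spp1_score)) {
    bad <- scores$sample_id[is.na(scores$c1qc_score) | is.na(scores$spp1_score)]
    stop("missing score for sample(s): ", paste(bad, collapse = ", "))
  }
  groups <- if (scope == "per_indication") {
    if (!"indication" %in% names(scores)) {
      stop("per_indication scope needs an 'indication' column")
    }
    split(seq_len(nrow(scores)), scores$indication)
  } else {
    list(pooled = seq_len(nrow(scores)))
  }
  bin <- character(nrow(scores))
  for (idx in groups) {
    c1 <- median_split(scores$c1qc_score[idx])
    sp <- median_split(scores$spp1_score[idx])
    bin[idx] <- paste0("C1QC", ifelse(c1 == "high", "hi", "lo"),
                       "_SPP1", ifelse(sp == "high", "hi", "lo"))
  }
  out <- scores
  out$bin <- factor(bin, levels = tam_bin_levels)
  out$binning_scope <- scope
  prev <- if ("indication" %in% names(out)) {
    tb <- table(out$indication, out$bin)
    as.data.frame(100 * prop.table(tb, 1), stringsAsFactors = FALSE,
                  responseName = "prevalence") |>
      stats::setNames(c("indication", "bin", "prevalence"))
  } else {
    data.frame(indication = "all", bin = tam_bin_levels,
               prevalence = as.numeric(100 * prop.table(table(out$bin))[tam_bin_levels]),
               stringsAsFactors = FALSE)
  }
  attr(out, "prevalence") <- prev
  out
}

#' Two-group comparison wrappers
#'
#' Thin plumbing over the standard two-sided tests used in cohort figure
#' panels: Student t, Mann-Whitney U (Wilcoxon rank-sum), paired t, and
#' Wilcoxon signed-rank.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector with exactly two levels (for paired tests,
#'   observations are paired by order within group).
#' @param test One of `"t"`, `"mannwhitney"`, `"paired_t"`, `"wilcoxon"`.
#' @return List with `test`, `statistic`, `p_value`, `n`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
#'                test = "mannwhitney")
compare_groups <- function(values, groups,
                           test = c("t", "mannwhitney", "paired_t", "wilcoxon")) {
  test <- match.arg(test)
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  paired <- test %in% c("paired_t", "wilcoxon")
  if (paired && length(x) != length(y)) {
    stop("paired tests need equal group lengths")
  }
  if (test %in% c("t", "paired_t") && (length(x) < 2L || length(y) < 2L)) {
    stop("t-tests need >= 2 observations per group")
  }
  res <- switch(test,
    t = t.test(x, y, alternative = "two.sided"),
    paired_t = t.test(x, y, paired = TRUE, alternative = "two.sided"),
    mannwhitney = wilcox.test(x, y, alternative = "two.sided"),
    wilcoxon = wilcox.test(x, y, paired = TRUE, alternative = "two.sided"))
  list(test = test, statistic = unname(res$statistic),
       p_value = res$p.value, n = c(length(x), length(y)))
}
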