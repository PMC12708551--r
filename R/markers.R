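#' Differential marker table: one cell type against all others
#'
#' Two-sided Wilcoxon rank-sum test per gene comparing cells of the target
#' label against all remaining cells, with Benjamini-Hochberg adjustment and
#' a pseudocount-stabilized log2 fold change of means. Rows are sorted by
#' descending log2 fold change (ties: ascending adjusted p, then gene).
#'
#' @param matrix Genes x cells expression matrix.
#' @param annotation Data frame with `cell_id`, `cell_type` covering the
#'   matrix columns.
#' @param target Target cell-type label (>= 3 cells required on each side).
#' @param pseudocount Added to both means before the log ratio (default 1,
#'   TPM-like scale).
#' @return Data frame with `gene`, `log2_fold_change`, `rank_statistic` (the
#'   Wilcoxon W for target vs rest), `p_value`, `adjusted_p`,
#'   `pct_expressing_target`, `pct_expressing_rest`.
#' @export
differential_markers <- function(matrix, annotation, target, pseudocount = 1) {
  m <- as.matrix(matrix)
  types <- annotation$cell_type[match(colnames(m), annotation$cell_id)]
  if (anyNA(types)) stop("annotation does not cover every matrix column")
  if (!target %in% types) stop("unknown target label: ", target)
  in_target <- types == target
  if (sum(in_target) < 3L || sum(!in_target) < 3L) {
    stop("need >= 3 cells in the target group and >= 3 outside it")
  }
  tg <- m[, in_target, drop = FALSE]
  bg <- m[, !in_target, drop = FALSE]
  mean_t <- rowMeans(tg)
  mean_r <- rowMeans(bg)
  stats_p <- t(vapply(seq_len(nrow(m)), function(i) {
    x <- tg[i, ]
    y <- bg[i, ]
    if (length(unique(c(x, y))) == 1L) return(c(length(x) * length(y) / 2, 1))
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                       exact = FALSE, correct = TRUE))
    c(unname(wt$statistic), wt$p.value)
  }, numeric(2)))
  p <- stats_p[, 2]
  p[is.na(p)] <- 1
  out <- data.frame(
    gene = rownames(m) %||% as.character(seq_len(nrow(m))),
    log2_fold_change = log2((mean_t + pseudocount) / (mean_r + pseudocount)),
    rank_statistic = stats_p[, 1],
    p_value = p,
    adjusted_p = p.adjust(p, method = "BH"),
    pct_expressing_target = rowMeans(tg > 0),
    pct_expressing_rest = rowMeans(bg > 0),
    stringsAsFactors = FALSE)
  out <- out[order(-out$log2_fold_change, out$adjusted_p, out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-cell-type mean expression profile
#'
#' Builds the reference table the specificity filter consumes: mean raw
#' expression of every gene in every annotated cell type. Real atlas exports
#' in the same gene x cell-type TSV layout can be used interchangeably.
#'
#' @inheritParams differential_markers
#' @return Numeric matrix, genes x cell types.
#' @export
reference_profile <- function(matrix, annotation) {
  m <- as.matrix(matrix)
  types <- annotation$cell_type[match(colnames(m), annotation$cell_id)]
  if (anyNA(types)) stop("annotation does not cover every matrix column")
  labs <- unique(types)
  out <- vapply(labs, function(lab) rowMeans(m[, types == lab, drop = FALSE]),
                numeric(nrow(m)))
  rownames(out) <- rownames(m)
  out
}

#' Specificity filter against reference cell-type profiles
#'
#' Retains candidate markers that are minimally expressed in non-macrophage
#' cell types and at most modestly expressed in macrophage types other than
#' the target, in *every* supplied reference: the maximal non-macrophage mean
#' must be <= `max_nonmac_fraction` x the target-type mean, and the maximal
#' other-macrophage mean <= `max_other_mac_fraction` x the target mean.
#' Candidate order is preserved; removed genes are reported with the violated
#' rule and reference in the `removed` attribute.
#'
#' @param markers Marker table from [differential_markers()] (or any data
#'   frame with a `gene` column).
#' @param references Named list of gene x cell-type mean matrices (see
#'   [reference_profile()]).
#' @param target Target cell-type label, present in every reference.
#' @param mac_labels Labels counted as macrophages (target included).
#' @param max_nonmac_fraction,max_other_mac_fraction Thresholds as fractions
#'   of the target-type mean; `Inf` disables a rule.
#' @param missing_policy What to do with a candidate absent from a reference:
#'   `"drop"` (default) or `"keep"` with a warning.
#' @return The filtered marker table (original order), with attribute
#'   `removed`: a data frame of `gene`, `reference`, `rule`.
#' @export
specificity_filter <- function(markers, references, target,
                               mac_labels = c("Mac_general", "Mac_C1QC", "Mac_SPP1"),
                               max_nonmac_fraction = 0.1,
                               max_other_mac_fraction = 0.5,
                               missing_policy = c("drop", "keep")) {
  missing_policy <- match.arg(missing_policy)
  if (!is.list(references) || length(references) == 0L) {
    stop("at least one reference profile is required")
  }
  if (is.null(names(references))) {
    names(references) <- paste0("reference", seq_along(references))
  }
  removed <- list()
  keep <- rep(TRUE, nrow(markers))
  for (ref_name in names(references)) {
    ref <- as.matrix(references[[ref_name]])
    if (!target %in% colnames(ref)) {
      stop("reference '", ref_name, "' lacks the target label ", target)
    }
    other_mac <- intersect(setdiff(mac_labels, target), colnames(ref))
    nonmac <- setdiff(colnames(ref), mac_labels)
    idx <- match(toupper(markers$gene), toupper(rownames(ref)))
    for (i in seq_len(nrow(markers))) {
      if (!keep[i]) next
      if (is.na(idx[i])) {
        if (missing_policy == "drop") {
          keep[i] <- FALSE
          removed[[length(removed) + 1L]] <- data.frame(
            gene = markers$gene[i], reference = ref_name,
            rule = "absent from reference", stringsAsFactors = FALSE)
        } else {
          warning("gene ", markers$gene[i], " absent from reference ",
                  ref_name, "; kept")
        }
        next
      }
      tmean <- ref[idx[i], target]
      fail_nonmac <- is.finite(max_nonmac_fraction) && length(nonmac) &&
        max(ref[idx[i], nonmac]) > max_nonmac_fraction * tmean
      fail_othermac <- is.finite(max_other_mac_fraction) && length(other_mac) &&
        max(ref[idx[i], other_mac]) > max_other_mac_fraction * tmean
      if (fail_nonmac || fail_othermac) {
        keep[i] <- FALSE
        removed[[length(removed) + 1L]] <- data.frame(
          gene = markers$gene[i], reference = ref_name,
          rule = if (fail_nonmac) "non-macrophage expression"
                 else "other-macrophage expression",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- markers[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- if (length(removed)) do.call(rbind, removed) else
    data.frame(gene = character(0), reference = character(0),
               rule = character(0), stringsAsFactors = FALSE)
  out
}

# Rank-based AUROC of `score` for separating positives from the rest;
# equivalent to the Mann-Whitney U statistic scaled to [0, 1].
auroc <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validate a signature on annotated single-cell datasets
#'
#' Scores every cell (mean z-score across cells), summarizes the score
#' distribution by cell type, and reports the AUROC with which the score
#' separates target cells from all others in each dataset, flagged against a
#' configurable floor. Datasets lacking the target label are skipped with a
#' warning.
#'
#' @param signature A [gene_signature()].
#' @param datasets Named list of `list(matrix =, annotation =)` datasets.
#' @param target Target cell-type label.
#' @param auroc_floor Pass/fail floor for the AUROC.
#' @param log_transform Passed to [zscore_by_gene()].
#' @return Data frame with one row per evaluated dataset (`dataset`,
#'   `n_cells`, `n_target`, `auroc`, `pass`), with attribute `by_type`: per
#'   dataset, mean/sd of the per-cell score by cell type.
#' @export
cross_validate <- function(signature, datasets, target, auroc_floor = 0.8,
                           log_transform = TRUE) {
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  by_type <- list()
  rows <- list()
  for (nm in names(datasets)) {
    ds <- datasets[[nm]]
    types <- ds$annotation$cell_type[match(colnames(ds$matrix),
                                           ds$annotation$cell_id)]
    if (!target %in% types) {
      warning("dataset '", nm, "' lacks target label ", target, "; skipped")
      next
    }
    sc <- score_signature(ds$matrix, signature, log_transform = log_transform)
    a <- auroc(sc$score, types == target)
    by_type[[nm]] <- do.call(rbind, lapply(split(sc$score, types), function(v) {
      data.frame(mean = mean(v), sd = sd(v), n = length(v))
    }))
    rows[[nm]] <- data.frame(
      dataset = nm, n_cells = length(types), n_target = sum(types == target),
      auroc = a, pass = a >= auroc_floor, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dataset = character(0), n_cells = integer(0),
               n_target = integer(0), auroc = numeric(0), pass = logical(0))
  rownames(out) <- NULL
  attr(out, "by_type") <- by_type
  out
}
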