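#' Pseudo-bulk spike-in design
#'
#' Describes the spike-in grid used to validate signature sensitivity: low
#' fractions (0 to 2.5% by default) of each spiked macrophage type are mixed
#' into a fixed background of non-macrophage cell types, emulating bulk
#' RNA-seq samples with high tumor content and low immune abundance.
#'
#' @param spike_fractions Spike fractions, including 0 (default six evenly
#'   spaced points over 0-2.5%).
#' @param spiked_types Cell types spiked in (default the general macrophage
#'   and both TAM subsets).
#' @param background_composition Named fractions over non-macrophage labels,
#'   summing to 1. The default (Tumor 0.6, Stroma 0.25, Tcell 0.15) mimics a
#'   tumor-cell-rich resection specimen.
#' @param cells_per_sample Cells pooled per pseudo-bulk sample.
#' @param replicates Replicates per (type, fraction).
#' @param mac_labels Labels counted as macrophages (must not appear in the
#'   background).
#' @param shared_zero Share the fraction-0 samples across spiked types
#'   (default) instead of generating them per type.
#' @param include_control Also generate a background-only control arm whose
#'   "spiked" cells are themselves drawn from the background mixture.
#' @param seed Integer seed; per-sample substreams are derived from it.
#' @return A validated `tam_pseudobulk_design` list.
#' @export
pseudobulk_design <- function(
    spike_fractions = c(0, 0.005, 0.01, 0.015, 0.02, 0.025),
    spiked_types = c("Mac_general", "Mac_C1QC", "Mac_SPP1"),
    background_composition = c(Tumor = 0.6, Stroma = 0.25, Tcell = 0.15),
    cells_per_sample = 1000L,
    replicates = 10L,
    mac_labels = c("Mac_general", "Mac_C1QC", "Mac_SPP1"),
    shared_zero = TRUE,
    include_control = TRUE,
    seed = 1L) {
  if (any(spike_fractions < 0 | spike_fractions > 1)) {
    stop("spike fractions must lie in [0, 1]")
  }
  if (!0 %in% spike_fractions) {
    stop("the spike-fraction grid must include 0")
  }
  if (abs(sum(background_composition) - 1) > 1e-9) {
    stop("background_composition must sum to 1")
  }
  if (any(names(background_composition) %in% mac_labels)) {
    stop("background_composition must not contain macrophage labels")
  }
  if (cells_per_sample < 1L || replicates < 1L) {
    stop("cells_per_sample and replicates must be positive")
  }
  structure(list(
    spike_fractions = sort(unique(spike_fractions)),
    spiked_types = spiked_types,
    background_composition = background_composition,
    cells_per_sample = as.integer(cells_per_sample),
    replicates = as.integer(replicates),
    mac_labels = mac_labels, shared_zero = isTRUE(shared_zero),
    include_control = isTRUE(include_control), seed = as.integer(seed)),
    class = "tam_pseudobulk_design")
}

# Deterministic integer allocation of n cells over fractional composition:
# floor, then distribute the remainder by largest fractional part (ties by
# position).
allocate_counts <- function(n, composition) {
  raw <- n * composition
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    add <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  stats::setNames(as.integer(base), names(composition))
}

control_arm_label <- "Background"

#' Build pseudo-bulk spike-in samples from annotated single cells
#'
#' For each (spiked type, fraction, replicate), draws
#' `round(fraction * cells_per_sample)` cells of the spiked type and fills
#' the remainder from the background composition, then aggregates the drawn
#' cells by per-gene mean (so profiles reflect composition, not depth).
#' Sampling is with replacement whenever a type holds fewer cells than
#' requested, and this is recorded in the metadata.
#'
#' @param matrix Genes x cells expression matrix.
#' @param annotation Cell annotation (`cell_id`, `cell_type`).
#' @param design A [pseudobulk_design()].
#' @return List with `matrix` (genes x pseudo-bulk samples) and `metadata`
#'   (one row per sample: `sample_id`, `spiked_type`, `fraction`,
#'   `replicate`, `n_spiked`, `n_background`, `with_replacement`).
#' @export
make_pseudobulk <- function(matrix, annotation, design) {
  m <- as.matrix(matrix)
  types <- annotation$cell_type[match(colnames(m), annotation$cell_id)]
  if (anyNA(types)) stop("annotation does not cover every matrix column")
  needed <- c(design$spiked_types, names(design$background_composition))
  absent <- setdiff(needed, types)
  if (length(absent)) stop("cell type(s) absent from annotation: ",
                           paste(absent, collapse = ", "))
  idx_by_type <- split(seq_len(ncol(m)), types)
  N <- design$cells_per_sample

  draw_cells <- function(type_counts, rng_seed) {
    withr::with_seed(rng_seed, {
      unlist(lapply(names(type_counts), function(lab) {
        k <- type_counts[[lab]]
        if (k == 0L) return(integer(0))
        pool <- idx_by_type[[lab]]
        sample(pool, k, replace = k > length(pool))
      }), use.names = FALSE)
    })
  }

  arms <- design$spiked_types
  if (design$include_control) arms <- c(arms, control_arm_label)
  profiles <- list()
  meta <- list()
  add_sample <- function(sid, arm, f, rep_i, n_spike, counts) {
    cells <- draw_cells(counts, derive_seed(design$seed, sid))
    profiles[[sid]] <<- rowMeans(m[, cells, drop = FALSE])
    wr <- any(vapply(names(counts), function(lab) {
      counts[[lab]] > length(idx_by_type[[lab]])
    }, logical(1)))
    meta[[sid]] <<- data.frame(
      sample_id = sid, spiked_type = arm, fraction = f, replicate = rep_i,
      n_spiked = n_spike, n_background = N - n_spike,
      with_replacement = wr, stringsAsFactors = FALSE)
  }

  if (design$shared_zero) {
    for (r in seq_len(design$replicates)) {
      sid <- sprintf("none_f0_r%02d", r)
      add_sample(sid, "none", 0, r, 0L,
                 allocate_counts(N, design$background_composition))
    }
  }
  for (arm in arms) {
    for (f in design$spike_fractions) {
      if (f == 0 && design$shared_zero) next
      n_spike <- as.integer(round(f * N))
      if (f > 0 && n_spike == 0L) {
        warning("fraction ", f, " rounds to 0 spiked cells at ",
                "cells_per_sample = ", N)
      }
      bg_counts <- allocate_counts(N - n_spike, design$background_composition)
      for (r in seq_len(design$replicates)) {
        sid <- sprintf("%s_f%g_r%02d", arm, f, r)
        counts <- bg_counts
        if (n_spike > 0L) {
          if (arm == control_arm_label) {
            # control: the "spike" is more background, keeping totals equal
            counts <- allocate_counts(N, design$background_composition)
          } else {
            counts <- c(stats::setNames(n_spike, arm), bg_counts)
          }
        }
        add_sample(sid, arm, f, r, if (arm == control_arm_label) 0L else n_spike,
                   counts)
      }
    }
  }
  mat <- do.call(cbind, profiles)
  rownames(mat) <- rownames(m)
  md <- do.call(rbind, meta)
  rownames(md) <- NULL
  list(matrix = mat, metadata = md)
}

#' Evaluate signature response to spike-in fractions
#'
#' Joins per-sample signature scores to the spike-in metadata and, for each
#' signature x spiked type, computes per-fraction mean scores, the Spearman
#' correlation of mean score with fraction, and the least-squares slope of
#' score on fraction expressed per percentage point. A signature is declared
#' specific for the spiked type whose slope ranks first among the
#' (non-control) arms.
#'
#' @param scores Long score table from [score_signatures()].
#' @param metadata Pseudo-bulk metadata from [make_pseudobulk()].
#' @return Data frame with `signature`, `spiked_type`, `rho`,
#'   `slope_per_pct`, `specific`; attribute `fraction_means` holds the
#'   per-fraction mean scores.
#' @export
evaluate_signature <- function(scores, metadata) {
  df <- merge(scores, metadata, by = "sample_id")
  if (length(unique(df$fraction)) < 2L) {
    stop("need >= 2 distinct spike fractions to estimate a trend")
  }
  arms <- setdiff(unique(df$spiked_type), "none")
  shared0 <- df[df$spiked_type == "none" & df$fraction == 0, , drop = FALSE]
  rows <- list()
  fr_means <- list()
  for (sig in unique(df$signature)) {
    for (arm in arms) {
      sub <- df[df$signature == sig & df$spiked_type == arm, , drop = FALSE]
      s0 <- shared0[shared0$signature == sig, , drop = FALSE]
      sub <- rbind(sub, s0)
      if (length(unique(sub$fraction)) < 2L) {
        stop("arm '", arm, "' has a single fraction; no trend estimable")
      }
      fm <- tapply(sub$score, sub$fraction, mean)
      fr <- as.numeric(names(fm))
      rho <- suppressWarnings(cor(fr, as.numeric(fm), method = "spearman"))
      slope <- unname(coef(lm(score ~ I(fraction * 100), data = sub))[2])
      rows[[paste(sig, arm)]] <- data.frame(
        signature = sig, spiked_type = arm, rho = rho,
        slope_per_pct = slope, stringsAsFactors = FALSE)
      fr_means[[paste(sig, arm, sep = "|")]] <-
        data.frame(signature = sig, spiked_type = arm, fraction = fr,
                   mean_score = as.numeric(fm), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$specific <- FALSE
  for (sig in unique(out$signature)) {
    sel <- out$signature == sig & out$spiked_type != control_arm_label
    best <- which(sel)[which.max(out$slope_per_pct[sel])]
    out$specific[best] <- TRUE
  }
  attr(out, "fraction_means") <- do.call(rbind, fr_means)
  out
}

#' Run the full pseudo-bulk spike-in validation
#'
#' Builds the pseudo-bulk samples, scores every signature on the pseudo-bulk
#' set (z-scores computed across the pseudo-bulk samples themselves), and
#' summarizes sensitivity/specificity per signature x spiked type.
#'
#' @inheritParams make_pseudobulk
#' @param signatures List of [gene_signature()] objects (non-empty).
#' @param log_transform Passed to the scorer.
#' @return List with `report` (from [evaluate_signature()]), `scores`,
#'   `metadata`, and the pseudo-bulk `matrix`.
#' @export
run_validation <- function(matrix, annotation, signatures, design,
                           log_transform = TRUE) {
  signatures <- as_signature_list(signatures)
  pb <- make_pseudobulk(matrix, annotation, design)
  scores <- score_signatures(pb$matrix, signatures,
                             log_transform = log_transform)
  report <- evaluate_signature(scores, pb$metadata)
  list(report = report, scores = scores, metadata = pb$metadata,
       matrix = pb$matrix)
}
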