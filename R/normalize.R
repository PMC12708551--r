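#' Quantile normalization across samples
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' rank-k normalized value is the mean of the rank-k raw values across
#' samples, with ties within a sample receiving the mean of their target
#' values. Delegates to [limma::normalizeQuantiles()] (`ties = TRUE`), the
#' standard implementation for bulk expression matrices.
#'
#' @param matrix Non-negative genes x samples numeric matrix with at least
#'   two samples.
#' @return Matrix of the same dimensions and dimnames.
#' @export
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
quantile_normalize <- function(matrix) {
  m <- as.matrix(matrix)
  if (!is.numeric(m)) stop("expression matrix must be numeric")
  if (ncol(m) < 2L) stop("quantile normalization needs >= 2 samples")
  if (any(m < 0, na.rm = TRUE)) stop("expression matrix must be non-negative")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Per-gene z-score transform
#'
#' Standardizes each gene across samples to mean 0, sd 1 (sample sd,
#' denominator n-1). By default values are log2(x + 1) transformed first,
#' which is standard for TPM-like data and protects the downstream mean
#' z-score from heavy right tails. Zero-variance genes cannot be
#' standardized; they are dropped with a warning and recorded in the
#' `genes_dropped_zero_variance` attribute.
#'
#' @param matrix Genes x samples numeric matrix, >= 2 samples.
#' @param log_transform Apply log2(x + 1) before standardizing.
#' @return Z-score matrix over the retained genes, with attribute
#'   `genes_dropped_zero_variance`.
#' @export
zscore_by_gene <- function(matrix, log_transform = TRUE) {
  m <- as.matrix(matrix)
  if (ncol(m) < 2L) stop("z-scoring needs >= 2 samples")
  if (isTRUE(log_transform)) m <- log2(m + 1)
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  dropped <- rownames(m)[s == 0] %||% character(0)
  if (is.null(rownames(m)) && any(s == 0)) dropped <- which(s == 0)
  if (length(dropped)) {
    warning(length(dropped), " zero-variance gene(s) dropped from z-scoring: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
  }
  keep <- s > 0
  z <- (m[keep, , drop = FALSE] - mu[keep]) / s[keep]
  attr(z, "genes_dropped_zero_variance") <- dropped
  z
}

#' Mean z-score signature scoring
#'
#' Scores each sample as the mean, over the signature genes present and
#' non-constant in the matrix, of the per-gene z-score. Gene symbol matching
#' is case-insensitive exact match. Missing genes are reported, never
#' silently ignored. By construction the scores for one signature have mean
#' ~0 across the scored sample set.
#'
#' @param matrix Genes x samples matrix (already normalized as desired).
#' @param signature A [gene_signature()].
#' @param log_transform Passed to [zscore_by_gene()].
#' @param zscores Optional precomputed z-score matrix (as returned by
#'   [zscore_by_gene()]); when supplied, `matrix`/`log_transform` are ignored.
#' @return Data frame with `sample_id`, `signature`, `score`,
#'   `n_genes_used`, plus attributes `genes_missing` and
#'   `genes_dropped_zero_variance`.
#' @export
score_signature <- function(matrix, signature, log_transform = TRUE,
                            zscores = NULL) {
  sig <- if (inherits(signature, "tam_signature")) signature else
    gene_signature("signature", signature)
  if (is.null(zscores)) {
    zscores <- suppressWarnings(zscore_by_gene(matrix, log_transform))
  }
  dropped_zero <- attr(zscores, "genes_dropped_zero_variance") %||% character(0)
  rn <- toupper(rownames(zscores))
  hit <- match(sig$genes, rn)
  missing <- sig$genes[is.na(hit)]
  missing_present_but_constant <- intersect(sig$genes, toupper(dropped_zero))
  missing <- setdiff(missing, missing_present_but_constant)
  used <- hit[!is.na(hit)]
  if (length(used) == 0L) {
    stop("no signature genes found in matrix for '", sig$name, "': ",
         paste(sig$genes, collapse = ", "))
  }
  score <- colMeans(zscores[used, , drop = FALSE])
  out <- data.frame(
    sample_id = colnames(zscores) %||% as.character(seq_along(score)),
    signature = sig$name, score = as.numeric(score),
    n_genes_used = length(used), stringsAsFactors = FALSE)
  if (length(missing)) {
    warning("signature '", sig$name, "': genes missing from matrix: ",
            paste(missing, collapse = ", "))
  }
  attr(out, "genes_missing") <- missing
  attr(out, "genes_dropped_zero_variance") <- missing_present_but_constant
  rownames(out) <- NULL
  out
}

#' Score several signatures on one matrix
#'
#' Computes the z-score matrix once and scores each signature against it,
#' returning a long table. Signatures with no genes in the matrix raise an
#' error (as in [score_signature()]).
#'
#' @inheritParams score_signature
#' @param signatures List of [gene_signature()] objects.
#' @param quantile_normalize Quantile-normalize the matrix first.
#' @return Long data frame of per-sample scores for every signature.
#' @export
score_signatures <- function(matrix, signatures, log_transform = TRUE,
                             quantile_normalize = FALSE) {
  signatures <- as_signature_list(signatures)
  m <- as.matrix(matrix)
  if (isTRUE(quantile_normalize)) m <- quantile_normalize(m)
  z <- suppressWarnings(zscore_by_gene(m, log_transform))
  do.call(rbind, lapply(signatures, function(s) {
    score_signature(zscores = z, signature = s, matrix = NULL)
  }))
}
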