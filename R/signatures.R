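#' Construct a gene signature
#'
#' A gene signature is a named, ordered list of gene symbols. Symbols are
#' case-normalized to upper case and must be unique after normalization.
#'
#' @param name Signature name (single string).
#' @param genes Character vector of gene symbols, non-empty.
#' @return An object of class `tam_signature` with elements `name` and `genes`.
#' @export
#' @examples
#' gene_signature("CD8", c("CD8A", "CD8B", "GZMB"))
gene_signature <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- toupper(as.character(genes))
  if (length(genes) == 0L) stop("signature '", name, "': gene list is empty")
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("signature '", name, "': duplicate genes removed: ",
            paste(dup, collapse = ", "))
    genes <- genes[!duplicated(genes)]
  }
  structure(list(name = name, genes = genes), class = "tam_signature")
}

#' @export
print.tam_signature <- function(x, ...) {
  cat("<tam_signature> ", x$name, " (", length(x$genes), " genes): ",
      paste(x$genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Built-in TAM and T-cell gene signatures
#'
#' Returns the five signatures used throughout the workflow:
#' \describe{
#'   \item{C1QC}{Phagocytosis-associated C1QC TAM markers:
#'     APOE, C1QC, C1QB, C1QA, TREM2, MRC1, CD163, MERTK.}
#'   \item{SPP1_new}{Macrophage-specific SPP1 TAM signature:
#'     PLAUR, SLC11A1, BRI3, FBP1, C15orf48.}
#'   \item{SPP1_Zhang}{Literature SPP1 TAM markers (also expressed by tumor
#'     and stromal cells, hence less suitable for bulk deconvolution):
#'     SPP1, PPARG, ADM, MARCO, VEGFA, VCAN, CXCL8, ANGPTL4.}
#'   \item{CD8}{CD8 T lymphocyte signature: CD8A, CD8B, GZMB.}
#'   \item{Trm}{Tissue-resident memory T-cell signature:
#'     CD8A, ITGAE (CD103), ZNF683 (HOBIT).}
#' }
#'
#' @return Named list of [gene_signature()] objects.
#' @export
builtin_signatures <- function() {
  sigs <- list(
    gene_signature("C1QC",
      c("APOE", "C1QC", "C1QB", "C1QA", "TREM2", "MRC1", "CD163", "MERTK")),
    gene_signature("SPP1_new",
      c("PLAUR", "SLC11A1", "BRI3", "FBP1", "C15orf48")),
    gene_signature("SPP1_Zhang",
      c("SPP1", "PPARG", "ADM", "MARCO", "VEGFA", "VCAN", "CXCL8", "ANGPTL4")),
    gene_signature("CD8", c("CD8A", "CD8B", "GZMB")),
    gene_signature("Trm", c("CD8A", "ITGAE", "ZNF683"))
  )
  stats::setNames(sigs, vapply(sigs, `[[`, "", "name"))
}

#' Read gene signatures from a GMT file
#'
#' GMT dialect: one signature per line, tab-separated, with at least three
#' fields (name, description, genes...). Duplicate genes within a signature
#' are removed with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of [gene_signature()] objects.
#' @export
read_signatures_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop("GMT parse error at line ", i,
           ": expected at least 3 tab-separated fields (name, description, genes)")
    }
    gene_signature(fields[[1]], fields[-(1:2)])
  })
  stats::setNames(sigs, vapply(sigs, `[[`, "", "name"))
}

#' Write gene signatures to a GMT file
#'
#' @param signatures List of [gene_signature()] objects.
#' @param path Output path.
#' @param description Description field written for every signature.
#' @return `path`, invisibly.
#' @export
write_signatures_gmt <- function(signatures, path, description = "tamsig") {
  if (inherits(signatures, "tam_signature")) signatures <- list(signatures)
  lines <- vapply(signatures, function(s) {
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

as_signature_list <- function(signatures) {
  if (inherits(signatures, "tam_signature")) signatures <- list(signatures)
  if (length(signatures) == 0L) stop("empty signature list")
  lapply(signatures, function(s) {
    if (!inherits(s, "tam_signature")) stop("not a tam_signature object")
    s
  })
}
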