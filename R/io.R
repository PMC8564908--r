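#' Median-center a raw expression matrix on the log2 scale
#'
#' Applies the standard normalization for downstream clustering and
#' classification: each feature is divided by its median across samples and
#' the ratio is log2-transformed, so every feature has median 0. Zeros
#' (common in FPKM input) are handled by adding, per feature, a pseudocount
#' of half the smallest nonzero value before transforming; features whose
#' median is still 0 (all-zero features) are dropped with a warning.
#'
#' @param raw nonnegative numeric matrix, samples as rows and features as
#'   columns (the on-disk layout), with full dimnames.
#' @param modality `"protein"` or `"mrna"`.
#' @param geneMap optional named character feature-to-symbol map.
#' @return A [ProfileMatrix-class] (features as rows).
#' @examples
#' raw <- matrix(c(1, 2, 4, 10, 20, 40), nrow = 3,
#'               dimnames = list(paste0("s", 1:3), c("gA", "gB")))
#' assay(medianCenterLog2(raw, "mrna"))
#' @export
medianCenterLog2 <- function(raw, modality = c("protein", "mrna"),
                             geneMap = NULL) {
  modality <- match.arg(modality)
  if (!is.matrix(raw) || !is.numeric(raw))
    inputError("'raw' must be a numeric matrix (samples x features)")
  if (anyNA(raw))
    inputError("'raw' contains missing values; strict mode rejects NA")
  if (any(raw < 0))
    inputError("'raw' must be nonnegative")
  if (is.null(rownames(raw)) || is.null(colnames(raw)))
    inputError("'raw' must have sample rownames and feature colnames")
  x <- t(raw)                                   # features x samples
  keep <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    if (any(v == 0) && any(v > 0))
      v <- v + min(v[v > 0]) / 2
    med <- median(v)
    if (med > 0) {
      x[i, ] <- log2(v / med)
      keep[i] <- TRUE
    }
  }
  if (!all(keep))
    warning(sprintf("dropped %d feature(s) with zero median: %s",
                    sum(!keep),
                    paste(head(rownames(x)[!keep], 5), collapse = ", ")))
  if (!any(keep))
    degenerateError("no feature has a positive median")
  ProfileMatrix(x[keep, , drop = FALSE], modality, geneMap = geneMap)
}

#' Pair protein features with mRNA genes for a biomarker set
#'
#' Restricts a biomarker set to features measurable in both modalities by
#' mapping protein probes to gene symbols and matching them against the
#' mRNA matrix. Features lacking a gene symbol (e.g. phospho-probes or
#' non-protein epitopes) or absent from the mRNA matrix are excluded and
#' reported in the `excluded` attribute.
#'
#' @param protein,mrna [ProfileMatrix-class] objects.
#' @param set a [BiomarkerSet-class] or character vector of protein feature
#'   IDs (default: all protein features).
#' @return data.frame with columns `protein_feature`, `gene_symbol`,
#'   `mrna_feature`; excluded features in `attr(, "excluded")`.
#' @export
matchFeatures <- function(protein, mrna, set = rownames(protein)) {
  if (!is(protein, "ProfileMatrix") || !is(mrna, "ProfileMatrix"))
    inputError("'protein' and 'mrna' must be ProfileMatrix objects")
  features <- if (is(set, "BiomarkerSet")) set@features else as.character(set)
  if (!length(features))
    inputError("'set' is empty")
  missing_f <- setdiff(features, rownames(protein))
  if (length(missing_f))
    inputError(sprintf("set feature(s) not in protein matrix: %s",
                       paste(head(missing_f, 5), collapse = ", ")))
  gm <- geneMap(protein)[features]
  matched <- !is.na(gm) & gm %in% rownames(mrna)
  pairs <- data.frame(protein_feature = features[matched],
                      gene_symbol = unname(gm[matched]),
                      mrna_feature = unname(gm[matched]),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0)
    degenerateError(
      "no set feature maps to the mRNA matrix; cross-modality evaluation impossible")
  attr(pairs, "excluded") <- features[!matched]
  pairs
}

#' Read and write pipeline tables
#'
#' Plain-text round-trip I/O for every table the pipeline consumes or
#' produces. Expression matrices are TSV with samples as rows (first column
#' `sample_id`) and features as columns; metadata, growth records and
#' per-cell IHC tables are CSV. `readProfile` verifies the
#' median-centering invariant unless `strict = FALSE`, and always rejects
#' missing values.
#'
#' @param x object to write.
#' @param path file path.
#' @param modality,geneMap passed to [ProfileMatrix()] on read.
#' @param strict logical; check per-feature medians are 0 (tolerance 1e-6).
#' @return `readProfile` a [ProfileMatrix-class]; the other readers
#'   data.frames; writers return `path` invisibly.
#' @name profile-io
NULL

#' @rdname profile-io
#' @export
writeProfile <- function(x, path) {
  stopifnot(is(x, "ProfileMatrix"))
  df <- data.frame(sample_id = colnames(x),
                   t(SummarizedExperiment::assay(x, "exprs")),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname profile-io
#' @export
readProfile <- function(path, modality = c("protein", "mrna"),
                        geneMap = NULL, strict = TRUE) {
  modality <- match.arg(modality)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    inputError("expression TSV must have a 'sample_id' first column")
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  if (anyNA(m))
    inputError("expression TSV contains missing values")
  x <- t(m)
  if (strict) {
    meds <- apply(x, 1L, median)
    if (any(abs(meds) > 1e-6))
      inputError("input is not median-centered per feature (use strict = FALSE to skip)")
  }
  ProfileMatrix(x, modality, geneMap = geneMap)
}

#' @rdname profile-io
#' @export
writeMetadata <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname profile-io
#' @export
readMetadata <- function(path) {
  md <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "validated", "observed_response")
  if (!all(req %in% names(md)))
    inputError(sprintf("metadata must contain columns: %s",
                       paste(req, collapse = ", ")))
  bad <- md$validated & md$observed_response == "unknown"
  if (any(bad))
    inputError("validated samples must carry an observed response")
  md
}

#' @rdname profile-io
#' @export
writeGrowth <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname profile-io
#' @export
readGrowth <- function(path) {
  g <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("pdx_id", "arm", "animal", "day", "volume_mm3")
  if (!all(req %in% names(g)))
    inputError(sprintf("growth table must contain columns: %s",
                       paste(req, collapse = ", ")))
  g
}

#' @rdname profile-io
#' @export
writeIHCCells <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname profile-io
#' @export
readIHCCells <- function(path) {
  cells <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("section_id", "cell_id", "marker", "mean_intensity")
  if (!all(req %in% names(cells)))
    inputError(sprintf("IHC cell table must contain columns: %s",
                       paste(req, collapse = ", ")))
  cells
}

#' Read a probe-to-symbol gene map
#'
#' Two-column CSV (`probe`, `symbol`); empty or `NA` symbols mark probes
#' with no mRNA counterpart. A fixture for the canonical 8-marker signature
#' (plus the unmapped PAR probe) ships in
#' `system.file("extdata", "signature_gene_map.csv", package = "rppasig")`.
#'
#' @param path CSV file path.
#' @return named character vector, probe to symbol (`NA` when unmapped).
#' @export
readGeneMap <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("probe", "symbol") %in% names(df)))
    inputError("gene map must have columns 'probe' and 'symbol'")
  sym <- df$symbol
  sym[!is.na(sym) & sym == ""] <- NA_character_
  setNames(sym, df$probe)
}
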