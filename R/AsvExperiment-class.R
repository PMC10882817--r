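#' AsvExperiment: ASV count tables with sample and taxonomy annotation
#'
#' `AsvExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] to hold an amplicon
#' sequence variant (ASV) read-count matrix with ASVs as rows and samples as
#' columns. Sample metadata (marker, variety, production field, sample type,
#' replicate) lives in `colData`, taxonomy lineages and their derived
#' screening flags in `rowData`.
#'
#' Validity requires a `"counts"` assay of non-negative whole numbers with
#' unique, non-empty row (ASV) and column (sample) names.
#'
#' @slot ... inherits all slots from `SummarizedExperiment`.
#' @aliases AsvExperiment-class
#' @export
setClass("AsvExperiment", contains = "SummarizedExperiment")

setValidity("AsvExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts matrix must have ASV rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    return("duplicate ASV ids")
  if (anyDuplicated(colnames(m)))
    return("duplicate sample ids")
  if (any(!nzchar(rownames(m))) || any(!nzchar(colnames(m))))
    return("empty ASV or sample id")
  if (!is.numeric(m))
    return("counts must be numeric")
  if (any(!isWholeNumber(m)))
    return("counts must be whole numbers")
  if (any(m < 0))
    return("counts must be non-negative")
  TRUE
})

# Closed vocabulary for sample annotation.
SAMPLE_TYPES <- c(
  "seed_tuber", "post_storage_seed_tuber", "daughter_tuber", "root",
  "adhering_soil", "peel", "heel_end", "eye", "flesh", "sprout"
)
MARKERS <- c("16S", "ITS")
COMPARTMENTS <- c("adhering_soil", "peel", "heel_end", "eye", "flesh")

#' Construct an AsvExperiment
#'
#' @param counts numeric matrix of read counts. By default rows are ASVs and
#'   columns samples; set `orientation = "samples_by_asvs"` if rows are
#'   samples.
#' @param sampleData optional `data.frame` of per-sample metadata. Matched to
#'   samples by a `sample_id` column if present, otherwise by rownames. A
#'   `sample_type` column, when present, must use the closed vocabulary
#'   (`seed_tuber`, `post_storage_seed_tuber`, `daughter_tuber`, `root`,
#'   `adhering_soil`, `peel`, `heel_end`, `eye`, `flesh`, `sprout`); a
#'   `marker` column must be `"16S"` or `"ITS"`.
#' @param taxonomy optional `data.frame` with columns `asv_id` and `lineage`
#'   (semicolon-separated ranks); screening flags are derived with
#'   [lineageFlags()] and stored in `rowData`.
#' @param orientation orientation of `counts`.
#' @return an [AsvExperiment-class] object.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 1L, 3L, 0L), nrow = 3,
#'             dimnames = list(paste0("asv", 1:3), c("s1", "s2")))
#' AsvExperiment(m)
#' @export
AsvExperiment <- function(counts, sampleData = NULL, taxonomy = NULL,
                          orientation = c("asvs_by_samples",
                                          "samples_by_asvs")) {
  orientation <- match.arg(orientation)
  counts <- as.matrix(counts)
  if (orientation == "samples_by_asvs") counts <- t(counts)
  storage.mode(counts) <- "integer"

  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(sampleData)) {
    sampleData <- as.data.frame(sampleData)
    if ("sample_id" %in% names(sampleData)) {
      rownames(sampleData) <- as.character(sampleData$sample_id)
    }
    missing <- setdiff(colnames(counts), rownames(sampleData))
    if (length(missing))
      failWith("no metadata for sample(s): ", paste(missing, collapse = ", "))
    sampleData <- sampleData[colnames(counts), , drop = FALSE]
    if ("sample_type" %in% names(sampleData)) {
      bad <- setdiff(unique(sampleData$sample_type), SAMPLE_TYPES)
      if (length(bad))
        failWith("unknown sample_type: ", paste(bad, collapse = ", "))
    }
    if ("marker" %in% names(sampleData)) {
      bad <- setdiff(unique(sampleData$marker), MARKERS)
      if (length(bad))
        failWith("unknown marker: ", paste(bad, collapse = ", "))
    }
    cd <- S4Vectors::DataFrame(sampleData)
  }

  rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    if (!all(c("asv_id", "lineage") %in% names(taxonomy)))
      failWith("taxonomy needs columns 'asv_id' and 'lineage'")
    rownames(taxonomy) <- as.character(taxonomy$asv_id)
    lineage <- rep(NA_character_, nrow(counts))
    names(lineage) <- rownames(counts)
    hit <- intersect(rownames(counts), rownames(taxonomy))
    lineage[hit] <- taxonomy[hit, "lineage"]
    rd <- S4Vectors::DataFrame(lineage = lineage,
                               lineageFlags(lineage),
                               row.names = rownames(counts))
  }

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd)
  methods::new("AsvExperiment", se)
}

#' @describeIn AsvExperiment ASV identifiers (rownames).
#' @param x an `AsvExperiment`.
#' @export
asvIds <- function(x) rownames(x)

#' @describeIn AsvExperiment sample identifiers (colnames).
#' @export
sampleIds <- function(x) colnames(x)

#' @describeIn AsvExperiment the read-count matrix (ASVs x samples).
#' @export
asvCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn AsvExperiment per-sample metadata as a base `data.frame`.
#' @export
sampleData <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' Select sample ids by metadata equality
#'
#' Convenience filter over `colData`: each named argument is a metadata
#' column; a sample is kept when every named column matches one of the given
#' values.
#'
#' @param x an [AsvExperiment-class].
#' @param ... named filters, e.g. `sample_type = "seed_tuber"`,
#'   `production_field = c("F1", "F2")`.
#' @return character vector of sample ids.
#' @export
selectSamples <- function(x, ...) {
  filt <- list(...)
  cd <- sampleData(x)
  keep <- rep(TRUE, ncol(x))
  for (nm in names(filt)) {
    if (!nm %in% names(cd))
      failWith("no metadata column '", nm, "'")
    keep <- keep & cd[[nm]] %in% filt[[nm]]
  }
  colnames(x)[keep]
}

#' Convert counts to per-sample relative abundances
#'
#' @param x an [AsvExperiment-class] or a numeric counts matrix
#'   (ASVs x samples).
#' @return numeric matrix (ASVs x samples) whose columns each sum to 1.
#' @details Errors if any sample has zero total reads, naming the sample.
#' @examples
#' m <- matrix(c(2L, 2L, 0L, 0L, 1L, 0L), nrow = 3,
#'             dimnames = list(paste0("a", 1:3), c("s1", "s2")))
#' relAbundance(m)
#' @export
relAbundance <- function(x) {
  m <- if (methods::is(x, "SummarizedExperiment")) asvCounts(x) else as.matrix(x)
  tot <- colSums(m)
  if (any(tot == 0))
    failWith("zero-total sample(s): ",
             paste(colnames(m)[tot == 0], collapse = ", "))
  sweep(m, 2, tot, "/")
}
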