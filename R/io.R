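# Readers and writers for the plain-text interchange formats: TSV count
# tables (first column = row id, tab separated, no quoting), BIOM JSON v1
# via the biomformat package, taxonomy TSV (asv_id <TAB> lineage) and sample
# metadata TSV.

#' Derive taxonomy screening flags from lineage strings
#'
#' Flags are deterministic, case-insensitive substring matches on the
#' semicolon-separated rank labels: `is_mitochondria`, `is_chloroplast`,
#' `is_viridiplantae` and `is_protista` match any rank; `is_bacteria` and
#' `is_fungi` match the top (first) rank only, so that e.g. the phylum
#' "Proteobacteria" does not satisfy the domain rule. Leading QIIME-style
#' rank prefixes (`d__`, `k__`, ...) are part of the label and do not
#' interfere with substring matching.
#'
#' @param lineage character vector of `;`-separated lineage strings; `NA`
#'   yields `NA` flags.
#' @return `data.frame` of six logical flag columns.
#' @examples
#' lineageFlags("Bacteria;Cyanobacteria;Oxyphotobacteria;Chloroplast")
#' @export
lineageFlags <- function(lineage) {
  one <- function(lin) {
    if (is.na(lin)) {
      return(rep(NA, 6L))
    }
    ranks <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    ranks <- ranks[nzchar(ranks)]
    top <- if (length(ranks)) ranks[[1]] else ""
    hasAny <- function(pat) any(grepl(pat, ranks, ignore.case = TRUE))
    c(
      is_mitochondria = hasAny("mitochondria"),
      is_chloroplast = hasAny("chloroplast"),
      is_bacteria = grepl("bacteria", top, ignore.case = TRUE),
      is_fungi = grepl("fungi", top, ignore.case = TRUE),
      is_viridiplantae = hasAny("viridiplantae"),
      is_protista = hasAny("protista")
    )
  }
  out <- t(vapply(lineage, one, logical(6L)))
  rownames(out) <- NULL
  as.data.frame(out)
}

#' Read an ASV count table
#'
#' @param path path to the table.
#' @param format `"tsv"` (first column holds row ids) or `"biom_json"`
#'   (BIOM v1 JSON, sparse or dense; rows are observations per the format, so
#'   `orientation` is ignored).
#' @param orientation whether TSV rows are samples or ASVs; the returned
#'   object always stores ASVs as rows.
#' @param sampleData,taxonomy optional metadata/taxonomy `data.frame`s or
#'   file paths (passed to [readSampleData()] / [readTaxonomy()]).
#' @return an [AsvExperiment-class].
#' @details Malformed input (duplicate ids, negative or non-integer counts,
#'   non-numeric cells) raises an error naming the offending cell.
#' @export
readCountTable <- function(path,
                           format = c("tsv", "biom_json"),
                           orientation = c("samples_by_asvs",
                                           "asvs_by_samples"),
                           sampleData = NULL, taxonomy = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) failWith("file not found: ", path)

  if (format == "tsv") {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, quote = "",
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 2) failWith("malformed header in ", path)
    rowIds <- as.character(raw[[1]])
    colIds <- colnames(raw)[-1]
    if (anyDuplicated(rowIds))
      failWith("duplicate row id(s): ",
               paste(unique(rowIds[duplicated(rowIds)]), collapse = ", "))
    if (anyDuplicated(colIds))
      failWith("duplicate column id(s): ",
               paste(unique(colIds[duplicated(colIds)]), collapse = ", "))
    m <- suppressWarnings(
      vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw))))
    m <- matrix(m, nrow = nrow(raw), dimnames = list(rowIds, colIds))
    bad <- which(is.na(m) | m < 0 | !isWholeNumber(m), arr.ind = TRUE)
    if (nrow(bad)) {
      failWith("invalid count at row '", rowIds[bad[1, 1]],
               "', column '", colIds[bad[1, 2]], "': not a non-negative integer")
    }
    counts <- if (orientation == "samples_by_asvs") t(m) else m
  } else {
    b <- biomformat::read_biom(path)
    counts <- as(biomformat::biom_data(b), "matrix")
  }

  if (is.character(sampleData) && length(sampleData) == 1L)
    sampleData <- readSampleData(sampleData)
  if (is.character(taxonomy) && length(taxonomy) == 1L)
    taxonomy <- readTaxonomy(taxonomy)
  AsvExperiment(counts, sampleData = sampleData, taxonomy = taxonomy)
}

#' Write an ASV count table
#'
#' @param x an [AsvExperiment-class].
#' @param path output path.
#' @param format `"tsv"` or `"biom_json"`.
#' @param orientation for TSV output, whether rows are samples (default) or
#'   ASVs.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(x, path,
                            format = c("tsv", "biom_json"),
                            orientation = c("samples_by_asvs",
                                            "asvs_by_samples")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  m <- asvCounts(x)
  if (format == "tsv") {
    if (orientation == "samples_by_asvs") m <- t(m)
    idName <- if (orientation == "samples_by_asvs") "sample_id" else "asv_id"
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- idName
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    biomformat::write_biom(biomformat::make_biom(data = m), path)
  }
  invisible(path)
}

#' Read a taxonomy table (asv_id TAB lineage)
#'
#' @param path TSV path with columns `asv_id` and `lineage`.
#' @return `data.frame` with `asv_id`, `lineage` and the [lineageFlags()]
#'   columns.
#' @export
readTaxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("asv_id", "lineage") %in% names(df)))
    failWith("taxonomy file needs columns 'asv_id' and 'lineage'")
  if (anyDuplicated(df$asv_id))
    failWith("duplicate asv_id in taxonomy file")
  cbind(df[c("asv_id", "lineage")], lineageFlags(df$lineage))
}

#' Read a sample metadata table
#'
#' @param path TSV path; must contain a `sample_id` column. `sample_type`
#'   and `marker` columns, when present, are validated against the closed
#'   vocabularies.
#' @return `data.frame` keyed by `sample_id`.
#' @export
readSampleData <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    failWith("metadata file needs a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    failWith("duplicate sample_id in metadata file")
  if ("sample_type" %in% names(df)) {
    bad <- setdiff(unique(df$sample_type), SAMPLE_TYPES)
    if (length(bad))
      failWith("unknown sample_type: ", paste(bad, collapse = ", "))
  }
  if ("marker" %in% names(df)) {
    bad <- setdiff(unique(df$marker), MARKERS)
    if (length(bad))
      failWith("unknown marker: ", paste(bad, collapse = ", "))
  }
  rownames(df) <- df$sample_id
  df
}
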