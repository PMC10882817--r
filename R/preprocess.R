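# Preprocessing of ASV tables: off-target taxon removal, rare-ASV
# filtering and rarefaction. The canonical pipeline order is off-target
# removal, then the rare-ASV filter, then rarefaction; runPipeline() logs
# the stages in that order.

#' Remove off-target taxa from a marker-gene count table
#'
#' For 16S data, drops ASVs annotated as mitochondria or chloroplast and
#' keeps only ASVs whose top rank is Bacteria. For ITS data, drops ASVs
#' annotated as Viridiplantae or Protista and keeps only ASVs whose top
#' rank is Fungi. Flags are the [lineageFlags()] columns stored in
#' `rowData`; every ASV must carry a taxonomy record.
#'
#' @param x an [AsvExperiment-class] with taxonomy in `rowData`.
#' @param marker `"16S"` or `"ITS"`.
#' @return the filtered [AsvExperiment-class]; samples are unchanged.
#' @export
removeOfftargetTaxa <- function(x, marker = c("16S", "ITS")) {
  marker <- match.arg(marker)
  rd <- SummarizedExperiment::rowData(x)
  need <- c("is_mitochondria", "is_chloroplast", "is_bacteria",
            "is_fungi", "is_viridiplantae", "is_protista")
  if (!all(need %in% colnames(rd)))
    failWith("no taxonomy flags in rowData; supply taxonomy when building ",
             "the AsvExperiment")
  missing <- rownames(x)[is.na(rd$is_bacteria)]
  if (length(missing))
    failWith("ASVs without taxonomy record: ",
             paste(utils::head(missing, 10), collapse = ", "),
             if (length(missing) > 10) ", ..." else "")
  keep <- if (marker == "16S") {
    rd$is_bacteria & !rd$is_mitochondria & !rd$is_chloroplast
  } else {
    rd$is_fungi & !rd$is_viridiplantae & !rd$is_protista
  }
  x[keep, ]
}

#' Filter rare ASVs by total reads and prevalence
#'
#' An ASV is retained iff its total read count across all samples is at
#' least `minTotalReads` and it is present (count >= 1) in at least
#' `minPrevalence` samples. The defaults implement the common
#' "fewer than 30 reads or present in fewer than 3 samples" removal rule
#' with strict "fewer than" semantics: totals of exactly 30 and prevalence
#' of exactly 3 are retained.
#'
#' @param x an [AsvExperiment-class].
#' @param minTotalReads minimum total reads (default 30).
#' @param minPrevalence minimum number of samples with at least one read
#'   (default 3).
#' @return the filtered [AsvExperiment-class] (possibly with zero ASVs).
#' @export
filterRareAsvs <- function(x, minTotalReads = 30, minPrevalence = 3) {
  m <- asvCounts(x)
  keep <- rowSums(m) >= minTotalReads & rowSums(m >= 1) >= minPrevalence
  x[keep, ]
}

# Multivariate hypergeometric draw: subsample `depth` reads without
# replacement from a count vector.
rarefyVector <- function(counts, depth) {
  reads <- rep.int(seq_along(counts), counts)
  tabulate(sample(reads, depth), nbins = length(counts))
}

#' Rarefy a count table to even depth
#'
#' Each sample's reads are subsampled uniformly without replacement
#' (multivariate hypergeometric) to exactly `depth` reads. Samples whose
#' total is below `depth` are dropped; their ids are recorded in
#' `metadata(x)$rarefaction$dropped` and reported via a message. Samples
#' whose total equals `depth` are returned unchanged.
#'
#' @param x an [AsvExperiment-class].
#' @param depth target reads per sample (>= 1).
#' @param seed integer RNG seed; the same seed reproduces the draw exactly.
#' @param pruneEmpty drop ASVs left with zero total reads after rarefaction.
#' @return the rarefied [AsvExperiment-class].
#' @export
rarefy <- function(x, depth, seed, pruneEmpty = FALSE) {
  if (length(depth) != 1 || !is.finite(depth) || depth < 1)
    failWith("depth must be a positive integer")
  depth <- as.integer(depth)
  m <- asvCounts(x)
  tot <- colSums(m)
  dropped <- colnames(m)[tot < depth]
  if (length(dropped))
    message("rarefy: dropping ", length(dropped),
            " sample(s) below depth ", depth, ": ",
            paste(dropped, collapse = ", "))
  keep <- tot >= depth
  if (!any(keep))
    failWith("no sample reaches depth ", depth)
  x <- x[, keep]
  m <- m[, keep, drop = FALSE]
  out <- withSeed(seed, {
    vapply(seq_len(ncol(m)), function(j) {
      col <- m[, j]
      if (sum(col) == depth) col
      else as.integer(rarefyVector(col, depth))
    }, integer(nrow(m)))
  })
  out <- matrix(as.integer(out), nrow = nrow(m), dimnames = dimnames(m))
  SummarizedExperiment::assay(x, "counts") <- out
  S4Vectors::metadata(x)$rarefaction <-
    list(depth = depth, seed = as.integer(seed), dropped = dropped)
  if (pruneEmpty) x <- x[rowSums(out) > 0, ]
  x
}
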