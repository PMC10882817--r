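# Source -> destination transmission accounting: which ASVs of a source
# community (e.g. seed tuber peel) are shared with, lost from, or newly
# acquired by a destination community (e.g. daughter tuber), plus the
# cumulative relative abundance each category represents in the
# destination. Storage persistence is the same comparison with pre- and
# post-storage seed tubers as source and destination.

#' TransmissionSummary: shared / lost / acquired accounting
#'
#' `shared` = source intersect destination, `lost` = source only,
#' `acquired` = destination only. `uniqueUnique` (optional) is the subset
#' of shared ASVs that are field-unique on both sides; it is nested inside
#' `shared` and never double-counted. `destAbundance` holds the mean
#' cumulative relative abundance of each category across destination
#' samples once [abundanceAccounting()] has been applied (`NA` before).
#'
#' @slot sourceName,destName group labels.
#' @slot shared,lost,acquired,uniqueUnique character vectors of ASV ids.
#' @slot destAbundance named numeric: `shared`, `acquired`,
#'   `unique_unique`.
#' @slot abundanceMode `"mean"`, `"pooled"` or `""` (not yet computed).
#' @export
setClass("TransmissionSummary", representation(
  sourceName = "character", destName = "character",
  shared = "character", lost = "character", acquired = "character",
  uniqueUnique = "character", destAbundance = "numeric",
  abundanceMode = "character"))

setValidity("TransmissionSummary", function(object) {
  if (length(intersect(object@shared, object@lost)) ||
      length(intersect(object@shared, object@acquired)) ||
      length(intersect(object@lost, object@acquired)))
    return("shared/lost/acquired must be disjoint")
  if (!all(object@uniqueUnique %in% object@shared))
    return("uniqueUnique must be a subset of shared")
  TRUE
})

setMethod("show", "TransmissionSummary", function(object) {
  nS <- nSource(object); nD <- nDest(object)
  cat("TransmissionSummary: ", object@sourceName, " -> ", object@destName,
      "\n", sep = "")
  cat("  source ASVs: ", nS, "   destination ASVs: ", nD, "\n", sep = "")
  cat(sprintf("  shared   %6d  (%s%% of source, %s%% of destination)\n",
              length(object@shared),
              percentHalfUp(length(object@shared) / nS),
              percentHalfUp(length(object@shared) / nD)))
  cat(sprintf("  lost     %6d  (%s%% of source)\n", length(object@lost),
              percentHalfUp(length(object@lost) / nS)))
  cat(sprintf("  acquired %6d  (%s%% of destination)\n",
              length(object@acquired),
              percentHalfUp(length(object@acquired) / nD)))
  if (length(object@uniqueUnique))
    cat("  unique-unique:", length(object@uniqueUnique), "\n")
  if (!all(is.na(object@destAbundance)))
    cat(sprintf(
      "  destination abundance (%s): shared %.3f, acquired %.3f\n",
      object@abundanceMode, object@destAbundance[["shared"]],
      object@destAbundance[["acquired"]]))
})

#' @describeIn TransmissionSummary number of source ASVs
#'   (`|shared| + |lost|`).
#' @param x a `TransmissionSummary`.
#' @export
nSource <- function(x) length(x@shared) + length(x@lost)

#' @describeIn TransmissionSummary number of destination ASVs
#'   (`|shared| + |acquired|`).
#' @export
nDest <- function(x) length(x@shared) + length(x@acquired)

#' Classify transmission of ASVs from a source to a destination group
#'
#' @param source,dest [DetectionSet-class] objects built from the same
#'   marker (checked when both carry `marker` metadata).
#' @return a [TransmissionSummary-class] with the category sets filled and
#'   abundances `NA`.
#' @export
classifyTransmission <- function(source, dest) {
  if (!length(detectedAsvs(source))) failWith("empty source set")
  if (!length(detectedAsvs(dest))) failWith("empty destination set")
  mk <- c(source@meta[["marker"]], dest@meta[["marker"]])
  if (length(mk) == 2 && mk[1] != mk[2])
    failWith("source and destination use different markers: ",
             paste(mk, collapse = " vs "))
  s <- detectedAsvs(source); d <- detectedAsvs(dest)
  methods::new("TransmissionSummary",
               sourceName = source@name, destName = dest@name,
               shared = intersect(s, d), lost = setdiff(s, d),
               acquired = setdiff(d, s), uniqueUnique = character(0),
               destAbundance = c(shared = NA_real_, acquired = NA_real_,
                                 unique_unique = NA_real_),
               abundanceMode = "")
}

#' Transmission fractions against both denominators
#'
#' @param x a [TransmissionSummary-class].
#' @return `data.frame` with one row per reported ratio (`lost/source`,
#'   `shared/source`, `shared/dest`, `acquired/dest`), raw fraction and
#'   integer percent.
#' @export
transmissionFractions <- function(x) {
  nS <- nSource(x); nD <- nDest(x)
  f <- c(lost_of_source = length(x@lost) / nS,
         shared_of_source = length(x@shared) / nS,
         shared_of_dest = length(x@shared) / nD,
         acquired_of_dest = length(x@acquired) / nD)
  data.frame(ratio = names(f), fraction = unname(f),
             percent = unname(percentHalfUp(f)), stringsAsFactors = FALSE)
}

#' Unique-unique overlap: field-unique ASVs on both source and destination
#'
#' The intersection of two field-uniqueness results, i.e. ASVs that are
#' unique to the same focal field on the source sample type and on the
#' destination sample type. These trace inherited field signatures.
#'
#' @param sourceUnique,destUnique [UniquenessResult-class] objects for the
#'   same focal field and marker.
#' @return character vector of ASV ids.
#' @export
uniqueUniqueOverlap <- function(sourceUnique, destUnique) {
  if (!identical(sourceUnique@focal, destUnique@focal))
    failWith("mismatched focal fields: ", sourceUnique@focal, " vs ",
             destUnique@focal)
  mk <- c(sourceUnique@meta[["marker"]], destUnique@meta[["marker"]])
  if (length(mk) == 2 && mk[1] != mk[2])
    failWith("mismatched markers: ", paste(mk, collapse = " vs "))
  intersect(uniqueAsvs(sourceUnique), uniqueAsvs(destUnique))
}

#' Attach a unique-unique set to a transmission summary
#'
#' @param x a [TransmissionSummary-class].
#' @param asvs ASV ids; must be a subset of the shared set.
#' @return the updated summary.
#' @export
setUniqueUnique <- function(x, asvs) {
  if (!all(asvs %in% x@shared))
    failWith("unique-unique ASVs must be a subset of the shared set")
  x@uniqueUnique <- asvs
  methods::validObject(x)
  x
}

#' Fill destination abundance fractions of a transmission summary
#'
#' For each category, the per-sample cumulative relative abundance of its
#' member ASVs is computed in the destination table and aggregated across
#' destination samples. `mode = "mean"` (default) takes the unweighted mean
#' of per-sample sums, which is invariant to per-sample sequencing depth;
#' `mode = "pooled"` sums raw reads across samples first and requires count
#' input. Shared and acquired fractions sum to 1 by construction.
#'
#' @param x a [TransmissionSummary-class].
#' @param dest an [AsvExperiment-class] holding the destination samples (or
#'   a relative-abundance matrix, ASVs x samples, for `mode = "mean"`).
#' @param samples optional subset of destination sample ids.
#' @param mode `"mean"` or `"pooled"`.
#' @return the summary with `destAbundance` filled.
#' @export
abundanceAccounting <- function(x, dest, samples = NULL,
                                mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  isExp <- methods::is(dest, "SummarizedExperiment")
  m <- if (isExp) asvCounts(dest) else as.matrix(dest)
  if (!is.null(samples)) {
    unknown <- setdiff(samples, colnames(m))
    if (length(unknown))
      failWith("destination sample(s) absent: ",
               paste(unknown, collapse = ", "))
    m <- m[, samples, drop = FALSE]
  }
  destAsvs <- c(x@shared, x@acquired)
  absent <- setdiff(destAsvs, rownames(m))
  if (length(absent))
    failWith("category ASVs absent from destination table: ",
             paste(utils::head(absent, 10), collapse = ", "))
  catShare <- function(rel, ids) {
    if (!length(ids)) return(0)
    mean(colSums(rel[ids, , drop = FALSE]))
  }
  if (mode == "mean") {
    rel <- relAbundance(m[destAsvs, , drop = FALSE])
    shared <- catShare(rel, x@shared)
    acquired <- catShare(rel, x@acquired)
    uu <- if (length(x@uniqueUnique)) catShare(rel, x@uniqueUnique)
          else NA_real_
  } else {
    if (!isExp) failWith("mode 'pooled' requires a count table")
    tot <- sum(m[destAsvs, ])
    shared <- sum(m[x@shared, , drop = FALSE]) / tot
    acquired <- sum(m[x@acquired, , drop = FALSE]) / tot
    uu <- if (length(x@uniqueUnique))
      sum(m[x@uniqueUnique, , drop = FALSE]) / tot else NA_real_
  }
  x@destAbundance <- c(shared = shared, acquired = acquired,
                       unique_unique = uu)
  x@abundanceMode <- mode
  x
}

#' Tidy export of a transmission summary
#'
#' @param x a [TransmissionSummary-class].
#' @return `data.frame` with one row per category (`shared`, `lost`,
#'   `acquired`, `unique_unique`), its ASV count and destination abundance
#'   (NA where not applicable), suitable for Sankey-style plotting.
#' @export
transmissionTable <- function(x) {
  data.frame(
    category = c("shared", "lost", "acquired", "unique_unique"),
    n_asvs = c(length(x@shared), length(x@lost), length(x@acquired),
               length(x@uniqueUnique)),
    dest_abundance = c(x@destAbundance[["shared"]], NA_real_,
                       x@destAbundance[["acquired"]],
                       x@destAbundance[["unique_unique"]]),
    stringsAsFactors = FALSE)
}
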