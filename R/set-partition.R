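# Detection sets, exclusive overlap partitions (the tabular core of Venn /
# UpSet displays), shared-fraction arithmetic and field-unique ASV
# identification.

#' DetectionSet: ASVs detected in a named sample group
#'
#' Holds the set of ASVs considered present in a sample group under an
#' explicit detection rule (minimum count per sample, minimum number of
#' samples reaching it). The rule is recorded so every downstream number is
#' traceable to it.
#'
#' @slot name group label.
#' @slot samples sample ids in the group.
#' @slot asvs ASV ids detected under the rule.
#' @slot rule named integer vector `c(min_count, min_samples)`.
#' @slot meta list of defining metadata (e.g. variety, sample_type, marker,
#'   production_field), used for stratum-consistency checks.
#' @export
setClass("DetectionSet", representation(
  name = "character", samples = "character", asvs = "character",
  rule = "integer", meta = "list"))

setValidity("DetectionSet", function(object) {
  if (length(object@name) != 1 || !nzchar(object@name))
    return("name must be a single non-empty string")
  if (!length(object@samples)) return("empty sample group")
  if (anyDuplicated(object@asvs)) return("duplicate ASV ids")
  TRUE
})

setMethod("show", "DetectionSet", function(object) {
  cat("DetectionSet '", object@name, "': ", length(object@asvs),
      " ASVs detected in ", length(object@samples),
      " samples (rule: count >= ", object@rule[["min_count"]],
      " in >= ", object@rule[["min_samples"]], " samples)\n", sep = "")
})

#' @describeIn DetectionSet the detected ASV ids.
#' @param x a `DetectionSet`.
#' @export
detectedAsvs <- function(x) x@asvs

#' Compute the detection set of a sample group
#'
#' An ASV is detected when it has at least `minCount` reads in at least
#' `minSamples` of the group's samples. The default rule (>= 1 read in
#' >= 1 sample) is the minimal occupancy rule; apply it to filtered,
#' rarefied tables so detection is comparable across groups.
#'
#' @param x an [AsvExperiment-class].
#' @param samples character vector of sample ids forming the group.
#' @param name group label.
#' @param minCount minimum per-sample read count (default 1).
#' @param minSamples minimum number of samples reaching `minCount`
#'   (default 1).
#' @param meta named list of defining metadata recorded on the set.
#' @return a [DetectionSet-class].
#' @export
detectionSet <- function(x, samples, name, minCount = 1L, minSamples = 1L,
                         meta = list()) {
  if (!length(samples)) failWith("empty sample group '", name, "'")
  unknown <- setdiff(samples, sampleIds(x))
  if (length(unknown))
    failWith("sample(s) not in table: ", paste(unknown, collapse = ", "))
  m <- asvCounts(x)[, samples, drop = FALSE]
  hit <- rowSums(m >= minCount) >= minSamples
  methods::new("DetectionSet", name = name, samples = samples,
               asvs = rownames(m)[hit],
               rule = c(min_count = as.integer(minCount),
                        min_samples = as.integer(minSamples)),
               meta = meta)
}

#' Build a detection set directly from ASV ids
#'
#' For set algebra on published or externally derived ASV lists, where no
#' count table is available; the detection rule is recorded as unknown
#' (zeros).
#'
#' @param name group label.
#' @param asvs character vector of ASV ids.
#' @param meta named list of defining metadata.
#' @return a [DetectionSet-class].
#' @export
detectionSetFromIds <- function(name, asvs, meta = list()) {
  methods::new("DetectionSet", name = name, samples = paste0(name, ":ids"),
               asvs = unique(as.character(asvs)),
               rule = c(min_count = 0L, min_samples = 0L), meta = meta)
}

#' OverlapPartition: exclusive overlap regions of detection sets
#'
#' Partitions the union of 2-6 detection sets into exclusive regions keyed
#' by the subset of groups that contain them (the numbers behind a Venn
#' diagram or UpSet plot). Region keys join group names with `"&"`.
#'
#' @slot groupNames the input group names, in order.
#' @slot regionCounts named integer vector of region sizes.
#' @slot regionMembers named list of member ASV ids per region (empty when
#'   the partition was built from printed counts only).
#' @export
setClass("OverlapPartition", representation(
  groupNames = "character", regionCounts = "integer",
  regionMembers = "list"))

setValidity("OverlapPartition", function(object) {
  n <- length(object@groupNames)
  if (n < 2 || n > 6) return("2 to 6 groups required")
  if (anyDuplicated(object@groupNames)) return("duplicate group names")
  parts <- strsplit(names(object@regionCounts), "&", fixed = TRUE)
  ok <- vapply(parts, function(p) all(p %in% object@groupNames), logical(1))
  if (!all(ok)) return("region key references unknown group")
  if (length(object@regionMembers) &&
      !identical(lengths(object@regionMembers)[names(object@regionCounts)],
                 structure(as.integer(object@regionCounts),
                           names = names(object@regionCounts))))
    return("region member lengths disagree with counts")
  if (any(object@regionCounts < 0)) return("negative region count")
  TRUE
})

setMethod("show", "OverlapPartition", function(object) {
  cat("OverlapPartition over", length(object@groupNames), "groups:",
      paste(object@groupNames, collapse = ", "), "\n")
  for (g in object@groupNames)
    cat("  |", g, "| =", groupTotal(object, g), "\n")
  df <- regionCounts(object)
  print(df[order(-df$count), ], row.names = FALSE)
})

#' Partition detection sets into exclusive overlap regions
#'
#' @param sets list of 2-6 [DetectionSet-class] objects with distinct names.
#' @return an [OverlapPartition-class]. Empty regions are omitted.
#' @export
overlapPartition <- function(sets) {
  if (length(sets) < 2 || length(sets) > 6)
    failWith("overlapPartition takes 2 to 6 sets")
  nms <- vapply(sets, function(s) s@name, character(1))
  if (anyDuplicated(nms)) failWith("duplicate group names")
  universe <- unique(unlist(lapply(sets, detectedAsvs)))
  member <- vapply(sets, function(s) universe %in% s@asvs,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, nms))
  key <- apply(member, 1, function(row) paste(nms[row], collapse = "&"))
  regions <- split(universe, key)
  methods::new("OverlapPartition", groupNames = nms,
               regionCounts = vapply(regions, length, integer(1)),
               regionMembers = regions)
}

#' Build an overlap partition from printed region counts
#'
#' Lets published Venn/UpSet region counts be used directly as input to
#' [sharedFraction()] without the underlying ASV ids.
#'
#' @param regionCounts named integer vector; names are `"&"`-joined group
#'   subsets, e.g. `c("seed&daughter" = 156, "daughter" = 1169)`.
#' @param groupNames the full ordered vector of group names.
#' @return an [OverlapPartition-class] with empty `regionMembers`.
#' @export
overlapPartitionFromCounts <- function(regionCounts, groupNames) {
  methods::new("OverlapPartition", groupNames = groupNames,
               regionCounts = structure(as.integer(regionCounts),
                                        names = names(regionCounts)),
               regionMembers = list())
}

#' @describeIn overlapPartition region counts as a `data.frame`
#'   (`region`, `count`).
#' @param partition an [OverlapPartition-class].
#' @export
regionCounts <- function(partition) {
  data.frame(region = names(partition@regionCounts),
             count = as.integer(partition@regionCounts),
             stringsAsFactors = FALSE)
}

#' @describeIn overlapPartition total set size of one group: the sum of all
#'   region counts whose key contains the group.
#' @param group a group name.
#' @export
groupTotal <- function(partition, group) {
  if (!group %in% partition@groupNames)
    failWith("unknown group '", group, "'")
  parts <- strsplit(names(partition@regionCounts), "&", fixed = TRUE)
  has <- vapply(parts, function(p) group %in% p, logical(1))
  sum(partition@regionCounts[has])
}

#' Fraction of a focal set shared with other sets
#'
#' Computes the fraction of the focal group's ASVs that fall in overlap
#' regions containing at least one of the `others`, e.g. the share of
#' daughter-tuber ASVs also detected on roots.
#'
#' @param partition an [OverlapPartition-class].
#' @param focal focal group name (denominator).
#' @param others character vector of other group names (numerator
#'   condition).
#' @return list with `numerator`, `denominator`, `fraction` (raw) and
#'   `percent` (integer, half-up).
#' @export
sharedFraction <- function(partition, focal, others) {
  for (g in c(focal, others))
    if (!g %in% partition@groupNames) failWith("unknown group '", g, "'")
  parts <- strsplit(names(partition@regionCounts), "&", fixed = TRUE)
  hasFocal <- vapply(parts, function(p) focal %in% p, logical(1))
  hasOther <- vapply(parts, function(p) any(others %in% p), logical(1))
  den <- sum(partition@regionCounts[hasFocal])
  if (den == 0) failWith("focal group '", focal, "' has zero total")
  num <- sum(partition@regionCounts[hasFocal & hasOther])
  f <- num / den
  list(numerator = as.integer(num), denominator = as.integer(den),
       fraction = f, percent = percentHalfUp(f))
}

#' UniquenessResult: ASVs unique to a focal production field
#'
#' @slot focal focal field name.
#' @slot uniqueAsvs ASVs detected in the focal field's set and in no other
#'   field's set.
#' @slot focalTotal size of the focal detection set.
#' @slot fraction `length(uniqueAsvs) / focalTotal`.
#' @slot meta stratum metadata carried over from the detection sets.
#' @export
setClass("UniquenessResult", representation(
  focal = "character", uniqueAsvs = "character", focalTotal = "integer",
  fraction = "numeric", meta = "list"))

setMethod("show", "UniquenessResult", function(object) {
  cat("UniquenessResult: ", length(object@uniqueAsvs), "/",
      object@focalTotal, " ASVs unique to '", object@focal, "' (",
      percentHalfUp(object@fraction, 1), "%)\n", sep = "")
})

#' @describeIn UniquenessResult the unique ASV ids.
#' @param x a `UniquenessResult`.
#' @export
uniqueAsvs <- function(x) x@uniqueAsvs

#' Identify field-unique ASVs
#'
#' An ASV is unique to the focal production field when it is detected in
#' that field's samples and in no other field's samples of the same
#' stratum. Uniqueness is meaningful only within a (variety x sample type x
#' marker) stratum; when the sets carry `variety`, `sample_type` or
#' `marker` metadata these must agree across fields.
#'
#' @param sets named list (keyed by field) of [DetectionSet-class] objects,
#'   one per production field (>= 2 fields).
#' @param focalField name of the focal field (must be a key of `sets`).
#' @return a [UniquenessResult-class].
#' @export
fieldUniqueAsvs <- function(sets, focalField) {
  if (length(sets) < 2) failWith("need sets from at least 2 fields")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    failWith("sets must be a uniquely named list keyed by field")
  if (!focalField %in% names(sets))
    failWith("focal field '", focalField, "' absent")
  for (key in c("variety", "sample_type", "marker")) {
    vals <- unique(unlist(lapply(sets, function(s) s@meta[[key]])))
    if (length(vals) > 1)
      failWith("sets span multiple ", key, " strata: ",
               paste(vals, collapse = ", "))
  }
  focal <- sets[[focalField]]
  others <- unique(unlist(lapply(sets[setdiff(names(sets), focalField)],
                                 detectedAsvs)))
  uni <- setdiff(detectedAsvs(focal), others)
  total <- length(detectedAsvs(focal))
  methods::new("UniquenessResult", focal = focalField, uniqueAsvs = uni,
               focalTotal = as.integer(total),
               fraction = if (total) length(uni) / total else 0,
               meta = focal@meta)
}
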