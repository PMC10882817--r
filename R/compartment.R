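# Sprout source attribution across the five seed tuber compartments
# (adhering soil, peel, heel end, eye, flesh), top-abundant sprout ASV
# reporting and the agglomerated-abundance ANOVA with Tukey's post-hoc
# test and compact letter display.

#' SourceAttribution: origin of sprout ASVs across tuber compartments
#'
#' @slot nSproutAsvs number of ASVs detected on sprouts.
#' @slot perCompartmentShared named integer: sprout ASVs also detected in
#'   each compartment.
#' @slot nInAny sprout ASVs detected in at least one compartment.
#' @slot nInAll sprout ASVs detected in all five compartments.
#' @slot sproutUnique ASVs detected on sprouts only.
#' @slot presence logical matrix (sprout ASVs x compartments).
#' @slot abundance named numeric: mean cumulative sprout relative abundance
#'   of the `sprout_unique`, `in_any` and `in_all` sets.
#' @export
setClass("SourceAttribution", representation(
  nSproutAsvs = "integer", perCompartmentShared = "integer",
  nInAny = "integer", nInAll = "integer", sproutUnique = "character",
  presence = "matrix", abundance = "numeric"))

setValidity("SourceAttribution", function(object) {
  if (object@nInAny + length(object@sproutUnique) != object@nSproutAsvs)
    return("in-any + sprout-unique must equal the sprout ASV total")
  if (length(object@perCompartmentShared) &&
      object@nInAll > min(object@perCompartmentShared))
    return("in-all exceeds a per-compartment count")
  TRUE
})

setMethod("show", "SourceAttribution", function(object) {
  n <- object@nSproutAsvs
  cat("SourceAttribution over", n, "sprout ASVs\n")
  cat(sprintf("  in >=1 compartment: %d (%s%%)\n", object@nInAny,
              percentHalfUp(object@nInAny / n)))
  cat(sprintf("  in all compartments: %d (%s%%)\n", object@nInAll,
              percentHalfUp(object@nInAll / n)))
  cat(sprintf("  sprout-unique: %d (%s%% of ASVs, %.1f%% of abundance)\n",
              length(object@sproutUnique),
              percentHalfUp(length(object@sproutUnique) / n),
              100 * object@abundance[["sprout_unique"]]))
  for (comp in names(object@perCompartmentShared))
    cat(sprintf("  shared with %-13s %4d (%s%%)\n", comp,
                object@perCompartmentShared[[comp]],
                percentHalfUp(object@perCompartmentShared[[comp]] / n)))
})

#' Attribute sprout ASVs to seed tuber compartments
#'
#' For every ASV detected on sprouts, records which of the five seed tuber
#' compartments also contain it, and computes the mean cumulative sprout
#' relative abundance of the sprout-unique set (detected in no
#' compartment), of the set found in at least one compartment, and of the
#' set found in all compartments. Sprout-unique abundance and in-any
#' abundance are exact complements.
#'
#' @param sprout an [AsvExperiment-class] of sprout samples (counts).
#' @param compartmentSets named list of [DetectionSet-class] objects for
#'   exactly the compartments `adhering_soil`, `peel`, `heel_end`, `eye`,
#'   `flesh`.
#' @param minCount,minSamples detection rule applied to the sprout table.
#' @return a [SourceAttribution-class].
#' @export
sourceAttribution <- function(sprout, compartmentSets,
                              minCount = 1L, minSamples = 1L) {
  missing <- setdiff(COMPARTMENTS, names(compartmentSets))
  if (length(missing))
    failWith("missing compartment set(s): ", paste(missing, collapse = ", "))
  compartmentSets <- compartmentSets[COMPARTMENTS]
  sproutSet <- detectionSet(sprout, sampleIds(sprout), "sprout",
                            minCount = minCount, minSamples = minSamples)
  ids <- detectedAsvs(sproutSet)
  presence <- vapply(compartmentSets,
                     function(s) ids %in% detectedAsvs(s),
                     logical(length(ids)))
  presence <- matrix(presence, nrow = length(ids),
                     dimnames = list(ids, COMPARTMENTS))
  inAny <- rowSums(presence) >= 1
  inAll <- rowSums(presence) == length(COMPARTMENTS)
  rel <- relAbundance(sprout)[ids, , drop = FALSE]
  share <- function(sel) if (!any(sel)) 0 else
    mean(colSums(rel[sel, , drop = FALSE]))
  shared <- colSums(presence)
  methods::new("SourceAttribution",
               nSproutAsvs = length(ids),
               perCompartmentShared = structure(as.integer(shared),
                                                names = names(shared)),
               nInAny = as.integer(sum(inAny)),
               nInAll = as.integer(sum(inAll)),
               sproutUnique = ids[!inAny], presence = presence,
               abundance = c(sprout_unique = share(!inAny),
                             in_any = share(inAny), in_all = share(inAll)))
}

#' Per-compartment sharing of sprout ASVs
#'
#' @param attribution a [SourceAttribution-class].
#' @return `data.frame` with `compartment`, `count` and integer `percent`
#'   of sprout ASVs shared with each compartment.
#' @export
perCompartmentSharing <- function(attribution) {
  cnt <- attribution@perCompartmentShared
  data.frame(compartment = names(cnt), count = as.integer(cnt),
             percent = percentHalfUp(cnt / attribution@nSproutAsvs),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' TopAsvReport: the most abundant sprout ASVs
#'
#' @slot threshold mean relative-abundance threshold.
#' @slot table `data.frame` of `asv` and `mean_abundance`, sorted
#'   descending.
#' @slot cumulativeShare sum of the reported mean abundances.
#' @export
setClass("TopAsvReport", representation(
  threshold = "numeric", table = "data.frame", cumulativeShare = "numeric"))

setMethod("show", "TopAsvReport", function(object) {
  cat("TopAsvReport:", nrow(object@table), "ASVs above",
      paste0(100 * object@threshold, "%"), "mean relative abundance,",
      "cumulative share", sprintf("%.1f%%\n", 100 * object@cumulativeShare))
  print(utils::head(object@table, 20), row.names = FALSE)
})

#' @describeIn TopAsvReport ids of the reported ASVs.
#' @param x a `TopAsvReport`.
#' @export
topAsvs <- function(x) x@table$asv

#' Identify the most abundant ASVs of a community
#'
#' Ranks ASVs by their mean relative abundance across samples and keeps
#' those strictly above `threshold` (default 1%).
#'
#' @param x an [AsvExperiment-class] or relative-abundance matrix
#'   (ASVs x samples).
#' @param threshold mean relative-abundance cutoff, exclusive.
#' @return a [TopAsvReport-class]; the table may be empty.
#' @export
topAbundantAsvs <- function(x, threshold = 0.01) {
  rel <- if (methods::is(x, "SummarizedExperiment")) relAbundance(x)
         else as.matrix(x)
  mu <- rowMeans(rel)
  keep <- mu > threshold
  ord <- order(mu[keep], decreasing = TRUE)
  tab <- data.frame(asv = names(mu[keep])[ord],
                    mean_abundance = unname(mu[keep][ord]),
                    stringsAsFactors = FALSE)
  methods::new("TopAsvReport", threshold = threshold, table = tab,
               cumulativeShare = sum(tab$mean_abundance))
}

# Compact letter display from pairwise rejection decisions.
# `diffPairs` is a 2-column character matrix of group pairs declared
# different. Insert-and-absorb: start from one set holding all groups;
# every significant pair splits each set containing both; subsets of other
# sets are then absorbed. Groups sharing a letter are never declared
# different.
compactLetters <- function(groups, diffPairs) {
  sets <- list(groups)
  if (length(diffPairs)) {
    for (k in seq_len(nrow(diffPairs))) {
      a <- diffPairs[k, 1]; b <- diffPairs[k, 2]
      newSets <- list()
      for (s in sets) {
        if (a %in% s && b %in% s) {
          newSets <- c(newSets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else {
          newSets <- c(newSets, list(s))
        }
      }
      # absorb sets contained in another set
      keep <- rep(TRUE, length(newSets))
      for (i in seq_along(newSets)) {
        for (j in seq_along(newSets)) {
          if (i != j && keep[j] &&
              all(newSets[[i]] %in% newSets[[j]]) &&
              (length(newSets[[i]]) < length(newSets[[j]]) || i > j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      sets <- unique(newSets[keep])
    }
  }
  sets <- sets[order(vapply(sets, function(s) min(match(s, groups)),
                            numeric(1)))]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    out[sets[[i]]] <- paste0(out[sets[[i]]], LETTERS[i])
  out
}

#' One-way ANOVA with Tukey HSD on agglomerated top-ASV abundance
#'
#' For each sample, the agglomerated abundance is the cumulative relative
#' abundance of a fixed ASV set (typically the top sprout ASVs); ASVs
#' absent from a table contribute zero. A standard one-way ANOVA compares
#' groups, followed by Tukey's HSD (Tukey-Kramer for unequal group sizes)
#' at `alpha`, summarized as a compact letter display in which groups
#' sharing a letter do not differ significantly.
#'
#' @param asvSet character vector of ASV ids to agglomerate.
#' @param tables named list mapping group label (e.g. sample type or
#'   compartment) to an [AsvExperiment-class] or relative-abundance matrix
#'   of that group's samples; every group needs >= 2 samples.
#' @param alpha significance level for the letter display.
#' @return list with `values` (per-sample `data.frame`: `group`, `sample`,
#'   `value`), `anova` (`F`, `p`, degrees of freedom), `tukey`
#'   (`data.frame` of pairwise differences and adjusted p) and `letters`
#'   (named character).
#' @export
agglomeratedAbundanceTest <- function(asvSet, tables, alpha = 0.05) {
  if (length(tables) < 2) failWith("need at least 2 groups")
  if (is.null(names(tables))) failWith("tables must be named by group")
  vals <- do.call(rbind, lapply(names(tables), function(g) {
    x <- tables[[g]]
    rel <- if (methods::is(x, "SummarizedExperiment")) relAbundance(x)
           else as.matrix(x)
    hit <- intersect(asvSet, rownames(rel))
    v <- if (length(hit)) colSums(rel[hit, , drop = FALSE])
         else stats::setNames(rep(0, ncol(rel)), colnames(rel))
    data.frame(group = g, sample = colnames(rel), value = unname(v),
               stringsAsFactors = FALSE)
  }))
  sizes <- table(vals$group)
  if (any(sizes < 2))
    failWith("group(s) with fewer than 2 samples: ",
             paste(names(sizes)[sizes < 2], collapse = ", "))
  vals$group <- factor(vals$group, levels = names(tables))
  fit <- stats::aov(value ~ group, data = vals)
  an <- summary(fit)[[1]]
  Fval <- an[["F value"]][1]
  pval <- an[["Pr(>F)"]][1]
  # Degenerate cases: between-group variance at floating-point zero means
  # no effect (F = 0, p = 1); zero residual with real separation means an
  # infinitely strong one.
  if (an[["Sum Sq"]][1] < 1e-12) {
    Fval <- 0; pval <- 1
  } else if (!is.finite(Fval)) {
    Fval <- Inf; pval <- 0
  }
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairNames <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- data.frame(group1 = vapply(pairNames, `[`, "", 1),
                      group2 = vapply(pairNames, `[`, "", 2),
                      diff = tk[, "diff"], p_adj = tk[, "p adj"],
                      row.names = NULL, stringsAsFactors = FALSE)
  tukey$p_adj[is.nan(tukey$p_adj)] <- 1
  diffPairs <- as.matrix(tukey[tukey$p_adj < alpha, c("group1", "group2")])
  letters <- compactLetters(levels(vals$group), diffPairs)
  list(values = vals,
       anova = list(F = Fval, p = pval,
                    df_between = an[["Df"]][1], df_within = an[["Df"]][2]),
       tukey = tukey, letters = letters)
}
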