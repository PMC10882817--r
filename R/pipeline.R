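# End-to-end orchestration: from a configuration (R list, YAML or JSON
# file) through preprocessing, detection-set algebra, transmission
# accounting and community statistics to a single machine-readable run
# report. The report is the source of truth; any TSV export is a derived
# view of it.

readRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (grepl("\\.ya?ml$", config)) {
      config <- yaml::read_yaml(config)
    } else if (grepl("\\.json$", config)) {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      failWith("config file must be .yaml/.yml or .json")
    }
  }
  if (!is.list(config)) failWith("config must be a list or a file path")
  config
}

#' Run the full analysis pipeline
#'
#' Executes, in a fixed order: data loading (or synthetic generation),
#' off-target taxon removal, rare-ASV filtering, rarefaction, per-group
#' detection sets, the overlap partition with shared fractions,
#' field-unique ASV identification, seed-to-offspring transmission
#' accounting with destination abundance, PERMANOVA on the configured
#' factor, and richness with a Kruskal-Wallis test across sample types.
#' The stage order is recorded in the report's `log`.
#'
#' @param config an R list, or path to a YAML/JSON file, with (all
#'   optional unless noted) entries:
#'   \describe{
#'     \item{`simulate`}{list of [simConfig()] arguments; when present the
#'       input tables are generated synthetically (seed tubers plus next
#'       generation).}
#'     \item{`input`}{alternative to `simulate`: list with `counts` path,
#'       `format`, `orientation`, `metadata` path, `taxonomy` path.}
#'     \item{`marker`}{`"16S"` (default) or `"ITS"`.}
#'     \item{`filter`}{`minTotalReads` (30), `minPrevalence` (3).}
#'     \item{`rarefy`}{`depth` (10000) and `seed` (required for the
#'       stage).}
#'     \item{`detection`}{`minCount` (1), `minSamples` (1).}
#'     \item{`focalVariety`, `focalField`}{stratum for uniqueness and
#'       transmission (defaults `"V1"`, `"F1"`).}
#'     \item{`permanova`}{`factor` (default `"production_field"`),
#'       `permutations` (999), `seed`.}
#'   }
#' @param outDir optional directory; when given, the report is written to
#'   `run_report.json` there.
#' @return the run report, an R list.
#' @export
runPipeline <- function(config, outDir = NULL) {
  config <- readRunConfig(config)
  marker <- config$marker %||% "16S"
  log <- character(0)
  report <- list(params = config)

  # --- input ----------------------------------------------------------
  if (!is.null(config$simulate)) {
    sc <- do.call(simConfig, config$simulate)
    sim <- simulateSeedTubers(sc)
    nxt <- simulateNextGeneration(sim$truth, sc)
    x <- SummarizedExperiment::cbind(sim$experiment, nxt$experiment)
    log <- c(log, "simulate")
  } else if (!is.null(config$input)) {
    inp <- config$input
    x <- readCountTable(inp$counts,
                        format = inp$format %||% "tsv",
                        orientation = inp$orientation %||% "samples_by_asvs",
                        sampleData = inp$metadata,
                        taxonomy = inp$taxonomy)
    log <- c(log, "load")
  } else {
    failWith("config needs either 'simulate' or 'input'")
  }
  report$input <- list(n_samples = ncol(x), n_asvs = nrow(x))

  # --- preprocessing (fixed order) ------------------------------------
  n0 <- nrow(x)
  x <- removeOfftargetTaxa(x, marker = marker)
  log <- c(log, "offtarget_removal")
  nOff <- nrow(x)
  filt <- config$filter %||% list()
  x <- filterRareAsvs(x, minTotalReads = filt$minTotalReads %||% 30,
                      minPrevalence = filt$minPrevalence %||% 3)
  log <- c(log, "rare_asv_filter")
  nFilt <- nrow(x)
  rar <- config$rarefy %||% list()
  depth <- rar$depth %||% 10000
  x <- rarefy(x, depth = depth, seed = rar$seed %||% 1, pruneEmpty = FALSE)
  log <- c(log, "rarefaction")
  report$preprocessing <- list(
    n_asvs_input = n0, n_asvs_after_offtarget = nOff,
    n_asvs_after_rare_filter = nFilt, rarefaction_depth = depth,
    rarefaction_seed = rar$seed %||% 1,
    samples_dropped = S4Vectors::metadata(x)$rarefaction$dropped)

  # --- detection sets in the focal variety ----------------------------
  det <- config$detection %||% list()
  minCount <- det$minCount %||% 1
  minSamples <- det$minSamples %||% 1
  focalVariety <- config$focalVariety %||% "V1"
  focalField <- config$focalField %||% "F1"
  cd <- sampleData(x)
  types <- intersect(c("seed_tuber", "post_storage_seed_tuber",
                       "daughter_tuber", "root"), unique(cd$sample_type))
  mkSet <- function(type, field = NULL, name = type) {
    args <- list(x, sample_type = type, variety = focalVariety)
    if (!is.null(field)) args$production_field <- field
    ids <- do.call(selectSamples, args)
    if (!length(ids)) return(NULL)
    detectionSet(x, ids, name, minCount = minCount,
                 minSamples = minSamples,
                 meta = list(variety = focalVariety, sample_type = type,
                             marker = marker,
                             production_field = field %||% "all"))
  }
  sets <- Filter(Negate(is.null),
                 stats::setNames(lapply(types, mkSet), types))
  log <- c(log, "detection_sets")
  report$detection <- list(
    rule = list(min_count = minCount, min_samples = minSamples),
    set_sizes = lapply(sets, function(s) length(detectedAsvs(s))))

  # --- overlap partition and shared fractions -------------------------
  trio <- intersect(c("seed_tuber", "daughter_tuber", "root"), names(sets))
  if (length(trio) >= 2) {
    part <- overlapPartition(sets[trio])
    rc <- regionCounts(part)
    report$partition <- stats::setNames(as.list(rc$count), rc$region)
    sf <- list()
    if (all(c("daughter_tuber", "root") %in% trio))
      sf$daughter_with_root <-
        sharedFraction(part, "daughter_tuber", "root")
    if (all(c("daughter_tuber", "seed_tuber") %in% trio))
      sf$daughter_with_seed <-
        sharedFraction(part, "daughter_tuber", "seed_tuber")
    if (all(c("root", "seed_tuber") %in% trio))
      sf$root_with_seed <- sharedFraction(part, "root", "seed_tuber")
    report$shared_fractions <- sf
    log <- c(log, "overlap_partition")
  }

  # --- field-unique ASVs ----------------------------------------------
  fields <- sort(unique(cd$production_field))
  uniques <- list()
  if (length(fields) >= 2) {
    for (type in trio) {
      perField <- Filter(Negate(is.null),
                         stats::setNames(lapply(fields, function(f)
                           mkSet(type, field = f, name = f)), fields))
      if (length(perField) >= 2 && focalField %in% names(perField)) {
        uniques[[type]] <- fieldUniqueAsvs(perField, focalField)
      }
    }
    report$field_unique <- lapply(uniques, function(u) list(
      focal_field = u@focal, n_unique = length(uniqueAsvs(u)),
      focal_total = u@focalTotal, fraction = u@fraction,
      percent = percentHalfUp(u@fraction, 1)))
    log <- c(log, "field_unique")
  }

  # --- transmission accounting ----------------------------------------
  srcSet <- if ("seed_tuber" %in% names(sets))
    mkSet("seed_tuber", field = focalField, name = "seed_tuber") else NULL
  trans <- list()
  for (destType in intersect(c("daughter_tuber", "root",
                               "post_storage_seed_tuber"), types)) {
    destSet <- mkSet(destType, field = focalField, name = destType)
    if (is.null(srcSet) || is.null(destSet)) next
    ts <- classifyTransmission(srcSet, destSet)
    if (!is.null(uniques[["seed_tuber"]]) && !is.null(uniques[[destType]])) {
      uu <- uniqueUniqueOverlap(uniques[["seed_tuber"]],
                                uniques[[destType]])
      ts <- setUniqueUnique(ts, intersect(uu, ts@shared))
    }
    destSamples <- selectSamples(x, sample_type = destType,
                                 variety = focalVariety,
                                 production_field = focalField)
    ts <- abundanceAccounting(ts, x, samples = destSamples, mode = "mean")
    tf <- transmissionFractions(ts)
    trans[[destType]] <- list(
      source = "seed_tuber", dest = destType,
      n_source = nSource(ts), n_dest = nDest(ts),
      n_shared = length(ts@shared), n_lost = length(ts@lost),
      n_acquired = length(ts@acquired),
      n_unique_unique = length(ts@uniqueUnique),
      fractions = stats::setNames(as.list(tf$fraction), tf$ratio),
      dest_abundance = as.list(ts@destAbundance))
  }
  if (length(trans)) {
    report$transmission <- trans
    log <- c(log, "transmission")
  }

  # --- community statistics -------------------------------------------
  pv <- config$permanova %||% list()
  pvFactor <- pv$factor %||% "production_field"
  if (pvFactor %in% names(cd) &&
      length(unique(cd[[pvFactor]])) >= 2) {
    dm <- brayCurtis(x)
    grouping <- stats::setNames(cd[[pvFactor]], rownames(cd))
    pr <- permanova(dm, grouping, nPerm = pv$permutations %||% 999,
                    seed = pv$seed %||% 1, factorName = pvFactor)
    report$permanova <- list(
      factor = pvFactor, pseudo_F = pr@pseudoF, R2 = pr@r2,
      p_value = pr@pValue, n_permutations = pr@nPerm, seed = pr@seed,
      ss_between = pr@ssBetween, ss_within = pr@ssWithin,
      ss_total = pr@ssTotal, n_samples = pr@n, n_groups = pr@nGroups)
    log <- c(log, "permanova")
  }
  if (length(unique(cd$sample_type)) >= 2) {
    rt <- richnessTest(x, stats::setNames(cd$sample_type, rownames(cd)))
    report$richness <- list(
      per_sample = as.list(rt$richness),
      kruskal_wallis = list(H = rt$H, df = rt$df, p = rt$p))
    log <- c(log, "richness")
  }

  report$log <- log
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         null = "null")
  }
  report
}
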