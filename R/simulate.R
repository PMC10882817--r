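# Synthetic community generator with recorded ground truth. Emulates the
# hierarchical structure the analysis assumes: several production fields
# sharing a core community but each carrying field-specific ASVs, a
# multiplicative genotype effect, a transmission bottleneck from seed
# tuber to next-generation organs against a dominant resident soil
# community, a richness gradient across tuber compartments, and selective
# amplification of a small ASV subset on sprouts. Counts are
# Dirichlet-multinomial so that replicate samples are overdispersed
# relative to multinomial sampling, as amplicon data are.

#' SimConfig: parameters of the community simulator
#'
#' Defaults mirror the sampling design the analysis targets: 3 production
#' fields by 2 varieties with 4 replicate samples per field, 10,000 reads
#' per sample, a shared log-normal core community with field-specific ASVs
#' on top, a seed-to-daughter transmission fraction of 0.2 (so 80% of the
#' next generation's expected abundance comes from the trial-field soil),
#' a decreasing compartment retention gradient from adhering soil to
#' flesh, and 18 sprout-favored ASVs amplified 50-fold.
#'
#' @slot nFields,nVarieties numbers of production fields and varieties.
#' @slot nCoreAsvs,nUniquePerField sizes of the shared core community and
#'   of each field's private ASV set.
#' @slot abundMu,abundSigma log-scale mean and sd of ASV base abundances.
#' @slot theta Dirichlet concentration scaler; larger means less
#'   overdispersion (multinomial in the limit).
#' @slot depth reads per sample.
#' @slot nSamples replicate samples per group; `nSproutSamples` for
#'   sprouts.
#' @slot pi transmission fraction: weight of the seed tuber profile in the
#'   expected next-generation profile.
#' @slot soilSize,soilCoreOverlap trial-field soil community size and the
#'   fraction of core ASVs it shares.
#' @slot fieldEffect multiplier on field-unique ASV abundances; the
#'   between-field effect-size knob.
#' @slot varietyEffect,varietyEffectFrac multiplicative genotype effect and
#'   the fraction of ASVs it touches.
#' @slot compartmentRetention nested retention fractions for adhering
#'   soil, peel, heel end, eye, flesh (non-increasing).
#' @slot sproutFavoredN,sproutSelection size of the sprout-favored ASV set
#'   and its amplification factor (>= 1).
#' @slot sproutMixtureWeights mixture weights of the 5 compartment
#'   profiles in the sprout expectation.
#' @slot seed default RNG seed for the generators.
#' @export
setClass("SimConfig", representation(
  nFields = "integer", nVarieties = "integer", nCoreAsvs = "integer",
  nUniquePerField = "integer", abundMu = "numeric", abundSigma = "numeric",
  theta = "numeric", depth = "integer", nSamples = "integer",
  nSproutSamples = "integer", pi = "numeric", soilSize = "integer",
  soilCoreOverlap = "numeric", fieldEffect = "numeric",
  varietyEffect = "numeric", varietyEffectFrac = "numeric",
  compartmentRetention = "numeric", sproutFavoredN = "integer",
  sproutSelection = "numeric", sproutMixtureWeights = "numeric",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@nFields < 1 || object@nVarieties < 1)
    return("need at least one field and one variety")
  if (object@nCoreAsvs == 0 && object@nUniquePerField == 0)
    return("community cannot be empty (no core and no unique ASVs)")
  if (object@pi < 0 || object@pi > 1) return("pi must be in [0, 1]")
  if (length(object@compartmentRetention) != 5)
    return("compartmentRetention must have 5 entries")
  if (any(diff(object@compartmentRetention) > 1e-12))
    return("compartmentRetention must be non-increasing")
  if (any(object@compartmentRetention <= 0))
    return("compartmentRetention must be positive")
  if (object@sproutSelection < 1) return("sproutSelection must be >= 1")
  if (length(object@sproutMixtureWeights) != 5 ||
      any(object@sproutMixtureWeights < 0))
    return("sproutMixtureWeights must be 5 non-negative weights")
  if (object@depth < 1 || object@nSamples < 2)
    return("depth >= 1 and nSamples >= 2 required")
  TRUE
})

#' Construct a simulator configuration
#'
#' @param nFields,nVarieties,nCoreAsvs,nUniquePerField,abundMu,abundSigma
#'   see [SimConfig-class].
#' @param theta,depth,nSamples,nSproutSamples,pi,soilSize,soilCoreOverlap
#'   see [SimConfig-class].
#' @param fieldEffect,varietyEffect,varietyEffectFrac see
#'   [SimConfig-class].
#' @param compartmentRetention,sproutFavoredN,sproutSelection see
#'   [SimConfig-class].
#' @param sproutMixtureWeights normalized internally to sum to 1.
#' @param seed default RNG seed.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nFields = 3, nVarieties = 2, nCoreAsvs = 300,
                      nUniquePerField = 120, abundMu = 0, abundSigma = 1.5,
                      theta = 500, depth = 10000, nSamples = 4,
                      nSproutSamples = 5, pi = 0.2, soilSize = 500,
                      soilCoreOverlap = 0.25, fieldEffect = 1,
                      varietyEffect = 2, varietyEffectFrac = 0.1,
                      compartmentRetention = c(1, 0.8, 0.6, 0.4, 0.2),
                      sproutFavoredN = 18, sproutSelection = 50,
                      sproutMixtureWeights = rep(0.2, 5), seed = 1) {
  w <- sproutMixtureWeights / sum(sproutMixtureWeights)
  methods::new("SimConfig",
               nFields = as.integer(nFields),
               nVarieties = as.integer(nVarieties),
               nCoreAsvs = as.integer(nCoreAsvs),
               nUniquePerField = as.integer(nUniquePerField),
               abundMu = abundMu, abundSigma = abundSigma, theta = theta,
               depth = as.integer(depth), nSamples = as.integer(nSamples),
               nSproutSamples = as.integer(nSproutSamples), pi = pi,
               soilSize = as.integer(soilSize),
               soilCoreOverlap = soilCoreOverlap,
               fieldEffect = fieldEffect, varietyEffect = varietyEffect,
               varietyEffectFrac = varietyEffectFrac,
               compartmentRetention = compartmentRetention,
               sproutFavoredN = as.integer(sproutFavoredN),
               sproutSelection = sproutSelection,
               sproutMixtureWeights = w, seed = as.integer(seed))
}

#' SyntheticTruth: recorded ground truth of a simulation
#'
#' @slot asvs the full ASV universe (core, field-unique, soil).
#' @slot coreSet,soilSet,fieldUnique ground-truth set structure;
#'   `fieldUnique` is a list keyed by field, pairwise disjoint and disjoint
#'   from the core.
#' @slot seedProfiles expected seed tuber relative-abundance profiles,
#'   keyed `"V<v>.F<f>"`, each a named vector over the universe.
#' @slot soilProfile expected trial-field soil profile.
#' @slot pi transmission fraction used for the next generation.
#' @slot destProfiles expected next-generation profiles (filled by
#'   [simulateNextGeneration()]).
#' @slot compartmentPools,sproutProfile,favoredSet compartment ASV pools,
#'   expected sprout profile and the sprout-favored set (filled by
#'   [simulateCompartmentsAndSprout()]).
#' @slot config the [SimConfig-class] used.
#' @export
setClass("SyntheticTruth", representation(
  asvs = "character", coreSet = "character", soilSet = "character",
  fieldUnique = "list", seedProfiles = "list", soilProfile = "numeric",
  pi = "numeric", destProfiles = "list", compartmentPools = "list",
  sproutProfile = "numeric", favoredSet = "character",
  config = "SimConfig"))

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@asvs), "ASVs (",
      length(object@coreSet), "core,",
      sum(lengths(object@fieldUnique)), "field-unique over",
      length(object@fieldUnique), "fields,",
      length(object@soilSet), "soil )\n")
  cat("  transmission fraction pi =", object@pi, "\n")
  if (length(object@favoredSet))
    cat("  sprout-favored set:", length(object@favoredSet), "ASVs\n")
})

# One Dirichlet-multinomial draw per row: expected composition `profile`,
# concentration theta * profile, `depth` reads.
rDirichletMultinomial <- function(nDraws, depth, profile, theta) {
  alpha <- theta * profile
  out <- matrix(0L, length(profile), nDraws,
                dimnames = list(names(profile), NULL))
  for (k in seq_len(nDraws)) {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(g) == 0) g[which.max(profile)] <- 1
    out[, k] <- as.integer(stats::rmultinom(1, depth, g / sum(g)))
  }
  out
}

fieldNames <- function(config) paste0("F", seq_len(config@nFields))
varietyNames <- function(config) paste0("V", seq_len(config@nVarieties))
profileKey <- function(v, f) paste(v, f, sep = ".")

# Synthetic lineage table so taxonomy-dependent stages run unchanged on
# simulated data (all ASVs are in-target bacteria).
syntheticTaxonomy <- function(asvs) {
  data.frame(asv_id = asvs,
             lineage = "Bacteria;Synthetic_phylum;Synthetic_genus",
             stringsAsFactors = FALSE)
}

#' Simulate seed tuber communities across fields and varieties
#'
#' Each field's expected community is the shared log-normal core plus that
#' field's private ASVs (scaled by `fieldEffect`); each variety beyond the
#' first multiplies a random ASV subset by `varietyEffect`. Per-sample
#' counts are Dirichlet-multinomial draws from the normalized profile at
#' concentration `theta` and the configured depth. The trial-field soil
#' profile (used by [simulateNextGeneration()]) is drawn here as well so
#' the full ASV universe and ground truth are fixed up front.
#'
#' @param config a [SimConfig-class].
#' @param seed RNG seed (defaults to `config@seed`).
#' @return list with `experiment` (an [AsvExperiment-class] of
#'   `seed_tuber` samples with synthetic taxonomy) and `truth`
#'   (a [SyntheticTruth-class]).
#' @export
simulateSeedTubers <- function(config, seed = config@seed) {
  methods::validObject(config)
  core <- sprintf("core_%04d", seq_len(config@nCoreAsvs))
  fields <- fieldNames(config)
  uniq <- lapply(fields, function(f)
    sprintf("%s_uniq_%04d", tolower(f), seq_len(config@nUniquePerField)))
  names(uniq) <- fields
  soil <- sprintf("soil_%04d", seq_len(config@soilSize))
  universe <- c(core, unlist(uniq, use.names = FALSE), soil)

  res <- withSeed(seed, {
    coreAb <- stats::rlnorm(length(core), config@abundMu, config@abundSigma)
    names(coreAb) <- core
    uniqAb <- lapply(uniq, function(ids) {
      x <- config@fieldEffect *
        stats::rlnorm(length(ids), config@abundMu, config@abundSigma)
      names(x) <- ids
      x
    })
    tuberIds <- c(core, unlist(uniq, use.names = FALSE))
    varMult <- list()
    for (v in varietyNames(config)) {
      mult <- stats::setNames(rep(1, length(universe)), universe)
      if (v != "V1" && config@varietyEffectFrac > 0) {
        hit <- sample(tuberIds,
                      ceiling(config@varietyEffectFrac * length(tuberIds)))
        mult[hit] <- config@varietyEffect
      }
      varMult[[v]] <- mult
    }
    profiles <- list()
    for (v in varietyNames(config)) {
      for (f in fields) {
        vec <- stats::setNames(numeric(length(universe)), universe)
        vec[core] <- coreAb
        vec[names(uniqAb[[f]])] <- uniqAb[[f]]
        vec <- vec * varMult[[v]]
        profiles[[profileKey(v, f)]] <- vec / sum(vec)
      }
    }
    soilIds <- c(soil, sample(core, round(config@soilCoreOverlap *
                                            length(core))))
    soilProfile <- stats::setNames(numeric(length(universe)), universe)
    soilProfile[soilIds] <- stats::rlnorm(length(soilIds), config@abundMu,
                                          config@abundSigma)
    soilProfile <- soilProfile / sum(soilProfile)

    counts <- NULL
    cd <- NULL
    for (v in varietyNames(config)) {
      for (f in fields) {
        draw <- rDirichletMultinomial(config@nSamples, config@depth,
                                      profiles[[profileKey(v, f)]],
                                      config@theta)
        ids <- sprintf("seed_tuber.%s.%s.r%d", v, f,
                       seq_len(config@nSamples))
        colnames(draw) <- ids
        counts <- cbind(counts, draw)
        cd <- rbind(cd, data.frame(
          sample_id = ids, marker = "16S", variety = v,
          production_field = f, sample_type = "seed_tuber",
          replicate = paste0("r", seq_len(config@nSamples)),
          stringsAsFactors = FALSE))
      }
    }
    list(counts = counts, cd = cd, profiles = profiles,
         soilProfile = soilProfile)
  })

  truth <- methods::new("SyntheticTruth",
                        asvs = universe, coreSet = core, soilSet = soil,
                        fieldUnique = uniq, seedProfiles = res$profiles,
                        soilProfile = res$soilProfile, pi = config@pi,
                        destProfiles = list(), compartmentPools = list(),
                        sproutProfile = numeric(0),
                        favoredSet = character(0), config = config)
  exp <- AsvExperiment(res$counts, sampleData = res$cd,
                       taxonomy = syntheticTaxonomy(universe))
  list(experiment = exp, truth = truth)
}

#' Simulate daughter tubers and roots of the next generation
#'
#' The expected next-generation profile of each (variety, field) group is
#' the mixture `pi * seed profile + (1 - pi) * soil profile`: a
#' transmission bottleneck against the dominant resident soil community of
#' the single trial field in which all seed tubers are planted. Daughter
#' tuber and root samples are independent Dirichlet-multinomial draws from
#' that mixture.
#'
#' @param truth the [SyntheticTruth-class] from [simulateSeedTubers()].
#' @param config a [SimConfig-class] (defaults to the one recorded in
#'   `truth`; `pi` is taken from here).
#' @param seed RNG seed.
#' @return list with `experiment` (`daughter_tuber` and `root` samples)
#'   and the updated `truth` (destination profiles and `pi` recorded).
#' @export
simulateNextGeneration <- function(truth, config = truth@config,
                                   seed = config@seed + 1) {
  piVal <- config@pi
  res <- withSeed(seed, {
    counts <- NULL
    cd <- NULL
    dest <- list()
    for (key in names(truth@seedProfiles)) {
      profile <- piVal * truth@seedProfiles[[key]] +
        (1 - piVal) * truth@soilProfile
      dest[[key]] <- profile
      vf <- strsplit(key, ".", fixed = TRUE)[[1]]
      for (type in c("daughter_tuber", "root")) {
        draw <- rDirichletMultinomial(config@nSamples, config@depth,
                                      profile, config@theta)
        ids <- sprintf("%s.%s.%s.r%d", type, vf[1], vf[2],
                       seq_len(config@nSamples))
        colnames(draw) <- ids
        counts <- cbind(counts, draw)
        cd <- rbind(cd, data.frame(
          sample_id = ids, marker = "16S", variety = vf[1],
          production_field = vf[2], sample_type = type,
          replicate = paste0("r", seq_len(config@nSamples)),
          stringsAsFactors = FALSE))
      }
    }
    list(counts = counts, cd = cd, dest = dest)
  })
  truth@destProfiles <- res$dest
  truth@pi <- piVal
  exp <- AsvExperiment(res$counts, sampleData = res$cd,
                       taxonomy = syntheticTaxonomy(truth@asvs))
  list(experiment = exp, truth = truth)
}

#' Simulate seed tuber compartments and sprouts for one field
#'
#' Compartment ASV pools are nested random subsets of the focal (variety,
#' field) tuber community with the configured retention fractions, which
#' produces the expected richness gradient from adhering soil down to
#' flesh. The expected sprout profile is a weighted mixture of the five
#' compartment profiles in which the sprout-favored ASVs (drawn from the
#' flesh pool, hence present in every compartment) are amplified by
#' `sproutSelection` and the profile renormalized.
#'
#' @param truth the [SyntheticTruth-class] from [simulateSeedTubers()].
#' @param config a [SimConfig-class].
#' @param seed RNG seed.
#' @param variety,field the focal group whose tubers are dissected.
#' @return list with `experiment` (five compartment sample types plus
#'   `sprout` samples) and the updated `truth` (pools, sprout profile,
#'   favored set).
#' @export
simulateCompartmentsAndSprout <- function(truth, config = truth@config,
                                          seed = config@seed + 2,
                                          variety = "V1", field = "F1") {
  key <- profileKey(variety, field)
  profile <- truth@seedProfiles[[key]]
  if (is.null(profile)) failWith("no seed profile for ", key)
  pool <- names(profile)[profile > 0]
  res <- withSeed(seed, {
    perm <- sample(pool)
    pools <- lapply(config@compartmentRetention, function(r)
      perm[seq_len(ceiling(r * length(perm)))])
    names(pools) <- COMPARTMENTS
    compProfiles <- lapply(pools, function(ids) {
      v <- profile
      v[setdiff(names(v), ids)] <- 0
      v / sum(v)
    })
    sprout <- Reduce(`+`, Map(`*`, compProfiles,
                              as.list(config@sproutMixtureWeights)))
    # Favored ASVs come from the mid-abundance band of the flesh pool
    # (present in every compartment by nesting): modestly abundant on the
    # tuber, so that the selection factor, not the base abundance,
    # determines their dominance on the sprout.
    fleshAb <- sprout[pools[["flesh"]]]
    qs <- stats::quantile(fleshAb, c(0.6, 0.9))
    band <- pools[["flesh"]][fleshAb >= qs[1] & fleshAb <= qs[2]]
    favored <- sample(band, min(config@sproutFavoredN, length(band)))
    sprout[favored] <- sprout[favored] * config@sproutSelection
    sprout <- sprout / sum(sprout)

    counts <- NULL
    cd <- NULL
    for (comp in COMPARTMENTS) {
      draw <- rDirichletMultinomial(config@nSamples, config@depth,
                                    compProfiles[[comp]], config@theta)
      ids <- sprintf("%s.%s.%s.r%d", comp, variety, field,
                     seq_len(config@nSamples))
      colnames(draw) <- ids
      counts <- cbind(counts, draw)
      cd <- rbind(cd, data.frame(
        sample_id = ids, marker = "16S", variety = variety,
        production_field = field, sample_type = comp,
        replicate = paste0("r", seq_len(config@nSamples)),
        stringsAsFactors = FALSE))
    }
    draw <- rDirichletMultinomial(config@nSproutSamples, config@depth,
                                  sprout, config@theta)
    ids <- sprintf("sprout.%s.%s.r%d", variety, field,
                   seq_len(config@nSproutSamples))
    colnames(draw) <- ids
    counts <- cbind(counts, draw)
    cd <- rbind(cd, data.frame(
      sample_id = ids, marker = "16S", variety = variety,
      production_field = field, sample_type = "sprout",
      replicate = paste0("r", seq_len(config@nSproutSamples)),
      stringsAsFactors = FALSE))
    list(counts = counts, cd = cd, pools = pools, sprout = sprout,
         favored = favored)
  })
  truth@compartmentPools <- res$pools
  truth@sproutProfile <- res$sprout
  truth@favoredSet <- res$favored
  exp <- AsvExperiment(res$counts, sampleData = res$cd,
                       taxonomy = syntheticTaxonomy(truth@asvs))
  list(experiment = exp, truth = truth)
}

#' Estimate the transmission fraction from a destination table
#'
#' Least-squares projection of the mean destination profile onto the line
#' between the soil and seed profiles: with `delta = seed - soil`,
#' `pi_hat = <mean_dest - soil, delta> / <delta, delta>`, clipped to
#' `[0, 1]`. This is the closed-form minimizer of the squared error of the
#' mixture model `pi * seed + (1 - pi) * soil` and serves as a validation
#' estimator for the generator, not as an inference method for real data.
#'
#' @param dest an [AsvExperiment-class] of destination samples or a
#'   relative-abundance matrix (ASVs x samples).
#' @param seedProfile,soilProfile named expected profiles on a shared ASV
#'   universe; destination ASVs absent from the universe are ignored,
#'   universe ASVs absent from the table count as zero.
#' @return estimated transmission fraction `pi_hat` in `[0, 1]`.
#' @export
recoverTransmissionFraction <- function(dest, seedProfile, soilProfile) {
  if (!identical(names(seedProfile), names(soilProfile)))
    failWith("seed and soil profiles must share one ASV universe")
  delta <- seedProfile - soilProfile
  if (all(abs(delta) < 1e-15))
    failWith("seed and soil profiles are identical; pi is undefined")
  rel <- if (methods::is(dest, "SummarizedExperiment")) relAbundance(dest)
         else as.matrix(dest)
  m <- stats::setNames(numeric(length(seedProfile)), names(seedProfile))
  hit <- intersect(rownames(rel), names(m))
  m[hit] <- rowMeans(rel[hit, , drop = FALSE])
  piHat <- sum((m - soilProfile) * delta) / sum(delta^2)
  min(max(piHat, 0), 1)
}
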