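# The community simulator: determinism, ground-truth structure, limiting
# behaviour and the transmission-fraction recovery estimator.

smallConfig <- function(...) {
  args <- utils::modifyList(
    list(nFields = 2, nVarieties = 1, nCoreAsvs = 60,
         nUniquePerField = 25, soilSize = 80, depth = 2000,
         nSamples = 3), list(...))
  do.call(simConfig, args)
}

test_that("simulator configs are validated", {
  expect_error(simConfig(pi = 1.5), "pi")
  expect_error(simConfig(compartmentRetention = c(0.2, 0.4, 0.6, 0.8, 1)),
               "non-increasing")
  expect_error(simConfig(nCoreAsvs = 0, nUniquePerField = 0), "empty")
  expect_error(simConfig(sproutSelection = 0.5), ">= 1")
})

test_that("seed tuber simulation is reproducible and truth-consistent", {
  cfg <- smallConfig(seed = 13)
  a <- simulateSeedTubers(cfg)
  b <- simulateSeedTubers(cfg)
  expect_identical(asvCounts(a$experiment), asvCounts(b$experiment))

  tr <- a$truth
  # field-unique sets pairwise disjoint and disjoint from the core
  expect_length(intersect(tr@fieldUnique$F1, tr@fieldUnique$F2), 0)
  expect_length(intersect(unlist(tr@fieldUnique), tr@coreSet), 0)
  # profiles normalized over the full universe
  for (p in tr@seedProfiles) expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(sum(tr@soilProfile), 1, tolerance = 1e-12)
  # samples have the configured depth and annotation
  expect_true(all(colSums(asvCounts(a$experiment)) == cfg@depth))
  expect_setequal(unique(sampleData(a$experiment)$sample_type), "seed_tuber")

  # a different seed changes counts but not the set structure
  c2 <- simulateSeedTubers(cfg, seed = 99)
  expect_false(identical(asvCounts(a$experiment), asvCounts(c2$experiment)))
  expect_identical(lengths(c2$truth@fieldUnique), lengths(tr@fieldUnique))
})

test_that("with no unique ASVs every field-unique set is empty", {
  cfg <- smallConfig(nUniquePerField = 0, seed = 5)
  sim <- simulateSeedTubers(cfg)
  x <- sim$experiment
  sets <- stats::setNames(lapply(c("F1", "F2"), function(f)
    detectionSet(x, selectSamples(x, production_field = f), f)),
    c("F1", "F2"))
  u <- fieldUniqueAsvs(sets, "F1")
  # detections differ only by sampling zeros of shared ASVs; the truth
  # uniqueness is empty
  expect_length(sim$truth@fieldUnique$F1, 0)
  expect_true(all(uniqueAsvs(u) %in% sim$truth@coreSet))
})

test_that("sample frequencies approach the profile at high concentration", {
  cfg <- smallConfig(theta = 1e6, depth = 50000, nSamples = 8, seed = 23)
  sim <- simulateSeedTubers(cfg)
  prof <- sim$truth@seedProfiles[["V1.F1"]]
  rel <- relAbundance(sim$experiment[, selectSamples(
    sim$experiment, production_field = "F1")])
  est <- rowMeans(rel)[names(prof)]
  n <- cfg@nSamples * cfg@depth
  se <- sqrt(prof * (1 - prof) / n)
  z <- abs(est - prof) / (se + 1e-12)
  # individual deviations stay in the binomial range; allow the usual
  # multiplicity over ~250 ASVs
  expect_gt(mean(z < 3), 0.97)
  expect_true(all(z < 6))
})

test_that("transmission extremes behave as forced", {
  cfg0 <- smallConfig(pi = 0, seed = 31, soilCoreOverlap = 0)
  sim <- simulateSeedTubers(cfg0)
  nxt <- simulateNextGeneration(sim$truth, cfg0)
  # pi = 0: destination profile carries no seed-exclusive (non-soil) mass
  dp <- nxt$truth@destProfiles[["V1.F1"]]
  seedOnly <- setdiff(names(dp)[sim$truth@seedProfiles[["V1.F1"]] > 0],
                      sim$truth@soilSet)
  expect_equal(sum(dp[seedOnly]), 0)
  # every seed-exclusive ASV is classified lost (no counts can appear)
  x <- nxt$experiment
  src <- detectionSet(sim$experiment,
                      selectSamples(sim$experiment, production_field = "F1"),
                      "seed_tuber")
  dst <- detectionSet(x, selectSamples(x, sample_type = "daughter_tuber",
                                       production_field = "F1"), "daughter")
  ts <- classifyTransmission(src, dst)
  expect_length(intersect(ts@shared, seedOnly), 0)

  # pi = 1 with no soil overlap: destination equals the seed profile and
  # shared abundance approaches 1
  cfg1 <- smallConfig(pi = 1, seed = 37, soilCoreOverlap = 0,
                      depth = 20000)
  sim1 <- simulateSeedTubers(cfg1)
  nxt1 <- simulateNextGeneration(sim1$truth, cfg1)
  expect_equal(nxt1$truth@destProfiles[["V1.F1"]],
               sim1$truth@seedProfiles[["V1.F1"]])
  src1 <- detectionSet(sim1$experiment,
                       selectSamples(sim1$experiment, production_field = "F1"),
                       "seed_tuber")
  x1 <- nxt1$experiment
  dst1 <- detectionSet(x1, selectSamples(x1, sample_type = "daughter_tuber",
                                         production_field = "F1"), "daughter")
  ts1 <- abundanceAccounting(
    classifyTransmission(src1, dst1), x1,
    samples = selectSamples(x1, sample_type = "daughter_tuber",
                            production_field = "F1"))
  expect_gt(ts1@destAbundance[["shared"]], 0.99)
})

test_that("compartment richness decreases from soil to flesh in expectation", {
  meanRich <- matrix(NA_real_, nrow = 5, ncol = 5,
                     dimnames = list(tuberTrace:::COMPARTMENTS, NULL))
  for (rep in 1:5) {
    cfg <- smallConfig(seed = 200 + rep)
    sim <- simulateSeedTubers(cfg)
    cmp <- simulateCompartmentsAndSprout(sim$truth, cfg)
    r <- richness(cmp$experiment)
    st <- sampleData(cmp$experiment)$sample_type
    for (comp in tuberTrace:::COMPARTMENTS)
      meanRich[comp, rep] <- mean(r[st == comp])
    # pools are nested
    pools <- cmp$truth@compartmentPools
    for (k in 2:5)
      expect_true(all(pools[[k]] %in% pools[[k - 1]]))
  }
  avg <- rowMeans(meanRich)
  expect_true(all(diff(avg) < 0))
})

test_that("sprout selection amplifies the favored set into the top ASVs", {
  cfg <- smallConfig(seed = 301, sproutFavoredN = 8, sproutSelection = 50)
  sim <- simulateSeedTubers(cfg)
  cmp <- simulateCompartmentsAndSprout(sim$truth, cfg)
  spr <- cmp$experiment[, selectSamples(cmp$experiment,
                                        sample_type = "sprout")]
  top <- topAbundantAsvs(spr, threshold = 0.01)
  expect_true(all(cmp$truth@favoredSet %in% topAsvs(top)))

  # s = 1: sprout profile is exactly the compartment mixture
  cfg1 <- smallConfig(seed = 302, sproutSelection = 1)
  sim1 <- simulateSeedTubers(cfg1)
  cmp1 <- simulateCompartmentsAndSprout(sim1$truth, cfg1)
  pools <- cmp1$truth@compartmentPools
  prof <- sim1$truth@seedProfiles[["V1.F1"]]
  mix <- Reduce(`+`, lapply(pools, function(ids) {
    v <- prof; v[setdiff(names(v), ids)] <- 0; 0.2 * v / sum(v)
  }))
  expect_equal(cmp1$truth@sproutProfile, mix, tolerance = 1e-12)
})

test_that("transmission-fraction recovery is exact on noiseless mixtures", {
  cfg <- smallConfig(seed = 41)
  sim <- simulateSeedTubers(cfg)
  seedP <- sim$truth@seedProfiles[["V1.F1"]]
  soilP <- sim$truth@soilProfile
  # destination equal to one endpoint
  expect_equal(recoverTransmissionFraction(
    matrix(seedP, ncol = 1, dimnames = list(names(seedP), "d1")),
    seedP, soilP), 1)
  expect_equal(recoverTransmissionFraction(
    matrix(soilP, ncol = 1, dimnames = list(names(soilP), "d1")),
    seedP, soilP), 0)
  # exact mixture at pi = 0.35
  mix <- 0.35 * seedP + 0.65 * soilP
  expect_equal(recoverTransmissionFraction(
    matrix(mix, ncol = 1, dimnames = list(names(mix), "d1")),
    seedP, soilP), 0.35, tolerance = 1e-9)
  expect_error(recoverTransmissionFraction(
    matrix(mix, ncol = 1, dimnames = list(names(mix), "d1")),
    seedP, seedP), "identical")
})
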