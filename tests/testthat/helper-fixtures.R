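# Small fixtures built in code, shared across test files.

# Random count matrix (ASVs x samples) with reproducible content.
randomCounts <- function(nAsv, nSamp, seed, lambda = 20) {
  withr::with_seed(seed, {
    m <- matrix(rpois(nAsv * nSamp, lambda), nrow = nAsv,
                dimnames = list(sprintf("asv%03d", seq_len(nAsv)),
                                sprintf("s%02d", seq_len(nSamp))))
    storage.mode(m) <- "integer"
    m
  })
}

randomExperiment <- function(nAsv = 20, nSamp = 6, seed = 1, lambda = 20,
                             sampleData = NULL) {
  AsvExperiment(randomCounts(nAsv, nSamp, seed, lambda),
                sampleData = sampleData)
}

# A detection set made directly from an id vector (for set-algebra tests
# that do not need a table).
asSet <- function(name, ids, meta = list()) {
  methods::new("DetectionSet", name = name,
               samples = paste0(name, "_s1"), asvs = ids,
               rule = c(min_count = 1L, min_samples = 1L), meta = meta)
}

# Uniqueness result made directly from components.
asUniqueness <- function(focal, unique, total, meta = list()) {
  methods::new("UniquenessResult", focal = focal, uniqueAsvs = unique,
               focalTotal = as.integer(total),
               fraction = length(unique) / total, meta = meta)
}

# Fixture mirroring the published sprout attribution: 223 sprout ASVs, of
# which 177 occur in at least one compartment, with per-compartment
# overlaps 148 / 128 / 124 / 109 / 103 (soil, peel, heel end, eye, flesh).
sproutFixture <- function() {
  ids <- sprintf("sp%03d", 1:223)
  counts <- matrix(1L, nrow = 223, ncol = 2,
                   dimnames = list(ids, c("spr1", "spr2")))
  sprout <- AsvExperiment(counts)
  comp <- list(
    adhering_soil = ids[1:148],
    peel = ids[40:167],
    heel_end = ids[30:153],
    eye = ids[60:168],
    flesh = ids[75:177])
  sets <- Map(asSet, names(comp), comp)
  list(sprout = sprout, sets = sets, ids = ids)
}

# Euclidean distance matrix of random 2-D points.
random2dDist <- function(n, seed) {
  withr::with_seed(seed, {
    pts <- matrix(rnorm(2 * n), ncol = 2)
    rownames(pts) <- paste0("p", seq_len(n))
    list(points = pts, d = dist(pts))
  })
}
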