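# Data model, I/O, taxonomy screening, rare-ASV filtering, rarefaction and
# relative abundance.

test_that("AsvExperiment validates counts and metadata", {
  m <- randomCounts(5, 3, seed = 1)
  x <- AsvExperiment(m)
  expect_s4_class(x, "AsvExperiment")
  expect_identical(asvCounts(x), m)
  expect_identical(asvIds(x), rownames(m))
  expect_identical(sampleIds(x), colnames(m))

  bad <- m
  bad[1, 1] <- -1L
  expect_error(AsvExperiment(bad), "non-negative")

  md <- data.frame(sample_id = colnames(m), sample_type = "seed_tuber",
                   marker = "16S")
  x2 <- AsvExperiment(m, sampleData = md)
  expect_identical(sampleData(x2)$sample_type, rep("seed_tuber", 3))
  md$sample_type[1] <- "leaf"
  expect_error(AsvExperiment(m, sampleData = md), "unknown sample_type")
  expect_error(AsvExperiment(m, sampleData = md[-1, ]), "no metadata")
})

test_that("TSV count tables round-trip through write/read", {
  m <- randomCounts(7, 4, seed = 42)
  x <- AsvExperiment(m)
  for (orient in c("samples_by_asvs", "asvs_by_samples")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeCountTable(x, path, format = "tsv", orientation = orient)
    y <- readCountTable(path, format = "tsv", orientation = orient)
    expect_identical(asvCounts(y)[rownames(m), colnames(m)], m)
  }
})

test_that("BIOM JSON count tables round-trip", {
  m <- randomCounts(6, 3, seed = 7)
  x <- AsvExperiment(m)
  path <- withr::local_tempfile(fileext = ".biom")
  writeCountTable(x, path, format = "biom_json")
  y <- readCountTable(path, format = "biom_json")
  expect_identical(asvCounts(y)[rownames(m), colnames(m)], m)
})

test_that("malformed TSV input is rejected with the offending cell named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("asv_id\ts1\ts2", "a1\t3\t-1", "a2\t0\t5"), path)
  expect_error(readCountTable(path, orientation = "asvs_by_samples"),
               "row 'a1', column 's2'")
  writeLines(c("asv_id\ts1\ts2", "a1\t3\t2.5", "a2\t0\t5"), path)
  expect_error(readCountTable(path, orientation = "asvs_by_samples"),
               "non-negative integer")
  writeLines(c("asv_id\ts1\ts2", "a1\t3\t1", "a1\t0\t5"), path)
  expect_error(readCountTable(path, orientation = "asvs_by_samples"),
               "duplicate row id")
})

test_that("lineage flags follow case-insensitive substring rules", {
  fl <- lineageFlags(c(
    "Bacteria;Cyanobacteria;Oxyphotobacteria;Chloroplast",
    "Bacteria;Proteobacteria;Rickettsiales;Mitochondria",
    "Bacteria;Firmicutes;Bacilli",
    "Fungi;Ascomycota",
    "Viridiplantae;Streptophyta",
    "Eukaryota;Protista",
    NA))
  expect_equal(fl$is_chloroplast, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, NA))
  expect_equal(fl$is_mitochondria, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, NA))
  expect_equal(fl$is_bacteria, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, NA))
  expect_equal(fl$is_fungi, c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, NA))
  expect_equal(fl$is_viridiplantae, c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, NA))
  expect_equal(fl$is_protista, c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, NA))
  # the domain rule looks at the top rank only
  expect_false(lineageFlags("Eukaryota;Proteobacteria")$is_bacteria)
})

test_that("off-target removal matches per-ASV flag evaluation", {
  lineages <- c(
    a1 = "Bacteria;Proteobacteria",
    a2 = "Bacteria;Cyanobacteria;Chloroplast",
    a3 = "Bacteria;Alphaproteobacteria;Mitochondria",
    a4 = "Archaea;Crenarchaeota",
    a5 = "Fungi;Basidiomycota",
    a6 = "Viridiplantae;Streptophyta",
    a7 = "Eukaryota;Protista;Cercozoa")
  m <- randomCounts(7, 4, seed = 3)
  rownames(m) <- names(lineages)
  tax <- data.frame(asv_id = names(lineages), lineage = unname(lineages))
  x <- AsvExperiment(m, taxonomy = tax)

  y16 <- removeOfftargetTaxa(x, "16S")
  expect_identical(asvIds(y16), "a1")
  yits <- removeOfftargetTaxa(x, "ITS")
  expect_identical(asvIds(yits), "a5")
  expect_identical(sampleIds(y16), sampleIds(x))

  # brute-force oracle over the flags
  fl <- lineageFlags(unname(lineages))
  keep16 <- fl$is_bacteria & !fl$is_mitochondria & !fl$is_chloroplast
  expect_identical(asvIds(y16), names(lineages)[keep16])

  # missing taxonomy record is an error listing the ASV
  x2 <- AsvExperiment(m, taxonomy = tax[-4, ])
  expect_error(removeOfftargetTaxa(x2, "16S"), "a4")
})

test_that("rare-ASV filter uses strict fewer-than semantics on both rules", {
  # a1: 29 reads over 5 samples -> removed (too few reads)
  # a2: 30 reads over exactly 3 samples -> retained (boundary inclusion)
  # a3: 1000 reads in 2 samples -> removed (too few samples)
  # a4: comfortable on both -> retained
  m <- rbind(
    a1 = c(6L, 6L, 6L, 6L, 5L),
    a2 = c(10L, 10L, 10L, 0L, 0L),
    a3 = c(500L, 500L, 0L, 0L, 0L),
    a4 = c(20L, 20L, 20L, 20L, 20L))
  colnames(m) <- paste0("s", 1:5)
  x <- filterRareAsvs(AsvExperiment(m))
  expect_identical(asvIds(x), c("a2", "a4"))
})

test_that("filtering steps commute with sample reordering", {
  m <- randomCounts(30, 8, seed = 11, lambda = 4)
  x <- AsvExperiment(m)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  xp <- AsvExperiment(m[, perm])
  expect_identical(asvIds(filterRareAsvs(x, 25, 4)),
                   asvIds(filterRareAsvs(xp, 25, 4)))
})

test_that("rarefaction conserves depth, bounds counts, drops shallow samples", {
  m <- randomCounts(15, 5, seed = 5, lambda = 30)
  m[, 2] <- 0L
  m[1, 2] <- 49L  # total 49 < depth
  x <- AsvExperiment(m)
  expect_message(y <- rarefy(x, depth = 100, seed = 9), "dropping 1 sample")
  expect_false("s02" %in% sampleIds(y))
  out <- asvCounts(y)
  expect_true(all(colSums(out) == 100))
  expect_true(all(out <= asvCounts(x)[, sampleIds(y)]))

  # identical seed reproduces the draw bit-for-bit
  y2 <- suppressMessages(rarefy(x, depth = 100, seed = 9))
  expect_identical(asvCounts(y2), out)

  # a sample whose total equals depth is untouched
  tot <- sum(m[, 1])
  z <- suppressMessages(rarefy(x, depth = tot, seed = 1))
  expect_identical(asvCounts(z)[, "s01"], m[, 1])

  expect_error(rarefy(x, depth = 0, seed = 1), "positive")
})

test_that("rarefaction is unbiased: expected counts near depth * proportion", {
  counts <- c(a = 500L, b = 300L, c = 150L, d = 50L)
  m <- matrix(counts, ncol = 1, dimnames = list(names(counts), "s1"))
  depth <- 200
  nRep <- 1000
  draws <- sapply(seq_len(nRep), function(i)
    asvCounts(rarefy(AsvExperiment(m), depth, seed = i))[, 1])
  p <- counts / sum(counts)
  expected <- depth * p
  # hypergeometric variance, finite-population corrected
  v <- depth * p * (1 - p) * (sum(counts) - depth) / (sum(counts) - 1)
  se <- sqrt(v / nRep)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se + 1e-9))
})

test_that("relative abundance normalizes rows and rejects empty samples", {
  m <- matrix(c(2L, 2L, 0L, 0L, 1L, 0L), nrow = 3,
              dimnames = list(paste0("a", 1:3), c("s1", "s2")))
  rel <- relAbundance(m)
  expect_equal(rel[, "s1"], c(a1 = 0.5, a2 = 0.5, a3 = 0))
  expect_equal(rel[, "s2"], c(a1 = 0, a2 = 1, a3 = 0))
  expect_equal(unname(colSums(relAbundance(randomCounts(10, 5, 2)))),
               rep(1, 5))
  m[, 2] <- 0L
  expect_error(relAbundance(m), "s2")
})
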