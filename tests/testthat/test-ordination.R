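# Bray-Curtis, PCoA, PERMANOVA, richness and Kruskal-Wallis. vegan / ape /
# cmdscale act as independent oracles for the first-principles
# implementations.

test_that("Bray-Curtis handles identical, disjoint and mixed communities", {
  m <- cbind(s1 = c(2L, 1L, 0L), s2 = c(0L, 1L, 3L), s3 = c(2L, 1L, 0L),
             s4 = c(0L, 0L, 7L))
  rownames(m) <- paste0("a", 1:3)
  d <- as.matrix(brayCurtis(m))
  expect_equal(d["s1", "s3"], 0)          # identical rows
  expect_equal(d["s1", "s4"], 1)          # disjoint supports
  expect_equal(d["s1", "s2"], 5 / 7)      # forced arithmetic
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  m2 <- m
  m2[, 2] <- 0L
  expect_error(brayCurtis(m2), "s2")
})

test_that("Bray-Curtis agrees with vegan::vegdist", {
  skip_if_not_installed("vegan")
  m <- randomCounts(25, 8, seed = 101, lambda = 8)
  ours <- brayCurtis(m)
  ref <- vegan::vegdist(t(m), method = "bray")
  expect_equal(as.matrix(ours), as.matrix(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("PCoA round-trips Euclidean configurations to 1e-9", {
  for (seed in c(7, 19, 37)) {
    fx <- random2dDist(n = 12, seed = seed)
    res <- pcoa(fx$d)
    rec <- dist(res@coordinates)
    expect_lt(max(abs(as.matrix(rec) - as.matrix(fx$d))), 1e-9)
    # only two meaningful positive axes for planar points
    expect_equal(sum(res@eigenvalues > 1e-8 * max(res@eigenvalues)), 2)
  }
})

test_that("PCoA matches classical MDS and handles symmetric designs", {
  fx <- random2dDist(n = 9, seed = 55)
  res <- pcoa(fx$d)
  ref <- cmdscale(fx$d, k = 2, eig = TRUE)
  expect_equal(abs(res@coordinates[, 1:2]), abs(ref$points),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(res@eigenvalues[1:2], ref$eig[1:2], tolerance = 1e-9)

  # three equidistant points: two equal positive eigenvalues
  D <- matrix(1, 3, 3) - diag(3)
  dimnames(D) <- list(paste0("p", 1:3), paste0("p", 1:3))
  eq <- pcoa(as.dist(D))
  pos <- eq@eigenvalues[eq@eigenvalues > 1e-10]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-12)

  # points on a line: one positive eigenvalue reproducing the distances
  line <- dist(matrix(c(0, 1, 3, 6), ncol = 1,
                      dimnames = list(paste0("q", 1:4), NULL)))
  lr <- pcoa(line)
  expect_equal(ncol(lr@coordinates), 1)
  expect_equal(as.matrix(dist(lr@coordinates)), as.matrix(line),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(pcoa(dist(matrix(1:2, ncol = 1))), "at least 3")
})

test_that("PERMANOVA decomposition matches vegan::adonis2", {
  skip_if_not_installed("vegan")
  withr::with_seed(111, {
    m <- randomCounts(30, 12, seed = 112, lambda = 10)
    g <- rep(c("A", "B", "C"), each = 4)
    d <- brayCurtis(m)
    ours <- permanova(d, g, nPerm = 999, seed = 5)
    ref <- vegan::adonis2(d ~ g, permutations = 999)
    expect_equal(ours@pseudoF, ref$F[1], tolerance = 1e-9)
    expect_equal(ours@r2, ref$R2[1], tolerance = 1e-9)
    expect_equal(ours@ssBetween, ref$SumOfSqs[1], tolerance = 1e-9)
    expect_equal(ours@ssWithin, ref$SumOfSqs[2], tolerance = 1e-9)
    # permutation p-values agree within Monte-Carlo noise
    expect_lt(abs(ours@pValue - ref$`Pr(>F)`[1]), 0.06)
    # decomposition identities
    expect_equal(ours@ssBetween + ours@ssWithin, ours@ssTotal,
                 tolerance = 1e-9)
    expect_equal(ours@r2, ours@ssBetween / ours@ssTotal)
  })
})

test_that("equidistant designs give the closed-form R2 = (a-1)/(N-1)", {
  for (cfg in list(c(a = 2, n = 3), c(a = 3, n = 2), c(a = 3, n = 4))) {
    N <- cfg[["a"]] * cfg[["n"]]
    D <- matrix(1, N, N) - diag(N)
    dimnames(D) <- list(paste0("s", 1:N), paste0("s", 1:N))
    g <- rep(paste0("g", seq_len(cfg[["a"]])), each = cfg[["n"]])
    res <- permanova(as.dist(D), g, nPerm = 99, seed = 3)
    expect_equal(res@r2, (cfg[["a"]] - 1) / (N - 1), tolerance = 1e-12)
    expect_gt(res@pValue, 0.9)  # relabelling-invariant configuration
  }
})

test_that("exact enumeration at N=4 reproduces the three-relabelling p-value", {
  fx <- random2dDist(n = 4, seed = 77)
  g <- c("A", "A", "B", "B")
  res <- permanova(fx$d, g, seed = 1, exact = TRUE)
  # oracle: enumerate the 3 distinct group partitions by hand
  D2 <- as.matrix(fx$d)^2
  ssT <- sum(D2) / (2 * 4)
  statOf <- function(idx) {
    other <- setdiff(1:4, idx)
    ssW <- (D2[idx[1], idx[2]] + D2[other[1], other[2]]) / 2
    ((ssT - ssW) / 1) / (ssW / 2)
  }
  partitions <- list(c(1, 2), c(1, 3), c(1, 4))
  Fs <- vapply(partitions, statOf, numeric(1))
  pOracle <- mean(Fs >= Fs[1] - 1e-12)
  expect_equal(res@pseudoF, Fs[1], tolerance = 1e-12)
  expect_equal(res@pValue, pOracle, tolerance = 1e-12)
})

test_that("PERMANOVA is invariant to consistent sample reordering", {
  m <- randomCounts(20, 10, seed = 121, lambda = 6)
  g <- stats::setNames(rep(c("A", "B"), each = 5), colnames(m))
  d1 <- brayCurtis(m)
  perm <- sample(colnames(m))
  d2 <- brayCurtis(m[, perm])
  r1 <- permanova(d1, g, nPerm = 199, seed = 4)
  r2 <- permanova(d2, g, nPerm = 199, seed = 4)
  expect_equal(r1@pseudoF, r2@pseudoF, tolerance = 1e-12)
  expect_equal(r1@r2, r2@r2, tolerance = 1e-12)
})

test_that("PERMANOVA rejects degenerate groupings", {
  fx <- random2dDist(n = 5, seed = 9)
  expect_error(permanova(fx$d, c("A", "A", "A", "A", "B"), seed = 1),
               "singleton")
  expect_error(permanova(fx$d, rep("A", 5), seed = 1), "at least 2 groups")
})

test_that("richness counts ASVs with reads and Kruskal-Wallis matches hand ranks", {
  m <- cbind(s1 = c(0L, 0L, 5L, 1L), s2 = c(1L, 1L, 1L, 1L),
             s3 = c(0L, 0L, 0L, 2L), s4 = c(3L, 0L, 1L, 1L),
             s5 = c(1L, 0L, 0L, 0L), s6 = c(2L, 2L, 2L, 0L))
  rownames(m) <- paste0("a", 1:4)
  expect_equal(richness(m),
               c(s1 = 2, s2 = 4, s3 = 1, s4 = 3, s5 = 1, s6 = 3))

  g <- c("A", "A", "B", "B", "C", "C")
  res <- richnessTest(m, stats::setNames(g, colnames(m)))
  # hand-computed H with mid-ranks and tie correction
  r <- richness(m)
  rk <- rank(r)
  N <- length(r)
  Hraw <- 12 / (N * (N + 1)) *
    sum(tapply(rk, g, function(v) length(v) * mean(v)^2)) - 3 * (N + 1)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  expect_equal(res$H, Hraw / C, tolerance = 1e-9)
  expect_equal(res$p, stats::kruskal.test(r, factor(g))$p.value)

  # identical richness everywhere: H = 0, p = 1, not an error
  flat <- matrix(1L, 2, 4, dimnames = list(c("a1", "a2"), paste0("s", 1:4)))
  resFlat <- richnessTest(flat, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  expect_equal(resFlat$H, 0)
  expect_equal(resFlat$p, 1)
})

test_that("Pielou evenness is 1 for uniform communities and NA for singletons", {
  m <- cbind(s1 = c(5L, 5L, 5L), s2 = c(9L, 1L, 0L), s3 = c(4L, 0L, 0L))
  rownames(m) <- paste0("a", 1:3)
  J <- pielouEvenness(m)
  expect_equal(J[["s1"]], 1)
  p <- c(0.9, 0.1)
  expect_equal(J[["s2"]], -sum(p * log(p)) / log(2))
  expect_true(is.na(J[["s3"]]))
})
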