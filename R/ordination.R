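# Distance-based community statistics written from first principles:
# Bray-Curtis dissimilarity, principal coordinates analysis by Gower
# double-centering, PERMANOVA with permutation p-values, observed richness
# and Kruskal-Wallis / evenness helpers. The vegan package is used in the
# test suite as an independent cross-check, never as the implementation.

#' Bray-Curtis dissimilarity matrix
#'
#' `d_ij = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)` over ASVs `k`, for
#' samples `i`, `j`. Accepts counts or relative abundances; on tables
#' rarefied to even depth the two give identical results.
#'
#' @param x an [AsvExperiment-class] or numeric matrix (ASVs x samples).
#' @return a [stats::dist] object labelled by sample id.
#' @export
brayCurtis <- function(x) {
  m <- if (methods::is(x, "SummarizedExperiment")) asvCounts(x)
       else as.matrix(x)
  tot <- colSums(m)
  if (any(tot == 0))
    failWith("zero-total sample(s): ",
             paste(colnames(m)[tot == 0], collapse = ", "))
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[, i]
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(abs(xi - m[, j])) / (tot[i] + tot[j])
    }
  }
  stats::as.dist(d)
}

#' PcoaResult: principal coordinates of a distance matrix
#'
#' @slot coordinates numeric matrix (samples x positive axes), columns
#'   `PCo1`, `PCo2`, ...
#' @slot eigenvalues all eigenvalues in descending order, including any
#'   negative ones (reported, not corrected).
#' @slot proportionExplained per positive axis, eigenvalue divided by the
#'   sum of positive eigenvalues.
#' @export
setClass("PcoaResult", representation(
  coordinates = "matrix", eigenvalues = "numeric",
  proportionExplained = "numeric"))

setMethod("show", "PcoaResult", function(object) {
  k <- min(3, length(object@proportionExplained))
  cat("PcoaResult:", nrow(object@coordinates), "samples,",
      ncol(object@coordinates), "positive axes\n")
  if (k)
    cat("  proportion explained:",
        paste(sprintf("PCo%d %.1f%%", seq_len(k),
                      100 * object@proportionExplained[seq_len(k)]),
              collapse = ", "), "\n")
  if (any(object@eigenvalues < -1e-8))
    cat("  note:", sum(object@eigenvalues < -1e-8),
        "negative eigenvalue(s) present\n")
})

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of the squared distance matrix,
#' `B = -1/2 J D^2 J` with `J = I - 11'/N`, followed by
#' eigendecomposition. Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Negative eigenvalues, which arise
#' for non-Euclidean dissimilarities such as Bray-Curtis, are reported
#' unchanged.
#'
#' @param d a [stats::dist] or symmetric matrix of dissimilarities
#'   (N >= 3).
#' @return a [PcoaResult-class].
#' @export
pcoa <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3) failWith("PCoA needs at least 3 samples")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1)
  pos <- e$values > tol
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  dimnames(coords) <- list(rownames(D), paste0("PCo", seq_len(sum(pos))))
  methods::new("PcoaResult", coordinates = coords,
               eigenvalues = e$values,
               proportionExplained = e$values[pos] / sum(e$values[pos]))
}

#' PermanovaResult: one-factor PERMANOVA decomposition
#'
#' @slot factorName name of the grouping factor.
#' @slot nGroups,n number of groups and of samples.
#' @slot ssBetween,ssWithin,ssTotal sums of squared distances.
#' @slot pseudoF pseudo-F statistic.
#' @slot r2 `ssBetween / ssTotal`.
#' @slot pValue permutation p-value.
#' @slot nPerm number of permutations (0 for exhaustive enumeration).
#' @slot seed RNG seed used for the permutations.
#' @export
setClass("PermanovaResult", representation(
  factorName = "character", nGroups = "integer", n = "integer",
  ssBetween = "numeric", ssWithin = "numeric", ssTotal = "numeric",
  pseudoF = "numeric", r2 = "numeric", pValue = "numeric",
  nPerm = "integer", seed = "integer"))

setMethod("show", "PermanovaResult", function(object) {
  cat("PERMANOVA (", if (object@nPerm) paste(object@nPerm, "permutations")
      else "exhaustive", ")\n", sep = "")
  df1 <- object@nGroups - 1L
  df2 <- object@n - object@nGroups
  cat(sprintf("%-12s Df  SumOfSqs      R2        F   Pr(>F)\n", ""))
  cat(sprintf("%-12s %2d  %8.4f  %6.4f  %7.3f  %7.4f\n",
              object@factorName, df1, object@ssBetween, object@r2,
              object@pseudoF, object@pValue))
  cat(sprintf("%-12s %2d  %8.4f\n", "Residual", df2, object@ssWithin))
  cat(sprintf("%-12s %2d  %8.4f\n", "Total", object@n - 1L,
              object@ssTotal))
})

# Within-group sum of squared distances: sum over groups g of
# (1/n_g) * sum_{i<j in g} d_ij^2, given the squared distance matrix and a
# list of index vectors.
ssWithinGroups <- function(D2, idxList) {
  s <- 0
  for (idx in idxList) s <- s + sum(D2[idx, idx]) / (2 * length(idx))
  s
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the total sum of squared inter-sample distances,
#' `SS_T = (1/N) sum_{i<j} d_ij^2`, into a within-group component
#' `SS_W = sum_g (1/n_g) sum_{i<j in g} d_ij^2` and a between-group
#' component `SS_A = SS_T - SS_W`. The pseudo-F statistic is
#' `(SS_A/(a-1)) / (SS_W/(N-a))` and `R2 = SS_A/SS_T`. Significance is
#' assessed by free random relabelling of samples:
#' `p = (1 + #{F_perm >= F_obs}) / (1 + nPerm)`. With `exact = TRUE` all
#' `N!` relabellings are enumerated instead (N <= 8) and
#' `p = #{F_perm >= F_obs} / N!` including the identity.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @param grouping factor/character of group labels, either named by sample
#'   id or in the order of `d`'s labels; >= 2 groups with >= 2 samples
#'   each.
#' @param nPerm number of random permutations (default 999).
#' @param seed integer RNG seed for the permutations.
#' @param factorName label recorded in the result.
#' @param exact enumerate all permutations instead of sampling.
#' @return a [PermanovaResult-class].
#' @export
permanova <- function(d, grouping, nPerm = 999, seed,
                      factorName = "group", exact = FALSE) {
  D <- as.matrix(d)
  N <- nrow(D)
  if (!is.null(names(grouping)) && !is.null(rownames(D))) {
    missing <- setdiff(rownames(D), names(grouping))
    if (length(missing))
      failWith("no group label for sample(s): ",
               paste(missing, collapse = ", "))
    grouping <- grouping[rownames(D)]
  }
  g <- factor(grouping)
  if (length(g) != N) failWith("grouping length disagrees with d")
  sizes <- table(g)
  if (length(sizes) < 2) failWith("need at least 2 groups")
  if (any(sizes < 2))
    failWith("singleton group(s): ",
             paste(names(sizes)[sizes < 2], collapse = ", "))
  D2 <- D^2
  ssT <- sum(D2) / (2 * N)
  a <- length(sizes)
  idx <- split(seq_len(N), g)
  ssW <- ssWithinGroups(D2, idx)
  ssA <- ssT - ssW
  Fobs <- (ssA / (a - 1)) / (ssW / (N - a))
  statFor <- function(ord) {
    w <- ssWithinGroups(D2, split(ord, g))
    ((ssT - w) / (a - 1)) / (w / (N - a))
  }
  if (exact) {
    if (N > 8) failWith("exact enumeration limited to N <= 8")
    perms <- allPermutations(N)
    Fs <- apply(perms, 1, statFor)
    p <- mean(Fs >= Fobs - 1e-12)
    nPermUsed <- 0L
    seedUsed <- NA_integer_
  } else {
    Fs <- withSeed(seed, {
      vapply(seq_len(nPerm), function(b) statFor(sample.int(N)),
             numeric(1))
    })
    p <- (1 + sum(Fs >= Fobs - 1e-12)) / (1 + nPerm)
    nPermUsed <- as.integer(nPerm)
    seedUsed <- as.integer(seed)
  }
  methods::new("PermanovaResult", factorName = factorName,
               nGroups = as.integer(a), n = as.integer(N),
               ssBetween = ssA, ssWithin = ssW, ssTotal = ssT,
               pseudoF = Fobs, r2 = ssA / ssT, pValue = p,
               nPerm = nPermUsed, seed = seedUsed)
}

# All permutations of 1..n as a matrix (n! rows).
allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Observed ASV richness per sample
#'
#' @param x an [AsvExperiment-class] or counts matrix (ASVs x samples).
#' @return named integer vector: number of ASVs with at least one read per
#'   sample. Compute on rarefied tables to compare across samples.
#' @export
richness <- function(x) {
  m <- if (methods::is(x, "SummarizedExperiment")) asvCounts(x)
       else as.matrix(x)
  colSums(m >= 1)
}

#' Pielou evenness per sample
#'
#' `J = H' / ln(S)` with Shannon `H'` on relative abundances and `S` the
#' observed richness; `NA` for samples with a single ASV.
#'
#' @param x an [AsvExperiment-class] or counts matrix (ASVs x samples).
#' @return named numeric vector.
#' @export
pielouEvenness <- function(x) {
  rel <- relAbundance(x)
  apply(rel, 2, function(p) {
    p <- p[p > 0]
    if (length(p) < 2) return(NA_real_)
    -sum(p * log(p)) / log(length(p))
  })
}

#' Richness comparison across groups by Kruskal-Wallis
#'
#' Computes per-sample observed richness and compares groups with the
#' standard Kruskal-Wallis rank-sum test (mid-ranks, tie correction, via
#' [stats::kruskal.test]). When every value is tied across all groups the
#' statistic is 0 and p is 1.
#'
#' @param x an [AsvExperiment-class] or counts matrix (ASVs x samples).
#' @param grouping factor/character of group labels named by sample id or
#'   in column order.
#' @return list with `richness` (named vector), `H`, `df` and `p`.
#' @export
richnessTest <- function(x, grouping) {
  r <- richness(x)
  if (!is.null(names(grouping))) grouping <- grouping[names(r)]
  g <- factor(grouping)
  if (length(unique(g)) < 2) failWith("need at least 2 groups")
  if (length(unique(r)) == 1) {
    return(list(richness = r, H = 0, df = length(levels(g)) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(r, g)
  list(richness = r, H = unname(kt$statistic),
       df = unname(kt$parameter), p = kt$p.value)
}
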