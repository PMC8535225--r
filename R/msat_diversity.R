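# Microsatellite (and MHC-as-one-locus) diversity statistics and
# Monte-Carlo Hardy-Weinberg / linkage-disequilibrium tests.

locus_alleles <- function(gt, locus) {
  j <- match(locus, gt$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  a1 <- gt$a1[, j]; a2 <- gt$a2[, j]
  typed <- !is.na(a1)
  list(a1 = a1[typed], a2 = a2[typed], typed = typed, j = j)
}

#' Per-locus allele frequencies
#'
#' Frequencies are computed over typed gene copies only; missing calls are
#' excluded from the denominator.
#'
#' @param gt a [genotype_table()].
#' @return A list of class `allele_frequencies`: per locus a list with `freq`
#'   (named numeric vector) and `n_copies`.
#' @export
allele_frequencies <- function(gt) {
  out <- lapply(gt$loci, function(loc) {
    la <- locus_alleles(gt, loc)
    copies <- c(la$a1, la$a2)
    if (length(copies) == 0)
      stop("locus with zero typed individuals: ", loc)
    tab <- table(copies)
    list(freq = setNames(as.numeric(tab) / length(copies), names(tab)),
         n_copies = length(copies))
  })
  names(out) <- gt$loci
  class(out) <- "allele_frequencies"
  out
}

#' Unbiased expected heterozygosity
#'
#' Nei's small-sample correction: \eqn{H_E = \frac{2n}{2n-1}(1 - \sum p_i^2)}
#' with `n` typed diploid individuals.
#'
#' @param p numeric vector of allele frequencies (must sum to 1).
#' @param n number of typed diploid individuals.
#' @return Unbiased expected heterozygosity.
#' @examples
#' unbiased_expected_het(c(0.5, 0.5), 10)
#' @export
unbiased_expected_het <- function(p, n) {
  if (abs(sum(p) - 1) > 1e-6) stop("frequencies must sum to 1")
  (2 * n / (2 * n - 1)) * (1 - sum(p^2))
}

#' Rarefied allelic richness at g gene copies
#'
#' \eqn{R_S(g) = \sum_i [1 - C(N - N_i, g) / C(N, g)]} where `N` is the number
#' of typed gene copies and `N_i` the copies of allele i.
#'
#' @param counts integer vector of allele copy counts.
#' @param g rarefaction size (gene copies), `g <= sum(counts)`.
#' @return Expected number of distinct alleles in a sample of g copies.
#' @export
allelic_richness <- function(counts, g) {
  N <- sum(counts)
  if (g > N) stop("rarefaction size exceeds number of typed gene copies")
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Per-locus diversity statistics
#'
#' For each locus: number typed, allele count, rarefied allelic richness,
#' observed heterozygosity, unbiased expected heterozygosity, the inbreeding
#' index `F_IS = 1 - H_O/H_E`, and the probabilities of identity for
#' unrelated individuals and for full siblings.  A summary of across-locus
#' means and SDs is attached as an attribute.
#'
#' @param gt a [genotype_table()].
#' @param g rarefaction size in gene copies; default twice the minimum number
#'   of typed individuals over loci.
#' @return A data.frame, one row per locus, with attribute `"summary"`.
#' @export
locus_diversity <- function(gt, g = NULL) {
  freqs <- allele_frequencies(gt)
  n_typed <- vapply(gt$loci, function(loc)
    sum(!is.na(gt$a1[, match(loc, gt$loci)])), numeric(1))
  if (is.null(g)) g <- 2 * min(n_typed)
  if (g > 2 * min(n_typed)) stop("g exceeds minimum typed gene copies")

  rows <- lapply(gt$loci, function(loc) {
    la <- locus_alleles(gt, loc)
    n <- length(la$a1)
    p <- freqs[[loc]]$freq
    counts <- as.integer(table(c(la$a1, la$a2)))
    H_O <- mean(la$a1 != la$a2)
    H_E <- unbiased_expected_het(p, n)
    F_IS <- if (H_E == 0) NA_real_ else 1 - H_O / H_E
    pid <- pid_locus(p)
    data.frame(locus = loc, n_typed = n, N_A = length(p),
               R_S = allelic_richness(counts, g),
               H_O = H_O, H_E = H_E, F_IS = F_IS,
               P_ID = pid$P_ID, P_ID_sib = pid$P_ID_sib,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  num <- c("N_A", "R_S", "H_O", "H_E", "F_IS", "P_ID", "P_ID_sib")
  attr(out, "summary") <- data.frame(
    stat = num,
    mean = vapply(num, function(v) mean(out[[v]], na.rm = TRUE), numeric(1)),
    sd = vapply(num, function(v) sd(out[[v]], na.rm = TRUE), numeric(1)),
    row.names = NULL)
  attr(out, "g") <- g
  out
}

pid_locus <- function(p) {
  s2 <- sum(p^2); s4 <- sum(p^4)
  P_ID <- s4 + sum((2 * outer(p, p))[upper.tri(outer(p, p))]^2)
  P_ID_sib <- 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
  list(P_ID = P_ID, P_ID_sib = P_ID_sib)
}

#' Probability of identity (unrelated and sibling)
#'
#' Per locus, `P_ID = sum p_i^4 + sum_{i<j} (2 p_i p_j)^2` is the probability
#' that two unrelated individuals share a genotype under HWE, and `P_ID_sib =
#' 0.25 + 0.5 sum p_i^2 + 0.5 (sum p_i^2)^2 - 0.25 sum p_i^4` the analogue for
#' full siblings.  Multilocus values are products over loci.
#'
#' @param freqs an [allele_frequencies()] object.
#' @return A list with per-locus data.frame `per_locus` and scalars
#'   `multilocus_P_ID`, `multilocus_P_ID_sib`.
#' @export
probability_identity <- function(freqs) {
  rows <- lapply(names(freqs), function(loc) {
    pid <- pid_locus(freqs[[loc]]$freq)
    data.frame(locus = loc, P_ID = pid$P_ID, P_ID_sib = pid$P_ID_sib,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_locus = per,
       multilocus_P_ID = prod(per$P_ID),
       multilocus_P_ID_sib = prod(per$P_ID_sib))
}

#' Monte-Carlo Hardy-Weinberg test
#'
#' Permutes the typed alleles at a locus among individuals and compares the
#' observed heterozygote count with its permutation distribution.  Because
#' the count is discrete, mid-p tail probabilities (half weight on the
#' atom at the observed value) are used so the test holds its nominal size.
#' Two one-sided p-values are returned: small
#' `p_het_excess` indicates more heterozygotes than expected (the pattern of a
#' bottlenecked or family-structured sample), small `p_het_deficit` indicates
#' a homozygote excess (the classic null-allele / inbreeding signal).
#'
#' @param gt a [genotype_table()].
#' @param locus locus name.
#' @param n_reps permutation replicates (default 10000, minimum 1000).
#' @param seed RNG seed.
#' @return A list with `p_het_excess`, `p_het_deficit`, `obs_het`, `skipped`.
#' @export
hwe_test <- function(gt, locus, n_reps = 10000, seed = 1) {
  stopifnot(n_reps >= 1000)
  la <- locus_alleles(gt, locus)
  copies <- c(la$a1, la$a2)
  if (length(unique(copies)) < 2)
    return(list(p_het_excess = NA_real_, p_het_deficit = NA_real_,
                obs_het = NA_integer_, skipped = TRUE))
  n <- length(la$a1)
  obs <- sum(la$a1 != la$a2)
  set.seed(seed)
  sim <- vapply(seq_len(n_reps), function(i) {
    perm <- sample(copies)
    sum(perm[seq_len(n)] != perm[n + seq_len(n)])
  }, numeric(1))
  # mid-p: the heterozygote count is discrete, and the full atom at the
  # observed value makes the plain tail markedly conservative
  ties <- sum(sim == obs)
  list(p_het_excess = (sum(sim > obs) + 0.5 * ties + 0.5) / (n_reps + 1),
       p_het_deficit = (sum(sim < obs) + 0.5 * ties + 0.5) / (n_reps + 1),
       obs_het = obs, skipped = FALSE)
}

# allele dosage matrix: individuals x alleles, entries 0/1/2, NA if untyped
dosage_matrix <- function(a1, a2) {
  alleles <- sort(unique(c(a1, a2)))
  X <- matrix(0L, length(a1), length(alleles),
              dimnames = list(NULL, as.character(alleles)))
  for (k in seq_along(alleles)) {
    X[, k] <- (a1 == alleles[k]) + (a2 == alleles[k])
  }
  X
}

# Burrows composite disequilibrium Delta for all allele pairs of two loci,
# over individuals typed at both.  Returns list(delta, r2, p, q, n).
burrows_pair <- function(a1A, a2A, a1B, a2B, nfactor = TRUE) {
  n <- length(a1A)
  X <- dosage_matrix(a1A, a2A)
  Y <- dosage_matrix(a1B, a2B)
  p <- colMeans(X) / 2
  q <- colMeans(Y) / 2
  delta <- crossprod(X, Y) / (2 * n) - 2 * outer(p, q)
  if (nfactor) delta <- delta * n / (n - 1)
  homA <- colMeans(X == 2L)
  homB <- colMeans(Y == 2L)
  piA <- p * (1 - p) + (homA - p^2)
  piB <- q * (1 - q) + (homB - q^2)
  r2 <- delta^2 / outer(piA, piB)
  list(delta = delta, r2 = r2, p = p, q = q, n = n)
}

#' Monte-Carlo linkage disequilibrium test
#'
#' The statistic is the sum over allele pairs of the squared Burrows
#' composite disequilibrium.  The null distribution is built by permuting one
#' locus's genotypes across individuals; p-values use (b+1)/(m+1) smoothing.
#'
#' @param gt a [genotype_table()].
#' @param locusA,locusB locus names.
#' @param n_reps permutation replicates (default 10000).
#' @param seed RNG seed.
#' @return A list with `p_value`, `statistic`, `skipped`.
#' @export
ld_test <- function(gt, locusA, locusB, n_reps = 10000, seed = 1) {
  stopifnot(n_reps >= 1000)
  jA <- match(locusA, gt$loci); jB <- match(locusB, gt$loci)
  ok <- !is.na(gt$a1[, jA]) & !is.na(gt$a1[, jB])
  a1A <- gt$a1[ok, jA]; a2A <- gt$a2[ok, jA]
  a1B <- gt$a1[ok, jB]; a2B <- gt$a2[ok, jB]
  if (length(unique(c(a1A, a2A))) < 2 || length(unique(c(a1B, a2B))) < 2)
    return(list(p_value = NA_real_, statistic = NA_real_, skipped = TRUE))
  stat <- function(i1B, i2B) sum(burrows_pair(a1A, a2A, i1B, i2B)$delta^2)
  obs <- stat(a1B, a2B)
  set.seed(seed)
  n <- length(a1A)
  sim <- vapply(seq_len(n_reps), function(i) {
    perm <- sample(n)
    stat(a1B[perm], a2B[perm])
  }, numeric(1))
  list(p_value = (sum(sim >= obs) + 1) / (n_reps + 1),
       statistic = obs, skipped = FALSE)
}
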