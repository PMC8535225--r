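# Sequence diversity, neutrality tests, haplotype phasing and networks.
#
# All comparisons use complete deletion: any alignment column containing a
# character other than A/C/G/T in any of the sequences under consideration is
# excluded from segregating-site, transition/transversion and distance
# computations.

seq_matrix <- function(panel, labels = names(panel$sequences)) {
  m <- do.call(rbind, strsplit(panel$sequences[labels], ""))
  rownames(m) <- labels
  m
}

usable_sites <- function(m) {
  ok <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  which(ok)
}

# copy labels: one per gene copy (haploid: 1 per individual; diploid: 2)
assignment_copies <- function(assignments) {
  if (is.null(assignments) || length(assignments) == 0)
    stop("empty assignment set")
  unlist(assignments, use.names = FALSE)
}

pair_diff_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

#' Collapse assigned sequences into haplotype classes
#'
#' Merges identical sequences (compared after complete deletion of ambiguous
#' sites) and tabulates counts and relative frequencies over all assigned
#' gene copies.
#'
#' @param panel a [seq_panel()].
#' @param assignments per-individual assignments (defaults to
#'   `panel$assignments`): a single label per individual for a haploid marker
#'   or a pair of labels for a diploid one.
#' @return A data.frame with columns `haplotype` (label of the first member
#'   of each merged class), `count` and `frequency`.
#' @export
collapse_haplotypes <- function(panel, assignments = panel$assignments) {
  copies <- assignment_copies(assignments)
  labs <- unique(copies)
  m <- seq_matrix(panel, labs)
  use <- usable_sites(m)
  key <- apply(m[, use, drop = FALSE], 1, paste, collapse = "")
  rep_lab <- labs[!duplicated(key)]
  class_of <- setNames(rep_lab[match(key, key[!duplicated(key)])], labs)
  cls <- class_of[copies]
  tab <- table(factor(cls, levels = rep_lab))
  data.frame(haplotype = names(tab),
             count = as.integer(tab),
             frequency = as.numeric(tab) / length(copies),
             row.names = NULL, stringsAsFactors = FALSE)
}

jc_correct <- function(p) {
  if (any(p >= 0.75))
    stop("Jukes-Cantor correction undefined for per-site distance >= 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

#' Sequence diversity statistics
#'
#' Computes segregating sites, transition/transversion counts, the mean
#' number of pairwise nucleotide differences `k`, nucleotide diversity per
#' site `pi` (= k/L over usable sites), its Jukes-Cantor-corrected version
#' `pi_jc` (JC applied per pair, then averaged) and haplotype (gene)
#' diversity `Hd = n/(n-1) (1 - sum p_i^2)`.  All quantities are over gene
#' copies implied by `assignments`.
#'
#' @inheritParams collapse_haplotypes
#' @return A list of class `seq_diversity_stats`.
#' @export
diversity_stats <- function(panel, assignments = panel$assignments) {
  copies <- assignment_copies(assignments)
  n <- length(copies)
  if (n < 2) stop("need at least 2 sequence copies")
  labs <- unique(copies)
  m <- seq_matrix(panel, labs)
  use <- usable_sites(m)
  mu <- m[, use, drop = FALSE]
  lab_counts <- as.integer(table(factor(copies, levels = labs)))
  # merge labels with identical usable-site sequences into haplotype classes
  key <- apply(mu, 1, paste, collapse = "")
  cls <- match(key, unique(key))
  counts <- as.integer(tapply(lab_counts, cls, sum))
  mu <- mu[!duplicated(cls), , drop = FALSE]

  # segregating sites and per-site mutation classification over copies
  S <- 0L; ts <- 0L; tv <- 0L
  purine <- c("A", "G")
  for (s in seq_len(ncol(mu))) {
    al <- unique(mu[, s])
    if (length(al) > 1) {
      S <- S + 1L
      prs <- combn(al, 2)
      for (q in seq_len(ncol(prs))) {
        a <- prs[1, q]; b <- prs[2, q]
        if ((a %in% purine) == (b %in% purine)) ts <- ts + 1L else tv <- tv + 1L
      }
    }
  }

  d <- pair_diff_matrix(mu)
  L <- ncol(mu)
  npairs <- choose(n, 2)
  wsum <- 0; wsum_jc <- 0
  for (i in seq_along(counts)) for (j in seq_along(counts)) {
    if (j <= i) next
    w <- counts[i] * counts[j]
    wsum <- wsum + w * d[i, j]
    wsum_jc <- wsum_jc + w * jc_correct(d[i, j] / L)
  }
  k <- wsum / npairs
  pi <- k / L
  pi_jc <- wsum_jc / npairs
  p <- counts / n
  Hd <- n / (n - 1) * (1 - sum(p^2))

  structure(list(n = n, L = panel$length, sites_used = L, S = S,
                 transitions = ts, transversions = tv,
                 k = k, pi = pi, pi_jc = pi_jc, Hd = Hd),
            class = "seq_diversity_stats")
}

#' @export
print.seq_diversity_stats <- function(x, ...) {
  cat(sprintf(paste0("n = %d copies, %d/%d usable sites, S = %d ",
                     "(%d ts, %d tv)\nk = %.4f  pi = %.5f  pi(JC) = %.5f  ",
                     "Hd = %.4f\n"),
              x$n, x$sites_used, x$L, x$S, x$transitions, x$transversions,
              x$k, x$pi, x$pi_jc, x$Hd))
  invisible(x)
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

fu_li_dstar_constants <- function(n) {
  an <- sum(1 / seq_len(n - 1))
  bn <- sum(1 / seq_len(n - 1)^2)
  an1 <- an + 1 / n
  cn <- if (n == 2) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  v <- ((n / (n - 1))^2 * bn + an^2 * dn -
          2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  u <- (n / (n - 1)) * (an - n / (n - 1)) - v
  list(an = an, u = u, v = v)
}

#' Frequency-spectrum neutrality tests
#'
#' Tajima's D contrasts the mean number of pairwise differences with the
#' number of segregating sites; Fu and Li's D* contrasts the number of
#' singleton mutations with the total number of mutations.  Under neutrality
#' both are near zero; significantly positive values at an immune locus
#' suggest balancing selection.  When `n_sim > 0`, two-tailed p-values are
#' obtained by neutral-coalescent simulation at the Watterson estimate of
#' theta (see [sim_coalescent()]); otherwise a conventional |D| > 2 flag is
#' reported.
#'
#' @inheritParams collapse_haplotypes
#' @param n_sim coalescent replicates for empirical p-values (0 to skip).
#' @param seed RNG seed used when `n_sim > 0`.
#' @return A list with `tajima_D`, `fu_li_Dstar`, `S`, `eta`, `eta_s`,
#'   significance flags and (optionally) simulation p-values.  With `S = 0`
#'   both statistics are `NA` with `computable = FALSE`.
#' @export
neutrality_tests <- function(panel, assignments = panel$assignments,
                             n_sim = 0, seed = 1) {
  copies <- assignment_copies(assignments)
  n <- length(copies)
  if (n < 4) stop("need at least 4 sequence copies")
  labs <- unique(copies)
  m <- seq_matrix(panel, labs)
  use <- usable_sites(m)
  mc <- m[match(copies, labs), use, drop = FALSE]  # one row per copy

  eta <- 0L; eta_s <- 0L; S <- 0L
  for (s in seq_len(ncol(mc))) {
    tab <- table(mc[, s])
    if (length(tab) > 1) {
      S <- S + 1L
      eta <- eta + length(tab) - 1L
      eta_s <- eta_s + sum(tab == 1L)
    }
  }
  if (S == 0)
    return(list(tajima_D = NA_real_, fu_li_Dstar = NA_real_, S = 0L,
                eta = 0L, eta_s = 0L, computable = FALSE))

  d <- pair_diff_matrix(mc)
  k <- sum(d[upper.tri(d)]) / choose(n, 2)

  tc <- tajima_constants(n)
  D <- (k - S / tc$a1) / sqrt(tc$e1 * S + tc$e2 * S * (S - 1))
  fc <- fu_li_dstar_constants(n)
  Dstar <- (n / (n - 1) * eta - fc$an * eta_s) /
    sqrt(fc$u * eta + fc$v * eta^2)

  out <- list(tajima_D = D, fu_li_Dstar = Dstar, S = S,
              eta = eta, eta_s = eta_s, computable = TRUE,
              tajima_sig = abs(D) > 2, fu_li_sig = abs(Dstar) > 2)
  if (n_sim > 0) {
    theta_w <- S / tc$a1
    sims <- sim_coalescent(n, theta_w, n_rep = n_sim, seed = seed)
    Ds <- vapply(sims, function(x) x$tajima_D, numeric(1))
    Fs <- vapply(sims, function(x) x$fu_li_Dstar, numeric(1))
    Ds <- Ds[is.finite(Ds)]; Fs <- Fs[is.finite(Fs)]
    out$p_tajima <- 2 * min(mean(Ds >= D), mean(Ds <= D))
    out$p_fu_li <- 2 * min(mean(Fs >= Dstar), mean(Fs <= Dstar))
    out$tajima_sig <- out$p_tajima < 0.05
    out$fu_li_sig <- out$p_fu_li < 0.05
  }
  out
}

# ---------------------------------------------------------------------------
# Haplotype-pair phasing against a known panel
# ---------------------------------------------------------------------------

# signature of an unordered pair of panel haplotypes: per-site sorted digrams
pair_signature <- function(m, h1, h2) {
  paste(pmin(m[h1, ], m[h2, ]), pmax(m[h1, ], m[h2, ]), collapse = "")
}

#' Unphased genotype signature from a haplotype pair
#'
#' Produces the per-site allele multiset an unphased diploid sequence read
#' would show for a given (possibly identical) pair of panel haplotypes.
#' Used to feed [phase_pairs()] and by the synthetic-data generator.
#'
#' @param panel a [seq_panel()].
#' @param pair character vector of two panel labels.
#' @return An opaque character signature.
#' @export
unphase_mhc <- function(panel, pair) {
  m <- seq_matrix(panel)
  pair_signature(m, pair[1], pair[2])
}

#' Phase haplotype pairs against a known panel
#'
#' Resolves each individual's unphased genotype to an unordered pair of panel
#' haplotypes.  Homozygotes and genotypes compatible with exactly one panel
#' pair are resolved with probability 1; remaining ambiguities are reduced by
#' pedigree transmission constraints (a pair impossible given a resolved
#' parent gets probability 0), then resolved by EM on panel haplotype
#' frequencies.  Pairs whose posterior falls below `min_posterior` are
#' reported as unresolved rather than guessed.
#'
#' @param genotypes named list or vector of signatures from [unphase_mhc()].
#' @param panel a [seq_panel()] of known haplotypes.
#' @param ped optional [pedigree()] used for transmission constraints.
#' @param min_posterior posterior threshold below which a pair is flagged
#'   unresolved (default 0.9).
#' @param max_iter,tol EM controls.
#' @return A data.frame with columns `id`, `hap1`, `hap2`, `probability`,
#'   `method` (`homozygote`, `panel_unique`, `pedigree`, `em`) and
#'   `resolved`.
#' @export
phase_pairs <- function(genotypes, panel, ped = NULL, min_posterior = 0.9,
                        max_iter = 200, tol = 1e-8) {
  ids <- names(genotypes)
  if (is.null(ids)) stop("genotypes must be named by individual id")
  m <- seq_matrix(panel)
  labs <- rownames(m)
  H <- length(labs)
  prs <- cbind(rep(seq_len(H), times = H), rep(seq_len(H), each = H))
  prs <- prs[prs[, 1] <= prs[, 2], , drop = FALSE]
  sig <- vapply(seq_len(nrow(prs)),
                function(r) pair_signature(m, labs[prs[r, 1]], labs[prs[r, 2]]),
                character(1))

  cand <- lapply(genotypes, function(g) which(sig == g))
  bad <- ids[vapply(cand, length, integer(1)) == 0]
  if (length(bad))
    stop("genotype inconsistent with every panel pair for: ",
         paste(bad, collapse = ", "))

  res <- data.frame(id = ids, hap1 = NA_character_, hap2 = NA_character_,
                    probability = NA_real_, method = NA_character_,
                    resolved = FALSE, stringsAsFactors = FALSE)
  set_pair <- function(i, r, prob, method) {
    res$hap1[i] <<- labs[prs[r, 1]]
    res$hap2[i] <<- labs[prs[r, 2]]
    res$probability[i] <<- prob
    res$method[i] <<- method
    res$resolved[i] <<- TRUE
  }
  for (i in seq_along(ids)) {
    if (length(cand[[i]]) == 1) {
      r <- cand[[i]]
      set_pair(i, r, 1,
               if (prs[r, 1] == prs[r, 2]) "homozygote" else "panel_unique")
    }
  }

  # pedigree transmission constraints, iterated to a fixpoint
  if (!is.null(ped)) {
    repeat {
      changed <- FALSE
      for (i in seq_along(ids)) {
        if (res$resolved[i] || length(cand[[i]]) < 2) next
        rec <- ped$records[ped$records$id == ids[i], ]
        if (nrow(rec) == 0) next
        for (pcol in c("sire_id", "dam_id")) {
          pid <- rec[[pcol]]
          if (is.na(pid)) next
          pi_row <- match(pid, ids)
          if (is.na(pi_row) || !res$resolved[pi_row]) next
          phaps <- match(c(res$hap1[pi_row], res$hap2[pi_row]), labs)
          keep <- vapply(cand[[i]], function(r)
            any(prs[r, ] %in% phaps), logical(1))
          if (any(!keep) && any(keep)) {
            cand[[i]] <- cand[[i]][keep]
            changed <- TRUE
          }
        }
        if (length(cand[[i]]) == 1) {
          set_pair(i, cand[[i]], 1, "pedigree")
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }

  # EM on panel haplotype frequencies over all individuals
  todo <- which(!res$resolved)
  freq <- rep(1 / H, H)
  for (it in seq_len(max_iter)) {
    expected <- rep(0, H)
    for (i in seq_along(ids)) {
      w <- pair_post(cand[[i]], prs, freq)
      for (q in seq_along(cand[[i]])) {
        r <- cand[[i]][q]
        expected[prs[r, 1]] <- expected[prs[r, 1]] + w[q]
        expected[prs[r, 2]] <- expected[prs[r, 2]] + w[q]
      }
    }
    new <- expected / sum(expected)
    if (max(abs(new - freq)) < tol) { freq <- new; break }
    freq <- new
  }
  for (i in todo) {
    w <- pair_post(cand[[i]], prs, freq)
    b <- which.max(w)
    r <- cand[[i]][b]
    res$hap1[i] <- labs[prs[r, 1]]
    res$hap2[i] <- labs[prs[r, 2]]
    res$probability[i] <- w[b]
    res$method[i] <- "em"
    res$resolved[i] <- w[b] >= min_posterior
  }
  attr(res, "em_frequencies") <- setNames(freq, labs)
  res
}

pair_post <- function(rs, prs, freq) {
  w <- vapply(rs, function(r) {
    f <- freq[prs[r, 1]] * freq[prs[r, 2]]
    if (prs[r, 1] != prs[r, 2]) 2 * f else f
  }, numeric(1))
  if (sum(w) == 0) rep(1 / length(w), length(w)) else w / sum(w)
}

# ---------------------------------------------------------------------------
# Minimum spanning network
# ---------------------------------------------------------------------------

#' Minimum spanning network over a haplotype panel
#'
#' Builds a minimum spanning tree over the distinct haplotypes with edge
#' weights equal to raw pairwise nucleotide differences (complete deletion of
#' ambiguous sites).  Kruskal's algorithm with deterministic tie-breaking:
#' edges are considered in order of (weight, label pair, lexicographic).  A
#' Tamura-Nei (TN93) distance matrix is attached for reference.
#'
#' @param panel a [seq_panel()] with at least two distinct haplotypes.
#' @param counts optional named haplotype counts to carry on the nodes.
#' @return A list of class `haplotype_network` with `nodes` (data.frame of
#'   label and count) and `edges` (data.frame `from`, `to`, `steps`), plus a
#'   `tn93` distance matrix attribute.
#' @export
build_msn <- function(panel, counts = NULL) {
  labs <- names(panel$sequences)
  if (length(labs) < 2) stop("need at least 2 haplotypes")
  m <- seq_matrix(panel)
  use <- usable_sites(m)
  d <- pair_diff_matrix(m[, use, drop = FALSE])

  ord <- order(labs)
  labs_s <- labs[ord]
  edges <- t(combn(labs_s, 2))
  w <- d[cbind(edges[, 1], edges[, 2])]
  o <- order(w, edges[, 1], edges[, 2])
  edges <- edges[o, , drop = FALSE]
  w <- w[o]

  parent <- setNames(labs, labs)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  keep <- logical(length(w))
  for (e in seq_along(w)) {
    ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
    if (ra != rb) { parent[[ra]] <- rb; keep[e] <- TRUE }
  }
  ed <- data.frame(from = edges[keep, 1], to = edges[keep, 2],
                   steps = as.integer(w[keep]), stringsAsFactors = FALSE)
  nodes <- data.frame(haplotype = labs,
                      count = if (is.null(counts)) NA_integer_
                              else as.integer(counts[labs]),
                      stringsAsFactors = FALSE)
  dna <- ape::as.DNAbin(strsplit(tolower(panel$sequences), ""))
  tn93 <- tryCatch(ape::dist.dna(ape::as.matrix.DNAbin(dna), model = "TN93",
                                 pairwise.deletion = TRUE),
                   error = function(e) NULL)
  structure(list(nodes = nodes, edges = ed, raw_dist = d, tn93 = tn93),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d nodes, %d edges, total weight %d\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$steps)))
  invisible(x)
}
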