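# Dyadic maximum-likelihood relatedness over the IBD-coefficient simplex
# (k0, k1, k2), relationship classification among U/HS/FS/PO, parametric
# bootstrap confidence sets, and category-wise comparison statistics.
#
# r = k1/2 + k2.  Fixed-category coefficients:
#   U  = (1, 0, 0)     HS = (0.5, 0.5, 0)
#   FS = (0.25, 0.5, 0.25)   PO = (0, 1, 0)

CATEGORY_K <- rbind(U = c(1, 0, 0),
                    HS = c(0.5, 0.5, 0),
                    FS = c(0.25, 0.5, 0.25),
                    PO = c(0, 1, 0))

hw_prob <- function(g, p) {
  pa <- p[as.character(g[1])]; pb <- p[as.character(g[2])]
  if (anyNA(pa) || anyNA(pb))
    stop("allele absent from frequency vector")
  if (g[1] == g[2]) unname(pa^2) else unname(2 * pa * pb)
}

# probability the unordered genotype g is formed by IBD allele x plus one
# random population allele
ibd_extra_prob <- function(x, g, p) {
  if (g[1] == g[2]) {
    if (x == g[1]) unname(p[as.character(g[1])]) else 0
  } else if (x == g[1]) {
    unname(p[as.character(g[2])])
  } else if (x == g[2]) {
    unname(p[as.character(g[1])])
  } else 0
}

# (P0, P1, P2): joint probability of the unordered genotype pair given 0, 1
# or 2 alleles shared identical by descent
ibd_component_probs <- function(g1, g2, p) {
  P0 <- hw_prob(g1, p) * hw_prob(g2, p)
  shared <- intersect(g1, g2)
  P1 <- 0
  for (x in shared) {
    P1 <- P1 + p[as.character(x)] * ibd_extra_prob(x, g1, p) *
      ibd_extra_prob(x, g2, p)
  }
  P2 <- if (g1[1] == g2[1] && g1[2] == g2[2]) hw_prob(g1, p) else 0
  c(P0 = unname(P0), P1 = unname(P1), P2 = P2)
}

#' Single-locus dyad likelihood given IBD coefficients
#'
#' \eqn{P(g_1, g_2 | k) = k_0 P_0 + k_1 P_1 + k_2 P_2}, where the components
#' condition on 0, 1 or 2 alleles shared identical by descent, non-IBD
#' alleles drawn independently from the population frequencies.
#'
#' @param g1,g2 length-2 vectors of allele labels.
#' @param k numeric vector `(k0, k1, k2)` summing to 1.
#' @param p named allele frequency vector for the locus.
#' @return The likelihood of the unordered genotype pair.
#' @export
dyad_likelihood <- function(g1, g2, k, p) {
  stopifnot(length(k) == 3, abs(sum(k) - 1) < 1e-9)
  sum(k * ibd_component_probs(g1, g2, p))
}

# component matrix over co-typed loci; rows = loci, cols = P0,P1,P2
dyad_components <- function(g1_a1, g1_a2, g2_a1, g2_a2, freqs) {
  ok <- !is.na(g1_a1) & !is.na(g2_a1)
  loci <- names(freqs)[ok]
  if (length(loci) == 0) stop("zero co-typed loci")
  t(vapply(which(ok), function(j)
    ibd_component_probs(c(g1_a1[j], g1_a2[j]), c(g2_a1[j], g2_a2[j]),
                        freqs[[j]]$freq),
    numeric(3)))
}

# cached k-grid over the simplex
k_grid_cache <- new.env(parent = emptyenv())
k_grid <- function(step = 0.01) {
  key <- as.character(step)
  if (!is.null(k_grid_cache[[key]])) return(k_grid_cache[[key]])
  k0 <- seq(0, 1, by = step)
  g <- expand.grid(k0 = k0, k1 = k0)
  g <- g[g$k0 + g$k1 <= 1 + 1e-12, ]
  K <- cbind(g$k0, g$k1, pmax(0, 1 - g$k0 - g$k1))
  k_grid_cache[[key]] <- K
  K
}

grid_lnl <- function(P, K) {
  L <- K %*% t(P)              # grid points x loci
  rowSums(log(L))
}

extract_dyad <- function(gt, id1, id2) {
  i1 <- match(id1, gt$ids); i2 <- match(id2, gt$ids)
  if (anyNA(c(i1, i2))) stop("unknown individual id")
  list(g1_a1 = gt$a1[i1, ], g1_a2 = gt$a2[i1, ],
       g2_a1 = gt$a1[i2, ], g2_a2 = gt$a2[i2, ])
}

#' Maximum-likelihood relatedness for a dyad
#'
#' Maximises the summed log-likelihood over the IBD-coefficient simplex by
#' grid search (default step 0.01) followed by local Nelder-Mead refinement;
#' \eqn{\hat r = k_1/2 + k_2}.  Loci missing in either member are skipped.
#' The feasibility constraint \eqn{k_1^2 \ge 4 k_0 k_2} is not imposed unless
#' requested.
#'
#' @param gt a [genotype_table()].
#' @param id1,id2 individual ids.
#' @param freqs an [allele_frequencies()] object (population frequencies).
#' @param grid_step grid resolution on the simplex.
#' @param constrain_feasible impose \eqn{k_1^2 \ge 4 k_0 k_2}.
#' @return A list with `r_hat`, `k_hat` (named k0,k1,k2) and `lnL`.
#' @export
estimate_r <- function(gt, id1, id2, freqs, grid_step = 0.01,
                       constrain_feasible = FALSE) {
  d <- extract_dyad(gt, id1, id2)
  P <- dyad_components(d$g1_a1, d$g1_a2, d$g2_a1, d$g2_a2, freqs)
  K <- k_grid(grid_step)
  if (constrain_feasible)
    K <- K[K[, 2]^2 >= 4 * K[, 1] * K[, 3] - 1e-12, , drop = FALSE]
  lnl <- grid_lnl(P, K)
  best <- which.max(lnl)
  k0 <- K[best, ]

  obj <- function(par) {
    k <- c(par[1], par[2], 1 - par[1] - par[2])
    if (any(k < 0) || any(k > 1)) return(1e18)
    if (constrain_feasible && k[2]^2 < 4 * k[1] * k[3]) return(1e18)
    l <- P %*% k
    if (any(l <= 0)) return(1e18)
    -sum(log(l))
  }
  opt <- suppressWarnings(
    optim(c(k0[1], k0[2]), obj, method = "Nelder-Mead",
          control = list(reltol = 1e-10)))
  k_hat <- c(opt$par[1], opt$par[2], 1 - sum(opt$par))
  if (-opt$value < max(lnl[is.finite(lnl)])) {  # refinement must not regress
    k_hat <- k0
    opt$value <- -lnl[best]
  }
  k_hat <- pmin(pmax(k_hat, 0), 1)
  k_hat <- k_hat / sum(k_hat)
  names(k_hat) <- c("k0", "k1", "k2")
  list(r_hat = unname(k_hat[2] / 2 + k_hat[3]), k_hat = k_hat,
       lnL = -opt$value)
}

category_lnl <- function(P) {
  vapply(rownames(CATEGORY_K), function(cat) {
    l <- P %*% CATEGORY_K[cat, ]
    if (any(l <= 0)) -Inf else sum(log(l))
  }, numeric(1))
}

#' Classify a dyad's relationship from marker data
#'
#' Evaluates the log-likelihood at the four fixed relationship categories
#' (unrelated, half-sib, full-sib, parent-offspring) and reports the maximum,
#' with ties broken toward the less-related category.  Also returns the free
#' ML estimate from [estimate_r()].
#'
#' @inheritParams estimate_r
#' @return A list of class `relatedness_result` with `dyad`, `r_hat`,
#'   `k_hat`, `lnL_by_category`, `best_category` and `ci_categories`
#'   (`NULL` until [relationship_ci()] is run).
#' @export
classify_relationship <- function(gt, id1, id2, freqs, grid_step = 0.01) {
  d <- extract_dyad(gt, id1, id2)
  P <- dyad_components(d$g1_a1, d$g1_a2, d$g2_a1, d$g2_a2, freqs)
  lnl <- category_lnl(P)
  best <- names(lnl)[which(lnl >= max(lnl) - 1e-9)][1]  # order U,HS,FS,PO
  est <- estimate_r(gt, id1, id2, freqs, grid_step)
  structure(list(dyad = c(id1, id2), r_hat = est$r_hat, k_hat = est$k_hat,
                 lnL_by_category = lnl, best_category = best,
                 ci_categories = NULL),
            class = "relatedness_result")
}

# simulate one dyad genotype pair under category k with a given missingness
# pattern (logical vector over loci; TRUE = co-typed)
sim_dyad_category <- function(k, freqs, cotyped) {
  L <- length(freqs)
  g1_a1 <- g1_a2 <- g2_a1 <- g2_a2 <- rep(NA_integer_, L)
  for (j in seq_len(L)) {
    if (!cotyped[j]) next
    p <- freqs[[j]]$freq
    al <- as.integer(names(p))
    draw <- function(n) al[sample.int(length(al), n, replace = TRUE, prob = p)]
    n_ibd <- sample(0:2, 1, prob = k)
    if (n_ibd == 0) {
      g1 <- draw(2); g2 <- draw(2)
    } else if (n_ibd == 1) {
      x <- draw(1)
      g1 <- c(x, draw(1)); g2 <- c(x, draw(1))
    } else {
      g1 <- draw(2); g2 <- g1
    }
    g1 <- sort(g1); g2 <- sort(g2)
    g1_a1[j] <- g1[1]; g1_a2[j] <- g1[2]
    g2_a1[j] <- g2[1]; g2_a2[j] <- g2[2]
  }
  list(g1_a1 = g1_a1, g1_a2 = g1_a2, g2_a1 = g2_a1, g2_a2 = g2_a2)
}

#' Simulation-based 95% confidence set of relationship categories
#'
#' For each non-best category R', dyads are simulated under R' (parametric
#' bootstrap by gene dropping from the population frequencies, preserving the
#' observed missingness pattern).  R' is rejected when the observed
#' log-likelihood difference (best vs R') exceeds the 95th percentile of the
#' simulated differences; the confidence set is the non-rejected categories
#' plus the best one.
#'
#' @inheritParams estimate_r
#' @param n_randomizations simulated dyads per alternative category
#'   (default 100000; at least 1000).
#' @param seed RNG seed.
#' @return A `relatedness_result` with `ci_categories` filled in.
#' @export
relationship_ci <- function(gt, id1, id2, freqs, n_randomizations = 100000,
                            seed = 1) {
  stopifnot(n_randomizations >= 1000)
  res <- classify_relationship(gt, id1, id2, freqs)
  d <- extract_dyad(gt, id1, id2)
  cotyped <- !is.na(d$g1_a1) & !is.na(d$g2_a1)
  lnl <- res$lnL_by_category
  best <- res$best_category
  set.seed(seed)
  keep <- best
  for (alt in setdiff(rownames(CATEGORY_K), best)) {
    obs_diff <- lnl[best] - lnl[alt]
    sim_diff <- vapply(seq_len(n_randomizations), function(i) {
      s <- sim_dyad_category(CATEGORY_K[alt, ], freqs, cotyped)
      Ps <- dyad_components(s$g1_a1, s$g1_a2, s$g2_a1, s$g2_a2, freqs)
      l <- category_lnl(Ps)
      l[best] - l[alt]
    }, numeric(1))
    if (!(obs_diff > quantile(sim_diff, 0.95, names = FALSE, type = 1)))
      keep <- c(keep, alt)
  }
  res$ci_categories <- intersect(rownames(CATEGORY_K), keep)
  res
}

#' Compare relatedness among pedigree relationship categories
#'
#' One-way ANOVA of pairwise relatedness across studbook relationship
#' categories, with post-hoc Tukey HSD: for each category pair the
#' studentized-range statistic \eqn{Q = |\bar y_i - \bar y_j| /
#' \sqrt{(MSE/2)(1/n_i + 1/n_j)}} and its p-value from the studentized range
#' distribution.
#'
#' @param r numeric vector of relatedness estimates.
#' @param category factor or character of studbook categories, same length.
#' @return A list with `anova` (`F`, `df`, `p_value`) and `tukey`
#'   (data.frame: pair, diff, Q, p_value).  Groups with fewer than two
#'   observations are dropped with a warning.
#' @export
compare_categories <- function(r, category) {
  category <- as.character(category)
  tab <- table(category)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("dropping group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !(category %in% small)
    r <- r[keep]; category <- category[keep]
  }
  if (length(unique(category)) < 2) stop("need at least 2 groups")
  f <- factor(category)
  if (stats::var(r) == 0) {   # all observations identical: no signal at all
    prs <- combn(levels(f), 2)
    tuk <- data.frame(pair = paste(prs[2, ], prs[1, ], sep = "-"),
                      diff = 0, Q = 0, p_value = 1, stringsAsFactors = FALSE)
    return(list(anova = list(F = 0, df = c(nlevels(f) - 1,
                                           length(r) - nlevels(f)),
                             p_value = 1),
                tukey = tuk))
  }
  fit <- aov(r ~ f)
  an <- anova(fit)
  mse <- an[["Mean Sq"]][2]
  df_err <- an[["Df"]][2]
  kgrp <- nlevels(f)
  means <- tapply(r, f, mean)
  ns <- tapply(r, f, length)
  prs <- combn(levels(f), 2)
  tuk <- do.call(rbind, lapply(seq_len(ncol(prs)), function(q) {
    g1 <- prs[1, q]; g2 <- prs[2, q]
    diff <- means[g2] - means[g1]
    se <- sqrt(mse / 2 * (1 / ns[g1] + 1 / ns[g2]))
    Q <- abs(diff) / se
    data.frame(pair = paste(g2, g1, sep = "-"), diff = unname(diff),
               Q = unname(Q),
               p_value = ptukey(Q, kgrp, df_err, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  list(anova = list(F = an[["F value"]][1],
                    df = an[["Df"]],
                    p_value = an[["Pr(>F)"]][1]),
       tukey = tuk)
}
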