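# Likelihood-based parentage: Mendelian transition probabilities, LOD and
# Delta scores, Mendelian exclusion counting, MHC-haplotype trio checks, and
# the combined case-resolution pipeline used for studbook reconciliation.

# probability that a parent genotype transmits allele a
transmit_prob <- function(a, g) {
  0.5 * sum(g == a)
}

#' Mendelian transition probability of an offspring genotype
#'
#' Exact probability of the offspring's unordered genotype given one or two
#' parental genotypes; an unknown parent is integrated over the population
#' allele frequencies under HWE.  With no parent supplied this reduces to the
#' HWE genotype probability.
#'
#' @param go,gp,gm length-2 allele vectors: offspring, candidate parent,
#'   other parent (`gm = NULL` for unknown).
#' @param p named allele frequency vector for the locus.
#' @return A probability.
#' @export
transition_prob <- function(go, gp = NULL, gm = NULL, p) {
  if (anyNA(p[as.character(go)]))
    stop("offspring allele absent from frequency vector")
  if (is.null(gp) && is.null(gm)) return(hw_prob(go, p))
  if (is.null(gp)) { gp <- gm; gm <- NULL }
  x <- go[1]; y <- go[2]
  if (is.null(gm)) {
    # one parent known: parent transmits one allele, the other comes from
    # the population
    if (x == y) {
      transmit_prob(x, gp) * unname(p[as.character(x)])
    } else {
      transmit_prob(x, gp) * unname(p[as.character(y)]) +
        transmit_prob(y, gp) * unname(p[as.character(x)])
    }
  } else {
    if (x == y) {
      transmit_prob(x, gp) * transmit_prob(x, gm)
    } else {
      transmit_prob(x, gp) * transmit_prob(y, gm) +
        transmit_prob(y, gp) * transmit_prob(x, gm)
    }
  }
}

genotype_at <- function(gt, id, j) {
  i <- match(id, gt$ids)
  if (is.na(i)) stop("unknown individual id: ", id)
  a1 <- gt$a1[i, j]
  if (is.na(a1)) return(NULL)
  c(a1, gt$a2[i, j])
}

#' Parentage LOD score for one candidate parent
#'
#' Per co-typed locus, the likelihood that the candidate is a parent is
#' \eqn{L_1 = (1-\epsilon) T + \epsilon P_{HW}(g_o)} with `T` the Mendelian
#' transition probability (known other parent incorporated), against
#' \eqn{L_2}, the same expression with the candidate replaced by an unknown
#' parent.  `LOD = sum ln(L1/L2)`; `mismatches` counts loci with `T = 0`
#' (Mendelian exclusions).  With `epsilon = 0`, any exclusion drives the LOD
#' to `-Inf` and the decision to `"excluded"`.
#'
#' @param gt a [genotype_table()].
#' @param offspring,candidate ids; `other` the known other parent id or
#'   `NULL`.
#' @param freqs an [allele_frequencies()] object.
#' @param epsilon per-locus genotyping error rate (default 0.01).
#' @return A list of class `parentage_result`: `offspring`, `candidate`,
#'   `other`, `LOD`, `mismatches`, `n_loci`, `delta` (filled by
#'   [delta_ranking()]) and `decision`.
#' @export
parentage_lod <- function(gt, offspring, candidate, other = NULL, freqs,
                          epsilon = 0.01) {
  lod <- 0
  mism <- 0L
  n_loci <- 0L
  for (j in seq_along(gt$loci)) {
    go <- genotype_at(gt, offspring, j)
    gc_ <- genotype_at(gt, candidate, j)
    if (is.null(go) || is.null(gc_)) next
    gm <- if (!is.null(other)) genotype_at(gt, other, j) else NULL
    p <- freqs[[j]]$freq
    n_loci <- n_loci + 1L
    T1 <- transition_prob(go, gc_, gm, p)
    T2 <- transition_prob(go, gm, NULL, p)   # candidate integrated out
    if (T1 == 0) mism <- mism + 1L
    L1 <- (1 - epsilon) * T1 + epsilon * hw_prob(go, p)
    L2 <- (1 - epsilon) * T2 + epsilon * hw_prob(go, p)
    lod <- lod + log(L1) - log(L2)
  }
  if (n_loci == 0) stop("zero co-typed loci")
  decision <- if (epsilon == 0 && mism > 0) "excluded"
              else if (lod > 0 && mism == 0) "supported"
              else "ambiguous"
  structure(list(offspring = offspring, candidate = candidate,
                 other = other, LOD = lod, mismatches = mism,
                 n_loci = n_loci, delta = NULL, decision = decision),
            class = "parentage_result")
}

#' Rank candidate parents by LOD and attach the Delta statistic
#'
#' Candidates are sorted by decreasing LOD; Delta (the difference between the
#' top two LOD scores) is attached to the top candidate.  An exact tie gives
#' Delta 0 and decision `"ambiguous"`.  With `epsilon > 0`, a candidate with
#' two or more exclusions whose LOD is below every competitor's is marked
#' `"excluded"`.
#'
#' @inheritParams parentage_lod
#' @param candidates character vector of candidate ids (length >= 2 for a
#'   Delta; a single candidate gets `delta = NULL`).
#' @return A list of `parentage_result`s, ranked.
#' @export
delta_ranking <- function(gt, offspring, candidates, other = NULL, freqs,
                          epsilon = 0.01) {
  res <- lapply(candidates, function(cand)
    parentage_lod(gt, offspring, cand, other, freqs, epsilon))
  lods <- vapply(res, `[[`, numeric(1), "LOD")
  ord <- order(-lods)
  res <- res[ord]; lods <- lods[ord]
  if (length(res) >= 2) {
    res[[1]]$delta <- lods[1] - lods[2]
    if (res[[1]]$delta < 1e-9) {
      res[[1]]$decision <- "ambiguous"
    }
    if (epsilon > 0) {
      for (i in seq_along(res)) {
        if (res[[i]]$mismatches >= 2 && lods[i] < min(lods[-i]))
          res[[i]]$decision <- "excluded"
      }
    }
  }
  res
}

#' MHC-haplotype trio consistency check
#'
#' A trio is consistent when the two offspring haplotypes can be assigned
#' bijectively to the two parents such that each assigned haplotype is
#' present in that parent's pair; an unknown parent accepts anything.  The
#' transmitted haplotypes are reported when the assignment is unique.
#'
#' @param offspring length-2 character vector of haplotype labels.
#' @param dam,sire length-2 label vectors or `NULL` if unknown.
#' @return A list of class `mhc_trio_check`: `consistent`, `transmitted`
#'   (named list `dam`/`sire`, `NA` when not uniquely determined).
#' @export
mhc_trio_check <- function(offspring, dam = NULL, sire = NULL) {
  stopifnot(length(offspring) == 2)
  can_give <- function(parent, h) is.null(parent) || h %in% parent
  asn <- list(c(1, 2), c(2, 1))      # offspring haplotype -> (dam, sire)
  valid <- vapply(asn, function(a)
    can_give(dam, offspring[a[1]]) && can_give(sire, offspring[a[2]]),
    logical(1))
  transmitted <- list(dam = NA_character_, sire = NA_character_)
  if (any(valid)) {
    dam_h <- unique(vapply(asn[valid], function(a) offspring[a[1]],
                           character(1)))
    sire_h <- unique(vapply(asn[valid], function(a) offspring[a[2]],
                            character(1)))
    if (length(dam_h) == 1 && !is.null(dam)) transmitted$dam <- dam_h
    if (length(sire_h) == 1 && !is.null(sire)) transmitted$sire <- sire_h
  }
  structure(list(consistent = any(valid), transmitted = transmitted),
            class = "mhc_trio_check")
}

#' Resolve a parentage case with combined microsatellite and MHC evidence
#'
#' The reconciliation pipeline for one offspring: (1) Mendelian exclusion of
#' candidates, (2) LOD/Delta ranking among survivors, (3) MHC trio check as
#' veto or confirmation, (4) a final decision with the full evidence trail.
#' If all candidates for a role are excluded, the decision for that role is
#' `"true parent unsampled"`.
#'
#' @param gt a [genotype_table()].
#' @param offspring offspring id.
#' @param dam_candidates,sire_candidates character vectors of candidate ids
#'   (may be length 1 for a known parent).
#' @param freqs an [allele_frequencies()] object.
#' @param mhc optional named list of haplotype pairs (id -> length-2 labels)
#'   for the MHC veto step.
#' @param epsilon genotyping error rate.
#' @param max_mismatch Mendelian exclusion threshold: candidates with more
#'   mismatching loci are dropped before ranking (default 0 when
#'   `epsilon = 0`, else 1).
#' @return A list of class `parentage_case` with per-role candidate tables
#'   and decisions.
#' @export
resolve_parentage_case <- function(gt, offspring, dam_candidates,
                                   sire_candidates, freqs, mhc = NULL,
                                   epsilon = 0.01,
                                   max_mismatch = if (epsilon == 0) 0 else 1) {
  stopifnot(length(dam_candidates) >= 1, length(sire_candidates) >= 1)
  off_pair <- if (!is.null(mhc)) mhc[[offspring]] else NULL

  resolve_role <- function(cands, role, other_best) {
    res <- lapply(cands, function(cand)
      parentage_lod(gt, offspring, cand, other_best, freqs, epsilon))
    tab <- data.frame(
      candidate = cands,
      LOD = vapply(res, `[[`, numeric(1), "LOD"),
      mismatches = vapply(res, `[[`, integer(1), "mismatches"),
      mendel_ok = NA, mhc_ok = NA, stringsAsFactors = FALSE)
    tab$mendel_ok <- tab$mismatches <= max_mismatch
    if (!is.null(off_pair)) {
      tab$mhc_ok <- vapply(seq_along(cands), function(i) {
        cp <- mhc[[cands[i]]]
        if (is.null(cp)) return(TRUE)         # untyped: uninformative
        op <- if (!is.null(other_best)) mhc[[other_best]] else NULL
        if (role == "dam") mhc_trio_check(off_pair, dam = cp, sire = op)$consistent
        else mhc_trio_check(off_pair, dam = op, sire = cp)$consistent
      }, logical(1))
    } else tab$mhc_ok <- TRUE
    surv <- tab[tab$mendel_ok & tab$mhc_ok, , drop = FALSE]
    if (nrow(surv) == 0) {
      decision <- "true parent unsampled"; best <- NA_character_; delta <- NA_real_
    } else {
      surv <- surv[order(-surv$LOD), , drop = FALSE]
      best <- surv$candidate[1]
      delta <- if (nrow(surv) >= 2) surv$LOD[1] - surv$LOD[2] else NA_real_
      decision <- if (surv$LOD[1] <= 0) "ambiguous"
                  else if (nrow(surv) == 1 || delta > 1e-9) "supported"
                  else "ambiguous"
    }
    list(table = tab, best = best, delta = delta, decision = decision)
  }

  # rank dams first with no sire assumed, then sires given the best dam,
  # then revisit dams given the best sire
  dam1 <- resolve_role(dam_candidates, "dam", NULL)
  sire1 <- resolve_role(sire_candidates, "sire",
                        if (!is.na(dam1$best)) dam1$best else NULL)
  dam2 <- resolve_role(dam_candidates, "dam",
                       if (!is.na(sire1$best)) sire1$best else NULL)
  structure(list(offspring = offspring, dam = dam2, sire = sire1),
            class = "parentage_case")
}
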