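test_that("Mendelian transition probabilities: boundary cases and enumeration oracle", {
  p <- c(`1` = 0.5, `2` = 0.3, `3` = 0.2)
  expect_equal(transition_prob(c(1, 1), c(2, 3), NULL, p), 0)
  expect_equal(transition_prob(c(1, 1), c(1, 1), c(1, 1), p), 1)
  # parent gives allele 1, population supplies allele 2
  expect_equal(transition_prob(c(1, 2), c(1, 1), NULL, p), 0.3,
               tolerance = 1e-12)

  set.seed(6)
  al <- 1:3
  pairs <- list()
  for (a in al) for (b in al) if (a <= b) pairs <- c(pairs, list(c(a, b)))
  for (gp in pairs) for (gm in c(pairs, list(NULL))) {
    tot <- 0
    for (go in pairs) {
      tp <- transition_prob(go, gp, gm, p)
      expect_equal(tp, oracle_transition_prob(go, gp, gm, p),
                   tolerance = 1e-12)
      tot <- tot + tp
    }
    expect_equal(tot, 1, tolerance = 1e-12)  # sums over offspring genotypes
  }
})

sim_trio_gt <- function(freqs, extra = list()) {
  # sire, dam drawn under HWE; kid by Mendelian transmission; extras appended
  al <- lapply(freqs, function(p) as.integer(names(p)))
  L <- length(freqs)
  draw <- function() vapply(seq_len(L), function(j)
    al[[j]][sample.int(length(al[[j]]), 1, prob = freqs[[j]])], integer(1))
  s1 <- draw(); s2 <- draw(); d1 <- draw(); d2 <- draw()
  k1 <- ifelse(runif(L) < 0.5, s1, s2)
  k2 <- ifelse(runif(L) < 0.5, d1, d2)
  calls <- list(sire = rbind(s1, s2), dam = rbind(d1, d2),
                kid = rbind(k1, k2))
  for (nm in names(extra)) calls[[nm]] <- extra[[nm]]
  gt <- toy_gt(calls, names(freqs))
  gt
}

std_freqs <- function(n_loci = 14, n_al = 6) {
  freqs <- lapply(seq_len(n_loci), function(i)
    setNames(rep(1 / n_al, n_al), as.character(100 + 2 * seq_len(n_al))))
  names(freqs) <- sprintf("L%02d", seq_len(n_loci))
  freqs
}

test_that("true parents earn positive LOD, unrelated candidates negative, over simulated trios", {
  set.seed(41)
  freqs <- std_freqs()
  fr <- freq_obj(freqs)
  n_rep <- 120
  lod_true <- lod_unrel <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    al <- lapply(freqs, function(p) as.integer(names(p)))
    u1 <- vapply(al, function(x) sample(x, 1), integer(1))
    u2 <- vapply(al, function(x) sample(x, 1), integer(1))
    gt <- sim_trio_gt(freqs, extra = list(unrel = rbind(u1, u2)))
    lod_true[i] <- parentage_lod(gt, "kid", "sire", "dam", fr, 0)$LOD
    lod_unrel[i] <- parentage_lod(gt, "kid", "unrel", "dam", fr,
                                  0.01)$LOD
  }
  expect_gte(mean(lod_true > 0), 0.95)
  expect_lt(mean(lod_unrel), 0)
})

test_that("a single excluding locus at epsilon = 0 gives -Inf LOD and exclusion", {
  fr <- freq_obj(list(L1 = c(`1` = 0.5, `2` = 0.5)))
  gt <- toy_gt(list(kid = rbind(1, 1), cand = rbind(2, 2)), "L1")
  res <- parentage_lod(gt, "kid", "cand", NULL, fr, epsilon = 0)
  expect_identical(res$LOD, -Inf)
  expect_equal(res$mismatches, 1L)
  expect_equal(res$decision, "excluded")
})

test_that("epsilon tolerance is monotone: no supported decision becomes excluded", {
  set.seed(43)
  freqs <- std_freqs(10)
  fr <- freq_obj(freqs)
  gt <- sim_trio_gt(freqs)
  for (eps in c(0, 0.001, 0.01, 0.05)) {
    res <- parentage_lod(gt, "kid", "sire", "dam", fr, eps)
    expect_false(res$decision == "excluded")  # true parent, no mismatch
  }
})

test_that("Delta ranking: arithmetic, exact ties, and brother-vs-brother resolution", {
  set.seed(47)
  freqs <- std_freqs()
  fr <- freq_obj(freqs)

  # identical twin candidates -> delta 0, ambiguous
  gt <- sim_trio_gt(freqs)
  twin <- rbind(gt$a1[gt$ids == "sire", ], gt$a2[gt$ids == "sire", ])
  gt2 <- toy_gt(list(sire = rbind(gt$a1[1, ], gt$a2[1, ]),
                     dam = rbind(gt$a1[2, ], gt$a2[2, ]),
                     kid = rbind(gt$a1[3, ], gt$a2[3, ]),
                     twin = twin), names(freqs))
  rk <- delta_ranking(gt2, "kid", c("sire", "twin"), "dam", fr, 0.01)
  expect_equal(rk[[1]]$delta, 0, tolerance = 1e-12)
  expect_equal(rk[[1]]$decision, "ambiguous")

  # two full brothers as candidate sires: truth top-ranked >= 80%
  n_rep <- 120
  hit <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    al <- lapply(freqs, function(p) as.integer(names(p)))
    g1 <- vapply(al, function(x) sample(x, 1), integer(1))
    g2 <- vapply(al, function(x) sample(x, 1), integer(1))
    h1 <- vapply(al, function(x) sample(x, 1), integer(1))
    h2 <- vapply(al, function(x) sample(x, 1), integer(1))
    bro1_1 <- ifelse(runif(14) < 0.5, g1, g2); bro1_2 <- ifelse(runif(14) < 0.5, h1, h2)
    bro2_1 <- ifelse(runif(14) < 0.5, g1, g2); bro2_2 <- ifelse(runif(14) < 0.5, h1, h2)
    d1 <- vapply(al, function(x) sample(x, 1), integer(1))
    d2 <- vapply(al, function(x) sample(x, 1), integer(1))
    k1 <- ifelse(runif(14) < 0.5, bro1_1, bro1_2)
    k2 <- ifelse(runif(14) < 0.5, d1, d2)
    gt3 <- toy_gt(list(bro1 = rbind(bro1_1, bro1_2),
                       bro2 = rbind(bro2_1, bro2_2),
                       dam = rbind(d1, d2), kid = rbind(k1, k2)),
                  names(freqs))
    rk3 <- delta_ranking(gt3, "kid", c("bro1", "bro2"), "dam", fr, 0.01)
    hit[i] <- rk3[[1]]$candidate == "bro1"
  }
  expect_gte(mean(hit), 0.8)
})

test_that("MHC trio check: consistency logic, transmitted haplotypes, dam/sire symmetry", {
  r1 <- mhc_trio_check(c("A3", "B6"), dam = c("B6", "B6"), sire = c("A2", "A4"))
  expect_false(r1$consistent)

  r2 <- mhc_trio_check(c("A3", "B6"), dam = c("B6", "B7"), sire = c("A3", "A4"))
  expect_true(r2$consistent)
  expect_equal(r2$transmitted$dam, "B6")
  expect_equal(r2$transmitted$sire, "A3")

  r3 <- mhc_trio_check(c("B6", "B6"), dam = c("B6", "B1"), sire = NULL)
  expect_true(r3$consistent)
  expect_equal(r3$transmitted$dam, "B6")

  # symmetric under swapping parental roles
  set.seed(2)
  haps <- sprintf("H%d", 1:5)
  for (i in 1:20) {
    off <- sample(haps, 2, TRUE)
    dm <- sample(haps, 2, TRUE)
    sr <- sample(haps, 2, TRUE)
    expect_equal(mhc_trio_check(off, dm, sr)$consistent,
                 mhc_trio_check(off, sr, dm)$consistent)
  }
})

test_that("case resolution: MHC veto, tie ambiguity, and the unsampled-parent verdict", {
  set.seed(53)
  freqs <- std_freqs()
  fr <- freq_obj(freqs)
  al <- lapply(freqs, function(p) as.integer(names(p)))
  g1 <- vapply(al, function(x) sample(x, 1), integer(1))
  g2 <- vapply(al, function(x) sample(x, 1), integer(1))
  d1 <- vapply(al, function(x) sample(x, 1), integer(1))
  d2 <- vapply(al, function(x) sample(x, 1), integer(1))
  k1 <- g1; k2 <- d1
  # identical-genotype brothers: microsatellites cannot separate them
  gt <- toy_gt(list(bro1 = rbind(g1, g2), bro2 = rbind(g1, g2),
                    dam = rbind(d1, d2), kid = rbind(k1, k2)),
               names(freqs))

  # MHC separates: kid carries H1 from the sire; bro2 lacks H1
  mhc <- list(kid = c("H1", "H9"), dam = c("H9", "H9"),
              bro1 = c("H1", "H2"), bro2 = c("H3", "H4"))
  case <- resolve_parentage_case(gt, "kid", "dam", c("bro1", "bro2"),
                                 fr, mhc = mhc, epsilon = 0.01)
  expect_equal(case$sire$best, "bro1")
  expect_equal(case$sire$decision, "supported")

  # MHC uninformative -> tie stays ambiguous
  mhc2 <- list(kid = c("H1", "H9"), dam = c("H9", "H9"),
               bro1 = c("H1", "H2"), bro2 = c("H1", "H4"))
  case2 <- resolve_parentage_case(gt, "kid", "dam", c("bro1", "bro2"),
                                  fr, mhc = mhc2, epsilon = 0.01)
  expect_equal(case2$sire$decision, "ambiguous")

  # all sire candidates Mendelian-excluded -> true parent unsampled
  bad <- vapply(al, function(x) sample(x, 1), integer(1))
  gt3 <- toy_gt(list(cand = rbind(bad, bad),
                     dam = rbind(d1, d2), kid = rbind(k1, k2)),
                names(freqs))
  # make candidate mismatch everywhere: shift alleles off the kid's
  gt3$a1[gt3$ids == "cand", ] <- gt3$a1[gt3$ids == "kid", ] + 2L
  gt3$a2[gt3$ids == "cand", ] <- gt3$a1[gt3$ids == "cand", ]
  fr3 <- allele_frequencies(gt3)
  case3 <- resolve_parentage_case(gt3, "kid", "dam", "cand", fr3,
                                  epsilon = 0)
  expect_equal(case3$sire$decision, "true parent unsampled")
})
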