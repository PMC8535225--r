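two_hap_panel <- function(n1 = 65, n2 = 44, ndiff = 3, L = 308) {
  s1 <- strrep("A", L)
  s2 <- paste0(strrep("G", ndiff), strrep("A", L - ndiff))
  ids <- sprintf("i%03d", seq_len(n1 + n2))
  assignments <- as.list(setNames(rep(c("S2", "Z1"), c(n1, n2)), ids))
  seq_panel(c(S2 = s1, Z1 = s2), assignments)
}

test_that("haplotype collapsing reproduces carrier frequencies and merges N-only differences", {
  p <- two_hap_panel()
  tab <- collapse_haplotypes(p)
  expect_equal(tab$count, c(65L, 44L))
  expect_equal(tab$frequency, c(65, 44) / 109, tolerance = 1e-12)

  one <- seq_panel(c(a = "ACGT", b = "ACGT"),
                   as.list(setNames(c("a", "b"), c("i1", "i2"))))
  expect_equal(nrow(collapse_haplotypes(one)), 1L)
  expect_equal(collapse_haplotypes(one)$frequency, 1)

  # differ only at a site with an ambiguity: merged under complete deletion
  amb <- seq_panel(c(a = "ACGT", b = "ACNT"),
                   as.list(setNames(c("a", "b"), c("i1", "i2"))))
  expect_equal(nrow(collapse_haplotypes(amb)), 1L)

  expect_error(collapse_haplotypes(p, assignments = list()), "empty")
})

test_that("diversity statistics match direct formula evaluation on the two-haplotype panel", {
  st <- diversity_stats(two_hap_panel())
  expect_equal(st$k, 65 * 44 * 3 / choose(109, 2), tolerance = 1e-12)
  expect_equal(st$k, 1.45770, tolerance = 1e-4)
  expect_equal(st$Hd, 0.48590, tolerance = 1e-4)
  expect_equal(st$S, 3L)
  expect_equal(st$transitions, 3L)  # A<->G
  expect_equal(st$transversions, 0L)
  expect_equal(st$pi, st$k / 308, tolerance = 1e-12)
})

test_that("identical sequences give zero diversity", {
  p <- seq_panel(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"),
                 as.list(setNames(c("a", "b", "c"), c("i1", "i2", "i3"))))
  st <- diversity_stats(p)
  expect_equal(st$S, 0L)
  expect_equal(st$k, 0)
  expect_equal(st$pi, 0)
  expect_equal(st$Hd, 0)
})

test_that("k, pi, Hd agree with the brute-force all-pairs oracle on random alignments", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    L <- 40
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), L, TRUE, prob = c(.7, .1, .1, .1)),
            collapse = ""), character(1))
    # force some sharing
    seqs[2] <- seqs[1]
    names(seqs) <- sprintf("h%d", seq_len(n))
    ids <- sprintf("i%d", seq_len(n))
    p <- seq_panel(seqs, as.list(setNames(names(seqs), ids)))
    st <- diversity_stats(p)
    br <- brute_seq_stats(unname(seqs))
    expect_equal(st$k, br$k, tolerance = 1e-12)
    expect_equal(st$pi, br$pi, tolerance = 1e-12)
    expect_equal(st$Hd, br$Hd, tolerance = 1e-12)
    expect_equal(st$S, br$S)
    expect_gte(st$pi_jc, st$pi)               # JC inflates distances
    if (st$S > 0) expect_gt(st$pi_jc, st$pi)
  }
})

test_that("neutrality tests flag S = 0 as not computable and singletons force negative D", {
  p0 <- seq_panel(setNames(rep("ACGTAC", 6), sprintf("h%d", 1:6)),
                  as.list(setNames(sprintf("h%d", 1:6), sprintf("i%d", 1:6))))
  nt0 <- neutrality_tests(p0)
  expect_false(nt0$computable)
  expect_true(is.na(nt0$tajima_D))

  # 6 copies, every variant a singleton on a different sequence
  base <- strrep("A", 20)
  seqs <- vapply(1:6, function(i) {
    s <- strsplit(base, "")[[1]]
    if (i <= 4) s[i] <- "G"
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("h%d", 1:6)
  p1 <- seq_panel(seqs, as.list(setNames(names(seqs), sprintf("i%d", 1:6))))
  nt1 <- neutrality_tests(p1)
  expect_lt(nt1$tajima_D, 0)
  expect_lt(nt1$fu_li_Dstar, 0)
  expect_equal(nt1$eta_s, 4L)
})

test_that("neutrality statistics are calibrated against the coalescent (both near zero, unit-scale variance)", {
  sims <- sim_coalescent(20, 5, n_rep = 400, seed = 99)
  D <- vapply(sims, function(x) x$tajima_D, numeric(1))
  Ds <- vapply(sims, function(x) x$fu_li_Dstar, numeric(1))
  expect_lt(abs(mean(D, na.rm = TRUE)), 0.2)
  expect_lt(abs(mean(Ds, na.rm = TRUE)), 0.2)
  expect_gt(sd(Ds, na.rm = TRUE), 0.6)
  expect_lt(sd(Ds, na.rm = TRUE), 1.4)
})

# two-site toy with a built-in phase ambiguity: A3+B6 and A4+B7 produce the
# same per-site allele multiset
amb_panel <- function() {
  seq_panel(c(A3 = "AA", B6 = "GG", A4 = "AG", B7 = "GA"))
}

test_that("phasing resolves homozygotes and pedigree-constrained pairs with probability 1", {
  panel <- amb_panel()
  sb <- studbook(c("dam1", "sire1", "kid1"),
                 c(NA, NA, "sire1"), c(NA, NA, "dam1"),
                 c("F", "M", "M"), 2000L, TRUE)
  ped <- build_pedigree(sb)
  g <- c(dam1 = unphase_mhc(panel, c("B6", "B6")),
         sire1 = unphase_mhc(panel, c("A3", "A4")),
         kid1 = unphase_mhc(panel, c("A3", "B6")))
  ph <- phase_pairs(g, panel, ped = ped)
  ph <- ph[match(c("dam1", "kid1"), ph$id), ]
  expect_equal(ph$method[1], "homozygote")
  expect_equal(ph$probability[1], 1)
  # kid is ambiguous between (A3,B6) and (A4,B7); dam B6/B6 forces (A3,B6)
  expect_equal(ph$method[2], "pedigree")
  expect_setequal(c(ph$hap1[2], ph$hap2[2]), c("A3", "B6"))
  expect_equal(ph$probability[2], 1)
})

test_that("phasing never assigns a pair excluded by a genotyped parent, and errors on impossible genotypes", {
  panel <- amb_panel()
  g <- c(x = paste0(unphase_mhc(panel, c("A3", "A3")), "ZZ"))
  expect_error(phase_pairs(g, panel), "x")
})

test_that("EM phasing resolves >=95% of ambiguous pairs correctly at realistic haplotype frequencies", {
  set.seed(31)
  # ten haplotypes over 8 sites; first four engineered so that (h1,h2) and
  # (h3,h4) collide, mirroring real MHC phase ambiguity
  core <- c("AAAAAAAA", "GGAAAAAA", "GAAAAAAA", "AGAAAAAA")
  extra <- vapply(1:6, function(i) {
    s <- rep("A", 8); s[2 + i] <- "G"; s[sample(8, 1)] <- "G"
    paste(s, collapse = "")
  }, character(1))
  seqs <- c(core, extra)
  names(seqs) <- sprintf("H%02d", 1:10)
  panel <- seq_panel(seqs)
  freq <- c(0.0288, 0.0337, 0.1587, 0.1298, 0.0673, 0.0433, 0.0144,
            0.4279, 0.0529, 0.0433)
  freq <- freq / sum(freq)
  n <- 100
  truth <- replicate(n, sort(names(seqs)[sample.int(10, 2, TRUE, prob = freq)]),
                     simplify = FALSE)
  names(truth) <- sprintf("i%03d", seq_len(n))
  g <- vapply(truth, function(pr) unphase_mhc(panel, pr), character(1))
  ph <- phase_pairs(g, panel)
  em <- ph$method == "em" & ph$resolved
  correct <- vapply(seq_len(nrow(ph)), function(i)
    setequal(c(ph$hap1[i], ph$hap2[i]), truth[[ph$id[i]]]) ||
      ph$hap1[i] == truth[[ph$id[i]]][1] && ph$hap2[i] == truth[[ph$id[i]]][2],
    logical(1))
  expect_true(all(correct[ph$method %in% c("homozygote", "panel_unique")]))
  if (any(em)) expect_gte(mean(correct[em]), 0.95)
})

test_that("minimum spanning network: forced tree, tree shape, and exhaustive-minimum weight", {
  # three haplotypes at mutual distances 2, 3, 5 -> edges 2 and 3
  p3 <- seq_panel(c(h1 = "AAAAA", h2 = "GGAAA", h3 = "GGGGG"))
  net <- build_msn(p3)
  expect_equal(sort(net$edges$steps), c(2L, 3L))
  expect_equal(nrow(net$edges), 2L)

  set.seed(17)
  for (rep in 1:4) {
    n <- sample(4:7, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "G"), 12, TRUE), collapse = ""), character(1))
    names(seqs) <- sprintf("h%d", seq_len(n))
    p <- seq_panel(seqs)
    net <- build_msn(p)
    expect_equal(nrow(net$edges), n - 1L)
    d <- p$sequences
    dm <- net$raw_dist
    expect_equal(sum(net$edges$steps), brute_mst_weight(dm))
  }
})

test_that("MST matches vegan::spantree on a random panel", {
  skip_if_not_installed("vegan")
  set.seed(23)
  seqs <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 15, TRUE), collapse = ""),
    character(1))
  names(seqs) <- sprintf("h%d", 1:6)
  p <- seq_panel(seqs)
  net <- build_msn(p)
  sp <- vegan::spantree(as.dist(net$raw_dist))
  expect_equal(sum(net$edges$steps), sum(sp$dist))
})
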