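test_that("generators are deterministic given the seed", {
  cfg <- sim_config(seed = 101)
  f1 <- sim_founders(cfg)
  f2 <- sim_founders(cfg)
  expect_identical(f1, f2)
  sp1 <- sim_pedigree(cfg, f1)
  sp2 <- sim_pedigree(cfg, f2)
  expect_identical(sp1$sb, sp2$sb)
  g1 <- gene_drop(sp1$ped, f1, seed = 5)
  g2 <- gene_drop(sp2$ped, f2, seed = 5)
  expect_identical(g1$gt, g2$gt)
  wf1 <- sim_wright_fisher(20, 20, 5, 6, 10, "random", seed = 7)
  wf2 <- sim_wright_fisher(20, 20, 5, 6, 10, "random", seed = 7)
  expect_identical(wf1, wf2)
})

test_that("founder allele frequencies follow the drawn pool (law of large numbers)", {
  cfg <- sim_config(n_founders = 5000, n_loci = 1, alleles_range = c(2, 2),
                    dirichlet_conc = 1e6, seed = 3)  # conc -> equifrequent
  f <- sim_founders(cfg)
  obs <- allele_frequencies(f$gt)[[1]]$freq
  expect_equal(unname(obs[1]), 0.5, tolerance = 0.02)
})

test_that("monomorphic pools make all founders identical homozygotes", {
  cfg <- sim_config(n_founders = 10, n_loci = 3, alleles_range = c(1, 1),
                    seed = 4)
  f <- sim_founders(cfg)
  expect_true(all(f$gt$a1 == f$gt$a2))
  for (j in 1:3) expect_equal(length(unique(f$gt$a1[, j])), 1L)
})

test_that("monogamous pairing avoids related pairs unless inbreeding is allowed", {
  cfg <- sim_config(n_founders = 12, n_generations = 3,
                    pairs_per_generation = 4, litter_mean = 4, seed = 13)
  sp <- sim_pedigree(cfg)
  K <- kinship_matrix(sp$ped)
  df <- sp$ped$records
  mated <- unique(stats::na.omit(df[, c("sire_id", "dam_id")]))
  for (q in seq_len(nrow(mated)))
    expect_equal(K[mated$sire_id[q], mated$dam_id[q]], 0)
})

test_that("gene dropping is Mendelian: forced crosses, matriline, segregation ratios", {
  sb <- studbook(c("P1", "P2", paste0("k", 1:8)),
                 c(NA, NA, rep("P1", 8)), c(NA, NA, rep("P2", 8)),
                 c("M", "F", rep("M", 8)), 2000L, TRUE)
  ped <- build_pedigree(sb)
  founders <- list(
    freqs = list(L01 = c(`100` = 0.5, `102` = 0.5)),
    gt = genotype_table(c("P1", "P2"), "L01",
                        rbind(100L, 104L), rbind(100L, 104L)),
    mt = c(P1 = "M1", P2 = "M2"),
    mhc = list(P1 = c("H1", "H1"), P2 = c("H2", "H2")))
  truth <- gene_drop(ped, founders, seed = 5)
  kids <- paste0("k", 1:8)
  expect_true(all(truth$gt$a1[kids, 1] == 100L))
  expect_true(all(truth$gt$a2[kids, 1] == 104L))      # (a,a) x (b,b) -> (a,b)
  expect_true(all(truth$mt[kids] == "M2"))            # matrilineal
  expect_true(all(vapply(truth$mhc[kids], function(x)
    setequal(x, c("H1", "H2")), logical(1))))

  # (a,b) x (c,d): four classes at 25% each
  founders2 <- founders
  founders2$gt <- genotype_table(c("P1", "P2"), "L01",
                                 rbind(100L, 104L), rbind(102L, 106L))
  big_sb <- studbook(c("P1", "P2", sprintf("k%04d", 1:4000)),
                     c(NA, NA, rep("P1", 4000)), c(NA, NA, rep("P2", 4000)),
                     c("M", "F", rep("M", 4000)), 2000L, TRUE)
  truth2 <- gene_drop(build_pedigree(big_sb), founders2, seed = 6)
  kid_ids <- sprintf("k%04d", 1:4000)
  cls <- paste(truth2$gt$a1[kid_ids, 1], truth2$gt$a2[kid_ids, 1])
  expect_equal(length(unique(cls)), 4L)
  chi <- suppressWarnings(stats::chisq.test(table(cls)))
  expect_gt(chi$p.value, 0.001)
})

test_that("genotyping-noise injector: identity, total missingness, calibrated error fraction", {
  cfg <- sim_config(n_founders = 200, n_loci = 14, seed = 15)
  f <- sim_founders(cfg)
  clean <- inject_genotyping_noise(f$gt, 0, 0, seed = 1)
  expect_identical(clean$gt$a1, f$gt$a1)
  expect_equal(nrow(clean$ledger), 0L)

  gone <- inject_genotyping_noise(f$gt, 0, 1, seed = 1)
  expect_true(all(is.na(gone$gt$a1)))

  noisy <- inject_genotyping_noise(f$gt, 0.01, 0, seed = 2)
  changed_alleles <- sum(noisy$gt$a1 != f$gt$a1) + sum(noisy$gt$a2 != f$gt$a2)
  n_alleles <- 2 * length(f$gt$ids) * length(f$gt$loci)
  # error draws can coincide with the original allele, so the observed
  # alteration rate sits slightly below the nominal per-allele rate
  expect_gt(changed_alleles / n_alleles, 0.004)
  expect_lt(changed_alleles / n_alleles, 0.012)
  expect_true(all(noisy$ledger$change == "error"))
})

test_that("studbook-error injector swaps a full sister in for the dam and records the truth", {
  cfg <- sim_config(n_founders = 10, n_generations = 2,
                    pairs_per_generation = 4, litter_mean = 4, seed = 17)
  sp <- sim_pedigree(cfg)
  none <- inject_studbook_errors(sp$sb, 0, 0, seed = 1)
  expect_identical(as.data.frame(none$sb), as.data.frame(sp$sb))

  err <- inject_studbook_errors(sp$sb, dam_swap_rate = 1, seed = 2)
  expect_gt(nrow(err$ledger), 0)
  for (q in seq_len(nrow(err$ledger))) {
    true_dam <- err$ledger$true_parent[q]
    rec_dam <- err$ledger$recorded_parent[q]
    expect_equal(classify_dyad(sp$ped, true_dam, rec_dam), "FS")
  }
})

test_that("Wright-Fisher at N = 2 loses heterozygosity at about 25% per generation", {
  set.seed(71)
  het_at <- function(gens) {
    hets <- replicate(60, {
      tryCatch({
        gt <- sim_wright_fisher(2, 2, 8, 12, gens, "random",
                                seed = sample.int(1e6, 1))
        mean(locus_diversity(gt)$H_O)
      }, error = function(e) 0)  # every locus fixed: heterozygosity 0
    })
    mean(hets)
  }
  h5 <- het_at(5)
  h8 <- het_at(8)
  ratio <- (h8 / h5)^(1 / 3)          # per-generation retention
  expect_equal(ratio, 0.75, tolerance = 0.12)
})

test_that("noise-free gene-dropped data pass every reconciliation stage cleanly", {
  cfg <- sim_config(n_founders = 16, n_generations = 2,
                    pairs_per_generation = 6, litter_mean = 4, seed = 23)
  f <- sim_founders(cfg)
  sp <- sim_pedigree(cfg, f)
  truth <- gene_drop(sp$ped, f, seed = 23)
  fr <- allele_frequencies(truth$gt)

  # marker overlay: zero violations
  ov <- overlay_markers(sp$ped, truth$mt, truth$mhc)
  expect_equal(nrow(ov$violations), 0L)

  # every true parent earns a positive LOD
  kids <- sp$sb$id[!is.na(sp$sb$sire_id)]
  some <- kids[seq(1, length(kids), length.out = min(8, length(kids)))]
  for (kid in some) {
    sire <- sp$sb$sire_id[sp$sb$id == kid]
    dam <- sp$sb$dam_id[sp$sb$id == kid]
    expect_gt(parentage_lod(truth$gt, kid, sire, dam, fr, 0)$LOD, 0)
    expect_gt(parentage_lod(truth$gt, kid, dam, sire, fr, 0)$LOD, 0)
  }

  # genetic categories derived from the pedigree itself are 100% consistent
  ids <- sp$sb$id
  prs <- utils::combn(ids[1:12], 2)
  genetic <- data.frame(
    id1 = prs[1, ], id2 = prs[2, ],
    best_category = vapply(seq_len(ncol(prs)), function(q) {
      cat <- classify_dyad(sp$ped, prs[1, q], prs[2, q])
      if (cat %in% c("GP", "AV", "FC")) "HS" else cat
    }, character(1)),
    r_hat = 0.1, stringsAsFactors = FALSE)
  rep_ <- consistency_report(sp$ped, genetic)
  expect_equal(rep_$summary$consistent_fraction, 1)
})
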