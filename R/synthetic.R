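# Synthetic pedigreed multi-marker data with the statistical structure the
# analysis assumes: a multi-generation pedigree founded by unrelated
# individuals, Mendelian transmission of unlinked microsatellites, maternal
# transmission of an mtDNA haplotype, biparental transmission of MHC
# haplotypes, genotyping error / missingness injectors, studbook-error
# injectors, and Wright-Fisher and neutral-coalescent simulators for
# estimator calibration.

#' Simulation configuration
#'
#' Defaults mirror the data shape of a North American captive painted-dog
#' style population: 28 founders, three descendant generations, 14 unlinked
#' microsatellite loci with 4-14 alleles each, two mtDNA haplotypes and ten
#' MHC haplotypes.
#'
#' @param n_founders number of founders (half of each sex).
#' @param n_generations descendant generations to simulate.
#' @param pairs_per_generation breeding pairs formed per generation.
#' @param litter_mean,litter_dispersion litter-size distribution: Poisson
#'   with the given mean when `litter_dispersion = Inf`, otherwise negative
#'   binomial with that dispersion (size) parameter.
#' @param n_loci number of microsatellite loci.
#' @param alleles_range integer range of allele counts per locus.
#' @param dirichlet_conc Dirichlet concentration for allele frequencies.
#' @param n_mt,n_mhc number of mtDNA / MHC haplotypes segregating among
#'   founders.
#' @param error_rate per-allele genotyping error rate.
#' @param missing_rate per-call missingness rate.
#' @param dam_swap_rate,sire_swap_rate per-offspring probabilities of the
#'   two injected studbook-error classes (dam replaced by a full sister;
#'   sire replaced by his brother).
#' @param allow_inbreeding permit pairs with nonzero pedigree kinship.
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 28, n_generations = 3,
                       pairs_per_generation = 8,
                       litter_mean = 5, litter_dispersion = Inf,
                       n_loci = 14, alleles_range = c(4, 14),
                       dirichlet_conc = 1, n_mt = 2, n_mhc = 10,
                       error_rate = 0, missing_rate = 0,
                       dam_swap_rate = 0, sire_swap_rate = 0,
                       allow_inbreeding = FALSE, seed = 1) {
  stopifnot(n_founders >= 2, n_generations >= 1, n_loci >= 1,
            error_rate >= 0, error_rate < 1,
            missing_rate >= 0, missing_rate <= 1,
            dam_swap_rate >= 0, dam_swap_rate <= 1,
                       sire_swap_rate >= 0, sire_swap_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

rdirichlet1 <- function(k, conc) {
  x <- stats::rgamma(k, conc)
  x / sum(x)
}

rlitter <- function(n, mean, dispersion) {
  if (is.infinite(dispersion)) rpois(n, mean)
  else stats::rnbinom(n, size = dispersion, mu = mean)
}

#' Simulate founder genotypes and marker pools
#'
#' Per-locus allele frequencies are drawn from a Dirichlet prior; founder
#' diploid genotypes are drawn under HWE; each founder receives one mtDNA
#' haplotype (transmitted maternally downstream) and an MHC haplotype pair.
#'
#' @param config a [sim_config()].
#' @return A list with `freqs` (per-locus named frequency vectors), `gt`
#'   (founder [genotype_table()]), `mt` (named haplotype vector), `mhc`
#'   (named list of pairs), `mt_freq`, `mhc_freq`, and `sexes`.
#' @export
sim_founders <- function(config) {
  set.seed(config$seed)
  ids <- sprintf("F%03d", seq_len(config$n_founders))
  sexes <- rep(c("M", "F"), length.out = config$n_founders)
  cand <- config$alleles_range[1]:config$alleles_range[2]
  n_all <- cand[sample.int(length(cand), config$n_loci, replace = TRUE)]
  loci <- sprintf("L%02d", seq_len(config$n_loci))
  freqs <- lapply(n_all, function(k)
    setNames(rdirichlet1(k, config$dirichlet_conc),
             as.character(100 + 2 * seq_len(k))))
  names(freqs) <- loci
  a1 <- a2 <- matrix(NA_integer_, length(ids), length(loci))
  for (j in seq_along(loci)) {
    al <- as.integer(names(freqs[[j]]))
    a1[, j] <- al[sample.int(length(al), length(ids), TRUE, prob = freqs[[j]])]
    a2[, j] <- al[sample.int(length(al), length(ids), TRUE, prob = freqs[[j]])]
  }
  gt <- genotype_table(ids, loci, a1, a2)
  mt_labels <- sprintf("M%d", seq_len(config$n_mt))
  mt_freq <- rdirichlet1(config$n_mt, 5)
  mt <- setNames(mt_labels[sample.int(config$n_mt, length(ids), TRUE,
                                      prob = mt_freq)], ids)
  mhc_labels <- sprintf("H%02d", seq_len(config$n_mhc))
  mhc_freq <- setNames(rdirichlet1(config$n_mhc, 2), mhc_labels)
  mhc <- lapply(ids, function(i)
    sort(mhc_labels[sample.int(config$n_mhc, 2, TRUE, prob = mhc_freq)]))
  names(mhc) <- ids
  list(freqs = freqs, gt = gt, mt = mt, mhc = mhc,
       mt_freq = setNames(mt_freq, mt_labels), mhc_freq = mhc_freq,
       sexes = setNames(sexes, ids))
}

#' Simulate a multi-generation monogamous pedigree
#'
#' Emulates a managed breeding program: each generation a fixed number of
#' monogamous pairs is drawn from the available adults; unless
#' `allow_inbreeding` is set, pairs with nonzero pedigree kinship are never
#' formed.  Litter sizes follow the configured distribution.
#'
#' @param config a [sim_config()].
#' @param founders optional output of [sim_founders()] (re-generated
#'   otherwise); only the sexes are used here.
#' @return A list with `sb` (the [studbook()]), `ped` (the built
#'   [pedigree()]).
#' @export
sim_pedigree <- function(config, founders = NULL) {
  if (is.null(founders)) founders <- sim_founders(config)
  set.seed(config$seed + 1)
  sb <- studbook(names(founders$sexes), NA, NA, unname(founders$sexes),
                 2000L, TRUE)
  counter <- 0L
  for (g in seq_len(config$n_generations)) {
    ped <- build_pedigree(sb)
    K <- kinship_matrix(ped)
    cur <- sb$id[ped$depth[sb$id] == g - 1]
    males <- sample(cur[sb$sex[match(cur, sb$id)] == "M"])
    females <- sample(cur[sb$sex[match(cur, sb$id)] == "F"])
    pairs <- list()
    used_f <- character(0)
    for (m in males) {
      if (length(pairs) >= config$pairs_per_generation) break
      ok <- females[!(females %in% used_f)]
      if (!config$allow_inbreeding)
        ok <- ok[K[m, ok] == 0]
      if (length(ok) == 0) next
      f <- ok[1]
      used_f <- c(used_f, f)
      pairs[[length(pairs) + 1]] <- c(m, f)
    }
    if (length(pairs) == 0) {
      warning("generation ", g, " truncated: no eligible pairs")
      break
    }
    sizes <- rlitter(length(pairs), config$litter_mean,
                     config$litter_dispersion)
    for (q in seq_along(pairs)) {
      if (sizes[q] == 0) next
      kid_ids <- sprintf("G%d_%03d", g, counter + seq_len(sizes[q]))
      counter <- counter + sizes[q]
      kids <- studbook(kid_ids, pairs[[q]][1], pairs[[q]][2],
                       sample(c("M", "F"), sizes[q], TRUE),
                       2000L + g, TRUE)
      sb <- studbook(c(sb$id, kids$id), c(sb$sire_id, kids$sire_id),
                     c(sb$dam_id, kids$dam_id), c(sb$sex, kids$sex),
                     c(sb$birth_year, kids$birth_year),
                     c(sb$alive, kids$alive))
    }
  }
  list(sb = sb, ped = build_pedigree(sb))
}

#' Gene-drop marker genotypes down a pedigree
#'
#' Each offspring receives one uniformly chosen allele from each parent at
#' every locus, its dam's mtDNA haplotype, and one MHC haplotype from each
#' parent.  No mutation is applied.
#'
#' @param ped a [pedigree()].
#' @param founders output of [sim_founders()]; every pedigree founder must
#'   be genotyped there.
#' @param seed RNG seed.
#' @return A list (`sim_truth`) with `gt` ([genotype_table()] for all
#'   individuals), `mt`, `mhc`, and `freqs` (the founder frequency pools).
#' @export
gene_drop <- function(ped, founders, seed = 1) {
  set.seed(seed)
  df <- ped$records
  ord <- order(ped$depth[df$id])
  ids <- df$id[ord]
  fids <- ped$founders
  if (!all(fids %in% founders$gt$ids))
    stop("ungenotyped founder(s): ",
         paste(setdiff(fids, founders$gt$ids), collapse = ", "))
  loci <- founders$gt$loci
  a1 <- a2 <- matrix(NA_integer_, length(ids), length(loci),
                     dimnames = list(ids, loci))
  mt <- setNames(rep(NA_character_, length(ids)), ids)
  mhc <- setNames(vector("list", length(ids)), ids)
  fidx <- match(ids, founders$gt$ids)
  sire <- setNames(df$sire_id, df$id)
  dam <- setNames(df$dam_id, df$id)
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (id %in% fids) {
      k <- fidx[i]
      a1[id, ] <- founders$gt$a1[k, ]
      a2[id, ] <- founders$gt$a2[k, ]
      mt[id] <- founders$mt[[id]]
      mhc[[id]] <- founders$mhc[[id]]
    } else {
      s <- sire[[id]]; d <- dam[[id]]
      pick <- function(p, j) if (runif(1) < 0.5) a1[p, j] else a2[p, j]
      for (j in seq_along(loci)) {
        x <- pick(s, j); y <- pick(d, j)
        a1[id, j] <- min(x, y); a2[id, j] <- max(x, y)
      }
      mt[id] <- mt[[d]]
      mhc[[id]] <- sort(c(sample(mhc[[s]], 1), sample(mhc[[d]], 1)))
    }
  }
  list(gt = genotype_table(ids, loci, a1, a2), mt = mt, mhc = mhc,
       freqs = founders$freqs)
}

#' Inject genotyping error and missingness
#'
#' Each allele is independently replaced with probability `error_rate` by an
#' allele drawn from the table's own frequency distribution at that locus;
#' each call is independently set missing with probability `missing_rate`.
#' Every alteration is recorded in a ledger.
#'
#' @param gt a [genotype_table()].
#' @param error_rate per-allele error probability.
#' @param missing_rate per-call missingness probability.
#' @param seed RNG seed.
#' @return A list with `gt` (noisy table) and `ledger` (data.frame: id,
#'   locus, change, old1, old2, new1, new2).
#' @export
inject_genotyping_noise <- function(gt, error_rate = 0, missing_rate = 0,
                                    seed = 1) {
  stopifnot(error_rate >= 0, error_rate < 1,
            missing_rate >= 0, missing_rate <= 1)
  set.seed(seed)
  freqs <- allele_frequencies(gt)
  a1 <- gt$a1; a2 <- gt$a2
  ledger <- list()
  log_row <- function(i, j, change, o1, o2, n1, n2) {
    ledger[[length(ledger) + 1]] <<- data.frame(
      id = gt$ids[i], locus = gt$loci[j], change = change,
      old1 = o1, old2 = o2, new1 = n1, new2 = n2, stringsAsFactors = FALSE)
  }
  for (j in seq_along(gt$loci)) {
    p <- freqs[[j]]$freq
    al <- as.integer(names(p))
    for (i in seq_along(gt$ids)) {
      if (is.na(a1[i, j])) next
      o1 <- a1[i, j]; o2 <- a2[i, j]
      n1 <- o1; n2 <- o2
      if (error_rate > 0) {
        if (runif(1) < error_rate)
          n1 <- al[sample.int(length(al), 1, prob = p)]
        if (runif(1) < error_rate)
          n2 <- al[sample.int(length(al), 1, prob = p)]
      }
      if (missing_rate > 0 && runif(1) < missing_rate) {
        a1[i, j] <- NA_integer_; a2[i, j] <- NA_integer_
        log_row(i, j, "missing", o1, o2, NA_integer_, NA_integer_)
        next
      }
      if (n1 != o1 || n2 != o2) {
        a1[i, j] <- min(n1, n2); a2[i, j] <- max(n1, n2)
        log_row(i, j, "error", o1, o2, min(n1, n2), max(n1, n2))
      }
    }
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(id = character(0), locus = character(0),
               change = character(0), old1 = integer(0), old2 = integer(0),
               new1 = integer(0), new2 = integer(0))
  list(gt = genotype_table(gt$ids, gt$loci, a1, a2), ledger = ledger)
}

#' Inject studbook recording errors
#'
#' Two error classes emulating realistic registry mistakes: the recorded dam
#' replaced by one of her full sisters, and the recorded sire replaced by
#' one of his (full) brothers.  Genotypes are untouched; the ledger records
#' the truth.
#'
#' @param sb a [studbook()].
#' @param dam_swap_rate,sire_swap_rate per-offspring swap probabilities
#'   (applied where an eligible sibling of the recorded parent exists).
#' @param seed RNG seed.
#' @return A list with `sb` (corrupted studbook) and `ledger` (data.frame:
#'   id, field, true_parent, recorded_parent).
#' @export
inject_studbook_errors <- function(sb, dam_swap_rate = 0, sire_swap_rate = 0,
                                   seed = 1) {
  set.seed(seed)
  df <- as.data.frame(sb)
  full_sibs <- function(id, sex) {
    r <- df[df$id == id, ]
    if (nrow(r) == 0 || is.na(r$sire_id) || is.na(r$dam_id)) return(character(0))
    sibs <- df$id[!is.na(df$sire_id) & !is.na(df$dam_id) &
                    df$sire_id == r$sire_id & df$dam_id == r$dam_id &
                    df$id != id & df$sex == sex]
    sibs
  }
  ledger <- list()
  for (q in seq_len(nrow(df))) {
    if (!is.na(df$dam_id[q]) && runif(1) < dam_swap_rate) {
      sis <- full_sibs(df$dam_id[q], "F")
      if (length(sis)) {
        new <- sis[sample.int(length(sis), 1)]
        ledger[[length(ledger) + 1]] <- data.frame(
          id = df$id[q], field = "dam_id", true_parent = df$dam_id[q],
          recorded_parent = new, stringsAsFactors = FALSE)
        df$dam_id[q] <- new
      }
    }
    if (!is.na(df$sire_id[q]) && runif(1) < sire_swap_rate) {
      bro <- full_sibs(df$sire_id[q], "M")
      if (length(bro)) {
        new <- bro[sample.int(length(bro), 1)]
        ledger[[length(ledger) + 1]] <- data.frame(
          id = df$id[q], field = "sire_id", true_parent = df$sire_id[q],
          recorded_parent = new, stringsAsFactors = FALSE)
        df$sire_id[q] <- new
      }
    }
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(id = character(0), field = character(0),
               true_parent = character(0), recorded_parent = character(0))
  out <- studbook(df$id, df$sire_id, df$dam_id, df$sex, df$birth_year,
                  df$alive)
  list(sb = out, ledger = ledger)
}

#' Wright-Fisher population simulator
#'
#' Discrete generations of constant size with random or monogamous pairing;
#' the final generation is sampled for effective-size estimator calibration.
#'
#' @param ne_true true population size per generation (>= 2).
#' @param sample_size individuals sampled from the final generation.
#' @param n_loci,n_alleles unlinked loci and (initially equifrequent)
#'   alleles per locus.
#' @param n_generations generations to run (>= 5).
#' @param mating `"random"` or `"monogamous"`.
#' @param seed RNG seed.
#' @return A [genotype_table()] of the sampled final generation.
#' @export
sim_wright_fisher <- function(ne_true, sample_size, n_loci = 14,
                              n_alleles = 8, n_generations = 20,
                              mating = c("random", "monogamous"), seed = 1) {
  mating <- match.arg(mating)
  stopifnot(ne_true >= 2, n_generations >= 5, sample_size <= ne_true)
  set.seed(seed)
  N <- ne_true
  a1 <- matrix(sample.int(n_alleles, N * n_loci, TRUE), N, n_loci)
  a2 <- matrix(sample.int(n_alleles, N * n_loci, TRUE), N, n_loci)
  sex <- rep(c("M", "F"), length.out = N)
  for (g in seq_len(n_generations)) {
    males <- which(sex == "M"); females <- which(sex == "F")
    if (mating == "random") {
      sires <- males[sample.int(length(males), N, TRUE)]
      dams <- females[sample.int(length(females), N, TRUE)]
    } else {
      np <- min(length(males), length(females))
      pm <- sample(males)[seq_len(np)]
      pf <- sample(females)[seq_len(np)]
      fam <- sample.int(np, N, TRUE)
      sires <- pm[fam]; dams <- pf[fam]
    }
    pick <- function(idx, A1, A2) {
      from1 <- matrix(runif(N * n_loci) < 0.5, N, n_loci)
      ifelse(from1, A1[idx, ], A2[idx, ])
    }
    new1 <- pick(sires, a1, a2)
    new2 <- pick(dams, a1, a2)
    a1 <- pmin(new1, new2); a2 <- pmax(new1, new2)
    sex <- sample(rep(c("M", "F"), length.out = N))
  }
  poly <- vapply(seq_len(n_loci), function(j)
    length(unique(c(a1[, j], a2[, j]))) > 1, logical(1))
  if (!any(poly))
    stop("all loci fixed during simulation; increase n_alleles or ne_true")
  take <- sample.int(N, sample_size)
  genotype_table(sprintf("WF%03d", seq_len(sample_size)),
                 sprintf("L%02d", seq_len(n_loci)),
                 a1[take, , drop = FALSE], a2[take, , drop = FALSE])
}

#' Neutral coalescent simulator (infinite sites, no recombination)
#'
#' Standard n-coalescent: exponential waiting times between coalescences,
#' mutations dropped on branches at rate theta/2 per unit coalescent time,
#' each creating a new segregating site carried by the branch's descendant
#' tips.  Used to calibrate the frequency-spectrum neutrality tests.
#'
#' @param n sample size (haploid copies).
#' @param theta scaled mutation rate (4 N mu).
#' @param n_rep replicates.
#' @param seed RNG seed.
#' @return A list of replicates, each with `S`, `k`, `eta_s` (derived
#'   singletons), `tajima_D`, `fu_li_Dstar` and `carriers` (n x S 0/1
#'   matrix).
#' @export
sim_coalescent <- function(n, theta, n_rep = 1, seed = 1) {
  set.seed(seed)
  tc <- tajima_constants(n)
  fc <- fu_li_dstar_constants(n)
  lapply(seq_len(n_rep), function(rep) {
    tips <- lapply(seq_len(n), function(i) i)
    sites <- list()
    k_lin <- n
    while (k_lin > 1) {
      t_k <- stats::rexp(1, k_lin * (k_lin - 1) / 2)
      for (l in seq_len(k_lin)) {
        nm <- rpois(1, theta / 2 * t_k)
        if (nm > 0)
          sites <- c(sites, rep(list(tips[[l]]), nm))
      }
      pr <- sample.int(k_lin, 2)
      tips[[pr[1]]] <- c(tips[[pr[1]]], tips[[pr[2]]])
      tips[[pr[2]]] <- NULL
      k_lin <- k_lin - 1
    }
    S <- length(sites)
    if (S == 0) {
      return(list(S = 0L, k = 0, eta_s = 0L,
                  tajima_D = NA_real_, fu_li_Dstar = NA_real_,
                  carriers = matrix(0L, n, 0)))
    }
    carriers <- matrix(0L, n, S)
    for (s in seq_len(S)) carriers[sites[[s]], s] <- 1L
    counts <- colSums(carriers)
    k <- sum(counts * (n - counts)) / choose(n, 2)
    eta_s <- sum(counts == 1L)
    D <- (k - S / tc$a1) / sqrt(tc$e1 * S + tc$e2 * S * (S - 1))
    Dstar <- (n / (n - 1) * S - fc$an * eta_s) /
      sqrt(fc$u * S + fc$v * S^2)
    list(S = S, k = k, eta_s = as.integer(eta_s), tajima_D = D,
         fu_li_Dstar = Dstar, carriers = carriers)
  })
}

#' Convert a 0/1 haplotype matrix to an aligned sequence panel
#'
#' Ancestral state `A`, derived `G`; invariant flanking columns pad the
#' alignment to `L` sites when requested.
#'
#' @param carriers 0/1 matrix (copies x segregating sites).
#' @param L total alignment length (>= ncol).
#' @return A [seq_panel()] with one sequence per row, labelled `hap<i>`,
#'   and haploid assignments `hap<i>` per copy.
#' @export
panel_from_binary <- function(carriers, L = ncol(carriers)) {
  stopifnot(L >= ncol(carriers))
  n <- nrow(carriers)
  m <- matrix("A", n, L)
  if (ncol(carriers) > 0)
    m[, seq_len(ncol(carriers))] <- ifelse(carriers == 1, "G", "A")
  seqs <- apply(m, 1, paste, collapse = "")
  names(seqs) <- sprintf("hap%d", seq_len(n))
  assignments <- as.list(setNames(names(seqs), sprintf("ind%d", seq_len(n))))
  seq_panel(seqs, assignments)
}
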