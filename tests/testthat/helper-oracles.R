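# Independent brute-force oracles used to validate the package's
# closed-form implementations on tiny inputs.

# all-pairs sequence statistics over explicit gene copies (no weighting
# shortcuts): copies is a character vector of sequence strings
brute_seq_stats <- function(copies) {
  m <- do.call(rbind, strsplit(copies, ""))
  ok <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, ok, drop = FALSE]
  n <- nrow(m)
  L <- ncol(m)
  diffs <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    diffs <- c(diffs, sum(m[i, ] != m[j, ]))
  k <- mean(diffs)
  key <- apply(m, 1, paste, collapse = "")
  p <- as.numeric(table(key)) / n
  Hd <- n / (n - 1) * (1 - sum(p^2))
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  list(k = k, pi = k / L, Hd = Hd, S = S)
}

# exhaustive minimum spanning tree weight via Pruefer-sequence enumeration
# (labelled trees on n nodes, n <= 7)
brute_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 2) return(d[1, 2])
  prufer_len <- n - 2
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), prufer_len)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    pr <- seqs[r, ]
    degree <- rep(1L, n)
    for (x in pr) degree[x] <- degree[x] + 1L
    w <- 0
    pr_work <- pr
    deg <- degree
    for (x in pr_work) {
      leaf <- which(deg == 1L)[1]
      w <- w + d[leaf, x]
      deg[leaf] <- 0L
      deg[x] <- deg[x] - 1L
    }
    last <- which(deg == 1L)
    w <- w + d[last[1], last[2]]
    best <- min(best, w)
  }
  best
}

# exact dyad-genotype-pair probability by enumeration of the generative
# process: condition on the IBD allele(s) drawn from the population, draw
# the remaining alleles independently
oracle_dyad_prob <- function(g1, g2, k, p) {
  al <- as.integer(names(p))
  match_pair <- function(x, y, g) x == g[1] && y == g[2]
  tot0 <- 0
  for (x1 in al) for (x2 in al) for (y1 in al) for (y2 in al) {
    pg1 <- sort(c(x1, x2)); pg2 <- sort(c(y1, y2))
    if (match_pair(pg1[1], pg1[2], g1) && match_pair(pg2[1], pg2[2], g2))
      tot0 <- tot0 + p[as.character(x1)] * p[as.character(x2)] *
        p[as.character(y1)] * p[as.character(y2)]
  }
  tot1 <- 0
  for (x in al) for (u in al) for (v in al) {
    pg1 <- sort(c(x, u)); pg2 <- sort(c(x, v))
    if (match_pair(pg1[1], pg1[2], g1) && match_pair(pg2[1], pg2[2], g2))
      tot1 <- tot1 + p[as.character(x)] * p[as.character(u)] *
        p[as.character(v)]
  }
  tot2 <- 0
  for (x in al) for (u in al) {
    pg <- sort(c(x, u))
    if (match_pair(pg[1], pg[2], g1) && match_pair(pg[1], pg[2], g2))
      tot2 <- tot2 + p[as.character(x)] * p[as.character(u)]
  }
  unname(k[1] * tot0 + k[2] * tot1 + k[3] * tot2)
}

# exact offspring-genotype probability by enumeration of parental gamete
# draws (known parents) and population draws (unknown parent)
oracle_transition_prob <- function(go, gp = NULL, gm = NULL, p) {
  al <- as.integer(names(p))
  gam_p <- function(g) if (is.null(g)) NULL else g  # two equally likely gametes
  tot <- 0
  from1 <- if (is.null(gp)) al else gp
  w1 <- if (is.null(gp)) p[as.character(al)] else rep(0.5, 2)
  from2 <- if (is.null(gm)) al else gm
  w2 <- if (is.null(gm)) p[as.character(al)] else rep(0.5, 2)
  for (i in seq_along(from1)) for (j in seq_along(from2)) {
    g <- sort(c(from1[i], from2[j]))
    if (g[1] == go[1] && g[2] == go[2]) tot <- tot + w1[i] * w2[j]
  }
  unname(tot)
}

# Monte-Carlo gene-dropping IBD probability (kinship) down a pedigree
mc_kinship <- function(ped, id1, id2, n_drops = 50000) {
  df <- ped$records
  ord <- order(ped$depth[df$id])
  ids <- df$id[ord]
  sire <- setNames(df$sire_id, df$id)[ids]
  dam <- setNames(df$dam_id, df$id)[ids]
  A1 <- A2 <- list()
  lab <- 0L
  for (i in seq_along(ids)) {
    id <- ids[i]
    inherit <- function(pid) {
      if (is.na(pid)) {
        lab <<- lab + 1L
        rep(lab, n_drops)
      } else {
        pick <- runif(n_drops) < 0.5
        ifelse(pick, A1[[pid]], A2[[pid]])
      }
    }
    A1[[id]] <- inherit(sire[[id]])
    A2[[id]] <- inherit(dam[[id]])
  }
  mean((A1[[id1]] == A1[[id2]]) + (A1[[id1]] == A2[[id2]]) +
         (A2[[id1]] == A1[[id2]]) + (A2[[id1]] == A2[[id2]])) / 4
}

# small helpers for building fixtures -------------------------------------

toy_gt <- function(calls, loci = NULL) {
  # calls: named list id -> matrix 2 x L (rows = two alleles)
  ids <- names(calls)
  L <- ncol(calls[[1]])
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(L))
  a1 <- t(vapply(calls, function(m) pmin(m[1, ], m[2, ]), numeric(L)))
  a2 <- t(vapply(calls, function(m) pmax(m[1, ], m[2, ]), numeric(L)))
  genotype_table(ids, loci, a1, a2)
}

# draw a diploid genotype table of unrelated individuals under HWE
hwe_table <- function(n, freqs) {
  loci <- names(freqs)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci))
  for (j in seq_along(loci)) {
    al <- as.integer(names(freqs[[j]]))
    a1[, j] <- al[sample.int(length(al), n, TRUE, prob = freqs[[j]])]
    a2[, j] <- al[sample.int(length(al), n, TRUE, prob = freqs[[j]])]
  }
  genotype_table(sprintf("I%03d", seq_len(n)), loci, a1, a2)
}

# named frequency list in the allele_frequencies layout
freq_obj <- function(freqs, n_copies = 1000) {
  out <- lapply(freqs, function(p) list(freq = p, n_copies = n_copies))
  class(out) <- "allele_frequencies"
  out
}

# simulate a dyad genotype pair under fixed IBD coefficients, returning a
# two-row genotype table
sim_dyad_gt <- function(k, freqs) {
  L <- length(freqs)
  a1 <- a2 <- matrix(NA_integer_, 2, L)
  for (j in seq_len(L)) {
    p <- freqs[[j]]
    al <- as.integer(names(p))
    draw <- function(n) al[sample.int(length(al), n, TRUE, prob = p)]
    state <- sample(0:2, 1, prob = k)
    if (state == 0) { g1 <- draw(2); g2 <- draw(2) }
    else if (state == 1) { x <- draw(1); g1 <- c(x, draw(1)); g2 <- c(x, draw(1)) }
    else { g1 <- draw(2); g2 <- g1 }
    a1[, j] <- c(min(g1), min(g2)); a2[, j] <- c(max(g1), max(g2))
  }
  genotype_table(c("d1", "d2"), names(freqs), a1, a2)
}
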