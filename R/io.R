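#' captivekin: genetic assessment and studbook reconciliation for captive populations
#'
#' The package is organised as a pipeline over three marker classes commonly
#' used in ex situ genetic management: a maternally inherited mitochondrial
#' control-region fragment, a highly polymorphic MHC class II locus whose
#' haplotypes behave as alleles of one nuclear locus, and a panel of unlinked
#' nuclear microsatellites.  Readers produce three containers
#' ([genotype_table()], [studbook()], [seq_panel()]) that every downstream
#' stage consumes; no analysis function reads files directly.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova aov optim ptukey qnorm quantile rpois runif sd
#'   setNames
#' @importFrom utils combn read.csv write.csv head
NULL

MISSING_ALLELE <- NA_integer_

# ---------------------------------------------------------------------------
# GenotypeTable
# ---------------------------------------------------------------------------

#' Construct a diploid genotype table
#'
#' A `genotype_table` stores unordered diploid allele calls for a set of
#' individuals at a set of loci.  Allele labels are positive integers
#' (typically fragment sizes) treated as opaque categories.  A call is either
#' fully present (two alleles) or fully missing; the two allele matrices are
#' stored with the smaller allele first.
#'
#' @param ids character vector of unique individual identifiers.
#' @param loci character vector of locus names.
#' @param a1,a2 integer matrices (`length(ids)` x `length(loci)`) with the two
#'   alleles of each call; `NA` in both encodes a missing call.
#' @return An object of class `genotype_table` with elements `ids`, `loci`,
#'   `a1`, `a2`.
#' @examples
#' gt <- genotype_table(c("A", "B"), "L1",
#'                      matrix(c(120L, 120L), 2), matrix(c(124L, 120L), 2))
#' gt$a1  # smaller allele first
#' @export
genotype_table <- function(ids, loci, a1, a2) {
  ids <- as.character(ids)
  loci <- as.character(loci)
  a1 <- matrix(as.integer(a1), nrow = length(ids), ncol = length(loci))
  a2 <- matrix(as.integer(a2), nrow = length(ids), ncol = length(loci))
  if (anyDuplicated(ids))
    stop("duplicated individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)[1, ]
    stop(sprintf("half-missing call for individual '%s' at locus '%s'",
                 ids[idx[1]], loci[idx[2]]))
  }
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop("allele labels must be positive integers")
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  dimnames(lo) <- dimnames(hi) <- list(ids, loci)
  structure(list(ids = ids, loci = loci, a1 = lo, a2 = hi),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d loci (%d missing calls)\n",
              length(x$ids), length(x$loci), sum(is.na(x$a1))))
  invisible(x)
}

#' Number of typed (non-missing) calls per individual and completeness summary
#'
#' @param gt a [genotype_table()].
#' @return A list with `n_typed` (per-individual count of typed loci),
#'   `n_complete` (individuals typed at every locus), and `pct_complete`
#'   (percentage, 0-100).
#' @export
completeness_summary <- function(gt) {
  n_typed <- rowSums(!is.na(gt$a1))
  n_complete <- sum(n_typed == length(gt$loci))
  list(n_typed = setNames(n_typed, gt$ids),
       n_complete = n_complete,
       pct_complete = 100 * n_complete / length(gt$ids))
}

#' Read a diploid genotype table from CSV
#'
#' The file must have a header column `id` followed by two columns per locus
#' named `<locus>.1` and `<locus>.2`.  Missing calls are encoded as `0` or an
#' empty cell in both columns; a half-missing call is an error (it would
#' silently create a phantom allele).
#'
#' @param path path to a CSV file.
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "id") stop("first column must be named 'id'")
  cn <- names(df)[-1]
  if (length(cn) %% 2 != 0) stop("expected two allele columns per locus")
  loci1 <- sub("\\.1$", "", cn[seq(1, length(cn), 2)])
  loci2 <- sub("\\.2$", "", cn[seq(2, length(cn), 2)])
  if (!identical(loci1, loci2) || any(!grepl("\\.1$", cn[seq(1, length(cn), 2)])))
    stop("allele columns must come in pairs '<locus>.1', '<locus>.2'")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicated individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  parse_col <- function(x) {
    x[x == "" | is.na(x)] <- "0"
    v <- suppressWarnings(as.integer(x))
    if (anyNA(v)) stop("non-integer allele label in genotype file")
    v[v == 0] <- NA_integer_
    v
  }
  a1 <- sapply(seq(2, ncol(df), 2), function(j) parse_col(df[[j]]))
  a2 <- sapply(seq(3, ncol(df), 2), function(j) parse_col(df[[j]]))
  a1 <- matrix(a1, nrow = length(ids))
  a2 <- matrix(a2, nrow = length(ids))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "half-missing call for individual '%s' at locus '%s' (one of two allele cells missing)",
      ids[idx[1]], loci1[idx[2]]))
  }
  genotype_table(ids, loci1, a1, a2)
}

#' Write a genotype table to CSV
#'
#' Inverse of [read_genotype_table()]; missing calls are written as `0,0`.
#'
#' @param gt a [genotype_table()].
#' @param path output path.
#' @export
write_genotype_table <- function(gt, path) {
  out <- data.frame(id = gt$ids, check.names = FALSE)
  for (j in seq_along(gt$loci)) {
    a1 <- gt$a1[, j]; a2 <- gt$a2[, j]
    a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
    out[[paste0(gt$loci[j], ".1")]] <- a1
    out[[paste0(gt$loci[j], ".2")]] <- a2
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Studbook
# ---------------------------------------------------------------------------

#' Construct a studbook
#'
#' A studbook is the genealogical registry of a managed population: one row
#' per individual with recorded sire and dam, sex, birth year and a living
#' flag.  Unknown parents are `NA`; founders have both parents unknown.
#'
#' @param id character vector of unique ids.
#' @param sire_id,dam_id character vectors; `NA` for unknown.
#' @param sex character, one of `"M"`, `"F"`, `"U"`.
#' @param birth_year integer or `NA`.
#' @param alive logical.
#' @return A `data.frame` of class `studbook`.
#' @export
studbook <- function(id, sire_id = NA, dam_id = NA, sex = "U",
                     birth_year = NA, alive = TRUE) {
  n <- length(id)
  df <- data.frame(id = as.character(id),
                   sire_id = rep_len(as.character(sire_id), n),
                   dam_id = rep_len(as.character(dam_id), n),
                   sex = rep_len(as.character(sex), n),
                   birth_year = rep_len(as.integer(birth_year), n),
                   alive = rep_len(as.logical(alive), n),
                   stringsAsFactors = FALSE)
  df$sire_id[df$sire_id %in% c("", "UNK")] <- NA
  df$dam_id[df$dam_id %in% c("", "UNK")] <- NA
  if (anyDuplicated(df$id))
    stop("duplicated id(s): ", paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (!all(df$sex %in% c("M", "F", "U"))) stop("sex must be M, F or U")
  self <- df$id == df$sire_id | df$id == df$dam_id
  if (any(self, na.rm = TRUE))
    stop("individual listed as its own parent: ",
         paste(df$id[which(self)], collapse = ", "))
  both <- !is.na(df$sire_id) & !is.na(df$dam_id) & df$sire_id == df$dam_id
  if (any(both))
    stop("sire and dam identical for: ", paste(df$id[both], collapse = ", "))
  # sex consistency of parent roles, where the parent is itself recorded
  sex_of <- setNames(df$sex, df$id)
  bad_sire <- !is.na(df$sire_id) & df$sire_id %in% df$id &
    sex_of[df$sire_id] == "F"
  bad_dam <- !is.na(df$dam_id) & df$dam_id %in% df$id &
    sex_of[df$dam_id] == "M"
  if (any(bad_sire, na.rm = TRUE))
    stop("sire with recorded sex F: ",
         paste(unique(df$sire_id[which(bad_sire)]), collapse = ", "))
  if (any(bad_dam, na.rm = TRUE))
    stop("dam with recorded sex M: ",
         paste(unique(df$dam_id[which(bad_dam)]), collapse = ", "))
  class(df) <- c("studbook", "data.frame")
  df
}

#' Read a studbook from CSV
#'
#' Columns: `id,sire_id,dam_id,sex,birth_year,alive`.  Unknown parents may be
#' encoded as an empty cell or `"UNK"`; both are normalised to `NA`.
#'
#' @param path path to a CSV file.
#' @return A [studbook()].
#' @export
read_studbook <- function(path) {
  df <- read.csv(path, colClasses = "character")
  need <- c("id", "sire_id", "dam_id", "sex", "birth_year", "alive")
  if (!all(need %in% names(df)))
    stop("studbook file must have columns: ", paste(need, collapse = ", "))
  by <- suppressWarnings(as.integer(df$birth_year))
  alive <- df$alive %in% c("1", "TRUE", "true", "T")
  studbook(df$id, df$sire_id, df$dam_id, df$sex, by, alive)
}

#' Write a studbook to CSV
#'
#' @param sb a [studbook()].
#' @param path output path.
#' @export
write_studbook <- function(sb, path) {
  out <- as.data.frame(sb)
  out$sire_id[is.na(out$sire_id)] <- ""
  out$dam_id[is.na(out$dam_id)] <- ""
  out$alive <- as.integer(out$alive)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SequencePanel
# ---------------------------------------------------------------------------

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

#' Construct an aligned sequence panel
#'
#' Holds equal-length aligned haplotype sequences plus per-individual
#' assignments: a single label for a haploid marker (mtDNA) or an unordered
#' label pair for a diploid marker (MHC haplotypes).
#'
#' @param sequences named character vector of aligned DNA sequences
#'   (uppercased on input).
#' @param assignments optional named list: each element a single haplotype
#'   label or a character vector of two labels.
#' @return An object of class `seq_panel` with elements `sequences`, `length`
#'   and `assignments`.
#' @export
seq_panel <- function(sequences, assignments = NULL) {
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be named")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1) {
    bad <- names(sequences)[lens != lens[1]][1]
    stop(sprintf("sequence '%s' has length %d, expected %d",
                 bad, nchar(sequences[bad]), lens[1]))
  }
  chars <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  bad <- setdiff(chars, IUPAC_CHARS)
  if (length(bad))
    stop("non-IUPAC character(s) in sequences: ", paste(bad, collapse = ", "))
  if (!is.null(assignments)) {
    labs <- unique(unlist(assignments))
    missing <- setdiff(labs, names(sequences))
    if (length(missing))
      stop("assignment label(s) absent from panel: ",
           paste(missing, collapse = ", "))
  }
  structure(list(sequences = sequences, length = unname(lens[1]),
                 assignments = assignments),
            class = "seq_panel")
}

#' Read an aligned FASTA file into a sequence panel
#'
#' Sequences must be pre-aligned (equal length).  Labels are taken from the
#' first whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file.
#' @param assignments optional assignments, as in [seq_panel()].
#' @return A [seq_panel()].
#' @export
read_fasta <- function(path, assignments = NULL) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  names(seqs) <- vapply(strsplit(names(dna), "\\s+"), `[`, character(1), 1)
  seq_panel(seqs, assignments)
}

#' Write a sequence panel to FASTA
#'
#' @param panel a [seq_panel()].
#' @param path output path.
#' @export
write_fasta <- function(panel, path) {
  dna <- ape::as.DNAbin(strsplit(tolower(panel$sequences), ""))
  ape::write.FASTA(dna, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# AnalysisConfig
# ---------------------------------------------------------------------------

#' Analysis configuration
#'
#' Central container for the tunable settings shared across pipeline stages.
#'
#' @param p_crit minimum allele frequency admitted into the LD effective-size
#'   computation (default 0.006, appropriate when rare alleles reflect
#'   genotyping dropout in a sample of ~100 diploids).
#' @param mating_system `"random"` or `"monogamous"`; used by the LD
#'   effective-size estimator.
#' @param error_rate per-locus genotyping error rate \eqn{\epsilon} used in
#'   parentage likelihoods (default 0.01).
#' @param n_randomizations Monte-Carlo replicates for permutation tests and
#'   relatedness confidence sets (default 10000).
#' @param rng_seed integer seed for all randomized operations (default 1).
#' @param rarefaction_size even number of gene copies for allelic-richness
#'   rarefaction, or `"auto"` (twice the minimum number of typed individuals
#'   over loci).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(p_crit = 0.006, mating_system = "random",
                            error_rate = 0.01, n_randomizations = 10000,
                            rng_seed = 1, rarefaction_size = "auto") {
  stopifnot(p_crit >= 0, p_crit <= 1,
            mating_system %in% c("random", "monogamous"),
            error_rate >= 0, error_rate < 1,
            n_randomizations >= 1)
  if (!identical(rarefaction_size, "auto"))
    stopifnot(rarefaction_size > 0, rarefaction_size %% 2 == 0)
  structure(list(p_crit = p_crit, mating_system = mating_system,
                 error_rate = error_rate,
                 n_randomizations = as.integer(n_randomizations),
                 rng_seed = as.integer(rng_seed),
                 rarefaction_size = rarefaction_size),
            class = "analysis_config")
}
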