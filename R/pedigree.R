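# Studbook graph construction, kinship recursion, dyad-category
# classification, and the genetics-vs-studbook consistency engine.

#' Build a pedigree from studbook records
#'
#' Verifies acyclicity, assigns a topological generation depth to each
#' individual (founders at 0), and creates external-parent placeholders
#' (with a warning) for parents referenced but not recorded.
#'
#' @param records a [studbook()].
#' @return An object of class `pedigree` with `records` (augmented
#'   studbook), `depth` (named integer vector) and `founders`.
#' @export
build_pedigree <- function(records) {
  df <- as.data.frame(records)
  refs <- setdiff(stats::na.omit(c(df$sire_id, df$dam_id)), df$id)
  if (length(refs)) {
    warning("creating external-parent placeholder(s): ",
            paste(refs, collapse = ", "))
    ext <- data.frame(id = refs, sire_id = NA_character_,
                      dam_id = NA_character_, sex = "U",
                      birth_year = NA_integer_, alive = FALSE,
                      stringsAsFactors = FALSE)
    df <- rbind(df, ext)
  }
  n <- nrow(df)
  idx <- setNames(seq_len(n), df$id)
  parents <- cbind(idx[df$sire_id], idx[df$dam_id])

  depth <- rep(NA_integer_, n)
  state <- integer(n)  # 0 unvisited, 1 in progress, 2 done
  depth_of <- function(i, path = character(0)) {
    if (state[i] == 2L) return(depth[i])
    if (state[i] == 1L)
      stop("pedigree cycle detected involving: ",
           paste(c(path, df$id[i]), collapse = " -> "))
    state[i] <<- 1L
    ps <- parents[i, ]
    ps <- ps[!is.na(ps)]
    d <- if (length(ps) == 0) 0L
         else max(vapply(ps, depth_of, integer(1),
                         path = c(path, df$id[i]))) + 1L
    depth[i] <<- d
    state[i] <<- 2L
    d
  }
  for (i in seq_len(n)) depth_of(i)
  founders <- df$id[is.na(df$sire_id) & is.na(df$dam_id)]
  structure(list(records = df, depth = setNames(depth, df$id),
                 founders = founders),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals (%d founders, max depth %d)\n",
              nrow(x$records), length(x$founders), max(x$depth)))
  invisible(x)
}

parent_ids <- function(ped, id) {
  r <- ped$records[match(id, ped$records$id), ]
  c(sire = r$sire_id, dam = r$dam_id)
}

#' Pedigree kinship coefficient
#'
#' Recursive kinship under the studbook convention that founders are
#' mutually unrelated and non-inbred: `f(i,i) = 0.5 (1 + f(sire_i, dam_i))`,
#' `f(i,j) = 0.5 (f(sire_i, j) + f(dam_i, j))` recursing on the
#' later-generation member; an unknown parent contributes 0.  The expected
#' relatedness of a dyad is `r = 2 f`.
#'
#' @param ped a [pedigree()].
#' @param i,j individual ids.
#' @return Kinship coefficient in [0, 1].
#' @export
kinship <- function(ped, i, j) {
  K <- kinship_matrix(ped)
  K[i, j]
}

#' Full kinship matrix for a pedigree
#'
#' @param ped a [pedigree()].
#' @return A symmetric matrix of kinship coefficients, ids as dimnames.
#' @export
kinship_matrix <- function(ped) {
  df <- ped$records
  ord <- order(ped$depth[df$id])
  ids <- df$id[ord]
  n <- length(ids)
  sire <- match(df$sire_id[ord], ids)
  dam <- match(df$dam_id[ord], ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) {
    fs <- if (!is.na(sire[a]) && !is.na(dam[a])) K[sire[a], dam[a]] else 0
    K[a, a] <- 0.5 * (1 + fs)
    if (a > 1) {
      for (b in seq_len(a - 1)) {
        v <- 0
        if (!is.na(sire[a])) v <- v + K[sire[a], b]
        if (!is.na(dam[a])) v <- v + K[dam[a], b]
        K[a, b] <- K[b, a] <- 0.5 * v
      }
    }
  }
  K
}

#' Inbreeding coefficient of an individual
#'
#' The kinship of the recorded parents (0 when either is unknown).
#'
#' @param ped a [pedigree()].
#' @param id individual id.
#' @return Inbreeding coefficient F.
#' @export
inbreeding <- function(ped, id) {
  ps <- parent_ids(ped, id)
  if (anyNA(ps)) return(0)
  kinship(ped, ps[["sire"]], ps[["dam"]])
}

is_sib <- function(ped, a, b) {
  pa <- parent_ids(ped, a); pb <- parent_ids(ped, b)
  shared <- sum(!is.na(pa) & !is.na(pb) & pa == pb)
  full <- shared == 2
  half <- !full && any(stats::na.omit(pa) %in% stats::na.omit(pb))
  c(full = full, half = half)
}

#' Classify a dyad's studbook relationship
#'
#' Deterministic classification into parent-offspring (PO), full siblings
#' (FS), half-siblings (HS), grandparental (GP), avuncular (AV: one is a
#' full or half sibling of the other's parent), first cousins (FC:
#' respective parents are siblings) or unrelated (U).  When several
#' categories apply, the one with the highest expected relatedness wins
#' (PO, FS > HS, GP, AV > FC).
#'
#' @param ped a [pedigree()].
#' @param i,j distinct individual ids.
#' @return A character scalar.
#' @export
classify_dyad <- function(ped, i, j) {
  stopifnot(i != j)
  pi_ <- parent_ids(ped, i); pj <- parent_ids(ped, j)
  if (i %in% pj || j %in% pi_) return("PO")
  sib <- is_sib(ped, i, j)
  if (sib[["full"]]) return("FS")
  if (sib[["half"]]) return("HS")
  # grandparent: i is a parent of a parent of j, or vice versa
  gp_of <- function(x, y) {
    py <- stats::na.omit(parent_ids(ped, y))
    any(vapply(py, function(p) x %in% stats::na.omit(parent_ids(ped, p)),
               logical(1)))
  }
  if (gp_of(i, j) || gp_of(j, i)) return("GP")
  # avuncular: i is a (full or half) sibling of a parent of j, or vice versa
  av_of <- function(x, y) {
    py <- stats::na.omit(parent_ids(ped, y))
    any(vapply(py, function(p) any(is_sib(ped, x, p)), logical(1)))
  }
  if (av_of(i, j) || av_of(j, i)) return("AV")
  # first cousins: a parent of i is a sibling of a parent of j
  for (p1 in stats::na.omit(pi_)) for (p2 in stats::na.omit(pj)) {
    if (p1 != p2 && any(is_sib(ped, p1, p2))) return("FC")
  }
  "U"
}

#' Genetics-versus-studbook consistency report
#'
#' Compares the genetic best category of each assessed dyad with its
#' studbook classification.  Marker-based classification cannot separate
#' grandparental, avuncular or first-cousin relationships from half-sib or
#' unrelated, so studbook GP/AV/FC is considered consistent with genetic HS
#' or U; PO, FS, HS and U must match exactly.  Dyads with `r_hat > 0.6` are
#' flagged as unexpectedly highly related.
#'
#' @param ped a [pedigree()].
#' @param genetic data.frame with columns `id1`, `id2`, `best_category`,
#'   `r_hat` (one row per assessed dyad).
#' @return A list of class `consistency_report` with `dyads` (per-dyad
#'   table) and `summary` (n assessed, n consistent, consistent fraction,
#'   count with r_hat > 0.6, n dyads lacking a genetic result).
#' @export
consistency_report <- function(ped, genetic) {
  need <- c("id1", "id2", "best_category", "r_hat")
  stopifnot(all(need %in% names(genetic)))
  sb_cat <- vapply(seq_len(nrow(genetic)), function(q)
    classify_dyad(ped, genetic$id1[q], genetic$id2[q]), character(1))
  consistent <- ifelse(
    sb_cat %in% c("PO", "FS", "HS", "U"),
    sb_cat == genetic$best_category,
    genetic$best_category %in% c("HS", "U"))
  dyads <- data.frame(id1 = genetic$id1, id2 = genetic$id2,
                      studbook_category = sb_cat,
                      genetic_category = genetic$best_category,
                      consistent = consistent,
                      r_hat = genetic$r_hat,
                      flag_high_r = genetic$r_hat > 0.6,
                      stringsAsFactors = FALSE)
  ids <- intersect(ped$records$id, unique(c(genetic$id1, genetic$id2)))
  n_possible <- choose(length(ids), 2)
  structure(list(
    dyads = dyads,
    summary = list(n_assessed = nrow(dyads),
                   n_consistent = sum(consistent),
                   consistent_fraction = mean(consistent),
                   pct_consistent = 100 * mean(consistent),
                   n_high_r = sum(dyads$flag_high_r),
                   n_missing = n_possible - nrow(dyads))),
    class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "consistency_report: %d dyads assessed, %d consistent (%.1f%%), %d with r > 0.6\n",
    s$n_assessed, s$n_consistent, s$pct_consistent, s$n_high_r))
  invisible(x)
}

#' Overlay haplotype markers on a pedigree and flag transmission violations
#'
#' Annotates each individual with its mtDNA haplotype and MHC haplotype pair
#' and flags (i) offspring whose mtDNA haplotype differs from the dam's
#' (both typed) and (ii) trios failing the MHC transmission check.
#'
#' @param ped a [pedigree()].
#' @param mt optional named character vector of mtDNA haplotype labels.
#' @param mhc optional named list of MHC haplotype pairs.
#' @return A list with `table` (annotated pedigree data.frame) and
#'   `violations` (data.frame: id, marker, detail).
#' @export
overlay_markers <- function(ped, mt = NULL, mhc = NULL) {
  df <- ped$records
  tab <- data.frame(id = df$id, sire_id = df$sire_id, dam_id = df$dam_id,
                    depth = ped$depth[df$id],
                    mt = if (is.null(mt)) NA_character_ else
                      unname(mt[df$id]),
                    mhc1 = NA_character_, mhc2 = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(mhc)) {
    for (q in seq_len(nrow(tab))) {
      p <- mhc[[tab$id[q]]]
      if (!is.null(p)) { tab$mhc1[q] <- p[1]; tab$mhc2[q] <- p[2] }
    }
  }
  viol <- list()
  for (q in seq_len(nrow(df))) {
    id <- df$id[q]; dam <- df$dam_id[q]; sire <- df$sire_id[q]
    if (!is.null(mt) && !is.na(dam) &&
        id %in% names(mt) && dam %in% names(mt) &&
        !is.na(mt[[id]]) && !is.na(mt[[dam]]) && mt[[id]] != mt[[dam]]) {
      viol[[length(viol) + 1]] <- data.frame(
        id = id, marker = "mtDNA",
        detail = sprintf("offspring %s but dam %s carries %s",
                         mt[[id]], dam, mt[[dam]]),
        stringsAsFactors = FALSE)
    }
    if (!is.null(mhc) && !is.null(mhc[[id]])) {
      dp <- if (!is.na(dam)) mhc[[dam]] else NULL
      sp <- if (!is.na(sire)) mhc[[sire]] else NULL
      if ((!is.null(dp) || !is.null(sp)) &&
          !mhc_trio_check(mhc[[id]], dam = dp, sire = sp)$consistent) {
        viol[[length(viol) + 1]] <- data.frame(
          id = id, marker = "MHC",
          detail = "offspring haplotype pair impossible given recorded parents",
          stringsAsFactors = FALSE)
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(id = character(0), marker = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  list(table = tab, violations = violations)
}
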