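## Therapy-set algebra: combined target groups, parameter pairs, repeat
## detection, the five diversity features (DTG, STG, DMP, SMP, DPD), a
## composite score, and factorial design-space sizing.

#' Default therapy taxonomy
#'
#' The taxonomy bundles (i) the target-group map -- which therapy parameters
#' each mechanism class of anticancer agents can control: A new-vessel
#' formation (no delegated parameter), B progrowth signal amplification
#' (`p01`, `p02`), C progrowth signal transmission (`age`), D DNA
#' replication (`p01`, `p02`, `Nmm`), E cell-cycle activation (`p01`,
#' `p02`); (ii) the mechanism class of each parameter (`age` acts by
#' delaying the progrowth signal; `p01`, `p02`, `Nmm` act on division); and
#' (iii) each parameter's physical dimension (`age` is a time in
#' iterations; the others are probabilities).
#'
#' @return List with fields `groups`, `mechanism`, `dimension`,
#'   `descriptions`.
#' @export
default_taxonomy <- function() {
  list(
    groups = list(
      A = character(0),
      B = c("p01", "p02"),
      C = "age",
      D = c("p01", "p02", "Nmm"),
      E = c("p01", "p02")),
    mechanism = c(p01 = "division", p02 = "division", Nmm = "division",
                  age = "signal-delay"),
    dimension = c(p01 = "probability", p02 = "probability",
                  Nmm = "probability", age = "time"),
    descriptions = c(
      A = "new vessel formation",
      B = "progrowth signal amplification",
      C = "progrowth signal transmission",
      D = "DNA replication",
      E = "cell cycle activation"))
}

pair_label <- function(x, y) paste(sort(c(x, y)), collapse = "+")

#' Parameter pairs available to a pair of target groups
#'
#' All unordered pairs `(x, y)` with `x` drawn from the first group's
#' parameter set, `y` from the second's, and `x != y`, deduplicated and in
#' a fixed deterministic order (taxonomy order of the first member, then of
#' the second).
#'
#' @param group_pair character vector of two distinct group letters.
#' @param taxonomy a [default_taxonomy()] list.
#' @return `data.frame` with columns `param1`, `param2`.
#' @export
parameter_pairs_for <- function(group_pair, taxonomy = default_taxonomy()) {
  stopifnot(length(group_pair) == 2L, group_pair[1L] != group_pair[2L])
  px <- taxonomy$groups[[group_pair[1L]]]
  py <- taxonomy$groups[[group_pair[2L]]]
  out <- data.frame(param1 = character(0), param2 = character(0))
  seen <- character(0)
  for (x in px) {
    for (y in py) {
      if (x == y) next
      key <- pair_label(x, y)
      if (key %in% seen) next
      seen <- c(seen, key)
      out <- rbind(out, data.frame(param1 = x, param2 = y))
    }
  }
  out
}

#' Enumerate combined target groups and tag repeats
#'
#' Forms all unordered pairs of distinct target groups (groups with empty
#' parameter sets are excluded), lists each pair's parameter pairs, and
#' tags a group pair as a repeat when its parameter-pair set equals or is
#' contained in that of an earlier pair (pairs are visited in alphabetical
#' group order).
#'
#' @param groups character vector of group letters to consider.
#' @inheritParams parameter_pairs_for
#' @return `data.frame` with columns `group1`, `group2`, `n_pairs`,
#'   `pairs` (comma-separated labels), `repeated`, `repeat_of`.
#' @export
enumerate_group_pairs <- function(groups = c("A", "B", "C", "D", "E"),
                                  taxonomy = default_taxonomy()) {
  stopifnot(length(groups) > 0L)
  groups <- sort(intersect(groups, names(taxonomy$groups)))
  groups <- groups[vapply(taxonomy$groups[groups], length, integer(1)) > 0L]
  if (length(groups) < 2L)
    return(data.frame(group1 = character(0), group2 = character(0),
                      n_pairs = integer(0), pairs = character(0),
                      repeated = logical(0), repeat_of = character(0)))
  combos <- utils::combn(groups, 2L)
  rows <- vector("list", ncol(combos))
  pair_sets <- vector("list", ncol(combos))
  for (i in seq_len(ncol(combos))) {
    gp <- combos[, i]
    pp <- parameter_pairs_for(gp, taxonomy)
    labels <- if (nrow(pp)) mapply(pair_label, pp$param1, pp$param2)
              else character(0)
    pair_sets[[i]] <- labels
    repeat_of <- NA_character_
    if (length(labels) > 0L && i > 1L) {
      for (j in seq_len(i - 1L)) {
        if (length(pair_sets[[j]]) > 0L &&
            all(labels %in% pair_sets[[j]])) {
          repeat_of <- paste0(combos[1L, j], combos[2L, j])
          break
        }
      }
    }
    rows[[i]] <- data.frame(
      group1 = gp[1L], group2 = gp[2L], n_pairs = length(labels),
      pairs = paste(labels, collapse = ", "),
      repeated = !is.na(repeat_of), repeat_of = repeat_of)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diversity features of one therapy parameter pair
#'
#' For a pair of players `(x, y)` fielded by the combined target group
#' `(X, Y)`: `STG` counts players belonging to both X and Y (shared
#' players), `DTG = players - STG` (players exclusive to one group); `DMP`
#' counts distinct action-mechanism classes among the players,
#' `SMP = players - DMP`; `DPD` is the number of distinct physical
#' dimensions when more than one is present, else 0.
#'
#' @param pair character vector of two therapy parameters.
#' @param group_pair character vector of the two group letters that field
#'   the pair.
#' @inheritParams parameter_pairs_for
#' @return List of class `absm_features` with fields `DTG`, `STG`, `DMP`,
#'   `SMP`, `DPD`.
#' @export
score_features <- function(pair, group_pair, taxonomy = default_taxonomy()) {
  stopifnot(length(pair) == 2L, length(group_pair) == 2L)
  valid <- parameter_pairs_for(group_pair, taxonomy)
  labels <- if (nrow(valid)) mapply(pair_label, valid$param1, valid$param2)
            else character(0)
  if (!pair_label(pair[1L], pair[2L]) %in% labels)
    stop("pair (", pair[1L], ", ", pair[2L], ") is not fielded by group pair ",
         group_pair[1L], group_pair[2L])
  shared <- vapply(pair, function(p)
    all(group_pair %in% group_for_parameter(p, taxonomy)), logical(1))
  STG <- sum(shared)
  DTG <- length(pair) - STG
  DMP <- length(unique(taxonomy$mechanism[pair]))
  SMP <- length(pair) - DMP
  ndim <- length(unique(taxonomy$dimension[pair]))
  DPD <- if (ndim > 1L) ndim else 0L
  structure(list(DTG = as.integer(DTG), STG = as.integer(STG),
                 DMP = as.integer(DMP), SMP = as.integer(SMP),
                 DPD = as.integer(DPD)),
            class = "absm_features")
}

#' @export
print.absm_features <- function(x, ...) {
  cat(sprintf("DTG %d, STG %d, DMP %d, SMP %d, DPD %d (composite %g)\n",
              x$DTG, x$STG, x$DMP, x$SMP, x$DPD, composite_score(x)))
  invisible(x)
}

#' Composite therapy score
#'
#' Signed weighted sum of the five features: diversity terms (DTG, DMP,
#' DPD) count positively, sameness terms (STG, SMP) negatively. The higher
#' the diversity terms and the lower the sameness terms, the better the
#' expected therapy.
#'
#' @param features an [score_features()] result (or any list with the five
#'   fields).
#' @param weights named non-negative weights for `DTG`, `DMP`, `DPD`,
#'   `STG`, `SMP`; defaults all 1.
#' @return Numeric score.
#' @export
composite_score <- function(features,
                            weights = c(DTG = 1, DMP = 1, DPD = 1,
                                        STG = 1, SMP = 1)) {
  w <- function(k) if (k %in% names(weights)) weights[[k]] else 1
  features$DTG * w("DTG") + features$DMP * w("DMP") +
    features$DPD * w("DPD") - features$STG * w("STG") -
    features$SMP * w("SMP")
}

#' Rank all candidate combination therapies
#'
#' Enumerates the non-repeated combined target groups, scores every
#' parameter pair with [score_features()], and orders them by composite
#' score (descending), breaking ties by `DPD`, `DMP`, `DTG` (descending)
#' and then by pair label.
#'
#' @inheritParams enumerate_group_pairs
#' @inheritParams composite_score
#' @return `data.frame` with columns `group_pair`, `param1`, `param2`,
#'   `DTG`, `STG`, `DMP`, `SMP`, `DPD`, `score`, ordered best first.
#' @export
rank_combinations <- function(groups = c("A", "B", "C", "D", "E"),
                              taxonomy = default_taxonomy(),
                              weights = c(DTG = 1, DMP = 1, DPD = 1,
                                          STG = 1, SMP = 1)) {
  enum <- enumerate_group_pairs(groups, taxonomy)
  enum <- enum[!enum$repeated & enum$n_pairs > 0L, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(enum))) {
    gp <- c(enum$group1[i], enum$group2[i])
    pp <- parameter_pairs_for(gp, taxonomy)
    for (j in seq_len(nrow(pp))) {
      pr <- c(pp$param1[j], pp$param2[j])
      fs <- score_features(pr, gp, taxonomy)
      rows[[length(rows) + 1L]] <- data.frame(
        group_pair = paste0(gp[1L], gp[2L]),
        param1 = pr[1L], param2 = pr[2L],
        DTG = fs$DTG, STG = fs$STG, DMP = fs$DMP, SMP = fs$SMP,
        DPD = fs$DPD, score = composite_score(fs, weights))
    }
  }
  out <- do.call(rbind, rows)
  label <- mapply(pair_label, out$param1, out$param2)
  ord <- order(-out$score, -out$DPD, -out$DMP, -out$DTG, label)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Size of a factorial combination-therapy design space
#'
#' Number of distinct regimens when each of `n_drugs` drugs can be given at
#' `n_levels` dose levels: `n_levels ^ n_drugs`. Screening 10 drugs at 3
#' doses already means 59049 combinations, the combinatorial wall the
#' feature ranking is designed to cut through.
#'
#' @param n_drugs,n_levels positive integers.
#' @return Exact count (integer when representable).
#' @export
design_space_size <- function(n_drugs, n_levels) {
  if (!is.numeric(n_drugs) || n_drugs < 1 || n_drugs != round(n_drugs) ||
      !is.numeric(n_levels) || n_levels < 1 || n_levels != round(n_levels))
    stop("n_drugs and n_levels must be positive integers")
  size <- n_levels^n_drugs
  if (size <= .Machine$integer.max) as.integer(size) else size
}
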