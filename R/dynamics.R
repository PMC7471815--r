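## Tumor state-transition rules: division, age- and rim-driven quiescence,
## nutrient-starvation necrosis, and the per-iteration tumor phase.

# Effective rim thickness threshold. The nutrient-limited layer thickness
# coeff * R_t^e vanishes as R_t -> 0, which on a lattice would quiesce a
# point-seeded tumor immediately; the outermost boundary shell (depth up to
# pitch*sqrt(2)) is therefore always exempt.
rim_threshold <- function(coeff, R_t, exponent, pitch) {
  max(coeff * R_t^exponent, pitch * sqrt(2))
}

#' Division probability of a proliferating cell
#'
#' For an `NA_1_1` cell: `p01 * max(0, 1 - R_t/R_max)` -- the base division
#' probability damped by the pressure response as the tumor approaches its
#' maximum extent. For an `NA_1_2` cell the division is additionally
#' modulated by its healthy neighbors:
#' `p02 * max(0, 1 - R_t/R_max) * n_NA0_neighbors / 8`. Always clamped to
#' `[0, 1]`.
#'
#' @inheritParams moore_neighbors
#' @param params an [model_params()] object.
#' @param R_t mean tumor radius in mm; computed from `tissue` when `NULL`.
#'   [tumor_step()] computes it once per iteration and passes it down.
#' @return Probability in `[0, 1]`.
#' @export
division_probability <- function(tissue, site, params, R_t = NULL) {
  site <- check_site(tissue, site)
  s <- tissue$states[site[1L], site[2L]]
  if (!is_proliferating(s))
    stop("division_probability: site (", site[1L], ",", site[2L],
         ") is not proliferating")
  if (is.null(R_t)) R_t <- tumor_geometry(tissue)$R_t
  pressure <- max(0, 1 - R_t / params$R_max)
  rho <- if (s == CELL_STATES[["NA_1_1"]]) {
    params$p01 * pressure
  } else {
    params$p02 * pressure *
      count_neighbor_states(tissue, site, "NA_0") / 8
  }
  min(max(rho, 0), 1)
}

#' Daughter cell types of an NA_1_1 mitosis
#'
#' With probability `Nmm` the mitosis yields one `NA_1_1` and one `NA_1_2`
#' daughter; otherwise two `NA_1_1` daughters. Consumes exactly one uniform
#' variate from the R RNG stream.
#'
#' @param Nmm probability in `[0, 1]`.
#' @return Integer vector `c(parent = , daughter = )` of [CELL_STATES]
#'   codes.
#' @export
daughter_types <- function(Nmm) {
  if (!is.numeric(Nmm) || length(Nmm) != 1L || is.na(Nmm) || Nmm < 0 || Nmm > 1)
    stop("Nmm must be a single probability in [0, 1]")
  if (runif(1) < Nmm) {
    c(parent = CELL_STATES[["NA_1_1"]], daughter = CELL_STATES[["NA_1_2"]])
  } else {
    c(parent = CELL_STATES[["NA_1_1"]], daughter = CELL_STATES[["NA_1_1"]])
  }
}

#' Attempt the division of one proliferating cell
#'
#' Draws one uniform against the cell's division probability. On success the
#' daughter is placed in a uniformly chosen `NA_0` Moore neighbor (the
#' attempt fails silently when none exists), daughter typing follows
#' [daughter_types()] for `NA_1_1` parents (an `NA_1_2` parent produces an
#' `NA_1_2` daughter without a draw), and both cells' age counters reset
#' to 0.
#'
#' RNG draw order: one uniform for the division decision; on success with
#' `k >= 1` free neighbors, one uniform for the placement; for `NA_1_1`
#' parents one further uniform for the daughter type.
#'
#' @inheritParams division_probability
#' @return List `(tissue, divided, daughter_site)`; `daughter_site` is
#'   `NULL` when no division happened.
#' @export
attempt_division <- function(tissue, site, params, R_t = NULL) {
  rho <- division_probability(tissue, site, params, R_t)
  if (runif(1) >= rho)
    return(list(tissue = tissue, divided = FALSE, daughter_site = NULL))
  nb <- moore_neighbors(tissue, site)
  free <- nb[tissue$states[nb] == CELL_STATES[["NA_0"]], , drop = FALSE]
  k <- nrow(free)
  if (k == 0L)
    return(list(tissue = tissue, divided = FALSE, daughter_site = NULL))
  d <- free[pick_one(k), ]
  s <- tissue$states[site[1L], site[2L]]
  if (s == CELL_STATES[["NA_1_1"]]) {
    types <- daughter_types(params$Nmm)
  } else {
    dt <- CELL_STATES[[params$na12_daughter]]
    types <- c(parent = s, daughter = dt)
  }
  tissue$states[site[1L], site[2L]] <- types[["parent"]]
  tissue$states[d[1L], d[2L]] <- types[["daughter"]]
  tissue$age[site[1L], site[2L]] <- 0L
  tissue$age[d[1L], d[2L]] <- 0L
  list(tissue = tissue, divided = TRUE, daughter_site = d)
}

#' Quiescence update: NA_1 cells leave the proliferating state
#'
#' An `NA_1` cell turns quiescent (`NA_2`) when (i) its age counter has
#' reached `age_max` (it exhausted its allowance of iterations without
#' dividing), or (ii) it sits deeper below the tumor edge than the
#' nutrient-limited proliferative rim thickness `b * R_t^rim_exponent`.
#' Age counters reset on transition. Deterministic (no RNG).
#'
#' @inheritParams division_probability
#' @return List `(tissue, changed)` where `changed` is the matrix of sites
#'   that turned `NA_2` (or `age_expiry_state` for the age rule).
#' @export
quiescence_update <- function(tissue, params, R_t = NULL) {
  if (is.null(R_t)) R_t <- tumor_geometry(tissue)$R_t
  delta_p <- rim_threshold(params$b, R_t, params$rim_exponent, tissue$pitch)
  prolif <- matrix(is_proliferating(tissue$states),
                   tissue$n_cell, tissue$n_cell)
  if (!any(prolif))
    return(list(tissue = tissue, changed = matrix(integer(0), 0L, 2L)))
  depth <- depth_map(tissue)
  over_age <- prolif & tissue$age >= params$age_max
  too_deep <- prolif & !is.na(depth) & depth > delta_p
  expiry <- CELL_STATES[[params$age_expiry_state]]
  tissue$states[over_age] <- expiry
  tissue$states[too_deep & !over_age] <- CELL_STATES[["NA_2"]]
  changed <- which(over_age | too_deep, arr.ind = TRUE)
  tissue$age[changed] <- 0L
  list(tissue = tissue, changed = changed)
}

#' Necrosis update: deep quiescent cells starve
#'
#' An `NA_2` cell becomes necrotic (`NA_3`) when it sits deeper below the
#' tumor edge than the nutrient-limited thickness `a * R_t^rim_exponent`.
#' Necrosis is absorbing: no rule ever removes an `NA_3` cell.
#' Deterministic (no RNG).
#'
#' @inheritParams division_probability
#' @return List `(tissue, changed)` with the sites that turned `NA_3`.
#' @export
necrosis_update <- function(tissue, params, R_t = NULL) {
  if (is.null(R_t)) R_t <- tumor_geometry(tissue)$R_t
  delta_n <- rim_threshold(params$a, R_t, params$rim_exponent, tissue$pitch)
  quies <- tissue$states == CELL_STATES[["NA_2"]]
  if (!any(quies))
    return(list(tissue = tissue, changed = matrix(integer(0), 0L, 2L)))
  depth <- depth_map(tissue)
  turn <- quies & !is.na(depth) & depth > delta_n
  tissue$states[turn] <- CELL_STATES[["NA_3"]]
  changed <- which(turn, arr.ind = TRUE)
  list(tissue = tissue, changed = changed)
}

#' One tumor-phase iteration
#'
#' Executes, in order: (1) age counters increment on the `NA_1` sites that
#' are deprived of the opportunity to proliferate -- those with no `NA_0`
#' Moore neighbor at the start of the iteration (the age counter tracks
#' time spent in the proliferating state without being able to divide, and
#' resets on division); (2) the `NA_1` sites present at the start of the
#' iteration are visited in a seeded random permutation (Fisher-Yates over
#' their column-major order) and [attempt_division()] is applied at each;
#' (3) [quiescence_update()]; (4) [necrosis_update()]. The mean tumor
#' radius `R_t` is computed once, before the divisions, and used by all
#' phases. The iteration counter `m` advances by exactly 1.
#'
#' @inheritParams division_probability
#' @return List `(tissue, events)` with `events = c(divisions, quiescences,
#'   necroses)`.
#' @export
tumor_step <- function(tissue, params) {
  R_t <- tumor_geometry(tissue)$R_t
  prolif <- is_proliferating(tissue$states)
  sites <- which(prolif)  # column-major linear indices, ascending
  n <- tissue$n_cell
  for (idx in sites) {
    site <- c(((idx - 1L) %% n) + 1L, ((idx - 1L) %/% n) + 1L)
    if (count_neighbor_states(tissue, site, "NA_0") == 0L)
      tissue$age[idx] <- tissue$age[idx] + 1L
  }
  divisions <- 0L
  if (length(sites) > 0L) {
    perm <- fy_permute(length(sites))
    n <- tissue$n_cell
    for (idx in sites[perm]) {
      site <- c(((idx - 1L) %% n) + 1L, ((idx - 1L) %/% n) + 1L)
      res <- attempt_division(tissue, site, params, R_t)
      tissue <- res$tissue
      divisions <- divisions + res$divided
    }
  }
  q <- quiescence_update(tissue, params, R_t)
  tissue <- q$tissue
  nx <- necrosis_update(tissue, params, R_t)
  tissue <- nx$tissue
  tissue$m <- tissue$m + 1L
  list(tissue = tissue,
       events = c(divisions = divisions,
                  quiescences = nrow(q$changed),
                  necroses = nrow(nx$changed)))
}
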