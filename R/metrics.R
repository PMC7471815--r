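#' Per-iteration tumor structure metrics
#'
#' Exact counts and fractions over the lattice: `n_T` tumorous cells
#' (proliferating + quiescent + necrotic), `n_PT` proliferating cells,
#' `PGF = n_T / n_cell^2` (pure tumor growth fraction, the tumor-size
#' measure), `GF = n_PT / n_T` (growth fraction, the aggressiveness
#' measure) and `NF = n_NA3 / n_T` (necrotic fraction, the
#' therapy-effectiveness measure), plus the geometry `R_t`, `R_n`, `W_p`
#' and the immune ledger. When the tumor is empty, `GF` and `NF` are
#' reported as 0 with `empty_tumor = TRUE` so that time-series output stays
#' rectangular.
#'
#' @param tissue an [new_tissue()] lattice.
#' @param geometry if `FALSE`, skip the radii (reported as `NA`); counting
#'   only.
#' @return One-row `data.frame` (a `MetricsRecord`): `m`, `n_T`, `n_PT`,
#'   `n_NA1_1`, `n_NA1_2`, `n_NA2`, `n_NA3`, `PGF`, `GF`, `NF`, `R_t`,
#'   `R_n`, `W_p`, `n_IA`, `n_BI`, `v`, `f`, `empty_tumor`.
#' @export
compute_metrics <- function(tissue, geometry = TRUE) {
  counts <- state_counts(tissue)
  n_T <- sum(counts[c("NA_1_1", "NA_1_2", "NA_2", "NA_3")])
  n_PT <- sum(counts[c("NA_1_1", "NA_1_2")])
  empty <- n_T == 0L
  geo <- if (geometry) tumor_geometry(tissue) else
    list(R_t = NA_real_, R_n = NA_real_, W_p = NA_real_)
  data.frame(
    m = tissue$m,
    n_T = n_T, n_PT = n_PT,
    n_NA1_1 = counts[["NA_1_1"]], n_NA1_2 = counts[["NA_1_2"]],
    n_NA2 = counts[["NA_2"]], n_NA3 = counts[["NA_3"]],
    PGF = n_T / tissue$n_cell^2,
    GF = if (empty) 0 else n_PT / n_T,
    NF = if (empty) 0 else counts[["NA_3"]] / n_T,
    R_t = geo$R_t, R_n = geo$R_n, W_p = geo$W_p,
    n_IA = sum(tissue$immune != IMMUNE_STATES[["IA_NONE"]]),
    n_BI = tissue$ledger$n_BI, v = tissue$ledger$v, f = tissue$ledger$f,
    empty_tumor = empty,
    row.names = NULL)
}

#' Critical point of a simulated trajectory
#'
#' The first iteration at which the proliferating population no longer
#' exceeds the necrotic one (`n_PT <= n_NA3`, both positive) -- the point
#' where the necrotic core overtakes the proliferating rim and the
#' proliferating population stops growing.
#'
#' @param series metrics `data.frame` as returned by [simulate_absm()]
#'   (one [compute_metrics()] row per iteration).
#' @return The iteration index `m`, or `NA` if the crossing never happens.
#' @export
critical_point <- function(series) {
  stopifnot(nrow(series) > 0L)
  hit <- which(series$n_PT <= series$n_NA3 &
               series$n_PT > 0L & series$n_NA3 > 0L)
  if (length(hit) == 0L) NA_integer_ else series$m[hit[1L]]
}

#' Metrics record at a given model day
#'
#' Maps a day to an iteration via `round(day * iterations_per_day)` and
#' returns that record.
#'
#' @inheritParams critical_point
#' @param day non-negative model day.
#' @param params an [model_params()] object supplying
#'   `iterations_per_day`.
#' @return One metrics row.
#' @export
day_snapshot <- function(series, day, params) {
  stopifnot(day >= 0)
  m_target <- as.integer(round(day * params$iterations_per_day))
  hit <- which(series$m == m_target)
  if (length(hit) == 0L)
    stop("series has no record at iteration ", m_target,
         " (day ", day, " at ", params$iterations_per_day,
         " iterations/day); simulate at least that many iterations")
  series[hit[1L], , drop = FALSE]
}
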