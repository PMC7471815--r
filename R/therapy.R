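## Virtual-patient profiles, High/Medium/Low dose -> parameter mapping, and
## the 3x3 dose-grid in silico combination-therapy experiment.

THERAPY_PARAMS <- c("p01", "p02", "Nmm", "age")

# "age" is the therapy-facing name of the model parameter age_max
therapy_field <- function(parameter) {
  if (parameter == "age") "age_max" else parameter
}

#' Virtual-patient profile
#'
#' A patient is characterized by baseline values of the four
#' therapy-relevant parameters -- `p01`, `p02`, `Nmm`, `age` -- their
#' "personalized genetics", plus fixed physiology (`a`, `b`, `R_max`,
#' `K_dT`, `K_dI`, `rho_t`, `rho_I`, immune settings). The default is the
#' reference patient used in all shipped dose-grid experiments:
#' `p01 = 0.7`, `p02 = 0.5`, `Nmm = 0.2`, `age = 1`.
#'
#' @param p01,p02,Nmm,age baseline values of the therapy-relevant
#'   parameters.
#' @param ... further [model_params()] fields (physiology, immune and time
#'   settings).
#' @return An `absm_patient` object (an [model_params()] object with an
#'   extra class).
#' @export
patient_profile <- function(p01 = 0.7, p02 = 0.5, Nmm = 0.2, age = 1L, ...) {
  p <- model_params(p01 = p01, p02 = p02, Nmm = Nmm, age_max = age, ...)
  class(p) <- c("absm_patient", class(p))
  p
}

#' Default High/Medium/Low dose table
#'
#' The dose value table used by the in silico experiments: per therapy
#' parameter, the parameter value selected by a qualitative High, Medium or
#' Low dose.
#'
#' @return `data.frame` with columns `parameter`, `H`, `M`, `L`.
#' @export
default_dose_table <- function() {
  data.frame(
    parameter = c("p01", "p02", "age", "Nmm"),
    H = c(0.81, 0.75, 9, 0.82),
    M = c(0.52, 0.42, 4, 0.38),
    L = c(0.23, 0.26, 1, 0.12))
}

dose_value <- function(table, parameter, level) {
  row <- match(parameter, table$parameter)
  if (is.na(row))
    stop("unknown therapy parameter: '", parameter,
         "' (expected one of ", paste(table$parameter, collapse = ", "), ")")
  if (!level %in% c("H", "M", "L"))
    stop("unknown dose level: '", level, "' (expected H, M or L)")
  table[[level]][row]
}

#' Apply one dose to a patient profile
#'
#' Returns a full parameter set equal to the profile except that the named
#' therapy parameter is replaced by the dose-table value for the given
#' level. The profile itself is never mutated; applying doses to distinct
#' parameters commutes.
#'
#' @param profile an [patient_profile()].
#' @param parameter one of `"p01"`, `"p02"`, `"Nmm"`, `"age"`.
#' @param level `"H"`, `"M"` or `"L"`.
#' @param table dose table as from [default_dose_table()].
#' @return An [model_params()] object.
#' @export
apply_dose <- function(profile, parameter, level,
                       table = default_dose_table()) {
  stopifnot(inherits(profile, "absm_params"))
  value <- dose_value(table, parameter, level)
  p <- unclass(profile)
  p[[therapy_field(parameter)]] <- if (parameter == "age")
    as.integer(value) else value
  out <- validate_params(p)
  class(out) <- "absm_params"
  out
}

#' Map a parameter value onto the unit dose interval
#'
#' Linearly rescales a parameter value onto `[0, 1]` using the dose table's
#' Low -> 0 and High -> 1 anchors, the normalized representation of the
#' Low..High dose span. Values outside the span are clipped with a warning.
#'
#' @param value parameter value to rescale.
#' @inheritParams apply_dose
#' @return Number in `[0, 1]`.
#' @export
dose_to_unit <- function(value, parameter, table = default_dose_table()) {
  lo <- dose_value(table, parameter, "L")
  hi <- dose_value(table, parameter, "H")
  span <- range(c(lo, hi))
  if (value < span[1L] || value > span[2L]) {
    warning("value ", value, " outside the [L, H] span of '", parameter,
            "'; clipped")
    value <- min(max(value, span[1L]), span[2L])
  }
  (value - lo) / (hi - lo)
}

#' Target groups controlled by a therapy parameter
#'
#' The target-group taxonomy maps therapy mechanism classes to parameters:
#' B (progrowth signal amplification) and E (cell-cycle activation) carry
#' `p01` and `p02`; C (progrowth signal transmission) carries `age`; D
#' (DNA replication) carries `p01`, `p02` and `Nmm`. Group A (new vessel
#' formation) has no delegated parameter.
#'
#' @inheritParams apply_dose
#' @param taxonomy a [default_taxonomy()] list.
#' @return Character vector of group letters.
#' @export
group_for_parameter <- function(parameter, taxonomy = default_taxonomy()) {
  if (!parameter %in% THERAPY_PARAMS)
    stop("unknown therapy parameter: '", parameter, "'")
  groups <- names(taxonomy$groups)
  groups[vapply(taxonomy$groups, function(g) parameter %in% g, logical(1))]
}

#' Dose-grid combination-therapy experiment
#'
#' Runs the full simulation (tumor phase + immune phase per iteration) from
#' the standard point-seed initial condition for every combination of dose
#' levels (H, M, L) of a pair of therapy parameters, for `n_reps`
#' replicates per combination, and summarizes the tumor structure (PGF, GF,
#' NF) at the snapshot day. One child seed per replicate is drawn from the
#' root seed and shared by all 9 cells (common random numbers), so the grid
#' is reproducible from `(seed, n_reps)`, cell contrasts are not blurred by
#' between-stream noise, and a zero-effect dose table yields 9 identical
#' cells.
#'
#' @inheritParams apply_dose
#' @param pair character vector of two distinct therapy parameters, e.g.
#'   `c("p01", "age")`.
#' @param sim_config list with `n_cell`, `pitch`, `day` (snapshot day) --
#'   defaults 100, 0.1 mm, day 12. Iterations are
#'   `round(day * iterations_per_day)` with `iterations_per_day` from the
#'   profile.
#' @param n_reps replicates per grid cell.
#' @param seed root seed for the grid.
#' @return An `absm_dose_grid` object: list with `pair`, `levels` (the
#'   literal dose values), a 9-row summary `data.frame` (mean and sd of
#'   PGF/GF/NF per cell), the per-replicate records, and the run
#'   configuration.
#' @export
run_dose_grid <- function(profile, pair, table = default_dose_table(),
                          sim_config = list(), n_reps = 20, seed = 1L) {
  stopifnot(length(pair) == 2L, n_reps >= 1)
  if (pair[1L] == pair[2L])
    stop("dose-grid parameters must be distinct, got '", pair[1L],
         "' twice")
  cfg <- modifyList(list(n_cell = 100L, pitch = 0.1, day = 12), sim_config)
  n_steps <- as.integer(round(cfg$day * profile$iterations_per_day))

  levels <- c("H", "M", "L")
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, n_reps)

  reps <- vector("list", 9L)
  summary_rows <- vector("list", 9L)
  cell <- 0L
  for (l1 in levels) {
    for (l2 in levels) {
      cell <- cell + 1L
      params <- apply_dose(profile, pair[1L], l1, table)
      params <- apply_dose(params, pair[2L], l2, table)
      class(params) <- "absm_params"
      runs <- vector("list", n_reps)
      for (r in seq_len(n_reps)) {
        sim <- simulate_absm(params, n_steps = n_steps,
                             n_cell = cfg$n_cell, pitch = cfg$pitch,
                             seed = child_seeds[r])
        snap <- day_snapshot(sim$metrics, cfg$day, params)
        runs[[r]] <- cbind(data.frame(level1 = l1, level2 = l2, rep = r),
                           snap)
      }
      runs <- do.call(rbind, runs)
      reps[[cell]] <- runs
      summary_rows[[cell]] <- data.frame(
        level1 = l1, value1 = dose_value(table, pair[1L], l1),
        level2 = l2, value2 = dose_value(table, pair[2L], l2),
        PGF = mean(runs$PGF), PGF_sd = sd(runs$PGF),
        GF = mean(runs$GF), GF_sd = sd(runs$GF),
        NF = mean(runs$NF), NF_sd = sd(runs$NF),
        n_reps = n_reps)
    }
  }
  structure(
    list(pair = pair,
         levels = lapply(setNames(pair, pair), function(p)
           setNames(vapply(levels, dose_value, numeric(1),
                           table = table, parameter = p), levels)),
         summary = do.call(rbind, summary_rows),
         replicates = do.call(rbind, reps),
         profile = profile, table = table, config = cfg,
         n_reps = n_reps, seed = seed),
    class = "absm_dose_grid")
}

#' @export
print.absm_dose_grid <- function(x, ...) {
  cat(sprintf("<absm_dose_grid> pair (%s, %s), day %g snapshot, %d reps/cell\n",
              x$pair[1L], x$pair[2L], x$config$day, x$n_reps))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s%g x %s%g: PGF %.3f (sd %.3f), GF %.3f, NF %.3f\n",
                s$level1[i], s$value1[i], s$level2[i], s$value2[i],
                s$PGF[i], s$PGF_sd[i], s$GF[i], s$NF[i]))
  }
  invisible(x)
}
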