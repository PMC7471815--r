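METRIC_COLS <- c("m", "n_T", "n_PT", "n_NA1_1", "n_NA1_2", "n_NA2", "n_NA3",
                 "PGF", "GF", "NF", "R_t", "R_n", "W_p", "n_IA", "n_BI",
                 "v", "f", "empty_tumor",
                 "divisions", "quiescences", "necroses", "moved", "kills",
                 "losses")

#' One full simulation iteration (tumor phase then immune phase)
#'
#' @inheritParams division_probability
#' @return List `(tissue, events)`; `events` holds the tumor and immune
#'   event counts of the iteration.
#' @export
absm_step <- function(tissue, params) {
  tres <- tumor_step(tissue, params)
  ires <- immune_step(tres$tissue, params)
  list(tissue = ires$tissue, events = c(tres$events, ires$events))
}

#' Run the agent-based tumor growth simulation
#'
#' Simulates `n_steps` iterations from a point-seeded tumor (one `NA_1_1`
#' cell at the lattice center) or from a supplied tissue. Two
#' implementations of the identical rule set are available: the compiled
#' engine (default) and the pure-R composition of the exported per-phase
#' operations. Both consume the R RNG stream in the same documented draw
#' order, so for a given seed they produce the identical trajectory; the
#' test suite exploits this as a cross-implementation oracle.
#'
#' @param params an [model_params()] object.
#' @param n_steps number of iterations to simulate.
#' @param n_cell,pitch lattice size and cell edge (mm), used when `tissue`
#'   is `NULL`.
#' @param tissue optional starting [new_tissue()] lattice.
#' @param seed optional integer; when supplied, `set.seed(seed)` is called
#'   before the run so the trajectory is fully reproducible.
#' @param engine `"cpp"` (compiled) or `"r"` (pure R rule composition).
#' @return Object of class `absm_sim`: list with the final `tissue` and
#'   `metrics`, a data.frame with one row per iteration (including the
#'   initial state at row 1) holding the [compute_metrics()] fields plus
#'   per-iteration event counts.
#' @export
simulate_absm <- function(params, n_steps, n_cell = 100, pitch = 0.1,
                          tissue = NULL, seed = NULL,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "absm_params"), n_steps >= 0)
  if (is.null(tissue)) tissue <- new_tissue(n_cell, pitch)
  if (!is.null(seed)) set.seed(seed)

  if (engine == "cpp") {
    par <- unclass(params)
    par$na12_code <- CELL_STATES[[params$na12_daughter]]
    par$expiry_code <- CELL_STATES[[params$age_expiry_state]]
    out <- absm_engine_cpp(tissue$states, tissue$immune, tissue$age,
                           tissue$m, tissue$ledger$v, tissue$ledger$f,
                           tissue$ledger$n_BI, tissue$pitch, par,
                           as.integer(n_steps))
    tissue$states <- out$states
    tissue$immune <- out$immune
    tissue$age <- out$age
    tissue$m <- out$m
    tissue$ledger <- list(n_BI = out$n_BI, v = out$v, f = out$f)
    metrics <- as.data.frame(out$metrics)
    names(metrics) <- METRIC_COLS
    metrics$empty_tumor <- metrics$empty_tumor > 0
    int_cols <- setdiff(METRIC_COLS,
                        c("PGF", "GF", "NF", "R_t", "R_n", "W_p",
                          "empty_tumor"))
    metrics[int_cols] <- lapply(metrics[int_cols], as.integer)
  } else {
    event_cols <- c("divisions", "quiescences", "necroses", "moved",
                    "kills", "losses")
    rows <- vector("list", n_steps + 1L)
    rows[[1L]] <- cbind(compute_metrics(tissue),
                        as.data.frame(as.list(setNames(rep(0L, 6L),
                                                       event_cols))))
    if (n_steps > 0) {
      for (k in seq_len(n_steps)) {
        res <- absm_step(tissue, params)
        tissue <- res$tissue
        ev <- as.integer(res$events[event_cols])
        rows[[k + 1L]] <- cbind(compute_metrics(tissue),
                                as.data.frame(as.list(setNames(ev,
                                                               event_cols))))
      }
    }
    metrics <- do.call(rbind, rows)
    metrics <- metrics[, METRIC_COLS]
    rownames(metrics) <- NULL
  }
  structure(list(tissue = tissue, metrics = metrics, params = params),
            class = "absm_sim")
}

#' @export
print.absm_sim <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("<absm_sim> %d iterations on a %dx%d lattice\n",
              last$m, x$tissue$n_cell, x$tissue$n_cell))
  cat(sprintf("  final: n_T %d, PGF %.3f, GF %.3f, NF %.3f, R_t %.2f mm\n",
              last$n_T, last$PGF, last$GF, last$NF, last$R_t))
  invisible(x)
}
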