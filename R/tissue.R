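#' Cell and immune state codes
#'
#' Integer codes for the states a lattice site can hold. Nonimmune states:
#' `NA_0` normal cell or empty space, `NA_1_1` proliferating tumor cell whose
#' division is insensitive to its microenvironment, `NA_1_2` proliferating
#' tumor cell whose division probability is modulated by healthy (`NA_0`)
#' neighbors, `NA_2` quiescent tumor cell, `NA_3` necrotic cell. Immune layer
#' states: `IA_NONE` no immune agent, `IA_0` natural killer cell, `IA_1`
#' cytotoxic T lymphocyte.
#'
#' @format Named integer vectors.
#' @export
CELL_STATES <- c(NA_0 = 0L, NA_1_1 = 1L, NA_1_2 = 2L, NA_2 = 3L, NA_3 = 4L)

#' @rdname CELL_STATES
#' @export
IMMUNE_STATES <- c(IA_NONE = 0L, IA_0 = 1L, IA_1 = 2L)

#' Is a state code tumorous / proliferating?
#'
#' A site is tumorous exactly when it holds `NA_1_1`, `NA_1_2`, `NA_2` or
#' `NA_3`; it is proliferating (an `NA_1` cell) exactly when it holds
#' `NA_1_1` or `NA_1_2`.
#'
#' @param state integer state code(s) from [CELL_STATES].
#' @return Logical vector.
#' @export
is_tumorous <- function(state) {
  state >= CELL_STATES[["NA_1_1"]] & state <= CELL_STATES[["NA_3"]]
}

#' @rdname is_tumorous
#' @export
is_proliferating <- function(state) {
  state == CELL_STATES[["NA_1_1"]] | state == CELL_STATES[["NA_1_2"]]
}

#' Create a host-tissue lattice
#'
#' The host tissue is an `n_cell` x `n_cell` square lattice. Each site holds
#' exactly one nonimmune state, an immune occupancy flag (at most one immune
#' agent per site, only on `NA_0` sites), and an age counter that counts
#' iterations since the last division and is meaningful only on proliferating
#' sites. By default a single `NA_1_1` cell is seeded at the lattice center,
#' the initial condition of a point-seeded avascular tumor.
#'
#' @param n_cell lattice side length (number of cells per edge).
#' @param pitch physical edge length of one cell, in mm.
#' @param seed_tumor if `TRUE` (default) place one `NA_1_1` cell at the
#'   center site `(floor((n_cell+1)/2), floor((n_cell+1)/2))`.
#' @return An object of class `absm_tissue`: a list with integer matrices
#'   `states`, `immune`, `age` (all `n_cell` x `n_cell`), scalars `n_cell`,
#'   `pitch`, iteration index `m`, and the immune combat ledger
#'   `ledger = list(n_BI, v, f)` (newborn immune agents last iteration,
#'   cumulative victories, cumulative failures).
#' @export
new_tissue <- function(n_cell, pitch = 0.1, seed_tumor = TRUE) {
  stopifnot(is.numeric(n_cell), length(n_cell) == 1L, n_cell >= 1,
            is.numeric(pitch), pitch > 0)
  n_cell <- as.integer(n_cell)
  z <- matrix(0L, n_cell, n_cell)
  tissue <- structure(
    list(states = z, immune = z, age = z,
         n_cell = n_cell, pitch = pitch, m = 0L,
         ledger = list(n_BI = 0L, v = 0L, f = 0L)),
    class = "absm_tissue")
  if (seed_tumor) {
    ctr <- as.integer(floor((n_cell + 1L) / 2L))
    tissue$states[ctr, ctr] <- CELL_STATES[["NA_1_1"]]
  }
  tissue
}

#' @export
print.absm_tissue <- function(x, ...) {
  counts <- state_counts(x)
  cat(sprintf("<absm_tissue> %dx%d lattice, pitch %g mm, iteration m = %d\n",
              x$n_cell, x$n_cell, x$pitch, x$m))
  cat(sprintf("  NA_0 %d | NA_1_1 %d | NA_1_2 %d | NA_2 %d | NA_3 %d | IA %d\n",
              counts[["NA_0"]], counts[["NA_1_1"]], counts[["NA_1_2"]],
              counts[["NA_2"]], counts[["NA_3"]], sum(x$immune != 0L)))
  cat(sprintf("  ledger: n_BI %d, v %d, f %d\n",
              x$ledger$n_BI, x$ledger$v, x$ledger$f))
  invisible(x)
}

#' Per-state site counts
#'
#' @param tissue an [new_tissue()] lattice.
#' @return Named integer vector of counts per nonimmune state; always sums to
#'   `n_cell^2`.
#' @export
state_counts <- function(tissue) {
  tab <- tabulate(tissue$states + 1L, nbins = 5L)
  setNames(tab, names(CELL_STATES))
}

check_site <- function(tissue, site) {
  if (length(site) != 2L || any(site < 1L) || any(site > tissue$n_cell))
    stop("site (", paste(site, collapse = ","), ") is outside the ",
         tissue$n_cell, "x", tissue$n_cell, " lattice")
  as.integer(site)
}

# Moore neighbor offsets in fixed row-major order
MOORE_OFFSETS <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

#' Moore neighborhood of a lattice site
#'
#' Returns the in-bounds sites at Chebyshev distance 1 from `site` (up to 8:
#' 8 for interior sites, 5 on an edge, 3 in a corner), in a fixed
#' deterministic row-major order.
#'
#' @param tissue an [new_tissue()] lattice.
#' @param site integer `(row, col)`, 1-based.
#' @return Integer matrix with columns `row`, `col`, one neighbor per row.
#' @export
moore_neighbors <- function(tissue, site) {
  site <- check_site(tissue, site)
  nb <- cbind(row = site[1L] + MOORE_OFFSETS[, "dr"],
              col = site[2L] + MOORE_OFFSETS[, "dc"])
  nb[nb[, 1L] >= 1L & nb[, 1L] <= tissue$n_cell &
     nb[, 2L] >= 1L & nb[, 2L] <= tissue$n_cell, , drop = FALSE]
}

#' Count neighbors of a site matching a state class
#'
#' Counts, over the Moore neighborhood of `site`, the sites matching
#' `predicate`: `"NA_1"` (any proliferating cell), `"NA_0"`, `"IA"` (any
#' immune agent), `"tumorous"`, or one specific state name from
#' [CELL_STATES].
#'
#' @inheritParams moore_neighbors
#' @param predicate character scalar naming the state class.
#' @return Integer count in `[0, 8]`.
#' @export
count_neighbor_states <- function(tissue, site, predicate) {
  nb <- moore_neighbors(tissue, site)
  idx <- cbind(nb[, 1L], nb[, 2L])
  s <- tissue$states[idx]
  n <- switch(predicate,
    "NA_1" = sum(is_proliferating(s)),
    "tumorous" = sum(is_tumorous(s)),
    "IA" = sum(tissue$immune[idx] != IMMUNE_STATES[["IA_NONE"]]),
    {
      if (!predicate %in% names(CELL_STATES))
        stop("unknown neighbor predicate: ", predicate)
      sum(s == CELL_STATES[[predicate]])
    })
  as.integer(n)
}
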