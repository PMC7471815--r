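## Immune agents: recruitment proportional to the proliferating tumor
## population, necrosis-triggered random-walk search, and stochastic combat
## with adjacent proliferating tumor cells.

immune_sites <- function(tissue) {
  which(tissue$immune != IMMUNE_STATES[["IA_NONE"]])  # column-major order
}

linear_to_site <- function(idx, n) {
  c(((idx - 1L) %% n) + 1L, ((idx - 1L) %/% n) + 1L)
}

#' Recruit newborn immune agents
#'
#' The number of newborns is proportional to the proliferating tumor
#' population: `n_BI = round(recruit_rate * n_PT)`. Newborns (natural
#' killers, `IA_0`) are placed on uniformly chosen unoccupied `NA_0` sites;
#' if fewer free sites exist, as many as possible are placed. Consumes one
#' uniform per placement.
#'
#' @inheritParams division_probability
#' @return List `(tissue, n_BI, placed)`.
#' @export
recruit <- function(tissue, params) {
  n_PT <- sum(is_proliferating(tissue$states))
  n_BI <- as.integer(floor(params$recruit_rate * n_PT + 0.5))
  placed <- 0L
  if (n_BI > 0L) {
    free <- which(tissue$states == CELL_STATES[["NA_0"]] &
                  tissue$immune == IMMUNE_STATES[["IA_NONE"]])
    K <- length(free)
    if (K > 0L) {
      chosen <- free[fy_select(K, min(n_BI, K))]
      tissue$immune[chosen] <- IMMUNE_STATES[["IA_0"]]
      placed <- length(chosen)
    }
  }
  tissue$ledger$n_BI <- n_BI
  list(tissue = tissue, n_BI = n_BI, placed = placed)
}

#' Random-walk search by immune agents
#'
#' Once activated (necrotic fraction at or above `activation_nf`), every
#' immune agent moves to a uniformly chosen Moore neighbor that is `NA_0`
#' and free of immune agents, staying put when none exists. Agents are
#' visited in a seeded random permutation of their column-major order, one
#' move per agent per iteration.
#'
#' @inheritParams division_probability
#' @return List `(tissue, moved)`.
#' @export
immune_walk <- function(tissue, params) {
  met <- compute_metrics(tissue)
  if (met$NF < params$activation_nf)
    return(list(tissue = tissue, moved = 0L))
  agents <- immune_sites(tissue)
  moved <- 0L
  if (length(agents) > 0L) {
    perm <- fy_permute(length(agents))
    for (idx in agents[perm]) {
      site <- linear_to_site(idx, tissue$n_cell)
      nb <- moore_neighbors(tissue, site)
      ok <- tissue$states[nb] == CELL_STATES[["NA_0"]] &
            tissue$immune[nb] == IMMUNE_STATES[["IA_NONE"]]
      cand <- nb[ok, , drop = FALSE]
      k <- nrow(cand)
      if (k > 0L) {
        dest <- cand[pick_one(k), ]
        tissue$immune[dest[1L], dest[2L]] <- tissue$immune[site[1L], site[2L]]
        tissue$immune[site[1L], site[2L]] <- IMMUNE_STATES[["IA_NONE"]]
        moved <- moved + 1L
      }
    }
  }
  list(tissue = tissue, moved = moved)
}

#' Immune-tumor combat
#'
#' Every immune agent with at least one proliferating (`NA_1`) Moore
#' neighbor engages one of them, chosen uniformly: with probability
#' `rho_I * K_dT` the tumor cell dies (site reverts to `NA_0`, a victory
#' `v`); otherwise, with probability `rho_t * K_dI`, the immune agent dies
#' instead (a failure `f`); otherwise the engagement is a stand-off. At most
#' one engagement per agent per iteration; agents engage in column-major
#' site order.
#'
#' RNG draw order per engaging agent: one uniform for target choice, one
#' for the tumor-kill trial, and (only if the tumor survives) one for the
#' immune-death trial.
#'
#' @inheritParams division_probability
#' @return List `(tissue, kills, losses)`; the cumulative ledger `v`/`f` in
#'   `tissue` is advanced accordingly.
#' @export
engage <- function(tissue, params) {
  kills <- 0L
  losses <- 0L
  for (idx in immune_sites(tissue)) {
    site <- linear_to_site(idx, tissue$n_cell)
    nb <- moore_neighbors(tissue, site)
    targets <- nb[is_proliferating(tissue$states[nb]), , drop = FALSE]
    k <- nrow(targets)
    if (k == 0L) next
    tgt <- targets[pick_one(k), ]
    if (runif(1) < params$rho_I * params$K_dT) {
      tissue$states[tgt[1L], tgt[2L]] <- CELL_STATES[["NA_0"]]
      tissue$age[tgt[1L], tgt[2L]] <- 0L
      kills <- kills + 1L
    } else if (runif(1) < params$rho_t * params$K_dI) {
      tissue$immune[site[1L], site[2L]] <- IMMUNE_STATES[["IA_NONE"]]
      losses <- losses + 1L
    }
  }
  tissue$ledger$v <- tissue$ledger$v + kills
  tissue$ledger$f <- tissue$ledger$f + losses
  list(tissue = tissue, kills = kills, losses = losses)
}

#' One immune-phase iteration
#'
#' Recruitment, then random-walk search (if activated), then combat, in that
#' order. Does not advance the iteration counter; [absm_step()] runs the
#' tumor phase and then this phase once per iteration.
#'
#' @inheritParams division_probability
#' @return List `(tissue, events)` with
#'   `events = c(n_BI, moved, kills, losses)`.
#' @export
immune_step <- function(tissue, params) {
  r <- recruit(tissue, params)
  w <- immune_walk(r$tissue, params)
  e <- engage(w$tissue, params)
  list(tissue = e$tissue,
       events = c(n_BI = r$n_BI, moved = w$moved,
                  kills = e$kills, losses = e$losses))
}
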