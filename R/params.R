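#' Model parameters of the agent-based tumor growth simulator
#'
#' Bundles every rate, probability and geometry parameter of the model.
#' Defaults are the virtual-patient baseline used throughout the in silico
#' therapy experiments: `p01 = 0.7`, `p02 = 0.5`, `Nmm = 0.2`,
#' `age_max = 1`, `a = 0.42`, `b = 0.11`, `R_max = 15` mm, `K_dT = 0.5`,
#' `K_dI = 0.2`.
#'
#' @param p01 base division probability of an `NA_1_1` cell, in `[0,1]`.
#' @param p02 base division probability of an `NA_1_2` cell, in `[0,1]`.
#' @param Nmm probability that an `NA_1_1` mitosis yields one `NA_1_1` and
#'   one `NA_1_2` daughter (otherwise two `NA_1_1`), in `[0,1]`.
#' @param age_max maximum number of iterations an `NA_1` cell may persist
#'   in the proliferating state while deprived of the opportunity to divide
#'   (no free `NA_0` neighbor) before turning quiescent (positive integer).
#'   The age counter accrues only on enclosed cells and resets on division.
#' @param a base necrotic layer thickness coefficient (mm^(1/3)); a cell
#'   deeper than `a * R_t^rim_exponent` below the tumor edge becomes
#'   nutrient-starved and necrotic.
#' @param b base proliferative rim thickness coefficient (mm^(1/3)); an
#'   `NA_1` cell deeper than `b * R_t^rim_exponent` turns quiescent.
#' @param R_max maximum tumor extent in mm; division probability carries the
#'   pressure factor `max(0, 1 - R_t/R_max)`.
#' @param K_dT tumor death constant: scales the probability
#'   `rho_I * K_dT` that an engaged tumor cell is killed.
#' @param K_dI immune death constant: scales the probability
#'   `rho_t * K_dI` that the engaging immune agent dies instead.
#' @param rho_t protumor probability in `[0,1]`.
#' @param rho_I antitumor probability in `[0,1]`.
#' @param recruit_rate immune newborns per proliferating tumor cell per
#'   iteration; `n_BI = round(recruit_rate * n_PT)`.
#' @param activation_nf necrotic fraction threshold at which immune agents
#'   start their random-walk search.
#' @param iterations_per_day simulation iterations per model day (time
#'   mapping used by [day_snapshot()] and the dose-grid experiments).
#' @param rim_exponent exponent of `R_t` in the quiescence/necrosis layer
#'   thickness rules (default 2/3).
#' @param na12_daughter the daughter type produced by an `NA_1_2` mitosis
#'   (`"NA_1_2"`, type-faithful, by default).
#' @param age_expiry_state state an over-age `NA_1` cell falls into
#'   (`"NA_2"` by default).
#' @return Object of class `absm_params` (a validated named list).
#' @export
model_params <- function(p01 = 0.7, p02 = 0.5, Nmm = 0.2, age_max = 1L,
                         a = 0.42, b = 0.11, R_max = 15, K_dT = 0.5,
                         K_dI = 0.2, rho_t = 0.5, rho_I = 0.5,
                         recruit_rate = 0.01, activation_nf = 0.01,
                         iterations_per_day = 6,
                         rim_exponent = 2 / 3,
                         na12_daughter = c("NA_1_2", "NA_1_1"),
                         age_expiry_state = c("NA_2", "NA_3")) {
  p <- list(p01 = p01, p02 = p02, Nmm = Nmm, age_max = age_max,
            a = a, b = b, R_max = R_max, K_dT = K_dT, K_dI = K_dI,
            rho_t = rho_t, rho_I = rho_I,
            recruit_rate = recruit_rate, activation_nf = activation_nf,
            iterations_per_day = iterations_per_day,
            rim_exponent = rim_exponent,
            na12_daughter = match.arg(na12_daughter),
            age_expiry_state = match.arg(age_expiry_state))
  validate_params(p)
}

validate_params <- function(p) {
  probs <- c("p01", "p02", "Nmm", "K_dT", "K_dI", "rho_t", "rho_I",
             "activation_nf")
  for (key in probs) {
    v <- p[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("parameter '", key, "' must be a single number in [0, 1], got ",
           deparse(v))
  }
  for (key in c("a", "b", "R_max")) {
    if (!is.numeric(p[[key]]) || length(p[[key]]) != 1L || p[[key]] <= 0)
      stop("parameter '", key, "' must be a single positive number")
  }
  if (!is.numeric(p$age_max) || length(p$age_max) != 1L || p$age_max < 1 ||
      p$age_max != round(p$age_max))
    stop("parameter 'age_max' must be a positive integer")
  p$age_max <- as.integer(p$age_max)
  if (!is.numeric(p$recruit_rate) || p$recruit_rate < 0)
    stop("parameter 'recruit_rate' must be non-negative")
  if (!is.numeric(p$iterations_per_day) || p$iterations_per_day <= 0)
    stop("parameter 'iterations_per_day' must be positive")
  if (!is.numeric(p$rim_exponent) || p$rim_exponent <= 0)
    stop("parameter 'rim_exponent' must be positive")
  structure(p, class = "absm_params")
}

#' @export
print.absm_params <- function(x, ...) {
  cat("<absm_params>\n")
  cat(sprintf("  division: p01 %g, p02 %g, Nmm %g, age_max %d\n",
              x$p01, x$p02, x$Nmm, x$age_max))
  cat(sprintf("  geometry: a %g, b %g mm^(1/3), R_max %g mm, rim exponent %g\n",
              x$a, x$b, x$R_max, x$rim_exponent))
  cat(sprintf("  immune:   rho_t %g, rho_I %g, K_dT %g, K_dI %g, recruit %g, activation NF %g\n",
              x$rho_t, x$rho_I, x$K_dT, x$K_dI, x$recruit_rate,
              x$activation_nf))
  cat(sprintf("  time:     %g iterations per day\n", x$iterations_per_day))
  invisible(x)
}
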