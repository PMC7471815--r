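## Configuration files, CSV writers and grayscale snapshot rendering.

#' Load (or default) a run configuration
#'
#' Reads a flat JSON configuration and fills every missing key with the
#' package defaults: the reference-patient genetics (`p01` 0.7, `p02` 0.5,
#' `Nmm` 0.2, `age` 1), the standard physiology (`a` 0.42, `b` 0.11,
#' `R_max` 15 mm, `K_dT` 0.5, `K_dI` 0.2), the default dose table, and the
#' simulation settings (`n_cell` 100, `pitch` 0.1 mm, `iterations_per_day`
#' 5, `day` 12, `n_reps` 20, `seed` 1). Validation errors name the
#' offending key.
#'
#' @param path path to a JSON file, or `NULL` for pure defaults.
#' @return List of class `absm_config` with fields `params`
#'   ([model_params()]), `dose_table`, `n_cell`, `pitch`, `day`, `n_reps`,
#'   `seed`.
#' @export
load_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("p01", "p02", "Nmm", "age", "a", "b", "R_max", "K_dT", "K_dI",
             "rho_t", "rho_I", "recruit_rate", "activation_nf",
             "iterations_per_day", "n_cell", "pitch", "day", "n_reps",
             "seed", "dose_table")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))

  par_keys <- c("p01", "p02", "Nmm", "a", "b", "R_max", "K_dT", "K_dI",
                "rho_t", "rho_I", "recruit_rate", "activation_nf",
                "iterations_per_day")
  par_args <- raw[intersect(names(raw), par_keys)]
  if (!is.null(raw$age)) par_args$age_max <- raw$age
  params <- tryCatch(do.call(model_params, par_args),
                     error = function(e) stop(conditionMessage(e),
                                              call. = FALSE))
  table <- default_dose_table()
  if (!is.null(raw$dose_table)) {
    tab <- as.data.frame(raw$dose_table)
    missing_cols <- setdiff(c("parameter", "H", "M", "L"), names(tab))
    if (length(missing_cols) > 0L)
      stop("config key 'dose_table' lacks column(s): ",
           paste(missing_cols, collapse = ", "))
    table <- tab[, c("parameter", "H", "M", "L")]
  }
  cfg <- list(params = params, dose_table = table,
              n_cell = as.integer(raw$n_cell %||% 100L),
              pitch = raw$pitch %||% 0.1,
              day = raw$day %||% 12,
              n_reps = as.integer(raw$n_reps %||% 20L),
              seed = as.integer(raw$seed %||% 1L))
  if (cfg$n_cell < 3L) stop("config key 'n_cell' must be at least 3")
  if (cfg$pitch <= 0) stop("config key 'pitch' must be positive")
  if (cfg$n_reps < 1L) stop("config key 'n_reps' must be at least 1")
  structure(cfg, class = "absm_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration
#'
#' Writes the configuration back to flat JSON; [load_config()] of the
#' result reproduces the configuration exactly.
#'
#' @param config an `absm_config` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  p <- config$params
  out <- list(p01 = p$p01, p02 = p$p02, Nmm = p$Nmm, age = p$age_max,
              a = p$a, b = p$b, R_max = p$R_max, K_dT = p$K_dT,
              K_dI = p$K_dI, rho_t = p$rho_t, rho_I = p$rho_I,
              recruit_rate = p$recruit_rate,
              activation_nf = p$activation_nf,
              iterations_per_day = p$iterations_per_day,
              n_cell = config$n_cell, pitch = config$pitch,
              day = config$day, n_reps = config$n_reps,
              seed = config$seed,
              dose_table = config$dose_table)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write a dose-grid result as CSV
#'
#' Mirrors the tabular layout of the dose-grid experiments: one header row
#' of level labels carrying the literal parameter-2 dose values (e.g.
#' `H0.81`), one data row per parameter-1 level, each cell
#' `"PGF=..,GF=..,NF=.."`.
#'
#' @param result an [run_dose_grid()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(result, path) {
  s <- result$summary
  lv1 <- unique(s$level1)
  lv2 <- unique(s$level2)
  header <- c("dose",
              vapply(lv2, function(l)
                sprintf("%s%g", l, result$levels[[2L]][[l]]),
                character(1)))
  lines <- paste(header, collapse = ",")
  for (l1 in lv1) {
    cells <- vapply(lv2, function(l2) {
      row <- s[s$level1 == l1 & s$level2 == l2, ]
      sprintf("\"PGF=%.2f,GF=%.2f,NF=%.2f\"", row$PGF, row$GF, row$NF)
    }, character(1))
    label <- sprintf("%s%g", l1, result$levels[[1L]][[l1]])
    lines <- c(lines, paste(c(label, cells), collapse = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a metrics time series as CSV
#'
#' One row per iteration with all metrics columns.
#'
#' @param series metrics `data.frame` from [simulate_absm()].
#' @inheritParams write_grid_csv
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  write.csv(series, path, row.names = FALSE)
  invisible(path)
}

# Fixed gray map for snapshots: normal tissue light grey, proliferating rim
# heavy grey, quiescent layer white, necrotic core black.
SNAPSHOT_GRAYS <- c(NA_0 = 200L, NA_1_1 = 90L, NA_1_2 = 90L, NA_2 = 255L,
                    NA_3 = 0L)

#' Render a tissue snapshot as an 8-bit grayscale image
#'
#' One pixel per lattice cell with the fixed gray map: `NA_0` 200 (light
#' grey, normal tissue), `NA_1` 90 (heavy grey, proliferating rim), `NA_2`
#' 255 (white, quiescent layer), `NA_3` 0 (black, necrotic core). Writes
#' plain-text PGM (P2) or, for a `.png` path, PNG (requires the `png`
#' package).
#'
#' @param tissue an [new_tissue()] lattice.
#' @param path output path ending in `.pgm` or `.png`.
#' @return `path`, invisibly.
#' @export
render_snapshot <- function(tissue, path) {
  gray <- matrix(SNAPSHOT_GRAYS[tissue$states + 1L],
                 tissue$n_cell, tissue$n_cell)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG snapshots requires the 'png' package; ",
           "use a .pgm path instead")
    png::writePNG(gray / 255, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(tissue$n_cell, tissue$n_cell), "255"), con)
    apply(gray, 1L, function(row)
      writeLines(paste(row, collapse = " "), con))
  }
  invisible(path)
}
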