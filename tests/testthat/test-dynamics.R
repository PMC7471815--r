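test_that("division probability follows the pressure and neighbor rules", {
  p <- model_params()

  # lone seed: R_t = 0, geometric factor 1, so rho = p01
  tis <- new_tissue(11)
  expect_equal(division_probability(tis, c(6, 6), p), 0.7)

  # NA_1_2 with zero free neighbors divides with probability 0
  blk <- matrix(CELL_STATES[["NA_2"]], 5, 5)
  blk[3, 3] <- CELL_STATES[["NA_1_2"]]
  tis <- tissue_from_states(blk)
  expect_equal(division_probability(tis, c(3, 3), p), 0)

  # NA_1_2 neighbor fraction: 2 free of 8
  blk <- matrix(CELL_STATES[["NA_2"]], 5, 5)
  blk[3, 3] <- CELL_STATES[["NA_1_2"]]
  blk[2, 2] <- CELL_STATES[["NA_0"]]
  blk[4, 4] <- CELL_STATES[["NA_0"]]
  tis <- tissue_from_states(blk)
  R_t <- tumor_geometry(tis)$R_t
  expect_equal(division_probability(tis, c(3, 3), p),
               0.5 * max(0, 1 - R_t / p$R_max) * 2 / 8)

  # pressure factor vanishes at the maximum tumor extent
  expect_equal(division_probability(new_tissue(11), c(6, 6), p, R_t = 20), 0)
  expect_equal(division_probability(new_tissue(11), c(6, 6), p, R_t = 15), 0)

  expect_error(division_probability(new_tissue(11, seed_tumor = FALSE),
                                    c(6, 6), p),
               "not proliferating")
})

test_that("daughter typing is degenerate at Nmm 0 and 1 and calibrated between", {
  set.seed(11)
  for (i in 1:20) {
    expect_equal(unname(daughter_types(0)),
                 unname(c(CELL_STATES[["NA_1_1"]], CELL_STATES[["NA_1_1"]])))
    expect_equal(unname(daughter_types(1)),
                 unname(c(CELL_STATES[["NA_1_1"]], CELL_STATES[["NA_1_2"]])))
  }
  expect_error(daughter_types(1.2), "probability")

  # mixed-pair frequency at Nmm = 0.2 within the binomial 3-sigma band
  set.seed(101)
  n <- 1e5
  mixed <- 0L
  for (i in seq_len(n)) {
    d <- daughter_types(0.2)
    mixed <- mixed + (d[["daughter"]] == CELL_STATES[["NA_1_2"]])
  }
  expect_lt(abs(mixed / n - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("division attempts place daughters only into free neighbors", {
  p <- model_params(p01 = 1, R_max = 1e6)

  # fully enclosed cell cannot place a daughter
  blk <- matrix(CELL_STATES[["NA_2"]], 5, 5)
  blk[3, 3] <- CELL_STATES[["NA_1_1"]]
  tis <- tissue_from_states(blk)
  set.seed(1)
  res <- attempt_division(tis, c(3, 3), p)
  expect_false(res$divided)
  expect_identical(res$tissue$states, tis$states)

  # rho = 1 with exactly one free neighbor: that neighbor becomes a daughter
  blk[2, 2] <- CELL_STATES[["NA_0"]]
  tis <- tissue_from_states(blk)
  set.seed(1)
  res <- attempt_division(tis, c(3, 3), p)
  expect_true(res$divided)
  expect_equal(unname(res$daughter_site), c(2, 2))
  expect_true(is_proliferating(res$tissue$states[2, 2]))
  expect_equal(res$tissue$age[3, 3], 0L)
})

test_that("rim thresholds scale as coeff * R_t^(2/3)", {
  p <- model_params()
  expect_equal(p$b * 8^(2 / 3), 0.44)
  expect_equal(p$a * 8^(2 / 3), 1.68)
})

test_that("quiescence follows the age and rim rules", {
  p <- model_params(age_max = 1L)

  # an enclosed NA_1 cell whose age allowance is exhausted turns NA_2
  blk <- matrix(CELL_STATES[["NA_2"]], 7, 7)
  blk[4, 4] <- CELL_STATES[["NA_1_1"]]
  tis <- tissue_from_states(blk)
  tis$age[4, 4] <- 1L
  res <- quiescence_update(tis, p)
  expect_equal(res$tissue$states[4, 4], CELL_STATES[["NA_2"]])
  expect_equal(res$tissue$age[4, 4], 0L)
  expect_equal(nrow(res$changed), 1L)

  # a boundary NA_1 cell with age 0 is left proliferating
  tis <- new_tissue(9)
  res <- quiescence_update(tis, p)
  expect_equal(nrow(res$changed), 0L)
  expect_true(is_proliferating(res$tissue$states[5, 5]))
})

test_that("necrosis only strikes deep quiescent cells and is absorbing", {
  p <- model_params()

  # a thin tumor has no cell deeper than delta_n
  blk <- matrix(0L, 9, 9)
  blk[5, 3:7] <- CELL_STATES[["NA_2"]]
  tis <- tissue_from_states(blk)
  res <- necrosis_update(tis, p)
  expect_equal(nrow(res$changed), 0L)

  # deep quiescent core of a large disk becomes necrotic
  tis <- disk_tissue(41, radius = 18)
  tis$states[tis$states == CELL_STATES[["NA_1_1"]]] <- CELL_STATES[["NA_2"]]
  res <- necrosis_update(tis, p)
  expect_gt(nrow(res$changed), 0L)
  # every converted site is deeper than the rim threshold
  R_t <- tumor_geometry(tis)$R_t
  delta_n <- max(p$a * R_t^(2 / 3), tis$pitch * sqrt(2))
  for (i in seq_len(nrow(res$changed)))
    expect_gt(depth_from_edge(tis, res$changed[i, ]), delta_n)
})

test_that("a tumor step advances m and applies each phase once", {
  p <- model_params()

  # all-normal lattice: no events, m advances
  tis <- new_tissue(9, seed_tumor = FALSE)
  set.seed(5)
  res <- tumor_step(tis, p)
  expect_equal(res$tissue$m, 1L)
  expect_equal(sum(res$events), 0L)

  # lone seed with certain division: exactly one division
  tis <- new_tissue(9)
  set.seed(5)
  res <- tumor_step(tis, model_params(p01 = 1, R_max = 1e6))
  expect_equal(unname(res$events["divisions"]), 1L)
  expect_equal(sum(is_proliferating(res$tissue$states)), 2L)
})

test_that("compiled engine replays the R rule composition exactly", {
  p <- model_params()
  # dense scenario with immune agents on a small lattice
  for (seed in c(3, 17)) {
    s_cpp <- simulate_absm(p, 25, n_cell = 25, seed = seed, engine = "cpp")
    s_r <- simulate_absm(p, 25, n_cell = 25, seed = seed, engine = "r")
    expect_identical(s_cpp$tissue$states, s_r$tissue$states)
    expect_identical(s_cpp$tissue$age, s_r$tissue$age)
    expect_identical(s_cpp$tissue$immune, s_r$tissue$immune)
    expect_identical(s_cpp$tissue$ledger, s_r$tissue$ledger)
    expect_equal(s_cpp$metrics, s_r$metrics, tolerance = 1e-12)
  }
  # tiny 5x5 lattice, step-by-step event log
  s_cpp <- simulate_absm(p, 3, n_cell = 5, seed = 9, engine = "cpp")
  s_r <- simulate_absm(p, 3, n_cell = 5, seed = 9, engine = "r")
  expect_equal(s_cpp$metrics$divisions, s_r$metrics$divisions)
  expect_identical(s_cpp$tissue$states, s_r$tissue$states)
})

test_that("trajectories are bitwise reproducible from the seed", {
  p <- model_params()
  a <- simulate_absm(p, 30, n_cell = 40, seed = 123)
  b <- simulate_absm(p, 30, n_cell = 40, seed = 123)
  expect_identical(a$tissue, b$tissue)
  expect_identical(a$metrics, b$metrics)
  c <- simulate_absm(p, 30, n_cell = 40, seed = 124)
  expect_false(identical(a$tissue$states, c$tissue$states))
})

test_that("state counts are conserved and necrosis is monotone over a run", {
  p <- model_params()
  tis <- new_tissue(40)
  set.seed(21)
  for (step in 1:30) {
    tis <- absm_step(tis, p)$tissue
    counts <- state_counts(tis)
    expect_equal(sum(counts), 40L^2)  # every site holds exactly one state
    expect_equal(sum(tis$age[!is_proliferating(tis$states)]), 0L)
  }
  sim <- simulate_absm(model_params(), 50, n_cell = 60, seed = 21)
  m <- sim$metrics
  expect_true(all(m$n_NA1_1 + m$n_NA1_2 + m$n_NA2 + m$n_NA3 == m$n_T))
  expect_true(all(diff(m$n_NA3) >= 0))
  expect_true(all(diff(m$v) >= 0))
  expect_true(all(diff(m$f) >= 0))
})

test_that("the grown tumor is layered: necrotic core, quiescent ring, rim", {
  sim <- simulate_absm(model_params(), 55, n_cell = 70, seed = 33)
  tis <- sim$tissue
  expect_gt(sum(tis$states == CELL_STATES[["NA_3"]]), 0L)
  mean_depth <- function(code) {
    sites <- which(matrix(tis$states %in% code, tis$n_cell, tis$n_cell),
                   arr.ind = TRUE)
    mean(apply(sites, 1L, function(s) depth_from_edge(tis, s)))
  }
  d1 <- mean_depth(c(CELL_STATES[["NA_1_1"]], CELL_STATES[["NA_1_2"]]))
  d2 <- mean_depth(CELL_STATES[["NA_2"]])
  d3 <- mean_depth(CELL_STATES[["NA_3"]])
  expect_gt(d3, d2)
  expect_gt(d2, d1)
})

test_that("mean tumor size responds monotonically to the division probability", {
  # coarse 3-point dose response on a reduced lattice
  mean_pgf <- function(p01, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_absm(model_params(p01 = p01), 36, n_cell = 50,
                           seed = s)
      sim$metrics$PGF[nrow(sim$metrics)]
    }, numeric(1)))
  }
  seeds <- 1:12
  pg <- c(mean_pgf(0.23, seeds), mean_pgf(0.52, seeds), mean_pgf(0.81, seeds))
  expect_true(all(diff(pg) > 0))
})
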