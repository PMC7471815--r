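test_that("recruitment is proportional to the proliferating population", {
  # zero rate recruits nobody
  tis <- disk_tissue(15, radius = 4)
  res <- recruit(tis, model_params(recruit_rate = 0))
  expect_equal(res$n_BI, 0L)
  expect_equal(sum(res$tissue$immune), 0L)

  # rate 0.1 with n_PT = 40 recruits exactly 4
  blk <- matrix(0L, 12, 12)
  blk[1:4, 1:10] <- CELL_STATES[["NA_1_1"]]  # 40 proliferating cells
  tis <- tissue_from_states(blk)
  set.seed(2)
  res <- recruit(tis, model_params(recruit_rate = 0.1))
  expect_equal(res$n_BI, 4L)
  expect_equal(res$placed, 4L)
  # newborns sit on NA_0 sites only
  born <- which(res$tissue$immune != 0L)
  expect_true(all(res$tissue$states[born] == CELL_STATES[["NA_0"]]))

  # a fully tumorous lattice leaves nowhere to place newborns
  blk <- matrix(CELL_STATES[["NA_1_1"]], 6, 6)
  tis <- tissue_from_states(blk)
  set.seed(2)
  res <- recruit(tis, model_params(recruit_rate = 0.5))
  expect_gt(res$n_BI, 0L)
  expect_equal(res$placed, 0L)
})

test_that("the random-walk search is gated by the necrotic fraction", {
  p <- model_params(activation_nf = 1)
  tis <- new_tissue(9, seed_tumor = FALSE)
  tis$immune[5, 5] <- IMMUNE_STATES[["IA_0"]]
  set.seed(3)
  res <- immune_walk(tis, p)  # NF = 0 < 1: no movement at all
  expect_equal(res$moved, 0L)
  expect_identical(res$tissue$immune, tis$immune)

  # an agent surrounded by tumor cells stays put even when activated
  blk <- matrix(CELL_STATES[["NA_2"]], 5, 5)
  blk[3, 3] <- 0L
  blk[1, 1] <- CELL_STATES[["NA_3"]]
  tis <- tissue_from_states(blk)
  tis$immune[3, 3] <- IMMUNE_STATES[["IA_0"]]
  set.seed(3)
  res <- immune_walk(tis, model_params(activation_nf = 0))
  expect_equal(res$moved, 0L)
})

test_that("walk directions are uniform over the Moore neighborhood", {
  p <- model_params(activation_nf = 0)
  n_steps <- 8000
  counts <- integer(8)
  set.seed(77)
  for (i in seq_len(n_steps)) {
    tis <- new_tissue(5, seed_tumor = FALSE)
    tis$immune[3, 3] <- IMMUNE_STATES[["IA_0"]]
    res <- immune_walk(tis, p)
    dest <- which(res$tissue$immune != 0L, arr.ind = TRUE)
    dr <- dest[1L] - 3L
    dc <- dest[2L] - 3L
    dir <- which(dr == c(-1, -1, -1, 0, 0, 1, 1, 1) &
                 dc == c(-1, 0, 1, -1, 1, -1, 0, 1))
    counts[dir] <- counts[dir] + 1L
  }
  expect_equal(sum(counts), n_steps)
  phat <- counts / n_steps
  band <- 3 * sqrt((1 / 8) * (7 / 8) / n_steps)
  expect_true(all(abs(phat - 1 / 8) < band))
})

test_that("combat kill and loss probabilities follow the death constants", {
  # rho_I = 0: the tumor is never killed
  blk <- matrix(0L, 3, 3)
  blk[1, 1] <- CELL_STATES[["NA_1_1"]]
  set.seed(4)
  p0 <- model_params(rho_I = 0, rho_t = 1, K_dI = 1)
  tis <- tissue_from_states(blk)
  tis$immune[2, 2] <- IMMUNE_STATES[["IA_0"]]
  res <- engage(tis, p0)
  expect_equal(res$kills, 0L)

  # rho_t = 0: the immune agent never dies
  set.seed(4)
  pI <- model_params(rho_I = 1, rho_t = 0, K_dT = 1)
  tis <- tissue_from_states(blk)
  tis$immune[2, 2] <- IMMUNE_STATES[["IA_0"]]
  res <- engage(tis, pI)
  expect_equal(res$losses, 0L)
  expect_equal(res$kills, 1L)
  expect_equal(res$tissue$states[1, 1], CELL_STATES[["NA_0"]])

  # kill frequency rho_I * K_dT = 0.5 over many engagements (3-sigma band)
  pk <- model_params(rho_I = 1, K_dT = 0.5, rho_t = 0)
  n <- 1e5
  kills <- 0L
  set.seed(55)
  base <- tissue_from_states(blk)
  base$immune[2, 2] <- IMMUNE_STATES[["IA_0"]]
  for (i in seq_len(n)) kills <- kills + engage(base, pk)$kills
  expect_lt(abs(kills / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("the immune phase updates the victory/failure ledger consistently", {
  p <- model_params(recruit_rate = 0.2, activation_nf = 0,
                    rho_I = 0.9, rho_t = 0.9, K_dT = 0.5, K_dI = 0.5)
  tis <- disk_tissue(21, radius = 5)
  set.seed(6)
  kills_total <- 0L
  losses_total <- 0L
  for (i in 1:15) {
    res <- immune_step(tis, p)
    kills_total <- kills_total + res$events[["kills"]]
    losses_total <- losses_total + res$events[["losses"]]
    tis <- res$tissue
    # no immune agent ever co-occupies a tumorous site
    occupied <- which(tis$immune != 0L)
    expect_true(all(!is_tumorous(tis$states[occupied])))
  }
  expect_equal(tis$ledger$v, kills_total)
  expect_equal(tis$ledger$f, losses_total)
  expect_gt(kills_total + losses_total, 0L)
})

test_that("with no immune agents the immune phase is inert", {
  p <- model_params(recruit_rate = 0)
  tis <- disk_tissue(15, radius = 4)
  set.seed(8)
  res <- immune_step(tis, p)
  expect_identical(res$tissue$states, tis$states)
  expect_identical(res$tissue$immune, tis$immune)
  expect_equal(sum(res$events), 0L)
})

test_that("immune-off runs reproduce the tumor-only trajectory bitwise", {
  p_off <- model_params(recruit_rate = 0)
  full <- simulate_absm(p_off, 20, n_cell = 25, seed = 99)

  tis <- new_tissue(25)
  set.seed(99)
  for (i in 1:20) tis <- tumor_step(tis, p_off)$tissue
  expect_identical(full$tissue$states, tis$states)
  expect_identical(full$tissue$age, tis$age)
  expect_equal(full$tissue$ledger$v, 0L)
  expect_equal(full$tissue$ledger$f, 0L)
})
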