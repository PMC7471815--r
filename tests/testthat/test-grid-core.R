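test_that("Moore neighborhoods respect lattice bounds and fixed ordering", {
  tis <- new_tissue(10)
  expect_equal(nrow(moore_neighbors(tis, c(5, 5))), 8L)
  expect_equal(nrow(moore_neighbors(tis, c(1, 1))), 3L)
  expect_equal(nrow(moore_neighbors(tis, c(1, 5))), 5L)
  expect_equal(nrow(moore_neighbors(tis, c(10, 10))), 3L)
  # row-major ordering
  nb <- moore_neighbors(tis, c(5, 5))
  expect_equal(nb[, "row"], c(4L, 4L, 4L, 5L, 5L, 6L, 6L, 6L))
  expect_equal(nb[, "col"], c(4L, 5L, 6L, 4L, 6L, 4L, 5L, 6L))
  expect_error(moore_neighbors(tis, c(0, 5)), "outside")
  expect_error(moore_neighbors(tis, c(5, 11)), "outside")
})

test_that("neighbor-state counting matches hand-built patches", {
  tis <- new_tissue(10, seed_tumor = FALSE)
  expect_equal(count_neighbor_states(tis, c(5, 5), "NA_1"), 0L)
  expect_equal(count_neighbor_states(tis, c(5, 5), "NA_0"), 8L)

  patch <- matrix(0L, 3, 3)
  patch[1, 2] <- CELL_STATES[["NA_1_1"]]
  patch[2, 3] <- CELL_STATES[["NA_1_1"]]
  patch[3, 1] <- CELL_STATES[["NA_3"]]
  tis <- tissue_from_states(patch)
  expect_equal(count_neighbor_states(tis, c(2, 2), "NA_1"), 2L)
  expect_equal(count_neighbor_states(tis, c(2, 2), "tumorous"), 3L)
  expect_equal(count_neighbor_states(tis, c(2, 2), "NA_0"), 5L)
  expect_error(count_neighbor_states(tis, c(2, 2), "bogus"),
               "unknown neighbor predicate")
})

test_that("tumor geometry matches the rasterized-disk expectations", {
  # single seeded cell: centroid coincides with the only cell
  tis <- new_tissue(11)
  geo <- tumor_geometry(tis)
  expect_equal(geo$R_t, 0)
  expect_equal(geo$R_n, 0)
  expect_false(geo$empty_tumor)

  # filled disk of radius 10 cells at pitch 0.1 mm; the rasterized boundary
  # includes diagonal-notch cells, so the mean sits slightly below the
  # nominal radius (brute-force oracle value 0.9438)
  tis <- disk_tissue(31, radius = 10)
  geo <- tumor_geometry(tis)
  expect_equal(geo$R_t, bf_geometry(tis)$R_t, tolerance = 1e-12)
  expect_lt(abs(geo$R_t - 1.0), tis$pitch)
  expect_equal(geo$R_n, 0)

  # inner necrotic disk of radius 4 cells (oracle value 0.3338)
  tis <- disk_tissue(31, radius = 10, inner_radius = 4)
  geo <- tumor_geometry(tis)
  expect_equal(geo$R_n, bf_geometry(tis)$R_n, tolerance = 1e-12)
  expect_lt(abs(geo$R_n - 0.4), tis$pitch)
  expect_lte(geo$R_n, geo$R_t)

  # empty lattice reports the empty-tumor flag
  geo <- tumor_geometry(new_tissue(5, seed_tumor = FALSE))
  expect_true(geo$empty_tumor)
  expect_equal(geo$R_t, 0)
})

test_that("geometry and depth agree with brute-force recomputation", {
  for (seed in 1:6) {
    tis <- random_tissue(if (seed %% 2) 15 else 25, seed)
    geo <- tumor_geometry(tis)
    bf <- bf_geometry(tis)
    expect_equal(geo$R_t, bf$R_t, tolerance = 1e-12)
    expect_equal(geo$R_n, bf$R_n, tolerance = 1e-12)
    expect_equal(geo$W_p, bf$W_p, tolerance = 1e-12)

    tumor_sites <- which(matrix(is_tumorous(tis$states),
                                tis$n_cell, tis$n_cell), arr.ind = TRUE)
    pick <- tumor_sites[seq(1, nrow(tumor_sites), length.out = 10), ,
                        drop = FALSE]
    for (i in seq_len(nrow(pick)))
      expect_equal(depth_from_edge(tis, pick[i, ]), bf_depth(tis, pick[i, ]))
  }
})

test_that("radii are invariant under 90-degree lattice rotation", {
  rotate_tissue <- function(tis) {
    rot <- function(mat) t(mat[nrow(mat):1, , drop = FALSE])
    tis$states <- rot(tis$states)
    tis$immune <- rot(tis$immune)
    tis$age <- rot(tis$age)
    tis
  }
  for (seed in 1:4) {
    tis <- random_tissue(19, seed)
    a <- tumor_geometry(tis)
    b <- tumor_geometry(rotate_tissue(tis))
    expect_equal(a$R_t, b$R_t, tolerance = 1e-9)
    expect_equal(a$R_n, b$R_n, tolerance = 1e-9)
    expect_equal(a$W_p, b$W_p, tolerance = 1e-9)
  }
})

test_that("depth from edge behaves at boundaries and for lone cells", {
  tis <- new_tissue(9)  # lone tumor cell at center
  ctr <- c(5, 5)
  expect_equal(depth_from_edge(tis, ctr), tis$pitch)

  # boundary cells of a disk are within one diagonal of the exterior
  tis <- disk_tissue(25, radius = 7)
  b <- bf_boundary(matrix(is_tumorous(tis$states), 25, 25))
  for (i in seq_len(nrow(b)))
    expect_lte(depth_from_edge(tis, b[i, ]), tis$pitch * sqrt(2) + 1e-12)

  # block-center depth equals the brute-force nearest-exterior distance
  blk <- matrix(0L, 31, 31)
  blk[6:26, 6:26] <- CELL_STATES[["NA_1_1"]]
  tis <- tissue_from_states(blk)
  expect_equal(depth_from_edge(tis, c(16, 16)), bf_depth(tis, c(16, 16)))
  expect_error(depth_from_edge(tis, c(1, 1)), "not tumorous")
})
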