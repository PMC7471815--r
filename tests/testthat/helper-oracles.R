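# Brute-force oracles, deliberately written with plain loops and no reuse of
# the package's vectorized internals.

# Build a tissue around a given state matrix.
tissue_from_states <- function(states, pitch = 0.1) {
  tis <- new_tissue(nrow(states), pitch = pitch, seed_tumor = FALSE)
  tis$states <- matrix(as.integer(states), nrow(states), ncol(states))
  tis
}

# Rasterized disk of tumor cells, optionally with an inner necrotic disk.
disk_tissue <- function(n, radius, inner_radius = 0, pitch = 0.1) {
  ctr <- (n + 1) / 2
  states <- matrix(0L, n, n)
  for (r in 1:n) {
    for (c in 1:n) {
      d2 <- (r - ctr)^2 + (c - ctr)^2
      if (d2 <= radius^2) states[r, c] <- CELL_STATES[["NA_1_1"]]
      if (inner_radius > 0 && d2 <= inner_radius^2)
        states[r, c] <- CELL_STATES[["NA_3"]]
    }
  }
  tissue_from_states(states, pitch)
}

random_tissue <- function(n, seed, p = c(0.55, 0.15, 0.1, 0.1, 0.1)) {
  set.seed(seed)
  states <- matrix(sample(0:4, n * n, replace = TRUE, prob = p), n, n)
  tissue_from_states(states)
}

bf_is_tumor <- function(s) s %in% 1:4

# Brute-force region boundary: member cells with an out-of-bounds or
# non-member Chebyshev-1 neighbor.
bf_boundary <- function(member) {
  n <- nrow(member)
  out <- NULL
  for (c in 1:n) {
    for (r in 1:n) {
      if (!member[r, c]) next
      boundary <- FALSE
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- r + dr; cc <- c + dc
          if (rr < 1 || rr > n || cc < 1 || cc > n || !member[rr, cc])
            boundary <- TRUE
        }
      }
      if (boundary) out <- rbind(out, c(r, c))
    }
  }
  out
}

bf_mean_radius <- function(member, centroid, pitch) {
  b <- bf_boundary(member)
  if (is.null(b)) return(0)
  total <- 0
  for (i in seq_len(nrow(b)))
    total <- total + sqrt((b[i, 1] - centroid[1])^2 +
                          (b[i, 2] - centroid[2])^2)
  pitch * total / nrow(b)
}

bf_geometry <- function(tissue) {
  n <- tissue$n_cell
  tumor <- matrix(FALSE, n, n)
  necro <- matrix(FALSE, n, n)
  inner <- matrix(FALSE, n, n)
  rs <- 0; cs <- 0; cnt <- 0
  for (c in 1:n) {
    for (r in 1:n) {
      s <- tissue$states[r, c]
      if (bf_is_tumor(s)) {
        tumor[r, c] <- TRUE
        rs <- rs + r; cs <- cs + c; cnt <- cnt + 1
        if (!(s %in% 1:2)) inner[r, c] <- TRUE
      }
      if (s == 4) necro[r, c] <- TRUE
    }
  }
  if (cnt == 0) return(list(R_t = 0, R_n = 0, W_p = 0))
  centroid <- c(rs / cnt, cs / cnt)
  R_t <- bf_mean_radius(tumor, centroid, tissue$pitch)
  R_n <- 0
  if (any(necro)) {
    nc <- which(necro, arr.ind = TRUE)
    R_n <- bf_mean_radius(necro, c(mean(nc[, 1]), mean(nc[, 2])),
                          tissue$pitch)
  }
  W_p <- if (any(inner))
    max(0, R_t - bf_mean_radius(inner, centroid, tissue$pitch)) else R_t
  list(R_t = R_t, R_n = R_n, W_p = W_p)
}

# Brute-force depth: scan every non-tumor site.
bf_depth <- function(tissue, site) {
  n <- tissue$n_cell
  best <- Inf
  for (c in 1:n) {
    for (r in 1:n) {
      if (bf_is_tumor(tissue$states[r, c])) next
      d <- sqrt((r - site[1])^2 + (c - site[2])^2)
      if (d < best) best <- d
    }
  }
  unname(tissue$pitch * best)
}

bf_state_counts <- function(tissue) {
  out <- integer(5)
  for (s in as.vector(tissue$states)) out[s + 1] <- out[s + 1] + 1
  out
}
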