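## Tumor geometry: mean radii and rim thickness.
## A region's boundary cells are its members with at least one Moore neighbor
## outside the region, or sitting on the lattice edge (the lattice boundary is
## absorbing, so edge contact is boundary contact).

region_boundary <- function(mask) {
  n <- nrow(mask)
  if (!any(mask)) return(matrix(integer(0), 0L, 2L))
  pad <- matrix(FALSE, n + 2L, n + 2L)
  pad[2:(n + 1L), 2:(n + 1L)] <- mask
  outside <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(MOORE_OFFSETS))) {
    dr <- MOORE_OFFSETS[k, 1L]; dc <- MOORE_OFFSETS[k, 2L]
    outside <- outside | !pad[(2L + dr):(n + 1L + dr), (2L + dc):(n + 1L + dc)]
  }
  which(mask & outside, arr.ind = TRUE)
}

mean_boundary_radius <- function(mask, centroid, pitch) {
  b <- region_boundary(mask)
  if (nrow(b) == 0L) return(0)
  pitch * mean(sqrt((b[, 1L] - centroid[1L])^2 + (b[, 2L] - centroid[2L])^2))
}

#' Tumor geometry: mean radii and proliferative rim thickness
#'
#' Computes `R_t`, the mean Euclidean distance (in mm) from the tumor
#' centroid to the tumor boundary cells; `R_n`, the same quantity for the
#' necrotic (`NA_3`) region about its own centroid (0 when no necrotic cell
#' exists); and `W_p`, the proliferative rim thickness, defined as `R_t`
#' minus the mean centroid distance of the boundary of the non-proliferating
#' tumor region (`R_t` itself when the whole tumor is proliferating),
#' clamped at 0.
#'
#' @param tissue an [new_tissue()] lattice.
#' @return List with fields `R_t`, `R_n`, `W_p` (mm) and logical
#'   `empty_tumor`. An empty lattice reports all radii 0 with
#'   `empty_tumor = TRUE`.
#' @export
tumor_geometry <- function(tissue) {
  tumor <- matrix(is_tumorous(tissue$states), tissue$n_cell, tissue$n_cell)
  if (!any(tumor))
    return(list(R_t = 0, R_n = 0, W_p = 0, empty_tumor = TRUE))
  cells <- which(tumor, arr.ind = TRUE)
  centroid <- c(mean(cells[, 1L]), mean(cells[, 2L]))
  R_t <- mean_boundary_radius(tumor, centroid, tissue$pitch)

  necro <- matrix(tissue$states == CELL_STATES[["NA_3"]],
                  tissue$n_cell, tissue$n_cell)
  R_n <- 0
  if (any(necro)) {
    ncells <- which(necro, arr.ind = TRUE)
    ncentroid <- c(mean(ncells[, 1L]), mean(ncells[, 2L]))
    R_n <- mean_boundary_radius(necro, ncentroid, tissue$pitch)
  }

  inner <- tumor & !matrix(is_proliferating(tissue$states),
                           tissue$n_cell, tissue$n_cell)
  W_p <- if (any(inner)) {
    max(0, R_t - mean_boundary_radius(inner, centroid, tissue$pitch))
  } else R_t
  list(R_t = R_t, R_n = R_n, W_p = W_p, empty_tumor = FALSE)
}

## Depth map: for every tumorous site, the Euclidean distance (site centers,
## in mm) to the nearest non-tumorous site; NA elsewhere. The nearest
## non-tumorous site is always Moore-adjacent to the tumor region, so the
## candidate set can be restricted to that fringe. Inf when the whole lattice
## is tumorous.
depth_map <- function(tissue) {
  n <- tissue$n_cell
  tumor <- matrix(is_tumorous(tissue$states), n, n)
  out <- matrix(NA_real_, n, n)
  if (!any(tumor)) return(out)
  if (all(tumor)) { out[] <- Inf; return(out) }
  fringe <- region_boundary(!tumor)  # non-tumor cells adjacent to tumor
  cells <- which(tumor, arr.ind = TRUE)
  d2 <- outer(cells[, 1L], fringe[, 1L], "-")^2 +
        outer(cells[, 2L], fringe[, 2L], "-")^2
  out[cells] <- tissue$pitch * sqrt(apply(d2, 1L, min))
  out
}

#' Depth of a tumorous site below the tumor edge
#'
#' Euclidean distance, in mm, from a tumorous site to the nearest
#' non-tumorous site (site centers). Boundary cells have depth at most
#' `pitch * sqrt(2)`; the rim quiescence and necrosis rules compare this
#' depth to the nutrient-limited layer thicknesses.
#'
#' @inheritParams moore_neighbors
#' @return Depth in mm (`Inf` if the whole lattice is tumorous).
#' @export
depth_from_edge <- function(tissue, site) {
  site <- check_site(tissue, site)
  if (!is_tumorous(tissue$states[site[1L], site[2L]]))
    stop("depth_from_edge: site (", site[1L], ",", site[2L],
         ") is not tumorous")
  tumor <- matrix(is_tumorous(tissue$states), tissue$n_cell, tissue$n_cell)
  if (all(tumor)) return(Inf)
  bg <- which(!tumor, arr.ind = TRUE)
  tissue$pitch * sqrt(min((bg[, 1L] - site[1L])^2 + (bg[, 2L] - site[2L])^2))
}
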