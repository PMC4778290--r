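## 2D hexagonal lobule construction: sequential DLA recipe and morphometrics.

#' Recipe for the sequential DLA construction of a 2D lobule
#'
#' Five construction stages: (i) main aggregation of `N_par` walkers on the
#' full grid; (ii) de-crowding of the centre by an independent erase
#' aggregation of `N_cen1_par` walkers on the central half-size subdomain;
#' (iii) refill of the centre with `N_cen2_par` walkers of size 2; (iv)
#' corner-well aggregations of `N_cor_par` walkers on M/3 subdomains at each
#' hexagon corner; (v) clipping to the bounding hexagon. Particle counts
#' scale linearly with the grid side; the main count follows
#' `N_par ~ 37 * M_dim` except at the reference size 256 where the canonical
#' 9500 is used.
#'
#' @param M_dim Grid side in cells (even, >= 16). Default 256.
#' @param N_par Main aggregation particle count. Default 9500 at
#'   `M_dim = 256`, otherwise `round(37 * M_dim)`.
#' @param dp Walker step/footprint size in cells (1, 2 or 3).
#' @param N_cen1_par Central erase count (default scales from 1200 at 256).
#' @param N_cen2_par Central refill count (default scales from 800 at 256).
#' @param N_cor_par Per-corner count (default scales from 500 at 256).
#' @param bias Probability per step that a walker moves toward the nucleus
#'   rather than in a uniformly random direction. Frozen default 0.5.
#' @param seed Master RNG seed recorded with the recipe.
#' @return Object of class `"dla_recipe"`.
#' @seealso [build_lobule_2d()]
#' @export
#' @examples
#' dla_recipe(M_dim = 64)$N_par  # 2368
dla_recipe <- function(M_dim = 256L, N_par = NULL, dp = 1L,
                       N_cen1_par = NULL, N_cen2_par = NULL,
                       N_cor_par = NULL, bias = 0.5, seed = 1L) {
  M_dim <- as.integer(M_dim)
  if (M_dim < 16L || M_dim %% 2L != 0L) {
    stop("M_dim must be even and >= 16", call. = FALSE)
  }
  if (!dp %in% 1:3) stop("dp must be 1, 2 or 3", call. = FALSE)
  N_par <- as.integer(N_par %||%
                        (if (M_dim == 256L) 9500L else round(37 * M_dim)))
  N_cen1_par <- as.integer(N_cen1_par %||% round(1200 * M_dim / 256))
  N_cen2_par <- as.integer(N_cen2_par %||% round(800 * M_dim / 256))
  N_cor_par <- as.integer(N_cor_par %||% round(500 * M_dim / 256))
  counts <- c(N_par, N_cen1_par, N_cen2_par, N_cor_par)
  if (any(counts < 0L)) stop("particle counts must be >= 0", call. = FALSE)
  if (bias < 0 || bias > 1) stop("bias must be in [0, 1]", call. = FALSE)
  structure(list(M_dim = M_dim, N_par = N_par, dp = as.integer(dp),
                 N_cen1_par = N_cen1_par, N_cen2_par = N_cen2_par,
                 N_cor_par = N_cor_par, bias = bias,
                 seed = as.integer(seed)),
            class = "dla_recipe")
}

#' @export
print.dla_recipe <- function(x, ...) {
  cat(sprintf(
    "DLA recipe: M_dim %d, N_par %d (dp %d), centre -%d/+%d, corners 6 x %d, bias %.2f, seed %d\n",
    x$M_dim, x$N_par, x$dp, x$N_cen1_par, x$N_cen2_par, x$N_cor_par,
    x$bias, x$seed))
  invisible(x)
}

#' In-hexagon cell mask
#'
#' Logical `M x M` matrix marking cells whose centre lies inside the regular
#' hexagon of across-corner diameter `M` cells, centred on the grid centre,
#' with corners at polar angles 0, 60, ..., 300 degrees.
#'
#' @param M_dim Grid side in cells (>= 2).
#' @return Logical matrix; `TRUE` inside the hexagon.
#' @export
#' @examples
#' mean(hex_mask(256))        # ~ 3*sqrt(3)/8
hex_mask <- function(M_dim) {
  M <- as.integer(M_dim)
  if (M < 2L) stop("M_dim must be >= 2", call. = FALSE)
  ctr <- M / 2
  x <- (seq_len(M) - 0.5) - ctr  # cell-centre offsets
  dx <- matrix(x, M, M, byrow = TRUE)   # column offset
  dy <- matrix(x, M, M)                 # row offset
  apo <- (M / 2) * sqrt(3) / 2
  eps <- 1e-9
  inside <- (abs(dx * cos(pi / 6) + dy * sin(pi / 6)) <= apo + eps) &
    (abs(dy) <= apo + eps) &
    (abs(dx * cos(5 * pi / 6) + dy * sin(5 * pi / 6)) <= apo + eps)
  inside
}

#' Planform area of a hexagon from its across-corner diameter
#'
#' `S = 3 * sqrt(3) * d^2 / 8`.
#'
#' @param d Across-corner diameter (any length unit; result in its square).
#' @return Hexagon area.
#' @export
#' @examples
#' hex_area(1536)  # ~1.53e6 (um^2 when d is in um)
hex_area <- function(d) {
  stopifnot(all(d >= 0))
  3 * sqrt(3) * d^2 / 8
}

## hexagon corner cells (r, c), rows = 6 corners in angle order 0..300 deg;
## coordinates round toward the grid centre so opposite corners mirror
hex_corner_cells <- function(M) {
  ang <- (0:5) * pi / 3
  ctr <- M / 2
  xx <- ctr + (M / 2) * cos(ang)
  yy <- ctr + (M / 2) * sin(ang)
  cl <- function(v) {
    inward <- ifelse(v >= ctr, ceiling(v - 1e-9), floor(v + 1e-9) + 1)
    pmin(M, pmax(1L, as.integer(inward)))
  }
  cbind(r = cl(yy), c = cl(xx))
}

## in-hexagon cells within Chebyshev radius 1 of a centre cell, as k x 2
port_block <- function(cell, mask) {
  M <- nrow(mask)
  rr <- max(1L, cell[1] - 1L):min(M, cell[1] + 1L)
  cc <- max(1L, cell[2] - 1L):min(M, cell[2] + 1L)
  g <- as.matrix(expand.grid(r = rr, c = cc))
  g[mask[g], , drop = FALSE]
}

#' Diffusion-limited aggregation on a masked lattice
#'
#' Grows a cluster by sequential biased random walkers on the 8-neighbour
#' lattice. A `dp x dp` nucleus footprint is pre-placed so the first walker
#' has something to stick to; each walker launches at a uniformly random
#' free in-domain cell, steps with probability `bias` toward the nucleus and
#' otherwise in a uniformly random direction (step length `dp`), relaunches
#' if it leaves the domain, and sticks as soon as any footprint cell is
#' 8-adjacent to the cluster. Deterministic given the R RNG state.
#'
#' @param domain Logical matrix: walkable cells.
#' @param n_particles Number of walkers to attach (>= 0).
#' @param dp Step and footprint size in cells.
#' @param nucleus Integer `c(row, col)` of the nucleus (inside the domain).
#' @param bias Centre-seeking step probability in [0, 1].
#' @param max_steps Walk length before a walker is relaunched; default
#'   `200 * max(dim(domain))`.
#' @return Integer 0/1 occupancy matrix of the same shape as `domain`.
#' @export
#' @examples
#' set.seed(1)
#' occ <- dla_aggregate(matrix(TRUE, 64, 64), 50, 1, c(32, 32))
#' sum(occ)  # 51 = nucleus + 50 walkers
dla_aggregate <- function(domain, n_particles, dp = 1L, nucleus,
                          bias = 0.5, max_steps = NULL) {
  stopifnot(is.matrix(domain), n_particles >= 0)
  nucleus <- as.integer(nucleus)
  if (nucleus[1] < 1 || nucleus[1] > nrow(domain) ||
      nucleus[2] < 1 || nucleus[2] > ncol(domain) ||
      !domain[nucleus[1], nucleus[2]]) {
    stop("nucleus lies outside the walk domain", call. = FALSE)
  }
  max_steps <- as.integer(max_steps %||% (200L * max(dim(domain))))
  dla_aggregate_cpp(domain, as.integer(n_particles), as.integer(dp),
                    nucleus[1] - 1L, nucleus[2] - 1L, bias, max_steps)
}

#' Build a 2D hexagonal lobule morphology
#'
#' Runs the five-stage sequential DLA recipe, clips to the bounding hexagon,
#' labels the remaining cells tissue, stamps the central inlet (portal vein)
#' and six corner outlet (hepatic vein) port blocks as sinusoid, and bridges
#' any sinusoid fragment not 8-connected to the inlet so that the flow
#' problem is solvable on every seed.
#'
#' @param recipe A [dla_recipe()].
#' @param seed Master seed; defaults to `recipe$seed`.
#' @return Object of class `c("lobule_2d", "lobule")` with elements
#'   `labels` (`M x M` integer matrix, see [lobule_labels()]), `inlet_cells`
#'   (k x 2), `outlet_cells` (named list `A`..`F` of k x 2 matrices, ports
#'   labeled counter-clockwise from the east corner), `cell_size_um`,
#'   `layer_thickness_um`, `recipe`, `seed`, `n_bridged`.
#' @export
#' @examples
#' m <- build_lobule_2d(dla_recipe(M_dim = 32, seed = 7))
#' sinusoid_area_fraction(m)
build_lobule_2d <- function(recipe, seed = recipe$seed) {
  stopifnot(inherits(recipe, "dla_recipe"))
  M <- recipe$M_dim
  sub_seeds <- derive_seeds(seed, 9L)
  full <- matrix(TRUE, M, M)
  ctr_cell <- rep(as.integer(ceiling(M / 2)), 2)

  run <- function(s, domain, n, dp, nucleus) {
    withr::with_seed(s,
      dla_aggregate(domain, n, dp, nucleus, bias = recipe$bias))
  }

  ## (i) main aggregation on the full field
  occ <- run(sub_seeds[1], full, recipe$N_par, recipe$dp, ctr_cell)

  ## (ii) erase: independent aggregation on the centred half-size subdomain,
  ## subtracted from the main field ("zero-valued particles")
  half <- M %/% 2L
  lo <- M %/% 4L + 1L
  hi <- lo + half - 1L
  sub <- matrix(TRUE, half, half)
  sub_ctr <- c(half %/% 2L, half %/% 2L)
  erase <- run(sub_seeds[2], sub, recipe$N_cen1_par, 1L, sub_ctr)
  blk <- occ[lo:hi, lo:hi]
  blk[erase == 1L] <- 0L
  ## (iii) refill with dp = 2 walkers
  refill <- run(sub_seeds[3], sub, recipe$N_cen2_par, 2L, sub_ctr)
  blk[refill == 1L] <- 1L
  occ[lo:hi, lo:hi] <- blk

  ## (iv) corner wells on M/3 subdomains centred on each hexagon corner
  corners <- hex_corner_cells(M)
  s_cor <- max(2L, as.integer(round(M / 3)))
  for (k in 1:6) {
    r0 <- corners[k, 1] - s_cor %/% 2L
    c0 <- corners[k, 2] - s_cor %/% 2L
    rr <- max(1L, r0):min(M, r0 + s_cor - 1L)
    cc <- max(1L, c0):min(M, c0 + s_cor - 1L)
    dom <- matrix(TRUE, length(rr), length(cc))
    nuc <- c(corners[k, 1] - rr[1] + 1L, corners[k, 2] - cc[1] + 1L)
    cor_occ <- run(sub_seeds[3L + k], dom, recipe$N_cor_par, 1L, nuc)
    blk <- occ[rr, cc]
    blk[cor_occ == 1L] <- 1L
    occ[rr, cc] <- blk
  }

  ## (v) clip to the bounding hexagon and label
  mask <- hex_mask(M)
  labels <- matrix(.LBL[["OUTSIDE"]], M, M)
  labels[mask] <- .LBL[["TISSUE"]]
  labels[mask & occ == 1L] <- .LBL[["SINUSOID"]]

  ## ports: 3x3 in-hexagon blocks at the centre and the six corners
  inlet <- port_block(ctr_cell, mask)
  outlets <- lapply(1:6, function(k) port_block(corners[k, ], mask))
  names(outlets) <- LETTERS[1:6]
  for (cells in c(list(inlet), outlets)) {
    labels[cells] <- .LBL[["SINUSOID"]]
  }
  if (any(vapply(outlets, nrow, 1L) == 0L) || nrow(inlet) == 0L) {
    stop("lobule generation failed: empty port block", call. = FALSE)
  }

  rep <- repair_connectivity_cpp(labels, inlet - 1L)
  labels <- rep$labels
  if (!any(labels == .LBL[["SINUSOID"]])) {
    stop("lobule generation failed: empty sinusoid set", call. = FALSE)
  }

  structure(list(labels = labels, inlet_cells = inlet,
                 outlet_cells = outlets, cell_size_um = 6,
                 layer_thickness_um = 6, recipe = recipe,
                 seed = as.integer(seed), n_bridged = rep$n_bridged),
            class = c("lobule_2d", "lobule"))
}

#' Sinusoid area fraction of a lobule
#'
#' Ratio of sinusoid-labeled cells (vein/port cells included) to all active
#' (in-hexagon) cells.
#'
#' @param m A lobule morphology.
#' @return Fraction in [0, 1].
#' @export
sinusoid_area_fraction <- function(m) {
  stopifnot(inherits(m, "lobule"))
  active <- m$labels != .LBL[["OUTSIDE"]]
  if (!any(active)) stop("morphology has no active cells", call. = FALSE)
  sum(m$labels == .LBL[["SINUSOID"]]) / sum(active)
}

#' @export
print.lobule_2d <- function(x, ...) {
  cat(sprintf(
    "2D lobule: %d x %d cells (%.0f um), sinusoid fraction %.3f, seed %d, %d bridged cells\n",
    nrow(x$labels), ncol(x$labels), x$cell_size_um,
    sinusoid_area_fraction(x), x$seed, x$n_bridged))
  invisible(x)
}

#' Assemble a lobule morphology from an explicit label matrix or array
#'
#' Low-level constructor for hand-built or image-derived geometries (e.g. a
#' straight channel for verification runs, or a segmented sinusoid mask).
#' No hexagon clipping, port stamping or connectivity repair is applied.
#'
#' @param labels Integer matrix (2D) or 3D array of [lobule_labels()] codes.
#' @param inlet_cells Integer k x 2 (or k x 3 for arrays) matrix of inlet
#'   cell indices (1-based row, col[, layer]).
#' @param outlet_cells Named list of outlet cell matrices, one per port.
#' @param cell_size_um Lateral cell size, um.
#' @param layer_thickness_um Per-layer thickness, um (scalar for 2D,
#'   vector of length `dim(labels)[3]` for 3D).
#' @return A `"lobule"` object as from [build_lobule_2d()] /
#'   [build_lobule_3d()].
#' @export
lobule_morphology <- function(labels, inlet_cells, outlet_cells,
                              cell_size_um = 6,
                              layer_thickness_um = cell_size_um) {
  if (!all(labels %in% .LBL)) {
    stop("labels must use codes from lobule_labels()", call. = FALSE)
  }
  labels[] <- as.integer(labels)
  is3d <- length(dim(labels)) == 3L
  if (is3d && length(layer_thickness_um) != dim(labels)[3]) {
    stop("layer_thickness_um must have one entry per layer", call. = FALSE)
  }
  structure(list(labels = labels, inlet_cells = as.matrix(inlet_cells),
                 outlet_cells = lapply(outlet_cells, as.matrix),
                 cell_size_um = cell_size_um,
                 layer_thickness_um = layer_thickness_um,
                 recipe = NULL, seed = NA_integer_, n_bridged = 0L),
            class = c(if (is3d) "lobule_3d" else "lobule_2d", "lobule"))
}
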