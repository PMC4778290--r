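## 3D lobule: stacked 2D DLA layers, tissue slabs, vertical connectors and
## vein columns.

#' Recipe for the stacked 3D lobule
#'
#' The 3D lobule alternates DLA (sinusoid) layers with `M_skip` tissue
#' (hepatocyte) layers, starting and ending on a DLA layer, so
#' `M_z_dim = n_dla + (n_dla - 1) * M_skip`. Defaults give the reference
#' stack of 33 DLA and 64 tissue layers (`M_z_dim = 97`, `M_skip = 2`) with
#' 6 um DLA layers and 12 um tissue layers (hepatocyte thickness).
#'
#' @param M_z_dim Total number of layers.
#' @param M_skip Tissue layers between consecutive DLA layers.
#' @param connector_fraction Fraction of in-hexagon columns per tissue slab
#'   that receive a vertical sinusoid connector (default 0.01).
#' @param dz_sinusoid_um,dz_tissue_um Layer thicknesses, um.
#' @param seed Master RNG seed.
#' @param layer_recipe [dla_recipe()] used for every DLA layer (each layer
#'   gets its own sub-seed).
#' @return Object of class `"stack_recipe"`.
#' @export
#' @examples
#' layer_plan(97, 2)$n_dla  # 33
stack_recipe <- function(M_z_dim = 97L, M_skip = 2L,
                         connector_fraction = 0.01, dz_sinusoid_um = 6,
                         dz_tissue_um = 12, seed = 1L,
                         layer_recipe = dla_recipe()) {
  plan <- layer_plan(M_z_dim, M_skip)  # validates the alternation arithmetic
  stopifnot(connector_fraction >= 0, connector_fraction <= 1,
            dz_sinusoid_um > 0, dz_tissue_um > 0,
            inherits(layer_recipe, "dla_recipe"))
  structure(list(M_z_dim = as.integer(M_z_dim), M_skip = as.integer(M_skip),
                 connector_fraction = connector_fraction,
                 dz_sinusoid_um = dz_sinusoid_um,
                 dz_tissue_um = dz_tissue_um, seed = as.integer(seed),
                 layer_recipe = layer_recipe, plan = plan),
            class = "stack_recipe")
}

#' Layer alternation plan of the 3D stack
#'
#' DLA layers sit at z = 1, M_skip + 2, 2 (M_skip + 1) + 1, ..., M_z_dim
#' (1-based); everything else is tissue.
#'
#' @param M_z_dim Total layers.
#' @param M_skip Tissue layers between DLA layers.
#' @return List with `n_dla`, `n_tissue` and `dla_z` (1-based DLA layer
#'   indices).
#' @export
#' @examples
#' layer_plan(7, 2)$dla_z  # 1 4 7
layer_plan <- function(M_z_dim, M_skip) {
  M_z_dim <- as.integer(M_z_dim)
  M_skip <- as.integer(M_skip)
  if (M_z_dim < 1L || M_skip < 0L ||
      (M_z_dim - 1L) %% (M_skip + 1L) != 0L) {
    stop("inconsistent stack: need M_z_dim = n_dla + (n_dla - 1) * M_skip",
         call. = FALSE)
  }
  dla_z <- seq.int(1L, M_z_dim, by = M_skip + 1L)
  list(n_dla = length(dla_z), n_tissue = M_z_dim - length(dla_z),
       dla_z = dla_z)
}

## 3x3 (8-neighbour) logical dilation
dilate3 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rt <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    ct <- max(1, 1 - dc):min(nc, nc - dc)
    out[rt, ct] <- out[rt, ct] | m[rs, cs]
  }
  out
}

#' Build a 3D lobule morphology
#'
#' Stacks independently generated 2D DLA layers separated by all-tissue
#' slabs, adds vertical 1-cell sinusoid connectors at random columns where
#' both bounding DLA layers carry a sinusoid within Chebyshev radius 1, and
#' stamps the central portal-vein column and six corner hepatic-vein columns
#' as sinusoid through every layer.
#'
#' @param recipe A [stack_recipe()].
#' @param seed Master seed; defaults to `recipe$seed`.
#' @return Object of class `c("lobule_3d", "lobule")`: `labels`
#'   (`M x M x M_z` integer array), `layer_kind` (per-layer `"DLA"` /
#'   `"TISSUE"`), `layer_thickness_um` (per-layer), `connectors`
#'   (data.frame `row, col, z_from, z_to`), `inlet_cells` / `outlet_cells`
#'   as k x 3 index matrices spanning all layers.
#' @export
build_lobule_3d <- function(recipe, seed = recipe$seed) {
  stopifnot(inherits(recipe, "stack_recipe"))
  plan <- recipe$plan
  lr <- recipe$layer_recipe
  M <- lr$M_dim
  Mz <- recipe$M_z_dim
  seeds <- derive_seeds(seed, plan$n_dla + 1L)
  conn_seed <- seeds[plan$n_dla + 1L]

  mask <- hex_mask(M)
  n_hex <- sum(mask)
  labels <- array(.LBL[["OUTSIDE"]], dim = c(M, M, Mz))
  layer_kind <- rep("TISSUE", Mz)
  layer_kind[plan$dla_z] <- "DLA"
  thick <- ifelse(layer_kind == "DLA", recipe$dz_sinusoid_um,
                  recipe$dz_tissue_um)

  tissue_layer <- matrix(.LBL[["OUTSIDE"]], M, M)
  tissue_layer[mask] <- .LBL[["TISSUE"]]
  layers2d <- vector("list", plan$n_dla)
  for (i in seq_len(plan$n_dla)) {
    layers2d[[i]] <- build_lobule_2d(lr, seed = seeds[i])
    labels[, , plan$dla_z[i]] <- layers2d[[i]]$labels
  }
  for (z in setdiff(seq_len(Mz), plan$dla_z)) {
    labels[, , z] <- tissue_layer
  }

  ## vertical connectors through each tissue slab
  connectors <- list()
  if (plan$n_dla > 1L && recipe$M_skip > 0L) {
    n_conn <- as.integer(round(recipe$connector_fraction * n_hex))
    withr::with_seed(conn_seed, {
      for (i in seq_len(plan$n_dla - 1L)) {
        z1 <- plan$dla_z[i]
        z2 <- plan$dla_z[i + 1L]
        below <- dilate3(labels[, , z1] == .LBL[["SINUSOID"]])
        above <- dilate3(labels[, , z2] == .LBL[["SINUSOID"]])
        eligible <- which(mask & below & above)
        if (n_conn > 0L && length(eligible) == 0L) {
          stop("no eligible connector sites between DLA layers ", z1,
               " and ", z2, call. = FALSE)
        }
        take <- eligible[sample.int(length(eligible),
                                    min(n_conn, length(eligible)))]
        if (length(take)) {
          rc <- arrayInd(take, c(M, M))
          for (z in (z1 + 1L):(z2 - 1L)) {
            labels[cbind(rc, z)] <- .LBL[["SINUSOID"]]
          }
          connectors[[length(connectors) + 1L]] <-
            data.frame(row = rc[, 1], col = rc[, 2], z_from = z1 + 1L,
                       z_to = z2 - 1L)
        }
      }
    })
  }
  connectors <- if (length(connectors)) do.call(rbind, connectors) else
    data.frame(row = integer(), col = integer(), z_from = integer(),
               z_to = integer())

  ## vein columns: port blocks of the first DLA layer, stamped in all layers
  base2d <- layers2d[[1]]
  stamp_col <- function(cells2d) {
    out <- vector("list", Mz)
    for (z in seq_len(Mz)) {
      labels[cbind(cells2d, z)] <<- .LBL[["SINUSOID"]]
      out[[z]] <- cbind(cells2d, layer = z)
    }
    do.call(rbind, out)
  }
  inlet <- stamp_col(base2d$inlet_cells)
  outlets <- lapply(base2d$outlet_cells, stamp_col)

  structure(list(labels = labels, layer_kind = layer_kind,
                 layer_thickness_um = thick, connectors = connectors,
                 inlet_cells = inlet, outlet_cells = outlets,
                 cell_size_um = base2d$cell_size_um, recipe = recipe,
                 seed = as.integer(seed),
                 n_bridged = sum(vapply(layers2d, `[[`, 1L, "n_bridged"))),
            class = c("lobule_3d", "lobule"))
}

#' @export
print.lobule_3d <- function(x, ...) {
  g <- geometry_summary(x)
  cat(sprintf(
    "3D lobule: %d x %d x %d cells, %d DLA / %d tissue layers, V = %.3g mm3, seed %d\n",
    dim(x$labels)[1], dim(x$labels)[2], dim(x$labels)[3],
    sum(x$layer_kind == "DLA"), sum(x$layer_kind == "TISSUE"),
    g$V_mm3, x$seed))
  invisible(x)
}

#' Geometric summary of a lobule
#'
#' Planform hexagon area, stack height and bulk model volume.
#'
#' @param m A lobule morphology.
#' @return List with `S_um2` (hexagon area), `height_um` (sum of layer
#'   thicknesses) and `V_mm3` (`S * height`).
#' @export
#' @examples
#' # reference stack: ~1.48 mm3
#' plan <- layer_plan(97, 2)
#' h <- plan$n_dla * 6 + plan$n_tissue * 12
#' hex_area(256 * 6) * h / 1e9
geometry_summary <- function(m) {
  stopifnot(inherits(m, "lobule"))
  M <- nrow(m$labels)
  S <- hex_area(M * m$cell_size_um)
  height <- sum(m$layer_thickness_um)
  list(S_um2 = S, height_um = height, V_mm3 = S * height / 1e9)
}
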