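## Shared fixtures: reduced-scale recipes keep subdomain particle densities
## equal to the reference (area scaling) so the tiny lattice is two-phase
## and unsaturated; built objects are cached per session.

area_recipe <- function(M = 32L, seed = 1L, ...) {
  f <- (M / 256)^2
  dla_recipe(M_dim = M, N_par = round(9500 * f),
             N_cen1_par = round(1200 * f), N_cen2_par = round(800 * f),
             N_cor_par = round(500 * f), seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

tiny_lobule <- function(seed = 1L) {
  cached(paste0("tiny", seed), build_lobule_2d(area_recipe(32L, seed)))
}

tiny_flow <- function(seed = 1L, delta_p = 50) {
  cached(paste0("tinyflow", seed, "_", delta_p), {
    props <- assign_properties(tiny_lobule(seed))
    solve_pressure(props, well_config(delta_p_Pa = delta_p))
  })
}

## straight channel: `width` sinusoid rows flanked by `tissue_rows` tissue
## rows on each side; wells at the two ends of the sinusoid rows
channel_morphology <- function(len = 60L, width = 1L, tissue_rows = 0L,
                               cell_size_um = 6) {
  nr <- width + 2L * tissue_rows
  labels <- matrix(lobule_labels()[["TISSUE"]], nr, len)
  srows <- tissue_rows + seq_len(width)
  labels[srows, ] <- lobule_labels()[["SINUSOID"]]
  inlet <- cbind(srows, 1L)
  outlet <- list(A = cbind(srows, len))
  lobule_morphology(labels, inlet, outlet, cell_size_um = cell_size_um)
}

## all-tissue channel (first-order uptake along the flow path)
tissue_channel <- function(len = 40L) {
  labels <- matrix(lobule_labels()[["TISSUE"]], 1L, len)
  lobule_morphology(labels, cbind(1L, 1L), list(A = cbind(1L, len)))
}

## independent 8-connectivity BFS oracle (R implementation, no package code)
bfs_reach8 <- function(mask, seeds) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  vis <- matrix(FALSE, nr, nc)
  queue <- list()
  for (i in seq_len(nrow(seeds))) {
    r <- seeds[i, 1]; c <- seeds[i, 2]
    if (mask[r, c] && !vis[r, c]) {
      vis[r, c] <- TRUE
      queue[[length(queue) + 1L]] <- c(r, c)
    }
  }
  while (length(queue)) {
    cell <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- cell[1] + dr; c2 <- cell[2] + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          mask[r2, c2] && !vis[r2, c2]) {
        vis[r2, c2] <- TRUE
        queue[[length(queue) + 1L]] <- c(r2, c2)
      }
    }
  }
  vis
}
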