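## Steady single-phase Darcy pressure solve on the labeled lattice.
## Internal units are SI (m, Pa, s); port rates are reported in cm^3/min.

.M3S_TO_CM3MIN <- 6e7

#' Inlet/outlet well configuration
#'
#' Wells are Dirichlet pressure cells: the central inlet block is held at
#' `p_out + delta_p`, the six corner outlet blocks at `p_out`. Exactly one of
#' `delta_p_Pa` (direct mode) or `target_inflow_cm3_min` (calibration mode,
#' see [calibrate_delta_p()]) must be given.
#'
#' @param delta_p_Pa Pressure drop inlet minus outlet, Pa (> 0).
#' @param p_out_Pa Outlet pressure datum, Pa (default 0).
#' @param target_inflow_cm3_min Target total volumetric inflow for
#'   calibration mode, cm^3/min (> 0).
#' @return Object of class `"well_config"`.
#' @export
well_config <- function(delta_p_Pa = NULL, p_out_Pa = 0,
                        target_inflow_cm3_min = NULL) {
  has_dp <- !is.null(delta_p_Pa)
  has_ti <- !is.null(target_inflow_cm3_min)
  if (has_dp == has_ti) {
    stop("give exactly one of delta_p_Pa or target_inflow_cm3_min",
         call. = FALSE)
  }
  if (has_dp && delta_p_Pa <= 0) stop("delta_p_Pa must be > 0",
                                      call. = FALSE)
  if (has_ti && target_inflow_cm3_min <= 0) {
    stop("target_inflow_cm3_min must be > 0", call. = FALSE)
  }
  structure(list(delta_p_Pa = delta_p_Pa, p_out_Pa = p_out_Pa,
                 target_inflow_cm3_min = target_inflow_cm3_min),
            class = "well_config")
}

#' Map medium properties onto a lobule lattice
#'
#' Label-driven per-cell porosity, permeability and effective diffusivity:
#' sinusoid cells get the sinusoid column of the [medium_table()], tissue
#' cells the tissue column; outside cells are inactive. The sinusoid-tissue
#' interface is a plain lattice transmissibility between unlike cells (the
#' space-of-Disse exchange is convective, with no extra membrane
#' resistance).
#'
#' @param m A lobule morphology.
#' @param tbl A [medium_table()].
#' @return Object of class `"property_fields"`: active-cell index map plus
#'   `phi`, `K_m2`, `D_m2s` vectors over active cells.
#' @export
assign_properties <- function(m, tbl = medium_table()) {
  stopifnot(inherits(m, "lobule"), inherits(tbl, "medium_table"))
  lab <- m$labels
  if (!all(lab %in% .LBL)) stop("morphology contains unlabeled cells",
                                call. = FALSE)
  dims <- dim(lab)
  if (length(dims) == 2L) dims <- c(dims, 1L)
  active <- which(lab != .LBL[["OUTSIDE"]])
  if (length(active) == 0L) stop("morphology has no active cells",
                                 call. = FALSE)
  idx <- array(0L, dim = dims)
  idx[active] <- seq_along(active)
  sin_cell <- lab[active] == .LBL[["SINUSOID"]]
  structure(list(
    morph = m, dims = dims, active = active, idx = idx,
    is_sinusoid = sin_cell,
    phi = ifelse(sin_cell, tbl$phi_sin, tbl$phi_tis),
    K_m2 = ifelse(sin_cell, tbl$K_sin_m2, tbl$K_tis_m2),
    D_m2s = ifelse(sin_cell, tbl$D_sin_m2s, tbl$D_tis_m2s),
    medium = tbl
  ), class = "property_fields")
}

## active-cell id of (row, col[, layer]) index matrix
cells_to_ids <- function(props, cells) {
  if (ncol(cells) == 2L) cells <- cbind(cells, 1L)
  ids <- props$idx[cells]
  if (any(ids == 0L)) stop("port cell is not an active lattice cell",
                           call. = FALSE)
  ids
}

## Link table for the lattice graph. Each link between active cells a and b
## carries weight w (areal 9-point: 2/3 face, 1/3 diagonal; five_point:
## face only), interface area A (m^2) and the two half-distances La, Lb (m)
## for harmonic interface averaging: T = w / (La/(A*Ka) + Lb/(A*Kb)).
## In-plane diagonal links use a face's geometric factor (lattice-unit
## convention); vertical links use per-layer half-thicknesses.
build_links <- function(props, scheme = c("nine_point", "five_point")) {
  scheme <- match.arg(scheme)
  dims <- props$dims
  nr <- dims[1]; nc <- dims[2]; nz <- dims[3]
  h <- props$morph$cell_size_um * 1e-6
  tz <- rep(props$morph$layer_thickness_um, length.out = nz) * 1e-6
  idx <- props$idx

  off_face <- list(c(1L, 0L), c(0L, 1L))
  off_diag <- list(c(1L, 1L), c(1L, -1L))
  wf <- if (scheme == "nine_point") 2 / 3 else 1
  wd <- if (scheme == "nine_point") 1 / 3 else 0

  ia <- ib <- integer(0)
  w <- A <- La <- Lb <- numeric(0)
  ## diagonal links carry the physical diagonal geometry (length sqrt(2) h,
  ## width h/sqrt(2)), i.e. half a face's geometric factor; together with
  ## the 2/3 / 1/3 weights the uniform-medium effective conductivity equals
  ## the 5-point one exactly (2/3 + 2 * 1/3 * 1/2 = 1)
  add_inplane <- function(offs, wt, diag) {
    for (off in offs) {
      dr <- off[1]; dc <- off[2]
      rs <- seq_len(nr - abs(dr))
      cs <- if (dc >= 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
      a <- idx[rs, cs, , drop = FALSE]
      b <- idx[rs + dr, cs + dc, , drop = FALSE]
      keep <- a > 0L & b > 0L
      if (!any(keep)) next
      zi <- slice.index(a, 3)[keep]
      na <- sum(keep)
      ia <<- c(ia, a[keep]); ib <<- c(ib, b[keep])
      w <<- c(w, rep(wt, na))
      A <<- c(A, (if (diag) h / sqrt(2) else h) * tz[zi])
      half <- if (diag) h / sqrt(2) else h / 2
      La <<- c(La, rep(half, na)); Lb <<- c(Lb, rep(half, na))
    }
  }
  add_inplane(off_face, wf, diag = FALSE)
  if (wd > 0) add_inplane(off_diag, wd, diag = TRUE)
  if (nz > 1L) {
    a <- idx[, , seq_len(nz - 1L), drop = FALSE]
    b <- idx[, , seq.int(2L, nz), drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) {
      zi <- slice.index(a, 3)[keep]
      na <- sum(keep)
      ia <- c(ia, a[keep]); ib <- c(ib, b[keep])
      w <- c(w, rep(1, na))
      A <- c(A, rep(h * h, na))
      La <- c(La, tz[zi] / 2); Lb <- c(Lb, tz[zi + 1L] / 2)
    }
  }
  list(ia = ia, ib = ib, w = w, A = A, La = La, Lb = Lb, scheme = scheme,
       h = h, tz = tz)
}

## harmonic-interface transmissibility-like coefficient for per-cell field f:
## w / (La/(A fa) + Lb/(A fb)); zero where either side is zero
link_coef <- function(links, f) {
  fa <- f[links$ia]
  fb <- f[links$ib]
  out <- numeric(length(fa))
  ok <- fa > 0 & fb > 0
  out[ok] <- links$w[ok] /
    (links$La[ok] / (links$A[ok] * fa[ok]) +
       links$Lb[ok] / (links$A[ok] * fb[ok]))
  out
}

#' Solve the steady Darcy pressure field
#'
#' Finite-volume discretization of `div((K/mu) grad p) = 0` on the active
#' lattice with harmonic-mean interface permeability, Dirichlet pressures on
#' the inlet/outlet well cells, and either the areal 9-point stencil
#' (default; diagonal in-plane links carry 1/3 of the transmissibility to
#' reduce grid-orientation bias) or the plain 5-point stencil. The sparse
#' SPD system is solved by Cholesky factorization and checked to a relative
#' residual of 1e-10.
#'
#' @param props [assign_properties()] output.
#' @param wells [well_config()]; calibration mode is dispatched to
#'   [calibrate_delta_p()] automatically.
#' @param scheme `"nine_point"` (default) or `"five_point"`.
#' @return Object of class `"flow_solution"`: `pressure_Pa` (array, NA
#'   outside), per-link fluxes, `port_rates_cm3_min` (named, positive out of
#'   the lobule), `total_inflow_cm3_min`, `delta_p_Pa`, and the diagnostic
#'   `interstitial_speed_cm_min` array.
#' @export
solve_pressure <- function(props, wells,
                           scheme = c("nine_point", "five_point")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(props, "property_fields"), inherits(wells,
                                                         "well_config"))
  if (is.null(wells$delta_p_Pa)) {
    wells <- calibrate_delta_p(props, wells, scheme)
  }
  m <- props$morph
  n <- length(props$active)
  links <- build_links(props, scheme)
  mu <- props$medium$mu_Pas
  Tr <- link_coef(links, props$K_m2) / mu  # m^3 / (Pa s)

  inlet_ids <- cells_to_ids(props, m$inlet_cells)
  outlet_ids <- lapply(m$outlet_cells, cells_to_ids, props = props)
  fixed <- c(inlet_ids, unlist(outlet_ids, use.names = FALSE))
  if (anyDuplicated(fixed)) stop("inlet and outlet wells overlap",
                                 call. = FALSE)
  p_fix <- rep(wells$p_out_Pa, length(fixed))
  p_fix[seq_along(inlet_ids)] <- wells$p_out_Pa + wells$delta_p_Pa
  is_fixed <- logical(n)
  is_fixed[fixed] <- TRUE
  pf <- numeric(n)
  pf[fixed] <- p_fix

  free <- which(!is_fixed)
  map <- integer(n)
  map[free] <- seq_along(free)

  ff <- !is_fixed[links$ia] & !is_fixed[links$ib]
  fa_fb <- xor(is_fixed[links$ia], is_fixed[links$ib])

  ## graph Laplacian restricted to free cells
  i1 <- map[links$ia[ff]]; j1 <- map[links$ib[ff]]; t1 <- Tr[ff]
  dii <- c(map[links$ia], map[links$ib])
  keepd <- dii > 0L
  Afree <- Matrix::sparseMatrix(
    i = c(i1, j1, dii[keepd]),
    j = c(j1, i1, dii[keepd]),
    x = c(-t1, -t1, rep(Tr, 2)[keepd]),
    dims = c(length(free), length(free))
  )
  b <- numeric(length(free))
  if (any(fa_fb)) {
    la <- links$ia[fa_fb]; lb <- links$ib[fa_fb]; tt <- Tr[fa_fb]
    fre <- ifelse(is_fixed[la], lb, la)
    fix <- ifelse(is_fixed[la], la, lb)
    bb <- tt * pf[fix]
    agg <- rowsum(bb, map[fre])
    b[as.integer(rownames(agg))] <- agg[, 1]
  }
  p <- pf
  if (length(free)) {
    sol <- Matrix::solve(methods::as(Matrix::forceSymmetric(Afree),
                                     "CsparseMatrix"), b)
    p[free] <- as.numeric(sol)
    res <- sqrt(sum((Afree %*% sol - b)^2))
    nb <- sqrt(sum(b^2))
    if (nb > 0 && res / nb > 1e-10) {
      stop(sprintf("pressure solve did not converge (relative residual %.2e)",
                   res / nb), call. = FALSE)
    }
  }

  q <- Tr * (p[links$ia] - p[links$ib])  # m^3/s, positive a -> b

  ## per-port production (flow out of the lobule into the port block)
  net_flux <- function(ids) {
    inset <- logical(n)
    inset[ids] <- TRUE
    sel_a <- inset[links$ia] & !inset[links$ib]
    sel_b <- inset[links$ib] & !inset[links$ia]
    sum(-q[sel_a]) + sum(q[sel_b])  # flow into the set
  }
  port_in <- vapply(outlet_ids, net_flux, numeric(1))
  total_in <- -net_flux(inlet_ids)  # inlet block is a net source
  if (total_in <= 0) {
    stop("no flow from inlet to outlets (disconnected wells?)",
         call. = FALSE)
  }
  cons <- abs(sum(port_in) - total_in) / total_in
  if (cons > 1e-8) {
    stop(sprintf("flow conservation violated: |sum(ports) - inflow|/inflow = %.2e",
                 cons), call. = FALSE)
  }

  ## interstitial speed diagnostic |u|/phi, cm/min
  absq <- abs(q)
  acc <- numeric(n)
  acc_a <- rowsum(absq, links$ia)
  acc[as.integer(rownames(acc_a))] <- acc[as.integer(rownames(acc_a))] +
    acc_a[, 1]
  acc_b <- rowsum(absq, links$ib)
  acc[as.integer(rownames(acc_b))] <- acc[as.integer(rownames(acc_b))] +
    acc_b[, 1]
  zi <- slice.index(array(seq_len(prod(props$dims)), props$dims), 3)
  face_area <- links$h * links$tz[zi[props$active]]
  speed <- (acc / 2) / (face_area * props$phi) * 100 * 60  # cm/min

  parr <- array(NA_real_, props$dims)
  parr[props$active] <- p
  sarr <- array(NA_real_, props$dims)
  sarr[props$active] <- speed

  structure(list(
    pressure_Pa = parr, links = links, Tr = Tr, q_m3s = q,
    port_rates_cm3_min = port_in * .M3S_TO_CM3MIN,
    total_inflow_cm3_min = total_in * .M3S_TO_CM3MIN,
    delta_p_Pa = wells$delta_p_Pa, p_out_Pa = wells$p_out_Pa,
    scheme = scheme, props = props,
    inlet_ids = inlet_ids, outlet_ids = outlet_ids,
    interstitial_speed_cm_min = sarr
  ), class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("Darcy flow (%s): dP = %.4g Pa, inflow %.4g cm3/min\n",
              x$scheme, x$delta_p_Pa, x$total_inflow_cm3_min))
  print(signif(x$port_rates_cm3_min, 4))
  invisible(x)
}

#' Calibrate the pressure drop to a target total inflow
#'
#' The Darcy problem is linear in the pressure drop, so a single unit
#' solve fixes the lobule conductance; the pressure drop is then scaled so
#' the total inflow matches the target exactly.
#'
#' @param props [assign_properties()] output.
#' @param wells [well_config()] with `target_inflow_cm3_min` set.
#' @param scheme Discretization scheme.
#' @return A [well_config()] in direct mode with `delta_p_Pa` set.
#' @export
calibrate_delta_p <- function(props, wells,
                              scheme = c("nine_point", "five_point")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(wells, "well_config"))
  target <- wells$target_inflow_cm3_min
  if (is.null(target)) stop("wells must carry target_inflow_cm3_min",
                            call. = FALSE)
  unit <- solve_pressure(props,
                         well_config(delta_p_Pa = 1,
                                     p_out_Pa = wells$p_out_Pa),
                         scheme)
  q1 <- unit$total_inflow_cm3_min
  if (q1 <= 0) stop("unit-pressure solve produced no inflow", call. = FALSE)
  well_config(delta_p_Pa = target / q1, p_out_Pa = wells$p_out_Pa)
}

#' Per-port steady production rates
#'
#' @param sol A [solve_pressure()] solution.
#' @return Data frame with columns `port` and `rate_cm3_min`, plus the total
#'   inflow as attribute `total_inflow_cm3_min`.
#' @export
port_flow_rates <- function(sol) {
  stopifnot(inherits(sol, "flow_solution"))
  out <- data.frame(port = names(sol$port_rates_cm3_min),
                    rate_cm3_min = unname(sol$port_rates_cm3_min))
  attr(out, "total_inflow_cm3_min") <- sol$total_inflow_cm3_min
  out
}
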