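## Transient convection-diffusion-reaction transport of dissolved species on
## a solved steady flow field. Dilute-tracer assumption: species do not feed
## back on the flow. Time unit: minutes; volumes m^3; concentrations are
## mole fractions.

#' Transported species definition
#'
#' @param name Species name (e.g. `"PAC"`, `"PAC-OH"`).
#' @param D_sin_m2s,D_tis_m2s Effective diffusivity in sinusoid / tissue,
#'   m^2/s.
#' @param x_inject Mole fraction carried by inflowing blood at the inlet.
#' @return Object of class `"species_spec"`.
#' @export
species_spec <- function(name, D_sin_m2s = 4.2e-10, D_tis_m2s = 4.2e-11,
                         x_inject = 0) {
  stopifnot(D_sin_m2s >= 0, D_tis_m2s >= 0, x_inject >= 0, x_inject < 1)
  structure(list(name = name, D_sin_m2s = D_sin_m2s, D_tis_m2s = D_tis_m2s,
                 x_inject = x_inject), class = "species_spec")
}

#' @rdname species_spec
#' @export
pac_species <- function(x_inject = 1.8e-8) {
  species_spec("PAC", x_inject = x_inject)
}

#' @rdname species_spec
#' @export
pacoh_species <- function() species_spec("PAC-OH")

#' Substrate-to-product reaction specification
#'
#' One-to-one conversion of a substrate species to a product species in
#' tissue cells (hepatocyte metabolism), with Michaelis-Menten or linear
#' kinetics and an optional per-tissue-cell zonation multiplier.
#'
#' @param kinetics A [kinetic_params()].
#' @param substrate,product Species names.
#' @param zone Optional [cyp_from_o2()] zonation field; `NULL` means a
#'   uniform multiplier of 1.
#' @return Object of class `"reaction_spec"`.
#' @export
reaction_spec <- function(kinetics = kinetic_params(), substrate = "PAC",
                          product = "PAC-OH", zone = NULL) {
  stopifnot(inherits(kinetics, "kinetic_params"))
  if (!is.null(zone) && !inherits(zone, "zonation_field")) {
    stop("zone must be a zonation_field or NULL", call. = FALSE)
  }
  structure(list(kinetics = kinetics, substrate = substrate,
                 product = product, zone = zone),
            class = "reaction_spec")
}

#' Local consumption rate of the kinetic model
#'
#' `zone * vmax * x / (Km + x)` in Michaelis-Menten mode,
#' `zone * (vmax/Km) * x` in linear mode; mole fraction per minute.
#'
#' @param x Substrate mole fraction (>= 0, vectorized).
#' @param k A [kinetic_params()].
#' @param zone Zonation multiplier (default 1).
#' @return Consumption rate, mole fraction / min.
#' @export
#' @examples
#' k <- kinetic_params()
#' mm_rate(k$Km_mf, k)  # vmax / 2
mm_rate <- function(x, k, zone = 1) {
  stopifnot(inherits(k, "kinetic_params"), all(x >= 0))
  if (k$mode == "linear") {
    zone * k$k_lin_per_min * x
  } else {
    zone * k$vmax_mf_min * x / (k$Km_mf + x)
  }
}

#' Assemble a transport system
#'
#' Precomputes the upwind convection operator, well source/sink terms,
#' per-species diffusion operators and reaction bookkeeping for a flow
#' solution. Pass `flow = NULL` with explicit `props` for a closed box
#' (diffusion/reaction only).
#'
#' @param flow A [solve_pressure()] solution, or `NULL`.
#' @param species A [species_spec()] or list of them.
#' @param reactions Optional [reaction_spec()] or list of them.
#' @param diffusion Logical: build diffusion operators.
#' @param props [assign_properties()] output; required when `flow` is NULL.
#' @return An opaque system list consumed by [advance_state()] and
#'   [run_infusion()].
#' @export
transport_system <- function(flow, species, reactions = NULL,
                             diffusion = TRUE, props = NULL) {
  if (!is.null(flow)) {
    stopifnot(inherits(flow, "flow_solution"))
    props <- flow$props
  }
  stopifnot(inherits(props, "property_fields"))
  if (inherits(species, "species_spec")) species <- list(species)
  if (inherits(reactions, "reaction_spec")) reactions <- list(reactions)
  n <- length(props$active)
  sp_names <- vapply(species, `[[`, "", "name")

  ## pore volumes, m^3
  h <- props$morph$cell_size_um * 1e-6
  tz <- rep(props$morph$layer_thickness_um,
            length.out = props$dims[3]) * 1e-6
  zi <- slice.index(array(0L, props$dims), 3)[props$active]
  PV <- props$phi * h * h * tz[zi]

  conv <- NULL
  src_per_x <- numeric(n)   # external inflow rate per cell, m^3/min
  sink <- numeric(n)        # external production rate per cell, m^3/min
  if (!is.null(flow)) {
    links <- flow$links
    q <- flow$q_m3s * 60  # m^3/min, positive ia -> ib
    up <- ifelse(q >= 0, links$ia, links$ib)
    dn <- ifelse(q >= 0, links$ib, links$ia)
    aq <- abs(q)
    ## divergence of each cell: positive = net outflow = external source
    div <- numeric(n)
    out_a <- rowsum(q, links$ia)
    div[as.integer(rownames(out_a))] <- out_a[, 1]
    in_b <- rowsum(q, links$ib)
    div[as.integer(rownames(in_b))] <- div[as.integer(rownames(in_b))] -
      in_b[, 1]
    src_per_x[flow$inlet_ids] <- pmax(div[flow$inlet_ids], 0)
    out_ids <- unlist(flow$outlet_ids, use.names = FALSE)
    sink[out_ids] <- pmax(-div[out_ids], 0)
    ## d(PV x)/dt contributions: +q x_up at dn, -q x_up at up, -sink x at cell
    conv <- Matrix::sparseMatrix(
      i = c(dn, up, seq_len(n)),
      j = c(up, up, seq_len(n)),
      x = c(aq, -aq, -sink),
      dims = c(n, n)
    )
  }

  diff_ops <- NULL
  if (diffusion) {
    links0 <- if (!is.null(flow)) flow$links else
      build_links(props, "nine_point")
    diff_ops <- lapply(species, function(sp) {
      D <- ifelse(props$is_sinusoid, sp$D_sin_m2s, sp$D_tis_m2s) * 60  # m^2/min
      G <- link_coef(links0, props$phi * D)  # m^3/min
      if (all(G == 0)) return(NULL)
      Matrix::sparseMatrix(
        i = c(links0$ia, links0$ib, links0$ia, links0$ib),
        j = c(links0$ib, links0$ia, links0$ia, links0$ib),
        x = c(G, G, -G, -G),
        dims = c(n, n)
      )
    })
  }

  rx <- NULL
  if (!is.null(reactions) && length(reactions)) {
    rx <- lapply(reactions, function(r) {
      isub <- match(r$substrate, sp_names)
      iprod <- match(r$product, sp_names)
      if (is.na(isub)) stop("reaction substrate '", r$substrate,
                            "' not among species", call. = FALSE)
      zone <- rep(1, n)
      if (!is.null(r$zone)) {
        zv <- r$zone$multiplier[props$active]
        if (length(r$zone$multiplier) != prod(props$dims)) {
          stop("zonation field does not match the lattice", call. = FALSE)
        }
        zone[!is.na(zv)] <- zv[!is.na(zv)]
      }
      tissue <- which(!props$is_sinusoid)
      list(isub = isub, iprod = iprod, k = r$kinetics,
           tissue = tissue, zone = zone[tissue])
    })
  }

  list(props = props, flow = flow, species = species, sp_names = sp_names,
       n = n, PV = PV, conv = conv, src_per_x = src_per_x, sink = sink,
       diff_ops = diff_ops, rx = rx)
}

#' Largest stable explicit time step (CFL bound)
#'
#' `dt = safety * min over cells of pore_volume / total outgoing flux`
#' (including the well production sink). Diffusion is integrated implicitly
#' and does not constrain the step.
#'
#' @param flow A [solve_pressure()] solution.
#' @param safety Safety factor (default 0.9).
#' @param dt_max Upper bound returned when there is no flow, min.
#' @return Time step in minutes.
#' @export
stable_dt <- function(flow, safety = 0.9, dt_max = 1) {
  stopifnot(inherits(flow, "flow_solution"))
  n <- length(flow$props$active)
  links <- flow$links
  q <- flow$q_m3s * 60
  out <- numeric(n)
  pos <- q > 0
  if (any(pos)) {
    o <- rowsum(q[pos], links$ia[pos])
    out[as.integer(rownames(o))] <- o[, 1]
  }
  neg <- q < 0
  if (any(neg)) {
    o <- rowsum(-q[neg], links$ib[neg])
    out[as.integer(rownames(o))] <- out[as.integer(rownames(o))] + o[, 1]
  }
  ## production sinks at outlet wells
  div <- numeric(n)
  oa <- rowsum(q, links$ia)
  div[as.integer(rownames(oa))] <- oa[, 1]
  ob <- rowsum(q, links$ib)
  div[as.integer(rownames(ob))] <- div[as.integer(rownames(ob))] - ob[, 1]
  out_ids <- unlist(flow$outlet_ids, use.names = FALSE)
  out[out_ids] <- out[out_ids] + pmax(-div[out_ids], 0)

  h <- flow$props$morph$cell_size_um * 1e-6
  tz <- rep(flow$props$morph$layer_thickness_um,
            length.out = flow$props$dims[3]) * 1e-6
  zi <- slice.index(array(0L, flow$props$dims), 3)[flow$props$active]
  PV <- flow$props$phi * h * h * tz[zi]
  ok <- out > 0
  if (!any(ok)) return(dt_max)
  min(safety * min(PV[ok] / out[ok]), dt_max)
}

## implicit MM decrement over dt: solves x' + dt z vmax x'/(Km + x') = x,
## unconditionally positive; exact exponential decrement in linear mode
react_decrement <- function(x, k, zone, dt) {
  if (k$vmax_mf_min == 0) return(numeric(length(x)))
  dx <- if (k$mode == "linear") {
    x * (1 - exp(-zone * k$k_lin_per_min * dt))
  } else {
    b <- k$Km_mf + dt * zone * k$vmax_mf_min - x
    xn <- (-b + sqrt(b * b + 4 * k$Km_mf * x)) / 2
    x - xn
  }
  pmin(pmax(dx, 0), x)  # guard float cancellation at the rate extremes
}

## one operator-split step; state is an n x n_species matrix. Internal core
## shared by advance_state() and run_infusion().
step_state <- function(sys, x, dt, diff_facts = NULL) {
  if (!is.null(sys$conv)) {
    adv <- as.matrix(sys$conv %*% x) / sys$PV
    for (s in seq_along(sys$species)) {
      adv[, s] <- adv[, s] +
        sys$src_per_x * sys$species[[s]]$x_inject / sys$PV
    }
    x <- x + dt * adv
  }
  if (!is.null(diff_facts)) {
    for (s in seq_along(diff_facts)) {
      if (is.null(diff_facts[[s]])) next
      x[, s] <- as.numeric(Matrix::solve(diff_facts[[s]],
                                         sys$PV * x[, s] / dt))
    }
  }
  reacted <- numeric(length(sys$species))
  if (!is.null(sys$rx)) {
    for (r in sys$rx) {
      dx <- react_decrement(x[r$tissue, r$isub], r$k, r$zone, dt)
      x[r$tissue, r$isub] <- x[r$tissue, r$isub] - dx
      amt <- sum(sys$PV[r$tissue] * dx)
      reacted[r$isub] <- reacted[r$isub] + amt
      if (!is.na(r$iprod)) {
        x[r$tissue, r$iprod] <- x[r$tissue, r$iprod] + dx
        reacted[r$iprod] <- reacted[r$iprod] - amt
      }
    }
  }
  list(x = x, reacted = reacted)
}

diffusion_factors <- function(sys, dt) {
  if (is.null(sys$diff_ops)) return(NULL)
  lapply(sys$diff_ops, function(L) {
    if (is.null(L)) return(NULL)
    A <- Matrix::Diagonal(x = sys$PV / dt) - L
    Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A),
                                 "CsparseMatrix"))
  })
}

#' Advance a species state by one operator-split step
#'
#' Explicit first-order upwind convection on the solved face fluxes, then
#' implicit diffusion, then the tissue reaction update (implicit
#' Michaelis-Menten / exact-exponential linear decrement). Exposed mainly
#' for verification; [run_infusion()] drives the full simulation.
#'
#' @param sys A transport system from [transport_system()].
#' @param x State matrix, active cells x species (mole fraction).
#' @param dt Time step, min (must satisfy [stable_dt()] when convecting).
#' @return Updated state matrix.
#' @export
advance_state <- function(sys, x, dt) {
  if (!is.null(sys$flow) && dt > stable_dt(sys$flow, safety = 1) * (1 + 1e-9)) {
    stop("dt violates the CFL bound; use stable_dt()", call. = FALSE)
  }
  st <- step_state(sys, x, dt, diffusion_factors(sys, dt))
  if (min(st$x) < -1e-14) {
    stop("negative concentration produced; internal inconsistency",
         call. = FALSE)
  }
  st$x
}

#' Run a continuous step-injection infusion
#'
#' Infuses blood carrying `x_inject` of each species through the central
#' inlet into the solved steady flow field and integrates the
#' convection-diffusion-reaction dynamics to `t_end`, recording per-port
#' production curves and optional field snapshots.
#'
#' @param flow A [solve_pressure()] solution (typically calibrated).
#' @param species A [species_spec()] or list of them.
#' @param reactions Optional [reaction_spec()] or list of them.
#' @param t_end End time, min (> 0).
#' @param dt Time step; default [stable_dt()].
#' @param diffusion Logical: include diffusive transport.
#' @param record_every Record the port state every this many steps (default
#'   targets ~2000 records).
#' @param snapshot_times Times (min) at which to store full concentration
#'   fields.
#' @param stop_when Optional function of the n_ports x n_species port
#'   concentration matrix returning `TRUE` to end the run early (e.g. a
#'   breakthrough criterion).
#' @return Object of class `"production_record"`: `time_min`, static
#'   `port_rates_cm3_min`, arrays `conc` and `cumulative`
#'   (time x port x species; cumulative production in mole fraction cm^3),
#'   `totals` (injected / produced / reacted / in place, mole fraction cm^3),
#'   `snapshots`, and run metadata.
#' @export
run_infusion <- function(flow, species, reactions = NULL, t_end,
                         dt = NULL, diffusion = TRUE, record_every = NULL,
                         snapshot_times = NULL, stop_when = NULL) {
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  sys <- transport_system(flow, species, reactions, diffusion)
  dt <- dt %||% stable_dt(flow)
  n_steps <- ceiling(t_end / dt)
  record_every <- record_every %||% max(1L, n_steps %/% 2000L)
  facts <- diffusion_factors(sys, dt)

  nsp <- length(sys$species)
  ports <- names(flow$outlet_ids)
  np <- length(ports)
  ## per-port outflow weights over outlet cells
  port_w <- lapply(flow$outlet_ids, function(ids) {
    w <- sys$sink[ids]
    list(ids = ids, w = w, tot = sum(w))
  })
  q_in_total <- sum(sys$src_per_x)  # m^3/min

  x <- matrix(0, sys$n, nsp)
  injected <- reacted <- numeric(nsp)
  produced <- matrix(0, np, nsp, dimnames = list(ports, sys$sp_names))
  rec_t <- numeric(0)
  rec_conc <- rec_cum <- array(numeric(0), c(0, np, nsp))
  recs <- list()
  snaps <- list()
  snap_pending <- sort(snapshot_times %||% numeric(0))

  port_conc <- function(x) {
    out <- matrix(0, np, nsp)
    for (p in seq_len(np)) {
      pw <- port_w[[p]]
      if (pw$tot > 0) {
        out[p, ] <- colSums(x[pw$ids, , drop = FALSE] * pw$w) / pw$tot
      }
    }
    out
  }

  t_now <- 0
  i <- 0L
  while (i < n_steps) {
    i <- i + 1L
    ## production bookkeeping uses the state at the start of the step,
    ## matching the explicit upwind update exactly
    for (p in seq_len(np)) {
      pw <- port_w[[p]]
      produced[p, ] <- produced[p, ] +
        dt * colSums(x[pw$ids, , drop = FALSE] * pw$w)
    }
    injected <- injected + dt * q_in_total *
      vapply(sys$species, `[[`, numeric(1), "x_inject")
    st <- step_state(sys, x, dt, facts)
    x <- st$x
    reacted <- reacted + st$reacted
    t_now <- t_now + dt

    if (i %% record_every == 0L || i == n_steps) {
      recs[[length(recs) + 1L]] <-
        list(t = t_now, conc = port_conc(x), cum = produced * 1e6)
    }
    while (length(snap_pending) && t_now >= snap_pending[1] - 1e-12) {
      f <- array(NA_real_, c(sys$props$dims, nsp))
      for (s in seq_len(nsp)) {
        fs <- array(NA_real_, sys$props$dims)
        fs[sys$props$active] <- x[, s]
        f[, , , s] <- fs
      }
      snaps[[sprintf("t=%g", snap_pending[1])]] <- f
      snap_pending <- snap_pending[-1]
    }
    if (!is.null(stop_when) && isTRUE(stop_when(port_conc(x)))) {
      if (i %% record_every != 0L && i != n_steps) {
        recs[[length(recs) + 1L]] <-
          list(t = t_now, conc = port_conc(x), cum = produced * 1e6)
      }
      break
    }
  }

  rec_t <- vapply(recs, `[[`, numeric(1), "t")
  conc <- array(0, c(length(recs), np, nsp),
                dimnames = list(NULL, ports, sys$sp_names))
  cum <- conc
  for (j in seq_along(recs)) {
    conc[j, , ] <- recs[[j]]$conc
    cum[j, , ] <- recs[[j]]$cum
  }

  in_place <- colSums(x * sys$PV)
  structure(list(
    time_min = rec_t,
    port_rates_cm3_min = flow$port_rates_cm3_min,
    conc = conc,
    cumulative = cum,  # mole fraction * cm^3
    totals = list(injected_mfcm3 = injected * 1e6,
                  produced_mfcm3 = produced * 1e6,
                  reacted_mfcm3 = reacted * 1e6,
                  in_place_mfcm3 = in_place * 1e6),
    species = sys$sp_names, dt_min = dt, t_end_min = t_now,
    diffusion = diffusion, snapshots = snaps,
    x_inject = vapply(sys$species, `[[`, numeric(1), "x_inject"),
    morph_dims = sys$props$dims
  ), class = "production_record")
}

#' @export
print.production_record <- function(x, ...) {
  cat(sprintf(
    "Production record: %d records to t = %.4g min (dt %.3g), species %s, diffusion %s\n",
    length(x$time_min), x$t_end_min, x$dt_min,
    paste(x$species, collapse = ", "), x$diffusion))
  invisible(x)
}

#' Mass-balance closure report
#'
#' Checks, per species family, that everything injected is accounted for by
#' what is in place, produced at the ports, or converted by reaction
#' (substrate consumed equals product generated, 1:1 stoichiometry).
#'
#' @param rec A [run_infusion()] record.
#' @param tol Relative closure tolerance for the `ok` flags (default 1e-6).
#' @return List with per-species and family closure errors and `ok` flags.
#' @export
mass_balance <- function(rec, tol = 1e-6) {
  stopifnot(inherits(rec, "production_record"))
  tt <- rec$totals
  inj <- tt$injected_mfcm3
  prod <- colSums(tt$produced_mfcm3)
  reac <- tt$reacted_mfcm3  # positive = consumed, negative = generated
  inpl <- tt$in_place_mfcm3
  scale <- pmax(inj, inpl + prod + abs(reac), 1e-300)
  err <- abs(inj - (inpl + prod + reac)) / scale
  fam_err <- abs(sum(inj) - (sum(inpl) + sum(prod) + sum(reac))) /
    max(sum(inj), 1e-300)
  list(species = rec$species, injected = inj, produced = prod,
       reacted = reac, in_place = inpl, closure_rel_err = err,
       family_rel_err = fam_err, ok = all(err <= tol) && fam_err <= tol)
}

#' Earliest port breakthrough time
#'
#' First recorded time at which any outlet port's concentration of the
#' species reaches `frac` of the injected level.
#'
#' @param rec A [run_infusion()] record.
#' @param species Species name (default first).
#' @param frac Breakthrough fraction of the injected mole fraction.
#' @return Time in minutes, or `NA` if never reached.
#' @export
breakthrough_time <- function(rec, species = rec$species[1], frac = 0.5) {
  s <- match(species, rec$species)
  if (is.na(s)) stop("unknown species '", species, "'", call. = FALSE)
  xi <- rec$x_inject[s]
  if (xi <= 0) return(NA_real_)
  hit <- apply(rec$conc[, , s, drop = FALSE] >= frac * xi, 1, any)
  if (!any(hit)) return(NA_real_)
  rec$time_min[which(hit)[1]]
}
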