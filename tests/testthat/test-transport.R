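test_that("CFL time step matches a direct per-cell scan", {
  sol <- tiny_flow(1)
  dt <- stable_dt(sol)
  # independent scan: 0.9 * min(pore volume / total outgoing flux)
  props <- sol$props
  n <- length(props$active)
  q <- sol$q_m3s * 60
  out <- numeric(n)
  for (k in seq_along(q)) {
    if (q[k] > 0) out[sol$links$ia[k]] <- out[sol$links$ia[k]] + q[k]
    else out[sol$links$ib[k]] <- out[sol$links$ib[k]] - q[k]
  }
  div <- numeric(n)
  for (k in seq_along(q)) {
    div[sol$links$ia[k]] <- div[sol$links$ia[k]] + q[k]
    div[sol$links$ib[k]] <- div[sol$links$ib[k]] - q[k]
  }
  for (ids in sol$outlet_ids) {
    out[ids] <- out[ids] + pmax(-div[ids], 0)
  }
  PV <- props$phi * 6e-6 * 6e-6 * 6e-6
  expect_equal(dt, 0.9 * min((PV / out)[out > 0]), tolerance = 1e-12)
})

test_that("CFL step scales as expected with the flow", {
  ch <- channel_morphology(len = 30)
  pch <- assign_properties(ch)
  f1 <- solve_pressure(pch, well_config(delta_p_Pa = 10), "five_point")
  f2 <- solve_pressure(pch, well_config(delta_p_Pa = 20), "five_point")
  expect_equal(stable_dt(f1), 2 * stable_dt(f2), tolerance = 1e-10)
  # uniform channel: dt = 0.9 phi V / q
  tbl <- medium_table()
  q <- f1$total_inflow_cm3_min / 6e7 * 60  # m^3/min
  PV <- tbl$phi_sin * (6e-6)^3
  expect_equal(stable_dt(f1), 0.9 * PV / q, tolerance = 1e-10)
})

test_that("kinetic rate law: half saturation, linear limit, zero", {
  k <- kinetic_params()
  expect_equal(mm_rate(k$Km_mf, k), k$vmax_mf_min / 2, tolerance = 1e-12)
  x <- 1e-4 * k$Km_mf
  expect_lt(abs(mm_rate(x, k) / (6.0e-3 * x) - 1), 2e-3)
  expect_identical(mm_rate(0, k), 0)
  expect_equal(mm_rate(k$Km_mf, k, zone = 2), k$vmax_mf_min,
               tolerance = 1e-12)
  klin <- kinetic_params(mode = "linear")
  expect_equal(mm_rate(x, klin), klin$k_lin_per_min * x, tolerance = 1e-12)
})

test_that("no flow, no diffusion, no reaction leaves the state unchanged", {
  props <- assign_properties(tiny_lobule(1))
  sys <- transport_system(NULL, pac_species(), diffusion = FALSE,
                          props = props)
  x <- matrix(runif(length(props$active)), ncol = 1)
  expect_identical(advance_state(sys, x, 0.1), x)
})

test_that("pure advection moves a front at the interstitial speed", {
  ch <- channel_morphology(len = 80)
  pch <- assign_properties(ch)
  sol <- solve_pressure(pch, well_config(delta_p_Pa = 5), "five_point")
  xin <- 1e-8
  rec <- run_infusion(sol, pac_species(x_inject = xin), NULL, t_end = 0.5,
                      diffusion = FALSE, record_every = 1000)
  # front position from cell transit time: q / (phi V) cells per minute
  tbl <- medium_table()
  q <- sol$total_inflow_cm3_min / 6e7 * 60
  v_cells <- q / (tbl$phi_sin * (6e-6)^3)
  t_tot <- rec$t_end_min
  sys <- transport_system(sol, pac_species(x_inject = xin),
                          diffusion = FALSE)
  nstep <- round(t_tot / rec$dt_min)
  x <- matrix(0, sys$n, 1)
  for (i in seq_len(nstep)) x <- advance_state(sys, x, rec$dt_min)
  front <- which(x[, 1] < 0.5 * xin)[1] - 1
  expect_lt(abs(front - v_cells * t_tot), 4)  # within numerical smearing
  # the state never exceeds the injected level (maximum principle)
  expect_lte(max(x), xin * (1 + 1e-12))
  expect_gte(min(x), -1e-20)
})

test_that("closed-box diffusion conserves mass and flattens the field", {
  props <- assign_properties(tiny_lobule(1))
  sys <- transport_system(NULL, pac_species(), diffusion = TRUE,
                          props = props)
  n <- length(props$active)
  x <- matrix(0, n, 1)
  x[seq_len(50), 1] <- 1e-8
  mass0 <- sum(sys$PV * x)
  v0 <- var(x[, 1])
  for (i in 1:20) x <- advance_state(sys, x, 0.01)
  expect_lt(abs(sum(sys$PV * x) / mass0 - 1), 1e-12)
  expect_lt(var(x[, 1]), v0)
  expect_gte(min(x), 0)
})

test_that("breakthrough curves respect the tracer maximum principle", {
  sol <- tiny_flow(1)
  xin <- 1.8e-8
  rec <- run_infusion(sol, pac_species(x_inject = xin), NULL, t_end = 0.3,
                      diffusion = FALSE)
  expect_gte(min(rec$conc), 0)
  expect_lte(max(rec$conc), xin * (1 + 1e-9))
  expect_true(all(diff(rec$time_min) > 0))
  bt <- breakthrough_time(rec, frac = 0.5)
  if (!is.na(bt)) expect_gt(bt, 0)
})

test_that("mass balance closes for conservative and reactive runs", {
  sol <- tiny_flow(1)
  rec <- run_infusion(sol, pac_species(), NULL, t_end = 0.2,
                      diffusion = FALSE)
  bal <- mass_balance(rec)
  expect_true(bal$ok)
  expect_lt(max(bal$closure_rel_err), 1e-6)

  rx <- reaction_spec(reaction_preset("base"))
  rec2 <- run_infusion(sol, list(pac_species(), pacoh_species()), rx,
                       t_end = 0.2, diffusion = TRUE)
  bal2 <- mass_balance(rec2)
  expect_true(bal2$ok)
  expect_lt(bal2$family_rel_err, 1e-6)
  # stoichiometry: substrate consumed equals product generated, exactly
  expect_identical(bal2$reacted[1], -bal2$reacted[2])
  # a 3-cell hand check: injected = in-place + produced for a short run
  ch <- channel_morphology(len = 3)
  fch <- solve_pressure(assign_properties(ch),
                        well_config(delta_p_Pa = 1), "five_point")
  rch <- run_infusion(fch, pac_species(x_inject = 1e-8), NULL,
                      t_end = 5 * stable_dt(fch), diffusion = FALSE)
  bch <- mass_balance(rch)
  q_in <- sum(fch$total_inflow_cm3_min) / 6e7 * 60
  n_steps <- round(rch$t_end_min / rch$dt_min)
  expect_lt(abs(bch$injected[1] /
                  (q_in * 1e-8 * n_steps * rch$dt_min * 1e6) - 1), 1e-10)
  expect_true(bch$ok)
})

test_that("Michaelis-Menten collapses to the linear limit far below Km", {
  sol <- tiny_flow(1)
  xin <- 1e-3 * kinetic_params()$Km_mf
  run_mode <- function(mode) {
    rx <- reaction_spec(kinetic_params(mode = mode))
    run_infusion(sol, list(pac_species(x_inject = xin), pacoh_species()),
                 rx, t_end = 0.2, diffusion = FALSE, record_every = 20)
  }
  r_mm <- run_mode("michaelis_menten")
  r_lin <- run_mode("linear")
  ref <- max(r_lin$conc)
  expect_gt(ref, 0)
  expect_lt(max(abs(r_mm$conc - r_lin$conc)) / ref, 0.005)
})

test_that("diffusion raises metabolite conversion at both studied rates", {
  sol <- tiny_flow(1)
  cum_pacoh <- function(rate, diffusion) {
    rx <- reaction_spec(reaction_preset(rate))
    rec <- run_infusion(sol, list(pac_species(), pacoh_species()), rx,
                        t_end = 0.3, diffusion = diffusion,
                        record_every = 50)
    sum(rec$totals$produced_mfcm3[, "PAC-OH"]) +
      rec$totals$in_place_mfcm3[2]
  }
  for (rate in c("base", "slow")) {
    expect_gt(cum_pacoh(rate, TRUE), cum_pacoh(rate, FALSE))
  }
})

test_that("faster kinetics produce more metabolite, zero rate none", {
  sol <- tiny_flow(1)
  run_rate <- function(kin) {
    rec <- run_infusion(sol, list(pac_species(), pacoh_species()),
                        reaction_spec(kin), t_end = 0.3,
                        diffusion = FALSE, record_every = 50)
    rec$totals
  }
  t_base <- run_rate(reaction_preset("base"))
  t_slow <- run_rate(reaction_preset("slow"))
  expect_gt(sum(t_base$produced_mfcm3[, "PAC-OH"]) +
              t_base$in_place_mfcm3[2],
            sum(t_slow$produced_mfcm3[, "PAC-OH"]) +
              t_slow$in_place_mfcm3[2])
  t_zero <- run_rate(kinetic_params(vmax_uM_min = 0))
  expect_identical(t_zero$in_place_mfcm3[2], 0)
  expect_true(all(t_zero$produced_mfcm3[, "PAC-OH"] == 0))
})

test_that("halving the time step barely changes the port curves", {
  sol <- tiny_flow(1)
  dt <- stable_dt(sol)
  run_dt <- function(dt) {
    run_infusion(sol, pac_species(), NULL, t_end = 0.2, dt = dt,
                 diffusion = FALSE, record_every = 1e6)  # final state only
  }
  r1 <- run_dt(dt / 2)
  r2 <- run_dt(dt / 4)
  c1 <- r1$conc[dim(r1$conc)[1], , 1]
  c2 <- r2$conc[dim(r2$conc)[1], , 1]
  expect_lt(max(abs(c1 - c2)) / 1.8e-8, 0.01)
})

test_that("run and advance validate their inputs", {
  sol <- tiny_flow(1)
  expect_error(run_infusion(sol, pac_species(), t_end = 0), "t_end")
  sys <- transport_system(sol, pac_species(), diffusion = FALSE)
  x <- matrix(0, length(sol$props$active), 1)
  expect_error(advance_state(sys, x, stable_dt(sol) * 5), "CFL")
  expect_error(species_spec("X", x_inject = 1.5))
  expect_error(
    reaction_spec(kinetic_params(), substrate = "PAC", zone = "nope"),
    "zonation_field")
})
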