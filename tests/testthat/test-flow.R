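test_that("two-cell column obeys Darcy's law exactly", {
  ch <- channel_morphology(len = 2)
  props <- assign_properties(ch)
  sol <- solve_pressure(props, well_config(delta_p_Pa = 40), "five_point")
  tbl <- medium_table()
  h <- 6e-6
  # T = K A / (mu dx), A = h * t with t = h, dx = h  =>  T = K h / mu
  q_expect <- tbl$K_sin_m2 * h / tbl$mu_Pas * 40  # m^3/s
  expect_equal(sol$total_inflow_cm3_min, q_expect * 6e7, tolerance = 1e-12)
  expect_equal(unname(sol$port_rates_cm3_min["A"]), q_expect * 6e7,
               tolerance = 1e-12)
})

test_that("pressure solve matches a dense direct oracle on a small grid", {
  set.seed(11)
  n <- 8L
  lab <- matrix(lobule_labels()[["TISSUE"]], n, n)
  lab[sample(n * n, 20)] <- lobule_labels()[["SINUSOID"]]
  lab[4, 4] <- lobule_labels()[["SINUSOID"]]
  lab[1, 1] <- lobule_labels()[["SINUSOID"]]
  m <- lobule_morphology(lab, cbind(4, 4), list(A = cbind(1, 1)))
  props <- assign_properties(m)
  sol <- solve_pressure(props, well_config(delta_p_Pa = 25), "five_point")

  # independent dense assembly: loop over faces, harmonic permeability
  tbl <- medium_table()
  K <- matrix(ifelse(lab == lobule_labels()[["SINUSOID"]],
                     tbl$K_sin_m2, tbl$K_tis_m2), n, n)
  h <- 6e-6
  id <- matrix(seq_len(n * n), n, n)
  A <- matrix(0, n * n, n * n)
  for (r in seq_len(n)) for (c in seq_len(n)) {
    for (d in list(c(0, 1), c(1, 0))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 > n || c2 > n) next
      Tij <- h * 2 / (1 / K[r, c] + 1 / K[r2, c2]) / tbl$mu_Pas
      i <- id[r, c]; j <- id[r2, c2]
      A[i, i] <- A[i, i] + Tij; A[j, j] <- A[j, j] + Tij
      A[i, j] <- A[i, j] - Tij; A[j, i] <- A[j, i] - Tij
    }
  }
  fixed <- c(id[4, 4], id[1, 1])
  pfix <- c(25, 0)
  free <- setdiff(seq_len(n * n), fixed)
  p <- numeric(n * n)
  p[fixed] <- pfix
  p[free] <- solve(A[free, free], -A[free, fixed] %*% pfix)
  expect_equal(as.numeric(sol$pressure_Pa[, , 1]), p, tolerance = 1e-10)
})

test_that("flow is linear in the pressure drop", {
  f1 <- tiny_flow(1, delta_p = 50)
  f2 <- solve_pressure(assign_properties(tiny_lobule(1)),
                       well_config(delta_p_Pa = 100))
  expect_equal(f2$port_rates_cm3_min, 2 * f1$port_rates_cm3_min,
               tolerance = 1e-10)
  expect_equal(f2$total_inflow_cm3_min, 2 * f1$total_inflow_cm3_min,
               tolerance = 1e-10)
})

test_that("port rates conserve mass and respect the maximum principle", {
  sol <- tiny_flow(1)
  expect_equal(sum(sol$port_rates_cm3_min), sol$total_inflow_cm3_min,
               tolerance = 1e-8)
  expect_true(all(sol$port_rates_cm3_min >= 0))
  p <- sol$pressure_Pa[!is.na(sol$pressure_Pa)]
  expect_gte(min(p), 0 - 1e-9)
  expect_lte(max(p), 50 + 1e-9)
})

test_that("pressure-drop calibration hits the target inflow exactly", {
  props <- assign_properties(tiny_lobule(1))
  target <- 2.5e-7
  wc <- calibrate_delta_p(props, well_config(target_inflow_cm3_min = target))
  sol <- solve_pressure(props, wc)
  expect_equal(sol$total_inflow_cm3_min, target, tolerance = 1e-8)
  # linearity: twice the target needs twice the pressure drop
  wc2 <- calibrate_delta_p(props,
                           well_config(target_inflow_cm3_min = 2 * target))
  expect_equal(wc2$delta_p_Pa, 2 * wc$delta_p_Pa, tolerance = 1e-10)
  # closed form on a uniform two-cell column: dP = target / conductance
  ch <- channel_morphology(len = 2)
  pch <- assign_properties(ch)
  tbl <- medium_table()
  cond <- tbl$K_sin_m2 * 6e-6 / tbl$mu_Pas * 6e7  # cm^3/min per Pa
  wch <- calibrate_delta_p(pch, well_config(target_inflow_cm3_min = 1e-8),
                           "five_point")
  expect_equal(wch$delta_p_Pa, 1e-8 / cond, tolerance = 1e-10)
  # calibration mode dispatches inside solve_pressure too
  sol2 <- solve_pressure(props, well_config(target_inflow_cm3_min = target))
  expect_equal(sol2$total_inflow_cm3_min, target, tolerance = 1e-8)
})

test_that("property assignment is label-driven and validated", {
  props <- assign_properties(tiny_lobule(1))
  tbl <- medium_table()
  expect_true(all(props$K_m2[props$is_sinusoid] == tbl$K_sin_m2))
  expect_true(all(props$K_m2[!props$is_sinusoid] == tbl$K_tis_m2))
  expect_equal(tbl$K_sin_um2 / tbl$K_tis_um2, 15.3, tolerance = 0.01)
  lab <- matrix(lobule_labels()[["OUTSIDE"]], 4, 4)
  m_empty <- suppressWarnings(
    lobule_morphology(lab, cbind(1, 1), list(A = cbind(4, 4))))
  expect_error(assign_properties(m_empty), "no active cells")
})

test_that("five- and nine-point schemes are consistent on a uniform medium", {
  mu <- morphology_from_mask(matrix(TRUE, 64, 64))
  pu <- assign_properties(mu)
  f9 <- solve_pressure(pu, well_config(delta_p_Pa = 10), "nine_point")
  f5 <- solve_pressure(pu, well_config(delta_p_Pa = 10), "five_point")
  expect_lt(abs(f9$total_inflow_cm3_min / f5$total_inflow_cm3_min - 1),
            0.02)
  # mirror symmetry of the port blocks: opposite ports agree closely
  expect_lt(max(f9$port_rates_cm3_min) / min(f9$port_rates_cm3_min), 1.1)
})

test_that("nine-point pressure field is at least as isotropic as five-point", {
  mu <- morphology_from_mask(matrix(TRUE, 65, 65))  # odd: exact centre cell
  pu <- assign_properties(mu)
  angular_sd <- function(scheme) {
    f <- solve_pressure(pu, well_config(delta_p_Pa = 10), scheme)
    ang <- seq(0, 2 * pi, length.out = 120)
    sd(vapply(ang, function(a) {
      f$pressure_Pa[round(33 + 12 * sin(a)), round(33 + 12 * cos(a)), 1]
    }, numeric(1)))
  }
  expect_lte(angular_sd("nine_point"), angular_sd("five_point") * 1.01)
})

test_that("3D stacking smooths port-to-port variability", {
  cv <- function(x) sd(x) / mean(x)
  cv2 <- cv3 <- numeric(0)
  for (s in 1:3) {
    f2 <- solve_pressure(assign_properties(tiny_lobule(s)),
                         well_config(delta_p_Pa = 10))
    sr <- stack_recipe(M_z_dim = 7, M_skip = 2, connector_fraction = 0.02,
                       seed = s, layer_recipe = area_recipe(32L, s))
    f3 <- solve_pressure(assign_properties(build_lobule_3d(sr)),
                         well_config(delta_p_Pa = 10))
    cv2 <- c(cv2, cv(f2$port_rates_cm3_min))
    cv3 <- c(cv3, cv(f3$port_rates_cm3_min))
  }
  expect_lt(mean(cv3), mean(cv2))
})

test_that("well configuration modes are mutually exclusive", {
  expect_error(well_config(), "exactly one")
  expect_error(well_config(delta_p_Pa = 1, target_inflow_cm3_min = 1),
               "exactly one")
  expect_error(well_config(delta_p_Pa = -1), "delta_p")
  expect_error(well_config(target_inflow_cm3_min = 0), "target_inflow")
})
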