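sp50 <- species_params(W_A = 50, q = 1)
rp_def <- resource_params()

test_that("PSPM right-hand side matches the stage-specific bookkeeping", {
  # consumers absent: pure semi-chemostat renewal
  st <- pspm_state(data.frame(c = numeric(0), s = numeric(0), g = numeric(0)),
                   R = 10, sp = sp50)
  d <- pspm_rhs(st, sp50, resource_params(Rmax = 20, delta = 0.1))
  expect_equal(d$dR, 1.0)

  # starving juvenile cohort: growth stops, mortality is augmented
  st <- pspm_state(data.frame(c = 0.3, s = 10, g = 0), R = 0.5, sp = sp50)
  nuJ <- net_production(0.5, "juvenile", sp50)
  expect_lt(nuJ, 0)
  d <- pspm_rhs(st, sp50, rp_def)
  expect_equal(d$cohorts$ds, 0)
  expect_equal(d$cohorts$dc, -(sp50$rates$mu - nuJ) * 0.3)
  expect_equal(d$cohorts$dg, 0)

  # adult at saturating resource stores at nu_A^+ * Sm per capita
  st <- pspm_state(data.frame(c = 0.01, s = 50, g = 0, adult = TRUE),
                   R = 1e9, sp = sp50)
  d <- pspm_rhs(st, sp50, rp_def)
  expect_equal(d$cohorts$ds, 0)
  expect_equal(d$cohorts$dg, net_production(1e9, "adult", sp50) * 50)
  expect_equal(d$cohorts$dg, 0.752, tolerance = 1e-3)
})

test_that("maturation event indicator tracks the largest juvenile cohort", {
  st <- pspm_state(data.frame(c = c(0.1, 0.2), s = c(49.9, 20), g = c(0, 0)),
                   R = 10, sp = sp50)
  expect_equal(maturation_event_fn(st, sp50), -0.1, tolerance = 1e-9)
  st2 <- pspm_state(data.frame(c = 0.1, s = 50, g = 2, adult = TRUE),
                    R = 10, sp = sp50)
  expect_identical(maturation_event_fn(st2, sp50), -Inf)
})

test_that("maturation relabels the cohort without touching biomass or resource", {
  st <- pspm_state(
    data.frame(c = c(0.05, 0.2, 0.4), s = c(50, 50, 30),
               g = c(1.2, 0, 0), adult = c(TRUE, FALSE, FALSE)),
    R = 7.5, sp = sp50)
  before <- raw_total_biomass(st)
  out <- apply_maturation(st, sp50)
  expect_equal(sum(out$cohorts$adult), 2L)
  expect_equal(raw_total_biomass(out), before)
  expect_equal(out$R, 7.5)
  # the matured cohort kept its numbers and (zero) storage
  expect_setequal(out$cohorts$c, c(0.05, 0.2, 0.4))
  # calling again with no cohort at Sm is a logic error
  expect_error(apply_maturation(out, sp50), "not at the maturation size")
})

test_that("reproduction pulse converts storage 1:1 into a newborn cohort", {
  sp <- species_params(W_A = 50, q = 1, Sm = 50, Sb = 5)
  st <- pspm_state(
    data.frame(c = c(1, 2), s = c(50, 50), g = c(0.5, 0.25),
               adult = c(TRUE, TRUE)),
    R = 12, sp = sp)
  before <- raw_total_biomass(st)
  out <- apply_reproduction_pspm(st, sp)
  newborn <- out$cohorts[!out$cohorts$adult, ]
  expect_equal(nrow(newborn), 1L)
  expect_equal(newborn$c, (0.5 * 1 + 0.25 * 2) / 5)  # = 0.2
  expect_equal(newborn$s, 5)
  expect_true(all(out$cohorts$g == 0))
  expect_equal(raw_total_biomass(out), before, tolerance = 1e-14)
  expect_equal(attr(out, "newborn_biomass"), 1.0)
  expect_equal(out$R, 12)

  # nothing stored: no cohort is created
  st0 <- pspm_state(data.frame(c = 1, s = 50, g = 0, adult = TRUE),
                    R = 12, sp = sp)
  out0 <- apply_reproduction_pspm(st0, sp)
  expect_equal(nrow(out0$cohorts), 1L)
  expect_equal(attr(out0, "newborn_biomass"), 0)
})

test_that("culling removes only sub-threshold cohorts and logs the loss", {
  st <- pspm_state(
    data.frame(c = c(0.5, 1e-20, 0.3), s = c(50, 40, 10),
               g = c(2, 0, 0), adult = c(TRUE, FALSE, FALSE)),
    R = 10, sp = sp50)
  same <- cull_and_compact(st, eps_c = 0)
  expect_equal(nrow(same$cohorts), 3L)
  expect_equal(attr(same, "culled_biomass"), 0)
  out <- cull_and_compact(st, eps_c = 1e-15)
  expect_equal(nrow(out$cohorts), 2L)
  expect_equal(attr(out, "culled_biomass"), 1e-20 * 40)
  outb <- cull_and_compact(st, eps_b = 1e-12)
  expect_equal(nrow(outb$cohorts), 2L)
})

test_that("biomass aggregation splits juveniles, adults and storage", {
  empty <- pspm_state(data.frame(c = numeric(0), s = numeric(0),
                                 g = numeric(0)), R = 5, sp = sp50)
  agg <- aggregate_biomasses(empty, sp50)
  expect_equal(unlist(agg[c("J", "A", "B", "total")]),
               c(J = 0, A = 0, B = 0, total = 0))

  juv <- pspm_state(data.frame(c = 0.1, s = 5, g = 0), R = 5, sp = sp50)
  agg <- aggregate_biomasses(juv, sp50)
  expect_equal(agg$J, 0.5); expect_equal(agg$A, 0); expect_equal(agg$B, 0)

  ad <- pspm_state(data.frame(c = 0.01, s = 50, g = 10, adult = TRUE),
                   R = 5, sp = sp50)
  agg <- aggregate_biomasses(ad, sp50)
  expect_equal(agg$A, 0.5); expect_equal(agg$B, 0.1)
  expect_equal(agg$total, 0.6)
})

test_that("without consumers the resource follows the analytic semi-chemostat curve", {
  empty <- pspm_state(data.frame(c = numeric(0), s = numeric(0),
                                 g = numeric(0)), R = 2, sp = sp50)
  cfg <- sim_config(model = "pspm", sp = sp50, rp = rp_def, n_years = 2,
                    init = empty)
  tr <- run_simulation(cfg)
  s <- tr$samples[tr$samples$event == "none", ]
  analytic <- 20 - (20 - 2) * exp(-0.1 * s$t)
  expect_equal(s$R, analytic, tolerance = 1e-7)
})

test_that("at constant resource a newborn cohort matures at -log(z)/nu with the expected biomass", {
  rp_fix <- resource_params(Rmax = 20, delta = 0.1, fixed = TRUE)
  R0 <- 15  # fixed; nu_J(R0) > 0
  nu <- net_production(R0, "juvenile", sp50)
  mu <- sp50$rates$mu
  a_m <- -log(sp50$z) / nu
  expect_lt(a_m, 250)  # matures within the first season here
  init <- pspm_state(data.frame(c = 0.1 / sp50$Sb, s = sp50$Sb, g = 0),
                     R = R0, sp = sp50)
  cfg <- sim_config(model = "pspm", sp = sp50, rp = rp_fix, n_years = 1,
                    init = init, sample_interval = NA)
  tr <- run_simulation(cfg)
  ev <- tr$samples[tr$samples$event == "maturation", ]
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$t, a_m, tolerance = 1e-6)
  # biomass arriving in the adult stage per unit newborn biomass
  per_newborn <- ev$A / 0.1 * sp50$Sb
  expect_equal(per_newborn,
               expected_adult_contribution(nu, mu, sp50$z, sp50$Sm),
               tolerance = 1e-6)
})

test_that("cohort size ordering is preserved under within-season growth", {
  init <- pspm_state(data.frame(c = c(0.2, 0.3, 0.1), s = c(30, 12, 6),
                                g = 0), R = 20, sp = sp50)
  cfg <- sim_config(model = "pspm", sp = sp50, rp = rp_def, n_years = 1,
                    init = init, sample_interval = NA)
  tr <- run_simulation(cfg)
  juv <- tr$final_state$cohorts
  juv <- juv[!juv$adult, ]
  expect_true(all(diff(juv$s) < 0))
})

test_that("production minus mortality accounts for the biomass slope along the trace", {
  cfg <- sim_config(model = "pspm", sp = sp50, rp = rp_def, n_years = 1,
                    sample_interval = 0.05)
  tr <- run_simulation(cfg)
  s <- tr$samples[tr$samples$event == "none", ]
  ev_t <- tr$samples$t[tr$samples$event != "none"]
  nuJ <- net_production(s$R, "juvenile", sp50)
  nuA <- net_production(s$R, "adult", sp50)
  expected <- positive_part(nuJ) * s$J + positive_part(nuA) * s$A -
    stage_mortality(nuJ, sp50$rates$mu) * s$J -
    stage_mortality(nuA, sp50$rates$mu) * (s$A + s$B)
  slope <- (s$total[-c(1, 2)] - s$total[seq_len(nrow(s) - 2)]) / 0.1
  mid <- seq(2, nrow(s) - 1)
  keep <- vapply(s$t[mid], function(t) all(abs(t - ev_t) > 0.2), logical(1))
  err <- abs(slope - expected[mid]) / pmax(abs(expected[mid]), 1e-8)
  expect_lt(max(err[keep]), 1e-4)
})
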