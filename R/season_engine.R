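#' Simulation configuration
#'
#' Bundles everything a run needs: which model to use, species and resource
#' parameters, the season length `Y` between reproduction pulses, the number
#' of seasons, the initial state, solver tolerances and trace sampling.
#' Runs are fully deterministic: identical configurations yield identical
#' traces.
#'
#' @param model `"pspm"` (cohort-based) or `"stage"` (stage-structured
#'   biomass).
#' @param sp a [species_params].
#' @param rp a [resource_params].
#' @param n_stages number of juvenile stages (stage model only).
#' @param Y season length in days between reproduction pulses. The winter is
#'   not simulated: all rates are assumed negligible then, so seasons are
#'   contiguous and the pulse closes each season.
#' @param n_years number of seasons to simulate.
#' @param init initial state (a [pspm_state] or [stage_state]); by default
#'   the resource starts at `Rmax` and a newborn inoculum of
#'   `init_biomass` mg/L is introduced at `t = 0` (just after a nominal
#'   reproduction instant).
#' @param init_biomass biomass (mg/L) of the default newborn inoculum.
#' @param sample_interval trace sampling interval in days (dense output on a
#'   fixed grid); use `NA` to record only season boundaries, which is much
#'   faster for long runs where only pulse sizes and post-pulse states are
#'   needed.
#' @param rtol,atol relative and absolute solver tolerances.
#' @param cull_eps_b relative-biomass culling threshold for near-extinct
#'   PSPM cohorts (applied after each reproduction pulse).
#' @param transient_fraction fraction of initial years treated as transient
#'   by summary helpers.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(model = c("stage", "pspm"),
                       sp = species_params(),
                       rp = resource_params(),
                       n_stages = 1L,
                       Y = 250,
                       n_years = 100L,
                       init = NULL,
                       init_biomass = 0.1,
                       sample_interval = 1,
                       rtol = 1e-8,
                       atol = 1e-10,
                       cull_eps_b = 1e-12,
                       transient_fraction = 0.5) {
  model <- match.arg(model)
  stopifnot(inherits(sp, "species_params"), inherits(rp, "resource_params"))
  stopifnot(Y > 0, n_years >= 1)
  if (length(n_stages) != 1L || n_stages < 1 || n_stages != round(n_stages))
    stop("'n_stages' must be a positive integer", call. = FALSE)
  if (!is.na(sample_interval) && sample_interval > Y)
    stop("'sample_interval' cannot exceed the season length", call. = FALSE)
  stopifnot(transient_fraction >= 0, transient_fraction < 1)
  if (is.null(init)) {
    init <- if (model == "pspm") {
      pspm_state(data.frame(c = init_biomass / sp$Sb, s = sp$Sb, g = 0),
                 R = rp$Rmax, t = 0, sp = sp)
    } else {
      stage_state(Jvec = c(init_biomass, rep(0, n_stages - 1)),
                  A = 0, B = 0, R = rp$Rmax, t = 0)
    }
  }
  structure(
    list(model = model, sp = sp, rp = rp, n_stages = as.integer(n_stages),
         Y = Y, n_years = as.integer(n_years), init = init,
         sample_interval = sample_interval, rtol = rtol, atol = atol,
         cull_eps_b = cull_eps_b, transient_fraction = transient_fraction),
    class = "sim_config"
  )
}

season_sample_times <- function(t0, t1, interval) {
  if (is.na(interval)) return(c(t0, t1))
  ts <- seq(t0, t1, by = interval)
  if (ts[length(ts)] < t1) ts <- c(ts, t1)
  ts
}

trace_row <- function(t, agg, n_cohorts, event, Jvec = NULL) {
  row <- data.frame(t = t, J = agg$J, A = agg$A, B = agg$B,
                    total = agg$total, R = agg$R,
                    n_cohorts = n_cohorts, event = event,
                    stringsAsFactors = FALSE)
  if (!is.null(Jvec))
    row <- cbind(row, as.data.frame(as.list(stats::setNames(
      Jvec, paste0("J_", seq_along(Jvec))))))
  row
}

stage_aggregate <- function(state) {
  J <- sum(state$Jvec)
  list(J = J, A = state$A, B = state$B,
       total = J + state$A + state$B, R = state$R)
}

# Integrate one PSPM season over [t0, t0 + Y], handling maturation events.
# Returns list(state, rows) where rows are the sampled trace rows of the
# season interior (excluding the season-boundary bookkeeping rows).
pspm_run_season <- function(state, cfg) {
  sp <- cfg$sp; rp <- cfg$rp
  t0 <- state$t; t_end <- t0 + cfg$Y
  rows <- list()
  grid <- season_sample_times(t0, t_end, cfg$sample_interval)
  repeat {
    # promote any cohort already within event tolerance of Sm
    while (is.finite(m <- maturation_event_fn(state, sp)) &&
           m >= -1e-9 * sp$Sm)
      state <- apply_maturation(state, sp)
    if (t_end - state$t <= 1e-9) { state$t <- t_end; break }
    parms <- pspm_parms(state, sp, rp)
    times <- unique(c(state$t, grid[grid > state$t + 1e-12], t_end))
    out <- deSolve::lsodar(y = pspm_flatten(state), times = times,
                           func = pspm_deriv_flat, parms = parms,
                           rootfunc = pspm_rootfun,
                           rtol = cfg$rtol, atol = cfg$atol)
    k <- parms$k
    nr <- nrow(out)
    # sampled rows (skip the first row: either already recorded or a
    # duplicate of the previous segment's endpoint)
    if (nr > 1L) {
      idx <- 2:nr
      if (k > 0L) {
        # out columns: [t, R, c_1..c_k, s_1..s_k, g_1..g_k]
        cmat <- out[idx, 2 + seq_len(k), drop = FALSE]
        smat <- out[idx, 2 + k + seq_len(k), drop = FALSE]
        gmat <- out[idx, 2 + 2 * k + seq_len(k), drop = FALSE]
        juv <- !parms$adult
        J <- rowSums(cmat[, juv, drop = FALSE] * smat[, juv, drop = FALSE])
        A <- rowSums(cmat[, !juv, drop = FALSE]) * sp$Sm
        B <- rowSums(cmat[, !juv, drop = FALSE] * gmat[, !juv, drop = FALSE])
      } else {
        J <- A <- B <- rep(0, length(idx))
      }
      R <- out[idx, 2]
      rows[[length(rows) + 1L]] <- data.frame(
        t = out[idx, 1], J = J, A = A, B = B, total = J + A + B, R = R,
        n_cohorts = k, event = "none", stringsAsFactors = FALSE)
    }
    troot <- attr(out, "troot")
    t_last <- out[nr, 1]
    state <- pspm_unflatten(out[nr, -1], k, t_last, parms$adult, sp$Sm)
    if (!is.null(troot) && length(troot) > 0 && is.finite(troot[1])) {
      state <- apply_maturation(state, sp)
      agg <- aggregate_biomasses(state, sp)
      rows[[length(rows) + 1L]] <- trace_row(t_last, agg,
                                             nrow(state$cohorts), "maturation")
      if (t_last >= t_end - 1e-9) { state$t <- t_end; break }
    } else {
      state$t <- t_end
      break
    }
  }
  list(state = state, rows = rows)
}

stage_run_season <- function(state, cfg) {
  sp <- cfg$sp; rp <- cfg$rp
  n <- cfg$n_stages
  t0 <- state$t; t_end <- t0 + cfg$Y
  times <- season_sample_times(t0, t_end, cfg$sample_interval)
  y <- c(state$Jvec, state$A, state$B, state$R)
  out <- deSolve::lsoda(y = y, times = times, func = stage_deriv_flat,
                        parms = stage_parms(sp, rp, n),
                        rtol = cfg$rtol, atol = cfg$atol)
  nr <- nrow(out)
  idx <- 2:nr
  Jmat <- out[idx, 1 + seq_len(n), drop = FALSE]
  Jtot <- rowSums(Jmat)
  A <- out[idx, n + 2]; B <- out[idx, n + 3]; R <- out[idx, n + 4]
  rows <- data.frame(t = out[idx, 1], J = Jtot, A = A, B = B,
                     total = Jtot + A + B, R = R,
                     n_cohorts = NA_integer_, event = "none",
                     stringsAsFactors = FALSE)
  rows <- cbind(rows, as.data.frame(Jmat) |>
                  stats::setNames(paste0("J_", seq_len(n))))
  yend <- out[nr, -1]
  state <- stage_state(Jvec = pmax(yend[seq_len(n)], 0),
                       A = max(yend[n + 1], 0), B = max(yend[n + 2], 0),
                       R = max(yend[n + 3], 0), t = t_end)
  list(state = state, rows = list(rows))
}

#' Run a seasonal simulation
#'
#' Semi-discrete driver shared by both models: each season of length `Y` is
#' integrated as a continuous ODE system (with maturation events detected by
#' root-finding and applied instantaneously in the PSPM), and the annual
#' reproduction pulse is applied exactly at the season boundary `t_n = n Y`.
#' Pre- and post-pulse states are both recorded so that discontinuities are
#' never interpolated across.
#'
#' @param cfg a [sim_config].
#' @return An object of class `season_trace`: a list with `samples` (data
#'   frame of sampled rows `t, J, A, B, total, R, n_cohorts, event`, plus
#'   per-stage columns `J_1..J_n` for the stage model), `pulses` (one row
#'   per season boundary with pre/post biomasses and the newborn-pulse
#'   biomass), `final_state` and `cfg`.
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  state <- cfg$init
  state$t <- 0
  is_pspm <- cfg$model == "pspm"
  aggfun <- if (is_pspm) function(s) aggregate_biomasses(s, cfg$sp)
            else stage_aggregate
  ncoh <- function(s) if (is_pspm) nrow(s$cohorts) else NA_integer_
  jvec <- function(s) if (is_pspm) NULL else s$Jvec
  all_rows <- list()
  pulse_rows <- vector("list", cfg$n_years)
  agg0 <- aggfun(state)
  all_rows[[1L]] <- trace_row(0, agg0, ncoh(state), "reproduction_post",
                              jvec(state))
  for (yr in seq_len(cfg$n_years)) {
    seas <- if (is_pspm) pspm_run_season(state, cfg)
            else stage_run_season(state, cfg)
    state <- seas$state
    rows <- seas$rows
    # the sampled row at the season boundary is the pre-pulse state
    pre <- aggfun(state)
    retagged <- FALSE
    if (length(rows) > 0L) {
      last <- rows[[length(rows)]]
      i <- nrow(last)
      if (abs(last$t[i] - state$t) < 1e-9) {
        last$event[i] <- "reproduction_pre"
        rows[[length(rows)]] <- last
        retagged <- TRUE
      }
    }
    if (!retagged)
      rows[[length(rows) + 1L]] <- trace_row(state$t, pre, ncoh(state),
                                             "reproduction_pre", jvec(state))
    state <- if (is_pspm) apply_reproduction_pspm(state, cfg$sp)
             else apply_reproduction_stage(state)
    newborn <- attr(state, "newborn_biomass")
    if (is_pspm && cfg$cull_eps_b > 0)
      state <- cull_and_compact(state, eps_b = cfg$cull_eps_b)
    post <- aggfun(state)
    rows[[length(rows) + 1L]] <- trace_row(state$t, post, ncoh(state),
                                           "reproduction_post", jvec(state))
    all_rows[[length(all_rows) + 1L]] <- do.call(rbind, rows)
    pulse_rows[[yr]] <- data.frame(
      year = yr, t = state$t, newborn_biomass = newborn,
      J_pre = pre$J, A_pre = pre$A, B_pre = pre$B,
      total_pre = pre$total, R_pre = pre$R,
      J_post = post$J, A_post = post$A, B_post = post$B,
      total_post = post$total, R_post = post$R)
  }
  samples <- do.call(rbind, all_rows)
  rownames(samples) <- NULL
  structure(list(samples = samples,
                 pulses = do.call(rbind, pulse_rows),
                 final_state = state, cfg = cfg),
            class = "season_trace")
}

#' @export
print.season_trace <- function(x, ...) {
  cat(sprintf(
    "Seasonal %s trace: %d year(s) of %g days, %d sampled rows\n",
    x$cfg$model, x$cfg$n_years, x$cfg$Y, nrow(x$samples)))
  invisible(x)
}

#' Write a trace to CSV
#'
#' Writes the sampled rows of a [run_simulation] trace to a CSV file.
#'
#' @param trace a `season_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "season_trace"))
  utils::write.csv(trace$samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cumulative biomass contribution to the adult stage by one newborn
#'
#' At constant resource conditions (juvenile net production `nu`, background
#' mortality `mu`), computes the cumulative biomass a single newborn
#' individual delivers to the adult stage as a function of age. In the
#' cohort model this is a step function: nothing matures before the age at
#' maturation `-log(z)/nu`, after which the surviving biomass `Sm z^(mu/nu)`
#' arrives at once. In the stage-structured model maturation is spread over
#' time (exponentially for one juvenile stage, gamma-distributed for `n`
#' stages); the curve is obtained by integrating the `n`-stage linear chain
#' seeded with one newborn of size `Sb = z Sm` and accumulating the flow
#' into the adult stage. Both curves approach the same limit.
#'
#' @param kind `"pspm"` or `"stage"`.
#' @param n number of juvenile stages (stage kind).
#' @param nu juvenile net biomass production (day^-1); a non-positive value
#'   yields a flat zero curve.
#' @param mu background mortality (day^-1).
#' @param z birth-to-maturation size ratio.
#' @param Sm size at maturation (g).
#' @param t_grid ages (days) at which to evaluate the curve.
#' @return A data frame with columns `t` and `cumulative` (g).
#' @export
cumulative_maturation_curve <- function(kind = c("pspm", "stage"), n = 1L,
                                        nu, mu, z, Sm, t_grid) {
  kind <- match.arg(kind)
  stopifnot(z > 0, z < 1, Sm > 0, mu >= 0, all(t_grid >= 0))
  t_grid <- sort(unique(t_grid))
  if (nu <= 0)
    return(data.frame(t = t_grid, cumulative = 0))
  if (kind == "pspm") {
    a_m <- -log(z) / nu
    cum <- ifelse(t_grid >= a_m, expected_adult_contribution(nu, mu, z, Sm), 0)
    return(data.frame(t = t_grid, cumulative = cum))
  }
  z_eff <- stage_size_ratio(z, n)
  gam <- maturation_rate(nu, mu, z_eff)
  deriv <- function(t, y, p) {
    Jv <- y[seq_len(n)]
    outflow <- gam * Jv
    inflow <- c(0, outflow[-n])
    dJ <- (nu - mu) * Jv - outflow + inflow
    list(c(dJ, outflow[n]))
  }
  y0 <- c(z * Sm, rep(0, n - 1), 0)
  times <- unique(c(0, t_grid))
  out <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  cum <- out[match(t_grid, out[, 1]), n + 2]
  data.frame(t = t_grid, cumulative = cum)
}
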