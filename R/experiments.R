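#' Time-averaged biomasses over the trailing part of a run
#'
#' Trapezoidal time-average of the sampled trace over the trailing
#' `fraction` of the simulated time span. Pre/post pulse rows share the same
#' time stamp, so the discontinuity contributes a zero-width interval and
#' the average is never interpolated across a pulse.
#'
#' @param trace a `season_trace` from [run_simulation].
#' @param fraction trailing fraction of the time span to average over,
#'   in (0, 1].
#' @param vars columns of the trace to average.
#' @return A named numeric vector of time averages.
#' @export
time_average <- function(trace, fraction = 0.6,
                         vars = c("J", "A", "B", "total", "R")) {
  stopifnot(inherits(trace, "season_trace"),
            fraction > 0, fraction <= 1)
  s <- trace$samples
  if (nrow(s) < 2L) stop("trace too short to average", call. = FALSE)
  t0 <- s$t[1]; t1 <- s$t[nrow(s)]
  t_start <- t1 - fraction * (t1 - t0)
  w <- s[s$t >= t_start - 1e-9, , drop = FALSE]
  if (nrow(w) < 2L) stop("averaging window is empty", call. = FALSE)
  dt <- diff(w$t)
  span <- w$t[nrow(w)] - w$t[1]
  vapply(vars, function(v) {
    x <- w[[v]]
    sum(dt * (x[-1] + x[-length(x)]) / 2) / span
  }, numeric(1))
}

#' Post-reproduction biomasses over a trailing window
#'
#' Extracts the tagged post-pulse states (one per season boundary) within
#' the trailing `window_days` of the run, the sampling convention used for
#' attractor portraits in bifurcation summaries.
#'
#' @param trace a `season_trace`.
#' @param window_days length of the trailing window (days).
#' @return A data frame with one row per reproduction pulse in the window
#'   (`year`, `t`, newborn biomass and pre/post biomasses).
#' @export
post_reproduction_series <- function(trace, window_days) {
  stopifnot(inherits(trace, "season_trace"), window_days > 0)
  p <- trace$pulses
  span <- max(p$t)
  if (window_days > span)
    stop("window is longer than the simulated period", call. = FALSE)
  p[p$t > span - window_days + 1e-9, , drop = FALSE]
}

#' Reproduction-gap statistics
#'
#' Counts seasons "without reproduction": a season boundary whose newborn
#' pulse is below `rel_threshold` times the total consumer biomass at the
#' pulse. Returns the longest consecutive run of such seasons and their
#' total number, optionally after discarding an initial transient.
#'
#' @param trace a `season_trace`.
#' @param rel_threshold relative pulse-size threshold in `[0, 1)`.
#' @param discard_fraction initial fraction of seasons to discard as
#'   transient.
#' @return A list with `max_gap_years` and `n_skipped_years`.
#' @export
reproduction_gap_stats <- function(trace, rel_threshold = 1e-6,
                                   discard_fraction = 0) {
  stopifnot(inherits(trace, "season_trace"),
            rel_threshold >= 0, rel_threshold < 1,
            discard_fraction >= 0, discard_fraction < 1)
  p <- trace$pulses
  keep <- p$year > discard_fraction * max(p$year)
  p <- p[keep, , drop = FALSE]
  ref <- pmax(p$total_pre, .Machine$double.xmin)
  skipped <- p$newborn_biomass < rel_threshold * ref
  if (!any(skipped))
    return(list(max_gap_years = 0L, n_skipped_years = 0L))
  runs <- rle(skipped)
  list(max_gap_years = max(runs$lengths[runs$values]),
       n_skipped_years = sum(skipped))
}

#' Specification of a bifurcation sweep
#'
#' A sweep steps one parameter along a grid, runs a long simulation at each
#' value (warm-started from the previous final state by default, the
#' standard continuation protocol for locating attractors), and summarizes
#' each step by time averages over the trailing `avg_fraction` of the step
#' and by post-reproduction samples over the trailing `post_window` days.
#'
#' @param param swept parameter: `"q"`, `"W_A"` or `"n_stages"`.
#' @param grid strictly monotone numeric grid of parameter values.
#' @param model `"pspm"` or `"stage"`.
#' @param n_stages juvenile stage count (stage model; ignored when sweeping
#'   `n_stages`).
#' @param days_per_step days simulated per grid value. The default 20,000 is
#'   a desk-scale protocol; set 200,000 for full-length steps.
#' @param avg_fraction trailing fraction used for time averages.
#' @param post_window trailing window (days) for post-reproduction samples;
#'   defaults to 5 percent of `days_per_step` (10,000 days at full scale).
#' @param warm_start continue each step from the previous final state.
#' @param sp,rp baseline parameters; the swept parameter overrides the
#'   corresponding field.
#' @param Y season length (days).
#' @param sample_interval trace sampling interval (days).
#' @param rel_threshold pulse threshold for [reproduction_gap_stats].
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(param = c("q", "W_A", "n_stages"), grid,
                       model = c("stage", "pspm"), n_stages = 1L,
                       days_per_step = 20000, avg_fraction = 0.6,
                       post_window = 0.05 * days_per_step,
                       warm_start = TRUE,
                       sp = species_params(), rp = resource_params(),
                       Y = 250, sample_interval = 1,
                       rel_threshold = 1e-6) {
  param <- match.arg(param)
  model <- match.arg(model)
  stopifnot(length(grid) >= 1, all(diff(grid) > 0) || all(diff(grid) < 0) ||
              length(grid) == 1)
  stopifnot(days_per_step >= Y, avg_fraction > 0, avg_fraction <= 1,
            post_window > 0, post_window <= days_per_step)
  structure(list(param = param, grid = grid, model = model,
                 n_stages = as.integer(n_stages),
                 days_per_step = days_per_step, avg_fraction = avg_fraction,
                 post_window = post_window, warm_start = warm_start,
                 sp = sp, rp = rp, Y = Y, sample_interval = sample_interval,
                 rel_threshold = rel_threshold),
            class = "sweep_spec")
}

sweep_species <- function(spec, value) {
  sp <- spec$sp
  switch(spec$param,
         q = species_params(W_A = sp$W_A, q = value, H = sp$H,
                            sigma = sp$sigma, z = sp$z),
         W_A = species_params(W_A = value, q = sp$q, H = sp$H,
                              sigma = sp$sigma, z = sp$z),
         n_stages = sp)
}

# Carry a final state over to the next sweep step; when W_A (and hence Sm)
# changes, cohorts at or beyond the new maturation size become adults.
adapt_state <- function(state, model, sp, n_stages) {
  if (is.null(state)) return(NULL)
  if (model == "stage") {
    if (length(state$Jvec) != n_stages) return(NULL)
    state$t <- 0
    return(state)
  }
  ch <- state$cohorts
  ch$s[ch$adult] <- sp$Sm
  ch$s[!ch$adult] <- pmin(pmax(ch$s[!ch$adult], sp$Sb), sp$Sm)
  pspm_state(ch, R = state$R, t = 0, sp = sp)
}

#' Run a bifurcation sweep
#'
#' Executes the sweep defined by a [sweep_spec]: steps in grid order, each a
#' long run warm-started from the previous final state, summarized by time
#' averages, post-pulse sample spread (cycle amplitude) and reproduction-gap
#' statistics. A solver failure at a step flags the row and restarts the
#' next step from the default initial state.
#'
#' @param spec a [sweep_spec].
#' @return A data frame of class `sweep_result`, one row per grid value,
#'   with the post-reproduction sample series attached as the
#'   `"post_series"` attribute (a list of data frames).
#' @export
bifurcation_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  state <- NULL
  rows <- vector("list", length(spec$grid))
  post <- vector("list", length(spec$grid))
  for (i in seq_along(spec$grid)) {
    value <- spec$grid[i]
    sp <- sweep_species(spec, value)
    n_st <- if (spec$param == "n_stages") as.integer(value) else spec$n_stages
    n_years <- max(2L, as.integer(round(spec$days_per_step / spec$Y)))
    init <- if (spec$warm_start) adapt_state(state, spec$model, sp, n_st)
            else NULL
    cfg <- sim_config(model = spec$model, sp = sp, rp = spec$rp,
                      n_stages = n_st, Y = spec$Y, n_years = n_years,
                      init = init, sample_interval = spec$sample_interval)
    res <- tryCatch(run_simulation(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(value = value, ok = FALSE, J = NA, A = NA,
                              B = NA, total = NA, R = NA,
                              cycle_amplitude = NA, max_gap_years = NA,
                              n_skipped_years = NA)
      state <- NULL
      next
    }
    state <- res$final_state
    avg <- time_average(res, spec$avg_fraction)
    ps <- post_reproduction_series(res, spec$post_window)
    gaps <- reproduction_gap_stats(res, spec$rel_threshold,
                                   discard_fraction = 1 - spec$avg_fraction)
    rows[[i]] <- data.frame(value = value, ok = TRUE,
                            J = avg[["J"]], A = avg[["A"]], B = avg[["B"]],
                            total = avg[["total"]], R = avg[["R"]],
                            cycle_amplitude = max(ps$total_post) -
                              min(ps$total_post),
                            max_gap_years = gaps$max_gap_years,
                            n_skipped_years = gaps$n_skipped_years)
    post[[i]] <- ps
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "post_series") <- post
  attr(out, "spec") <- spec
  class(out) <- c("sweep_result", class(out))
  out
}

#' Relative differences between two sweep summaries
#'
#' Quantifies cross-model agreement: for each shared summary output and grid
#' point, `|a - b| / max(|a|, |b|, tiny)`.
#'
#' @param summaryA,summaryB `sweep_result` tables (or data frames with a
#'   `value` column and shared numeric outputs) on identical grids.
#' @param vars outputs to compare.
#' @param tiny floor preventing division by zero.
#' @return A data frame with the grid `value` and one relative-difference
#'   column per output.
#' @export
compare_models <- function(summaryA, summaryB,
                           vars = c("J", "A", "B", "total", "R"),
                           tiny = 1e-12) {
  if (nrow(summaryA) != nrow(summaryB) ||
      any(abs(summaryA$value - summaryB$value) > 1e-12))
    stop("sweep grids do not match", call. = FALSE)
  out <- data.frame(value = summaryA$value)
  for (v in vars) {
    a <- summaryA[[v]]; b <- summaryB[[v]]
    out[[v]] <- abs(a - b) / pmax(abs(a), abs(b), tiny)
  }
  out
}

#' Scenario presets
#'
#' Ready-made configurations for the standard numerical experiments:
#' `"symmetric"` (equal competitors, q = 1, W_A = 50), `"adult_superior"`
#' (q = 1.5, W_A = 50), `"juvenile_superior"` (q = 0.5, W_A = 50) and
#' `"small_juvenile_superior"` (q = 0.5, W_A = 1, the regime with
#' single-cohort cycles and skipped reproduction years).
#'
#' @param name preset name.
#' @param model `"pspm"` or `"stage"`.
#' @param n_stages juvenile stage count for the stage model.
#' @param n_years number of seasons.
#' @param sample_interval trace sampling interval (days), `NA` for
#'   boundaries only.
#' @return A [sim_config].
#' @export
preset_config <- function(name = c("symmetric", "adult_superior",
                                   "juvenile_superior",
                                   "small_juvenile_superior"),
                          model = c("stage", "pspm"), n_stages = 1L,
                          n_years = 100L, sample_interval = 1) {
  name <- match.arg(name)
  model <- match.arg(model)
  sp <- switch(name,
               symmetric = species_params(W_A = 50, q = 1),
               adult_superior = species_params(W_A = 50, q = 1.5),
               juvenile_superior = species_params(W_A = 50, q = 0.5),
               small_juvenile_superior = species_params(W_A = 1, q = 0.5))
  sim_config(model = model, sp = sp, rp = resource_params(),
             n_stages = n_stages, n_years = n_years,
             sample_interval = sample_interval)
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the standard parameter symbols: `model`, `n_stages`, `W_A`,
#' `q`, `H`, `sigma`, `z`, `Y`, `Sm`, `Sb`, `Rmax`, `delta`, `n_years`,
#' `sample_interval`, `init_biomass`. Missing keys fall back to defaults.
#'
#' @param path path to a YAML file.
#' @return A [sim_config].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  grab <- function(key, default) if (!is.null(y[[key]])) y[[key]] else default
  W_A <- grab("W_A", 50)
  z <- grab("z", 0.1)
  Sm <- grab("Sm", W_A)
  sp <- species_params(W_A = W_A, q = grab("q", 1), H = grab("H", 3),
                       sigma = grab("sigma", 0.5), z = z,
                       Sm = Sm, Sb = grab("Sb", z * Sm))
  rp <- resource_params(Rmax = grab("Rmax", 20), delta = grab("delta", 0.1))
  sim_config(model = grab("model", "stage"), sp = sp, rp = rp,
             n_stages = grab("n_stages", 1L), Y = grab("Y", 250),
             n_years = grab("n_years", 100L),
             init_biomass = grab("init_biomass", 0.1),
             sample_interval = grab("sample_interval", 1))
}
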