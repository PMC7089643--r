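#' Construct a PSPM state
#'
#' State of the cohort-based physiologically structured population model:
#' an ordered set of cohorts (adults first, then juveniles by descending
#' size), the resource density and the current time. Each cohort carries a
#' number density `c` (mg L^-1 g^-1), an individual body size `s` (g), a
#' per-capita reproductive storage `g` (g) and an `adult` flag. Adults sit
#' exactly at the maturation size `Sm` and do not grow; only adults may
#' carry storage. The stage label is explicit rather than inferred from
#' size, so that a juvenile cohort caught precisely at `Sm` by the event
#' locator is not silently misclassified.
#'
#' @param cohorts a data frame (or matrix) with columns `c`, `s`, `g` and
#'   optionally `adult` (defaults to `s >= Sm` when `sp` is given, else all
#'   juvenile); may have zero rows.
#' @param R resource density (mg/L), nonnegative.
#' @param t time (days).
#' @param sp a [species_params] object, used to validate sizes and derive
#'   the default `adult` flag.
#' @return An object of class `pspm_state`.
#' @export
pspm_state <- function(cohorts, R, t = 0, sp = NULL) {
  cohorts <- as.data.frame(cohorts)
  if (nrow(cohorts) == 0L)
    cohorts <- data.frame(c = numeric(0), s = numeric(0), g = numeric(0),
                          adult = logical(0))
  stopifnot(all(c("c", "s", "g") %in% names(cohorts)))
  if (is.null(cohorts$adult))
    cohorts$adult <- if (is.null(sp)) rep(FALSE, nrow(cohorts))
                     else cohorts$s >= sp$Sm
  cohorts <- cohorts[c("c", "s", "g", "adult")]
  stopifnot(all(cohorts$c >= 0), all(cohorts$g >= 0), R >= 0)
  if (!is.null(sp)) {
    stopifnot(all(cohorts$s >= sp$Sb - 1e-12 * sp$Sb),
              all(cohorts$s <= sp$Sm * (1 + 1e-12)))
    if (any(cohorts$g > 0 & !cohorts$adult))
      stop("juvenile cohorts cannot carry reproductive storage", call. = FALSE)
    cohorts$s[cohorts$adult] <- sp$Sm
  }
  ord <- order(cohorts$adult, cohorts$s, decreasing = TRUE)
  cohorts <- cohorts[ord, , drop = FALSE]
  rownames(cohorts) <- NULL
  structure(list(cohorts = cohorts, R = R, t = t), class = "pspm_state")
}

#' @export
print.pspm_state <- function(x, ...) {
  cat(sprintf(
    "PSPM state at t = %g days: %d cohort(s) (%d adult), R = %.4g mg/L\n",
    x$t, nrow(x$cohorts), sum(x$cohorts$adult), x$R))
  invisible(x)
}

#' Time derivatives of a PSPM state
#'
#' Continuous within-season dynamics: juvenile cohorts lose numbers to
#' (starvation-augmented) mortality and grow at the mass-specific net
#' production rate; adult cohorts do not grow but accumulate per-capita
#' storage at rate `nu_A^+ * Sm`; the resource follows semi-chemostat
#' renewal minus total consumer ingestion. Stored biomass neither forages
#' nor pays maintenance.
#'
#' @param state a [pspm_state].
#' @param sp a [species_params].
#' @param rp a [resource_params].
#' @return A list with `cohorts` (data frame of `dc`, `ds`, `dg`) and `dR`.
#' @export
pspm_rhs <- function(state, sp, rp) {
  adult <- state$cohorts$adult
  ch <- state$cohorts
  R <- state$R
  f <- functional_response(R, sp$H)
  nuJ <- sp$sigma * (2 - sp$q) * sp$rates$M * f - sp$rates$T
  nuA <- sp$sigma * sp$q * sp$rates$M * f - sp$rates$T
  dJ <- stage_mortality(nuJ, sp$rates$mu)
  dA <- stage_mortality(nuA, sp$rates$mu)
  dc <- ifelse(adult, -dA * ch$c, -dJ * ch$c)
  ds <- ifelse(adult, 0, positive_part(nuJ) * ch$s)
  dg <- ifelse(adult, positive_part(nuA) * sp$Sm, 0)
  grazing <- sp$rates$M * f *
    ((2 - sp$q) * sum(ch$c[!adult] * ch$s[!adult]) +
       sp$q * sum(ch$c[adult]) * sp$Sm)
  dR <- if (rp$fixed) 0 else rp$delta * (rp$Rmax - R) - grazing
  list(cohorts = data.frame(dc = dc, ds = ds, dg = dg), dR = dR)
}

#' Maturation event indicator
#'
#' Signed distance of the largest juvenile cohort from the maturation size:
#' negative before the event, zero when the cohort reaches `Sm`. With no
#' juvenile cohorts a `-Inf` sentinel is returned (no event possible).
#'
#' @param state a [pspm_state].
#' @param sp a [species_params].
#' @return `max(s_juvenile) - Sm`, or `-Inf` if there are no juveniles.
#' @export
maturation_event_fn <- function(state, sp) {
  juv <- !state$cohorts$adult
  if (!any(juv)) return(-Inf)
  max(state$cohorts$s[juv]) - sp$Sm
}

#' Apply a maturation event
#'
#' Relabels the largest juvenile cohort as an adult cohort, equal in number,
#' size and storage; its size is pinned to exactly `Sm` so adult sizes never
#' drift. All other cohorts and the resource are unchanged.
#'
#' @param state a [pspm_state] whose largest juvenile cohort has reached
#'   `Sm` within `tol` (relative).
#' @param sp a [species_params].
#' @param tol relative tolerance on `|s - Sm|` at the event.
#' @return The updated [pspm_state].
#' @export
apply_maturation <- function(state, sp, tol = 1e-7) {
  juv <- which(!state$cohorts$adult)
  if (length(juv) == 0L)
    stop("no juvenile cohort to mature", call. = FALSE)
  m <- juv[which.max(state$cohorts$s[juv])]
  if (abs(state$cohorts$s[m] - sp$Sm) > tol * sp$Sm)
    stop("largest juvenile cohort is not at the maturation size", call. = FALSE)
  state$cohorts$s[m] <- sp$Sm
  state$cohorts$adult[m] <- TRUE
  ord <- order(state$cohorts$adult, state$cohorts$s, decreasing = TRUE)
  state$cohorts <- state$cohorts[ord, , drop = FALSE]
  rownames(state$cohorts) <- NULL
  state
}

#' Apply the annual reproduction pulse (PSPM)
#'
#' Converts all stored reproductive biomass instantaneously into a single
#' newborn cohort of size `Sb`: the new cohort's number density is
#' `sum(g_i c_i) / Sb`, every existing cohort keeps its numbers and size but
#' has its storage reset to zero, and the resource is unchanged. Total
#' consumer biomass is conserved (storage converts 1:1 into newborn mass).
#' If no storage is present the state is returned unchanged.
#'
#' @param state a [pspm_state].
#' @param sp a [species_params].
#' @return The post-pulse [pspm_state], with attribute `"newborn_biomass"`
#'   giving the biomass (mg/L) of the newborn cohort.
#' @export
apply_reproduction_pspm <- function(state, sp) {
  spent <- sum(state$cohorts$g * state$cohorts$c)
  state$cohorts$g <- rep(0, nrow(state$cohorts))
  if (spent > 0) {
    newborn <- data.frame(c = spent / sp$Sb, s = sp$Sb, g = 0, adult = FALSE)
    state$cohorts <- rbind(state$cohorts, newborn)
    rownames(state$cohorts) <- NULL
  }
  attr(state, "newborn_biomass") <- spent
  state
}

#' Remove near-extinct cohorts
#'
#' Drops cohorts whose number density falls below `eps_c`, or whose biomass
#' `c * (s + g)` falls below a fraction `eps_b` of total consumer biomass.
#' The removed biomass is recorded in the `"culled_biomass"` attribute so
#' leakage can be monitored.
#'
#' @param state a [pspm_state].
#' @param eps_c absolute number-density threshold (mg L^-1 g^-1).
#' @param eps_b relative biomass threshold.
#' @return The compacted [pspm_state].
#' @export
cull_and_compact <- function(state, eps_c = 0, eps_b = 0) {
  stopifnot(eps_c >= 0, eps_b >= 0)
  ch <- state$cohorts
  biom <- ch$c * (ch$s + ch$g)
  total <- sum(biom)
  drop <- ch$c < eps_c | (eps_b > 0 & biom < eps_b * total)
  lost <- sum(biom[drop])
  state$cohorts <- ch[!drop, , drop = FALSE]
  rownames(state$cohorts) <- NULL
  attr(state, "culled_biomass") <- lost
  state
}

#' Stage-aggregated biomasses of a PSPM state
#'
#' @param state a [pspm_state].
#' @param sp a [species_params].
#' @return A list with juvenile biomass `J`, adult structural biomass `A`,
#'   reproductive-storage biomass `B`, `total = J + A + B` and the resource
#'   density `R` (all mg/L).
#' @export
aggregate_biomasses <- function(state, sp) {
  adult <- state$cohorts$adult
  ch <- state$cohorts
  J <- sum(ch$c[!adult] * ch$s[!adult])
  A <- sum(ch$c[adult]) * sp$Sm
  B <- sum(ch$c[adult] * ch$g[adult])
  list(J = J, A = A, B = B, total = J + A + B, R = state$R)
}

# ---- flattened representation for the ODE solver ------------------------

# y = c(R, c_1..c_k, s_1..s_k, g_1..g_k); the adult mask is frozen per
# integration segment (maturation events halt the solver).
pspm_flatten <- function(state) {
  ch <- state$cohorts
  c(state$R, ch$c, ch$s, ch$g)
}

pspm_unflatten <- function(y, k, t, adult, Sm) {
  if (k == 0L) {
    cohorts <- data.frame(c = numeric(0), s = numeric(0), g = numeric(0),
                          adult = logical(0))
  } else {
    s <- y[(k + 2):(2 * k + 1)]
    s[adult] <- Sm  # adults never grow; keep the pin exact
    cohorts <- data.frame(c = pmax(y[2:(k + 1)], 0),
                          s = s,
                          g = pmax(y[(2 * k + 2):(3 * k + 1)], 0),
                          adult = adult)
  }
  structure(list(cohorts = cohorts, R = max(y[1], 0), t = t),
            class = "pspm_state")
}

pspm_deriv_flat <- function(t, y, parms) {
  k <- parms$k
  R <- y[1]
  f <- R / (parms$H + R)
  nuJ <- parms$wJ * f - parms$T
  nuA <- parms$wA * f - parms$T
  dJ <- parms$mu - min(nuJ, 0)
  dA <- parms$mu - min(nuA, 0)
  if (k > 0L) {
    cv <- y[2:(k + 1)]
    sv <- y[(k + 2):(2 * k + 1)]
    adult <- parms$adult
    dc <- ifelse(adult, -dA * cv, -dJ * cv)
    ds <- ifelse(adult, 0, max(nuJ, 0) * sv)
    dg <- ifelse(adult, max(nuA, 0) * parms$Sm, 0)
    grazing <- parms$M * f *
      ((2 - parms$q) * sum(cv[!adult] * sv[!adult]) +
         parms$q * sum(cv[adult]) * parms$Sm)
  } else {
    dc <- ds <- dg <- numeric(0)
    grazing <- 0
  }
  dR <- if (parms$fixed) 0 else parms$delta * (parms$Rmax - R) - grazing
  list(c(dR, dc, ds, dg))
}

pspm_rootfun <- function(t, y, parms) {
  k <- parms$k
  juv <- if (k > 0L) !parms$adult else logical(0)
  if (!any(juv)) return(-1)
  max(y[(k + 2):(2 * k + 1)][juv]) - parms$Sm
}

pspm_parms <- function(state, sp, rp) {
  list(k = nrow(state$cohorts),
       adult = state$cohorts$adult,
       M = sp$rates$M, T = sp$rates$T, mu = sp$rates$mu,
       wJ = sp$sigma * (2 - sp$q) * sp$rates$M,
       wA = sp$sigma * sp$q * sp$rates$M,
       H = sp$H, q = sp$q, Sm = sp$Sm,
       Rmax = rp$Rmax, delta = rp$delta, fixed = rp$fixed)
}
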