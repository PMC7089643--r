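#' Construct a stage-structured state
#'
#' State of the stage-structured biomass model: juvenile biomass per stage
#' (`Jvec`, length `n`), adult biomass `A`, reproductive-storage biomass `B`
#' and resource density `R`, all in mg/L.
#'
#' @param Jvec juvenile biomass per stage (mg/L), nonnegative.
#' @param A adult biomass (mg/L).
#' @param B reproductive-storage biomass (mg/L).
#' @param R resource density (mg/L).
#' @param t time (days).
#' @return An object of class `stage_state`.
#' @export
stage_state <- function(Jvec, A = 0, B = 0, R, t = 0) {
  stopifnot(length(Jvec) >= 1L, all(Jvec >= 0), A >= 0, B >= 0, R >= 0)
  structure(list(Jvec = as.numeric(Jvec), A = A, B = B, R = R, t = t),
            class = "stage_state")
}

#' @export
print.stage_state <- function(x, ...) {
  cat(sprintf(
    "Stage state at t = %g days: J = %.4g (%d stage%s), A = %.4g, B = %.4g, R = %.4g mg/L\n",
    x$t, sum(x$Jvec), length(x$Jvec), if (length(x$Jvec) > 1) "s" else "",
    x$A, x$B, x$R))
  invisible(x)
}

#' Time derivatives of the stage-structured biomass model
#'
#' Within-season dynamics for `n >= 1` energetically equivalent juvenile
#' stages chained in series, an adult stage and a storage pool. Each
#' juvenile stage gains biomass through net production, loses it to
#' mortality, and passes it to the next stage (the last into the adult
#' stage) at the size-independent maturation rate
#' `gamma = maturation_rate(nu_J, d_J, z^(1/n))`. Adults route their net
#' production into the storage pool `B`, which pays no maintenance, does not
#' forage, and perishes with its owners at the adult mortality rate. The
#' resource follows semi-chemostat renewal minus ingestion by juveniles
#' (foraging weight `2 - q`) and adults (weight `q`); stored biomass does
#' not feed.
#'
#' @param state a [stage_state].
#' @param sp a [species_params].
#' @param rp a [resource_params].
#' @return A list with `dJvec`, `dA`, `dB`, `dR`.
#' @export
stage_rhs <- function(state, sp, rp) {
  n <- length(state$Jvec)
  y <- c(state$Jvec, state$A, state$B, state$R)
  d <- stage_deriv_flat(state$t, y, stage_parms(sp, rp, n))[[1]]
  list(dJvec = d[seq_len(n)], dA = d[n + 1], dB = d[n + 2], dR = d[n + 3])
}

#' Apply the annual reproduction pulse (stage model)
#'
#' The storage pool converts instantaneously into newborn biomass entering
#' the first juvenile stage: `J_1 += B`, `B = 0`; `A` and `R` are unchanged
#' and total consumer biomass is conserved.
#'
#' @param state a [stage_state].
#' @return The post-pulse [stage_state], with attribute `"newborn_biomass"`.
#' @export
apply_reproduction_stage <- function(state) {
  spent <- state$B
  state$Jvec[1] <- state$Jvec[1] + spent
  state$B <- 0
  attr(state, "newborn_biomass") <- spent
  state
}

# ---- flattened representation for the ODE solver ------------------------

# y = c(J_1..J_n, A, B, R)
stage_parms <- function(sp, rp, n) {
  list(n = n,
       M = sp$rates$M, T = sp$rates$T, mu = sp$rates$mu,
       wJ = sp$sigma * (2 - sp$q) * sp$rates$M,
       wA = sp$sigma * sp$q * sp$rates$M,
       H = sp$H, q = sp$q,
       z_eff = stage_size_ratio(sp$z, n),
       Rmax = rp$Rmax, delta = rp$delta, fixed = rp$fixed)
}

stage_deriv_flat <- function(t, y, parms) {
  n <- parms$n
  Jv <- y[seq_len(n)]
  A <- y[n + 1]; B <- y[n + 2]; R <- y[n + 3]
  f <- max(R, 0) / (parms$H + max(R, 0))
  nuJ <- parms$wJ * f - parms$T
  nuA <- parms$wA * f - parms$T
  dJm <- parms$mu - min(nuJ, 0)
  dAm <- parms$mu - min(nuA, 0)
  gam <- maturation_rate(nuJ, dJm, parms$z_eff)
  outflow <- gam * Jv
  inflow <- c(0, outflow[-n])
  dJ <- max(nuJ, 0) * Jv - outflow - dJm * Jv + inflow
  dA <- outflow[n] - dAm * A
  dB <- max(nuA, 0) * A - dAm * B
  dR <- if (parms$fixed) 0 else
    parms$delta * (parms$Rmax - R) -
      ((2 - parms$q) * sum(Jv) + parms$q * A) * parms$M * f
  list(c(dJ, dA, dB, dR))
}
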