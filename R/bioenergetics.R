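#' Allometric mass-specific rates
#'
#' Derives the mass-specific maximum ingestion rate `M`, maintenance rate `T`
#' and background mortality rate `mu` from a characteristic adult body size
#' `W_A` by quarter-power scaling. The prefactors (0.1, 0.01, 0.0015 per day
#' at `W_A = 1` g) follow the standard bioenergetic parameterization for
#' invertebrate consumers.
#'
#' @param W_A characteristic adult body size in grams; must be positive.
#' @return An object of class `rate_set`: a list with components `M`, `T`
#'   and `mu`, all in day^-1.
#' @examples
#' allometric_rates(50)
#' @export
allometric_rates <- function(W_A) {
  if (!is.numeric(W_A) || length(W_A) != 1L || !is.finite(W_A) || W_A <= 0)
    stop("'W_A' must be a single positive number", call. = FALSE)
  scale <- W_A^(-0.25)
  structure(
    list(M = 0.1 * scale, T = 0.01 * scale, mu = 0.0015 * scale),
    class = "rate_set"
  )
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Mass-specific rates (day^-1):\n")
  cat(sprintf("  max ingestion M  = %.6g\n", x$M))
  cat(sprintf("  maintenance   T  = %.6g\n", x$T))
  cat(sprintf("  mortality     mu = %.6g\n", x$mu))
  invisible(x)
}

#' Consumer species parameters
#'
#' Bundles the bioenergetic parameters of a consumer species. All
#' mass-specific rates are derived from `W_A` unless a `rates` object is
#' supplied explicitly. The size at maturation defaults to `W_A` (adults do
#' not grow) and the size at birth to `z * Sm`.
#'
#' @param W_A characteristic adult body size (g).
#' @param q stage competition asymmetry: juveniles forage with weight
#'   `(2 - q)`, adults with weight `q`, so `q < 1` favours juveniles and
#'   `q > 1` favours adults. Must lie in (0, 2).
#' @param H half-saturation resource density (mg/L).
#' @param sigma assimilation efficiency in (0, 1].
#' @param z ratio of size at birth to size at maturation, in (0, 1).
#' @param Sm size at maturation (g); defaults to `W_A`.
#' @param Sb size at birth (g); defaults to `z * Sm`.
#' @param rates optional `rate_set`; defaults to [allometric_rates]`(W_A)`.
#' @return An object of class `species_params`.
#' @examples
#' sp <- species_params(W_A = 50, q = 1)
#' sp$rates$M
#' @export
species_params <- function(W_A = 50, q = 1, H = 3, sigma = 0.5, z = 0.1,
                           Sm = W_A, Sb = z * Sm, rates = allometric_rates(W_A)) {
  stopifnot(is.numeric(q), length(q) == 1L, q > 0, q < 2)
  stopifnot(is.numeric(H), length(H) == 1L, H > 0)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0, sigma <= 1)
  stopifnot(is.numeric(z), length(z) == 1L, z > 0, z < 1)
  stopifnot(is.numeric(Sm), length(Sm) == 1L, Sm > 0)
  stopifnot(is.numeric(Sb), length(Sb) == 1L, Sb > 0, Sb < Sm)
  stopifnot(inherits(rates, "rate_set"))
  structure(
    list(rates = rates, W_A = W_A, q = q, H = H, sigma = sigma,
         z = z, Sm = Sm, Sb = Sb),
    class = "species_params"
  )
}

#' Resource parameters
#'
#' Parameters of the shared resource, which follows semi-chemostat growth
#' `dR/dt = delta * (Rmax - R)` in the absence of consumers.
#'
#' @param Rmax maximum resource density (mg/L).
#' @param delta turnover rate (day^-1).
#' @param fixed if `TRUE` the resource is held constant (dR/dt = 0); used for
#'   constant-environment calculations such as maturation-curve checks.
#' @return An object of class `resource_params`.
#' @export
resource_params <- function(Rmax = 20, delta = 0.1, fixed = FALSE) {
  stopifnot(is.numeric(Rmax), length(Rmax) == 1L, Rmax > 0)
  stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0)
  stopifnot(is.logical(fixed), length(fixed) == 1L)
  structure(list(Rmax = Rmax, delta = delta, fixed = fixed),
            class = "resource_params")
}

#' Holling type II functional response
#'
#' @param R resource density (mg/L), vectorized; must be nonnegative.
#' @param H half-saturation density (mg/L).
#' @return Fraction of the maximum ingestion rate realized, in `[0, 1)`.
#' @export
functional_response <- function(R, H) {
  if (any(R < 0)) stop("resource density must be nonnegative", call. = FALSE)
  stopifnot(H > 0)
  R / (H + R)
}

#' Mass-specific net biomass production
#'
#' Assimilated intake minus maintenance, per unit body mass. Juveniles forage
#' with weight `(2 - q)`, adults with weight `q`. The value is negative under
#' starvation (intake below maintenance).
#'
#' @param R resource density (mg/L), vectorized.
#' @param stage `"juvenile"` or `"adult"`.
#' @param sp a [species_params] object.
#' @return Net production rate (day^-1); may be negative.
#' @export
net_production <- function(R, stage = c("juvenile", "adult"), sp) {
  stage <- match.arg(stage)
  w <- if (stage == "juvenile") 2 - sp$q else sp$q
  sp$sigma * w * sp$rates$M * functional_response(R, sp$H) - sp$rates$T
}

#' Positive part of a rate
#'
#' Net production restricted to positive values: under starvation growth,
#' maturation and reproductive investment all stop.
#'
#' @param nu rate(s), vectorized.
#' @return `pmax(nu, 0)`.
#' @export
positive_part <- function(nu) pmax(nu, 0)

#' Stage-specific per-capita mortality
#'
#' Background mortality augmented by starvation loss: when net production
#' `nu` is negative the biomass shortfall is paid as additional mortality,
#' so the result is `mu - min(nu, 0)`.
#'
#' @param nu net biomass production rate(s) (day^-1), vectorized.
#' @param mu background mortality rate (day^-1), nonnegative.
#' @return Per-capita mortality rate(s), always `>= mu`.
#' @export
stage_mortality <- function(nu, mu) {
  stopifnot(all(mu >= 0))
  mu - pmin(nu, 0)
}

#' Size-independent maturation rate
#'
#' Per-capita rate at which juvenile biomass is promoted to the next stage in
#' the stage-structured model. The rate is constructed so that, at constant
#' resource density, the expected lifetime biomass an individual delivers to
#' the adult stage matches the cohort model, in which an individual grows
#' exponentially at rate `nu` from `z_eff * S` to `S` and survives with
#' mortality `d`:
#'
#'   gamma(nu, d) = (nu - d) / (1 - z_eff^(1 - d/nu))   for nu > 0,
#'   gamma = 0 otherwise.
#'
#' The apparent singularity at `nu = d` is removable with limit
#' `-d / log(z_eff)`; the implementation evaluates the expression through
#' `expm1`, which is accurate uniformly in `|nu - d|` and continuous through
#' the limit.
#'
#' @param nu juvenile net biomass production (day^-1), vectorized.
#' @param d juvenile per-capita mortality (day^-1), vectorized, nonnegative.
#' @param z_eff ratio of stage-entry size to stage-exit size, in (0, 1).
#' @return Maturation rate(s) (day^-1), nonnegative and continuous in `nu`.
#' @export
maturation_rate <- function(nu, d, z_eff) {
  if (!is.numeric(z_eff) || length(z_eff) != 1L || z_eff <= 0 || z_eff >= 1)
    stop("'z_eff' must lie strictly between 0 and 1", call. = FALSE)
  stopifnot(all(d >= 0))
  n <- max(length(nu), length(d))
  nu <- rep_len(nu, n); d <- rep_len(d, n)
  out <- numeric(n)
  pos <- nu > 0
  if (any(pos)) {
    # gamma = (nu - d)/(1 - z^(1 - d/nu)) rewritten with w = (1 - d/nu) log(z):
    # gamma = nu * w / (-log(z) * expm1(w)); w/expm1(w) -> 1 as w -> 0.
    lz <- log(z_eff)
    w <- (1 - d[pos] / nu[pos]) * lz
    ratio <- ifelse(w == 0, 1, w / expm1(w))
    out[pos] <- -nu[pos] * ratio / lz
  }
  out
}

#' Size ratio of one of n equivalent juvenile sub-stages
#'
#' Splits the juvenile size range `[Sb, Sm]` (overall entry/exit ratio `z`)
#' into `n` sub-stages that are equal on a log-size scale, so each stage has
#' entry/exit ratio `z^(1/n)` and the product over stages recovers `z`.
#'
#' @param z overall birth-to-maturation size ratio, in (0, 1).
#' @param n number of juvenile stages, integer `>= 1`.
#' @return The per-stage size ratio `z^(1/n)`.
#' @export
stage_size_ratio <- function(z, n) {
  stopifnot(z > 0, z < 1)
  if (length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer", call. = FALSE)
  z^(1 / n)
}

#' Expected lifetime biomass contribution to the adult stage
#'
#' Under constant conditions with positive net production `nu`, a newborn of
#' size `Sb = z * Sm` matures after `-log(z)/nu` days with survival
#' `z^(mu/nu)`, so the expected biomass it delivers to the adult stage is
#' `Sm * z^(mu/nu)`. This is the quantity the stage-structured maturation
#' rate is built to preserve.
#'
#' @param nu juvenile net biomass production (day^-1), vectorized.
#' @param mu background mortality (day^-1), vectorized, nonnegative.
#' @param z birth-to-maturation size ratio, in (0, 1).
#' @param Sm size at maturation (g).
#' @return Expected biomass (g) delivered to the adult stage per newborn;
#'   zero when `nu <= 0` (no maturation).
#' @export
expected_adult_contribution <- function(nu, mu, z, Sm) {
  stopifnot(z > 0, z < 1, Sm > 0, all(mu >= 0))
  ifelse(nu > 0, Sm * z^(mu / nu), 0)
}
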