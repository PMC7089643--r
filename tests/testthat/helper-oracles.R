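# Shared fixtures and independent oracles used across test files.

default_sp <- function(W_A = 50, q = 1) species_params(W_A = W_A, q = q)

# Quadrature oracle for the expected lifetime biomass delivered to the
# adult stage in the one-stage model: integral of gamma * Sb * exp((nu -
# mu - gamma) t) over [0, Inf), evaluated by adaptive quadrature and thus
# independent of the closed-form survival expression.
quadrature_contribution <- function(nu, mu, z, Sm) {
  gam <- maturation_rate(nu, mu, z)
  stats::integrate(function(t) gam * z * Sm * exp((nu - mu - gam) * t),
                   lower = 0, upper = Inf, rel.tol = 1e-10)$value
}

# Random but reproducible grid of (nu, mu, z) parameter combinations with
# positive net production, spanning the biologically relevant ranges.
param_grid <- function(n = 120, seed = 42) {
  set.seed(seed)
  data.frame(nu = runif(n, 1e-4, 0.05),
             mu = runif(n, 0, 0.01),
             z = runif(n, 0.02, 0.9))
}

# Total consumer biomass of a PSPM state, independent of the package's
# aggregation helper.
raw_total_biomass <- function(state) {
  with(state$cohorts, sum(c * (s + g)))
}
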