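# Reference parameter set shared across tests: k_in = 1/day, k = 2,
# beta = 0.7, C0 = 200 nM; E0 = 120, Emax = 0.6931, IC50 = 300 nM,
# gamma = 1; c = 4.6e-3 /(nM day), lambda = 0.5/day, T0 = 1000 mm^3,
# Tmax = 2e4 mm^3; theta = 0.1 d.
default_payload <- function(...) payload_params(...)
default_dr <- function(...) dose_response_params(...)
default_tumor <- function(...) tumor_params(...)

# random valid payload parameter sets for property-style loops
random_payload <- function() {
  payload_params(
    k_in = runif(1, 0.5, 2),
    k_out = runif(1, 0.2, 3),
    beta = runif(1, 0.05, 1),
    C0 = runif(1, 10, 300)
  )
}

grid60 <- seq(0, 60, by = 0.1)
grid30 <- seq(0, 30, by = 0.1)
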