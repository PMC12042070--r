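# Random valid energetic contexts spanning wide, ecologically plausible
# ranges (microbial to mammalian scales) for property-style tests.
random_contexts <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    D <- 10^runif(n, -3, 4)
    E <- 10^runif(n, 0, 1)
    MN <- 10^runif(n, -8, 5)
    Nlow <- 10^runif(n, -6, 6)
    Nhigh <- Nlow * 10^runif(n, 0, 4)
    IS <- runif(n, 0.05, 0.99)
    energetic_context(D, E, MN, Nlow, Nhigh, IS)
  })
}

# config used by the deterministic end-to-end identity tests
noiseless_config <- function(n, seed = 1L) {
  generator_config(n_records = n, obs_noise_sigma_a = 0, obs_noise_sigma_h = 0,
                   seed = seed)
}
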