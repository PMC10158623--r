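# Shared fixtures: everything is generated in code, no stored data.

fix_carrier <- function() cytodex3()

fix_setup <- function(c_MC = 10, c_Glc = 25, c_Gln = 12, ...) {
  culture_setup(c_MC = c_MC, seed_density = 6000, c_Glc = c_Glc,
                c_Gln = c_Gln, carrier = fix_carrier(), ...)
}

# truth with the default cadence (24 h to 120 h, then 48 h)
fix_truth <- function(noise = 0.15) ground_truth(noise = noise)

# small free set for quick round-trip fits
fix_free <- c("mu_max", "Y_X_Glc", "Y_Lac_Glc", "q_LS_max")

# init guess: truth with the free parameters offset by fixed factors
fix_init <- function(free = fix_free, factor = 1.4) {
  p <- unclass(kinetic_params())
  p[free] <- p[free] * factor
  as_kinetic_params(p)
}

# a tiny 2-factor space for design oracles
fix_space2 <- function() factor_space(c("a", "b"), c(0, 10), c(1, 20))

# brute-force oracle helper: all n-multisets of candidate indices
multisets <- function(nc, n) {
  if (n == 1) return(matrix(seq_len(nc), ncol = 1))
  prev <- multisets(nc, n - 1)
  do.call(rbind, lapply(seq_len(nrow(prev)), function(i) {
    last <- prev[i, n - 1]
    cbind(matrix(prev[i, ], nrow = nc - last + 1, ncol = n - 1,
                 byrow = TRUE), seq(last, nc))
  }))
}

fix_space3 <- function() default_factor_space()
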