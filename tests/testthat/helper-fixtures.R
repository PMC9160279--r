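# shared fixtures: the characterized sludge composition and helpers

sludge_ultimate_path <- function() {
  system.file("extdata", "sludge_ultimate.csv", package = "biogasim")
}

sludge_proximate_path <- function() {
  system.file("extdata", "sludge_proximate.csv", package = "biogasim")
}

sludge_ua <- function() load_ultimate_analysis(sludge_ultimate_path())

sludge_formula <- function(basis_mass = 100) {
  to_empirical_formula(sludge_ua(), basis_mass)
}

# independent oracle: solve the explicit 5x5 element-balance linear
# system for CaHbOcNdSe + w H2O -> n1 CH4 + n2 CO2 + n3 NH3 + n4 H2S
# (unknowns w, n1, n2, n3, n4; rows are C, H, O, N, S balances)
balance_oracle <- function(f) {
  A <- rbind(
    c(0, 1, 1, 0, 0),   # C
    c(-2, 4, 0, 3, 2),  # H: b + 2w on the reactant side
    c(-1, 0, 2, 0, 0),  # O: c + w
    c(0, 0, 0, 1, 0),   # N
    c(0, 0, 0, 0, 1)    # S
  )
  x <- solve(A, c(f$a, f$b, f$c, f$d, f$e))
  names(x) <- c("water", "ch4", "co2", "nh3", "h2s")
  x
}

# random biomass-like elemental formula (feasible for the Boyle model)
random_formula <- function() {
  repeat {
    cf <- runif(1, 0.3, 0.6)
    hf <- runif(1, 0.04, 0.10)
    nf <- runif(1, 0, 0.05)
    sf <- runif(1, 0, 0.02)
    of <- 1 - cf - hf - nf - sf
    if (of < 0) next
    ua <- ultimate_analysis(cf, hf, nf, sf, of)
    f <- to_empirical_formula(ua, 100)
    ok <- tryCatch({ boyle_coefficients(f); TRUE },
                   biogasim_infeasible_feedstock = function(e) FALSE)
    if (ok) return(f)
  }
}
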