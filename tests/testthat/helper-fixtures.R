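# Shared fixtures: all synthetic, built in code at test time.

# A minimal all-forest grid with one invaded cell; handy for simulator tests.
single_cell_grid <- function(P0 = 10, K = 100) {
  g <- generate_grid(1, generator_config(land_type_props = c(forest = 1),
                                         n_foci = 1),
                     seed = 1)
  g$occupancy0 <- P0
  g$carrying_capacity <- rep(K, 1)
  g
}

forest_grid <- function(n, n_foci = 3, seed = 1) {
  generate_grid(n, generator_config(land_type_props = c(forest = 1),
                                    n_foci = n_foci), seed = seed)
}

make_survey_pair <- function(P1, P2, t1 = 2003, t2 = 2008,
                             excluded = rep(NA_character_, length(P1))) {
  structure(list(t1 = t1, t2 = t2, P_t1 = P1, P_t2 = P2, excluded = excluded),
            class = "survey_pair")
}

# All 24 permutations of 1:4, for exhaustive Mantel enumeration.
perms4 <- function() {
  out <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b))) {
    out[[length(out) + 1]] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
  }
  out
}
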