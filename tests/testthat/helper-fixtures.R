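# shared fixtures: small pedigrees and herds built in code

# founders S, D; offspring O
trio_ped <- function() {
  pedigree(c("S", "D", "O"), c(NA, NA, "S"), c(NA, NA, "D"))
}

# founders -> full sibs X, Y -> inbred C (full-sib mating)
fullsib_ped <- function() {
  pedigree(c("S", "D", "X", "Y", "C"),
           c(NA, NA, "S", "S", "X"),
           c(NA, NA, "D", "D", "Y"))
}

# random valid pedigree of n animals: each non-founder picks earlier parents
random_ped <- function(n, p_known = 0.7) {
  ids <- sprintf("A%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && stats::runif(1) < p_known) {
      pick <- sample(i - 1L, 2L)
      sire[i] <- ids[pick[1]]
      dam[i] <- ids[pick[2]]
    }
  }
  pedigree(ids, sire, dam)
}

# small herd for sampler smoke tests (kept tiny for speed)
small_herd <- function(seed = 424, ...) {
  cfg <- sim_config(n_sires = 15, n_dams = 80, n_generations = 2,
                    n_herds = 2, years = 2014:2018, seed = seed, ...)
  simulate_herd(cfg)
}

quick_spec <- function(model = 1, cycles = 2000, burn = 400, thin = 4,
                       seed = 99, ...) {
  model_spec(model = model, total_cycles = cycles, burn_in = burn,
             thin = thin, seed = seed, ...)
}
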