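# Shared fixtures: tiny hand-built tables and deterministic simulations.

# minimal 2-genotype paired table with hand-pickable trait values
tiny_table <- function(sla = c(180, 190, 230, 240)) {
  trait_table(data.frame(
    genotype_id = rep(c("D01", "W01"), 2),
    population = rep(c("Dune", "Woods"), 2),
    habitat = rep(c("open", "shaded"), each = 2),
    SLA = sla))
}

# deterministic table: no genotype variation, no noise -> values equal means
noiseless_config <- function(means = default_trait_means(), n = 10, ...) {
  means$cv_pct <- 0
  sim_config(means = means, sigma_G = 0, sigma_PL = 0, n_genotypes = n, ...)
}

# restrict the default parameterization to a subset of traits (fast sims)
means_subset <- function(traits) {
  m <- default_trait_means()
  m[m$trait %in% traits, ]
}

# default simulation used across tests
default_sim <- function(seed = 42, ...) {
  simulate_experiment(sim_config(seed = seed, ...))
}
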