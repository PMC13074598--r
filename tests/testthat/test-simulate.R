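test_that("degenerate noise settings return the configured means exactly", {
  sim <- simulate_experiment(noiseless_config(n = 3))
  m <- default_trait_means()
  # directly drawn traits equal mu[p,h] exactly; Chl_tot / Chl_ab_ratio are
  # derived from Chl_a and Chl_b, so Chl_tot equals the sum of parent means
  off <- sim_config()$odac_offset
  for (tr in setdiff(unique(m$trait), c("Chl_tot", "Chl_ab_ratio"))) {
    for (i in seq_len(nrow(sim$table))) {
      mu <- m$mean[m$trait == tr & m$population == sim$table$population[i] &
                     m$habitat == sim$table$habitat[i]]
      if (tr == "MDA" && sim$table$population[i] == "Dune") mu <- mu * off
      expect_identical(sim$table[[tr]][i], mu)
    }
  }
  expect_equal(sim$table$Chl_tot, sim$table$Chl_a + sim$table$Chl_b)
  # MDA carries the Dune offset
  dune_open <- sim$table$MDA[sim$table$population == "Dune"]
  woods_open <- sim$table$MDA[sim$table$population == "Woods"]
  expect_equal(unique(dune_open) / unique(woods_open),
               sim_config()$odac_offset)
})

test_that("the seed fully determines the table and different seeds differ", {
  a <- simulate_experiment(sim_config(seed = 7))
  b <- simulate_experiment(sim_config(seed = 7))
  c <- simulate_experiment(sim_config(seed = 8))
  expect_identical(a$table, b$table)
  expect_identical(a$truth$genotype_effects, b$truth$genotype_effects)
  expect_false(identical(a$table, c$table))
})

test_that("per-trait substreams are unaffected by dropping other traits", {
  full <- simulate_experiment(sim_config(seed = 3))
  sla_only <- simulate_experiment(sim_config(means = means_subset("SLA"),
                                             seed = 3))
  expect_identical(sla_only$table$SLA, full$table$SLA)
})

test_that("simulated tables are balanced, positive and CV-calibrated", {
  sim <- default_sim(seed = 1)
  expect_true(validate_paired_design(sim$table)$balanced)
  for (tr in trait_columns(sim$table)) expect_true(all(sim$table[[tr]] > 0))

  # group means recover the configured locations within 3 SE
  s <- summarize_groups(sim$table)
  m <- default_trait_means()
  checked <- 0
  off <- sim_config()$odac_offset
  for (i in seq_len(nrow(s))) {
    if (!s$trait[i] %in% m$trait) next
    if (s$trait[i] %in% c("Chl_tot", "Chl_ab_ratio")) next  # derived
    mu <- m$mean[m$trait == s$trait[i] & m$population == s$population[i] &
                   m$habitat == s$habitat[i]]
    if (s$trait[i] == "MDA" && s$population[i] == "Dune") mu <- mu * off
    expect_lt(abs(s$mean[i] - mu), 3.5 * max(s$se[i], 1e-12))
    checked <- checked + 1
  }
  expect_equal(checked, 11 * 4)
})

test_that("truncated-normal noise stays positive and hits the mean", {
  cf <- sim_config(means = means_subset("SLA"), noise = "truncated-normal",
                   n_genotypes = 10, seed = 11)
  sim <- simulate_experiment(cf)
  expect_true(all(sim$table$SLA > 0))
  s <- summarize_groups(sim$table)
  expect_lt(abs(s$mean[1] - 180.6) / 180.6, 0.2)
})

test_that("a one-sd habitat effect is detected in most replicates", {
  # planted effect: shaded mean = open mean * (1 + CV), i.e. one within-group
  # sd; the two-way habitat term should reject in >= 80% of replicates
  m <- means_subset("SLA")
  m$mean <- ifelse(m$habitat == "shaded", 100 * 1.15, 100)
  m$cv_pct <- 15
  hits <- 0
  reps <- 200
  for (i in seq_len(reps)) {
    cf <- sim_config(means = m, sigma_G = 0, sigma_PL = 0, seed = 5000 + i)
    tab <- simulate_experiment(cf)$table
    at <- two_way_anova_balanced(tab$SLA, tab$habitat, tab$population)
    if (at$p[at$term == "habitat"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.73)
})

test_that("config files round-trip through YAML and JSON", {
  cf <- sim_config(n_genotypes = 4, seed = 99, odac_offset = 2.5)
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_genotypes = 4, seed = 99, odac_offset = 2.5), yml)
  cf_y <- read_sim_config(yml)
  expect_equal(cf_y$n_genotypes, 4L)
  expect_equal(cf_y$odac_offset, 2.5)
  expect_identical(simulate_experiment(cf_y)$table,
                   simulate_experiment(cf)$table)

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_genotypes = 4, seed = 99, odac_offset = 2.5),
                       js, auto_unbox = TRUE)
  expect_identical(simulate_experiment(read_sim_config(js))$table,
                   simulate_experiment(cf)$table)
})

test_that("configurations implying non-positive locations are refused", {
  expect_error(sim_config(n_genotypes = 1), "n_genotypes")
  m <- means_subset("SLA")
  m$mean[1] <- -1
  expect_error(sim_config(means = m), "> 0")
  cf <- sim_config(means = means_subset("SLA"), sigma_G = 0.8, seed = 2)
  # sigma_G this large eventually drives 1 + G below zero
  expect_error(
    {
      for (s in 1:50) {
        cf$seed <- s
        simulate_experiment(cf)
      }
    }, "non-positive location")
})
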