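test_that("CSV loading round-trips a complete table and preserves auxiliaries", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(genotype_id = c("D01", "D01"), population = "Dune",
                   habitat = c("open", "shaded"),
                   SLA = c(180.6, 232.4), LDMC = c(0.1996, 0.1801),
                   extra_trait = c(1.5, 2.5))
  utils::write.csv(df, path, row.names = FALSE)
  tab <- load_trait_table(path)
  expect_s3_class(tab, "trait_table")
  expect_equal(nrow(tab), 2)
  expect_true("extra_trait" %in% trait_columns(tab))
  expect_equal(tab$SLA, c(180.6, 232.4))

  out <- withr::local_tempfile(fileext = ".csv")
  sim <- default_sim()
  write_trait_table(sim$table, out)
  back <- load_trait_table(out)
  for (tr in trait_columns(sim$table)) {
    expect_equal(back[[tr]], sim$table[[tr]], tolerance = 1e-15)
  }
})

test_that("delimiter auto-detection handles tab and semicolon exports", {
  df <- data.frame(genotype_id = "D01", population = "Dune", habitat = "open",
                   SLA = 180.6)
  for (sep in c("\t", ";")) {
    path <- withr::local_tempfile(fileext = ".txt")
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    expect_equal(load_trait_table(path)$SLA, 180.6)
  }
})

test_that("schema and validation errors name the offending column or row", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(genotype_id = "D01", population = "Dune",
                              SLA = 100), path, row.names = FALSE)
  expect_error(load_trait_table(path), "habitat")

  base <- data.frame(genotype_id = "D01", population = "Dune",
                     habitat = "open")
  expect_error(trait_table(cbind(base, SLA = -3)), "non-positive.*SLA")
  expect_error(trait_table(cbind(base, Chl_a = 8, Chl_b = 2, Chl_tot = 11)),
               "Chl_tot")
  expect_error(trait_table(cbind(base, Chl_a = 8, Chl_b = 2, Chl_ab_ratio = 3)),
               "Chl_ab_ratio")
  dup <- rbind(base, base)
  dup$SLA <- c(1, 2)
  expect_error(trait_table(dup), "duplicate")
  expect_error(trait_table(cbind(base, SLA = NA_real_)), "missing")
  expect_silent(trait_table(cbind(base, SLA = NA_real_), allow_missing = TRUE))
})

test_that("Chl_tot and Chl_ab_ratio are recomputed when absent", {
  tab <- trait_table(data.frame(genotype_id = "D01", population = "Dune",
                                habitat = "open", Chl_a = 8, Chl_b = 2))
  expect_equal(tab$Chl_tot, 10)
  expect_equal(tab$Chl_ab_ratio, 4)
})

test_that("paired-design validation reports balance and missing cells", {
  sim <- default_sim()
  rep_full <- validate_paired_design(sim$table)
  expect_true(rep_full$balanced)
  expect_equal(unname(rep_full$n_genotypes), c(10L, 10L))

  drop_one <- sim$table[!(sim$table$genotype_id == "D03" &
                            sim$table$habitat == "shaded"), ]
  rep_miss <- validate_paired_design(drop_one)
  expect_false(rep_miss$balanced)
  expect_equal(rep_miss$missing_cells$genotype_id, "D03")
  expect_equal(rep_miss$missing_cells$habitat, "shaded")

  dune_only <- sim$table[sim$table$population == "Dune", ]
  expect_false(validate_paired_design(dune_only)$balanced)

  shuffled <- sim$table[sample(nrow(sim$table)), ]
  expect_equal(validate_paired_design(shuffled)$balanced, rep_full$balanced)
})

test_that("group summaries match hand-computed mean, SE and CV", {
  tab <- trait_table(data.frame(
    genotype_id = c("D01", "D02", "D03", "W01", "W02"),
    population = c("Dune", "Dune", "Dune", "Woods", "Woods"),
    habitat = "open",
    SLA = c(1, 2, 3, 5, 5)))
  s <- summarize_groups(tab)
  dune <- s[s$population == "Dune", ]
  expect_equal(dune$mean, 2)
  expect_equal(dune$se, 1 / sqrt(3), tolerance = 1e-12)  # sd = 1
  expect_equal(dune$cv_pct, 50)
  woods <- s[s$population == "Woods", ]
  expect_equal(woods$mean, 5)
  expect_equal(woods$se, 0)
  expect_equal(woods$cv_pct, 0)
})

test_that("CV%% is scale invariant and singleton groups are flagged", {
  sim <- default_sim()
  s1 <- summarize_groups(sim$table)
  scaled <- sim$table
  scaled$SLA <- scaled$SLA * 7.3
  s2 <- summarize_groups(scaled)
  sel <- s1$trait == "SLA"
  expect_equal(s2$cv_pct[s2$trait == "SLA"], s1$cv_pct[sel], tolerance = 1e-12)

  single <- trait_table(data.frame(
    genotype_id = c("D01", "D02", "W01"),
    population = c("Dune", "Dune", "Woods"), habitat = "open",
    SLA = c(1, 2, 3)))
  expect_warning(s <- summarize_groups(single), "size 1")
  expect_true(is.na(s$se[s$population == "Woods"]))
  expect_true(s$degenerate[s$population == "Woods"])
})

test_that("noiseless simulation at reference means reproduces them exactly", {
  sim <- simulate_experiment(noiseless_config())
  s <- summarize_groups(sim$table)
  sel <- s$trait == "SLA" & s$population == "Dune" & s$habitat == "open"
  expect_identical(s$mean[sel], 180.6)
  expect_identical(s$cv_pct[sel], 0)
})
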