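test_that("identical config and seed give byte-identical tables", {
  cfg1 <- sim_config(seed = 123)
  cfg2 <- sim_config(seed = 123)
  for (gen in list(gen_mating_trials, gen_oviposition, gen_compound_table,
                   gen_courtship, gen_broods, gen_pupal_fates,
                   gen_occurrence_grid)) {
    a <- gen(cfg1); b <- gen(cfg2)
    attr(a, "roster") <- attr(b, "roster") <- NULL
    expect_identical(a, b)
  }
  expect_false(identical(gen_broods(sim_config(seed = 124)),
                         gen_broods(cfg1)))
})

test_that("generators use independent substreams", {
  cfg <- sim_config(seed = 5)
  a <- gen_broods(cfg)
  invisible(gen_mating_trials(cfg))  # consuming another stream
  b <- gen_broods(cfg)
  expect_identical(a, b)
})

test_that("config validation rejects malformed parameters", {
  expect_error(sim_config(mating_probabilities = rbind(E = c(0.5, 0.4, 0),
                                                       Pb = c(0, 1, 0),
                                                       Ps = c(0, 0, 1))),
               "sum to 1")
  expect_error(sim_config(hatch_p = c("E x E" = 1.3)), "\\[0, 1\\]")
  expect_error(sim_config(hatch_rho = -0.1), "hatch_rho")
  expect_error(sim_config(compound_sdlog = -1), "non-negative")
  expect_error(sim_config(range_overlap_fraction = 2), "overlap")
  expect_error(sim_config(oviposition_theta = 0), "positive")
})

test_that("degenerate mating probabilities give a diagonal count matrix", {
  cfg <- sim_config(seed = 2, p_mating = c(E = 1, Pb = 1, Ps = 1),
                    mating_probabilities = diag(3),
                    n_trials = c(E = 30, Pb = 30, Ps = 30))
  mc <- mating_counts_from_trials(gen_mating_trials(cfg), taxa3)
  expect_equal(mc$counts, diag(30L, 3) + 0L, ignore_attr = TRUE)
})

test_that("empirical mating frequencies match configured values at large n", {
  cfg <- sim_config(seed = 66, n_trials = c(E = 4000, Pb = 4000, Ps = 4000),
                    p_mating = c(E = 0.9, Pb = 0.9, Ps = 0.9))
  mc <- mating_counts_from_trials(gen_mating_trials(cfg), taxa3)
  for (f in taxa3) {
    n <- sum(mc$counts[f, ])
    phat <- mc$counts[f, ] / n
    p <- cfg$mating_probabilities[f, ]
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(phat - p) <= 3 * se + 1e-12), info = f)
  }
})

test_that("beta-binomial broods: rho = 0 gives Pearson dispersion near 1", {
  cfg <- sim_config(seed = 10, n_broods = 500, hatch_rho = 0,
                    parasitism_rate = 0, hatch_p = c("E x E" = 0.8),
                    sterile_crosses = character())
  b <- gen_broods(cfg)
  p <- sum(b$eggs_hatched) / sum(b$eggs_laid)
  pearson <- sum((b$eggs_hatched - b$eggs_laid * p)^2 /
                   (b$eggs_laid * p * (1 - p))) / (nrow(b) - 1)
  expect_gt(pearson, 0.85); expect_lt(pearson, 1.15)
  # p = 1 -> everything hatches
  cfg1 <- sim_config(seed = 10, hatch_p = c("E x E" = 1), hatch_rho = 0,
                     parasitism_rate = 0, sterile_crosses = character())
  b1 <- gen_broods(cfg1)
  expect_equal(b1$eggs_hatched, b1$eggs_laid)
})

test_that("oviposition and courtship generators recover configured means", {
  cfg <- sim_config(seed = 44, n_females_host = c(E = 300, Pb = 3, Ps = 3))
  ovi <- gen_oviposition(cfg)
  e <- ovi[ovi$taxon == "E", ]
  emp <- tapply(e$eggs, e$plant, mean)
  mu <- cfg$eggs_per_female * cfg$oviposition_means["E", names(emp)]
  se <- sqrt((mu + mu^2 / cfg$oviposition_theta) / 300)
  expect_true(all(abs(emp - mu) <= 3 * se + 1e-9))

  cfg2 <- sim_config(seed = 45, n_trials_courtship = c(E = 400, Pb = 2, Ps = 2),
                     courtship_female_sd = 0.3)
  crt <- gen_courtship(cfg2)
  eE <- crt[crt$female_taxon == "E" & crt$male_taxon == "E", ]
  mu_e <- cfg2$courtship_rates["E", 1]
  # lognormal activity has mean 1; NB variance inflated by activity variance
  v <- mu_e + mu_e^2 / cfg2$courtship_theta +
    mu_e^2 * (exp(cfg2$courtship_female_sd^2) - 1)
  expect_lt(abs(mean(eE$count) - mu_e), 3 * sqrt(v / nrow(eE)))
})

test_that("occurrence grids hit the requested overlap fraction", {
  for (f in c(0, 0.5, 1)) {
    cfg <- sim_config(seed = 30 + f * 10, range_overlap_fraction = f,
                      n_occurrences = 400)
    occ <- gen_occurrence_grid(cfg)
    x <- geography_x(occ, c("E", "Pb"), cell_size = 1)
    expect_equal(x, f, tolerance = 0.05 + 1e-9)
  }
})

test_that("gen_bundle writes the full CSV bundle with ground truth", {
  dir <- withr::local_tempdir()
  paths <- gen_bundle(sim_config(seed = 12), dir)
  expect_true(all(file.exists(paths)))
  gt <- yaml::read_yaml(file.path(dir, "ground_truth.yaml"))
  expect_equal(gt$seed, 12)
  expect_equal(gt$hatch_rho, 0.05)
})
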