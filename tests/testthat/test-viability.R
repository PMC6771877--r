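test_that("parasitism filter adjusts denominators and validates counts", {
  b <- as_iso_table(data.frame(
    brood_id = c("B1", "B2"), cross_type = "E x E",
    eggs_laid = c(10, 8), eggs_hatched = c(6, 8), eggs_parasitized = c(2, 0),
    protocol_phase = "after", stringsAsFactors = FALSE), "broods")
  f <- parasitism_filter(b)
  expect_equal(f$denominator, c(8, 8))
  expect_equal(f$eggs_hatched / f$denominator, c(6 / 8, 1))
  bad <- b; bad$eggs_parasitized[1] <- 11; bad$eggs_hatched[1] <- 0
  expect_error(parasitism_filter(bad), "eggs_parasitized > eggs_laid")
  # generator cross-check: filtered denominators match ground truth
  cfg <- sim_config(seed = 3)
  g <- parasitism_filter(gen_broods(cfg))
  expect_equal(g$denominator, g$eggs_laid - g$eggs_parasitized)
  expect_gt(sum(g$eggs_parasitized), 0)
})

test_that("Wilson CI contains the estimate and handles boundaries", {
  for (kn in list(c(0, 10), c(10, 10), c(3, 7), c(131, 175))) {
    ci <- binom_ci(kn[1], kn[2])
    p <- kn[1] / kn[2]
    expect_true(ci["lower"] <= p && p <= ci["upper"])
    expect_true(ci["lower"] >= 0 && ci["upper"] <= 1)
  }
  expect_equal(unname(binom_ci(0, 10)["lower"]), 0)
  expect_equal(unname(binom_ci(10, 10)["upper"]), 1)
  # Clopper-Pearson matches stats::binom.test
  bt <- binom.test(3, 7)$conf.int
  expect_equal(unname(binom_ci(3, 7, method = "clopper-pearson")),
               as.numeric(bt), tolerance = 1e-9)
})

test_that("pupal test chi-squared equals the brute-force 2xc Pearson sum", {
  fates <- paper_pupal_fates()
  out <- pupal_survival_test(fates)
  # oracle: direct sum over the observed/expected table
  tot <- fates$emerged + fates$failed_emerge + fates$never_emerged +
    fates$failed_pupation
  obs <- rbind(fates$emerged, tot - fates$emerged)
  expc <- outer(rowSums(obs) / sum(obs), tot) * 1
  expect_equal(out$chi2, sum((obs - expc)^2 / expc))
  # and stats::prop.test without continuity correction
  pt <- suppressWarnings(prop.test(fates$emerged, tot, correct = FALSE))
  expect_equal(out$chi2, unname(pt$statistic))
  expect_equal(out$df, 6L)
  # equal proportions give zero
  eq <- data.frame(cross_type = c("a", "b"), emerged = c(10, 20),
                   failed_emerge = c(10, 20), never_emerged = 0,
                   failed_pupation = 0)
  expect_equal(pupal_survival_test(eq)$chi2, 0)
  # zero-pupae crosses are dropped
  z <- rbind(eq, data.frame(cross_type = "c", emerged = 0, failed_emerge = 0,
                            never_emerged = 0, failed_pupation = 0))
  expect_warning(outz <- pupal_survival_test(z), "zero pupae")
  expect_equal(outz$df, 1L)
})

test_that("hatch model with binomial data recovers phi near 1", {
  set.seed(2)
  n_broods <- 100
  d <- as_iso_table(data.frame(
    brood_id = sprintf("B%03d", 1:n_broods),
    cross_type = rep(c("E x E", "Pb x Pb"), each = n_broods / 2),
    eggs_laid = 40,
    eggs_hatched = rbinom(n_broods, 40, rep(c(0.8, 0.9), each = n_broods / 2)),
    eggs_parasitized = 0, protocol_phase = "after",
    stringsAsFactors = FALSE), "broods")
  hm <- hatch_model(d)
  expect_gt(hm$phi, 0.8); expect_lt(hm$phi, 1.2)
  # phi fixed at 1 limit: predictions match plain logistic regression
  gl <- glm(cbind(eggs_hatched, 40 - eggs_hatched) ~ cross_type,
            binomial, data = d)
  expect_equal(hm$mu$mu,
               unname(plogis(predict(gl, data.frame(cross_type = hm$mu$cross_type)))),
               tolerance = 1e-6)
})

test_that("hatch model recovers beta-binomial overdispersion within 25%", {
  # rho chosen so the quasi-binomial phi of 40-egg broods is ~3:
  # phi ~= 1 + (m - 1) rho  =>  rho = 2 / 39
  rho <- 2 / 39
  cfg <- sim_config(seed = 17, n_broods = 100, hatch_rho = rho,
                    parasitism_rate = 0,
                    hatch_p = c("E x E" = 0.85, "Pb x Pb" = 0.8))
  hm <- suppressWarnings(hatch_model(gen_broods(cfg)))  # sterile broods drop
  expect_gt(hm$phi, 3 * 0.75)
  expect_lt(hm$phi, 3 * 1.25)
  expect_true(all(hm$mu$mu > 0.7 & hm$mu$mu < 0.95))
})

test_that("hatch model survives complete separation and reports tests", {
  d <- as_iso_table(data.frame(
    brood_id = sprintf("B%02d", 1:20),
    cross_type = rep(c("E x E", "Pb x Pb"), each = 10),
    eggs_laid = 30,
    eggs_hatched = c(rep(30, 10), rbinom(10, 30, 0.8)),
    eggs_parasitized = 0, protocol_phase = "after",
    stringsAsFactors = FALSE), "broods")
  hm <- suppressWarnings(hatch_model(d))
  muE <- hm$mu$mu[hm$mu$cross_type == "E x E"]
  expect_gt(muE, 0.99)
  expect_true(is.finite(hm$cross_test$statistic))
})

test_that("sterility classifier follows the evidence rules", {
  b <- as_iso_table(data.frame(
    brood_id = sprintf("B%02d", 1:8),
    cross_type = c(rep("Pb x Ps", 3), rep("E x Pb", 3), "Ps x E", "E x E"),
    eggs_laid = c(0, 0, 0, 30, 25, 40, 0, 35),
    eggs_hatched = c(0, 0, 0, 25, 20, 33, 0, 30),
    eggs_parasitized = 0, protocol_phase = "after",
    stringsAsFactors = FALSE), "broods")
  out <- sterility_classifier(b)
  expect_equal(out$status[out$cross_type == "Pb x Ps"], "sterile")
  expect_equal(out$status[out$cross_type == "E x Pb"], "fertile")
  expect_equal(out$status[out$cross_type == "Ps x E"], "insufficient_evidence")
  # dissection evidence resolves single-female crosses; conflicts flagged
  dis <- data.frame(cross_type = c("Ps x E", "E x E"), sterile = c(TRUE, TRUE))
  out2 <- sterility_classifier(b, dis)
  expect_equal(out2$status[out2$cross_type == "Ps x E"], "sterile")
  expect_equal(out2$status[out2$cross_type == "E x E"], "conflicting")
  # generator: sterile cross labels produce zero eggs
  cfg <- sim_config(seed = 8)
  g <- sterility_classifier(gen_broods(cfg))
  expect_true(all(g$status[g$cross_type %in% cfg$sterile_crosses] == "sterile"))
})
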