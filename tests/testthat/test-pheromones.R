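make_compound_df <- function(...) {
  as_iso_table(data.frame(..., stringsAsFactors = FALSE), "compounds")
}

test_that("prefilter removes contaminants and singletons, logs removals", {
  d <- make_compound_df(
    individual_id = c("m1", "m2", "m3", "m1", "m1"),
    taxon = "E", sex = "male", region = "androconia",
    compound_id = c("a", "a", "a", "dirt", "once"),
    amount = c(1, 2, 3, 5, 1))
  audit_trail(clear = TRUE)
  out <- prefilter_compounds(d, contaminants = "dirt")
  expect_setequal(unique(out$compound_id), "a")
  log <- audit_trail()
  expect_true(any(log$event == "contaminant_removed" & log$detail == "dirt"))
  expect_true(any(log$event == "singleton_removed" & log$detail == "once"))
  # identity when nothing to remove
  d2 <- make_compound_df(individual_id = c("m1", "m2"), taxon = "E",
                         sex = "male", region = "androconia",
                         compound_id = "a", amount = c(1, 2))
  expect_equal(nrow(prefilter_compounds(d2)), 2)
})

test_that("screen: uniform enrichment gives the exact signed-rank p = 1/32 at n = 5", {
  ctl <- c(1, 2, 3, 4, 5)
  ids <- paste0("m", 1:5)
  d <- make_compound_df(
    individual_id = rep(ids, 2), taxon = "E", sex = "male",
    region = rep(c("androconia", "hindwing_control"), each = 5),
    compound_id = "a", amount = c(ctl * 10, ctl))
  res <- enrichment_screen(d)
  expect_equal(res$p_signed_rank, 1 / 32)
  expect_true(res$retained)
  expect_equal(res$reason, "vs_male_control")
})

test_that("screen rejects identical androconia and controls", {
  ids <- paste0("m", 1:5)
  d <- make_compound_df(
    individual_id = rep(ids, 2), taxon = "E", sex = "male",
    region = rep(c("androconia", "hindwing_control"), each = 5),
    compound_id = "a", amount = rep(c(1, 2, 3, 4, 5), 2))
  res <- enrichment_screen(d)
  expect_false(res$retained)
  expect_equal(res$reason, "not_enriched")
})

test_that("screen is invariant to sample order and positive rescaling", {
  cfg <- sim_config(seed = 77)
  tbl <- prefilter_compounds(gen_compound_table(cfg))
  base <- enrichment_screen(tbl)
  shuf <- tbl[sample(nrow(tbl)), ]
  expect_equal(enrichment_screen(shuf)$retained[order(enrichment_screen(shuf)$compound_id)],
               base$retained[order(base$compound_id)])
  scaled <- tbl; scaled$amount <- scaled$amount * 37.5
  expect_equal(enrichment_screen(scaled)$retained, base$retained)
})

test_that("screen recovers true pheromones from the synthetic table", {
  cfg <- sim_config(seed = 99)
  tbl <- gen_compound_table(cfg)
  roster <- attr(tbl, "roster")
  filt <- prefilter_compounds(tbl)
  # singletons must already be gone
  expect_false(any(grepl("^sing", unique(filt$compound_id))))
  res <- enrichment_screen(filt)
  truth <- roster$compound_id[roster$role == "true_pheromone"]
  others <- setdiff(res$compound_id, truth)
  recovery <- mean(truth %in% res$compound_id[res$retained])
  fp <- if (length(others)) mean(others %in% res$compound_id[res$retained]) else 0
  expect_gte(recovery, 0.9)
  # compound-wise screening at alpha = 0.05 with two one-sided tests and no
  # multiple-testing correction: per-null retention probability is a little
  # above alpha, so allow up to 3 of the 15 null compounds through
  expect_lte(fp, 3 / 15)
})

test_that("Bray-Curtis: hand-worked case, bounds, vegan agreement", {
  m <- rbind(a = c(0.8, 0.2), b = c(0.2, 0.8))
  expect_equal(bray_curtis_matrix(m)["a", "b"], 0.6)
  m2 <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0))
  bc <- bray_curtis_matrix(m2)
  expect_equal(bc["a", "b"], 1)
  expect_equal(bc["a", "c"], 0)
  expect_error(bray_curtis_matrix(rbind(c(0, 0), c(1, 1))), "all-zero")
  # independent oracle: vegan::vegdist on a synthetic proportion matrix
  cfg <- sim_config(seed = 13)
  prop <- compound_proportions(prefilter_compounds(gen_compound_table(cfg)))
  expect_equal(unname(bray_curtis_matrix(prop)),
               unname(as.matrix(vegan::vegdist(prop, "bray"))),
               tolerance = 1e-12)
})

test_that("ANOSIM R matches the rank definition and the vegan oracle at n = 6", {
  set.seed(42)
  pts <- rbind(matrix(rnorm(6, 0), 3), matrix(rnorm(6, 3), 3))
  d <- as.matrix(dist(pts))
  g <- rep(c("u", "v"), each = 3)
  ours <- anosim_test(d, g, n_permutations = 499, seed = 9)
  veg <- suppressWarnings(vegan::anosim(as.dist(d), g, permutations = 99))
  expect_equal(ours$statistic, unname(veg$statistic), tolerance = 1e-12)
  # exhaustive check of the definition: ranks of the 15 pairs
  ut <- upper.tri(d); rk <- rank(d[ut]); same <- outer(g, g, "==")[ut]
  expect_equal(ours$statistic,
               (mean(rk[!same]) - mean(rk[same])) / (15 / 2))
})

test_that("ANOSIM: perfect separation gives R = 1; errors on bad groups", {
  # all between-group dissimilarities exceed all within-group; 4+4 points so
  # the permutation p-value floor (2 / choose(8,4) per split) is below 0.05
  d <- matrix(10, 8, 8); d[1:4, 1:4] <- 1; d[5:8, 5:8] <- 1; diag(d) <- 0
  g <- rep(c("a", "b"), each = 4)
  out <- anosim_test(d, g, n_permutations = 199, seed = 2)
  expect_equal(out$statistic, 1)
  expect_lte(out$p, 0.05)
  expect_error(anosim_test(d, rep("a", 8)), "2 groups")
  expect_error(anosim_test(d, c("a", rep("b", 7))), "2 members")
})

test_that("ANOSIM null: E[R] near 0 and super-uniform p", {
  set.seed(31)
  n_rep <- 100; ps <- numeric(n_rep); rs <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    pts <- matrix(rnorm(24), 12)
    d <- as.matrix(dist(pts))
    g <- rep(c("a", "b"), each = 6)
    out <- anosim_test(d, g, n_permutations = 99, seed = r)
    ps[r] <- out$p; rs[r] <- out$statistic
  }
  expect_lt(abs(mean(rs)), 0.1)
  # rejection rate at alpha = 0.05 within 3 binomial SE
  expect_lte(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("NMDS: representable configuration, determinism, cluster recovery", {
  set.seed(8)
  pts <- rbind(matrix(rnorm(10, 0, 0.3), 5), matrix(rnorm(10, 4, 0.3), 5))
  d <- as.matrix(dist(pts))
  ord <- nmds_ordination(d, n_starts = 10, seed = 3)
  expect_lt(ord$stress, 0.01)    # 2-D Euclidean input is perfectly representable
  expect_equal(colMeans(ord$points), c(NMDS1 = 0, NMDS2 = 0), tolerance = 1e-10)
  ord2 <- nmds_ordination(d, n_starts = 10, seed = 3)
  expect_identical(ord$points, ord2$points)
  expect_error(nmds_ordination(d[1:3, 1:3]), "at least 4")
  expect_error(nmds_ordination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  # synthetic taxa separate into label-consistent clusters
  cfg <- sim_config(seed = 21)
  prop <- compound_proportions(prefilter_compounds(gen_compound_table(cfg)))
  bc <- bray_curtis_matrix(prop)
  o <- nmds_ordination(bc, n_starts = 15, seed = 4)
  km <- kmeans(o$points, centers = 3, nstart = 20)
  agreement <- max(table(km$cluster, attr(prop, "taxon"))) # dominant cell
  cl <- table(km$cluster, attr(prop, "taxon"))
  purity <- sum(apply(cl, 1, max)) / sum(cl)
  expect_gte(purity, 0.9)
})
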