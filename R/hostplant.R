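#' Pianka's niche overlap index
#'
#' O = sum(p q) / sqrt(sum(p^2) sum(q^2)) over the shared resource list; 0
#' when no resources are shared, 1 when resource use is identical. Counts
#' are normalized internally, so the index is scale invariant (it is the
#' cosine similarity of the two proportion vectors).
#'
#' @param p,q non-negative resource-use vectors (counts or proportions) of
#'   equal length.
#' @return overlap O in [0, 1].
#' @export
pianka_overlap <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(p < 0) || any(q < 0)) stop("resource-use vectors must be non-negative")
  if (sum(p) == 0 || sum(q) == 0) stop("all-zero resource-use vector: overlap undefined")
  p <- p / sum(p); q <- q / sum(q)
  sum(p * q) / sqrt(sum(p^2) * sum(q^2))
}

#' Pairwise Pianka overlap matrix from an oviposition table
#'
#' @param ovi an `oviposition` table (taxon, plant, eggs) or a taxon x plant
#'   count matrix.
#' @return symmetric matrix of pairwise overlaps with unit diagonal.
#' @export
overlap_matrix <- function(ovi) {
  m <- if (is.matrix(ovi)) ovi else
    stats::xtabs(eggs ~ taxon + plant, data = ovi)
  taxa <- rownames(m)
  out <- diag(1, length(taxa)); dimnames(out) <- list(taxa, taxa)
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) if (i < j)
    out[i, j] <- out[j, i] <- pianka_overlap(m[i, ], m[j, ])
  out
}

#' Test for a host-plant preference difference between two taxa
#'
#' Compares negative-binomial count models of per-female, per-plant egg
#' counts with and without the taxon x plant interaction. Individual-female
#' heterogeneity is absorbed by per-female fixed effects, the conditional
#' analogue of the random-intercept fit: conditioning on each female's
#' total, only the distribution of her eggs across plants carries
#' information, which is exactly the interaction hypothesis. The test
#' statistic is the deviance difference scaled by the alternative model's
#' Pearson dispersion, referred to an F distribution (slightly
#' anticonservative at very sparse designs; `n_boot` switches to a
#' parametric-bootstrap p-value). Plants with zero total eggs are dropped
#' with a logged warning.
#'
#' @param ovi an `oviposition_individual` table (female_id, taxon, plant, eggs).
#' @param pair two taxon ids to compare.
#' @param n_boot if > 0, number of parametric-bootstrap replicates used for
#'   the p-value instead of the F reference.
#' @return list with `statistic` (scaled deviance F), `df`, `p`,
#'   `delta_aic`; `df = 0` and `p = NA` for a degenerate single-plant design.
#' @export
preference_difference_test <- function(ovi, pair, n_boot = 0) {
  d <- as.data.frame(ovi)
  d <- d[d$taxon %in% pair, ]
  tot <- tapply(d$eggs, d$plant, sum)
  dead <- names(tot)[tot == 0]
  if (length(dead)) {
    audit_log("hostplant", "zero_egg_plants_dropped", paste(dead, collapse = ";"))
    warning("dropping plant(s) with zero total eggs: ", paste(dead, collapse = ", "))
    d <- d[!d$plant %in% dead, ]
  }
  n_plants <- length(unique(d$plant))
  n_taxa <- length(unique(d$taxon))
  if (n_plants < 2 || n_taxa < 2)
    return(list(statistic = NA_real_, df = 0L, p = NA_real_, delta_aic = NA_real_))
  d$taxon <- factor(d$taxon)
  d$plant <- factor(d$plant)
  d$fid <- factor(d$female_id)
  # common theta from the null fit; moment fallback if the iteration diverges
  theta <- tryCatch(
    suppressWarnings(MASS::glm.nb(eggs ~ fid + plant, data = d,
                                  control = stats::glm.control(maxit = 100))$theta),
    error = function(e) {
      pois <- suppressWarnings(stats::glm(eggs ~ fid + plant,
                                          family = stats::poisson(), data = d))
      mu <- stats::fitted(pois)
      1 / max(sum((d$eggs - mu)^2 / mu - 1) / sum(mu), 1e-3)
    })
  theta <- min(max(theta, 0.05), 1e4)
  fam <- MASS::negative.binomial(theta)
  fit <- function(formula, data = d)
    suppressWarnings(stats::glm(formula, family = fam, data = data))
  m0 <- fit(eggs ~ fid + plant)
  m1 <- fit(eggs ~ fid + plant + plant:taxon)
  df_int <- m0$df.residual - m1$df.residual
  dev_drop <- max(0, m0$deviance - m1$deviance)
  phi <- sum(stats::residuals(m1, "pearson")^2) / m1$df.residual
  f_stat <- dev_drop / df_int / phi
  p <- if (n_boot > 0) {
    mu0 <- stats::fitted(m0)
    stat_b <- replicate(n_boot, {
      db <- d
      db$eggs <- stats::rnbinom(nrow(db), mu = mu0, size = theta)
      b0 <- fit(eggs ~ fid + plant, data = db)
      b1 <- fit(eggs ~ fid + plant + plant:taxon, data = db)
      max(0, b0$deviance - b1$deviance)
    })
    (1 + sum(stat_b >= dev_drop)) / (n_boot + 1)
  } else stats::pf(f_stat, df_int, m1$df.residual, lower.tail = FALSE)
  list(statistic = f_stat, df = df_int,
       p = p, delta_aic = stats::AIC(m0) - stats::AIC(m1))
}

#' Host-plant gene-flow probability from niche overlap
#'
#' The host-plant barrier takes x equal to the pair's Pianka overlap, so
#' Ri = 1 - 2 O; identical host use (O = 1) gives Ri = -1 and fully
#' disjoint host use gives Ri = 1.
#'
#' @param O Pianka overlap in [0, 1].
#' @return x in [0, 1].
#' @export
hostplant_x <- function(O) {
  if (any(O < 0 | O > 1)) stop("overlap must lie in [0, 1]")
  O
}
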