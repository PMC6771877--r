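#' Remove likely contaminants and singleton compounds
#'
#' Mirrors the pre-screen filter applied to GC-MS compound tables: compounds
#' on an explicit contaminant list, and compounds detected (amount > 0) in
#' fewer than `min_occurrences` samples, are removed before enrichment
#' testing. Every removal is logged to the audit trail.
#'
#' @param tbl a `compounds` table (long format; see [read_table()]).
#' @param contaminants character vector of compound ids to drop.
#' @param min_occurrences minimum number of samples a compound must appear
#'   in (default 2, i.e. singletons are dropped).
#' @return filtered table of the same class.
#' @export
prefilter_compounds <- function(tbl, contaminants = character(),
                                min_occurrences = 2) {
  d <- as.data.frame(tbl)
  drop1 <- intersect(unique(d$compound_id), contaminants)
  for (cmp in drop1) audit_log("pheromones", "contaminant_removed", cmp)
  d <- d[!d$compound_id %in% drop1, ]
  occ <- tapply(d$amount > 0, d$compound_id, sum)
  rare <- names(occ)[occ < min_occurrences]
  for (cmp in rare) audit_log("pheromones", "singleton_removed", cmp)
  d <- d[!d$compound_id %in% rare, ]
  class(d) <- class(tbl)
  d
}

## amount of `compound` for each sample (individual x region), absent = 0
.compound_amounts <- function(d, compound, region, sex = NULL) {
  sel <- d$region == region
  if (!is.null(sex)) sel <- sel & d$sex == sex
  ids <- unique(d$individual_id[sel])
  amt <- stats::setNames(numeric(length(ids)), ids)
  rows <- sel & d$compound_id == compound
  got <- tapply(d$amount[rows], d$individual_id[rows], sum)
  amt[names(got)] <- got
  amt
}

#' Screen compounds for androconial enrichment
#'
#' A compound is classed as a putative male sex pheromone component if it is
#' present in greater amounts in the male androconial region than male
#' non-androconial (hind-wing) controls -- one-sided paired Wilcoxon
#' signed-rank across males sampled in both regions -- or than female
#' controls (one-sided Mann-Whitney U), or both. Exact null distributions
#' are used for small samples (the default `wilcox.test` exact regime,
#' n <= 25 without ties); taxa without female controls simply skip that
#' comparison. Rank tests make the screen invariant to any positive
#' rescaling of the amounts.
#'
#' @param tbl a (pre-filtered) `compounds` table.
#' @param alpha per-compound significance level (one-sided), default 0.05.
#' @return object of class `"screen_result"`: data.frame with one row per
#'   compound (p-values for both comparisons, medians, `retained`, `reason`).
#' @export
enrichment_screen <- function(tbl, alpha = 0.05) {
  d <- as.data.frame(tbl)
  compounds <- sort(unique(d$compound_id))
  male <- d[d$sex == "male", ]
  res <- lapply(compounds, function(cmp) {
    andro <- .compound_amounts(male, cmp, "androconia")
    mctl <- .compound_amounts(male, cmp, "hindwing_control")
    fctl <- .compound_amounts(d[d$sex == "female", ], cmp, "female_control")
    paired_ids <- intersect(names(andro), names(mctl))
    p_paired <- NA_real_
    if (length(paired_ids) >= 3) {
      dz <- andro[paired_ids] - mctl[paired_ids]
      if (any(dz != 0))
        p_paired <- suppressWarnings(
          stats::wilcox.test(andro[paired_ids], mctl[paired_ids],
                             paired = TRUE, alternative = "greater")$p.value)
      else p_paired <- 1
    }
    p_u <- NA_real_
    if (length(fctl) >= 2 && length(andro) >= 2)
      p_u <- suppressWarnings(
        stats::wilcox.test(andro, fctl, alternative = "greater")$p.value)
    med_a <- stats::median(andro)
    med_c <- stats::median(c(mctl, fctl))
    enriched <- med_a > med_c
    via_paired <- !is.na(p_paired) && p_paired < alpha
    via_u <- !is.na(p_u) && p_u < alpha
    retained <- enriched && (via_paired || via_u)
    reason <- if (retained) {
      if (via_paired && via_u) "both"
      else if (via_paired) "vs_male_control" else "vs_female_control"
    } else "not_enriched"
    data.frame(compound_id = cmp, p_signed_rank = p_paired, p_mann_whitney = p_u,
               median_androconia = med_a, median_control = med_c,
               retained = retained, reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("screen_result", class(out))
  out
}

#' Per-individual compound proportion matrix
#'
#' Converts androconial amounts over a retained compound set to per-sample
#' proportions (each individual's profile sums to 1), the input used for
#' Bray-Curtis dissimilarity.
#'
#' @param tbl a `compounds` table.
#' @param compounds compound ids to keep (e.g. the retained screen set).
#' @param region wing region to profile, default `"androconia"`.
#' @return individuals x compounds proportion matrix with a `taxon`
#'   attribute giving each row's taxon.
#' @export
compound_proportions <- function(tbl, compounds = NULL, region = "androconia") {
  d <- as.data.frame(tbl)
  d <- d[d$region == region, ]
  if (!is.null(compounds)) d <- d[d$compound_id %in% compounds, ]
  m <- stats::xtabs(amount ~ individual_id + compound_id, data = d)
  m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  rs <- rowSums(m)
  if (any(rs == 0)) stop("individual with all-zero profile: ",
                         rownames(m)[which(rs == 0)[1]])
  m <- m / rs
  tax <- d$taxon[match(rownames(m), d$individual_id)]
  attr(m, "taxon") <- tax
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(p, q) = sum|p - q| / sum(p + q) between per-individual profiles; 0 for
#' identical profiles, 1 for disjoint ones.
#'
#' @param m individuals x compounds non-negative matrix (rows typically
#'   proportions summing to 1).
#' @return symmetric dissimilarity matrix with zero diagonal, class `"dist"`
#'   convertible; returned as a plain matrix.
#' @export
bray_curtis_matrix <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative abundances")
  if (any(rowSums(m) == 0)) stop("individual with all-zero profile")
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    num <- sum(abs(m[i, ] - m[j, ]))
    den <- sum(m[i, ] + m[j, ])
    out[i, j] <- out[j, i] <- num / den
  }
  out
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 minimization by monotone regression (via
#' \code{vegan::monoMDS}) from `n_starts` random configurations plus a
#' classical-scaling start; the best (lowest-stress) solution is returned
#' with centered coordinates. With a fixed seed the result is reproducible.
#'
#' @param d symmetric dissimilarity matrix.
#' @param k target dimension (default 2).
#' @param n_starts number of random starts in addition to the metric start.
#' @param seed integer seed.
#' @return object of class `"ordination_result"`: list with `points`
#'   (n x k), `stress`, `n_starts`, `seed`.
#' @export
nmds_ordination <- function(d, k = 2, n_starts = 20, seed = 1) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("dissimilarity matrix must be symmetric")
  if (nrow(d) < 4) stop("need at least 4 points")
  dd <- stats::as.dist(d)
  best <- NULL
  with_substream(seed, "nmds", {
    init <- stats::cmdscale(dd, k = k)
    if (ncol(init) < k) init <- cbind(init, matrix(0, nrow(init), k - ncol(init)))
    fit0 <- vegan::monoMDS(dd, y = init, k = k, model = "global")
    best <- fit0
    for (s in seq_len(n_starts)) {
      y0 <- matrix(stats::rnorm(nrow(d) * k), ncol = k)
      fit <- vegan::monoMDS(dd, y = y0, k = k, model = "global")
      if (fit$stress < best$stress) best <- fit
    }
  })
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  dimnames(pts) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  structure(list(points = pts[, , drop = FALSE], stress = best$stress,
                 n_starts = n_starts, seed = seed),
            class = "ordination_result")
}

## ANOSIM R for one labelling of a rank matrix (upper triangle ranks);
## denominator M/2 (M = n(n-1)/2 pairs) scales R to [-1, 1]
.anosim_r <- function(rank_ut, same_group, M) {
  rb <- mean(rank_ut[!same_group])
  rw <- mean(rank_ut[same_group])
  (rb - rw) / (M / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' R = (mean between-group rank - mean within-group rank) / (M / 2), with
#' M = n(n-1)/2 pairwise dissimilarities ranked smallest first, so R is
#' scaled to [-1, 1] with 1 at perfect separation. Significance
#' comes from random permutation of group labels:
#' p = (number of permuted R >= observed + 1) / (n_permutations + 1).
#'
#' @param d symmetric dissimilarity matrix.
#' @param groups group label per row of `d`; every group needs >= 2 members.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return object of class `"anosim_result"`: list with `statistic` (R),
#'   `p`, `n_permutations`, `permuted` (the permuted R values).
#' @export
anosim_test <- function(d, groups, n_permutations = 999, seed = 1) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(d))
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  n <- nrow(d)
  ut <- upper.tri(d)
  rank_ut <- rank(d[ut])
  M <- n * (n - 1) / 2
  same <- outer(groups, groups, "==")[ut]
  r_obs <- .anosim_r(rank_ut, same, M)
  perm <- numeric(n_permutations)
  with_substream(seed, "anosim", {
    for (b in seq_len(n_permutations)) {
      g <- sample(groups)
      perm[b] <- .anosim_r(rank_ut, outer(g, g, "==")[ut], M)
    }
  })
  p <- (sum(perm >= r_obs) + 1) / (n_permutations + 1)
  structure(list(statistic = r_obs, p = p, n_permutations = n_permutations,
                 permuted = perm),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("ANOSIM R =", round(x$statistic, 3), ", P =",
      format(x$p, digits = 3), "(", x$n_permutations, "permutations )\n")
  invisible(x)
}
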