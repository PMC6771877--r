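#' Multinomial log-likelihood of mating counts
#'
#' log L = sum_i y_i * log(P_i), with the convention 0 * log 0 = 0. A
#' positive count on a zero-probability cell returns -Inf (not an error).
#'
#' @param counts non-negative integer vector y of matings per type.
#' @param prob probability vector P (sums to <= 1 + tolerance).
#' @return the log-likelihood (possibly -Inf).
#' @export
multinomial_loglik <- function(counts, prob) {
  stopifnot(length(counts) == length(prob))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(prob < 0)) stop("probabilities must be non-negative")
  if (sum(prob) > 1 + 1e-8) stop("probabilities must sum to <= 1")
  pos <- counts > 0
  if (!any(pos)) return(0)
  if (any(prob[pos] == 0)) return(-Inf)
  sum(counts[pos] * log(prob[pos]))
}

## Profile log-likelihood for a single coordinate P_i at value p, maximizing
## over the remaining coordinates. The conditional MLE spreads mass (1 - p)
## proportionally to the remaining counts, which collapses the profile to a
## binomial form: y_i log p + (n - y_i) log(1 - p) + constant.
profile_loglik <- function(p, y_i, n, rest_const) {
  t1 <- if (y_i > 0) y_i * log(p) else 0
  t2 <- if (n - y_i > 0) (n - y_i) * log1p(-p) else 0
  t1 + t2 + rest_const
}

## Edwards support limits for one coordinate: all p with profile log-lik
## within `drop` units of the maximum. Bisection on each side of the MLE.
support_limits_one <- function(y_i, n, y_rest, drop = 2, tol = 1e-6) {
  phat <- y_i / n
  rest_const <- sum(ifelse(y_rest > 0, y_rest * log(y_rest / sum(y_rest)), 0))
  if (sum(y_rest) == 0) rest_const <- 0
  llmax <- profile_loglik(max(phat, .Machine$double.xmin), y_i, n, rest_const)
  if (y_i == 0) llmax <- rest_const   # limit p -> 0
  target <- llmax - drop
  f <- function(p) profile_loglik(p, y_i, n, rest_const) - target
  # f increases on [0, phat] and decreases on [phat, 1]
  lower <- if (y_i == 0) 0 else {
    lo <- 1e-12; hi <- phat
    if (f(lo) >= 0) 0 else {
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (f(mid) < 0) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
  }
  upper <- if (y_i == n) 1 else {
    lo <- max(phat, 1e-12); hi <- 1 - 1e-12
    if (f(hi) >= 0) 1 else {
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (f(mid) >= 0) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
  }
  c(lower = lower, upper = upper)
}

#' Maximum-likelihood mating probabilities with support limits
#'
#' For counts y over k mating types the MLE is closed form, P_i = y_i / n.
#' Support limits follow the Edwards likelihood convention: for each P_i,
#' the set of values whose profile log-likelihood (remaining mass
#' redistributed at its conditional MLE) lies within `drop` (default 2)
#' units of the maximum.
#'
#' @param counts non-negative integer vector of matings per male taxon, or a
#'   `"mating_counts"` object together with `female_taxon`.
#' @param female_taxon row to analyse when `counts` is a `"mating_counts"`.
#' @param drop log-likelihood drop defining the support interval.
#' @param tol bisection tolerance.
#' @return object of class `"mating_mle"`: list with `estimate`, `support`
#'   (k x 2 matrix), `loglik`, `n`, `k`.
#' @export
fit_mating_mle <- function(counts, female_taxon = NULL, drop = 2, tol = 1e-6) {
  if (inherits(counts, "mating_counts")) {
    stopifnot(!is.null(female_taxon))
    counts <- counts$counts[female_taxon, ]
  }
  y <- as.numeric(counts)
  n <- sum(y)
  if (n < 1) stop("no matings observed")
  phat <- y / n
  sup <- t(vapply(seq_along(y), function(i)
    support_limits_one(y[i], n, y[-i], drop = drop, tol = tol),
    numeric(2)))
  rownames(sup) <- names(counts)
  structure(list(estimate = stats::setNames(phat, names(counts)),
                 support = sup,
                 loglik = multinomial_loglik(y, phat),
                 n = n, k = length(y)),
            class = "mating_mle")
}

#' @export
print.mating_mle <- function(x, ...) {
  cat("Multinomial mating-probability MLE (n =", x$n, "matings,", x$k, "types)\n")
  tab <- cbind(estimate = round(x$estimate, 3), round(x$support, 3))
  print(tab)
  cat("log-likelihood at maximum:", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' Likelihood-ratio test for pooling two mating experiments
#'
#' Tests whether mating probabilities differ between the 3-male and 15-male
#' experimental designs: 2(k-1) free parameters when fit separately versus
#' k-1 when pooled; chi-squared with k-1 df.
#'
#' @param counts_a,counts_b count vectors (same taxon order) from the two
#'   designs, or `"mating_counts"` objects with `female_taxon`.
#' @param female_taxon row to analyse for `"mating_counts"` inputs.
#' @return list with `chi2`, `df`, `p`.
#' @export
pooling_lrt <- function(counts_a, counts_b, female_taxon = NULL) {
  grab <- function(x) {
    if (inherits(x, "mating_counts")) x$counts[female_taxon, ] else as.numeric(x)
  }
  ya <- grab(counts_a); yb <- grab(counts_b)
  stopifnot(length(ya) == length(yb))
  k <- length(ya)
  if (sum(ya) == 0 || sum(yb) == 0) {
    warning("one design has no matings; pooling test skipped (df undefined)")
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_))
  }
  ll_sep <- multinomial_loglik(ya, ya / sum(ya)) +
    multinomial_loglik(yb, yb / sum(yb))
  pooled <- (ya + yb) / sum(ya + yb)
  ll_pool <- multinomial_loglik(ya, pooled) + multinomial_loglik(yb, pooled)
  chi2 <- max(0, 2 * (ll_sep - ll_pool))
  df <- k - 1L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Probability of heterospecific mating for a taxon pair
#'
#' x = H / (H + C), where H counts the pair's heterospecific matings (A
#' females with B males plus B females with A males) and C its conspecific
#' matings, restricted to the 2 x 2 sub-table for the pair.
#'
#' @param counts a `"mating_counts"` object or a k x k count matrix with
#'   dimnames.
#' @param pair character vector of two taxon ids.
#' @return x in [0, 1]; NA with a warning if the pair has no matings.
#' @export
mating_x <- function(counts, pair) {
  m <- if (inherits(counts, "mating_counts")) counts$counts else as.matrix(counts)
  stopifnot(length(pair) == 2, all(pair %in% rownames(m)))
  a <- pair[1]; b <- pair[2]
  H <- m[a, b] + m[b, a]
  C <- m[a, a] + m[b, b]
  if (H + C == 0) {
    warning("no matings for pair ", a, "-", b, "; x undefined")
    return(NA_real_)
  }
  H / (H + C)
}
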