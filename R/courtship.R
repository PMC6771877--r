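#' Probability of courting the conspecific colour pattern
#'
#' Binomial GLM on hover counts toward a male's own versus the alternative
#' wing model, with a categorical predictor for each pairwise comparison.
#' Without covariates the per-comparison estimate equals the raw proportion
#' with its Wald binomial CI. An optional binary location covariate can be
#' assessed by likelihood-ratio test before pooling data across sites.
#'
#' @param events data.frame with columns `comparison` (label of the pairwise
#'   model choice), `own` and `alternative` (event counts), and optionally
#'   `location`.
#' @param conf confidence level for the intervals.
#' @return list with `table` (one row per comparison: probability, CI,
#'   `differs_from_half`) and, when a location column is present,
#'   `location_test` (chi2, df, p).
#' @export
color_preference_fit <- function(events, conf = 0.95) {
  d <- as.data.frame(events)
  stopifnot(all(c("comparison", "own", "alternative") %in% names(d)))
  agg <- stats::aggregate(cbind(own, alternative) ~ comparison, data = d, sum)
  zero <- agg$own + agg$alternative == 0
  if (any(zero)) {
    warning("comparison(s) with zero events skipped: ",
            paste(agg$comparison[zero], collapse = ", "))
    agg <- agg[!zero, ]
  }
  loc_test <- NULL
  if ("location" %in% names(d) && length(unique(d$location)) > 1) {
    d$comparison <- factor(d$comparison)
    f0 <- if (nlevels(d$comparison) > 1) cbind(own, alternative) ~ comparison
    else cbind(own, alternative) ~ 1
    m0 <- stats::glm(f0, binomial, data = d)
    m1 <- stats::glm(stats::update(f0, ~ . + location), binomial, data = d)
    chi2 <- max(0, m0$deviance - m1$deviance)
    df <- m0$df.residual - m1$df.residual
    loc_test <- list(chi2 = chi2, df = df,
                     p = stats::pchisq(chi2, df, lower.tail = FALSE))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  tab <- do.call(rbind, lapply(seq_len(nrow(agg)), function(i) {
    n <- agg$own[i] + agg$alternative[i]
    p <- agg$own[i] / n
    # Wald interval on the logit scale, guarded at the boundary
    if (p %in% c(0, 1)) {
      ci <- binom_ci(agg$own[i], n)
    } else {
      eta <- stats::qlogis(p); se <- sqrt(1 / (n * p * (1 - p)))
      ci <- stats::plogis(c(eta - z * se, eta + z * se))
    }
    data.frame(comparison = agg$comparison[i], n_events = n, probability = p,
               lower = ci[[1]], upper = ci[[2]],
               differs_from_half = ci[[1]] > 0.5 | ci[[2]] < 0.5,
               stringsAsFactors = FALSE)
  }))
  list(table = tab, location_test = loc_test)
}

#' Courtship rates by male taxon toward each female taxon
#'
#' Negative-binomial count model of per-trial courtship events (one
#' behaviour at a time, hover by default) fitted separately for each female
#' taxon, with male taxon as predictor. Between-female heterogeneity is
#' absorbed by the NB dispersion together with a per-trial exposure offset
#' (log of the trial's total events across male taxa), a documented
#' simplification of a female-level random intercept. Returns expected
#' events per trial with Wald CIs and Bonferroni-adjusted pairwise male
#' contrasts.
#'
#' @param obs a `courtship` table (trial_id, female_taxon, male_taxon,
#'   behavior, count).
#' @param behavior which behaviour to model: "hover" (default), "approach"
#'   or "alight".
#' @param use_offset include the per-trial exposure offset (default TRUE).
#' @return list keyed by female taxon; each element has `expected`
#'   (male taxon, rate, lower, upper) and `contrasts` (pair, z, p_adj).
#' @export
courtship_rate_fit <- function(obs, behavior = "hover", use_offset = TRUE) {
  d <- as.data.frame(obs)
  d <- d[d$behavior == behavior, ]
  if (!nrow(d)) stop("no observations for behavior '", behavior, "'")
  # one row per trial x male taxon
  agg <- stats::aggregate(count ~ trial_id + female_taxon + male_taxon, data = d, sum)
  out <- list()
  for (ft in unique(agg$female_taxon)) {
    a <- agg[agg$female_taxon == ft, ]
    if (length(unique(a$trial_id)) < 2) {
      warning("female taxon ", ft, ": fewer than 2 trials; no fit")
      next
    }
    if (all(a$count == 0)) {
      warning("female taxon ", ft, ": all-zero counts; no fit")
      next
    }
    tot <- tapply(a$count, a$trial_id, sum)
    a$expo <- log(pmax(tot[as.character(a$trial_id)], 0.5) /
                    mean(pmax(tot, 0.5)))
    a$male_taxon <- factor(a$male_taxon)
    form <- if (use_offset) count ~ male_taxon + offset(expo) else count ~ male_taxon
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(form, data = a,
                                    control = stats::glm.control(maxit = 100))),
      error = function(e) stats::glm(form, family = stats::poisson(), data = a))
    nd <- data.frame(male_taxon = factor(levels(a$male_taxon),
                                         levels = levels(a$male_taxon)),
                     expo = 0)
    pr <- stats::predict(fit, newdata = nd, type = "link", se.fit = TRUE)
    expected <- data.frame(male_taxon = levels(a$male_taxon),
                           rate = exp(pr$fit),
                           lower = exp(pr$fit - 1.96 * pr$se.fit),
                           upper = exp(pr$fit + 1.96 * pr$se.fit),
                           stringsAsFactors = FALSE)
    # pairwise Wald contrasts on the link scale
    cf <- stats::coef(fit); V <- stats::vcov(fit)
    lv <- levels(a$male_taxon)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    ctr <- do.call(rbind, lapply(pairs, function(pp) {
      cv <- stats::setNames(numeric(length(cf)), names(cf))
      for (s in 1:2) {
        nm <- paste0("male_taxon", pp[s])
        if (nm %in% names(cv)) cv[nm] <- cv[nm] + c(1, -1)[s]
      }
      est <- sum(cv * cf); se <- sqrt(drop(t(cv) %*% V %*% cv))
      z <- if (se > 0) est / se else 0
      data.frame(pair = paste(pp, collapse = "-"), z = z,
                 p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
    }))
    ctr$p_adj <- pmin(1, ctr$p * nrow(ctr))
    out[[ft]] <- list(expected = expected, contrasts = ctr, theta = fit$theta)
  }
  out
}

#' Gene-flow probability from live courtship
#'
#' x = proportion of courtship directed heterospecifically, averaged over
#' the two reciprocal directions of the pair so unequal trial numbers do not
#' bias the estimate. If only one direction was observed, its value is
#' returned with a provenance flag.
#'
#' @param obs a `courtship` table or trial x male aggregate.
#' @param pair two taxon ids.
#' @param behavior behaviour analysed (default "hover").
#' @return list with `x`, `directions` (per-direction heterospecific
#'   proportions), `one_direction_only` flag.
#' @export
courtship_x <- function(obs, pair, behavior = "hover") {
  d <- as.data.frame(obs)
  if ("behavior" %in% names(d)) d <- d[d$behavior == behavior, ]
  stopifnot(length(pair) == 2)
  dir_prop <- function(female) {
    a <- d[d$female_taxon == female & d$male_taxon %in% pair, ]
    tot <- sum(a$count)
    if (tot == 0) return(NA_real_)
    other <- setdiff(pair, female)
    sum(a$count[a$male_taxon == other]) / tot
  }
  props <- vapply(pair, dir_prop, numeric(1))
  if (all(is.na(props))) stop("no courtship observed for pair")
  one_dir <- any(is.na(props))
  list(x = mean(props, na.rm = TRUE), directions = props,
       one_direction_only = one_dir)
}

#' Gene-flow probability from colour-pattern preference
#'
#' x = mean over the two reciprocal comparisons of (1 - P(court own
#' phenotype)); indifference (P = 0.5 both ways) gives x = 0.5, Ri = 0.
#'
#' @param p_own named probabilities of courting own phenotype, one per
#'   direction of the pair (length 1 or 2).
#' @return list with `x` and `one_direction_only` flag.
#' @export
color_x <- function(p_own) {
  p_own <- p_own[!is.na(p_own)]
  if (!length(p_own)) stop("no preference estimates supplied")
  if (any(p_own < 0 | p_own > 1)) stop("probabilities must lie in [0, 1]")
  list(x = mean(1 - p_own), one_direction_only = length(p_own) < 2)
}
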