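#' Exclude parasitized eggs from hatch-rate denominators
#'
#' Eggs in which a parasitoid was found are removed from the hatch-rate
#' calculation: each brood's denominator becomes eggs laid minus eggs
#' parasitized. Exclusion totals are logged to the audit trail.
#'
#' @param broods a `broods` table.
#' @return the same table with a `denominator` column added.
#' @export
parasitism_filter <- function(broods) {
  d <- as.data.frame(broods)
  if (!"eggs_parasitized" %in% names(d)) d$eggs_parasitized <- 0
  if (any(d$eggs_parasitized > d$eggs_laid))
    stop("eggs_parasitized > eggs_laid at row ",
         which(d$eggs_parasitized > d$eggs_laid)[1])
  d$denominator <- d$eggs_laid - d$eggs_parasitized
  audit_log("viability", "parasitized_eggs_excluded", sum(d$eggs_parasitized))
  class(d) <- class(broods)
  d
}

#' Quasi-binomial hatch-rate model
#'
#' Logistic regression of per-brood hatch proportions with variance
#' V(mu) = Phi * mu * (1 - mu): the dispersion Phi is estimated as the
#' Pearson statistic over the residual degrees of freedom, and factor tests
#' divide deviance differences by Phi (F-type scaled LRT). The model first
#' includes the before/after protocol covariate, then asks whether adding
#' cross type improves fit. Per-cross predicted hatch probabilities with
#' normal-theory CIs on the probability scale are reported at the
#' reference protocol level ("after", the individual-container regime).
#'
#' @param broods a `broods` table (run through [parasitism_filter()]; if the
#'   `denominator` column is absent the filter is applied first).
#' @param conf confidence level.
#' @return object of class `"hatch_model"`: list with `mu` (per-cross
#'   data.frame: cross_type, mu, lower, upper), `phi`, `protocol_effect`,
#'   `cross_test` (stat, df, p), and the underlying `fit`.
#' @export
hatch_model <- function(broods, conf = 0.95) {
  d <- as.data.frame(broods)
  if (!"denominator" %in% names(d)) d <- as.data.frame(parasitism_filter(broods))
  drop <- d$denominator == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " brood(s) with zero denominator")
    d <- d[!drop, ]
  }
  keep <- names(which(table(d$cross_type) >= 2))
  dropped <- setdiff(unique(d$cross_type), keep)
  if (length(dropped)) {
    warning("cross(es) with < 2 broods dropped: ", paste(dropped, collapse = ", "))
    d <- d[d$cross_type %in% keep, ]
  }
  d$cross_type <- factor(d$cross_type)
  has_protocol <- "protocol_phase" %in% names(d) &&
    length(unique(d$protocol_phase)) >= 2
  d$protocol_phase <- if (has_protocol)
    factor(d$protocol_phase, levels = c("after", "before"))
  else factor("after")
  resp <- cbind(d$eggs_hatched, d$denominator - d$eggs_hatched)
  f_base <- if (has_protocol) resp ~ protocol_phase else resp ~ 1
  f_full <- if (has_protocol) resp ~ protocol_phase + cross_type
  else resp ~ cross_type
  m_prot <- stats::glm(f_base, family = stats::quasibinomial(), data = d)
  m_full <- stats::glm(f_full, family = stats::quasibinomial(), data = d)
  phi <- sum(stats::residuals(m_full, "pearson")^2) / m_full$df.residual
  # scaled LRT for the cross-type factor
  df_cross <- m_prot$df.residual - m_full$df.residual
  stat <- max(0, (m_prot$deviance - m_full$deviance) / phi)
  cross_test <- list(statistic = stat, df = df_cross,
                     p = stats::pchisq(stat, df_cross, lower.tail = FALSE))
  prot_eff <- if (has_protocol) {
    co <- summary(m_full)$coefficients
    row <- grep("^protocol_phase", rownames(co))
    list(estimate = co[row, 1], se = co[row, 2], p = co[row, 4])
  } else NULL
  z <- stats::qnorm(1 - (1 - conf) / 2)
  nd <- data.frame(cross_type = levels(d$cross_type),
                   protocol_phase = factor("after", levels = levels(d$protocol_phase)))
  pr <- stats::predict(m_full, newdata = nd, type = "link", se.fit = TRUE)
  mu <- data.frame(cross_type = nd$cross_type,
                   mu = stats::plogis(pr$fit),
                   lower = stats::plogis(pr$fit - z * pr$se.fit),
                   upper = stats::plogis(pr$fit + z * pr$se.fit),
                   stringsAsFactors = FALSE)
  structure(list(mu = mu, phi = phi, protocol_effect = prot_eff,
                 cross_test = cross_test, fit = m_full),
            class = "hatch_model")
}

#' Classify cross fertility status
#'
#' A cross is "sterile" when no eggs were laid by any of its females or
#' when a gonad-dissection flag marks undeveloped ovaries; a cross with a
#' single egg-less female and no dissection evidence is "insufficient
#' evidence". Conflicting evidence (eggs laid but dissection says sterile)
#' is flagged for review rather than auto-classified. Sterile crosses
#' contribute Ri = 1 to the F1-fertility barrier.
#'
#' @param broods a `broods` table (cross_type, eggs_laid; one row per
#'   female-brood).
#' @param dissections optional data.frame with `cross_type` and `sterile`
#'   (logical) from ovary dissection.
#' @return data.frame: cross_type, n_females, eggs_total, status in
#'   `{"sterile", "fertile", "insufficient_evidence", "conflicting"}`.
#' @export
sterility_classifier <- function(broods, dissections = NULL) {
  d <- as.data.frame(broods)
  agg <- stats::aggregate(eggs_laid ~ cross_type, data = d, sum)
  nfem <- stats::aggregate(brood_id ~ cross_type, data = d, function(x) length(unique(x)))
  out <- merge(agg, nfem, by = "cross_type")
  names(out) <- c("cross_type", "eggs_total", "n_females")
  out$status <- ifelse(out$eggs_total > 0, "fertile",
                       ifelse(out$n_females >= 2, "sterile", "insufficient_evidence"))
  if (!is.null(dissections)) {
    for (i in seq_len(nrow(dissections))) {
      ct <- dissections$cross_type[i]
      j <- which(out$cross_type == ct)
      if (!length(j)) {
        out <- rbind(out, data.frame(cross_type = ct, eggs_total = 0, n_females = 0,
                                     status = if (dissections$sterile[i]) "sterile" else "fertile"))
        next
      }
      if (dissections$sterile[i]) {
        out$status[j] <- if (out$eggs_total[j] > 0) "conflicting" else "sterile"
      } else if (out$status[j] != "fertile" && out$eggs_total[j] == 0) {
        out$status[j] <- "conflicting"
      }
    }
  }
  out[order(out$cross_type), c("cross_type", "n_females", "eggs_total", "status")]
}

#' Test for equality of pupal emergence proportions across crosses
#'
#' Pearson chi-squared on the emerged-versus-failed 2 x c table, without
#' continuity correction, plus a per-cross emergence proportion with its
#' Wilson score CI (Clopper-Pearson available via `ci_method`).
#'
#' @param fates a `pupal_fates` table (cross_type, emerged, failed_emerge,
#'   never_emerged, failed_pupation) or a data.frame with `emerged` and
#'   `total` columns.
#' @param conf confidence level.
#' @param ci_method passed to [binom_ci()].
#' @return list with `chi2`, `df`, `p`, and `proportions` (cross_type, n,
#'   emerged, proportion, lower, upper).
#' @export
pupal_survival_test <- function(fates, conf = 0.95,
                                ci_method = c("wilson", "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  d <- as.data.frame(fates)
  if (!"total" %in% names(d)) {
    fail_cols <- intersect(c("failed_emerge", "never_emerged", "failed_pupation"),
                           names(d))
    d$total <- d$emerged + rowSums(d[, fail_cols, drop = FALSE])
  }
  zero <- d$total == 0
  if (any(zero)) {
    warning("cross(es) with zero pupae dropped: ",
            paste(d$cross_type[zero], collapse = ", "))
    d <- d[!zero, ]
  }
  if (nrow(d) < 2) stop("need at least 2 crosses")
  emer <- d$emerged; tot <- d$total
  # Pearson chi-squared on the 2 x c table, no continuity correction
  p_pool <- sum(emer) / sum(tot)
  expected <- rbind(tot * p_pool, tot * (1 - p_pool))
  observed <- rbind(emer, tot - emer)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- nrow(d) - 1L
  props <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    ci <- binom_ci(emer[i], tot[i], conf = conf, method = ci_method)
    data.frame(cross_type = d$cross_type[i], n = tot[i], emerged = emer[i],
               proportion = emer[i] / tot[i],
               lower = ci[["lower"]], upper = ci[["upper"]],
               stringsAsFactors = FALSE)
  }))
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       proportions = props)
}
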