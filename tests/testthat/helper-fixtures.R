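# Shared fixtures built in code: the study's printed count tables.

taxa3 <- c("E", "Pb", "Ps")

# Female-taxon x male-taxon mating counts from the mate-choice results
paper_mating_counts <- function() {
  m <- matrix(c(13, 0, 0,
                0, 13, 10,
                0, 5, 3),
              3, 3, byrow = TRUE, dimnames = list(taxa3, taxa3))
  structure(list(counts = m, n_trials = c(52L, 55L, 54L)),
            class = "mating_counts")
}

# Pupal fate counts for the seven cross types
paper_pupal_fates <- function() {
  as_iso_table(data.frame(
    cross_type = c("E x E", "Pb x Pb", "Ps x Ps", "E x Pb",
                   "(E x Pb) x (E x Pb)", "Pb x Ps", "Pb x (Pb x Ps)"),
    emerged = c(131, 255, 24, 24, 173, 31, 79),
    failed_emerge = c(14, 9, 3, 1, 8, 0, 1),
    never_emerged = c(18, 4, 4, 3, 17, 1, 1),
    failed_pupation = c(12, 20, 0, 2, 7, 0, 2),
    stringsAsFactors = FALSE), "pupal_fates")
}

# Dense-grid oracle for one coordinate's Edwards support limits: scans the
# profile log-likelihood (conditional-MLE redistribution of remaining mass)
# on a uniform grid and returns the range within `drop` units of the max.
grid_support_oracle <- function(y_i, n, y_rest, drop = 2, step = 1e-4) {
  p <- seq(step, 1 - step, by = step)
  rest_const <- if (sum(y_rest) > 0)
    sum(ifelse(y_rest > 0, y_rest * log(y_rest / sum(y_rest)), 0)) else 0
  ll <- ifelse(rep(y_i, length(p)) > 0, y_i * log(p), 0) +
    ifelse(rep(n - y_i, length(p)) > 0, (n - y_i) * log(1 - p), 0) + rest_const
  llmax <- max(ll, if (y_i == 0 || y_i == n) rest_const else -Inf)
  keep <- p[ll >= llmax - drop]
  c(lower = if (y_i == 0) 0 else min(keep),
    upper = if (y_i == n) 1 else max(keep))
}

# Full-simplex brute-force oracle for 3-type support limits (coordinate 1)
simplex_support_oracle <- function(y, drop = 2, step = 1e-3) {
  stopifnot(length(y) == 3)
  g <- seq(0, 1, by = step)
  grid <- expand.grid(p1 = g, p2 = g)
  grid <- grid[grid$p1 + grid$p2 <= 1 + 1e-12, ]
  grid$p3 <- pmax(1 - grid$p1 - grid$p2, 0)
  term <- function(yy, pp) {
    if (yy == 0) return(rep(0, length(pp)))
    ifelse(pp == 0, -Inf, yy * log(pp))
  }
  ll <- term(y[1], grid$p1) + term(y[2], grid$p2) + term(y[3], grid$p3)
  keep <- grid$p1[ll >= max(ll) - drop]
  c(lower = min(keep), upper = max(keep))
}
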