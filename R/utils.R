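#' @keywords internal
"_PACKAGE"

#' Default taxon labels
#'
#' The packaged default taxon set: a sympatric Amazonian pair plus an Andean
#' relative ("E", "Pb", "Ps"). All downstream code accepts any set of k >= 2
#' unique labels.
#'
#' @param ids character vector of unique taxon ids (k >= 2).
#' @return character vector of taxon ids.
#' @export
taxon_set <- function(ids = c("E", "Pb", "Ps")) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("taxon ids must be unique")
  if (length(ids) < 2) stop("need at least 2 taxa")
  ids
}

## Deterministic substream seed derived from a root seed and a stream name.
## Adding a new generator (new name) never perturbs existing streams.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  force(code)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Default interval used for per-cross emergence proportions. Degenerate
#' counts behave sensibly: k = 0 gives a lower endpoint of 0 and k = n an
#' upper endpoint of 1.
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @param method "wilson" (default) or "clopper-pearson".
#' @return numeric vector c(lower, upper).
#' @export
binom_ci <- function(k, n, conf = 0.95, method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  stopifnot(n >= 1, k >= 0, k <= n)
  if (method == "clopper-pearson") {
    a <- (1 - conf) / 2
    lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
    hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
    return(c(lower = lo, upper = hi))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = if (k == 0) 0 else max(0, ctr - half),
    upper = if (k == n) 1 else min(1, ctr + half))
}

## Shared audit trail: every filter/exclusion decision is recorded here so a
## pipeline run can dump it alongside its outputs.
.audit_env <- new.env(parent = emptyenv())
.audit_env$log <- list()

audit_log <- function(stage, event, detail = "") {
  .audit_env$log[[length(.audit_env$log) + 1L]] <-
    data.frame(stage = stage, event = event, detail = as.character(detail),
               stringsAsFactors = FALSE)
  invisible(NULL)
}

#' Retrieve (and optionally clear) the audit trail of filter decisions
#'
#' @param clear if TRUE, reset the trail after returning it.
#' @return data.frame with columns stage, event, detail.
#' @export
audit_trail <- function(clear = FALSE) {
  out <- do.call(rbind, .audit_env$log)
  if (is.null(out)) out <- data.frame(stage = character(), event = character(),
                                      detail = character(), stringsAsFactors = FALSE)
  if (clear) .audit_env$log <- list()
  out
}
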