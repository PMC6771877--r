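#' Sobel-Chen isolation index from a gene-flow probability
#'
#' Ri = 1 - 2x: Ri = 1 is complete isolation (x = 0), Ri = 0 random mating
#' (x = 0.5) and Ri = -1 complete disassortative gene flow (x = 1).
#'
#' @param x probability of heterospecific gene flow, in [0, 1].
#' @return Ri in [-1, 1].
#' @export
ri_from_x <- function(x) {
  if (any(is.na(x))) return(rep(NA_real_, length(x))[seq_along(x)])
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]")
  1 - 2 * x
}

#' Inverse of [ri_from_x()]
#' @param ri isolation index in [-1, 1].
#' @return x in [0, 1].
#' @export
x_from_ri <- function(ri) {
  if (any(ri < -1 | ri > 1)) stop("Ri must lie in [-1, 1]")
  (1 - ri) / 2
}

#' Geographic gene-flow probability from occurrence records
#'
#' Default estimator: occurrences are rasterized to a square grid and x is
#' the mean over the two taxa of the fraction of a taxon's occupied cells
#' that the other taxon also occupies. Disjoint ranges give x = 0 (Ri = 1),
#' identical occupancy x = 1 (Ri = -1).
#'
#' @param occ an `occurrences` table (taxon, lon, lat).
#' @param pair two taxon ids.
#' @param cell_size grid cell edge in coordinate units.
#' @return x in [0, 1].
#' @export
geography_x <- function(occ, pair, cell_size = 1) {
  d <- as.data.frame(occ)
  stopifnot(length(pair) == 2)
  cells <- lapply(pair, function(tx) {
    r <- d[d$taxon == tx, ]
    if (!nrow(r)) stop("no occurrence records for taxon ", tx)
    unique(paste(floor(r$lon / cell_size), floor(r$lat / cell_size)))
  })
  shared <- intersect(cells[[1]], cells[[2]])
  mean(c(length(shared) / length(cells[[1]]),
         length(shared) / length(cells[[2]])))
}

#' One barrier estimate for one taxon pair
#'
#' @param pair two taxon ids.
#' @param barrier barrier name (e.g. "mating", "host_plant", "geography").
#' @param x gene-flow probability (omit for assigned/unavailable cells).
#' @param ri isolation index; computed from `x` when omitted.
#' @param method provenance: "computed", "assigned" or "unavailable".
#' @param note free-text provenance note.
#' @return data.frame row with class `"barrier_estimate"`.
#' @export
barrier_estimate <- function(pair, barrier, x = NA_real_, ri = NULL,
                             method = c("computed", "assigned", "unavailable"),
                             note = "") {
  method <- match.arg(method)
  if (is.null(ri)) ri <- if (is.na(x)) NA_real_ else ri_from_x(x)
  if (!is.na(ri) && (ri < -1 || ri > 1)) stop("Ri must lie in [-1, 1]")
  out <- data.frame(pair = paste(pair, collapse = "-"), barrier = barrier,
                    x = x, ri = ri, method = method, note = note,
                    stringsAsFactors = FALSE)
  class(out) <- c("barrier_estimate", class(out))
  out
}

#' Assemble the per-pair, per-barrier isolation table
#'
#' Merges computed x-based estimates with explicitly assigned cells (such
#' as Ri = 1 recorded for female hybrid sterility) and unavailable cells.
#' Every cell carries its provenance; duplicate (pair, barrier) cells with
#' conflicting values are an error. Values are kept at full precision;
#' see [format_ri_table()] for 2-dp display.
#'
#' @param estimates list of [barrier_estimate()] rows (or a single
#'   data.frame of them).
#' @return data.frame of class `"ri_table"`.
#' @export
assemble_ri_table <- function(estimates) {
  if (inherits(estimates, "data.frame")) estimates <- list(estimates)
  tab <- do.call(rbind, lapply(estimates, as.data.frame))
  if (is.null(tab))
    tab <- data.frame(pair = character(), barrier = character(), x = numeric(),
                      ri = numeric(), method = character(), note = character(),
                      stringsAsFactors = FALSE)
  key <- paste(tab$pair, tab$barrier)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    same <- all(vapply(dup, function(k) {
      v <- tab$ri[key == k]; length(unique(round(v, 10))) == 1
    }, logical(1)))
    if (!same) stop("conflicting duplicate cell(s): ", paste(unique(dup), collapse = ", "))
    tab <- tab[!duplicated(key), ]
  }
  class(tab) <- c("ri_table", class(tab))
  tab
}

#' Format an isolation table for display
#'
#' Rounds Ri to 2 decimal places, rendering values in (0.98, 1) that arise
#' from a nonzero x as ">0.99"; unavailable cells print as "-".
#'
#' @param tab an `"ri_table"`.
#' @return data.frame of formatted strings (pair x barrier wide layout).
#' @export
format_ri_table <- function(tab) {
  fmt <- function(ri, x, method) {
    if (method == "unavailable" || is.na(ri)) return("-")
    if (!is.na(x) && x > 0 && ri > 0.98 && ri < 1) return(">0.99")
    formatC(round(ri, 2), format = "fg")
  }
  tab$display <- mapply(fmt, tab$ri, tab$x, tab$method)
  wide <- stats::reshape(tab[, c("pair", "barrier", "display")],
                         idvar = "pair", timevar = "barrier", direction = "wide")
  names(wide) <- sub("^display\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
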