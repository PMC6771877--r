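## Delimited-text schemas shared by all pipeline stages. Dialect: CSV, UTF-8,
## "." decimal, one header row. Unicode minus / en-dash in numeric fields is
## normalized to ASCII "-" on read.

.schemas <- list(
  mating_trials = list(
    cols = c("trial_id", "female_taxon", "composition", "outcome", "observed"),
    counts = character()),
  mating_counts = list(
    cols = c("female_taxon", "male_taxon", "matings"),
    counts = "matings"),
  oviposition = list(
    cols = c("taxon", "plant", "eggs"),
    counts = "eggs"),
  oviposition_individual = list(
    cols = c("female_id", "taxon", "plant", "eggs"),
    counts = "eggs"),
  compounds = list(
    cols = c("individual_id", "taxon", "sex", "region", "compound_id", "amount"),
    counts = character()),
  courtship = list(
    cols = c("trial_id", "female_taxon", "male_taxon", "behavior", "count", "window_id"),
    counts = "count"),
  broods = list(
    cols = c("brood_id", "cross_type", "eggs_laid", "eggs_hatched",
             "eggs_parasitized", "protocol_phase"),
    counts = c("eggs_laid", "eggs_hatched", "eggs_parasitized")),
  pupal_fates = list(
    cols = c("cross_type", "emerged", "failed_emerge", "never_emerged",
             "failed_pupation"),
    counts = c("emerged", "failed_emerge", "never_emerged", "failed_pupation")),
  occurrences = list(
    cols = c("taxon", "lon", "lat"),
    counts = character()),
  color_preference = list(
    cols = c("comparison", "male_taxon", "own", "alternative", "location"),
    counts = c("own", "alternative"))
)

#' Table schemas understood by the readers
#' @return character vector of schema names.
#' @export
schema_names <- function() names(.schemas)

normalize_minus <- function(x) {
  if (is.character(x)) gsub("−|–", "-", x) else x
}

#' Read a validated pipeline table from CSV
#'
#' Readers reject exactly the inputs that violate a table invariant: a
#' missing column is a schema error naming the column; a negative count is a
#' validation error naming the row; brood records with hatched + parasitized
#' exceeding eggs laid are rejected.
#'
#' @param path CSV file path.
#' @param schema one of [schema_names()].
#' @return a validated data.frame with class `c(schema, "iso_table")`.
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, names(.schemas))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df[] <- lapply(df, normalize_minus)
  sc <- .schemas[[schema]]
  for (cc in sc$counts) if (cc %in% names(df)) df[[cc]] <- as.numeric(df[[cc]])
  for (nc in intersect(c("amount", "lon", "lat", "mean_annual_temp", "annual_precip"),
                       names(df)))
    df[[nc]] <- as.numeric(df[[nc]])
  as_iso_table(df, schema)
}

#' Coerce and validate a data.frame against a pipeline schema
#' @param df data.frame.
#' @param schema one of [schema_names()].
#' @return validated data.frame with class `c(schema, "iso_table")`.
#' @export
as_iso_table <- function(df, schema) {
  schema <- match.arg(schema, names(.schemas))
  sc <- .schemas[[schema]]
  optional <- c("location", "observed", "window_id", "eggs_parasitized",
                "protocol_phase", "female_id")
  missing_cols <- setdiff(setdiff(sc$cols, optional), names(df))
  if (length(missing_cols))
    stop("schema '", schema, "': missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cc in sc$counts) {
    if (!cc %in% names(df)) next
    bad <- which(!is.na(df[[cc]]) & (df[[cc]] < 0 | df[[cc]] != round(df[[cc]])))
    if (length(bad))
      stop("column '", cc, "': negative or non-integer count at row ", bad[1])
  }
  if (schema == "broods") {
    if (!"eggs_parasitized" %in% names(df)) df$eggs_parasitized <- 0
    bad <- which(df$eggs_hatched + df$eggs_parasitized > df$eggs_laid)
    if (length(bad))
      stop("broods: eggs_hatched + eggs_parasitized > eggs_laid at row ", bad[1])
  }
  if (schema == "compounds" && any(df$amount < 0, na.rm = TRUE))
    stop("compounds: negative amount at row ", which(df$amount < 0)[1])
  if (schema == "occurrences" && any(!is.finite(df$lon) | !is.finite(df$lat)))
    stop("occurrences: non-finite coordinates at row ",
         which(!is.finite(df$lon) | !is.finite(df$lat))[1])
  if (schema == "mating_trials") {
    if (!"observed" %in% names(df)) df$observed <- TRUE
    df$observed <- as.logical(df$observed)
    bad <- which(!df$composition %in% c(3, 15))
    if (length(bad)) stop("mating_trials: composition must be 3 or 15 (row ",
                          bad[1], ")")
  }
  class(df) <- unique(c(schema, "iso_table", class(df)))
  df
}

#' Write a pipeline table to CSV
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse a cross-type label into a pedigree
#'
#' Labels follow the mother-first convention, e.g. `"Pb x E"` is a brood
#' with a Pb mother and an E father; parentheses mark hybrid parents, so
#' `"(E x Pb) x (E x Pb)"` is an F1 x F1 cross. Both "x" and the
#' multiplication sign are accepted as separators.
#'
#' @param label character cross label.
#' @return a list with elements `mother` and `father`, each either a taxon
#'   id string or a nested pedigree list; pure taxa parse to the id itself.
#' @export
parse_cross_label <- function(label) {
  s <- gsub("×", "x", label)
  s <- trimws(s)
  if (s == "") stop("empty cross label")
  parse_node <- function(str) {
    str <- trimws(str)
    if (str == "") stop("malformed cross label: '", label, "'")
    # split at the top-level " x " (depth 0)
    depth <- 0L; split_at <- NA_integer_
    chars <- strsplit(str, "")[[1]]
    for (i in seq_along(chars)) {
      ch <- chars[i]
      if (ch == "(") depth <- depth + 1L
      else if (ch == ")") {
        depth <- depth - 1L
        if (depth < 0L) stop("unbalanced parentheses in '", label, "'")
      } else if (ch == "x" && depth == 0L &&
                 i > 1 && i < length(chars) &&
                 chars[i - 1] == " " && chars[i + 1] == " ") {
        split_at <- i; break
      }
    }
    if (is.na(split_at)) {
      if (depth != 0L) stop("unbalanced parentheses in '", label, "'")
      if (grepl("^\\(.*\\)$", str))
        return(parse_node(substr(str, 2, nchar(str) - 1)))
      if (grepl("[()]", str)) stop("unbalanced parentheses in '", label, "'")
      return(str)
    }
    mother <- substr(str, 1, split_at - 2)
    father <- substr(str, split_at + 2, nchar(str))
    if (trimws(mother) == "" || trimws(father) == "")
      stop("malformed cross label: '", label, "'")
    list(mother = parse_node(mother), father = parse_node(father))
  }
  out <- parse_node(s)
  if (!is.list(out)) stop("malformed cross label (no ' x ' separator): '",
                          label, "'")
  out
}

#' Tabulate realized matings from trial records
#'
#' Builds the k x k female-taxon by male-taxon count matrix analysed by the
#' mating-probability likelihood. Trials with no mating contribute no count
#' (only realized matings enter the likelihood), and matings inferred from a
#' spermatophore but not directly observed are excluded because the male's
#' identity is unknown; both exclusions are logged to the audit trail.
#'
#' @param trials a `mating_trials` table (see [read_table()]).
#' @param taxa taxon ids defining row/column order.
#' @param composition optionally restrict to trials with 3 or 15 males.
#' @return list with `counts` (k x k matrix), `n_trials` (per female taxon)
#'   of class `"mating_counts"`.
#' @export
mating_counts_from_trials <- function(trials, taxa = taxon_set(),
                                      composition = NULL) {
  stopifnot(inherits(trials, "mating_trials") || all(
    c("female_taxon", "outcome") %in% names(trials)))
  if (!is.null(composition)) trials <- trials[trials$composition %in% composition, ]
  counts <- matrix(0L, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  n_trials <- table(factor(trials$female_taxon, levels = taxa))
  mated <- !is.na(trials$outcome) & trials$outcome != "" & trials$outcome != "none"
  audit_log("mating", "no_mating_trials_excluded", sum(!mated))
  obs <- if ("observed" %in% names(trials)) trials$observed else TRUE
  unobs <- mated & !obs
  if (any(unobs))
    audit_log("mating", "unobserved_matings_excluded", sum(unobs))
  use <- trials[mated & obs, ]
  bad <- which(!use$outcome %in% taxa)
  if (length(bad)) stop("outcome not in taxon set at trial ", use$trial_id[bad[1]])
  for (i in seq_len(nrow(use)))
    counts[use$female_taxon[i], use$outcome[i]] <-
      counts[use$female_taxon[i], use$outcome[i]] + 1L
  structure(list(counts = counts, n_trials = as.integer(n_trials)),
            class = "mating_counts")
}
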