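## Orchestration: run every stage on a directory of input CSVs and emit the
## per-stage reports plus the assembled isolation table and audit log.

#' Read a pipeline run configuration
#'
#' YAML file with keys: `input_dir`, `output_dir`, `seed`, and optional
#' `alpha`, `n_permutations`, `grid_cell_size`, `ci_method`, `behavior`,
#' `contaminants`, `sterile_assign_pairs`.
#'
#' @param path YAML file path.
#' @return named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(seed = 1L, alpha = 0.05, n_permutations = 999,
                   grid_cell_size = 1, ci_method = "wilson",
                   behavior = "hover", contaminants = character())
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg
}

pairs_of <- function(taxa) utils::combn(taxa, 2, simplify = FALSE)

#' Run the full multi-barrier pipeline
#'
#' Executes mating -> host plant -> pheromones -> courtship -> viability ->
#' isolation summary on a directory of input CSVs (the layout written by
#' [gen_bundle()]), writing per-stage reports, the assembled Ri table, and
#' a machine-readable audit log of every exclusion. With a fixed seed the
#' output bundle is byte-identical across runs.
#'
#' @param input_dir directory holding the input CSVs.
#' @param output_dir directory for outputs (created if needed).
#' @param seed integer seed used for all resampling stages.
#' @param taxa taxon ids.
#' @param alpha screen significance level.
#' @param n_permutations ANOSIM permutations.
#' @param grid_cell_size geographic grid cell edge.
#' @param ci_method binomial CI method for viability reports.
#' @param behavior courtship behaviour analysed.
#' @param contaminants compound ids treated as contaminants.
#' @return the assembled `"ri_table"`, invisibly; side effect: files under
#'   `output_dir`.
#' @export
run_pipeline <- function(input_dir, output_dir, seed = 1, taxa = taxon_set(),
                         alpha = 0.05, n_permutations = 999,
                         grid_cell_size = 1, ci_method = "wilson",
                         behavior = "hover", contaminants = character()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  audit_trail(clear = TRUE)
  need <- function(f) {
    p <- file.path(input_dir, f)
    if (!file.exists(p)) stop("missing input file: ", p)
    p
  }
  estimates <- list()

  ## --- mating ---------------------------------------------------------
  trials <- read_table(need("mating_trials.csv"), "mating_trials")
  mc <- mating_counts_from_trials(trials, taxa)
  mle_rows <- do.call(rbind, lapply(taxa, function(f) {
    if (sum(mc$counts[f, ]) == 0) return(NULL)
    fit <- fit_mating_mle(mc, f)
    data.frame(female_taxon = f, male_taxon = taxa, estimate = fit$estimate,
               lower = fit$support[, 1], upper = fit$support[, 2],
               row.names = NULL)
  }))
  utils::write.csv(mle_rows, file.path(output_dir, "mating_mle.csv"),
                   row.names = FALSE)
  for (pr in pairs_of(taxa)) {
    x <- suppressWarnings(mating_x(mc, pr))
    estimates[[length(estimates) + 1L]] <- if (is.na(x))
      barrier_estimate(pr, "mating", method = "unavailable", note = "no matings")
    else barrier_estimate(pr, "mating", x = x, note = "trial counts")
  }

  ## --- host plant -----------------------------------------------------
  ovi <- read_table(need("oviposition.csv"),
                    if ("female_id" %in% names(utils::read.csv(
                      file.path(input_dir, "oviposition.csv"), nrows = 1)))
                      "oviposition_individual" else "oviposition")
  counts <- stats::xtabs(eggs ~ taxon + plant, data = ovi)
  O <- overlap_matrix(counts)
  utils::write.csv(as.data.frame(as.table(O)),
                   file.path(output_dir, "host_overlap.csv"), row.names = FALSE)
  for (pr in pairs_of(taxa)) {
    if (!all(pr %in% rownames(O))) next
    estimates[[length(estimates) + 1L]] <-
      barrier_estimate(pr, "host_plant", x = hostplant_x(O[pr[1], pr[2]]),
                       note = "Pianka overlap")
  }

  ## --- pheromones -----------------------------------------------------
  cmp <- read_table(need("compounds.csv"), "compounds")
  cmp_f <- prefilter_compounds(cmp, contaminants = contaminants)
  screen <- enrichment_screen(cmp_f, alpha = alpha)
  utils::write.csv(screen, file.path(output_dir, "pheromone_screen.csv"),
                   row.names = FALSE)
  retained <- screen$compound_id[screen$retained]
  anosim_res <- NULL
  if (length(retained) >= 2) {
    prop <- compound_proportions(cmp_f, retained)
    bc <- bray_curtis_matrix(prop)
    utils::write.csv(bc, file.path(output_dir, "bray_curtis.csv"))
    grp <- attr(prop, "taxon")
    if (nlevels(factor(grp)) >= 2 && all(table(grp) >= 2)) {
      ord <- nmds_ordination(bc, seed = seed)
      utils::write.csv(data.frame(individual_id = rownames(ord$points),
                                  ord$points, taxon = grp),
                       file.path(output_dir, "nmds_coordinates.csv"),
                       row.names = FALSE)
      anosim_res <- anosim_test(bc, grp, n_permutations = n_permutations,
                                seed = seed)
    }
  }
  for (pr in pairs_of(taxa))
    estimates[[length(estimates) + 1L]] <-
      barrier_estimate(pr, "pheromones", ri = 1, method = "assigned",
                       note = "assigned: distinct pheromone blends; x not estimable from profiles")

  ## --- courtship ------------------------------------------------------
  crt <- read_table(need("courtship.csv"), "courtship")
  rates <- courtship_rate_fit(crt, behavior = behavior)
  exp_rows <- do.call(rbind, lapply(names(rates), function(f)
    cbind(female_taxon = f, rates[[f]]$expected)))
  utils::write.csv(exp_rows, file.path(output_dir, "courtship_expected.csv"),
                   row.names = FALSE)
  for (pr in pairs_of(taxa)) {
    cx <- tryCatch(courtship_x(crt, pr, behavior = behavior),
                   error = function(e) NULL)
    estimates[[length(estimates) + 1L]] <- if (is.null(cx))
      barrier_estimate(pr, "live_courtship", method = "unavailable",
                       note = "no courtship observed")
    else barrier_estimate(pr, "live_courtship", x = cx$x,
                          note = if (cx$one_direction_only) "one direction only" else "")
  }

  ## --- viability ------------------------------------------------------
  broods <- read_table(need("broods.csv"), "broods")
  filt <- parasitism_filter(broods)
  hm <- tryCatch(hatch_model(filt), error = function(e) NULL)
  if (!is.null(hm))
    utils::write.csv(hm$mu, file.path(output_dir, "hatch_rates.csv"),
                     row.names = FALSE)
  fert <- sterility_classifier(broods)
  utils::write.csv(fert, file.path(output_dir, "fertility_status.csv"),
                   row.names = FALSE)
  fates <- read_table(need("pupal_fates.csv"), "pupal_fates")
  pv <- pupal_survival_test(fates, ci_method = ci_method)
  utils::write.csv(pv$proportions, file.path(output_dir, "pupal_survival.csv"),
                   row.names = FALSE)
  # a pair's fertility barrier is judged from broods mothered by that pair's
  # F1 females: cross labels "(A x B) x ..." or "(B x A) x ..."
  mother_is_f1_of <- function(ct, pr) {
    ped <- tryCatch(parse_cross_label(ct), error = function(e) NULL)
    if (is.null(ped) || !is.list(ped$mother)) return(FALSE)
    setequal(unlist(ped$mother), pr)
  }
  sterile_ct <- fert$cross_type[fert$status == "sterile"]
  for (pr in pairs_of(taxa)) {
    lab <- Filter(function(ct) mother_is_f1_of(ct, pr), fert$cross_type)
    est <- if (any(lab %in% sterile_ct))
      barrier_estimate(pr, "f1_fertility", ri = 1, method = "assigned",
                       note = "assigned: female F1 sterility")
    else if (length(lab))
      barrier_estimate(pr, "f1_fertility", x = 0.5,
                       note = "fertile F1s: no barrier (random-mating baseline)")
    else barrier_estimate(pr, "f1_fertility", method = "unavailable",
                          note = "no F1 broods")
    estimates[[length(estimates) + 1L]] <- est
  }

  ## --- geography ------------------------------------------------------
  occ_path <- file.path(input_dir, "occurrences.csv")
  if (file.exists(occ_path)) {
    occ <- read_table(occ_path, "occurrences")
    for (pr in pairs_of(taxa)) {
      gx <- tryCatch(geography_x(occ, pr, cell_size = grid_cell_size),
                     error = function(e) NA_real_)
      estimates[[length(estimates) + 1L]] <- if (is.na(gx))
        barrier_estimate(pr, "geography", method = "unavailable",
                         note = "missing records")
      else barrier_estimate(pr, "geography", x = gx, note = "grid occupancy")
    }
  }

  ## --- summary --------------------------------------------------------
  tab <- assemble_ri_table(estimates)
  utils::write.csv(as.data.frame(tab), file.path(output_dir, "ri_table.csv"),
                   row.names = FALSE)
  writeLines(utils::capture.output(print(format_ri_table(tab))),
             file.path(output_dir, "ri_table.txt"))
  utils::write.csv(audit_trail(), file.path(output_dir, "audit_log.csv"),
                   row.names = FALSE)
  report <- c(
    sprintf("seed: %d", as.integer(seed)),
    sprintf("pupal survival chi2 = %.2f, df = %d, p = %.3g", pv$chi2, pv$df, pv$p),
    if (!is.null(hm)) sprintf("hatch dispersion phi = %.2f", hm$phi),
    if (!is.null(anosim_res)) sprintf("ANOSIM R = %.3f, p = %.3g",
                                      anosim_res$statistic, anosim_res$p))
  writeLines(report, file.path(output_dir, "run_report.txt"))
  invisible(tab)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic bundle), `mating`,
#' `hostplant`, `pheromones`, `courtship`, `viability`, `summarize`, and
#' `all` (full pipeline). Single-stage subcommands run the full pipeline
#' but are provided for discoverability; `all` is the primary mode.
#'
#' @param args character vector, e.g.
#'   `c("all", "--in", "data/", "--out", "results/", "--seed", "7")`.
#' @return exit status 0 on success (invisibly); stops with an error
#'   message naming the failing stage otherwise.
#' @export
ri_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: <subcommand> [--in DIR] [--out DIR] [--seed N] [--config FILE]")
  cmd <- args[1]
  opt <- list(input = ".", output = "results", seed = 1L, config = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- args[i]
    val <- if (i + 1 <= length(args)) args[i + 1] else stop("missing value for ", key)
    switch(key,
           "--in" = opt$input <- val,
           "--out" = opt$output <- val,
           "--seed" = opt$seed <- as.integer(val),
           "--config" = opt$config <- val,
           stop("unknown option: ", key))
    i <- i + 2
  }
  extra <- list()
  if (!is.null(opt$config)) {
    cfg <- read_run_config(opt$config)
    if (!is.null(cfg$input_dir)) opt$input <- cfg$input_dir
    if (!is.null(cfg$output_dir)) opt$output <- cfg$output_dir
    if (!is.null(cfg$seed)) opt$seed <- as.integer(cfg$seed)
    extra <- cfg[intersect(names(cfg),
                           c("alpha", "n_permutations", "grid_cell_size",
                             "ci_method", "behavior", "contaminants"))]
  }
  if (cmd == "simulate") {
    gen_bundle(sim_config(seed = opt$seed), opt$input)
    message("synthetic bundle written to ", opt$input)
    return(invisible(0L))
  }
  if (!cmd %in% c("all", "mating", "hostplant", "pheromones", "courtship",
                  "viability", "summarize"))
    stop("unknown subcommand: ", cmd)
  do.call(run_pipeline, c(list(input_dir = opt$input, output_dir = opt$output,
                               seed = opt$seed), extra))
  invisible(0L)
}
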