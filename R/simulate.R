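## Seeded synthetic-data generators. Each generator draws from its own
## substream derived from the root seed, so adding a generator never
## perturbs the streams of existing ones, and an identical config always
## reproduces byte-identical tables.

default_oviposition_means <- function(taxa, n_plants = 21) {
  plants <- sprintf("P%02d", seq_len(n_plants))
  # Taxon-specific preference profiles: a dominant plant (rank 1 share
  # matching the multi-female cage experiment: 0.41 / 0.24 / 0.38) with
  # geometric decay over the rest and taxon-specific orderings.
  prof <- function(top_share, order) {
    rest <- 0.6^(seq_len(n_plants - 1))
    p <- c(top_share, (1 - top_share) * rest / sum(rest))
    p[order(order)]
  }
  m <- rbind(
    E  = prof(0.41, c(3, seq_len(n_plants)[-3])),
    Pb = prof(0.24, c(1, 2, 4:n_plants, 3)),
    Ps = prof(0.38, c(1, 5, 2, 4, 3, 6:n_plants))
  )[seq_along(taxa), , drop = FALSE]
  rownames(m) <- taxa; colnames(m) <- plants
  m
}

#' Simulation configuration with study-design defaults
#'
#' Bundles every ground-truth parameter of the synthetic generators. The
#' defaults mirror the study's experimental design: three taxa (E, Pb, Ps);
#' 253 mating trials with the observed per-taxon mating rates and
#' conditional mate-choice probabilities; 10/13/5 male pheromone samples
#' with 5 paired hind-wing controls each and 2/2/0 female controls; hover
#' courtship at a fivefold own-taxon rate; beta-binomially overdispersed
#' hatch rates with 10% egg parasitism and broods mothered by the four
#' sterile female-F1 genotypes (labelled "(A x B) x C": an F1 mother)
#' laying nothing; pupal-fate probabilities at the observed proportions; and
#' two-range occurrence grids with a controllable overlap fraction.
#'
#' @param seed integer root seed; all generators derive substreams from it.
#' @param taxa taxon ids.
#' @param n_trials mating trials per female taxon.
#' @param p_mating per-taxon probability that a trial produces a mating.
#' @param mating_probabilities k x k matrix; row f = conditional
#'   probability of each male taxon given a mating by a female of taxon f.
#' @param oviposition_means taxon x plant proportion matrix.
#' @param oviposition_theta negative-binomial dispersion (variance
#'   mu + mu^2/theta) for per-plant egg counts.
#' @param eggs_per_female mean total eggs per female in host trials.
#' @param n_females_host females per taxon in the individual host trial.
#' @param n_compound_true,n_compound_contaminant,n_compound_flat,n_compound_singleton
#'   composition of the synthetic compound list: true pheromones,
#'   contaminants (equal in all regions), non-enriched wing compounds, and
#'   singletons (detected in one sample).
#' @param n_males_pheromone named vector of male sample sizes per taxon.
#' @param n_female_controls named vector of female control samples.
#' @param enrichment_factor androconial enrichment of true pheromones.
#' @param compound_sdlog log-scale noise sd for amounts.
#' @param courtship_rates k x k matrix of mean events/trial (rows = female
#'   taxon, cols = male taxon).
#' @param courtship_female_sd between-female log-scale sd.
#' @param courtship_theta NB dispersion for courtship counts.
#' @param n_trials_courtship trials per female taxon.
#' @param hatch_p named per-cross mean hatch probabilities.
#' @param hatch_rho beta-binomial overdispersion (0 = binomial).
#' @param parasitism_rate fraction of laid eggs parasitized.
#' @param n_broods broods per cross.
#' @param brood_size mean eggs per brood.
#' @param sterile_crosses cross labels that lay no eggs.
#' @param pupal_fate_probs cross x fate probability matrix (fates: emerged,
#'   failed_emerge, never_emerged, failed_pupation).
#' @param n_pupae pupae per cross.
#' @param range_overlap_fraction fraction of each taxon's range cells
#'   co-occupied by the other taxon, in [0, 1].
#' @param n_occurrences points per taxon in the occurrence grid.
#' @param range_cells cells along each range's extent.
#' @param climate_means,climate_sds per-taxon (temperature C, rainfall mm)
#'   envelope means and sds.
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(
    seed = 1,
    taxa = taxon_set(),
    n_trials = c(E = 84, Pb = 85, Ps = 84),
    p_mating = c(E = 13 / 84, Pb = 23 / 85, Ps = 8 / 84),
    mating_probabilities = rbind(E = c(1, 0, 0),
                                 Pb = c(0, 13 / 23, 10 / 23),
                                 Ps = c(0, 5 / 8, 3 / 8)),
    oviposition_means = default_oviposition_means(taxa),
    oviposition_theta = 2,
    eggs_per_female = 12,
    n_females_host = c(E = 14, Pb = 13, Ps = 10),
    n_compound_true = 25,
    n_compound_contaminant = 5,
    n_compound_flat = 10,
    n_compound_singleton = 3,
    n_males_pheromone = c(E = 10, Pb = 13, Ps = 5),
    n_female_controls = c(E = 2, Pb = 2, Ps = 0),
    enrichment_factor = 8,
    compound_sdlog = 0.5,
    courtship_rates = rbind(E = c(5, 1, 1), Pb = c(1, 5, 1), Ps = c(1, 1, 2)),
    courtship_female_sd = 0.5,
    courtship_theta = 2,
    n_trials_courtship = c(E = 24, Pb = 24, Ps = 24),
    hatch_p = c("E x E" = 0.85, "Pb x Pb" = 0.85, "Ps x Ps" = 0.8,
                "E x Pb" = 0.8, "Pb x E" = 0.8, "Pb x Ps" = 0.8,
                "(E x Pb) x (E x Pb)" = 0.75),
    hatch_rho = 0.05,
    parasitism_rate = 0.1,
    n_broods = 12,
    brood_size = 40,
    sterile_crosses = c("(Ps x Pb) x Pb", "(Pb x Ps) x Pb",
                        "(Ps x E) x E", "(E x Ps) x E"),
    pupal_fate_probs = NULL,
    n_pupae = c("E x E" = 175, "Pb x Pb" = 288, "Ps x Ps" = 31,
                "E x Pb" = 30, "(E x Pb) x (E x Pb)" = 205,
                "Pb x Ps" = 32, "Pb x (Pb x Ps)" = 83),
    range_overlap_fraction = 0.5,
    n_occurrences = 200,
    range_cells = 20,
    climate_means = rbind(E = c(24, 1400), Pb = c(25, 1600), Ps = c(24, 900)),
    climate_sds = c(1, 150)) {
  k <- length(taxa)
  dimnames(mating_probabilities) <- list(taxa, taxa)
  if (is.null(pupal_fate_probs)) {
    pupal_fate_probs <- rbind(
      "E x E" = c(131, 14, 18, 12), "Pb x Pb" = c(255, 9, 4, 20),
      "Ps x Ps" = c(24, 3, 4, 0), "E x Pb" = c(24, 1, 3, 2),
      "(E x Pb) x (E x Pb)" = c(173, 8, 17, 7), "Pb x Ps" = c(31, 0, 1, 0),
      "Pb x (Pb x Ps)" = c(79, 1, 1, 2))
    pupal_fate_probs <- pupal_fate_probs / rowSums(pupal_fate_probs)
    colnames(pupal_fate_probs) <- c("emerged", "failed_emerge",
                                    "never_emerged", "failed_pupation")
  }
  cfg <- list(seed = as.integer(seed), taxa = taxa, n_trials = n_trials,
              p_mating = p_mating, mating_probabilities = mating_probabilities,
              oviposition_means = oviposition_means,
              oviposition_theta = oviposition_theta,
              eggs_per_female = eggs_per_female, n_females_host = n_females_host,
              n_compound_true = n_compound_true,
              n_compound_contaminant = n_compound_contaminant,
              n_compound_flat = n_compound_flat,
              n_compound_singleton = n_compound_singleton,
              n_males_pheromone = n_males_pheromone,
              n_female_controls = n_female_controls,
              enrichment_factor = enrichment_factor,
              compound_sdlog = compound_sdlog,
              courtship_rates = courtship_rates,
              courtship_female_sd = courtship_female_sd,
              courtship_theta = courtship_theta,
              n_trials_courtship = n_trials_courtship,
              hatch_p = hatch_p, hatch_rho = hatch_rho,
              parasitism_rate = parasitism_rate, n_broods = n_broods,
              brood_size = brood_size, sterile_crosses = sterile_crosses,
              pupal_fate_probs = pupal_fate_probs, n_pupae = n_pupae,
              range_overlap_fraction = range_overlap_fraction,
              n_occurrences = n_occurrences, range_cells = range_cells,
              climate_means = climate_means, climate_sds = climate_sds)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  rs <- rowSums(cfg$mating_probabilities)
  if (any(abs(rs - 1) > 1e-8))
    stop("mating_probabilities rows must sum to 1")
  if (any(cfg$p_mating < 0 | cfg$p_mating > 1))
    stop("p_mating must lie in [0, 1]")
  if (any(cfg$hatch_p < 0 | cfg$hatch_p > 1))
    stop("hatch probabilities must lie in [0, 1]")
  if (cfg$hatch_rho < 0 || cfg$hatch_rho >= 1) stop("hatch_rho must lie in [0, 1)")
  if (cfg$oviposition_theta <= 0 || cfg$courtship_theta <= 0)
    stop("dispersion theta must be positive")
  if (cfg$compound_sdlog < 0) stop("compound_sdlog must be non-negative")
  if (cfg$range_overlap_fraction < 0 || cfg$range_overlap_fraction > 1)
    stop("range_overlap_fraction must lie in [0, 1]")
  if (any(abs(rowSums(cfg$pupal_fate_probs) - 1) > 1e-8))
    stop("pupal_fate_probs rows must sum to 1")
  invisible(cfg)
}

#' Simulate mate-choice trials
#'
#' Each trial presents one virgin female to a group of 3 or 15 males (one
#' or five of each taxon, alternating between designs) and draws the
#' outcome: no mating with probability 1 - p_mating, otherwise a male taxon
#' from the female taxon's conditional probability vector.
#'
#' @param config a [sim_config()].
#' @return a `mating_trials` table.
#' @export
gen_mating_trials <- function(config) {
  taxa <- config$taxa
  rows <- with_substream(config$seed, "mating_trials", {
    out <- list()
    id <- 0L
    for (f in taxa) {
      nt <- config$n_trials[[f]]
      for (i in seq_len(nt)) {
        id <- id + 1L
        comp <- if (i %% 2 == 0) 15L else 3L
        mated <- stats::runif(1) < config$p_mating[[f]]
        outcome <- if (mated)
          sample(taxa, 1, prob = config$mating_probabilities[f, ]) else "none"
        out[[id]] <- data.frame(trial_id = sprintf("T%04d", id), female_taxon = f,
                                composition = comp, outcome = outcome,
                                observed = TRUE, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  as_iso_table(rows, "mating_trials")
}

#' Simulate per-female oviposition counts
#'
#' Per-plant egg counts per female are negative binomial with mean
#' (female total) x (taxon's plant proportion) and dispersion theta
#' (variance mu + mu^2/theta).
#'
#' @param config a [sim_config()].
#' @return an `oviposition_individual` table.
#' @export
gen_oviposition <- function(config) {
  m <- config$oviposition_means
  plants <- colnames(m)
  rows <- with_substream(config$seed, "oviposition", {
    out <- list()
    for (tx in config$taxa) {
      for (f in seq_len(config$n_females_host[[tx]])) {
        mu <- config$eggs_per_female * m[tx, ]
        cnt <- stats::rnbinom(length(mu), mu = mu, size = config$oviposition_theta)
        out[[length(out) + 1L]] <- data.frame(
          female_id = paste0(tx, "_F", f), taxon = tx, plant = plants,
          eggs = cnt, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  as_iso_table(rows, "oviposition_individual")
}

## ground-truth compound roster for gen_compound_table
compound_roster <- function(config) {
  data.frame(
    compound_id = c(sprintf("pher%02d", seq_len(config$n_compound_true)),
                    sprintf("cont%02d", seq_len(config$n_compound_contaminant)),
                    sprintf("flat%02d", seq_len(config$n_compound_flat)),
                    sprintf("sing%02d", seq_len(config$n_compound_singleton))),
    role = rep(c("true_pheromone", "contaminant", "flat", "singleton"),
               c(config$n_compound_true, config$n_compound_contaminant,
                 config$n_compound_flat, config$n_compound_singleton)),
    stringsAsFactors = FALSE)
}

#' Simulate a GC-MS compound amount table
#'
#' Log-normal amounts (nmol) around taxon- and region-specific means. True
#' pheromones are enriched in male androconia by `enrichment_factor` with
#' taxon-specific baseline means (so taxa separate in composition);
#' contaminants appear at equal mean amounts in every region; "flat"
#' compounds occur on wings without androconial enrichment; singletons are
#' detected in exactly one sample. Regions sampled: androconia for all
#' males, hindwing_control for 5 males per taxon, female_control for
#' configured females.
#'
#' @param config a [sim_config()].
#' @return a `compounds` table; the ground-truth roster is attached as
#'   attribute `"roster"`.
#' @export
gen_compound_table <- function(config) {
  roster <- compound_roster(config)
  taxa <- config$taxa
  sdl <- config$compound_sdlog
  rows <- with_substream(config$seed, "compounds", {
    samples <- list()
    for (tx in taxa) {
      for (i in seq_len(config$n_males_pheromone[[tx]])) {
        id <- paste0(tx, "_M", i)
        samples[[length(samples) + 1L]] <- list(id = id, taxon = tx, sex = "male",
                                                region = "androconia")
        if (i <= 5)
          samples[[length(samples) + 1L]] <- list(id = id, taxon = tx, sex = "male",
                                                  region = "hindwing_control")
      }
      nf <- config$n_female_controls[[tx]]
      for (i in seq_len(nf))
        samples[[length(samples) + 1L]] <- list(id = paste0(tx, "_F", i),
                                                taxon = tx, sex = "female",
                                                region = "female_control")
    }
    # taxon-specific baseline means per true pheromone: each taxon expresses
    # a shifted subset strongly, giving distinct blends
    base <- matrix(0.2, length(taxa), config$n_compound_true,
                   dimnames = list(taxa, NULL))
    for (ti in seq_along(taxa)) {
      idx <- ((seq_len(config$n_compound_true) + (ti - 1) * 8) %%
                config$n_compound_true) + 1
      base[ti, idx[seq_len(min(10, config$n_compound_true))]] <-
        seq(2, 0.5, length.out = min(10, config$n_compound_true))
    }
    out <- list()
    for (s in samples) {
      for (j in seq_len(nrow(roster))) {
        cmp <- roster$compound_id[j]; role <- roster$role[j]
        mu <- switch(role,
          true_pheromone = {
            b <- base[s$taxon, as.integer(sub("pher", "", cmp))]
            if (s$region == "androconia") b * config$enrichment_factor else b
          },
          contaminant = 0.5,
          flat = 0.8,
          singleton = 0)
        if (role == "singleton") next  # placed separately below

        amt <- if (mu > 0) stats::rlnorm(1, log(mu), sdl) else 0
        out[[length(out) + 1L]] <- data.frame(
          individual_id = s$id, taxon = s$taxon, sex = s$sex, region = s$region,
          compound_id = cmp, amount = amt, stringsAsFactors = FALSE)
      }
    }
    # singletons: one detection each, placed in successive androconial samples
    andro_ids <- unique(vapply(Filter(function(s) s$region == "androconia", samples),
                               `[[`, character(1), "id"))
    for (k in seq_len(config$n_compound_singleton)) {
      s_id <- andro_ids[((k - 1) %% length(andro_ids)) + 1]
      tx <- sub("_.*", "", s_id)
      out[[length(out) + 1L]] <- data.frame(
        individual_id = s_id, taxon = tx, sex = "male", region = "androconia",
        compound_id = sprintf("sing%02d", k),
        amount = stats::rlnorm(1, log(0.3), sdl), stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  tbl <- as_iso_table(rows, "compounds")
  attr(tbl, "roster") <- roster
  tbl
}

#' Simulate courtship observation counts
#'
#' Per trial (one virgin female, five males of each taxon) the hover count
#' from each male taxon is negative binomial around the configured rate
#' times a log-normal female activity effect shared by the trial's three
#' counts.
#'
#' @param config a [sim_config()].
#' @param behavior behaviour label to emit (default "hover").
#' @return a `courtship` table.
#' @export
gen_courtship <- function(config, behavior = "hover") {
  taxa <- config$taxa
  rows <- with_substream(config$seed, paste0("courtship_", behavior), {
    out <- list()
    id <- 0L
    for (f in taxa) {
      for (tr in seq_len(config$n_trials_courtship[[f]])) {
        id <- id + 1L
        act <- stats::rlnorm(1, -config$courtship_female_sd^2 / 2,
                             config$courtship_female_sd)
        for (mt in taxa) {
          mu <- config$courtship_rates[f, match(mt, taxa)] * act
          out[[length(out) + 1L]] <- data.frame(
            trial_id = sprintf("C%04d", id), female_taxon = f, male_taxon = mt,
            behavior = behavior,
            count = stats::rnbinom(1, mu = mu, size = config$courtship_theta),
            window_id = 1L, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  })
  as_iso_table(rows, "courtship")
}

#' Simulate brood hatch records
#'
#' Per-brood hatch counts are beta-binomial: the brood's hatch probability
#' is Beta with mean p and overdispersion rho (rho = 0 collapses to
#' binomial), a configurable fraction of eggs is flagged parasitized (and
#' cannot hatch), and sterile cross labels lay no eggs.
#'
#' @param config a [sim_config()].
#' @return a `broods` table.
#' @export
gen_broods <- function(config) {
  rows <- with_substream(config$seed, "broods", {
    out <- list()
    id <- 0L
    for (ct in names(config$hatch_p)) {
      p <- config$hatch_p[[ct]]
      for (b in seq_len(config$n_broods)) {
        id <- id + 1L
        laid <- stats::rpois(1, config$brood_size)
        par <- stats::rbinom(1, laid, config$parasitism_rate)
        pb <- if (config$hatch_rho > 0) {
          ab <- (1 - config$hatch_rho) / config$hatch_rho
          stats::rbeta(1, p * ab, (1 - p) * ab)
        } else p
        hatched <- stats::rbinom(1, laid - par, pb)
        out[[id]] <- data.frame(brood_id = sprintf("B%04d", id), cross_type = ct,
                                eggs_laid = laid, eggs_hatched = hatched,
                                eggs_parasitized = par,
                                protocol_phase = if (b <= config$n_broods / 3)
                                  "before" else "after",
                                stringsAsFactors = FALSE)
      }
    }
    for (ct in config$sterile_crosses) {
      for (b in seq_len(max(2, config$n_broods %/% 2))) {
        id <- id + 1L
        out[[id]] <- data.frame(brood_id = sprintf("B%04d", id), cross_type = ct,
                                eggs_laid = 0, eggs_hatched = 0,
                                eggs_parasitized = 0, protocol_phase = "after",
                                stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  as_iso_table(rows, "broods")
}

#' Simulate pupal fate counts
#'
#' Multinomial fates per cross at the configured probabilities.
#'
#' @param config a [sim_config()].
#' @return a `pupal_fates` table.
#' @export
gen_pupal_fates <- function(config) {
  pr <- config$pupal_fate_probs
  rows <- with_substream(config$seed, "pupal_fates", {
    do.call(rbind, lapply(rownames(pr), function(ct) {
      n <- config$n_pupae[[ct]]
      cnt <- as.vector(stats::rmultinom(1, n, pr[ct, ]))
      data.frame(cross_type = ct, emerged = cnt[1], failed_emerge = cnt[2],
                 never_emerged = cnt[3], failed_pupation = cnt[4],
                 stringsAsFactors = FALSE)
    }))
  })
  as_iso_table(rows, "pupal_fates")
}

#' Simulate occurrence records on overlapping ranges
#'
#' Two (or k) taxa occupy equal-width rectangular bands of grid cells whose
#' pairwise shared fraction equals `range_overlap_fraction` between
#' consecutive taxa; occurrence points sample occupied cells uniformly with
#' within-cell jitter, and climate values are drawn from per-taxon normal
#' envelopes.
#'
#' @param config a [sim_config()].
#' @return an `occurrences` table.
#' @export
gen_occurrence_grid <- function(config) {
  f <- config$range_overlap_fraction
  W <- config$range_cells
  taxa <- config$taxa
  rows <- with_substream(config$seed, "occurrences", {
    out <- list()
    for (ti in seq_along(taxa)) {
      x0 <- (ti - 1) * W * (1 - f)   # consecutive ranges share fraction f
      cells_x <- seq.int(floor(x0), floor(x0) + W - 1)
      n <- config$n_occurrences
      cx <- c(cells_x, sample(cells_x, max(0, n - length(cells_x)), replace = TRUE))[seq_len(n)]
      out[[ti]] <- data.frame(
        taxon = taxa[ti],
        lon = cx + stats::runif(n),
        lat = stats::runif(n, 0, 1),
        mean_annual_temp = stats::rnorm(n, config$climate_means[ti, 1],
                                        config$climate_sds[1]),
        annual_precip = stats::rnorm(n, config$climate_means[ti, 2],
                                     config$climate_sds[2]),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  as_iso_table(rows, "occurrences")
}

#' Write the full synthetic CSV bundle plus ground truth
#'
#' Generates every input table from one config and writes them to `dir`
#' together with a `ground_truth.yaml` recording the generating parameters.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return named character vector of written file paths, invisibly.
#' @export
gen_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    mating_trials = "mating_trials.csv", oviposition = "oviposition.csv",
    compounds = "compounds.csv", courtship = "courtship.csv",
    broods = "broods.csv", pupal_fates = "pupal_fates.csv",
    occurrences = "occurrences.csv")
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  write_table(gen_mating_trials(config), paths["mating_trials"])
  write_table(gen_oviposition(config), paths["oviposition"])
  write_table(gen_compound_table(config), paths["compounds"])
  write_table(gen_courtship(config), paths["courtship"])
  write_table(gen_broods(config), paths["broods"])
  write_table(gen_pupal_fates(config), paths["pupal_fates"])
  write_table(gen_occurrence_grid(config), paths["occurrences"])
  gt <- file.path(dir, "ground_truth.yaml")
  cfg <- unclass(config)
  cfg$mating_probabilities <- apply(config$mating_probabilities, 1, as.list,
                                    simplify = FALSE)
  cfg$oviposition_means <- NULL
  cfg$pupal_fate_probs <- NULL
  cfg$courtship_rates <- apply(config$courtship_rates, 1, as.list,
                               simplify = FALSE)
  cfg$climate_means <- NULL; cfg$climate_sds <- NULL
  yaml::write_yaml(cfg, gt)
  invisible(c(paths, ground_truth = gt))
}
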