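#' Run the full resistance-genetics analysis pipeline
#'
#' Executes the monitoring, F2-screen, probit, inheritance and genotyping
#' stages in order and writes paper-style report tables (CSV), a JSON
#' results bundle and a run manifest to \code{out_dir}. Rendered tables
#' are views of the JSON bundle; every number in them is re-derivable from
#' it.
#'
#' Two input modes are supported, chosen by the config:
#' \itemize{
#'   \item \code{simulate: true} - a synthetic study is generated from the
#'     config's simulation parameters (see [sim_config()]), covering
#'     per-population monitoring bioassays, genotype panels, F2 screens
#'     and the cross/backcross series; the generated CSVs are written to
#'     \code{out_dir/data/} so each stage's input is inspectable.
#'   \item \code{inputs:} - paths to user CSVs (\code{bioassay},
#'     \code{isolines}, \code{genotypes}); only the stages whose inputs
#'     are present run.
#' }
#' All randomness flows from the single top-level \code{seed}.
#'
#' @param config Path to a YAML or JSON config file, or an equivalent
#'   named list. Recognised top-level fields: \code{seed},
#'   \code{simulate}, \code{sim} (overrides for [sim_config()]),
#'   \code{inputs}, \code{diagnostic_dose}, \code{reference_strain},
#'   \code{n_populations}, \code{seasons}, \code{abbott},
#'   \code{bourguet_clip}, \code{monogenic_rule}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the results bundle (a named list, also written as
#'   \code{results.json}).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "data"), showWarnings = FALSE)
  set.seed(cfg$seed)

  settings <- list(
    estimator = "plus-one-over-4n",
    abbott = isTRUE(cfg$abbott),
    bourguet_clip = !isFALSE(cfg$bourguet_clip),
    monogenic_rule = cfg$monogenic_rule %||% "mixed",
    heterogeneity_ci = TRUE,
    diagnostic_dose = cfg$diagnostic_dose %||% 0.41,
    n_per_group = (if (is.list(cfg[["sim"]])) cfg[["sim"]]$n_per_dose) %||% 64L
  )
  message("pipeline settings: ",
          paste(names(settings), unlist(lapply(settings, format)),
                sep = "=", collapse = ", "))

  data <- if (isTRUE(cfg$simulate)) {
    generate_study(cfg, file.path(out_dir, "data"))
  } else {
    read_study_inputs(cfg)
  }

  results <- list(settings = settings)

  # stage 1: discriminating-dose monitoring
  if (!is.null(data$monitoring)) {
    mort <- summarize_discriminating_dose(data$monitoring,
                                          settings$diagnostic_dose,
                                          abbott = settings$abbott)
    results$discriminating_dose <- list(
      per_population = mort,
      per_season = season_mortality_summary(mort)
    )
  }

  # stage 2: F2 screen
  if (!is.null(data$isolines)) {
    iso <- classify_isolines(data$isolines)
    by_season <- composite_frequency(iso, by = "season")
    by_pop <- composite_frequency(iso, by = "population")
    results$f2_screen <- list(per_season = by_season$estimates,
                              season_comparisons = by_season$comparisons,
                              per_population = by_pop$estimates)
  }

  # stage 3 + 4: probit fits and inheritance on the cross series
  if (!is.null(data$crosses)) {
    results$inheritance <- analyze_crosses(data$crosses, settings)
  }

  # stage 5: genotyping and association
  if (!is.null(data$genotypes)) {
    freq <- tabulate_genotypes(data$genotypes)
    results$genotypes <- list(per_population = freq,
                              ranking = rank_genotypes(freq)$ranking)
    if (!is.null(results$discriminating_dose)) {
      assoc <- associate_mortality(freq,
                                   results$discriminating_dose$per_population)
      results$association <- assoc[c("slope", "intercept", "f_stat",
                                     "df1", "df2", "r", "r_signed",
                                     "p_value", "n_populations")]
    }
  }

  write_report(results, out_dir)
  write_manifest(cfg, data, out_dir)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

# build the sim_config from config overrides
config_sim <- function(cfg) {
  args <- cfg[["sim"]] %||% list()
  args$seed <- cfg$seed
  for (nm in c("allele_freqs", "genotype_lc50", "genotype_slope")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  do.call(sim_config, args)
}

generate_study <- function(cfg, data_dir) {
  sim <- config_sim(cfg)
  n_pops <- cfg$n_populations %||% 12L
  seasons <- cfg$seasons %||% c("2019", "2020", "2021")
  p_r <- sim$allele_freqs[["M"]] + sim$allele_freqs[["K"]]
  k_ratio <- if (p_r > 0)
    sim$allele_freqs[["K"]] / p_r else 0

  monitoring <- list(); genotypes <- list(); isolines <- list()
  for (i in seq_len(n_pops)) {
    pop <- sprintf("pop%02d", i)
    season <- seasons[((i - 1L) %% length(seasons)) + 1L]
    # between-population spread of the resistance-allele frequency
    p_pop <- stats::rbeta(1L, 2, 2 * (1 - p_r) / max(p_r, 1e-6))
    pop_sim <- sim
    pop_sim$allele_freqs <- c(I = 1 - p_pop, M = p_pop * (1 - k_ratio),
                              K = p_pop * k_ratio)
    # HWE genotype-class mixture at this population's frequency
    mix <- c(SS = (1 - p_pop)^2, RS = 2 * p_pop * (1 - p_pop),
             RR = p_pop^2)
    bio <- simulate_bioassay(pop_sim, mix = mix, strain = pop,
                             doses = sim$diagnostic_dose,
                             n_per_dose = 512L, seed = NULL)
    bio$population <- pop; bio$season <- season
    monitoring[[i]] <- bio
    gp <- simulate_genotype_panel(pop_sim, n_individuals = 20L,
                                  population = pop, season = season,
                                  seed = NULL)
    genotypes[[i]] <- gp
    isolines[[i]] <- simulate_f2_screen(pop_sim, population = pop,
                                        season = season, seed = NULL)
  }
  data <- list(
    monitoring = do.call(rbind, monitoring),
    genotypes = do.call(rbind, genotypes),
    isolines = do.call(rbind, isolines),
    crosses = simulate_crosses(sim, seed = NULL)
  )
  utils::write.csv(data$monitoring,
                   file.path(data_dir, "monitoring_bioassay.csv"),
                   row.names = FALSE)
  utils::write.csv(data$genotypes, file.path(data_dir, "genotypes.csv"),
                   row.names = FALSE)
  utils::write.csv(data$isolines, file.path(data_dir, "isolines.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, data$crosses),
                   file.path(data_dir, "crosses_bioassay.csv"),
                   row.names = FALSE)
  data
}

read_study_inputs <- function(cfg) {
  paths <- cfg$inputs %||% list()
  data <- list()
  if (!is.null(paths$bioassay)) {
    data$monitoring <- validate_bioassay(
      utils::read.csv(paths$bioassay, stringsAsFactors = FALSE))
  }
  if (!is.null(paths$isolines)) {
    data$isolines <- utils::read.csv(paths$isolines,
                                     stringsAsFactors = FALSE)
  }
  if (!is.null(paths$genotypes)) {
    data$genotypes <- utils::read.csv(paths$genotypes,
                                      stringsAsFactors = FALSE)
  }
  if (!is.null(paths$crosses)) {
    cr <- read_bioassay(paths$crosses)
    data$crosses <- split(cr, cr$strain)
    names(data$crosses) <- tolower(names(data$crosses))
  }
  data
}

analyze_crosses <- function(crosses, settings) {
  fits <- lapply(crosses[c("sus", "res", "f1_h1", "f1_h2")], fit_probit)
  tab <- probit_table(fits, reference = "Sus")

  stone <- do.call(rbind, lapply(c("f1_h1", "f1_h2"), function(f1) {
    d <- stone_dominance(fits$sus$lc50, fits$res$lc50, fits[[f1]]$lc50,
                         res_censored = fits$res$censored)
    data.frame(cross = f1, stone_d = d$value, is_bound = d$is_bound,
               label = dominance_label(d), stringsAsFactors = FALSE)
  }))

  obs_mort <- function(records, d) {
    sub <- records[records$concentration_ug_cm2 == d, , drop = FALSE]
    100 * sum(sub$n_dead) / sum(sub$n_treated)
  }
  doses <- sort(unique(
    crosses$sus$concentration_ug_cm2[crosses$sus$concentration_ug_cm2 > 0]))
  bourguet <- do.call(rbind, lapply(doses, function(d) {
    do.call(rbind, lapply(c("f1_h1", "f1_h2"), function(f1) {
      dom <- bourguet_dominance(obs_mort(crosses$sus, d),
                                obs_mort(crosses[[f1]], d),
                                obs_mort(crosses$res, d),
                                concentration = d,
                                clip = settings$bourguet_clip)
      data.frame(concentration = d, cross = f1, bourguet_d = dom$value,
                 bourguet_d_raw = dom$raw, stringsAsFactors = FALSE)
    }))
  }))

  mono <- do.call(rbind, lapply(c("bc1", "bc2"), function(bc) {
    f1 <- if (bc == "bc1") "f1_h1" else "f1_h2"
    t <- monogenic_table(crosses[[bc]], fits[[f1]], fits$res,
                         f1_records = crosses[[f1]],
                         res_records = crosses$res,
                         rule = settings$monogenic_rule)
    t$backcross <- bc
    t
  }))

  lande <- tryCatch({
    bc_fit <- fit_probit(crosses$bc1)
    ef <- lande_effective_factors(
      log10(fits$res$lc50), log10(fits$sus$lc50),
      tolerance_variance(bc_fit), tolerance_variance(fits$f1_h1))
    data.frame(n_e = ef$n_e, range_log10 = ef$phenotypic_range,
               sigma2_s = ef$segregational_variance)
  }, error = function(e) data.frame(n_e = NA_real_,
                                    range_log10 = NA_real_,
                                    sigma2_s = NA_real_))

  list(probit_fits = tab, stone = stone, bourguet = bourguet,
       monogenic = mono, effective_factors = lande)
}

write_report <- function(results, out_dir) {
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  wr(results$discriminating_dose$per_population,
     "discriminating_mortality.csv")
  wr(results$f2_screen$per_season, "f2_frequency_by_season.csv")
  wr(results$f2_screen$per_population, "f2_frequency_by_population.csv")
  wr(results$inheritance$probit_fits, "probit_fits.csv")
  wr(results$inheritance$stone, "stone_dominance.csv")
  wr(results$inheritance$bourguet, "bourguet_dominance.csv")
  if (!is.null(results$inheritance$monogenic)) {
    m <- results$inheritance$monogenic
    m$flag <- ifelse(!is.na(m$significant) & m$significant, "*", "")
    wr(m, "monogenic_test.csv")
  }
  wr(results$genotypes$per_population, "genotype_frequencies.csv")
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE, force = TRUE)
}

write_manifest <- function(cfg, data, out_dir) {
  data_dir <- file.path(out_dir, "data")
  files <- if (dir.exists(data_dir))
    list.files(data_dir, full.names = TRUE) else character(0)
  checksums <- if (length(files) > 0L)
    as.list(tools::md5sum(files)) else list()
  names(checksums) <- basename(files)
  manifest <- list(
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(
      textConnection_md5(cfg))),
    input_checksums = checksums,
    package_version = as.character(utils::packageVersion("resistkit")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

# hash a config list via its canonical serialized form
textConnection_md5 <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  tools::md5sum(tmp)
}
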