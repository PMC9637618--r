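#' Configuration of a two-wave network analysis run
#'
#' Input is either a pair of cohort CSV paths (or in-memory tables) or a
#' [generator_config()] from which both waves are simulated. Per-stratum
#' sampler seeds are derived from `seed` by fixed offsets (wave 1:
#' male `+1`, female `+2`; wave 2: male `+3`, female `+4`) and recorded in
#' every artifact.
#'
#' @param wave1,wave2 CSV paths or [cohort_table()]s (optional when
#'   `generator` is given).
#' @param generator optional [generator_config()].
#' @param n_draws,burn_in,thin sampler settings (defaults 5000/500/1).
#' @param level credible level for edge selection and differences (0.95).
#' @param pp_threshold confirmation threshold on posterior probabilities
#'   (0.95).
#' @param seed master integer seed.
#' @param out_dir artifact directory (created if needed); `NULL` disables
#'   writing.
#' @param schema a [variable_schema()].
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(wave1 = NULL, wave2 = NULL, generator = NULL,
                            n_draws = 5000, burn_in = 500, thin = 1,
                            level = 0.95, pp_threshold = 0.95, seed,
                            out_dir = NULL, schema = default_schema()) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(generator) && is.null(wave1))
    stop("provide wave1 data or a generator config")
  structure(list(wave1 = wave1, wave2 = wave2, generator = generator,
                 n_draws = n_draws, burn_in = burn_in, thin = thin,
                 level = level, pp_threshold = pp_threshold,
                 seed = as.integer(seed), out_dir = out_dir,
                 schema = schema),
            class = "analysis_config")
}

resolve_table <- function(x, config, wave) {
  if (inherits(x, "cohort_table")) return(x)
  if (is.character(x)) return(read_cohort_csv(x, config$schema))
  if (!is.null(config$generator)) {
    w1 <- generate_wave1(config$generator)
    if (wave == 1) return(w1)
    return(simulate_attrition(w1, config$generator))
  }
  stop("no wave ", wave, " data available")
}

fit_stratum <- function(table, config, seed_offset) {
  gibbs_sample(table, n_draws = config$n_draws, burn_in = config$burn_in,
               thin = config$thin, seed = config$seed + seed_offset)
}

write_num_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Exploratory (wave 1) analysis: fit, select, compare, hypothesize
#'
#' Splits the wave-1 cohort by sex, fits the copula graphical model in each
#' stratum, selects edges by credible interval, computes per-edge posterior
#' differences (female minus male — the direction is fixed and labelled in
#' every output), forms directional hypotheses from significant
#' differences, and computes a shared averaged layout. All artifacts (edge
#' lists, difference table, hypotheses YAML, layout, SVG figures, run
#' metadata) go to `config$out_dir` when set.
#'
#' @param config an [analysis_config()].
#' @return a `wave_report` list.
#' @export
run_exploratory <- function(config) {
  wave1 <- with_stage("wave-1 input", resolve_table(config$wave1, config, 1))
  strata <- with_stage("sex split", split_by_sex(wave1))
  fit_f <- with_stage("female fit", fit_stratum(strata$female, config, 2L))
  fit_m <- with_stage("male fit", fit_stratum(strata$male, config, 1L))
  est_f <- select_edges(fit_f, config$level)
  est_m <- select_edges(fit_m, config$level)
  diffs <- with_stage("group comparison",
                      edge_differences(fit_f, fit_m,
                                       n_draws = config$n_draws,
                                       level = config$level))
  hyps <- form_hypotheses(diffs)
  layout <- fr_layout_averaged(list(est_f, est_m), seed = config$seed)
  report <- list(stage = "exploratory",
                 estimates = list(female = est_f, male = est_m),
                 differences = diffs, hypotheses = hyps, layout = layout,
                 difference_direction = "female_minus_male",
                 seed = config$seed, n_draws = config$n_draws)
  if (!is.null(config$out_dir))
    report$artifacts <- write_report(report, config)
  report
}

#' Confirmatory (wave 2) analysis: refit and test hypotheses
#'
#' Fits per-sex networks on the wave-2 cohort and evaluates each stored
#' directional hypothesis by its posterior probability, confirming those
#' above the threshold. The report records the MD5 hash of the hypothesis
#' file it tested and a combined summary classifying every edge across both
#' sexes.
#'
#' @param config an [analysis_config()].
#' @param hypotheses path to a YAML file from [run_exploratory()] /
#'   [write_hypotheses()], or a hypotheses data frame.
#' @return a `wave_report` list.
#' @export
run_confirmatory <- function(config, hypotheses) {
  hyp_hash <- NA_character_
  if (is.character(hypotheses)) {
    hyp_hash <- unname(tools::md5sum(hypotheses))
    hypotheses <- with_stage("hypothesis input", read_hypotheses(hypotheses))
  }
  wave2 <- with_stage("wave-2 input", resolve_table(config$wave2, config, 2))
  strata <- with_stage("sex split", split_by_sex(wave2))
  fit_f <- with_stage("female fit", fit_stratum(strata$female, config, 4L))
  fit_m <- with_stage("male fit", fit_stratum(strata$male, config, 3L))
  est_f <- select_edges(fit_f, config$level)
  est_m <- select_edges(fit_m, config$level)
  confirmed <- with_stage("confirmation",
                          posterior_probability(fit_f, fit_m, hypotheses,
                                                config$pp_threshold))
  layout <- fr_layout_averaged(list(est_f, est_m), seed = config$seed)
  report <- list(stage = "confirmatory",
                 estimates = list(female = est_f, male = est_m),
                 confirmations = confirmed,
                 shared_edges = shared_edge_report(est_f, est_m),
                 layout = layout, hypothesis_file_md5 = hyp_hash,
                 difference_direction = "female_minus_male",
                 seed = config$seed, n_draws = config$n_draws)
  if (!is.null(config$out_dir))
    report$artifacts <- write_report(report, config)
  report
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

write_report <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  paths <- c(
    edges_female = write_num_csv(network_edge_list(report$estimates$female),
                                 out(paste0(report$stage,
                                            "_edges_female.csv"))),
    edges_male = write_num_csv(network_edge_list(report$estimates$male),
                               out(paste0(report$stage, "_edges_male.csv"))),
    layout = write_num_csv(data.frame(node = rownames(report$layout),
                                      report$layout),
                           out(paste0(report$stage, "_layout.csv"))))
  for (s in c("female", "male")) {
    fp <- out(paste0(report$stage, "_network_", s, ".svg"))
    render_network_figure(report$estimates[[s]], report$layout, fp)
    paths[paste0("figure_", s)] <- fp
  }
  if (report$stage == "exploratory") {
    paths["differences"] <- write_num_csv(
      as.data.frame(report$differences), out("exploratory_differences.csv"))
    paths["hypotheses"] <- out("hypotheses.yaml")
    write_hypotheses(report$hypotheses, paths[["hypotheses"]])
  } else {
    paths["confirmations"] <- write_num_csv(
      as.data.frame(report$confirmations), out("confirmatory_pp.csv"))
    paths["summary_csv"] <- write_num_csv(summary_table(report),
                                          out("summary_table.csv"))
    paths["summary_md"] <- write_summary_md(summary_table(report),
                                            out("summary_table.md"))
  }
  meta <- list(stage = report$stage, seed = report$seed,
               n_draws = report$n_draws, level = config$level,
               pp_threshold = config$pp_threshold,
               difference_direction = report$difference_direction,
               hypothesis_file_md5 = report$hypothesis_file_md5,
               note = paste("no multiplicity correction across edges;",
                            "exploratory-confirmatory design"))
  yaml::write_yaml(meta, out(paste0(report$stage, "_run.yaml")))
  paths["run_meta"] <- out(paste0(report$stage, "_run.yaml"))
  paths
}

summary_table <- function(report) {
  tab <- report$shared_edges
  names(tab)[names(tab) == "partial_a"] <- "partial_female"
  names(tab)[names(tab) == "partial_b"] <- "partial_male"
  tab$label <- sub("^a_only$", "female_only", tab$label)
  tab$label <- sub("^b_only$", "male_only", tab$label)
  conf <- report$confirmations
  key <- paste(tab$node_i, tab$node_j)
  ck <- paste(conf$node_i, conf$node_j)
  ck2 <- paste(conf$node_j, conf$node_i)
  m <- match(key, ck)
  m[is.na(m)] <- match(key, ck2)[is.na(m)]
  tab$hypothesis <- ifelse(is.na(m), "", conf$direction[m])
  tab$pp <- ifelse(is.na(m), NA_real_, conf$pp[m])
  tab$confirmed <- ifelse(is.na(m), NA, conf$confirmed[m])
  tab
}

write_summary_md <- function(tab, path) {
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, format = "g",
                                                  digits = 3))
  lines <- c("| Edge | Wave-2 status | Partial (F) | Partial (M) | Hypothesis | PP | Confirmed |",
             "|---|---|---|---|---|---|---|",
             sprintf("| %s--%s | %s | %s | %s | %s | %s | %s |",
                     tab$node_i, tab$node_j, tab$label,
                     fmt(tab$partial_female), fmt(tab$partial_male),
                     tab$hypothesis, fmt(tab$pp),
                     ifelse(is.na(tab$confirmed), "",
                            ifelse(tab$confirmed, "yes", "no"))))
  writeLines(lines, path)
  path
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write the bundled two-wave scenario as CSVs),
#' `explore` (wave-1 exploratory analysis), `confirm` (wave-2 confirmatory
#' analysis against a hypotheses file), `check` (between-wave paired
#' t-tests and completer/dropout comparison). Common flags: `--seed INT`,
#' `--out DIR`, `--draws INT`, `--burn INT`, `--level FLOAT`,
#' `--pp-threshold FLOAT`, `--wave1 CSV`, `--wave2 CSV`,
#' `--hypotheses PATH`, `--n INT` (simulate).
#'
#' @param args character vector (defaults to the command line).
#' @return invisibly, the report or written paths.
#' @export
rankggm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: rankggm <simulate|explore|confirm|check> [--flags]")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- list(seed = 1L, out = "rankggm_out", draws = 5000L, burn = 500L,
               level = 0.95, pp_threshold = 0.95, n = 450L,
               wave1 = NULL, wave2 = NULL, hypotheses = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opts)) stop("unknown flag: ", args[i])
    opts[[key]] <- utils::type.convert(args[i + 1], as.is = TRUE)
    i <- i + 2
  }
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  run_id <- sprintf("%s-seed%d", cmd, opts$seed)
  message("[", run_id, "] starting")
  cfg <- function() analysis_config(
    wave1 = opts$wave1, wave2 = opts$wave2,
    generator = if (is.null(opts$wave1) || (cmd == "confirm" &&
                                            is.null(opts$wave2)))
      fixture_config(seed = opts$seed,
                     n_per_sex = c(male = opts$n, female = opts$n)),
    n_draws = opts$draws, burn_in = opts$burn, level = opts$level,
    pp_threshold = opts$pp_threshold, seed = opts$seed, out_dir = opts$out)
  res <- switch(cmd,
    simulate = {
      gc <- fixture_config(seed = opts$seed,
                           n_per_sex = c(male = opts$n, female = opts$n))
      w1 <- generate_wave1(gc)
      w2 <- simulate_attrition(w1, gc)
      p1 <- file.path(opts$out, "wave1.csv")
      p2 <- file.path(opts$out, "wave2.csv")
      write_cohort_csv(w1, p1)
      write_cohort_csv(w2, p2)
      c(p1, p2)
    },
    explore = run_exploratory(cfg()),
    confirm = {
      if (is.null(opts$hypotheses))
        stop("confirm requires --hypotheses PATH")
      run_confirmatory(cfg(), opts$hypotheses)
    },
    check = {
      config <- cfg()
      w1 <- resolve_table(config$wave1, config, 1)
      w2 <- resolve_table(config$wave2, config, 2)
      tt <- do.call(rbind, lapply(node_names(config$schema), function(v) {
        r <- paired_wave_ttest(w1, w2, v)
        data.frame(variable = v, t = r$t, df = r$df, p = r$p, d = r$d,
                   n_pairs = r$n_pairs, degenerate = r$degenerate)
      }))
      cc <- compare_completers(w1, w1$subject %in% w2$subject)
      write_num_csv(tt, file.path(opts$out, "paired_ttests.csv"))
      write_num_csv(cc, file.path(opts$out, "completer_comparison.csv"))
      list(paired_ttests = tt, completer_comparison = cc)
    },
    stop("unknown subcommand: ", cmd))
  message("[", run_id, "] done; artifacts in ", opts$out)
  invisible(res)
}
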