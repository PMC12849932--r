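## Orchestration: a serializable run configuration, the simulation stage, the
## three analysis stages, and a structured run report. All randomness flows
## from the single config seed through named child streams.

#' Assemble a run configuration
#'
#' A fully serializable description of one reproducible run: the seed, the
#' design and generator parameters, and every analysis switch whose setting
#' affects published numbers (normalization scope, link function, beta
#' extraction mode, permutation count, FDR level).
#'
#' @param seed Master integer seed; all child streams derive from it.
#' @param n_participants Number of simulated participants (the study had 50).
#' @param n_runs Runs per participant (default 3, i.e. 81 trials).
#' @param agent [agent_params()] for the behavioral generator.
#' @param neural [neural_gen_spec()] for the neural generator.
#' @param n_perm Permutation iterations (default 10000).
#' @param alpha Two-tailed FDR level (default 0.05).
#' @param norm_scope Min-max normalization scope, "global" or "participant".
#' @param link Choice regression link, "logistic" or "linear".
#' @param beta_method Per-participant beta extraction, "mixed" or
#'   "independent".
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_participants = 50L, n_runs = 3L,
                       agent = agent_params(), neural = neural_gen_spec(),
                       n_perm = 10000L, alpha = 0.05,
                       norm_scope = c("global", "participant"),
                       link = c("logistic", "linear"),
                       beta_method = c("mixed", "independent")) {
  stopifnot(inherits(agent, "agent_params"), inherits(neural, "neural_gen_spec"))
  structure(list(
    seed = as.integer(seed), n_participants = as.integer(n_participants),
    n_runs = as.integer(n_runs), agent = agent, neural = neural,
    n_perm = as.integer(n_perm), alpha = alpha,
    norm_scope = match.arg(norm_scope), link = match.arg(link),
    beta_method = match.arg(beta_method)
  ), class = "run_config")
}

#' @noRd
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the simulation stage
#'
#' Generates the full synthetic data bundle: the trial skeleton, rating
#' tables, factor scores (the generated ratings projected through
#' [factor_scores()], so downstream recovery exercises the full
#' ratings-to-choice path), filled trials, and the neural maps with their
#' planted parameters. Optionally writes the behavioral tables and a manifest
#' of all planted parameters to `out_dir`; neural maps are kept in memory
#' unless `write_neural = TRUE` (tab-delimited text, practical only at reduced
#' scale).
#'
#' @param config [run_config()] object.
#' @param out_dir Optional output directory.
#' @param write_neural Also write parcellation/maps as TSV (default FALSE).
#' @return Invisible list: `trials`, `ratings`, `factors`, `neural`,
#'   `manifest`.
#' @export
run_simulation <- function(config, out_dir = NULL, write_neural = FALSE) {
  stopifnot(inherits(config, "run_config"))
  pids <- sprintf("sub%03d", seq_len(config$n_participants))
  design <- build_design(config$n_runs, seed = child_seed(config$seed, "design"))
  ratings <- simulate_ratings(config$agent, pids,
                              seed = child_seed(config$seed, "ratings"))
  fs <- factor_scores(ratings)
  trials <- simulate_choices(config$agent, design, fs$scores,
                             seed = child_seed(config$seed, "choices"))
  neural <- simulate_condition_maps(config$neural, config$n_participants,
                                    seed = child_seed(config$seed, "neural"))
  manifest <- list(
    seed = config$seed, config_hash = config_hash(config),
    n_participants = config$n_participants, n_runs = config$n_runs,
    planted = list(
      w_communal = as.list(config$agent$w_communal),
      w_obligation = as.list(config$agent$w_obligation),
      a_by_condition = as.list(config$neural$a_by_condition),
      b_by_condition = as.list(config$neural$b_by_condition),
      signal_parcels = config$neural$signal_parcels,
      signal_amplitude = config$neural$signal_amplitude,
      neural_noise_sd = config$neural$neural_noise_sd
    ),
    child_seeds = list(design = child_seed(config$seed, "design"),
                       ratings = child_seed(config$seed, "ratings"),
                       choices = child_seed(config$seed, "choices"),
                       neural = child_seed(config$seed, "neural"))
  )
  bundle <- list(trials = trials, ratings = ratings, factors = fs,
                 neural = neural, manifest = manifest)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(ratings, file.path(out_dir, "ratings.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (write_neural) {
      utils::write.table(data.frame(voxel = seq_along(neural$parcellation),
                                    parcel = neural$parcellation),
                         file.path(out_dir, "parcellation.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(data.frame(communal = neural$communal_map,
                                    obligation = neural$obligation_map),
                         file.path(out_dir, "pattern_maps.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      for (pid in names(neural$maps)) {
        utils::write.table(neural$maps[[pid]],
                           file.path(out_dir, paste0("maps_", pid, ".tsv")),
                           sep = "\t", row.names = FALSE, col.names = FALSE)
      }
    }
  }
  invisible(bundle)
}

#' @noRd
table_by_condition <- function(df, value_col) {
  pids <- unique(df$participant_id)
  lv <- condition_levels()
  M <- matrix(NA_real_, length(pids), length(lv),
              dimnames = list(pids, lv))
  for (cc in lv) {
    sub <- df[df$condition == cc, ]
    M[match(sub$participant_id, pids), cc] <- sub[[value_col]]
  }
  M
}

#' Run the behavioral analysis stage
#'
#' Choice-probability ANOVA battery, factor-based relative weight of Communal
#' Concern with its own battery, and the two Relative Self-payoff
#' comparisons.
#'
#' @param bundle Data bundle from [run_simulation()] (or an equivalent list
#'   with `trials`, `ratings`, `factors`).
#' @param config [run_config()] object.
#' @return List of result tables and StatResults.
#' @export
run_behavior <- function(bundle, config) {
  trials <- bundle$trials
  ok <- !is.na(trials$choice)
  agg <- stats::aggregate(list(p_alt = trials$choice[ok] == "altruistic"),
                          by = list(participant_id = trials$participant_id[ok],
                                    condition = trials$condition[ok]),
                          FUN = mean)
  choice_tab <- table_by_condition(agg, "p_alt")
  rw <- relative_weights(trials, factors = bundle$factors$scores,
                         link = config$link, method = config$beta_method)
  rw_tab <- table_by_condition(rw, "relative_weight")
  keep <- stats::complete.cases(rw_tab)
  res <- list(
    choice_table = choice_tab,
    choice_anova = rm_anova_gg(choice_tab),
    choice_trend = linear_trend(choice_tab),
    choice_pairwise = pairwise_comparisons(choice_tab),
    relative_weights = rw,
    rw_table = rw_tab,
    rw_anova = rm_anova_gg(rw_tab[keep, , drop = FALSE]),
    rw_trend = linear_trend(rw_tab[keep, , drop = FALSE]),
    rw_pairwise = pairwise_comparisons(rw_tab[keep, , drop = FALSE]),
    self_payoff_strategic = self_payoff_comparison(trials, "strategic",
                                                   cond_hi = "A1S3",
                                                   cond_ref = "A1S1"),
    self_payoff_altruistic = self_payoff_comparison(trials, "altruistic",
                                                    cond_hi = "A3S1",
                                                    cond_ref = "A1S1"),
    variance_explained = bundle$factors$variance_explained
  )
  res
}

#' Run the neural pattern-expression stage
#'
#' Expression table on both motive maps, min-max normalization at the
#' configured scope, the neural relative weight of Communal Concern, its
#' GG-corrected ANOVA and linear trend, and the within-participant permutation
#' test.
#'
#' @param bundle Data bundle with a `neural` element.
#' @param config [run_config()] object.
#' @return List of tables and test results.
#' @export
run_expression <- function(bundle, config) {
  nb <- bundle$neural
  et <- expression_table(nb$maps, nb$communal_map, nb$obligation_map, nb$grid)
  et <- minmax_normalize(et, scope = config$norm_scope)
  nrw <- neural_relative_weight(et)
  tab <- table_by_condition(nrw, "neural_relative_weight")
  n_dropped <- sum(!stats::complete.cases(tab))
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  list(expression = et, nrw = nrw, nrw_table = tab, n_dropped = n_dropped,
       nrw_anova = rm_anova_gg(tab),
       nrw_trend = linear_trend(tab),
       nrw_pairwise = pairwise_comparisons(tab),
       permutation = permutation_test(tab, n_perm = config$n_perm,
                                      seed = child_seed(config$seed, "perm")))
}

#' Run the parcel-wise RSA stage
#'
#' @param bundle Data bundle with a `neural` element.
#' @param config [run_config()] object.
#' @return Parcel results table from [rsa_parcelwise()].
#' @export
run_rsa <- function(bundle, config) {
  nb <- bundle$neural
  rsa_parcelwise(nb$maps, nb$parcellation, alpha = config$alpha)
}

#' Run the full pipeline
#'
#' Simulation, behavioral stage, neural-expression stage, and parcel-wise RSA
#' in sequence, with a structured report echoing the configuration, the child
#' seeds, and every test result. A stage failure halts the run naming the
#' stage; results of completed stages are preserved in the error's `partial`
#' attribute.
#'
#' @param config [run_config()] object.
#' @param out_dir Optional directory: writes `report.json`, the behavioral
#'   tables and the parcel results table.
#' @return List: `config`, `manifest`, `behavior`, `expression`, `rsa`.
#' @export
run_full <- function(config, out_dir = NULL) {
  results <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(paste0("stage '", name, "' failed: ", conditionMessage(e)))
      attr(err, "partial") <- results
      stop(err)
    })
  }
  bundle <- stage("simulate", run_simulation(config, out_dir = out_dir))
  results$manifest <- bundle$manifest
  results$behavior <- stage("behavior", run_behavior(bundle, config))
  results$expression <- stage("neural_expression", run_expression(bundle, config))
  results$rsa <- stage("rsa", run_rsa(bundle, config))
  if (!is.null(out_dir)) {
    utils::write.csv(results$rsa, file.path(out_dir, "parcel_results.csv"),
                     row.names = FALSE, quote = FALSE)
    report <- list(
      package_version = as.character(utils::packageVersion("reciprsa")),
      seed = config$seed, config_hash = config_hash(config),
      switches = list(norm_scope = config$norm_scope, link = config$link,
                      beta_method = config$beta_method,
                      n_perm = config$n_perm, alpha = config$alpha),
      child_seeds = bundle$manifest$child_seeds,
      behavior = list(
        choice_anova = as.list(results$behavior$choice_anova),
        choice_trend = as.list(results$behavior$choice_trend),
        rw_anova = as.list(results$behavior$rw_anova),
        rw_trend = as.list(results$behavior$rw_trend),
        self_payoff_strategic = as.list(results$behavior$self_payoff_strategic),
        self_payoff_altruistic = as.list(results$behavior$self_payoff_altruistic),
        variance_explained = results$behavior$variance_explained
      ),
      expression = list(
        nrw_anova = as.list(results$expression$nrw_anova),
        nrw_trend = as.list(results$expression$nrw_trend),
        permutation_p_f = results$expression$permutation$p_f,
        permutation_p_beta = results$expression$permutation$p_beta
      ),
      rsa = list(n_significant = sum(results$rsa$significant),
                 by_model = lapply(split(results$rsa, results$rsa$model),
                                   function(d) sum(d$significant)))
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  results
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write the synthetic bundle) and `run-all` (full
#' pipeline with report). Invoked by the `inst/cli/reciprsa` script:
#' `Rscript -e 'reciprsa::reciprsa_main()' simulate --seed 1 --out DIR`.
#'
#' @param args Character vector of arguments (default: command line).
#' @return Invisible result of the subcommand.
#' @export
reciprsa_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("-h", "--help"))
    stop("usage: reciprsa <simulate|run-all> [--seed S] [--n-participants N] ",
         "[--n-perm P] [--out DIR] [--small]", call. = FALSE)
  cmd <- args[1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--n-participants", type = "integer", default = 50L,
                            dest = "n_participants"),
      optparse::make_option("--n-perm", type = "integer", default = 10000L,
                            dest = "n_perm"),
      optparse::make_option("--out", type = "character", default = "reciprsa_out"),
      optparse::make_option("--small", action = "store_true", default = FALSE,
                            help = "reduced neural scale (20 parcels)")
    )), args = args[-1])
  neural <- if (opts$small) {
    neural_gen_spec(n_parcels = 20L, voxels_per_parcel = 30L,
                    signal_parcels = list(general = 1:2, altruistic = 3:4,
                                          strategic = 5:6, linear = 7:8))
  } else neural_gen_spec()
  config <- run_config(seed = opts$seed, n_participants = opts$n_participants,
                       n_perm = opts$n_perm, neural = neural)
  switch(cmd,
         "simulate" = invisible(run_simulation(config, out_dir = opts$out,
                                               write_neural = opts$small)),
         "run-all" = invisible(run_full(config, out_dir = opts$out)),
         stop("unknown subcommand: ", cmd, call. = FALSE))
}
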