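#' @keywords internal
"_PACKAGE"

## Task constants: three reciprocal-efficiency conditions, nine benefactor-cost
## levels, a 25-yuan endowment for the allocation decision, and a pain-time
## conversion of 0.8 s per yuan capped at 16 s.

#' Task constants for the interpersonal reciprocity task
#'
#' Central configuration block holding the payoff constants of the task:
#' condition labels with their (altruistic, strategic) efficiency multipliers,
#' the nine benefactor-cost levels, the participant's endowment, and the
#' pain-reduction conversion rate and cap.
#'
#' @return A list with elements `conditions` (data.frame: `label`,
#'   `eff_altruistic`, `eff_strategic`), `costs` (integer vector), `endowment`,
#'   `pain_rate`, `pain_cap_s`.
#' @export
#' @examples
#' task_constants()$conditions
task_constants <- function() {
  list(
    conditions = data.frame(
      label = c("A1S3", "A1S1", "A3S1"),
      eff_altruistic = c(1L, 1L, 3L),
      eff_strategic = c(3L, 1L, 1L),
      stringsAsFactors = FALSE
    ),
    costs = seq(4L, 20L, by = 2L),
    endowment = 25L,
    pain_rate = 0.8,
    pain_cap_s = 16
  )
}

#' Condition labels in canonical order
#' @return Character vector `c("A1S3", "A1S1", "A3S1")`.
#' @export
condition_levels <- function() c("A1S3", "A1S1", "A3S1")

#' Efficiency multiplier for one benefactor type in one condition
#'
#' @param condition Condition label ("A1S3", "A1S1" or "A3S1").
#' @param benefactor_type "altruistic" or "strategic".
#' @return Integer multiplier (1 or 3).
#' @export
#' @examples
#' efficiency_of("A1S3", "strategic")  # 3
efficiency_of <- function(condition, benefactor_type = c("altruistic", "strategic")) {
  benefactor_type <- match.arg(benefactor_type)
  cond <- task_constants()$conditions
  i <- match(condition, cond$label)
  if (anyNA(i)) stop("unknown condition label: ", paste(condition[is.na(i)], collapse = ", "))
  if (benefactor_type == "altruistic") cond$eff_altruistic[i] else cond$eff_strategic[i]
}

#' The canonical 27-cell condition grid
#'
#' The fixed ordering of the 27 design cells (3 efficiency conditions x 9 cost
#' levels) shared by every module that indexes condition maps or RDM rows:
#' A1S3 at costs 4..20, then A1S1, then A3S1.
#'
#' @return data.frame with 27 rows and columns `cell` (1..27), `condition`,
#'   `cost`.
#' @export
condition_grid <- function() {
  tc <- task_constants()
  data.frame(
    cell = seq_len(27L),
    condition = rep(condition_levels(), each = length(tc$costs)),
    cost = rep(tc$costs, times = 3L),
    stringsAsFactors = FALSE
  )
}

#' Build the trial skeleton of the interpersonal task
#'
#' Generates `n_runs` runs of 27 trials each; every run contains exactly one
#' trial per (condition x cost) cell, in an order randomized independently per
#' run. Choice and allocation columns are created empty, to be filled by an
#' agent simulation or parsed data.
#'
#' @param n_runs Number of runs (the task used 3, i.e. 81 trials).
#' @param seed Integer seed controlling the within-run shuffles.
#' @return data.frame with columns `run`, `trial_in_run`, `condition`, `cost`,
#'   `choice` (NA character), `allocation` (NA integer).
#' @export
#' @examples
#' d <- build_design(3, seed = 1)
#' nrow(d)  # 81
build_design <- function(n_runs, seed = 1L) {
  if (!is.numeric(n_runs) || length(n_runs) != 1L || is.na(n_runs) || n_runs < 1)
    stop("n_runs must be a single integer >= 1")
  n_runs <- as.integer(n_runs)
  grid <- condition_grid()
  rng <- local_rng(seed)
  runs <- lapply(seq_len(n_runs), function(r) {
    ord <- sample.int(nrow(grid))
    data.frame(
      run = r,
      trial_in_run = seq_len(nrow(grid)),
      condition = grid$condition[ord],
      cost = grid$cost[ord],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, runs)
  out$choice <- NA_character_
  out$allocation <- NA_integer_
  out
}

#' Pain reduction purchased by a benefactor's expenditure
#'
#' Each yuan the benefactor spends shortens the participant's pain stimulation
#' by 0.8 s, capped at 16 s so the pain never vanishes entirely.
#'
#' @param cost Benefactor's expenditure in yuan, in [0, 20].
#' @return Pain reduction in seconds.
#' @export
#' @examples
#' pain_reduction(20)  # 16
pain_reduction <- function(cost) {
  if (any(!is.finite(cost)) || any(cost < 0 | cost > 20))
    stop("cost must lie in [0, 20]")
  tc <- task_constants()
  pmin(tc$pain_rate * cost, tc$pain_cap_s)
}

#' Amount the chosen benefactor receives
#'
#' The benefactor receives the participant's allocation multiplied by the
#' reciprocal efficiency (1 or 3).
#'
#' @param allocation Yuan allocated, in [0, 25].
#' @param efficiency Reciprocal efficiency multiplier, 1 or 3.
#' @return Yuan received by the benefactor.
#' @export
#' @examples
#' benefactor_receipt(1, 3)  # 3
benefactor_receipt <- function(allocation, efficiency) {
  tc <- task_constants()
  if (any(!is.finite(allocation)) || any(allocation < 0 | allocation > tc$endowment))
    stop("allocation must lie in [0, ", tc$endowment, "]")
  if (!all(efficiency %in% c(1, 3)))
    stop("efficiency must be 1 or 3")
  efficiency * allocation
}

#' Relative Self-payoff of an allocation
#'
#' The self-interest index: the amount kept divided by the total value created,
#' (endowment - a) / ((endowment - a) + efficiency * a). Equals 1 when nothing
#' is given and 0 when everything is given.
#'
#' @param allocation Yuan allocated, 0 <= allocation <= endowment.
#' @param efficiency Reciprocal efficiency multiplier.
#' @param endowment Endowment in yuan (default 25).
#' @return Ratio in [0, 1].
#' @export
#' @examples
#' relative_self_payoff(10, 3)  # 15/45
relative_self_payoff <- function(allocation, efficiency, endowment = 25) {
  if (any(endowment <= 0)) stop("endowment must be positive")
  if (any(!is.finite(allocation)) || any(allocation < 0) || any(allocation > endowment))
    stop("allocation must lie in [0, endowment]")
  kept <- endowment - allocation
  kept / (kept + efficiency * allocation)
}

#' Read a trial table from delimited text
#'
#' Expects a comma-separated file with header
#' `participant_id,run,condition,cost,choice,allocation`. Unknown condition
#' labels or cost levels are rejected; choices must be "altruistic",
#' "strategic" or empty/NA (missing responses).
#'
#' @param path File path.
#' @return data.frame of trials.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "run", "condition", "cost", "choice", "allocation")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trial table missing columns: ", paste(miss, collapse = ", "))
  tc <- task_constants()
  bad_cond <- setdiff(unique(df$condition), tc$conditions$label)
  if (length(bad_cond)) stop("unknown condition labels: ", paste(bad_cond, collapse = ", "))
  bad_cost <- setdiff(unique(df$cost), tc$costs)
  if (length(bad_cost)) stop("unknown cost levels: ", paste(bad_cost, collapse = ", "))
  df$choice[df$choice %in% c("", "NA", "missing")] <- NA_character_
  bad_choice <- setdiff(unique(df$choice[!is.na(df$choice)]), c("altruistic", "strategic"))
  if (length(bad_choice)) stop("unknown choice values: ", paste(bad_choice, collapse = ", "))
  if (any(!is.na(df$allocation) & is.na(df$choice)))
    stop("allocation present on trials with missing choice")
  df
}

#' Write a trial table as delimited text
#' @param trials data.frame of trials.
#' @param path File path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
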