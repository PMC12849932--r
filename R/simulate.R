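## Synthetic-data generator. The study it emulates is empirical, so the
## generative models here are the package's own stand-ins: a logistic choice
## agent whose condition-wise motive weights are planted and later recovered
## by the behavioral stage, and a voxel-level map generator whose motive-map
## loadings and parcel representational geometries are planted and recovered
## by the expression and RSA stages.

#' Parameters of the synthetic behavioral agent
#'
#' The agent trades off two motives when choosing which benefactor to repay:
#' communal concern (gratitude/guilt toward a perceived altruist) and
#' obligation (pressure to meet a strategic benefactor's expectation).
#' Condition-wise weights `w_communal` / `w_obligation` are the generative
#' counterparts of the per-condition choice-regression coefficients; their
#' defaults plant a strictly increasing relative weight of Communal Concern
#' across (A1S3, A1S1, A3S1), the pattern the analysis stage must recover.
#'
#' @param w_communal Named non-negative weights per condition.
#' @param w_obligation Named non-negative weights per condition.
#' @param choice_noise_sd SD of trial-level logit noise (> 0).
#' @param allocation_generosity Mean proportion of the 25-yuan endowment given.
#' @param rating_effect_care Altruistic-minus-strategic gap in perceived care
#'   at the reference (mean) cost, on the 0-100 scale.
#' @param rating_effect_belief Strategic-minus-altruistic gap in second-order
#'   belief and sense of obligation at the reference cost.
#' @param rating_effect_emotions Altruistic-minus-strategic gap in gratitude
#'   and guilt at the reference cost.
#' @param rating_cost_slope Growth of each gap per yuan of benefactor cost.
#' @param rating_noise_sd SD of cell-level rating noise (> 0 in data, may be
#'   set to 0 for noiseless checks).
#' @return List of class `agent_params`.
#' @export
agent_params <- function(w_communal = c(A1S3 = 0.5, A1S1 = 1.5, A3S1 = 3.0),
                         w_obligation = c(A1S3 = 3.0, A1S1 = 1.5, A3S1 = 0.5),
                         choice_noise_sd = 0.5,
                         allocation_generosity = 0.5,
                         rating_effect_care = 20,
                         rating_effect_belief = 20,
                         rating_effect_emotions = 15,
                         rating_cost_slope = 0.5,
                         rating_noise_sd = 8) {
  lv <- condition_levels()
  stopifnot(all(lv %in% names(w_communal)), all(lv %in% names(w_obligation)))
  if (any(w_communal < 0) || any(w_obligation < 0)) stop("motive weights must be non-negative")
  if (choice_noise_sd < 0 || rating_noise_sd < 0) stop("noise sds must be non-negative")
  if (allocation_generosity < 0 || allocation_generosity > 1)
    stop("allocation_generosity must lie in [0, 1]")
  structure(list(
    w_communal = w_communal[lv], w_obligation = w_obligation[lv],
    choice_noise_sd = choice_noise_sd,
    allocation_generosity = allocation_generosity,
    rating_effect_care = rating_effect_care,
    rating_effect_belief = rating_effect_belief,
    rating_effect_emotions = rating_effect_emotions,
    rating_cost_slope = rating_cost_slope,
    rating_noise_sd = rating_noise_sd
  ), class = "agent_params")
}

## Baseline rating means (0-100 scale) at the reference cost; chosen to keep
## noiseless means well inside the scale so clamping never distorts gaps.
.rating_base <- c(care = 55, second_order_belief = 45, gratitude = 60,
                  guilt = 40, obligation = 50)
.rating_main_cost_slope <- 1.0  # all ratings drift up with benefactor cost
.participant_shift_sd <- 5     # stable rater-level response bias

#' Simulate post-task subjective rating profiles
#'
#' For each participant x benefactor type x cost cell, generates the six
#' ratings (perceived care, second-order belief, gratitude, guilt, obligation,
#' indebtedness) on the 0-100 scale. Perceived care, gratitude and guilt run
#' higher for the altruistic benefactor; second-order belief and obligation
#' run higher for the strategic benefactor; every gap widens linearly with the
#' benefactor's cost. Indebtedness is a noisy blend of guilt and obligation
#' and is excluded from factor scoring downstream.
#'
#' @param agent [agent_params()] object.
#' @param participant_ids Vector of participant identifiers.
#' @param costs Cost levels rated (default the task's nine levels).
#' @param seed Integer seed.
#' @return data.frame with one row per participant x type x cost.
#' @export
simulate_ratings <- function(agent, participant_ids, costs = task_constants()$costs,
                             seed = 1L) {
  stopifnot(inherits(agent, "agent_params"))
  if (length(costs) < 2) stop("need at least two cost levels")
  local_rng(seed)
  ref <- mean(costs)
  grid <- expand.grid(participant_id = participant_ids,
                      benefactor_type = c("altruistic", "strategic"),
                      cost = costs, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(match(grid$participant_id, participant_ids),
                     grid$benefactor_type, grid$cost), , drop = FALSE]
  rownames(grid) <- NULL
  n <- nrow(grid)
  sgn <- ifelse(grid$benefactor_type == "altruistic", 1, -1)  # + favors altruistic
  gap <- function(effect) (effect + agent$rating_cost_slope * (grid$cost - ref)) / 2
  drift <- .rating_main_cost_slope * (grid$cost - ref)

  # per-participant response bias, shared across types and costs per variable
  shift <- matrix(stats::rnorm(length(participant_ids) * 5, 0, .participant_shift_sd),
                  nrow = length(participant_ids),
                  dimnames = list(NULL, names(.rating_base)))
  pidx <- match(grid$participant_id, participant_ids)

  noisy <- function(mu) {
    x <- mu + stats::rnorm(n, 0, agent$rating_noise_sd)
    pmin(pmax(x, 0), 100)
  }
  care <- noisy(.rating_base["care"] + drift + sgn * gap(agent$rating_effect_care) +
                  shift[pidx, "care"])
  belief <- noisy(.rating_base["second_order_belief"] + drift -
                    sgn * gap(agent$rating_effect_belief) +
                    shift[pidx, "second_order_belief"])
  gratitude <- noisy(.rating_base["gratitude"] + drift +
                       sgn * gap(agent$rating_effect_emotions) +
                       shift[pidx, "gratitude"])
  guilt <- noisy(.rating_base["guilt"] + drift + sgn * gap(agent$rating_effect_emotions) +
                   shift[pidx, "guilt"])
  obligation <- noisy(.rating_base["obligation"] + drift -
                        sgn * gap(agent$rating_effect_belief) +
                        shift[pidx, "obligation"])
  indebtedness <- noisy(0.5 * (guilt + obligation))

  data.frame(grid, care = care, second_order_belief = belief,
             gratitude = gratitude, guilt = guilt, obligation = obligation,
             indebtedness = indebtedness, stringsAsFactors = FALSE)
}

#' Simulate reciprocal partner choices and allocations
#'
#' Fills a trial skeleton for every participant present in `factors`. The
#' choice follows a logistic model on the altruistic-minus-strategic contrast
#' of the two factor scores at the trial's cost level:
#' `P(altruistic) = plogis(w_c[cond] * dPC_communal - w_o[cond] * dPC_obligation + e)`,
#' with trial noise `e ~ N(0, choice_noise_sd)`. The allocation is
#' `round(allocation_generosity * 25)` plus bounded integer noise, clipped to
#' the 0-25 endowment.
#'
#' @param agent [agent_params()] object.
#' @param design Single-participant trial skeleton from [build_design()].
#' @param factors data.frame with columns `participant_id`, `benefactor_type`,
#'   `cost`, `pc_communal`, `pc_obligation` (both types at every cost).
#' @param seed Integer seed.
#' @return data.frame of filled trials (one block per participant).
#' @export
simulate_choices <- function(agent, design, factors, seed = 1L) {
  stopifnot(inherits(agent, "agent_params"))
  need <- c("participant_id", "benefactor_type", "cost", "pc_communal", "pc_obligation")
  miss <- setdiff(need, names(factors))
  if (length(miss)) stop("factors missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(factors)) stop("factors table is empty")
  local_rng(seed)
  pids <- unique(factors$participant_id)
  tc <- task_constants()
  out <- vector("list", length(pids))
  for (k in seq_along(pids)) {
    pid <- pids[k]
    f <- factors[factors$participant_id == pid, , drop = FALSE]
    alt <- f[f$benefactor_type == "altruistic", ]
    str <- f[f$benefactor_type == "strategic", ]
    ia <- match(design$cost, alt$cost); is_ <- match(design$cost, str$cost)
    if (anyNA(ia) || anyNA(is_))
      stop("factors must cover both benefactor types at every cost (participant ",
           pid, ")")
    dpc_c <- alt$pc_communal[ia] - str$pc_communal[is_]
    dpc_o <- alt$pc_obligation[ia] - str$pc_obligation[is_]
    wc <- agent$w_communal[design$condition]
    wo <- agent$w_obligation[design$condition]
    eta <- wc * dpc_c - wo * dpc_o +
      stats::rnorm(nrow(design), 0, agent$choice_noise_sd)
    choice <- ifelse(stats::runif(nrow(design)) < stats::plogis(eta),
                     "altruistic", "strategic")
    alloc <- round(agent$allocation_generosity * tc$endowment) +
      sample(-3:3, nrow(design), replace = TRUE)
    alloc <- pmin(pmax(alloc, 0L), tc$endowment)
    out[[k]] <- data.frame(participant_id = pid, design[c("run", "trial_in_run",
                                                          "condition", "cost")],
                           choice = choice, allocation = as.integer(alloc),
                           dpc_communal = dpc_c, dpc_obligation = dpc_o,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Specification of the synthetic neural generator
#'
#' Describes the voxel layout (a block parcellation: parcel p owns a contiguous
#' run of voxels), the two orthonormal motive pattern maps with their planted
#' condition-wise loadings `a` (communal) and `b` (obligation), and the parcels
#' carrying planted representational geometry for each cognitive model.
#'
#' @param n_parcels Number of parcels (default 200, the parcellation used for
#'   parcel-wise RSA).
#' @param voxels_per_parcel Voxels owned by each parcel.
#' @param signal_parcels Named list mapping cognitive-model names (subset of
#'   "general", "altruistic", "strategic", "linear") to disjoint parcel index
#'   sets.
#' @param signal_amplitude Norm of each planted parcel pattern component.
#' @param neural_noise_sd SD of iid voxel noise.
#' @param a_by_condition Planted communal-map loadings per condition.
#' @param b_by_condition Planted obligation-map loadings per condition.
#' @return List of class `neural_gen_spec`.
#' @export
neural_gen_spec <- function(n_parcels = 200L, voxels_per_parcel = 50L,
                            signal_parcels = list(general = 1:5, altruistic = 6:10,
                                                  strategic = 11:15, linear = 16:20),
                            signal_amplitude = 1,
                            neural_noise_sd = 1,
                            a_by_condition = c(A1S3 = 1, A1S1 = 2, A3S1 = 3),
                            b_by_condition = c(A1S3 = 3, A1S1 = 2, A3S1 = 1)) {
  stopifnot(n_parcels >= 1, voxels_per_parcel >= 3)
  bad <- setdiff(names(signal_parcels), names(cognitive_models()))
  if (length(bad)) stop("unknown cognitive model(s): ", paste(bad, collapse = ", "))
  all_sig <- unlist(signal_parcels, use.names = FALSE)
  if (anyDuplicated(all_sig)) stop("signal_parcels sets must be disjoint")
  if (length(all_sig) && (max(all_sig) > n_parcels || min(all_sig) < 1))
    stop("signal parcel indices out of range")
  lv <- condition_levels()
  stopifnot(all(lv %in% names(a_by_condition)), all(lv %in% names(b_by_condition)))
  structure(list(
    n_parcels = as.integer(n_parcels),
    voxels_per_parcel = as.integer(voxels_per_parcel),
    n_voxels = as.integer(n_parcels) * as.integer(voxels_per_parcel),
    signal_parcels = signal_parcels,
    signal_amplitude = signal_amplitude,
    neural_noise_sd = neural_noise_sd,
    a_by_condition = a_by_condition[lv],
    b_by_condition = b_by_condition[lv]
  ), class = "neural_gen_spec")
}

## Orthonormalize columns of M against columns of B, then against each other.
#' @noRd
orthonormalize_against <- function(M, B = NULL) {
  Q <- if (is.null(B)) NULL else qr.Q(qr(B))
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    if (!is.null(Q)) v <- v - Q %*% crossprod(Q, v)
    if (j > 1) {
      prev <- M[, seq_len(j - 1), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) stop("degenerate basis during orthonormalization")
    M[, j] <- v / nv
  }
  M
}

#' Simulate condition-wise neural contrast maps with planted structure
#'
#' Every participant-condition voxel vector is the sum of (i) the condition's
#' planted loadings on two orthonormal motive maps,
#' `a[cond] * communal + b[cond] * obligation`; (ii) for each signal parcel, a
#' planted pattern that rotates with the parcel's assigned cognitive-model
#' code, so that at zero noise the parcel's correlation-distance RDM is an
#' exact monotone transform of that model's cognitive RDM; and (iii) iid
#' Gaussian voxel noise. Parcel basis vectors are constructed orthogonal to
#' the constant vector and to both motive maps, so the planted `(a, b)` are
#' exactly identifiable by dot products at zero noise.
#'
#' @param spec [neural_gen_spec()] object.
#' @param n_participants Number of participants.
#' @param seed Integer seed.
#' @return List with `maps` (per participant, a 27 x n_voxels matrix in
#'   [condition_grid()] row order), `parcellation` (integer vector, parcel id
#'   per voxel), `communal_map`, `obligation_map` (unit-norm orthogonal voxel
#'   vectors), `grid`, and `spec`.
#' @export
simulate_condition_maps <- function(spec, n_participants, seed = 1L) {
  stopifnot(inherits(spec, "neural_gen_spec"), n_participants >= 1)
  local_rng(seed)
  V <- spec$n_voxels
  grid <- condition_grid()
  parcellation <- rep(seq_len(spec$n_parcels), each = spec$voxels_per_parcel)

  motive <- orthonormalize_against(matrix(stats::rnorm(V * 2), ncol = 2))
  communal_map <- motive[, 1]; obligation_map <- motive[, 2]

  # Deterministic signal template shared by all participants (27 x V)
  template <- tcrossprod(spec$a_by_condition[grid$condition], communal_map) +
    tcrossprod(spec$b_by_condition[grid$condition], obligation_map)
  models <- cognitive_models()
  for (m in names(spec$signal_parcels)) {
    codes <- models[[m]][grid$condition]
    span <- max(codes) - min(codes)
    phi <- (codes - min(codes)) / span * (pi / 2)
    for (p in spec$signal_parcels[[m]]) {
      vox <- which(parcellation == p)
      B <- cbind(1, communal_map[vox], obligation_map[vox])
      E <- orthonormalize_against(matrix(stats::rnorm(length(vox) * 2), ncol = 2), B)
      patt <- spec$signal_amplitude * (cos(phi) %o% E[, 1] + sin(phi) %o% E[, 2])
      template[, vox] <- template[, vox] + patt
    }
  }

  maps <- vector("list", n_participants)
  names(maps) <- sprintf("sub%03d", seq_len(n_participants))
  for (i in seq_len(n_participants)) {
    noise <- matrix(stats::rnorm(27L * V, 0, spec$neural_noise_sd), nrow = 27L)
    maps[[i]] <- template + noise
  }
  list(maps = maps, parcellation = parcellation, communal_map = communal_map,
       obligation_map = obligation_map, grid = grid, spec = spec)
}
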