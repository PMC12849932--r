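## Cross-study pattern-expression stage: dot-product expression of condition
## maps on the communal and obligation weight maps, min-max normalization,
## the neural relative weight of Communal Concern, and its within-participant
## permutation test.

#' Pattern expression of a contrast map on a weight map
#'
#' The dot product of a condition contrast map with a whole-brain multivariate
#' weight map, scoring how strongly the map's signature is expressed.
#' Non-finite voxels are excluded pairwise but must stay below 5% of the grid.
#'
#' @param condition_map Numeric voxel vector.
#' @param pattern_map Numeric voxel vector on the identical grid.
#' @return Scalar expression value.
#' @export
pattern_expression <- function(condition_map, pattern_map) {
  if (length(condition_map) != length(pattern_map))
    stop("grid mismatch: condition map has ", length(condition_map),
         " voxels, pattern map has ", length(pattern_map))
  ok <- is.finite(condition_map) & is.finite(pattern_map)
  if (mean(!ok) >= 0.05)
    stop("excessive non-finite voxels: ", sum(!ok), " of ", length(ok))
  sum(condition_map[ok] * pattern_map[ok])
}

#' Expression table of condition maps on both motive maps
#'
#' Scores every participant's three condition-level maps (cost levels averaged
#' within efficiency condition, matching the per-condition contrast maps the
#' expression analysis consumes) against the communal and obligation weight
#' maps.
#'
#' @param maps List of per-participant 27 x V matrices ([condition_grid()]
#'   row order), or 3 x V matrices already at condition level.
#' @param communal_map,obligation_map Weight maps (voxel vectors).
#' @param grid Condition grid (default [condition_grid()]), used when maps
#'   have 27 rows.
#' @return data.frame: `participant_id`, `condition`, `map_name`, `raw_value`.
#' @export
expression_table <- function(maps, communal_map, obligation_map,
                             grid = condition_grid()) {
  lv <- condition_levels()
  rows <- list()
  for (pid in names(maps)) {
    M <- maps[[pid]]
    cond_mat <- if (nrow(M) == length(lv)) {
      rownames(M) <- lv
      M
    } else {
      t(vapply(lv, function(cc) colMeans(M[grid$condition == cc, , drop = FALSE]),
               numeric(ncol(M))))
    }
    for (cc in lv) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, condition = cc,
        map_name = c("communal", "obligation"),
        raw_value = c(pattern_expression(cond_mat[cc, ], communal_map),
                      pattern_expression(cond_mat[cc, ], obligation_map)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Min-max normalize expression values
#'
#' Rescales `raw_value` to [0, 1] within each normalization group. The default
#' scope normalizes each map's values jointly across all participants and
#' conditions (preserving between-participant ordering); `"participant"` scope
#' normalizes within each participant x map instead.
#'
#' @param table Expression table from [expression_table()].
#' @param scope "global" (per map, default) or "participant" (per
#'   participant x map).
#' @return The table with a `norm_value` column; the scope used is recorded in
#'   the `"norm_scope"` attribute.
#' @export
minmax_normalize <- function(table, scope = c("global", "participant")) {
  scope <- match.arg(scope)
  grp <- if (scope == "global") table$map_name else
    paste(table$participant_id, table$map_name)
  norm <- ave(table$raw_value, grp, FUN = function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(NA_real_, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  })
  if (anyNA(norm)) {
    bad <- unique(grp[is.na(norm)])
    stop("degenerate normalization group (constant values): ",
         paste(bad, collapse = ", "))
  }
  table$norm_value <- norm
  attr(table, "norm_scope") <- scope
  table
}

#' Neural relative weight of Communal Concern
#'
#' For each (participant, condition), the ratio
#' `|NV_communal| / (|NV_communal| + |NV_obligation|)` of the (normalized)
#' expression values; `NA` when both are exactly zero.
#'
#' @param table Expression table with a `norm_value` column (or `raw_value`
#'   when `use` = "raw_value").
#' @param use Column to use, default "norm_value".
#' @return data.frame: `participant_id`, `condition`,
#'   `neural_relative_weight`.
#' @export
neural_relative_weight <- function(table, use = c("norm_value", "raw_value")) {
  use <- match.arg(use)
  if (!use %in% names(table)) stop("column not present: ", use)
  com <- table[table$map_name == "communal", ]
  obl <- table[table$map_name == "obligation", ]
  key <- function(d) paste(d$participant_id, d$condition)
  i <- match(key(com), key(obl))
  if (anyNA(i)) stop("obligation expression missing for some (participant, condition)")
  data.frame(participant_id = com$participant_id, condition = com$condition,
             neural_relative_weight = relative_weight(com[[use]], obl[[use]][i]),
             stringsAsFactors = FALSE)
}

#' @noRd
.trend_beta <- function(values) mean(values[, 3] - values[, 1]) / 2

#' @noRd
.rm_f <- function(values) {
  n <- nrow(values); k <- ncol(values)
  grand <- mean(values)
  col_m <- colMeans(values); row_m <- rowMeans(values)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_err <- sum(sweep(values, 1, row_m)^2) - ss_cond
  if (ss_err == 0) return(if (ss_cond == 0) 0 else Inf)
  (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
}

#' Within-participant permutation test for the condition effect
#'
#' Permutes the three condition labels independently within each participant
#' and recomputes the repeated-measures ANOVA F and the linear-contrast
#' coefficient on each iteration, building empirical null distributions. The
#' empirical p is the proportion of permuted statistics greater than or equal
#' to the observed value (one-tailed exceedance; ties count, so p is never an
#' unattainable 0 when the observed value recurs under the null). When
#' `exhaustive = TRUE` (automatic for 6 or fewer participants) all
#' `6^n` within-participant label assignments are enumerated instead of
#' sampled.
#'
#' @param values Complete participant x 3 condition table, columns in
#'   (A1S3, A1S1, A3S1) order.
#' @param n_perm Number of permutation iterations (the analysis used 10000).
#' @param seed Integer seed.
#' @param exhaustive Force or forbid full enumeration; default `NULL`
#'   enumerates when `nrow(values) <= 6`.
#' @return List: `p_f`, `p_beta`, `observed_f`, `observed_beta`, `null_f`,
#'   `null_beta`, `n_perm`, `exhaustive`.
#' @export
permutation_test <- function(values, n_perm = 10000L, seed = 1L, exhaustive = NULL) {
  values <- assert_complete_table(values)
  if (ncol(values) != 3) stop("permutation test requires 3 condition columns")
  if (n_perm < 1) stop("n_perm must be >= 1")
  n <- nrow(values)
  exhaustive <- exhaustive %||% (n <= 6)
  obs_f <- .rm_f(values)
  obs_b <- .trend_beta(values)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  stat_for <- function(idx) {
    # idx: length-n vector of permutation indices (1..6), one per participant
    perm_values <- matrix(values[cbind(rep(seq_len(n), 3),
                                       as.vector(perms[idx, ]))], nrow = n)
    c(.rm_f(perm_values), .trend_beta(perm_values))
  }
  if (exhaustive) {
    total <- 6^n
    if (total > 6^8) stop("exhaustive enumeration infeasible for n = ", n)
    grid <- as.matrix(expand.grid(rep(list(1:6), n)))
    stats <- t(apply(grid, 1, stat_for))
    n_used <- total
  } else {
    local_rng(seed)
    stats <- matrix(NA_real_, n_perm, 2)
    for (it in seq_len(n_perm)) {
      stats[it, ] <- stat_for(sample.int(6L, n, replace = TRUE))
    }
    n_used <- n_perm
  }
  # exceedance counts ties; the tolerance keeps permutations that are
  # equivalent up to float rounding (e.g. a common relabeling) counted as ties
  tol_f <- 1e-8 * (1 + abs(obs_f)); tol_b <- 1e-8 * (1 + abs(obs_b))
  list(p_f = mean(stats[, 1] >= obs_f - tol_f),
       p_beta = mean(stats[, 2] >= obs_b - tol_b),
       observed_f = obs_f, observed_beta = obs_b,
       null_f = stats[, 1], null_beta = stats[, 2],
       n_perm = n_used, exhaustive = exhaustive)
}
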