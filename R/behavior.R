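## Behavioral stage: two-factor scoring of the six subjective ratings,
## per-condition mixed-effects choice regressions yielding the relative weight
## of Communal Concern, Relative Self-payoff comparisons, and the
## repeated-measures test battery (GG-corrected ANOVA, linear trend, paired
## comparisons, Mann-Whitney).

#' @noRd
stat_result <- function(effect_name, estimate = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        statistic = NA_real_, stat_name = NA_character_,
                        df1 = NA_real_, df2 = NA_real_, epsilon = NA_real_,
                        p = NA_real_, effect_size = NA_real_, note = NA_character_) {
  data.frame(effect_name = effect_name, estimate = estimate, se = se,
             ci_low = ci_low, ci_high = ci_high, statistic = statistic,
             stat_name = stat_name, df1 = df1, df2 = df2, epsilon = epsilon,
             p = p, effect_size = effect_size, note = note,
             stringsAsFactors = FALSE)
}

.communal_vars <- c("care", "gratitude", "guilt")
.obligation_vars <- c("second_order_belief", "obligation")

#' Two-factor scoring of subjective ratings
#'
#' Fits the fixed-structure two-factor model of the rating battery: a communal
#' factor loading on perceived care, gratitude and guilt, and an obligation
#' factor loading on second-order belief and sense of obligation, with all
#' cross-loadings fixed at zero (indebtedness is excluded from factoring).
#' Each factor is estimated as the first principal axis of its block's
#' correlation matrix, which makes the scores invariant to affine rescaling of
#' any input variable. Factor scores are standardized (unit variance).
#'
#' @param ratings data.frame as produced by [simulate_ratings()] or read from
#'   a rating table: one row per participant x benefactor type x cost with the
#'   five factored variables present.
#' @return List with `scores` (the input keys plus `pc_communal`,
#'   `pc_obligation`), `loadings` (5 x 2 matrix, variable-score correlations),
#'   and `variance_explained` (proportion of the five variables' total
#'   standardized variance captured by the two factors).
#' @export
factor_scores <- function(ratings) {
  vars <- c(.communal_vars, .obligation_vars)
  miss <- setdiff(vars, names(ratings))
  if (length(miss)) stop("ratings missing variables: ", paste(miss, collapse = ", "))
  X <- as.matrix(ratings[vars])
  if (anyNA(X)) stop("ratings contain missing values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance rating variable: ",
         paste(vars[sds == 0], collapse = ", "))
  block_pc <- function(cols) {
    Z <- scale(X[, cols, drop = FALSE])
    R <- stats::cor(X[, cols, drop = FALSE])
    e <- eigen(R, symmetric = TRUE)
    v <- e$vectors[, 1]
    if (sum(v) < 0) v <- -v
    lambda <- e$values[1]
    list(scores = as.numeric(Z %*% v) / sqrt(lambda),
         loadings = v * sqrt(lambda), lambda = lambda)
  }
  com <- block_pc(.communal_vars)
  obl <- block_pc(.obligation_vars)
  loadings <- matrix(0, nrow = length(vars), ncol = 2,
                     dimnames = list(vars, c("communal", "obligation")))
  loadings[.communal_vars, "communal"] <- com$loadings
  loadings[.obligation_vars, "obligation"] <- obl$loadings
  keys <- intersect(c("participant_id", "benefactor_type", "cost"), names(ratings))
  scores <- cbind(ratings[keys], pc_communal = com$scores, pc_obligation = obl$scores)
  list(scores = scores, loadings = loadings,
       variance_explained = (com$lambda + obl$lambda) / length(vars))
}

#' Relative weight of Communal Concern from two betas
#'
#' `|beta_communal| / (|beta_communal| + |beta_obligation|)`; `NA` when both
#' betas are exactly zero (0/0 has no weight interpretation).
#'
#' @param beta_communal,beta_obligation Regression coefficients.
#' @return Ratio in [0, 1], or `NA`.
#' @export
#' @examples
#' relative_weight(0.3, 0.1)  # 0.75
relative_weight <- function(beta_communal, beta_obligation) {
  tot <- abs(beta_communal) + abs(beta_obligation)
  ifelse(tot == 0, NA_real_, abs(beta_communal) / tot)
}

#' @noRd
fit_condition_glmm <- function(df, link) {
  binom <- identical(link, "logistic")
  forms <- list(
    y ~ dpc_communal + dpc_obligation + (1 + dpc_communal + dpc_obligation | participant_id),
    y ~ dpc_communal + dpc_obligation + (1 + dpc_communal + dpc_obligation || participant_id),
    y ~ dpc_communal + dpc_obligation + (1 | participant_id)
  )
  for (k in seq_along(forms)) {
    fit <- tryCatch(suppressMessages(suppressWarnings(
      if (binom) {
        lme4::glmer(forms[[k]], data = df, family = stats::binomial(), nAGQ = 0L,
                    control = lme4::glmerControl(calc.derivs = FALSE))
      } else {
        lme4::lmer(forms[[k]], data = df,
                   control = lme4::lmerControl(calc.derivs = FALSE))
      }
    )), error = function(e) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5))
      return(list(fit = fit, structure = k))
    if (!is.null(fit) && k == length(forms))
      return(list(fit = fit, structure = k))
  }
  stop("mixed choice regression failed for all random-effect structures")
}

#' Per-condition choice regressions and the relative weight of Communal Concern
#'
#' For each efficiency condition, regresses the binary partner choice
#' (altruistic = 1) on the altruistic-minus-strategic contrasts of the two
#' factor scores, with by-participant random slopes for each fixed effect
#' (falling back to uncorrelated slopes, then random intercept only, when the
#' fit is singular; the realized structure is recorded). Per-participant betas
#' are the conditional modes: fixed effect plus that participant's random
#' slope. The relative weight of Communal Concern is
#' `|beta_communal| / (|beta_communal| + |beta_obligation|)`.
#'
#' @param trials Filled trial table including `dpc_communal`/`dpc_obligation`
#'   columns, or raw trials plus `factors` to derive them.
#' @param factors Optional `scores` data.frame from [factor_scores()] used to
#'   derive the per-cost contrasts when the trial table lacks them.
#' @param link "logistic" (default) or "linear" probability link.
#' @param method "mixed" (default; conditional modes from one model per
#'   condition) or "independent" (separate per-participant regressions, for
#'   sensitivity checks).
#' @return data.frame with one row per participant x condition:
#'   `beta_communal`, `beta_obligation`, `relative_weight`, `structure` (the
#'   random-effect structure used: 1 full, 2 uncorrelated, 3 intercept-only;
#'   NA for independent fits).
#' @export
relative_weights <- function(trials, factors = NULL,
                             link = c("logistic", "linear"),
                             method = c("mixed", "independent")) {
  link <- match.arg(link)
  method <- match.arg(method)
  if (!all(c("dpc_communal", "dpc_obligation") %in% names(trials))) {
    if (is.null(factors))
      stop("trials lack dpc_* columns; supply `factors` from factor_scores()")
    alt <- factors[factors$benefactor_type == "altruistic", ]
    str <- factors[factors$benefactor_type == "strategic", ]
    key <- function(d) paste(d$participant_id, d$cost)
    ia <- match(key(trials), key(alt)); is_ <- match(key(trials), key(str))
    if (anyNA(ia) || anyNA(is_))
      stop("factors must cover both benefactor types at every (participant, cost)")
    trials$dpc_communal <- alt$pc_communal[ia] - str$pc_communal[is_]
    trials$dpc_obligation <- alt$pc_obligation[ia] - str$pc_obligation[is_]
  }
  trials <- trials[!is.na(trials$choice), , drop = FALSE]
  pids <- unique(trials$participant_id)
  if (length(pids) < 2) stop("need at least 2 participants for mixed choice regressions")
  has_all <- tapply(trials$condition, trials$participant_id,
                    function(x) all(condition_levels() %in% x))
  if (!all(has_all)) stop("every participant needs trials in every condition")

  out <- list()
  for (cond in condition_levels()) {
    df <- trials[trials$condition == cond, , drop = FALSE]
    df$y <- as.integer(df$choice == "altruistic")
    df$participant_id <- factor(df$participant_id, levels = pids)
    if (method == "mixed") {
      fitted <- fit_condition_glmm(df, link)
      fe <- lme4::fixef(fitted$fit)
      re <- lme4::ranef(fitted$fit)$participant_id
      bc <- rep(unname(fe["dpc_communal"]), length(pids))
      bo <- rep(unname(fe["dpc_obligation"]), length(pids))
      ri <- match(pids, rownames(re))
      if ("dpc_communal" %in% colnames(re)) bc <- bc + re[ri, "dpc_communal"]
      if ("dpc_obligation" %in% colnames(re)) bo <- bo + re[ri, "dpc_obligation"]
      structure_used <- fitted$structure
    } else {
      bc <- bo <- numeric(length(pids))
      for (k in seq_along(pids)) {
        dk <- df[df$participant_id == pids[k], , drop = FALSE]
        fit <- if (link == "logistic") {
          suppressWarnings(stats::glm(y ~ dpc_communal + dpc_obligation,
                                      data = dk, family = stats::binomial()))
        } else {
          stats::lm(y ~ dpc_communal + dpc_obligation, data = dk)
        }
        co <- stats::coef(fit)
        bc[k] <- unname(co["dpc_communal"]); bo[k] <- unname(co["dpc_obligation"])
      }
      structure_used <- NA_integer_
    }
    out[[cond]] <- data.frame(participant_id = pids, condition = cond,
                              beta_communal = bc, beta_obligation = bo,
                              relative_weight = relative_weight(bc, bo),
                              structure = structure_used,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical univariate RM-ANOVA on a complete participant x condition table.
#' The Greenhouse-Geisser epsilon is computed from the double-centered sample
#' covariance of the condition columns and scales both degrees of freedom; the
#' reported p uses the corrected dfs. Partial eta squared is returned as the
#' effect size.
#'
#' @param values Numeric matrix or data.frame, rows = participants, columns =
#'   within-participant levels (complete, no missing cells).
#' @param levels Optional level labels (defaults to column names).
#' @return One-row [data.frame] (StatResult): `statistic` = F, `df1`/`df2` =
#'   GG-corrected dfs, `epsilon`, `p` (GG-corrected), `effect_size` = partial
#'   eta squared. The uncorrected p is in the `note` field.
#' @export
rm_anova_gg <- function(values, levels = colnames(values)) {
  values <- assert_complete_table(values)
  n <- nrow(values); k <- ncol(values)
  if (k < 2) stop("need at least 2 within-participant levels")
  if (n < 3) stop("need at least 3 participants")
  grand <- mean(values)
  col_m <- colMeans(values); row_m <- rowMeans(values)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_total_within <- sum(sweep(values, 1, row_m)^2)
  ss_err <- ss_total_within - ss_cond
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err == 0) {
    if (ms_cond == 0) 0 else Inf
  } else ms_cond / ms_err
  # GG epsilon from the double-centered covariance matrix
  S <- stats::cov(values)
  C <- diag(k) - matrix(1 / k, k, k)
  S_dc <- C %*% S %*% C
  tr <- sum(diag(S_dc)); tr2 <- sum(S_dc^2)
  eps <- if (tr2 == 0) 1 else tr^2 / ((k - 1) * tr2)
  eps <- min(max(eps, 1 / (k - 1)), 1)
  p_unc <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p_gg <- stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
  eta_p2 <- if (ss_cond + ss_err == 0) 0 else ss_cond / (ss_cond + ss_err)
  stat_result(effect_name = "rm_anova", statistic = f, stat_name = "F",
              df1 = eps * df1, df2 = eps * df2, epsilon = eps, p = p_gg,
              effect_size = eta_p2,
              note = sprintf("p_uncorrected=%.6g", p_unc))
}

#' Within-participant linear trend over three ordered conditions
#'
#' Applies the contrast (-1, 0, +1) over the ordered levels per participant
#' and tests the contrast scores against zero with a one-sample F
#' (equivalently t squared), df = (1, n - 1). The estimate reported is the
#' slope per condition step, i.e. half the mean contrast score (for levels
#' one step apart the contrast spans two steps).
#'
#' @param values Complete participant x 3 table, columns in the tested order
#'   (A1S3, A1S1, A3S1).
#' @return One-row StatResult. When all contrast scores are identical and
#'   nonzero the trend is exact: `statistic` is `Inf`, `p` is 0 and the note
#'   flags the zero-variance branch.
#' @export
linear_trend <- function(values) {
  values <- assert_complete_table(values)
  if (ncol(values) != 3) stop("linear trend requires exactly 3 ordered levels")
  n <- nrow(values)
  if (n < 2) stop("need at least 2 participants")
  s <- values[, 3] - values[, 1]
  m <- mean(s); v <- stats::var(s)
  if (v == 0) {
    if (m == 0)
      return(stat_result("linear_trend", estimate = 0, se = 0, statistic = 0,
                         stat_name = "F", df1 = 1, df2 = n - 1, p = 1))
    return(stat_result("linear_trend", estimate = m / 2, se = 0, statistic = Inf,
                       stat_name = "F", df1 = 1, df2 = n - 1, p = 0,
                       note = "exact trend: zero contrast variance"))
  }
  se_s <- sqrt(v / n)
  f <- (m / se_s)^2
  p <- stats::pf(f, 1, n - 1, lower.tail = FALSE)
  tcrit <- stats::qt(0.975, n - 1)
  stat_result("linear_trend", estimate = m / 2, se = se_s / 2,
              ci_low = (m - tcrit * se_s) / 2, ci_high = (m + tcrit * se_s) / 2,
              statistic = f, stat_name = "F", df1 = 1, df2 = n - 1, p = p)
}

#' Paired comparisons between all condition pairs
#'
#' Paired mean differences (later-ordered column minus earlier) with standard
#' error, 95% confidence interval and two-tailed paired-t p value, one row per
#' pair, uncorrected (a Holm adjustment is available via `adjust`).
#'
#' @param values Complete participant x condition table.
#' @param adjust "none" (default) or "holm".
#' @return data.frame of StatResults, one per pair.
#' @export
pairwise_comparisons <- function(values, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  values <- assert_complete_table(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 3) stop("need at least 3 participants")
  labs <- colnames(values) %||% paste0("L", seq_len(k))
  rows <- list()
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    d <- values[, j] - values[, i]
    m <- mean(d); se <- stats::sd(d) / sqrt(n)
    if (se == 0) {
      t <- if (m == 0) 0 else Inf
      p <- if (m == 0) 1 else 0
      ci <- c(m, m)
    } else {
      t <- m / se
      p <- 2 * stats::pt(-abs(t), n - 1)
      ci <- m + c(-1, 1) * stats::qt(0.975, n - 1) * se
    }
    rows[[length(rows) + 1L]] <-
      stat_result(paste0(labs[j], " - ", labs[i]), estimate = m, se = se,
                  ci_low = ci[1], ci_high = ci[2], statistic = t,
                  stat_name = "t", df1 = n - 1, p = p)
  }
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, "holm")
  out
}

#' Mann-Whitney U test between two independent samples
#'
#' Reports the U statistic of the first sample, the tie-corrected
#' normal-approximation Z, and a two-tailed p value: exact (no ties, moderate
#' n) via the null U distribution, otherwise the normal approximation. The
#' effect size is the rank-biserial correlation.
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact p; default `NULL`
#'   uses exact when there are no ties and both samples have at most 50
#'   observations.
#' @return One-row StatResult: `statistic` = U, `estimate` = Z,
#'   `effect_size` = rank-biserial.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain missing values")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  nn <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
  z <- if (sigma2 == 0) 0 else (u1 - mu) / sqrt(sigma2)
  has_ties <- tie_term > 0
  use_exact <- exact %||% (!has_ties && n1 <= 50 && n2 <= 50)
  if (use_exact && has_ties) stop("exact p unavailable with ties")
  p <- if (use_exact) {
    if (u1 > mu) {
      min(1, 2 * stats::pwilcox(u1 - 1, n1, n2, lower.tail = FALSE))
    } else {
      min(1, 2 * stats::pwilcox(u1, n1, n2))
    }
  } else {
    2 * stats::pnorm(-abs(z))
  }
  stat_result("mann_whitney", estimate = z, statistic = u1, stat_name = "U",
              p = p, effect_size = 2 * u1 / (n1 * n2) - 1,
              note = if (use_exact) "exact" else "normal approximation")
}

#' Compare Relative Self-payoff between two efficiency conditions
#'
#' Restricts to trials where `chosen_type` was the chosen benefactor, computes
#' each trial's Relative Self-payoff using that benefactor's efficiency in the
#' trial's condition, averages within participant x condition, and compares
#' the two participant-level samples with [mann_whitney()] (unpaired: a
#' participant enters only the conditions where they have qualifying trials).
#' Positive Z means the reference condition's Relative Self-payoff is larger,
#' i.e. self-payoff decreased as efficiency increased.
#'
#' @param trials Filled trial table (with `participant_id`, `condition`,
#'   `choice`, `allocation`).
#' @param chosen_type "altruistic" or "strategic".
#' @param cond_hi Condition where the chosen type has efficiency 3.
#' @param cond_ref Reference condition (efficiency 1).
#' @param endowment Endowment (default 25).
#' @return One-row StatResult from [mann_whitney()] with a descriptive
#'   `effect_name`; the participant-level samples are attached as the
#'   `"samples"` attribute.
#' @export
self_payoff_comparison <- function(trials, chosen_type = c("strategic", "altruistic"),
                                   cond_hi, cond_ref, endowment = 25) {
  chosen_type <- match.arg(chosen_type)
  sub <- trials[!is.na(trials$choice) & trials$choice == chosen_type &
                  trials$condition %in% c(cond_hi, cond_ref), , drop = FALSE]
  cnt <- table(factor(sub$condition, levels = c(cond_hi, cond_ref)))
  if (any(cnt == 0))
    stop("no qualifying trials (", chosen_type, " chosen): ",
         paste(names(cnt), cnt, sep = "=", collapse = ", "))
  eff <- efficiency_of(sub$condition, chosen_type)
  sub$rsp <- relative_self_payoff(sub$allocation, eff, endowment)
  agg <- stats::aggregate(rsp ~ participant_id + condition, data = sub, FUN = mean)
  x <- agg$rsp[agg$condition == cond_ref]
  y <- agg$rsp[agg$condition == cond_hi]
  res <- mann_whitney(x, y)
  res$effect_name <- paste0("relative_self_payoff ", chosen_type, ": ",
                            cond_ref, " vs ", cond_hi)
  attr(res, "samples") <- list(ref = x, hi = y)
  res
}
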