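## Representational similarity stage: the four hand-coded cognitive
## dissimilarity models, per-parcel neural RDMs from the 27 condition maps
## (correlation distance), mixed-effects regression of neural on cognitive
## dissimilarity with participant random intercepts, BH-FDR across parcels,
## and an ROI-restricted mode.

#' The four cognitive dissimilarity codings
#'
#' Condition codes defining the four cognitive models: `general` (both
#' high-efficiency conditions alike, the equal-efficiency condition apart),
#' `altruistic` (efficiency of the altruistic benefactor), `strategic`
#' (efficiency of the strategic benefactor), and `linear` (monotone increase
#' from A1S3 through A1S1 to A3S1). Only the similarity pattern the codes
#' induce matters, not their absolute values.
#'
#' @return Named list of named numeric code vectors over
#'   (A1S3, A1S1, A3S1).
#' @export
cognitive_models <- function() {
  list(
    general = c(A1S3 = 3, A1S1 = 1, A3S1 = 3),
    altruistic = c(A1S3 = 1, A1S1 = 1, A3S1 = 3),
    strategic = c(A1S3 = 3, A1S1 = 1, A3S1 = 1),
    linear = c(A1S3 = 1, A1S1 = 2, A3S1 = 3)
  )
}

#' Cognitive RDM from a condition coding
#'
#' Builds the 27 x 27 dissimilarity matrix of a cognitive model over the
#' canonical condition grid: cell (i, j) is the absolute difference of the two
#' cells' condition codes (cost levels inherit their condition's code, so
#' cells sharing a condition are 0-dissimilar). A binary same/different mode
#' is available; for the two-valued codings it is proportional to the default
#' and differs only for the linear model.
#'
#' @param model Model name (see [cognitive_models()]) or a named code vector.
#' @param grid Condition grid (default [condition_grid()]).
#' @param binary If `TRUE`, use 0/1 same/different codes instead of absolute
#'   code differences.
#' @return 27 x 27 matrix with attributes `kind` = "cognitive" and `name`.
#' @export
cognitive_rdm <- function(model, grid = condition_grid(), binary = FALSE) {
  codes <- if (is.character(model)) {
    mm <- cognitive_models()
    if (!model %in% names(mm)) stop("unknown cognitive model: ", model)
    mm[[model]]
  } else model
  if (!all(unique(grid$condition) %in% names(codes)))
    stop("model codes do not cover all conditions in the grid")
  cellcode <- codes[grid$condition]
  D <- abs(outer(cellcode, cellcode, "-"))
  if (binary) D <- (D > 0) * 1
  dimnames(D) <- NULL
  diag(D) <- 0
  structure(D, kind = "cognitive",
            name = if (is.character(model)) model else "custom")
}

#' Neural RDM of one parcel
#'
#' Pairwise correlation dissimilarity (1 - Pearson r) between the 27
#' conditions' voxel vectors restricted to one parcel.
#'
#' @param maps 27 x V matrix of one participant's condition maps in canonical
#'   grid order.
#' @param parcellation Integer parcel label per voxel.
#' @param parcel_id Parcel to extract.
#' @return 27 x 27 matrix with attributes `kind` = "neural" and `parcel_id`,
#'   or `NULL` (with a warning) when a condition's voxel vector has zero
#'   variance in the parcel.
#' @export
parcel_rdm <- function(maps, parcellation, parcel_id) {
  if (ncol(maps) != length(parcellation))
    stop("parcellation length (", length(parcellation),
         ") does not match voxel count (", ncol(maps), ")")
  vox <- which(parcellation == parcel_id)
  if (!length(vox)) stop("parcel not present in parcellation: ", parcel_id)
  if (length(vox) < 3) stop("parcel ", parcel_id, " has fewer than 3 voxels")
  X <- maps[, vox, drop = FALSE]
  if (any(apply(X, 1, stats::sd) == 0)) {
    warning("degenerate parcel ", parcel_id, ": zero-variance condition pattern; skipped")
    return(NULL)
  }
  D <- 1 - stats::cor(t(X))
  D[D < 0] <- 0   # clip tiny negative rounding on the diagonal's neighbors
  diag(D) <- 0
  structure(D, kind = "neural", parcel_id = parcel_id)
}

#' Lower-triangle vectorization of an RDM
#'
#' Flattens the 351 below-diagonal entries in the fixed canonical order
#' (pair (2,1), (3,1), ..., (27,1), (3,2), ...) shared by neural and
#' cognitive vectors.
#'
#' @param rdm Symmetric dissimilarity matrix with zero diagonal.
#' @return Numeric vector of length `n (n - 1) / 2`.
#' @export
vectorize_lower <- function(rdm) {
  rdm_attr <- attributes(rdm)
  m <- unclass(rdm)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("RDM must be a square matrix")
  if (max(abs(m - t(m))) > 1e-8) stop("RDM must be symmetric")
  m[lower.tri(m)]
}

#' Rebuild a symmetric RDM from its lower-triangle vector
#' @param v Vector from [vectorize_lower()].
#' @return Symmetric matrix with zero diagonal.
#' @export
rdm_from_vector <- function(v) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (n != round(n)) stop("vector length is not a triangular number")
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m + t(m)
}

#' Mixed-effects RDM regression for one parcel
#'
#' Regresses the participants' neural dissimilarity vectors on a cognitive
#' dissimilarity vector with a random intercept per participant, returning the
#' slope, its standard error, Z = slope/SE with a normal reference, the 95%
#' confidence interval, and the two-tailed p.
#'
#' Because every participant shares the same predictor vector (the design is
#' balanced), the REML solution has a closed form: the slope is the
#' within-participant (participant-centered) least-squares slope and its
#' variance involves only the residual variance. The default `engine = "auto"`
#' uses this closed form; `engine = "lmer"` fits the same model with
#' \pkg{lme4} (falling back to fixed participant effects if the fit is
#' singular), useful as a cross-check or for unbalanced data.
#'
#' @param neural_vectors Matrix (participants x pairs) or list of equal-length
#'   vectors.
#' @param model_vector Cognitive dissimilarity vector.
#' @param engine "auto" (closed form), "lmer", or "fixed" (pooled OLS with
#'   participant fixed effects).
#' @return One-row data.frame: `coefficient`, `se`, `z`, `ci_low`, `ci_high`,
#'   `p_raw`.
#' @export
mixed_rsa <- function(neural_vectors, model_vector,
                      engine = c("auto", "lmer", "fixed")) {
  engine <- match.arg(engine)
  Y <- if (is.list(neural_vectors)) do.call(rbind, neural_vectors) else
    as.matrix(neural_vectors)
  n <- nrow(Y); m <- ncol(Y)
  if (n < 3) stop("need at least 3 participants")
  if (m != length(model_vector))
    stop("neural vectors (", m, ") and model vector (", length(model_vector),
         ") differ in length")
  if (stats::sd(model_vector) == 0)
    stop("constant model vector: slope not identifiable")
  x <- model_vector
  if (engine == "auto") {
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    # slope is orthogonal to the participant-mean space, so the GLS estimate
    # reduces to the within-participant least-squares slope
    b <- sum(xc * colMeans(Y)) / sxx
    resid <- sweep(Y, 1, rowMeans(Y)) - outer(rep(1, n), xc * b)
    df_res <- n * m - n - 1
    sigma2 <- sum(resid^2) / df_res
    se <- sqrt(sigma2 / (n * sxx))
  } else if (engine == "lmer") {
    df <- data.frame(y = as.vector(t(Y)), x = rep(x, n),
                     pid = factor(rep(seq_len(n), each = m)))
    fit <- suppressMessages(lme4::lmer(y ~ x + (1 | pid), data = df))
    if (lme4::isSingular(fit, tol = 1e-5)) {
      message("singular random-intercept fit; falling back to participant fixed effects")
      return(mixed_rsa(Y, x, engine = "fixed"))
    }
    sm <- summary(fit)$coefficients
    b <- sm["x", "Estimate"]; se <- sm["x", "Std. Error"]
  } else {
    df <- data.frame(y = as.vector(t(Y)), x = rep(x, n),
                     pid = factor(rep(seq_len(n), each = m)))
    fit <- stats::lm(y ~ x + pid, data = df)
    sm <- summary(fit)$coefficients
    b <- sm["x", "Estimate"]; se <- sm["x", "Std. Error"]
  }
  z <- if (se == 0) {
    if (b == 0) 0 else sign(b) * Inf
  } else b / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(coefficient = b, se = se, z = z,
             ci_low = b - 1.959964 * se, ci_high = b + 1.959964 * se,
             p_raw = p)
}

#' Benjamini-Hochberg FDR correction of parcel results
#'
#' Adds BH step-up adjusted p values and a two-tailed significance flag at
#' level `alpha`.
#'
#' @param results data.frame with a `p_raw` column (one row per parcel/ROI).
#' @param alpha FDR level (default 0.05).
#' @return `results` with `p_fdr` and `significant` columns.
#' @export
fdr_correct <- function(results, alpha = 0.05) {
  if (any(results$p_raw < 0 | results$p_raw > 1, na.rm = TRUE))
    stop("p_raw values must lie in [0, 1]")
  results$p_fdr <- stats::p.adjust(results$p_raw, method = "BH")
  results$significant <- results$p_fdr < alpha
  results
}

#' Parcel-wise RSA across the whole parcellation
#'
#' For each parcel: computes every participant's correlation-distance RDM,
#' vectorizes the lower triangles, and regresses them on each cognitive
#' model's dissimilarity vector with participant random intercepts. FDR is
#' controlled per model across parcels (the models are fit separately).
#' Degenerate parcels (zero-variance condition patterns) are skipped and
#' listed in the `"skipped"` attribute.
#'
#' @param maps List of per-participant 27 x V matrices.
#' @param parcellation Integer parcel label per voxel.
#' @param models Character vector of model names (default all four).
#' @param alpha FDR level.
#' @param engine Engine passed to [mixed_rsa()].
#' @return data.frame: `parcel_id`, `model`, `coefficient`, `se`, `z`,
#'   `ci_low`, `ci_high`, `p_raw`, `p_fdr`, `significant`.
#' @export
rsa_parcelwise <- function(maps, parcellation, models = names(cognitive_models()),
                           alpha = 0.05, engine = "auto") {
  grid <- condition_grid()
  model_vecs <- lapply(models, function(m) vectorize_lower(cognitive_rdm(m, grid)))
  names(model_vecs) <- models
  parcels <- sort(unique(parcellation))
  skipped <- integer(0)
  rows <- list()
  for (p in parcels) {
    vecs <- vector("list", length(maps))
    ok <- TRUE
    for (i in seq_along(maps)) {
      rdm <- withCallingHandlers(
        parcel_rdm(maps[[i]], parcellation, p),
        warning = function(w) invokeRestart("muffleWarning"))
      if (is.null(rdm)) { ok <- FALSE; break }
      vecs[[i]] <- vectorize_lower(rdm)
    }
    if (!ok) { skipped <- c(skipped, p); next }
    Y <- do.call(rbind, vecs)
    for (m in models) {
      res <- mixed_rsa(Y, model_vecs[[m]], engine = engine)
      rows[[length(rows) + 1L]] <- cbind(parcel_id = p, model = m, res,
                                         stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  parts <- split(out, out$model)
  out <- do.call(rbind, lapply(parts, fdr_correct, alpha = alpha))
  out <- out[order(out$parcel_id, match(out$model, models)), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' ROI-restricted RSA
#'
#' Treats each named region of interest (e.g. the four striatal subregions:
#' putamen, caudate, pallidum, ventral striatum) as a single parcel:
#' correlation-distance RDM, lower-triangle vectorization, mixed-effects RDM
#' regression against one cognitive model, and FDR across the ROI set.
#'
#' @param maps List of per-participant 27 x V matrices.
#' @param roi_masks Named list of logical vectors (one per ROI, `TRUE` for
#'   member voxels) or integer voxel-index vectors.
#' @param model Cognitive model name.
#' @param alpha FDR level.
#' @param engine Engine passed to [mixed_rsa()].
#' @return data.frame with one row per ROI (`roi` column) plus the
#'   [fdr_correct()] columns.
#' @export
roi_rsa <- function(maps, roi_masks, model, alpha = 0.05, engine = "auto") {
  if (is.null(names(roi_masks)) || any(names(roi_masks) == ""))
    stop("roi_masks must be a named list")
  V <- ncol(maps[[1]])
  model_vec <- vectorize_lower(cognitive_rdm(model))
  rows <- list()
  for (nm in names(roi_masks)) {
    mask <- roi_masks[[nm]]
    vox <- if (is.logical(mask)) {
      if (length(mask) != V) stop("ROI ", nm, " mask length does not match grid")
      which(mask)
    } else as.integer(mask)
    if (length(vox) < 3) stop("ROI ", nm, " has fewer than 3 voxels")
    if (any(vox < 1 | vox > V)) stop("ROI ", nm, " indexes voxels outside the grid")
    lab <- integer(V); lab[vox] <- 1L
    vecs <- lapply(maps, function(M) vectorize_lower(parcel_rdm(M, lab, 1L)))
    res <- mixed_rsa(do.call(rbind, vecs), model_vec, engine = engine)
    rows[[length(rows) + 1L]] <- cbind(roi = nm, model = model, res,
                                       stringsAsFactors = FALSE)
  }
  out <- fdr_correct(do.call(rbind, rows), alpha = alpha)
  rownames(out) <- NULL
  out
}
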