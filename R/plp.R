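#' Configuration for projection to latent pathways
#'
#' @param max_components maximum number of selected modes (one latent
#'   component binds exactly one signed elementary mode).
#' @param min_variance_gain stop when the best remaining candidate adds less
#'   than this many percentage points of explained flux variance.
#' @param allow_signed permit negated twins of fully reversible modes as
#'   candidates (irreversible modes are non-negative by definition).
#' @param nipals_tol,nipals_max_iter inner-loop safety parameters; with the
#'   output loading fixed to an elementary mode the inner pass is closed
#'   form, so these only guard degenerate input.
#' @return object of class `plp_config`.
#' @export
plp_config <- function(max_components = 20, min_variance_gain = 0.5,
                       allow_signed = TRUE, nipals_tol = 1e-10,
                       nipals_max_iter = 100) {
  structure(list(max_components = max_components,
                 min_variance_gain = min_variance_gain,
                 allow_signed = allow_signed,
                 nipals_tol = nipals_tol,
                 nipals_max_iter = nipals_max_iter),
            class = "plp_config")
}

#' Explained variance of a flux reconstruction
#'
#' `100 * (1 - sum((R - R_hat)^2) / sum(R^2))`, evaluated on the data scale
#' used for fitting.
#'
#' @param R observed flux matrix.
#' @param R_hat reconstructed flux matrix of the same shape.
#' @return percentage of explained variance.
#' @export
explained_variance <- function(R, R_hat) {
  stopifnot(all(dim(R) == dim(R_hat)))
  denom <- sum(R^2)
  if (denom == 0) stop("explained_variance: zero denominator (all-zero R)")
  100 * (1 - sum((R - R_hat)^2) / denom)
}

#' Fit a projection-to-latent-pathways model
#'
#' A constrained partial-least-squares regression of flux data `R` on
#' envirome data `X` in which the output loadings are fixed a priori to
#' elementary flux modes: `X = T W' + E_X`, `R = Lambda E_sel' + E_R`,
#' `Lambda = T B + E_U`. Candidate modes are taken with unit Euclidean norm
#' over the measured fluxes; mode weights are affine functions of the scaled
#' envirome (the intercept plays the role that response centring plays in
#' ordinary PLS and absorbs the envirome-independent part of a weight).
#'
#' Selection is greedy, one latent pathway per step: a candidate mode is
#' scored by the flux variance explained jointly by the already-selected
#' modes plus the candidate, with all weights regressed on the envirome
#' (`R_hat = P_X R P_E`, both projections closed form), and the maximizer is
#' added. This makes the first selection exactly the mode of maximum
#' single-mode explained variance, keeps the cumulative explained variance
#' non-decreasing, and reaches 100% in the noise-free limit where `R` lies
#' in the span of the active modes with weights affine in `X`. Ties go to
#' the lowest mode index. Selection stops at `max_components`, or when the
#' best remaining gain falls below `min_variance_gain` percentage points.
#'
#' A fully reversible mode spans the same direction with either orientation;
#' its reported sign is the sign of its mean fitted weight (negative =
#' operating in reverse, rendered `-k`). Irreversible modes always report
#' sign +1; a negative fitted weight for one is a diagnostic, visible in
#' `Lambda_hat`.
#'
#' `X` is taken on the scale of the supplied dataset (autoscaled columns by
#' default); `R` is fitted in rate units so the mode constraint holds
#' exactly. Reported mode weights are rescaled to the canonical mode scaling
#' (smallest nonzero coefficient 1).
#'
#' @param dataset an `envirome_dataset` (or a list with scaled `X`, raw `R`).
#' @param ems an `elementary_mode_set`; rows of `ems$E` matching the columns
#'   of `R` are used (see `measured`).
#' @param measured reaction ids giving the rows of `E` that correspond to
#'   the columns of `R`; defaults to `colnames(dataset$R)`.
#' @param config a [plp_config()].
#' @return object of class `plp_model` with elements `selected` (data.frame
#'   mode, name, sign, gain, cumulative_variance), `W`, `P`, `T`, `b`, `b0`,
#'   `C`/`c0` (regression coefficients and intercepts of canonical-scale
#'   mode weights on the scaled envirome), `E_sel` (unit-norm signed
#'   loadings), `Lambda_hat` (fitted canonical-scale signed weights),
#'   `fitted`, `residual_X`, `residual_R`, `scaling`, `measured`, `ems`.
#' @export
plp_fit <- function(dataset, ems, measured = NULL, config = plp_config()) {
  X <- as.matrix(dataset$X)
  R <- as.matrix(dataset$R)
  if (nrow(X) < 2) stop("PLP needs at least 2 observations")
  if (all(R == 0)) stop("all-zero flux matrix R")
  if (ems$n_modes == 0) stop("empty elementary-mode set")
  measured <- measured %||% colnames(R) %||% rownames(ems$E)
  if (!all(measured %in% rownames(ems$E)))
    stop("measured flux ids missing from the mode matrix")
  Em <- ems$E[measured, , drop = FALSE]
  norms <- sqrt(colSums(Em^2))
  candidates <- which(norms > 0)
  Eu <- sweep(Em, 2, pmax(norms, 1e-300), "/")   # unit-norm columns
  tss <- sum(R^2)
  Xa <- cbind(`(Intercept)` = 1, X)
  XtXinv <- mat_pinv(crossprod(Xa))
  A_mat <- Xa %*% (XtXinv %*% crossprod(Xa, R))  # P_X R
  M <- crossprod(A_mat)                          # explained-SS kernel
  explained_ss <- function(sel) {
    Ek <- Eu[, sel, drop = FALSE]
    G <- mat_pinv(crossprod(Ek))
    sum(diag(G %*% crossprod(Ek, M %*% Ek)))
  }
  sel_idx <- integer(0)
  gains <- numeric(0); cumvar <- numeric(0)
  prev_ss <- 0
  while (length(sel_idx) < min(config$max_components, length(candidates))) {
    best <- NULL
    for (ci in candidates) {
      if (ci %in% sel_idx) next
      ss <- explained_ss(c(sel_idx, ci))
      if (is.null(best) || ss > best$ss + 1e-12 * tss) best <- list(ci = ci, ss = ss)
    }
    if (is.null(best)) break
    gain <- 100 * (best$ss - prev_ss) / tss
    if (length(sel_idx) > 0 && gain < config$min_variance_gain) break
    sel_idx <- c(sel_idx, best$ci)
    gains <- c(gains, gain)
    cumvar <- c(cumvar, 100 * best$ss / tss)
    prev_ss <- best$ss
  }
  if (length(sel_idx) == 0) stop("no component could be extracted")
  A <- length(sel_idx)
  # joint affine weight model for the selected modes (unit-norm scale)
  Ek <- Eu[, sel_idx, drop = FALSE]
  Gcoef <- XtXinv %*% crossprod(Xa, R %*% Ek %*% mat_pinv(crossprod(Ek)))
  Lambda_unit <- Xa %*% Gcoef                    # np x A
  fitted <- Lambda_unit %*% t(Ek)
  colnames(fitted) <- colnames(R)
  # signs: fully reversible modes report the orientation of their weight
  sel_sgn <- rep(1L, A)
  fr <- ems$fully_reversible[sel_idx]
  if (config$allow_signed) sel_sgn[fr & colMeans(Lambda_unit) < 0] <- -1L
  b0vec <- Gcoef[1, ]
  Gs <- Gcoef[-1, , drop = FALSE]                # nx x A slopes
  bvec <- sqrt(colSums(Gs^2))
  W <- sweep(Gs, 2, pmax(bvec, 1e-300), "/")
  Tm <- X %*% W
  P <- if (A > 0) t(mat_pinv(Tm) %*% X) else NULL
  rownames(W) <- colnames(X)
  Cfull <- matrix(0, ems$n_modes, ncol(X),
                  dimnames = list(colnames(ems$E), colnames(X)))
  c0full <- stats::setNames(numeric(ems$n_modes), colnames(ems$E))
  for (a in seq_len(A)) {
    Cfull[sel_idx[a], ] <- sel_sgn[a] * Gs[, a] / norms[sel_idx[a]]
    c0full[sel_idx[a]] <- sel_sgn[a] * b0vec[a] / norms[sel_idx[a]]
  }
  E_sel <- sweep(Eu[, sel_idx, drop = FALSE], 2, sel_sgn, "*")
  Lambda_hat <- sweep(Lambda_unit, 2, sel_sgn / norms[sel_idx], "*")
  colnames(Lambda_hat) <- colnames(ems$E)[sel_idx]
  mode_names <- colnames(ems$E) %||% as.character(seq_len(ems$n_modes))
  structure(list(
    selected = data.frame(mode = sel_idx, name = mode_names[sel_idx],
                          sign = sel_sgn, gain = gains,
                          cumulative_variance = cumvar),
    W = W, P = P, T = Tm, b = bvec, b0 = b0vec,
    C = Cfull, c0 = c0full, E_sel = E_sel,
    Lambda_hat = Lambda_hat, fitted = fitted,
    residual_X = X - Tm %*% t(P), residual_R = R - fitted,
    tss = tss,
    scaling = dataset$scaling %||% NULL,
    measured = measured,
    x_names = colnames(X),
    ems = ems, config = config),
    class = "plp_model")
}

#' @export
print.plp_model <- function(x, ...) {
  cat(sprintf("<plp_model> %d selected modes, cumulative explained variance %.1f%%\n",
              nrow(x$selected), utils::tail(x$selected$cumulative_variance, 1)))
  sg <- ifelse(x$selected$sign < 0, "-", "")
  cat("  ranking:", paste0(sg, x$selected$name, collapse = ", "), "\n")
  invisible(x)
}

#' Predict flux data from new envirome observations
#'
#' `R_hat = X_scaled C_sel' E_canon'`: the regression coefficients map the
#' scaled envirome to mode weights and the selected modes map weights to
#' rates. On the training data this reproduces the in-sample reconstruction
#' exactly.
#'
#' @param object a `plp_model`.
#' @param X_new raw envirome matrix with the training factor columns; when
#'   omitted the training reconstruction is returned.
#' @param scaled set `TRUE` if `X_new` is already on the fitted scale.
#' @param ... unused.
#' @return matrix of predicted rates (rate units).
#' @export
predict.plp_model <- function(object, X_new = NULL, scaled = FALSE, ...) {
  if (is.null(X_new)) return(object$fitted)
  X_new <- as.matrix(X_new)
  if (!identical(colnames(X_new), object$x_names))
    stop("X_new columns do not match the training envirome factors")
  if (!scaled) {
    if (is.null(object$scaling)) stop("model carries no scaling constants")
    X_new <- sweep(sweep(X_new, 2, object$scaling$center), 2,
                   object$scaling$scale, "/")
  }
  sel <- object$selected$mode
  Ecan <- sweep(object$ems$E[object$measured, sel, drop = FALSE], 2,
                object$selected$sign, "*")
  Lam <- sweep(X_new %*% t(object$C[sel, , drop = FALSE]), 2,
               object$c0[sel], "+")
  out <- Lam %*% t(Ecan)
  colnames(out) <- object$measured
  out
}

#' Functional enviromics map
#'
#' Arranges the PLP regression coefficients as an nx x nem matrix: entry
#' (i, j) is the coefficient of envirome factor i in the linear model of
#' mode j's weight, read as the strength of up-/down-regulation of that core
#' cellular function by that factor. Columns of never-selected modes are
#' exactly zero. The variance-scaled copy weights each column by the mode's
#' incremental explained-variance share, emphasising functions that carry
#' flux variance.
#'
#' @param model a `plp_model`.
#' @return object of class `functional_enviromics_map`: `raw` (nx x nem),
#'   `variance_scaled`, `selected`.
#' @export
build_fem <- function(model) {
  raw <- t(model$C)                      # nx x nem
  vs <- raw
  share <- stats::setNames(rep(0, ncol(raw)), colnames(raw))
  share[model$selected$mode] <- model$selected$gain / 100
  vs <- sweep(raw, 2, share, "*")
  structure(list(raw = raw, variance_scaled = vs,
                 selected = model$selected),
            class = "functional_enviromics_map")
}

#' @export
print.functional_enviromics_map <- function(x, ...) {
  cat(sprintf("<functional_enviromics_map> %d envirome factors x %d modes (%d selected)\n",
              nrow(x$raw), ncol(x$raw), nrow(x$selected)))
  invisible(x)
}

#' Grow a PLP model until the reduced network is consistent
#'
#' Runs the greedy selection once, then for increasing prefix sizes reduces
#' the network to the reactions participating in the selected modes and runs
#' WLS-MFA with the chi-square consistency test on the phase's measured
#' rates. The first prefix whose reduced network is consistent stops the
#' reconstruction; if none is, the full model is returned flagged
#' inconsistent.
#'
#' @param dataset an `envirome_dataset`.
#' @param ems `elementary_mode_set` over the full network's reactions.
#' @param net the full `metabolic_network`.
#' @param measured_rates named vector of measured fluxes for the MFA step;
#'   defaults to the column means of `dataset$R`.
#' @param err an [error_model()].
#' @param alpha chi-square significance level.
#' @param config a [plp_config()].
#' @return list with `model` (truncated to the stopping size), `network`
#'   (reduced), `mfa` (the `mfa_result`), `n_modes`, `consistent`.
#' @export
plp_fit_consistent <- function(dataset, ems, net, measured_rates = NULL,
                               err = error_model(), alpha = 0.05,
                               config = plp_config()) {
  model <- plp_fit(dataset, ems, config = config)
  if (is.null(measured_rates))
    measured_rates <- colMeans(as.matrix(dataset$R))
  res <- NULL
  for (k in seq_len(nrow(model$selected))) {
    sel <- model$selected$mode[seq_len(k)]
    supp <- rownames(ems$E)[rowSums(abs(ems$E[, sel, drop = FALSE])) > 1e-9]
    red <- reduce_network(net, supp)
    meas <- measured_rates[names(measured_rates) %in% red$reactions$id]
    res <- tryCatch(mfa_wls(red, meas, err, alpha), error = function(e) NULL)
    if (!is.null(res) && isTRUE(res$consistent)) {
      trunc <- truncate_plp(model, k)
      return(list(model = trunc, network = red, mfa = res,
                  n_modes = k, consistent = TRUE))
    }
  }
  list(model = model, network = net, mfa = res %||% NULL,
       n_modes = nrow(model$selected), consistent = FALSE)
}

# Keep the first k greedily selected modes of a fitted model. The greedy
# selection order is nested, but the joint weight regression depends on the
# selected set, so the prefix model's coefficients are recomputed.
truncate_plp <- function(model, k) {
  if (k >= nrow(model$selected)) return(model)
  ds <- list(X = model$T %*% t(model$P) + model$residual_X,
             R = model$fitted + model$residual_R,
             scaling = model$scaling)
  colnames(ds$X) <- model$x_names
  cfg <- model$config
  cfg$max_components <- k
  cfg$min_variance_gain <- 0
  plp_fit(ds, model$ems, measured = model$measured, config = cfg)
}

#' Moving-window PLP over metabolic phases
#'
#' Fits an independent PLP model to every (culture, phase) cell of a
#' partitioned dataset and summarises pathway conservation with
#' [conservation_report()]. Phases with fewer than 2 observations are
#' skipped with a warning.
#'
#' @param dataset an `envirome_dataset` whose `meta` has `culture` and
#'   `phase` columns.
#' @param ems the `elementary_mode_set`.
#' @param config a [plp_config()].
#' @return list with `models` (nested per culture, per phase), `selections`
#'   (signed mode ids per culture/phase), and `report`.
#' @export
plp_moving_window <- function(dataset, ems, config = plp_config()) {
  meta <- dataset$meta
  if (is.null(meta) || is.null(meta$culture) || is.null(meta$phase))
    stop("dataset meta must provide culture and phase columns")
  models <- list(); selections <- list()
  for (cu in unique(meta$culture)) {
    models[[cu]] <- list(); selections[[cu]] <- list()
    for (ph in unique(meta$phase[meta$culture == cu])) {
      rows <- which(meta$culture == cu & meta$phase == ph)
      if (length(rows) < 2) {
        warning("phase ", ph, " of ", cu, " has fewer than 2 observations; skipped")
        next
      }
      sub <- dataset
      sub$X <- dataset$X[rows, , drop = FALSE]
      sub$R <- dataset$R[rows, , drop = FALSE]
      m <- plp_fit(sub, ems, config = config)
      models[[cu]][[ph]] <- m
      selections[[cu]][[ph]] <- m$selected$mode * m$selected$sign
    }
  }
  list(models = models, selections = selections,
       report = conservation_report(selections))
}

#' Pathway-conservation report across phases and cultures
#'
#' Given per-culture lists of per-phase signed mode selections (negative ids
#' are reversed fully reversible modes), computes (a) for each culture the
#' fraction of distinct signed pathways selected in at least two of its
#' phases, averaged over cultures, and (b) the sign-insensitive fraction of
#' mode ids selected in at least two distinct cultures.
#'
#' @param selections list (per culture) of lists (per phase) of signed
#'   integer mode ids.
#' @return list with `within_culture_pct` (average of per-culture repeat
#'   fractions, percent), `per_culture_pct`, and `between_cultures_pct`.
#' @export
conservation_report <- function(selections) {
  per_culture <- vapply(selections, function(phases) {
    tab <- table(unlist(lapply(phases, unique)))
    if (!length(tab)) return(NA_real_)
    100 * mean(tab >= 2)
  }, numeric(1))
  sets <- lapply(selections, function(phases) unique(abs(unlist(phases))))
  tab2 <- table(unlist(sets))
  between <- if (length(tab2)) 100 * mean(tab2 >= 2) else NA_real_
  list(within_culture_pct = mean(per_culture, na.rm = TRUE),
       per_culture_pct = per_culture,
       between_cultures_pct = between)
}
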