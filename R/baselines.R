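# Reduce an equality system A x = b to independent rows (QR pivoting);
# returns NULL rows when the system is trivially empty.
independent_rows <- function(A) {
  if (nrow(A) == 0) return(integer(0))
  qrA <- qr(t(A))
  sort(qrA$pivot[seq_len(qrA$rank)])
}

#' Minimum-norm elementary-mode weighting
#'
#' The quadratic-programming baseline for decomposing a flux vector onto
#' elementary modes: among the weightings reproducing `r`, pick the one of
#' smallest sum of squared weights. In `"hard"` mode the decomposition
#' constraint `E lambda = r` is enforced exactly (infeasibility is reported,
#' not raised). In `"soft"` mode (the default for measured, noisy rate
#' vectors) the problem is lexicographic: first minimise
#' `||E lambda - r||^2`, then minimise `sum(lambda^2)` among the minimisers
#' (to tolerance 1e-8). Weights of irreversible modes are constrained
#' non-negative; fully reversible modes enter unconstrained in sign.
#' Weights refer to the canonical mode scaling of the supplied matrix.
#'
#' @param E mode matrix (fluxes x modes, canonical scaling).
#' @param r flux vector to decompose.
#' @param fully_reversible logical per mode.
#' @param mode `"soft"` or `"hard"`.
#' @return object of class `weight_solution`: `lambda`, `residual_norm`,
#'   `objective` (sum of squared weights), `feasible`.
#' @export
min_norm_weights <- function(E, r, fully_reversible = rep(FALSE, ncol(E)),
                             mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  E <- as.matrix(E)
  if (ncol(E) < 1) stop("E must have at least one mode")
  nem <- ncol(E)
  # quadprog needs finite bounds; this box is far outside any sane weight
  lb <- ifelse(fully_reversible, -1e9, 0)
  solve_stage2 <- function(target) {
    # min sum(lambda^2) s.t. E lambda = target, sign constraints; the
    # equality system is reduced to independent rows first (redundant
    # balances are common when nem >> rank(E)) and the full system is
    # re-verified on the solution.
    rows <- independent_rows(E)
    sol <- tryCatch(
      pracma::quadprog(C = diag(nem), d = rep(0, nem),
                       Aeq = E[rows, , drop = FALSE], beq = target[rows],
                       lb = lb),
      error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    lam <- sol$xmin
    if (max(abs(E %*% lam - target)) > 1e-6 * max(1, max(abs(target))))
      return(NULL)
    lam
  }
  if (mode == "hard") {
    lam <- solve_stage2(r)
    if (is.null(lam)) {
      return(structure(list(lambda = rep(NA_real_, nem),
                            residual_norm = NA_real_, objective = NA_real_,
                            feasible = FALSE), class = "weight_solution"))
    }
  } else {
    # stage 1: constrained least squares min ||E lambda - r||^2
    ridge <- 1e-10 * max(colSums(E^2))
    s1 <- pracma::quadprog(C = crossprod(E) + ridge * diag(nem),
                           d = as.numeric(-crossprod(E, r)), lb = lb)
    fit <- as.numeric(E %*% s1$xmin)
    # stage 2: min-norm among (near-)minimisers, pinned to the stage-1 fit
    lam <- solve_stage2(fit)
    if (is.null(lam)) lam <- s1$xmin
  }
  lam[abs(lam) < 1e-10] <- 0
  structure(list(lambda = lam,
                 residual_norm = sqrt(sum((E %*% lam - r)^2)),
                 objective = sum(lam^2),
                 feasible = TRUE),
            class = "weight_solution")
}

# Linear program helper: optimise obj over {x >= 0 : A3 x = b3} with an
# added large box sum(x) <= box. The box keeps every problem bounded, so a
# solver failure means infeasibility and a solution at the box marks an
# unbounded direction.
lp_box <- function(obj, A3, b3, maxi = FALSE, box = 1e8) {
  s <- tryCatch(
    pracma::linprog(cc = obj,
                    A = matrix(1, 1, length(obj)), b = box,
                    Aeq = A3, beq = b3, maximize = maxi,
                    maxiter = 100 * (length(obj) + nrow(A3) + 2)),
    error = function(e) list(errno = -99))
  if (!identical(s$errno, 1))
    return(list(value = NA_real_, soln = NULL, solved = FALSE, at_box = FALSE))
  list(value = s$fval, soln = s$x, solved = TRUE,
       at_box = sum(s$x) > 0.99 * box)
}

#' The alpha-spectrum of a flux decomposition
#'
#' Per-mode feasible range of the weighting factor: for every mode i, the
#' minimum and maximum of `lambda_i` subject to `E lambda = r` and the sign
#' constraints, computed by linear programming. An infeasible decomposition
#' flags every mode; an unbounded maximum is reported as `Inf`.
#'
#' @inheritParams min_norm_weights
#' @return object of class `alpha_spectrum`: data.frame with `mode`, `min`,
#'   `max`, `feasible`.
#' @export
alpha_spectrum <- function(E, r, fully_reversible = rep(FALSE, ncol(E))) {
  E <- as.matrix(E)
  nem <- ncol(E)
  # split signed variables: lambda = p - n, n only for fully reversible modes
  nfree <- sum(fully_reversible)
  Esplit <- cbind(E, -E[, fully_reversible, drop = FALSE])
  free_of <- which(fully_reversible)
  coef_for <- function(i) {
    v <- numeric(nem + nfree)
    v[i] <- 1
    if (fully_reversible[i]) v[nem + match(i, free_of)] <- -1
    v
  }
  rows <- independent_rows(Esplit)
  drop_ok <- length(rows) == nrow(Esplit) ||
    TRUE  # dropped rows are re-verified on the solution below
  Esub <- Esplit[rows, , drop = FALSE]
  rsub <- r[rows]
  feas <- lp_box(rep(0, nem + nfree), Esub, rsub)
  ok <- isTRUE(feas$solved) &&
    max(abs(Esplit %*% feas$soln - r)) <= 1e-6 * max(1, max(abs(r)))
  out <- data.frame(mode = colnames(E) %||% paste0("m", seq_len(nem)),
                    min = NA_real_, max = NA_real_, feasible = ok)
  if (!ok) return(structure(out, class = c("alpha_spectrum", "data.frame")))
  for (i in seq_len(nem)) {
    lo <- lp_box(coef_for(i), Esub, rsub, maxi = FALSE)
    hi <- lp_box(coef_for(i), Esub, rsub, maxi = TRUE)
    out$min[i] <- if (lo$at_box) -Inf else lo$value
    out$max[i] <- if (hi$at_box) Inf else hi$value
  }
  structure(out, class = c("alpha_spectrum", "data.frame"))
}

#' Census of active modes across a set of weight solutions
#'
#' For each threshold, counts the modes whose weight exceeds it in at least
#' `min_fraction` of the solutions (default: any solution). When the flux
#' data `R` and the mode matrix `E` are supplied, modes are also ranked by
#' the explained variance of their single-mode reconstructions.
#'
#' @param solutions list of `weight_solution`s sharing the mode universe.
#' @param thresholds numeric thresholds on the weight magnitude scale.
#' @param min_fraction fraction of solutions in which the weight must exceed
#'   the threshold for the mode to count (default `> 0`, i.e. any).
#' @param E,R optional mode matrix and observed flux matrix (rows aligned
#'   with `solutions`) for the variance ranking.
#' @return list with `counts` (named by threshold), `exceeds` (mode x
#'   threshold logical), and optionally `variance_ranking` (data.frame).
#' @export
weight_census <- function(solutions, thresholds = c(0.1, 1),
                          min_fraction = NULL, E = NULL, R = NULL) {
  L <- do.call(rbind, lapply(solutions, `[[`, "lambda"))
  if (is.null(L)) stop("no solutions supplied")
  counts <- stats::setNames(numeric(length(thresholds)), thresholds)
  exceeds <- matrix(FALSE, ncol(L), length(thresholds))
  for (k in seq_along(thresholds)) {
    frac <- colMeans(L > thresholds[k], na.rm = TRUE)
    hit <- if (is.null(min_fraction)) frac > 0 else frac >= min_fraction
    exceeds[, k] <- hit
    counts[k] <- sum(hit)
  }
  ranking <- NULL
  if (!is.null(E) && !is.null(R)) {
    E <- as.matrix(E); R <- as.matrix(R)
    var_i <- vapply(seq_len(ncol(E)), function(i)
      explained_variance(R, L[, i, drop = FALSE] %*% t(E[, i, drop = FALSE])),
      numeric(1))
    ranking <- data.frame(mode = colnames(E) %||% paste0("m", seq_len(ncol(E))),
                          single_mode_variance = var_i)
    ranking <- ranking[order(-ranking$single_mode_variance), ]
    rownames(ranking) <- NULL
  }
  list(counts = counts, exceeds = exceeds, variance_ranking = ranking)
}

#' Numerical KKT check for a minimum-norm solution
#'
#' Verifies stationarity of `min sum(lambda^2)` subject to the decomposition
#' constraints: the gradient `2 lambda` must lie in the row space of `E` up
#' to non-negative multipliers on the active bound constraints.
#'
#' @param E mode matrix; @param lambda candidate solution;
#' @param fully_reversible sign flags; @param tol tolerance.
#' @return `TRUE` if the KKT conditions hold within `tol`.
#' @export
kkt_check <- function(E, lambda, fully_reversible = rep(FALSE, ncol(E)),
                      tol = 1e-6) {
  grad <- 2 * lambda
  scale <- max(1, max(abs(grad)))
  active <- !fully_reversible & lambda <= tol
  # stationarity: 2 lambda = E' nu + mu with mu >= 0 supported on the active
  # bounds, i.e. exists nu with E' nu = grad on inactive rows and
  # E' nu <= grad on active rows. Solved as a feasibility QP (min nu'nu).
  Et <- t(E)
  Aeq <- Et[!active, , drop = FALSE]
  rows <- independent_rows(Aeq)
  nu <- tryCatch(
    pracma::quadprog(C = diag(ncol(Et)), d = rep(0, ncol(Et)),
                     A = if (any(active)) Et[active, , drop = FALSE] else NULL,
                     b = if (any(active)) grad[active] + tol * scale else NULL,
                     Aeq = Aeq[rows, , drop = FALSE],
                     beq = grad[!active][rows])$xmin,
    error = function(e) NULL)
  if (is.null(nu)) return(FALSE)
  eq_resid <- max(abs(Et[!active, , drop = FALSE] %*% nu - grad[!active]), 0)
  ineq_viol <- if (any(active))
    max(Et[active, , drop = FALSE] %*% nu - grad[active], 0) else 0
  eq_resid <= tol * scale && ineq_viol <= 2 * tol * scale
}
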