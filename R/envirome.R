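#' Culture time series
#'
#' Container for a (fed-)batch culture record: sampling times (h), viable
#' cell density (10^6 cells/mL), working volume (mL), a table of envirome
#' factors over time (temperature, pH, osmolality, extracellular
#' concentrations in mM), and a feed schedule. Feeds are piecewise-constant:
#' each row of `feeds` gives a start time (h), a rate (mL/h) holding until
#' the next row (or `end`), and the feed concentration (mM) of each compound
#' column.
#'
#' @param time numeric, strictly increasing sampling times (h).
#' @param viable_cells numeric, 10^6 cells/mL, non-negative.
#' @param volume numeric, mL, positive.
#' @param factors data.frame (one row per sampling time) of envirome factors;
#'   concentration columns are in mM.
#' @param feeds optional data.frame with columns `time`, `rate`, then one
#'   column per fed compound (mM); `NULL` means batch.
#' @param id culture identifier.
#' @return object of class `culture_time_series`.
#' @export
culture_time_series <- function(time, viable_cells, volume, factors,
                                feeds = NULL, id = "culture") {
  stopifnot(length(time) == length(viable_cells),
            length(time) == length(volume),
            nrow(factors) == length(time))
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(viable_cells < 0)) stop("viable_cells must be non-negative")
  if (any(volume <= 0)) stop("volume must be positive")
  structure(list(time = time, viable_cells = viable_cells, volume = volume,
                 factors = factors, feeds = feeds, id = id),
            class = "culture_time_series")
}

#' Phase windows
#'
#' @param start,end window bounds in hours, `start < end`.
#' @param label optional phase label.
#' @return object of class `phase_window`.
#' @export
phase_window <- function(start, end, label = sprintf("%g-%g h", start, end)) {
  if (!(start < end)) stop("phase window requires start < end")
  structure(list(start = start, end = end, label = label),
            class = "phase_window")
}

# cumulative feed input (umol) of `compound` between t0 and t1
feed_input <- function(series, compound, t0, t1) {
  f <- series$feeds
  if (is.null(f) || !compound %in% names(f)) return(0)
  total <- 0
  times <- c(f$time, Inf)
  for (i in seq_len(nrow(f))) {
    a <- max(t0, times[i]); b <- min(t1, times[i + 1])
    if (b > a) total <- total + f$rate[i] * f[[compound]][i] * (b - a)
  }
  total
}

#' Estimate specific exchange rates over a phase window
#'
#' For each compound the specific rate q (nmol per 10^6 cells per h,
#' consumption negative) solves the fed-batch amount balance
#' `d(V C)/dt = q Xv V + F C_feed` by least squares on the integrated form:
#' the change in amount net of feed input is regressed (through the origin)
#' on the trapezoid integral of viable cells. The specific growth rate mu
#' (1/h) is fitted separately by log-linear regression of total viable cells.
#'
#' @param series a `culture_time_series`.
#' @param window a `phase_window`; at least 3 samples must fall inside.
#' @param compounds which factor columns to treat as concentrations
#'   (default: all numeric factor columns except temperature/pH/osmolality).
#' @return list with `rates` (named numeric, nmol/(10^6 cells h)) and
#'   `mu` (1/h).
#' @export
estimate_specific_rates <- function(series, window,
                                    compounds = NULL) {
  sel <- which(series$time >= window$start & series$time <= window$end)
  if (length(sel) < 3) stop("phase window contains fewer than 3 samples")
  if (any(series$viable_cells[sel] <= 0))
    stop("nonpositive viable cell density inside the window")
  t <- series$time[sel]
  Xv <- series$viable_cells[sel]
  V <- series$volume[sel]
  if (is.null(compounds)) {
    compounds <- setdiff(names(series$factors)[vapply(series$factors, is.numeric,
                                                      logical(1))],
                         c("temperature", "pH", "osmolality"))
  }
  # integral of Xv*V (10^6 cells * h), cumulative trapezoid from first sample
  xvv <- Xv * V
  cumcells <- c(0, cumsum(diff(t) * (utils::head(xvv, -1) + utils::tail(xvv, -1)) / 2))
  rates <- vapply(compounds, function(cmp) {
    C <- series$factors[[cmp]][sel]
    amount <- V * C                      # umol
    fed <- vapply(t, function(tk) feed_input(series, cmp, t[1], tk), numeric(1))
    y <- (amount - amount[1] - fed) * 1000   # nmol
    if (all(cumcells == 0)) return(NA_real_)
    sum(y * cumcells) / sum(cumcells^2)
  }, numeric(1))
  mu_fit <- stats::lm(log(xvv) ~ t)
  list(rates = rates, mu = unname(stats::coef(mu_fit)[2]))
}

#' Segment a culture into quasi-steady-state phases
#'
#' With `breakpoints` supplied, returns those windows verbatim. In automatic
#' mode, recursive binary segmentation on piecewise-linear fits of the
#' concentration profiles: a split is accepted when the F statistic of the
#' residual reduction exceeds `f_threshold` and both halves keep at least 3
#' samples.
#'
#' @param series a `culture_time_series` with at least 6 samples.
#' @param breakpoints optional numeric vector of interior breakpoint times.
#' @param f_threshold F-statistic acceptance threshold for automatic splits.
#' @param compounds concentration columns used for segmentation (default as
#'   in [estimate_specific_rates()]).
#' @return list of `phase_window` objects, non-overlapping and ordered.
#' @export
segment_phases <- function(series, breakpoints = NULL, f_threshold = 30,
                           compounds = NULL) {
  t <- series$time
  if (length(t) < 6) stop("segmentation needs at least 6 samples")
  if (!is.null(breakpoints)) {
    if (any(breakpoints <= min(t)) || any(breakpoints >= max(t)))
      stop("breakpoints outside the observed time range")
    bounds <- c(min(t), sort(breakpoints), max(t))
    return(lapply(seq_len(length(bounds) - 1), function(i)
      phase_window(bounds[i], bounds[i + 1],
                   label = paste0("Ph", as.roman(i)))))
  }
  if (is.null(compounds))
    compounds <- setdiff(names(series$factors)[vapply(series$factors, is.numeric,
                                                      logical(1))],
                         c("temperature", "pH", "osmolality"))
  Y <- as.matrix(series$factors[compounds])
  rss_lin <- function(idx) {
    sum(vapply(seq_len(ncol(Y)), function(k) {
      f <- stats::lm.fit(cbind(1, t[idx]), Y[idx, k])
      sum(f$residuals^2)
    }, numeric(1)))
  }
  split_rec <- function(idx) {
    n <- length(idx)
    if (n < 6) return(list(idx))
    rss0 <- rss_lin(idx)
    best <- NULL; best_rss <- Inf
    for (cut in 3:(n - 3)) {
      r <- rss_lin(idx[1:cut]) + rss_lin(idx[(cut + 1):n])
      if (r < best_rss) { best_rss <- r; best <- cut }
    }
    k <- 2 * ncol(Y)                       # extra parameters of the split fit
    df2 <- max(1, ncol(Y) * (n - 4))
    Fstat <- ((rss0 - best_rss) / k) / (best_rss / df2 + 1e-300)
    if (is.finite(Fstat) && Fstat > f_threshold) {
      c(split_rec(idx[1:best]), split_rec(idx[(best + 1):length(idx)]))
    } else list(idx)
  }
  parts <- split_rec(seq_along(t))
  lapply(seq_along(parts), function(i)
    phase_window(t[parts[[i]][1]], t[utils::tail(parts[[i]], 1)],
                 label = paste0("Ph", as.roman(i))))
}

#' Assemble an envirome dataset
#'
#' Pairs phase-wise envirome observations `X` (np x nx) with specific-rate
#' observations `R` (np x nr_meas). By default every sampling time inside a
#' phase is one observation row carrying the phase's rate vector
#' (`granularity = "sample"`); `"phase_mean"` pools each phase to one row of
#' factor means (the layout of phase-averaged rate tables). `X` columns are
#' autoscaled (mean 0, variance 1) unless requested otherwise; zero-variance
#' columns are retained, flagged, and left with divisor 1 so they carry zero
#' weight downstream. Scaling constants are stored so raw values are exactly
#' recoverable with [descale_X()].
#'
#' @param series_list list of `culture_time_series`.
#' @param phases_list list (parallel to `series_list`) of lists of
#'   `phase_window`s.
#' @param rates_list optional pre-computed rate vectors: a list (per culture)
#'   of lists (per phase) of named rate vectors including `mu`. When `NULL`,
#'   rates are estimated with [estimate_specific_rates()].
#' @param scaling `"autoscale"`, `"center"`, or `"none"`.
#' @param granularity `"sample"` or `"phase_mean"`.
#' @return object of class `envirome_dataset`: `X`, `R`, `meta` (culture,
#'   phase, time per row), `scaling` (type, center, scale, zero_variance).
#' @export
assemble_envirome <- function(series_list, phases_list, rates_list = NULL,
                              scaling = c("autoscale", "center", "none"),
                              granularity = c("sample", "phase_mean")) {
  scaling <- match.arg(scaling)
  granularity <- match.arg(granularity)
  fac_names <- names(series_list[[1]]$factors)
  for (s in series_list)
    if (!identical(names(s$factors), fac_names))
      stop("inconsistent factor names across cultures")
  Xrows <- list(); Rrows <- list(); meta <- list()
  for (ci in seq_along(series_list)) {
    series <- series_list[[ci]]
    for (pi in seq_along(phases_list[[ci]])) {
      win <- phases_list[[ci]][[pi]]
      if (is.null(rates_list)) {
        est <- estimate_specific_rates(series, win)
        rvec <- c(mu = est$mu, est$rates)
      } else rvec <- rates_list[[ci]][[pi]]
      sel <- which(series$time >= win$start & series$time <= win$end)
      fx <- as.matrix(series$factors[sel, , drop = FALSE])
      if (granularity == "phase_mean") {
        Xrows[[length(Xrows) + 1]] <- colMeans(fx)
        Rrows[[length(Rrows) + 1]] <- rvec
        meta[[length(meta) + 1]] <- data.frame(culture = series$id,
                                               phase = win$label,
                                               time = mean(series$time[sel]))
      } else {
        for (k in seq_along(sel)) {
          Xrows[[length(Xrows) + 1]] <- fx[k, ]
          Rrows[[length(Rrows) + 1]] <- rvec
          meta[[length(meta) + 1]] <- data.frame(culture = series$id,
                                                 phase = win$label,
                                                 time = series$time[sel[k]])
        }
      }
    }
  }
  X <- do.call(rbind, Xrows)
  R <- do.call(rbind, Rrows)
  meta <- do.call(rbind, meta)
  envirome_dataset(X, R, meta = meta, scaling = scaling)
}

#' Construct an envirome dataset from matrices
#'
#' @param X numeric matrix np x nx of envirome observations (raw units).
#' @param R numeric matrix np x nr of specific rates, row-aligned with `X`.
#' @param meta optional per-row metadata data.frame (`culture`, `phase`, ...).
#' @param scaling as in [assemble_envirome()].
#' @return an `envirome_dataset`.
#' @export
envirome_dataset <- function(X, R, meta = NULL,
                             scaling = c("autoscale", "center", "none")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X); R <- as.matrix(R)
  if (nrow(X) != nrow(R)) stop("X and R must share the row count")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (scaling %in% c("autoscale", "center")) ctr <- colMeans(X)
  Xs <- sweep(X, 2, ctr)
  zero_var <- apply(Xs, 2, function(c) all(abs(c) < 1e-12))
  if (scaling == "autoscale") {
    scl <- apply(Xs, 2, stats::sd)
    scl[zero_var | scl == 0] <- 1
  }
  Xs <- sweep(Xs, 2, scl, "/")
  structure(list(X = Xs, R = R, meta = meta,
                 scaling = list(type = scaling, center = ctr, scale = scl,
                                zero_variance = zero_var)),
            class = "envirome_dataset")
}

#' @export
print.envirome_dataset <- function(x, ...) {
  cat(sprintf("<envirome_dataset> %d observations, %d envirome factors, %d rates (%s scaling)\n",
              nrow(x$X), ncol(x$X), ncol(x$R), x$scaling$type))
  invisible(x)
}

#' Recover raw envirome values from a dataset
#'
#' @param ds an `envirome_dataset`.
#' @return the raw (de-scaled) X matrix.
#' @export
descale_X <- function(ds) {
  sweep(sweep(ds$X, 2, ds$scaling$scale, "*"), 2, ds$scaling$center, "+")
}

#' Apply a dataset's scaling to new observations
#'
#' @param ds an `envirome_dataset` (provides the scaling constants).
#' @param X_new raw matrix with the same columns as the training data.
#' @return scaled matrix.
#' @export
scale_like <- function(ds, X_new) {
  X_new <- as.matrix(X_new)
  if (!identical(colnames(X_new), colnames(ds$X)))
    stop("X_new columns do not match the training envirome factors")
  sweep(sweep(X_new, 2, ds$scaling$center), 2, ds$scaling$scale, "/")
}
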