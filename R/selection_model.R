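#' Deterministic two-clone selection model
#'
#' A focal clone at initial frequency `p0` competes against the rest of the
#' population (frequency `q = 1 - p`) with relative fitness `w_star`, the
#' ratio of per-generation multiplication factors. After `t` generations the
#' odds of the focal clone scale as `p_t/q_t = (p0/q0) * w_star^t`. The
#' observable population growth rate is modelled as the frequency-weighted
#' mean of the two clonal growth rates `eta_anc` (background) and `eta_sel`
#' (focal clone), both in doublings per day.
#'
#' @param p0 Initial focal-clone frequency, strictly in (0, 1).
#' @param w_star Relative fitness per generation, > 0.
#' @param eta_anc Growth rate of the non-focal background, doublings/day.
#' @param eta_sel Growth rate of the focal clone, doublings/day.
#' @return An object of class `selection_params`.
#' @examples
#' sp <- selection_params(p0 = 0.0103, w_star = 2.23,
#'                        eta_anc = 0.25, eta_sel = 0.5)
#' clone_frequency(sp, t = 10)
#' @export
selection_params <- function(p0, w_star, eta_anc = NA_real_, eta_sel = NA_real_) {
  stopifnot(is.numeric(p0), length(p0) == 1L, is.finite(p0),
            is.numeric(w_star), length(w_star) == 1L, is.finite(w_star))
  if (p0 <= 0 || p0 >= 1)
    stop("p0 must lie strictly in (0, 1), got ", p0)
  if (w_star <= 0)
    stop("w_star must be positive, got ", w_star)
  if (!is.na(eta_anc) && !is.finite(eta_anc)) stop("eta_anc must be finite")
  if (!is.na(eta_sel) && !is.finite(eta_sel)) stop("eta_sel must be finite")
  structure(list(p0 = p0, w_star = w_star,
                 eta_anc = eta_anc, eta_sel = eta_sel),
            class = "selection_params")
}

#' @export
print.selection_params <- function(x, ...) {
  cat(sprintf("selection_params: p0 = %.4g (%.3g%%), w* = %.4g\n",
              x$p0, 100 * x$p0, x$w_star))
  if (!is.na(x$eta_anc) || !is.na(x$eta_sel))
    cat(sprintf("  growth rates (doublings/day): background %.4g, focal %.4g\n",
                x$eta_anc, x$eta_sel))
  invisible(x)
}

#' Focal-clone frequency after t generations
#'
#' Closed form `p_t = p0 * w*^t / (p0 * w*^t + (1 - p0))`, equivalent to
#' iterating the per-generation update (multiply focal abundance by `w*`,
#' renormalize) `t` times. `t` may be real-valued.
#'
#' @param params A [selection_params()] object.
#' @param t Generation index (vectorized), >= 0.
#' @return Frequencies in (0, 1), same length as `t`.
#' @export
clone_frequency <- function(params, t) {
  stopifnot(inherits(params, "selection_params"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and non-negative")
  p0 <- params$p0
  # work on the log-odds scale so large w*^t cannot overflow
  logit <- log(p0) - log1p(-p0) + t * log(params$w_star)
  stats::plogis(logit)
}

#' Model-predicted population growth rate at generation t
#'
#' Frequency-weighted mean of the clonal growth rates:
#' `GR(t) = eta_anc + (eta_sel - eta_anc) * p_t`.
#'
#' @inheritParams clone_frequency
#' @return Growth rates in doublings/day, same length as `t`.
#' @export
predicted_growth_rate <- function(params, t) {
  if (is.na(params$eta_anc) || is.na(params$eta_sel))
    stop("params must carry eta_anc and eta_sel to predict growth rates")
  params$eta_anc + (params$eta_sel - params$eta_anc) * clone_frequency(params, t)
}

#' First generation at which the focal clone reaches a frequency threshold
#'
#' Solves `w*^t = threshold/(1-threshold) * q0/p0` in closed form and returns
#' the smallest integer `t` with `p_t >= threshold` (0 if already there).
#'
#' @inheritParams clone_frequency
#' @param threshold Target frequency, strictly in (0, 1).
#' @return Integer generation count, or `NA` with a warning when `w* <= 1`
#'   and the threshold exceeds `p0` (never reached).
#' @export
time_to_frequency <- function(params, threshold) {
  stopifnot(inherits(params, "selection_params"),
            is.numeric(threshold), length(threshold) == 1L)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly in (0, 1)")
  if (params$p0 >= threshold) return(0L)
  if (params$w_star <= 1) {
    warning("w_star <= 1: threshold above p0 is never reached")
    return(NA_integer_)
  }
  odds_ratio <- (threshold / (1 - threshold)) * (1 - params$p0) / params$p0
  t <- ceiling(log(odds_ratio) / log(params$w_star))
  # guard against ceiling() landing one short through floating point
  while (clone_frequency(params, t) < threshold) t <- t + 1
  as.integer(t)
}

#' Growth rate from initial and final cell counts
#'
#' From `N_f = N_0 * 2^(eta * t)`: `eta = log2(N_f/N_0) / t_days`, in
#' doublings per day. Negative when the population shrank.
#'
#' @param n0,nf Initial and final viable cell counts, > 0 (vectorized).
#' @param t_days Elapsed time in days, > 0.
#' @return Growth rate(s) in doublings/day.
#' @examples
#' growth_rate_from_counts(20000, 160000, 3)  # 1 doubling/day
#' @export
growth_rate_from_counts <- function(n0, nf, t_days) {
  stopifnot(is.numeric(n0), is.numeric(nf), is.numeric(t_days))
  if (any(n0 <= 0) || any(nf <= 0)) stop("cell counts must be positive")
  if (any(t_days <= 0)) stop("t_days must be positive")
  log2(nf / n0) / t_days
}

#' Convert days in culture to generations
#'
#' The trajectory fit is indexed in generations; chronic-culture experiments
#' record days. The default doubling time of 1.875 days/generation equates a
#' 75-day selection with ~40 generations.
#'
#' @param days Days in culture (vectorized).
#' @param days_per_generation Doubling time in days (default 1.875).
#' @return Generation indices (real-valued).
#' @export
days_to_generations <- function(days, days_per_generation = 1.875) {
  stopifnot(days_per_generation > 0)
  days / days_per_generation
}

#' Read a growth-rate trajectory TSV
#'
#' Expects columns `replicate`, `generation`, `growth_rate_per_day` and
#' aggregates replicates to mean, SEM and n per generation.
#'
#' @param path Path to a tab-separated file.
#' @return A `growth_trajectory`: data.frame with columns `t`, `gr`, `sem`,
#'   `n`, sorted by `t`.
#' @export
read_trajectory <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("replicate", "generation", "growth_rate_per_day")
  if (!all(need %in% names(dt)))
    stop("trajectory file must have columns: ", paste(need, collapse = ", "))
  growth_rate_per_day <- generation <- NULL # NSE bindings
  agg <- dt[, list(gr = mean(growth_rate_per_day),
                   sem = stats::sd(growth_rate_per_day) / sqrt(.N),
                   n = .N),
            by = list(t = generation)]
  data.table::setorder(agg, t)
  growth_trajectory(agg$t, agg$gr, sem = agg$sem, n = agg$n)
}

#' Construct a growth trajectory
#'
#' @param t Generation indices, strictly increasing, >= 0.
#' @param gr Mean growth rate per generation point, doublings/day.
#' @param sem Standard error of the mean (optional).
#' @param n Replicate count per point (default 1).
#' @return A `growth_trajectory` data.frame.
#' @export
growth_trajectory <- function(t, gr, sem = NA_real_, n = 1L) {
  stopifnot(is.numeric(t), is.numeric(gr), length(t) == length(gr))
  if (any(!is.finite(gr))) stop("growth rates must be finite")
  if (is.unsorted(t, strictly = TRUE))
    stop("generation indices must be strictly increasing")
  if (any(n < 1)) stop("replicate counts must be >= 1")
  out <- data.frame(t = t, gr = gr,
                    sem = rep_len(as.numeric(sem), length(t)),
                    n = rep_len(as.integer(n), length(t)))
  class(out) <- c("growth_trajectory", "data.frame")
  out
}

lm_residuals <- function(par, t, gr, fixed) {
  full <- c(as.list(par), fixed)
  sp <- selection_params(full$p0, full$w_star, full$eta_anc, full$eta_sel)
  gr - predicted_growth_rate(sp, t)
}

#' Fit the selection model to a growth-rate trajectory
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of
#' `GR(t) = eta_anc + (eta_sel - eta_anc) * p_t(p0, w*)` to the observed
#' mean growth rates. By default all four parameters are free; `fix_eta`
#' pins the endpoint growth rates to supplied values, leaving a
#' two-parameter `(p0, w*)` fit. The `p0`-`w*` likelihood surface has a
#' ridge for weakly informative trajectories, so the fit is multi-started
#' from jittered initial guesses and the lowest-cost solution is kept.
#'
#' @param trajectory A [growth_trajectory()] (or data.frame with `t`, `gr`).
#' @param start Named list of starting values; defaults are neutral-ish
#'   guesses (`p0 = 0.1`, `w_star = 1.5`, endpoints from the data).
#' @param fix_eta Optional named list with `eta_anc` and/or `eta_sel` to
#'   hold fixed.
#' @param n_restarts Number of additional jittered starts (default 10).
#' @param seed Seed for the jittered restarts (default 1).
#' @param bootstrap Number of residual-bootstrap replicates for parameter
#'   intervals (0 = none).
#' @param ftol Cost tolerance for the optimizer.
#' @return A `selection_fit` list: `params` ([selection_params()]), `rss`,
#'   `converged`, `unidentifiable` (flat-trajectory flag), and `ci` (95%
#'   bootstrap percentile intervals) when requested.
#' @examples
#' sp <- selection_params(0.0103, 2.23, 0.25, 0.5)
#' traj <- growth_trajectory(0:40, predicted_growth_rate(sp, 0:40))
#' fit <- fit_selection_model(traj)
#' fit$params
#' @export
fit_selection_model <- function(trajectory, start = list(), fix_eta = list(),
                                n_restarts = 10, seed = 1, bootstrap = 0,
                                ftol = 1e-10) {
  stopifnot(is.data.frame(trajectory),
            all(c("t", "gr") %in% names(trajectory)))
  t <- trajectory$t
  gr <- trajectory$gr
  free <- setdiff(c("p0", "w_star", "eta_anc", "eta_sel"), names(fix_eta))
  if (length(t) < length(free))
    stop("need at least as many trajectory points as free parameters (",
         length(free), ")")

  lo_all <- c(p0 = 1e-6, w_star = 1e-3, eta_anc = -10, eta_sel = -10)
  hi_all <- c(p0 = 1 - 1e-6, w_star = 1e3, eta_anc = 10, eta_sel = 10)
  default_start <- c(p0 = 0.1, w_star = 1.5,
                     eta_anc = gr[1], eta_sel = gr[length(gr)])
  st <- default_start
  st[names(start)] <- unlist(start)
  st <- pmin(pmax(st[free], lo_all[free]), hi_all[free])
  fixed <- lapply(fix_eta, as.numeric)

  run_one <- function(par0) {
    fit <- try(minpack.lm::nls.lm(
      par = par0, lower = lo_all[free], upper = hi_all[free],
      fn = lm_residuals, t = t, gr = gr, fixed = fixed,
      control = minpack.lm::nls.lm.control(ftol = ftol, ptol = 1e-12,
                                           maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    fit
  }

  starts <- list(st)
  if (n_restarts > 0) {
    set.seed(seed)
    for (i in seq_len(n_restarts)) {
      jit <- st
      if ("p0" %in% free)
        jit["p0"] <- stats::runif(1, 1e-4, 0.5)
      if ("w_star" %in% free)
        jit["w_star"] <- exp(stats::runif(1, log(0.5), log(10)))
      if ("eta_anc" %in% free)
        jit["eta_anc"] <- st["eta_anc"] * stats::runif(1, 0.5, 1.5)
      if ("eta_sel" %in% free)
        jit["eta_sel"] <- st["eta_sel"] * stats::runif(1, 0.5, 1.5)
      starts[[i + 1L]] <- pmin(pmax(jit, lo_all[free]), hi_all[free])
    }
  }

  fits <- Filter(Negate(is.null), lapply(starts, run_one))
  if (!length(fits)) stop("all optimizer starts failed")
  rss <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  best <- fits[[which.min(rss)]]
  par <- c(best$par, unlist(fixed))
  sp <- selection_params(par[["p0"]], par[["w_star"]],
                         par[["eta_anc"]], par[["eta_sel"]])

  # a trajectory with no selection signal cannot pin down p0 or w*
  unident <- stats::sd(gr) < 1e-8 ||
    abs(par[["eta_sel"]] - par[["eta_anc"]]) < 1e-6

  ci <- NULL
  if (bootstrap > 0 && !is.null(trajectory$n) && !all(is.na(trajectory$sem))) {
    resid <- gr - predicted_growth_rate(sp, t)
    boots <- matrix(NA_real_, nrow = bootstrap, ncol = length(free),
                    dimnames = list(NULL, free))
    set.seed(seed + 1L)
    for (b in seq_len(bootstrap)) {
      gr_b <- predicted_growth_rate(sp, t) + sample(resid, replace = TRUE)
      fb <- try(minpack.lm::nls.lm(
        par = best$par, lower = lo_all[free], upper = hi_all[free],
        fn = lm_residuals, t = t, gr = gr_b, fixed = fixed,
        control = minpack.lm::nls.lm.control(ftol = ftol, maxiter = 200)),
        silent = TRUE)
      if (!inherits(fb, "try-error")) boots[b, ] <- fb$par
    }
    ci <- apply(boots, 2, stats::quantile,
                probs = c(0.025, 0.975), na.rm = TRUE)
  }

  structure(list(params = sp,
                 rss = sum(best$fvec^2),
                 converged = best$info %in% 1:4,
                 unidentifiable = unident,
                 ci = ci,
                 n_points = length(t)),
            class = "selection_fit")
}

#' @export
print.selection_fit <- function(x, ...) {
  cat("selection_fit\n")
  print(x$params)
  cat(sprintf("  rss = %.4g over %d points; converged: %s%s\n",
              x$rss, x$n_points, x$converged,
              if (isTRUE(x$unidentifiable)) "; p0/w* unidentifiable" else ""))
  invisible(x)
}

#' Serialize a selection fit to JSON
#'
#' @param fit A `selection_fit`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
fit_report_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "selection_fit"))
  obj <- list(p0 = fit$params$p0, w_star = fit$params$w_star,
              eta_anc = fit$params$eta_anc, eta_sel = fit$params$eta_sel,
              rss = fit$rss, converged = fit$converged,
              unidentifiable = fit$unidentifiable,
              ci = if (!is.null(fit$ci)) as.data.frame(fit$ci))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
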