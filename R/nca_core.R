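# Noncompartmental analysis: Cmax/Tmax, trapezoidal AUClast/AUMClast with BLQ
# handling, terminal log-linear rate-constant regression, and the derived
# parameter chain (T0.5e, MRT, Vd, CL).

# plain linear trapezoid over sampled points
.trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(t))
}

#' Maximum observed concentration and its time
#'
#' @param profile A \code{\link{pk_profile}}.
#' @return List with \code{cmax_mg_per_L}, \code{tmax_h} and
#'   \code{degenerate} (\code{TRUE} when every observation is BLQ, in which
#'   case Cmax is 0 at the first sampled time and a warning is raised). Ties
#'   are broken by the earliest time.
#' @examples
#' p <- sci_study_profiles()[["1"]]
#' find_cmax(p)  # 7.2 mg/L at 1.5 h
#' @export
find_cmax <- function(profile) {
  pts <- profile$points
  if (nrow(pts) == 0L) stop("empty profile")
  if (all(pts$blq | pts$conc_mg_per_L == 0)) {
    warning("degenerate profile (all BLQ): Cmax is 0 at the first sampled time")
    return(list(cmax_mg_per_L = 0, tmax_h = pts$time_h[1L], degenerate = TRUE))
  }
  i <- which.max(pts$conc_mg_per_L)  # first maximum = earliest time (sorted)
  list(cmax_mg_per_L = pts$conc_mg_per_L[i], tmax_h = pts$time_h[i],
       degenerate = FALSE)
}

#' Linear trapezoidal AUClast and AUMClast with BLQ handling
#'
#' Integrates the concentration-time curve by the linear trapezoidal rule
#' from the profile's first sampled time. Under the default policy, BLQ
#' observations enter as concentration 0 and the integration extends through
#' the \emph{first} BLQ sample after the last quantifiable point, then stops;
#' segments with BLQ at both ends contribute nothing. This is the scheme that
#' reproduces the reported exposure values of the bundled study (see the
#' methods vignette). AUMClast integrates \eqn{t \cdot C(t)} over the same
#' window with the same rule.
#'
#' @param profile A \code{\link{pk_profile}} with at least two points.
#' @param blq_rule BLQ integration policy: \code{"zero_through_first_blq"}
#'   (default, described above), \code{"drop_blq"} (BLQ points are discarded
#'   and the curve integrated over quantifiable points only), or
#'   \code{"loq_half"} (BLQ points replaced by \code{loq/2} over the default
#'   window).
#' @param loq Limit of quantification in mg/L; required for
#'   \code{"loq_half"}.
#'
#' @return List of class \code{trapezoid_result}: \code{auclast_mg_h_per_L},
#'   \code{aumclast_mg_h2_per_L}, \code{t_first_h}, \code{t_last_integrated_h},
#'   \code{c_last_quantifiable_mg_per_L}.
#' @examples
#' integrate_trapezoid(sci_study_profiles()[["1"]])$auclast_mg_h_per_L  # 40.775
#' @export
integrate_trapezoid <- function(profile,
                                blq_rule = c("zero_through_first_blq",
                                             "drop_blq", "loq_half"),
                                loq = NA_real_) {
  blq_rule <- match.arg(blq_rule)
  pts <- profile$points
  if (nrow(pts) < 2L) stop("need at least two points to integrate")
  if (is.unsorted(pts$time_h, strictly = TRUE))
    stop("profile times must be strictly increasing")
  quant <- !pts$blq & pts$conc_mg_per_L > 0
  if (!any(quant)) {
    warning("all-BLQ profile: AUClast is 0")
    return(structure(list(auclast_mg_h_per_L = 0, aumclast_mg_h2_per_L = 0,
                          t_first_h = pts$time_h[1L],
                          t_last_integrated_h = pts$time_h[1L],
                          c_last_quantifiable_mg_per_L = 0),
                     class = "trapezoid_result"))
  }
  last_q <- max(which(quant))
  if (blq_rule == "drop_blq") {
    keep <- which(quant)
    tt <- pts$time_h[keep]
    cc <- pts$conc_mg_per_L[keep]
    t_end <- tt[length(tt)]
  } else {
    end <- if (last_q < nrow(pts) && pts$blq[last_q + 1L]) last_q + 1L else last_q
    tt <- pts$time_h[seq_len(end)]
    cc <- pts$conc_mg_per_L[seq_len(end)]
    if (blq_rule == "loq_half") {
      if (is.na(loq)) stop("blq_rule 'loq_half' requires loq")
      cc[pts$blq[seq_len(end)]] <- loq / 2
    }
    t_end <- tt[length(tt)]
  }
  structure(list(
    auclast_mg_h_per_L = .trapz(tt, cc),
    aumclast_mg_h2_per_L = .trapz(tt, tt * cc),
    t_first_h = pts$time_h[1L],
    t_last_integrated_h = t_end,
    c_last_quantifiable_mg_per_L = pts$conc_mg_per_L[last_q]),
    class = "trapezoid_result")
}

#' Terminal-phase log-linear regression for the elimination rate constant
#'
#' Fits ordinary least squares of \eqn{\ln C} on time over quantifiable
#' points of the terminal phase; K (lambda-z) is the negative slope. The
#' window is either given explicitly or selected automatically among all
#' contiguous runs of quantifiable points that end at the last quantifiable
#' observation and start at or after Tmax: the run with the best adjusted
#' R-squared wins (runs of three or more points are preferred; a two-point
#' run is used only when nothing longer exists), with ties broken in favour
#' of more points.
#'
#' @param profile A \code{\link{pk_profile}}.
#' @param window Optional numeric \code{c(start_h, end_h)}: use exactly the
#'   quantifiable points with \code{start_h <= time <= end_h}.
#'
#' @return Object of class \code{lambda_z_fit}: \code{k_per_h} (positive for
#'   a declining phase, \code{NA} otherwise), \code{intercept_ln_conc},
#'   \code{n_points}, \code{window} (start/end hours), \code{r_squared},
#'   \code{adj_r_squared}, \code{declining}. A non-declining terminal phase
#'   (slope >= 0) yields a flagged result with \code{k_per_h = NA} rather
#'   than an error; fewer than two usable points is an error.
#' @examples
#' p <- pk_profile("x", c(2, 4, 8), 5 * exp(-0.2 * c(2, 4, 8)))
#' fit_lambda_z(p)$k_per_h  # 0.2 exactly
#' @export
fit_lambda_z <- function(profile, window = NULL) {
  pts <- profile$points
  quant <- !pts$blq & pts$conc_mg_per_L > 0
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] <= window[2])
    sel <- which(quant & pts$time_h >= window[1] & pts$time_h <= window[2])
    if (length(sel) < 2L)
      stop("fewer than two quantifiable points in the requested window")
    return(.lz_ols(pts$time_h[sel], pts$conc_mg_per_L[sel]))
  }
  if (sum(quant) < 2L)
    stop("fewer than two quantifiable points; cannot fit terminal phase")
  tmax <- find_cmax(profile)$tmax_h
  qi <- which(quant)
  last_q <- qi[length(qi)]
  # contiguous runs of quantifiable points ending at the last quantifiable
  # observation; the run must start at or after Tmax
  starts <- qi[qi >= min(qi[pts$time_h[qi] >= tmax])]
  candidates <- list()
  for (s in starts) {
    run <- s:last_q
    if (length(run) < 2L || !all(quant[run])) next
    candidates[[length(candidates) + 1L]] <-
      .lz_ols(pts$time_h[run], pts$conc_mg_per_L[run])
  }
  if (length(candidates) == 0L) {
    # Tmax is the last quantifiable observation, so no terminal window
    # starting at or after it exists; fit the trailing contiguous
    # quantifiable run instead (a rising profile then comes back flagged
    # non-declining rather than erroring)
    s <- last_q
    while (s > 1L && quant[s - 1L]) s <- s - 1L
    if (last_q - s + 1L < 2L)
      stop("no contiguous quantifiable terminal window of two or more points")
    return(.lz_ols(pts$time_h[s:last_q], pts$conc_mg_per_L[s:last_q]))
  }
  score <- vapply(candidates, function(f)
    if (f$n_points >= 3L) f$adj_r_squared else -Inf, numeric(1))
  if (all(!is.finite(score)))  # only two-point runs available
    score <- vapply(candidates, function(f) f$r_squared, numeric(1))
  npts <- vapply(candidates, function(f) f$n_points, integer(1))
  best <- order(-score, -npts)[1L]
  candidates[[best]]
}

.lz_ols <- function(t, c) {
  fit <- stats::lm(log(c) ~ t)
  slope <- unname(stats::coef(fit)[2L])
  n <- length(t)
  # direct R^2 (summary.lm warns on numerically perfect noise-free fits)
  sst <- sum((log(c) - mean(log(c)))^2)
  r2 <- if (n == 2L || sst == 0) 1 else
    max(0, min(1, 1 - sum(stats::residuals(fit)^2) / sst))
  adj <- if (n > 2L) 1 - (1 - r2) * (n - 1) / (n - 2) else NA_real_
  declining <- is.finite(slope) && slope < 0
  structure(list(
    k_per_h = if (declining) -slope else NA_real_,
    intercept_ln_conc = unname(stats::coef(fit)[1L]),
    n_points = n,
    window = c(start_h = t[1L], end_h = t[n]),
    r_squared = r2,
    adj_r_squared = adj,
    declining = declining),
    class = "lambda_z_fit")
}

#' Derived noncompartmental parameters from AUClast and K
#'
#' Applies the standard derived-parameter chain: elimination half-life
#' \eqn{T_{0.5e} = \ln 2 / K}, mean residence time (by default
#' \eqn{MRT = 1/K}; alternatively the moment estimator
#' \eqn{AUMC_{last}/AUC_{last}}), apparent volume of distribution
#' \eqn{V_d = \mathrm{dose}/(K \cdot AUC_{last})} and clearance
#' \eqn{CL = K \cdot V_d}.
#'
#' @param auclast AUClast in mg.h/L, positive.
#' @param k_per_h Terminal elimination rate constant in 1/h, positive
#'   (numeric, or a \code{lambda_z_fit}).
#' @param dose_mg Administered dose in mg, positive.
#' @param ln2_constant Value of ln 2 used for the half-life; full machine
#'   precision \code{log(2)} by default, with the truncated literal 0.693
#'   available for matching legacy reports.
#' @param mrt_method \code{"inverse_k"} (default) or \code{"aumc"}; the
#'   latter requires \code{aumclast}.
#' @param aumclast AUMClast in mg.h^2/L, used only by
#'   \code{mrt_method = "aumc"}.
#'
#' @return List with \code{t_half_h}, \code{mrt_h}, \code{vd_L},
#'   \code{cl_L_per_h}.
#' @examples
#' derive_parameters(25.3, 0.161, 4.06)  # Vd 0.9967 L, CL 0.160 L/h
#' @export
derive_parameters <- function(auclast, k_per_h, dose_mg,
                              ln2_constant = log(2),
                              mrt_method = c("inverse_k", "aumc"),
                              aumclast = NULL) {
  mrt_method <- match.arg(mrt_method)
  if (inherits(k_per_h, "lambda_z_fit")) k_per_h <- k_per_h$k_per_h
  if (!is.finite(auclast) || auclast <= 0) stop("auclast must be positive")
  if (!is.finite(k_per_h) || k_per_h <= 0) stop("k_per_h must be positive")
  if (!is.finite(dose_mg) || dose_mg <= 0) stop("dose_mg must be positive")
  vd <- dose_mg / (k_per_h * auclast)
  mrt <- if (mrt_method == "inverse_k") 1 / k_per_h else {
    if (is.null(aumclast)) stop("mrt_method 'aumc' requires aumclast")
    aumclast / auclast
  }
  list(t_half_h = ln2_constant / k_per_h,
       mrt_h = mrt,
       vd_L = vd,
       cl_L_per_h = k_per_h * vd)
}

#' Pool staggered profiles into a mean concentration-time profile
#'
#' Builds the group-level profile of a sparse (staggered) design: the time
#' grid is the union of all sampled times, and at each time the concentration
#' is the mean over the subjects actually sampled there, counting BLQ as 0.
#' The pooled dose is the mean dose of the contributing subjects.
#'
#' @param profiles Non-empty list of \code{\link{pk_profile}} objects.
#' @param rounding_dp Optional number of decimal places to which mean
#'   concentrations are rounded (half away from zero) before any downstream
#'   NCA; \code{NULL} (default) keeps full precision.
#' @param subject_id Id given to the pooled profile.
#'
#' @return A \code{pk_profile}; means that are exactly 0 are flagged BLQ.
#' @examples
#' pooled <- pooled_mean_profile(sci_study_profiles())
#' pooled$points$conc_mg_per_L[pooled$points$time_h == 1.5]  # 5.9333
#' @export
pooled_mean_profile <- function(profiles, rounding_dp = NULL,
                                subject_id = "pooled") {
  if (length(profiles) == 0L) stop("no profiles to pool")
  long <- do.call(rbind, lapply(profiles, as.data.frame))
  times <- sort(unique(long$time_h))
  conc <- vapply(times, function(tt)
    mean(long$conc_mg_per_L[long$time_h == tt]), numeric(1))
  if (!is.null(rounding_dp)) conc <- round_half_away(conc, rounding_dp)
  doses <- vapply(profiles, function(p) p$dose_mg, numeric(1))
  weights <- vapply(profiles, function(p) p$body_weight_g, numeric(1))
  pk_profile(subject_id, times, conc, blq = conc == 0,
             body_weight_g = if (all(is.na(weights))) NA_real_ else
               mean(weights, na.rm = TRUE),
             dose_mg = if (all(is.na(doses))) NA_real_ else
               mean(doses, na.rm = TRUE))
}

#' NCA configuration
#'
#' Bundles the policies of a noncompartmental run. Every policy has the
#' package default; see the methods vignette for the rationale behind each.
#'
#' @param blq_rule BLQ integration policy for
#'   \code{\link{integrate_trapezoid}}.
#' @param lambda_z_mode \code{"auto"} (automatic terminal-window selection),
#'   \code{"window"} (explicit \code{window}), or \code{"fixed"} (use
#'   \code{fixed_k} as the rate constant, bypassing regression).
#' @param fixed_k Positive rate constant in 1/h for
#'   \code{lambda_z_mode = "fixed"}.
#' @param window Numeric \code{c(start_h, end_h)} for
#'   \code{lambda_z_mode = "window"}.
#' @param ln2_constant ln 2 used in the half-life; \code{log(2)} by default.
#' @param mrt_method \code{"inverse_k"} or \code{"aumc"}.
#' @param pooled_rounding_dp Decimal places for pooled mean concentrations
#'   before integration (\code{NULL} = no rounding).
#' @param confidence Confidence level for group summaries.
#' @param loq Limit of quantification for the \code{"loq_half"} BLQ rule.
#' @return List of class \code{nca_config}.
#' @export
nca_config <- function(blq_rule = "zero_through_first_blq",
                       lambda_z_mode = c("auto", "window", "fixed"),
                       fixed_k = NULL, window = NULL,
                       ln2_constant = log(2),
                       mrt_method = "inverse_k",
                       pooled_rounding_dp = NULL,
                       confidence = 0.95,
                       loq = NA_real_) {
  lambda_z_mode <- match.arg(lambda_z_mode)
  if (lambda_z_mode == "fixed" &&
      (is.null(fixed_k) || !is.finite(fixed_k) || fixed_k <= 0))
    stop("lambda_z_mode 'fixed' requires a positive fixed_k")
  if (lambda_z_mode == "window" && is.null(window))
    stop("lambda_z_mode 'window' requires a window")
  structure(list(blq_rule = blq_rule, lambda_z_mode = lambda_z_mode,
                 fixed_k = fixed_k, window = window,
                 ln2_constant = ln2_constant, mrt_method = mrt_method,
                 pooled_rounding_dp = pooled_rounding_dp,
                 confidence = confidence, loq = loq),
            class = "nca_config")
}

#' Full noncompartmental analysis of one profile
#'
#' Composes \code{\link{find_cmax}}, \code{\link{integrate_trapezoid}},
#' \code{\link{fit_lambda_z}} (or a fixed rate constant) and
#' \code{\link{derive_parameters}} into one result record. A profile without
#' a declining terminal phase yields a partial result (Cmax/Tmax/AUClast
#' only) flagged incomplete rather than an error.
#'
#' @param profile A \code{\link{pk_profile}} with \code{dose_mg} set (the
#'   dose is only required for the derived parameters).
#' @param config An \code{\link{nca_config}}.
#'
#' @return Object of class \code{nca_result}: \code{subject_id},
#'   \code{dose_mg}, \code{cmax_mg_per_L}, \code{tmax_h},
#'   \code{auclast_mg_h_per_L}, \code{aumclast_mg_h2_per_L}, \code{k_per_h},
#'   \code{t_half_h}, \code{mrt_h}, \code{vd_L}, \code{cl_L_per_h},
#'   \code{complete} (logical), and \code{lambda_z} (the fit, or NULL).
#' @examples
#' p <- sci_study_profiles()[["5"]]
#' run_nca(p, nca_config(lambda_z_mode = "fixed", fixed_k = 0.161))
#' @export
run_nca <- function(profile, config = nca_config()) {
  stopifnot(inherits(config, "nca_config"))
  cm <- withCallingHandlers(find_cmax(profile),
                            warning = function(w) invokeRestart("muffleWarning"))
  res <- list(subject_id = profile$subject_id, dose_mg = profile$dose_mg,
              cmax_mg_per_L = cm$cmax_mg_per_L, tmax_h = cm$tmax_h,
              auclast_mg_h_per_L = NA_real_, aumclast_mg_h2_per_L = NA_real_,
              k_per_h = NA_real_, t_half_h = NA_real_, mrt_h = NA_real_,
              vd_L = NA_real_, cl_L_per_h = NA_real_,
              complete = FALSE, lambda_z = NULL)
  if (cm$degenerate)
    return(structure(res, class = "nca_result"))
  tr <- integrate_trapezoid(profile, blq_rule = config$blq_rule,
                            loq = config$loq)
  res$auclast_mg_h_per_L <- tr$auclast_mg_h_per_L
  res$aumclast_mg_h2_per_L <- tr$aumclast_mg_h2_per_L
  k <- switch(config$lambda_z_mode,
    fixed = config$fixed_k,
    window = {
      fit <- fit_lambda_z(profile, window = config$window)
      res$lambda_z <- fit
      fit$k_per_h
    },
    auto = {
      fit <- tryCatch(fit_lambda_z(profile), error = function(e) NULL)
      res$lambda_z <- fit
      if (is.null(fit)) NA_real_ else fit$k_per_h
    })
  if (!is.na(k) && is.finite(k) && k > 0 && !is.na(res$dose_mg) &&
      res$auclast_mg_h_per_L > 0) {
    d <- derive_parameters(res$auclast_mg_h_per_L, k, res$dose_mg,
                           ln2_constant = config$ln2_constant,
                           mrt_method = config$mrt_method,
                           aumclast = res$aumclast_mg_h2_per_L)
    res$k_per_h <- k
    res$t_half_h <- d$t_half_h
    res$mrt_h <- d$mrt_h
    res$vd_L <- d$vd_L
    res$cl_L_per_h <- d$cl_L_per_h
    res$complete <- TRUE
  }
  structure(res, class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("<nca_result> subject ", x$subject_id,
      if (!x$complete) " (incomplete: no terminal phase)", "\n", sep = "")
  print(as.data.frame(nca_results_table(list(x))), row.names = FALSE)
  invisible(x)
}

#' Assemble NCA results into a reporting table
#'
#' One row per result in the conventional column order (Cmax, Tmax, AUClast,
#' Vd, CL, K, T0.5e, MRT).
#'
#' @param results List of \code{nca_result} objects (a single result is
#'   accepted).
#' @return Data frame with columns \code{subject_id}, \code{cmax_mg_per_L},
#'   \code{tmax_h}, \code{auclast_mg_h_per_L}, \code{vd_L}, \code{cl_L_per_h},
#'   \code{k_per_h}, \code{t_half_h}, \code{mrt_h}, \code{dose_mg}.
#' @export
nca_results_table <- function(results) {
  if (inherits(results, "nca_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(subject_id = r$subject_id,
               cmax_mg_per_L = r$cmax_mg_per_L,
               tmax_h = r$tmax_h,
               auclast_mg_h_per_L = r$auclast_mg_h_per_L,
               vd_L = r$vd_L,
               cl_L_per_h = r$cl_L_per_h,
               k_per_h = r$k_per_h,
               t_half_h = r$t_half_h,
               mrt_h = r$mrt_h,
               dose_mg = r$dose_mg,
               stringsAsFactors = FALSE)))
}
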