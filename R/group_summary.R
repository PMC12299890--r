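# Per-group descriptive statistics: mean, SEM and symmetric confidence
# intervals (Student t by default) for each NCA parameter.

#' Mean, SEM and confidence interval of a set of values
#'
#' Computes the arithmetic mean, the standard error of the mean (sample
#' standard deviation with the n-1 denominator, divided by sqrt(n)) and a
#' symmetric two-sided confidence interval \eqn{\bar{x} \pm q \cdot SEM},
#' where \eqn{q} is the Student t quantile on n-1 degrees of freedom
#' (default) or the normal quantile.
#'
#' Bounds are reported as computed: a lower bound below zero for a
#' nonnegative quantity is not truncated.
#'
#' @param values Numeric vector, non-empty. A single value yields the mean
#'   with \code{NA} SEM and bounds.
#' @param confidence Confidence level, default 0.95.
#' @param method \code{"t"} (default) or \code{"normal"} quantiles.
#' @return List of class \code{summary_stats}: \code{n}, \code{mean},
#'   \code{sem}, \code{ci_low}, \code{ci_high}, \code{confidence}.
#' @examples
#' summarize_values(c(7.2, 6.2, 6.8))  # mean 6.733, SEM 0.291, CI 5.483-7.984
#' @export
summarize_values <- function(values, confidence = 0.95,
                             method = c("t", "normal")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("no values to summarize")
  m <- mean(values)
  if (n == 1L)
    return(structure(list(n = 1L, mean = m, sem = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          confidence = confidence),
                     class = "summary_stats"))
  sem <- stats::sd(values) / sqrt(n)
  q <- if (method == "t") stats::qt(1 - (1 - confidence) / 2, df = n - 1)
       else stats::qnorm(1 - (1 - confidence) / 2)
  structure(list(n = n, mean = m, sem = sem,
                 ci_low = m - q * sem, ci_high = m + q * sem,
                 confidence = confidence),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d: %.4g +/- %.4g (%.0f%% CI %.4g to %.4g)\n",
              x$n, x$mean, x$sem, 100 * x$confidence, x$ci_low, x$ci_high))
  invisible(x)
}

#' Group summaries of an NCA results table
#'
#' Summarizes every NCA parameter (Cmax, Tmax, AUClast, Vd, CL, K, T0.5e,
#' MRT) within each group of subjects: one row per group and parameter with
#' n, mean, SEM and confidence bounds.
#'
#' @param results Data frame as returned by \code{\link{nca_results_table}},
#'   or a list of \code{nca_result} objects.
#' @param grouping Named list mapping group label to a character vector of
#'   subject ids; default puts all subjects in one group \code{"all"}. Every
#'   group must be non-empty; a group of one subject yields mean-only rows
#'   with a warning.
#' @param confidence Confidence level.
#' @param method Quantile family, \code{"t"} or \code{"normal"}.
#' @return Data frame with columns \code{group}, \code{parameter}, \code{n},
#'   \code{mean}, \code{sem}, \code{ci_low}, \code{ci_high}, parameters in
#'   reporting order.
#' @examples
#' res <- lapply(sci_study_profiles(), function(p)
#'   run_nca(p, nca_config(lambda_z_mode = "fixed",
#'                         fixed_k = sci_reference_k()$k_per_h[
#'                           match(p$subject_id, sci_reference_k()$subject_id)])))
#' summarize_table(res, grouping = list(`1-3` = c("1", "2", "3"),
#'                                      `4-6` = c("4", "5", "6")))
#' @export
summarize_table <- function(results, grouping = NULL, confidence = 0.95,
                            method = c("t", "normal")) {
  method <- match.arg(method)
  if (!is.data.frame(results)) results <- nca_results_table(results)
  params <- c("cmax_mg_per_L", "tmax_h", "auclast_mg_h_per_L", "vd_L",
              "cl_L_per_h", "k_per_h", "t_half_h", "mrt_h")
  if (is.null(grouping))
    grouping <- list(all = results$subject_id)
  rows <- list()
  for (g in names(grouping)) {
    ids <- as.character(grouping[[g]])
    sub <- results[results$subject_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0L) stop("group '", g, "' matches no subjects")
    if (nrow(sub) == 1L)
      warning("group '", g, "' has a single subject; mean-only summary")
    for (p in params) {
      s <- summarize_values(sub[[p]], confidence = confidence, method = method)
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, parameter = p, n = s$n, mean = s$mean,
                   sem = s$sem, ci_low = s$ci_low, ci_high = s$ci_high,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
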