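# End-to-end pipeline, figures and provenance. These functions (plus the thin
# command-line wrapper in inst/cli/scipk) tie the modules together: read,
# analyse per subject, pool, summarize, write, plot.

#' Run the full NCA pipeline on a study
#'
#' Performs per-subject NCA, pools the staggered profiles into a mean
#' profile and analyses it, and summarizes every parameter per group.
#' Optionally writes all results (CSV + JSON), a group-summary CSV, and a
#' machine-readable provenance record sufficient to re-run deterministically.
#'
#' @param profiles Named list of \code{\link{pk_profile}} objects with doses
#'   attached.
#' @param config An \code{\link{nca_config}}. \code{pooled_rounding_dp}
#'   controls rounding of pooled means before integration.
#' @param grouping Named list of subject-id vectors for
#'   \code{\link{summarize_table}}; default one group of all subjects.
#' @param fixed_k_table Optional data frame (\code{subject_id},
#'   \code{k_per_h}) of externally supplied terminal rate constants, e.g.
#'   \code{\link{sci_reference_k}}. When given, each subject (and the pooled
#'   profile via the id \code{"pooled"}) uses its fixed K instead of the
#'   config's lambda-z mode; subjects absent from the table fall back to the
#'   config.
#' @param out_dir Optional output directory (created if needed); when given,
#'   writes \code{results.csv/json}, \code{summary.csv},
#'   \code{pooled_result.csv/json} and \code{provenance.json}.
#'
#' @return List of class \code{study_nca}: \code{per_subject} (list of
#'   \code{nca_result}), \code{results} (data frame),
#'   \code{pooled_profile}, \code{pooled_result}, \code{summary} (data
#'   frame), and \code{files} (paths written, or NULL).
#' @examples
#' fit <- run_study_nca(sci_study_profiles(),
#'                      config = nca_config(pooled_rounding_dp = 2),
#'                      grouping = list(`1-3` = as.character(1:3),
#'                                      `4-6` = as.character(4:6)),
#'                      fixed_k_table = sci_reference_k())
#' fit$pooled_result$auclast_mg_h_per_L  # 23.47
#' @export
run_study_nca <- function(profiles, config = nca_config(), grouping = NULL,
                          fixed_k_table = NULL, out_dir = NULL) {
  if (length(profiles) == 0L) stop("no profiles")
  config_for <- function(id) {
    if (!is.null(fixed_k_table)) {
      j <- match(id, as.character(fixed_k_table$subject_id))
      if (!is.na(j)) {
        cf <- config
        cf$lambda_z_mode <- "fixed"
        cf$fixed_k <- fixed_k_table$k_per_h[j]
        return(cf)
      }
    }
    config
  }
  per_subject <- lapply(profiles, function(p)
    run_nca(p, config_for(p$subject_id)))
  results <- nca_results_table(per_subject)
  pooled <- pooled_mean_profile(profiles,
                                rounding_dp = config$pooled_rounding_dp)
  pooled_result <- run_nca(pooled, config_for(pooled$subject_id))
  summary_df <- summarize_table(results, grouping = grouping,
                                confidence = config$confidence)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      write_results(results, file.path(out_dir, "results.csv")),
      {
        utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                         row.names = FALSE)
        file.path(out_dir, "summary.csv")
      },
      write_results(nca_results_table(pooled_result),
                    file.path(out_dir, "pooled_result.csv")))
    prov <- list(package = "scipk",
                 version = as.character(utils::packageVersion("scipk")),
                 r_version = R.version.string,
                 config = unclass(config),
                 subjects = names(profiles),
                 grouping = grouping,
                 fixed_k = fixed_k_table)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE, force = TRUE)
    files <- c(files, file.path(out_dir, "provenance.json"))
  }
  structure(list(per_subject = per_subject, results = results,
                 pooled_profile = pooled, pooled_result = pooled_result,
                 summary = summary_df, files = files),
            class = "study_nca")
}

#' @export
print.study_nca <- function(x, ...) {
  cat("<study_nca> ", nrow(x$results), " subjects\n", sep = "")
  print(x$results, row.names = FALSE)
  cat("pooled profile:\n")
  print(nca_results_table(x$pooled_result), row.names = FALSE)
  invisible(x)
}

#' Compare automatic lambda-z fits against reference rate constants
#'
#' For each subject, attempts the automatic terminal-window regression and
#' tabulates the fitted K next to an externally supplied reference value, to
#' document where and by how much the two diverge.
#'
#' @param profiles Named list of \code{\link{pk_profile}} objects.
#' @param reference_k Data frame (\code{subject_id}, \code{k_per_h}).
#' @return Data frame with columns \code{subject_id}, \code{k_auto_per_h}
#'   (\code{NA} when no declining window exists), \code{n_points},
#'   \code{r_squared}, \code{k_reference_per_h}, \code{ratio}
#'   (auto/reference).
#' @export
lambda_z_divergence <- function(profiles, reference_k = sci_reference_k()) {
  rows <- lapply(profiles, function(p) {
    fit <- tryCatch(fit_lambda_z(p), error = function(e) NULL)
    j <- match(p$subject_id, as.character(reference_k$subject_id))
    kref <- if (is.na(j)) NA_real_ else reference_k$k_per_h[j]
    kauto <- if (is.null(fit)) NA_real_ else fit$k_per_h
    data.frame(subject_id = p$subject_id,
               k_auto_per_h = kauto,
               n_points = if (is.null(fit)) NA_integer_ else fit$n_points,
               r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
               k_reference_per_h = kref,
               ratio = kauto / kref,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate a study and write it in the package's CSV formats
#'
#' Writes the long-format concentration table, the dose table, and a
#' ground-truth JSON (simulation parameters, seed, design) so the dataset
#' can be regenerated bit-identically.
#'
#' @param out_dir Output directory (created if needed).
#' @param design,params,n_per_group,seed Passed to
#'   \code{\link{generate_study}}.
#' @return Character vector of files written, invisibly.
#' @export
simulate_study_csv <- function(out_dir, design = study_design(),
                               params = sim_params(), n_per_group = 3L,
                               seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- generate_study(design = design, params = params,
                             n_per_group = n_per_group, seed = seed)
  conc_path <- file.path(out_dir, "concentrations.csv")
  write_concentration_table(profiles, conc_path)
  doses <- data.frame(
    subject_id = names(profiles),
    body_weight_g = vapply(profiles, function(p) p$body_weight_g, numeric(1)),
    dose_mg = vapply(profiles, function(p) p$dose_mg, numeric(1)))
  dose_path <- file.path(out_dir, "doses.csv")
  utils::write.csv(doses, dose_path, row.names = FALSE)
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(list(params = unclass(params), seed = seed,
                            n_per_group = n_per_group,
                            design = lapply(design, identity)),
                       truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(conc_path, dose_path, truth_path))
}

#' Concentration-time plot of individual profiles
#'
#' One line per subject on a common axis (hours vs mg/L); BLQ observations
#' are drawn at 0 with open symbols.
#'
#' @param profiles List of \code{\link{pk_profile}} objects (one is fine).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles) {
  if (inherits(profiles, "pk_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("no profiles to plot")
  long <- do.call(rbind, lapply(profiles, as.data.frame))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h,
                                     y = .data$conc_mg_per_L,
                                     colour = .data$subject_id,
                                     group = .data$subject_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$blq), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                labels = c("quantified", "BLQ"),
                                name = NULL) +
    ggplot2::labs(x = "Time post-dose [h]",
                  y = "Serum concentration [mg/L]",
                  colour = "Subject") +
    ggplot2::theme_bw()
}

#' Pooled mean concentration-time plot with SEM bars
#'
#' Group-level profile of a staggered design: mean concentration at each
#' sampled time (BLQ as 0) with error bars of one standard error of the mean
#' where two or more subjects contribute.
#'
#' @param profiles List of \code{\link{pk_profile}} objects.
#' @return A ggplot object.
#' @export
plot_pooled_profile <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles to plot")
  long <- do.call(rbind, lapply(profiles, as.data.frame))
  agg <- do.call(rbind, lapply(split(long, long$time_h), function(s)
    data.frame(time_h = s$time_h[1L],
               mean = mean(s$conc_mg_per_L),
               sem = if (nrow(s) > 1L)
                 stats::sd(s$conc_mg_per_L) / sqrt(nrow(s)) else NA_real_)))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$time_h, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.4, na.rm = TRUE) +
    ggplot2::labs(x = "Time post-dose [h]",
                  y = "Mean serum concentration [mg/L]") +
    ggplot2::theme_bw()
}

#' Save study figures with deterministic names
#'
#' Writes \code{profiles_<label>.png} and \code{pooled_<label>.png} into a
#' directory.
#'
#' @param profiles List of \code{\link{pk_profile}} objects.
#' @param out_dir Output directory.
#' @param label File-name label, default \code{"study"}.
#' @param width,height,dpi Passed to \code{ggplot2::ggsave}.
#' @return Character vector of the two file paths, invisibly.
#' @export
save_study_figures <- function(profiles, out_dir, label = "study",
                               width = 7, height = 4.5, dpi = 150) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(out_dir, paste0("profiles_", label, ".png"))
  f2 <- file.path(out_dir, paste0("pooled_", label, ".png"))
  ggplot2::ggsave(f1, plot_profiles(profiles), width = width,
                  height = height, dpi = dpi)
  ggplot2::ggsave(f2, plot_pooled_profile(profiles), width = width,
                  height = height, dpi = dpi)
  invisible(c(f1, f2))
}
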