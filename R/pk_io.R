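# Data model and I/O for long-format concentration-time tables.
#
# Units are fixed package-wide: time in hours, concentration in mg/L, dose in
# mg, body weight in grams. No unit inference is attempted. BLQ (below the
# limit of quantification) observations are stored as concentration 0 with
# blq = TRUE, matching how sparse rodent PK datasets usually report them.

#' Construct a single-subject concentration-time profile
#'
#' A \code{pk_profile} holds one subject's dose, body weight, and time-ordered
#' concentration observations. Times must be strictly increasing with no
#' duplicates; BLQ observations carry concentration 0.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param time_h Numeric vector of sampling times in hours, non-negative.
#' @param conc_mg_per_L Numeric vector of serum concentrations in mg/L,
#'   non-negative, same length as \code{time_h}.
#' @param blq Logical vector flagging below-quantification-limit observations.
#'   Defaults to \code{conc_mg_per_L == 0}.
#' @param body_weight_g Body weight in grams (positive), or \code{NA}.
#' @param dose_mg Administered dose in mg (positive), or \code{NA}.
#'
#' @return An object of class \code{pk_profile}: a list with elements
#'   \code{subject_id}, \code{body_weight_g}, \code{dose_mg}, and
#'   \code{points} (a data frame with columns \code{time_h},
#'   \code{conc_mg_per_L}, \code{blq}).
#'
#' @examples
#' pk_profile("r1", time_h = c(0, 1, 2), conc_mg_per_L = c(0, 5, 2.5))
#' @export
pk_profile <- function(subject_id, time_h, conc_mg_per_L,
                       blq = conc_mg_per_L == 0,
                       body_weight_g = NA_real_, dose_mg = NA_real_) {
  subject_id <- as.character(subject_id)
  stopifnot(length(subject_id) == 1L, !is.na(subject_id))
  time_h <- as.numeric(time_h)
  conc_mg_per_L <- as.numeric(conc_mg_per_L)
  blq <- as.logical(blq)
  if (length(conc_mg_per_L) != length(time_h) || length(blq) != length(time_h))
    stop("time_h, conc_mg_per_L and blq must have equal length")
  if (anyNA(time_h) || anyNA(conc_mg_per_L) || anyNA(blq))
    stop("missing values are not allowed in profile points")
  if (any(time_h < 0))
    stop("negative sampling time for subject '", subject_id, "'")
  if (any(conc_mg_per_L < 0))
    stop("negative concentration for subject '", subject_id, "'")
  if (is.unsorted(time_h, strictly = TRUE)) {
    if (anyDuplicated(time_h)) {
      dup <- time_h[duplicated(time_h)][1L]
      stop("duplicate sampling time (subject '", subject_id, "', t = ",
           dup, " h)")
    }
    stop("sampling times must be strictly increasing (subject '",
         subject_id, "')")
  }
  if (any(blq & conc_mg_per_L != 0))
    stop("BLQ observations must carry concentration 0 (subject '",
         subject_id, "')")
  body_weight_g <- as.numeric(body_weight_g)
  dose_mg <- as.numeric(dose_mg)
  if (!is.na(body_weight_g) && body_weight_g <= 0)
    stop("body_weight_g must be positive")
  if (!is.na(dose_mg) && dose_mg <= 0)
    stop("dose_mg must be positive")
  structure(
    list(subject_id = subject_id,
         body_weight_g = body_weight_g,
         dose_mg = dose_mg,
         points = data.frame(time_h = time_h,
                             conc_mg_per_L = conc_mg_per_L,
                             blq = blq)),
    class = "pk_profile")
}

#' @export
print.pk_profile <- function(x, ...) {
  cat("<pk_profile> subject ", x$subject_id,
      if (!is.na(x$dose_mg)) paste0(", dose ", x$dose_mg, " mg"),
      if (!is.na(x$body_weight_g)) paste0(", ", x$body_weight_g, " g"),
      ": ", nrow(x$points), " points, ",
      sum(x$points$blq), " BLQ\n", sep = "")
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.pk_profile <- function(x, ...) {
  cbind(subject_id = x$subject_id, x$points,
        stringsAsFactors = FALSE)
}

#' Describe a staggered sampling design
#'
#' A study design maps group labels to sampling-time grids. The default is the
#' two-subgroup destructive design of the bundled rat study: subgroup 1
#' sampled at 0, 0.25, 0.5, 1, 1.5, 12 and 24 h post-dose, subgroup 2 at
#' 2, 4, 8, 36 and 48 h.
#'
#' @param groups Named list of numeric time grids (hours). Each grid must be
#'   non-empty, strictly increasing and non-negative.
#'
#' @return An object of class \code{study_design} (the validated named list).
#' @examples
#' study_design()  # the default two-subgroup grid
#' @export
study_design <- function(groups = list(
    subgroup1 = c(0, 0.25, 0.5, 1, 1.5, 12, 24),
    subgroup2 = c(2, 4, 8, 36, 48))) {
  if (!is.list(groups) || length(groups) == 0L || is.null(names(groups)) ||
      any(!nzchar(names(groups))))
    stop("groups must be a non-empty named list of time grids")
  for (g in names(groups)) {
    grid <- as.numeric(groups[[g]])
    if (length(grid) == 0L || anyNA(grid) || any(grid < 0) ||
        is.unsorted(grid, strictly = TRUE))
      stop("time grid for group '", g,
           "' must be non-empty, non-negative and strictly increasing")
    groups[[g]] <- grid
  }
  structure(groups, class = "study_design")
}

# Accepted source spellings for BLQ in concentration columns.
.blq_sentinels <- c("BLQ", "blq", "<LOQ", "<loq")

#' Read a long-format concentration table
#'
#' Reads a CSV (or an already-loaded data frame) with columns
#' \code{subject_id}, \code{time_h}, \code{conc_mg_per_L} and optionally
#' \code{blq}, and returns one \code{\link{pk_profile}} per subject. BLQ
#' observations may be encoded either as the sentinel strings \code{"BLQ"} /
#' \code{"<LOQ"} in the concentration column or as concentration 0 with a
#' logical \code{blq} column; internally they become concentration 0 with
#' \code{blq = TRUE}.
#'
#' @param source Path to a CSV file (comma-separated, header required, UTF-8,
#'   "." decimal) or a data frame with the columns above.
#'
#' @return A named list of \code{pk_profile} objects, sorted by subject id,
#'   each with points sorted by time. Duplicate (subject, time) pairs and
#'   negative times or concentrations are rejected with an error naming the
#'   offending pair. An empty table yields an empty list with a warning.
#'
#' @seealso \code{\link{write_concentration_table}} for the inverse,
#'   \code{\link{attach_doses}} to add dosing information.
#' @examples
#' csv <- system.file("extdata", "sci_serum_concentrations.csv",
#'                    package = "scipk")
#' profiles <- read_concentration_table(csv)
#' length(profiles)  # 6 rats
#' @export
read_concentration_table <- function(source) {
  tab <- if (is.data.frame(source)) source else
    utils::read.csv(source, stringsAsFactors = FALSE,
                    colClasses = "character", encoding = "UTF-8")
  needed <- c("subject_id", "time_h", "conc_mg_per_L")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0L) {
    warning("empty concentration table; returning no profiles")
    return(structure(list(), names = character(0)))
  }
  conc_raw <- as.character(tab$conc_mg_per_L)
  blq_sent <- conc_raw %in% .blq_sentinels
  conc <- suppressWarnings(as.numeric(conc_raw))
  conc[blq_sent] <- 0
  if (anyNA(conc))
    stop("unparseable concentration value(s): ",
         paste(unique(conc_raw[is.na(conc)]), collapse = ", "))
  blq <- blq_sent
  if ("blq" %in% names(tab)) {
    flag <- .parse_logical(tab$blq)
    blq <- blq | flag
  }
  df <- data.frame(subject_id = as.character(tab$subject_id),
                   time_h = suppressWarnings(as.numeric(as.character(tab$time_h))),
                   conc_mg_per_L = conc, blq = blq,
                   stringsAsFactors = FALSE)
  if (anyNA(df$time_h)) stop("unparseable time value(s)")
  dup <- duplicated(df[c("subject_id", "time_h")])
  if (any(dup)) {
    d <- df[dup, ][1L, ]
    stop("duplicate (subject, time) pair: ('", d$subject_id, "', ",
         d$time_h, " h)")
  }
  df <- df[order(df$subject_id, df$time_h), ]
  profiles <- lapply(split(df, df$subject_id), function(s)
    pk_profile(s$subject_id[1L], s$time_h, s$conc_mg_per_L, s$blq))
  profiles[order(names(profiles))]
}

.parse_logical <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  x %in% c("true", "t", "1", "yes")
}

#' Write profiles back to a long-format concentration CSV
#'
#' Inverse of \code{\link{read_concentration_table}}: emits one row per
#' observation with BLQ encoded as the sentinel string \code{"BLQ"}, so that
#' reading the file back reproduces the profiles exactly.
#'
#' @param profiles List of \code{pk_profile} objects.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_concentration_table <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, as.data.frame))
  out <- data.frame(
    subject_id = rows$subject_id,
    time_h = rows$time_h,
    conc_mg_per_L = ifelse(rows$blq, "BLQ",
                           format(rows$conc_mg_per_L, digits = 15,
                                  trim = TRUE, scientific = FALSE)),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach doses and body weights to profiles
#'
#' @param profiles Named list of \code{pk_profile} objects.
#' @param dose_table Path to a CSV or a data frame with columns
#'   \code{subject_id}, \code{body_weight_g}, \code{dose_mg}.
#' @param expected_mg_per_kg Optional nominal dose rate (mg per kg body
#'   weight). When given, each subject's dose is checked against
#'   \code{body_weight_g / 1000 * expected_mg_per_kg} allowing for rounding of
#'   the recorded dose to two decimals; inconsistencies raise a warning. The
#'   bundled study dosed at 10 mg/kg.
#'
#' @return The profiles with \code{dose_mg} and \code{body_weight_g}
#'   populated. A profile subject absent from the dose table is an error
#'   naming the subject.
#' @examples
#' profs <- read_concentration_table(
#'   system.file("extdata", "sci_serum_concentrations.csv", package = "scipk"))
#' profs <- attach_doses(profs,
#'   system.file("extdata", "sci_doses.csv", package = "scipk"),
#'   expected_mg_per_kg = 10)
#' mean(vapply(profs, function(p) p$dose_mg, numeric(1)))  # 3.92 mg
#' @export
attach_doses <- function(profiles, dose_table, expected_mg_per_kg = NULL) {
  dt <- if (is.data.frame(dose_table)) dose_table else
    utils::read.csv(dose_table, stringsAsFactors = FALSE)
  needed <- c("subject_id", "body_weight_g", "dose_mg")
  if (!all(needed %in% names(dt)))
    stop("dose table must have columns: ", paste(needed, collapse = ", "))
  dt$subject_id <- as.character(dt$subject_id)
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    j <- match(p$subject_id, dt$subject_id)
    if (is.na(j))
      stop("subject '", p$subject_id, "' missing from dose table")
    w <- as.numeric(dt$body_weight_g[j])
    d <- as.numeric(dt$dose_mg[j])
    if (!is.null(expected_mg_per_kg)) {
      nominal <- w / 1000 * expected_mg_per_kg
      # recorded doses are rounded to 2 dp, so allow half a unit in the last place
      if (abs(d - nominal) > 0.005 + 1e-9)
        warning("dose for subject '", p$subject_id, "' (", d,
                " mg) inconsistent with ", expected_mg_per_kg,
                " mg/kg at ", w, " g (expected ~", round(nominal, 3), " mg)")
    }
    p$body_weight_g <- w
    p$dose_mg <- d
    profiles[[i]] <- p
  }
  profiles
}

#' Write NCA results to CSV and JSON
#'
#' Writes one row per profile in the conventional reporting column order
#' (Cmax, Tmax, AUClast, Vd, CL, K, T0.5e, MRT) as both a CSV and a JSON
#' mirror with identical content.
#'
#' @param results Data frame of NCA results, as returned by
#'   \code{\link{nca_results_table}} (must contain the columns listed there).
#' @param path Output path; \code{".csv"} is appended if absent and the JSON
#'   mirror replaces the extension with \code{".json"}.
#' @param digits Optional number of decimal places for rounding at the
#'   reporting layer (half-away-from-zero); internal values are never rounded.
#' @return Invisibly, a character vector of the two files written.
#' @export
write_results <- function(results, path, digits = NULL) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("results must be a nonempty data frame")
  csv_path <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
  json_path <- sub("\\.csv$", ".json", csv_path)
  out <- results
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], round_half_away, digits = digits)
  }
  utils::write.csv(out, csv_path, row.names = FALSE)
  jsonlite::write_json(out, json_path, dataframe = "rows", digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(csv_path, json_path))
}

#' Round half away from zero
#'
#' Reporting-layer rounding matching how PK tables are conventionally
#' printed (2.425 -> 2.43), unlike \code{round()}'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Count BLQ observations across profiles
#'
#' @param profiles List of \code{pk_profile} objects.
#' @return Integer total of BLQ-flagged points.
#' @export
count_blq <- function(profiles) {
  sum(vapply(profiles, function(p) sum(p$points$blq), integer(1)))
}

#' Load the bundled scyllo-inositol rat study
#'
#' Returns the complete serum concentration dataset of the single-oral-dose
#' (10 mg/kg) scyllo-inositol study in six Wistar rats that motivated this
#' package, with doses and body weights attached. Three rats were sampled at
#' 0-24 h and three at 2-48 h (staggered subgroups).
#'
#' @return Named list of six \code{pk_profile} objects.
#' @seealso \code{\link{sci_reference_k}} for the terminal rate constants
#'   reported with this dataset.
#' @export
sci_study_profiles <- function() {
  profs <- read_concentration_table(
    system.file("extdata", "sci_serum_concentrations.csv", package = "scipk"))
  attach_doses(profs,
               system.file("extdata", "sci_doses.csv", package = "scipk"),
               expected_mg_per_kg = 10)
}

#' Reference terminal elimination rate constants for the bundled study
#'
#' The per-rat and pooled terminal rate constants (K, 1/h) reported with the
#' bundled dataset. Their terminal-phase point selection is not documented
#' and cannot be reproduced by contiguous-window log-linear regression on the
#' concentrations (see the methods vignette), so they are provided as fixed
#' inputs for reproducing the reported parameter tables.
#'
#' @return Data frame with columns \code{subject_id} (including the row
#'   \code{"pooled"}) and \code{k_per_h}.
#' @export
sci_reference_k <- function() {
  utils::read.csv(system.file("extdata", "sci_reference_k.csv",
                              package = "scipk"),
                  stringsAsFactors = FALSE,
                  colClasses = c("character", "numeric"))
}
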