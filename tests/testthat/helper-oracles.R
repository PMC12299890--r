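# Independent oracles, kept deliberately separate from the package's own
# code paths: a segment-by-segment trapezoid sum and a direct
# normal-equations log-linear regression.

oracle_trapz <- function(t, c) {
  total <- 0
  for (i in seq_len(length(t) - 1L)) {
    total <- total + (c[i] + c[i + 1L]) / 2 * (t[i + 1L] - t[i])
  }
  total
}

# slope/intercept of ln(c) ~ t by the normal equations
oracle_loglinear <- function(t, c) {
  y <- log(c)
  n <- length(t)
  sx <- sum(t); sy <- sum(y); sxy <- sum(t * y); sxx <- sum(t^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# random strictly-declining quantifiable profile for oracle comparisons
random_declining_profile <- function(n = 5L, id = "rnd") {
  t <- sort(stats::runif(n, 0.5, 24))
  c0 <- stats::runif(1, 5, 10)
  k <- stats::runif(1, 0.05, 0.5)
  conc <- c0 * exp(-k * t) * exp(stats::rnorm(n, 0, 0.05))
  pk_profile(id, t, conc, blq = rep(FALSE, n), dose_mg = 1)
}

# random valid profile collection (possibly with BLQ points) for round trips
random_profile_set <- function(n_subjects = 4L) {
  profs <- list()
  for (i in seq_len(n_subjects)) {
    n <- sample(2:8, 1)
    t <- sort(sample(seq(0, 48, by = 0.25), n))
    conc <- round(stats::runif(n, 0, 8), 3)
    blq <- stats::runif(n) < 0.25
    conc[blq] <- 0
    id <- paste0("s", i)
    profs[[id]] <- pk_profile(id, t, conc, blq = conc == 0)
  }
  profs
}

# compare a computed value against a printed table cell: accept agreement to
# 0.5% relative error, or to one unit in the last printed decimal place
# (absorbs the table's own rounding/truncation of short-printed cells)
expect_printed <- function(actual, printed, label) {
  dp <- nchar(sub("^[^.]*\\.?", "",
                  format(printed, trim = TRUE, scientific = FALSE)))
  ok <- abs(actual - printed) <= 0.005 * abs(printed) + 1e-12 ||
        abs(actual - printed) <= 10^(-dp) + 1e-12
  expect_true(ok, info = sprintf("%s: computed %.6g vs printed %.6g",
                                 label, actual, printed))
}

table2_reference <- function() {
  data.frame(
    subject_id = as.character(1:6),
    cmax = c(7.2, 6.2, 6.8, 3.2, 6.1, 5.4),
    tmax = c(1.5, 1.5, 1, 2, 4, 2),
    auclast = c(40.78, 38.63, 29.7, 11.4, 25.3, 22.6),
    vd = c(0.039, 7.93, 4.578, 0.358, 0.9967, 0.566),
    cl = c(0.1, 0.11, 0.126, 0.325, 0.16, 0.162),
    k = c(2.521, 0.01387, 0.0276, 0.9102, 0.161, 0.2861),
    t_half = c(0.2749, 49.97, 25.14, 0.7615, 4.306, 2.422),
    mrt = c(0.397, 72.09, 36.26, 1.099, 6.212, 3.495),
    stringsAsFactors = FALSE)
}
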