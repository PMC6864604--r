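#' Construct a calibration model from known coefficients
#'
#' The calibration line relates the T/C ratio y to the decadic log of
#' analyte mass, `x = log10(quantity / reference)`, as `y = m x + b`. This
#' constructor wraps externally supplied coefficients (for example a
#' previously published line) in the same object that [fit_calibration()]
#' returns, so either can drive prediction, simulation and classification.
#'
#' @param slope T/C units per decade of analyte mass.
#' @param intercept T/C at the reference quantity.
#' @param reference_fg reference analyte mass (x = 0), femtograms.
#' @param sigma,r_squared,lob optional quality metrics when known.
#' @return An object of class `lfa_calibration`.
#' @export
calibration_model <- function(slope, intercept, reference_fg = 10,
                              sigma = NA_real_, r_squared = NA_real_,
                              lob = 0) {
  stopifnot(reference_fg > 0)
  structure(list(slope = slope, intercept = intercept,
                 reference_fg = reference_fg, sigma = sigma,
                 r_squared = r_squared, lob = lob,
                 lod = if (slope > 0 && !is.na(sigma)) lod(lob, sigma, slope) else NA_real_,
                 loq = if (slope > 0 && !is.na(sigma)) loq(sigma, slope) else NA_real_,
                 n = NA_integer_, diagnostics = NULL),
            class = "lfa_calibration")
}

check_readings <- function(readings) {
  need <- c("quantity_fg", "tc_ratio")
  if (!is.data.frame(readings) || !all(need %in% names(readings))) {
    stop("readings must be a data frame with columns quantity_fg and tc_ratio",
         call. = FALSE)
  }
  if (any(readings$quantity_fg <= 0)) {
    stop("analyte quantities must be positive", call. = FALSE)
  }
  if (any(readings$tc_ratio < 0)) {
    stop("T/C ratios must be non-negative", call. = FALSE)
  }
  readings
}

#' Fit the T/C calibration line
#'
#' Ordinary least squares of the T/C ratio on `x = log10(quantity /
#' reference)`. The standard error of detection sigma is the root mean
#' square of the residuals with divisor N (the reading count, not N - 2),
#' and R-squared is the conventional `1 - SS_res / SS_tot`. The limit of
#' blank defaults to 0 unless blank readings are supplied, in which case
#' `LOB = mean(blanks) + 1.645 sd(blanks)`; LOD and LOQ are reported on the
#' log-quantity axis (see [lod()] and [loq()]).
#'
#' @param readings data frame with columns `quantity_fg` and `tc_ratio`
#'   (extra columns such as `set_id` are carried along untouched).
#' @param reference_fg analyte mass mapped to x = 0 (default 10 fg).
#' @param blanks optional vector of T/C readings from analyte-free strips.
#' @return An `lfa_calibration` with fields `slope`, `intercept`, `sigma`,
#'   `r_squared`, `lob`, `lod`, `loq`, `n` and a `diagnostics` list
#'   (`residuals`, `ss_residual`, `ss_total`, `x`, `y`).
#' @export
fit_calibration <- function(readings, reference_fg = 10, blanks = NULL) {
  readings <- check_readings(readings)
  x <- log10(readings$quantity_fg / reference_fg)
  y <- readings$tc_ratio
  if (length(unique(x)) < 2L) {
    stop("rank deficiency: need readings at two or more distinct quantities",
         call. = FALSE)
  }
  fit <- lm(y ~ x)
  res <- unname(residuals(fit))
  n <- length(y)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  m <- unname(coef(fit)[2])
  b <- unname(coef(fit)[1])
  sigma <- std_error(res, n)
  lob <- if (is.null(blanks)) 0 else mean(blanks) + 1.645 * sd(blanks)
  diag <- list(residuals = res, ss_residual = ss_res, ss_total = ss_tot,
               x = x, y = y)
  structure(list(slope = m, intercept = b, reference_fg = reference_fg,
                 sigma = sigma, r_squared = r_squared(diag),
                 lob = lob,
                 lod = if (m != 0) lod(lob, sigma, m) else NA_real_,
                 loq = if (m != 0) loq(sigma, m) else NA_real_,
                 n = n, diagnostics = diag),
            class = "lfa_calibration")
}

#' @export
print.lfa_calibration <- function(x, ...) {
  cat(sprintf("<lfa_calibration> y = %.4f x + %.4f   (x = log10(quantity / %g fg))\n",
              x$slope, x$intercept, x$reference_fg))
  cat(sprintf("  sigma = %.4f, R^2 = %.4f, n = %s\n",
              x$sigma, x$r_squared, x$n))
  if (!is.na(x$lod)) {
    cat(sprintf("  LOB = %.4f, LOD = %.4f, LOQ = %.4f (log-quantity scale)\n",
                x$lob, x$lod, x$loq))
  }
  invisible(x)
}

#' Coefficient of determination
#'
#' Conventional R-squared, `1 - SS_residual / SS_total`, of a least-squares
#' fit with intercept; always in \[0, 1\].
#'
#' @param diag a diagnostics list with `ss_residual` and `ss_total` (as in
#'   the `diagnostics` field of [fit_calibration()]).
#' @return R-squared value.
#' @export
r_squared <- function(diag) {
  if (diag$ss_total <= 0) {
    stop("degenerate fit: total sum of squares is zero", call. = FALSE)
  }
  1 - diag$ss_residual / diag$ss_total
}

#' Standard error of detection
#'
#' Root mean square of the fit residuals with divisor N.
#'
#' @param residuals residual vector `Y - Y'`.
#' @param n number of data points (defaults to `length(residuals)`).
#' @return sigma >= 0.
#' @export
std_error <- function(residuals, n = length(residuals)) {
  if (n < 1) stop("need at least one residual", call. = FALSE)
  sqrt(sum(residuals^2) / n)
}

#' Limit of detection / quantification
#'
#' `LOD = LOB + 1.645 sigma / m` and `LOQ = 10 sigma / m`, expressed on the
#' calibration x-axis (decades of analyte mass above the reference). Use
#' [quantity_from_x()] to convert to femtograms.
#'
#' @param lob limit of blank on the x scale (0 when no blanks measured).
#' @param sigma standard error of detection.
#' @param m calibration slope (non-zero).
#' @return Value on the log-quantity scale.
#' @export
lod <- function(lob, sigma, m) {
  if (m == 0) stop("calibration slope is zero", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  lob + 1.645 * sigma / m
}

#' @rdname lod
#' @export
loq <- function(sigma, m) {
  if (m == 0) stop("calibration slope is zero", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  10 * sigma / m
}

#' Per-class reading statistics
#'
#' Mean, sample standard deviation (n - 1 divisor) and coefficient of
#' variation `CV = 100 s / mu` percent of the T/C readings for each analyte
#' quantity. CV is `NA` (flagged undefined) where the class mean is zero.
#'
#' @param readings data frame with `quantity_fg` and `tc_ratio`; every class
#'   must have at least two readings.
#' @return Data frame with one row per quantity, ascending: `quantity_fg`,
#'   `n`, `mean`, `sd`, `cv`.
#' @export
class_stats <- function(readings) {
  readings <- check_readings(readings)
  qs <- sort(unique(readings$quantity_fg))
  out <- lapply(qs, function(q) {
    v <- readings$tc_ratio[readings$quantity_fg == q]
    if (length(v) < 2L) {
      stop(sprintf(
        "standard deviation undefined: class %g fg has a single reading", q),
        call. = FALSE)
    }
    mu <- mean(v); s <- sd(v)
    data.frame(quantity_fg = q, n = length(v), mean = mu, sd = s,
               cv = if (mu == 0) NA_real_ else 100 * s / mu)
  })
  do.call(rbind, out)
}

#' Predict analyte quantity from a T/C ratio
#'
#' Inverts the calibration line: `x = (tc - b) / m`, quantity =
#' `reference * 10^x`. Extrapolation beyond the fitted range is permitted;
#' callers that report results flag it via the fitted x range in
#' `diagnostics`.
#'
#' @param tc T/C ratio(s).
#' @param model an `lfa_calibration` with positive slope.
#' @return Analyte mass in femtograms.
#' @export
predict_quantity <- function(tc, model) {
  stopifnot(inherits(model, "lfa_calibration"))
  if (model$slope <= 0) stop("model slope must be > 0", call. = FALSE)
  model$reference_fg * 10^((tc - model$intercept) / model$slope)
}

#' Convert between x scale and quantity
#'
#' @param x value on the log-quantity axis.
#' @param model an `lfa_calibration` (provides the reference quantity).
#' @return [quantity_from_x()]: mass in fg; [x_from_quantity()]: x value.
#' @export
quantity_from_x <- function(x, model) model$reference_fg * 10^x

#' @rdname quantity_from_x
#' @param quantity_fg analyte mass in fg.
#' @export
x_from_quantity <- function(quantity_fg, model) {
  log10(quantity_fg / model$reference_fg)
}

#' Analyte mass / concentration conversions
#'
#' For a sample of `volume_ul` microliters: a concentration of 1 pg/mL
#' corresponds to `volume_ul` femtograms of analyte (e.g. 10 ng/mL in 10 uL
#' is 100 pg). Molarity follows from the molecular weight:
#' 1 pg/mL = (1 / MW) nM for MW in daltons.
#'
#' @param concentration_pg_ml concentration in pg/mL.
#' @param volume_ul sample volume in microliters (> 0).
#' @return [mass_from_concentration()]: mass in fg;
#'   [concentration_from_mass()]: concentration in pg/mL;
#'   [concentration_to_nM()]: molarity in nanomolar.
#' @export
mass_from_concentration <- function(concentration_pg_ml, volume_ul) {
  if (any(volume_ul <= 0)) stop("volume must be > 0", call. = FALSE)
  concentration_pg_ml * volume_ul
}

#' @rdname mass_from_concentration
#' @param mass_fg analyte mass in femtograms.
#' @export
concentration_from_mass <- function(mass_fg, volume_ul) {
  if (any(volume_ul <= 0)) stop("volume must be > 0", call. = FALSE)
  mass_fg / volume_ul
}

#' @rdname mass_from_concentration
#' @param molecular_weight molecular weight in Da.
#' @export
concentration_to_nM <- function(concentration_pg_ml, molecular_weight) {
  if (any(molecular_weight <= 0)) {
    stop("molecular weight must be > 0", call. = FALSE)
  }
  concentration_pg_ml / molecular_weight
}

#' Read or write a readings table
#'
#' CSV with columns `set_id`, `quantity_fg`, `reading_index`, `tc_ratio`.
#'
#' @param path CSV file path.
#' @return [read_readings()]: a data frame; [write_readings()]: `path`,
#'   invisibly.
#' @export
read_readings <- function(path) {
  check_readings(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_readings
#' @param readings a readings data frame.
#' @export
write_readings <- function(readings, path) {
  write.csv(check_readings(readings), path, row.names = FALSE)
  invisible(path)
}
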