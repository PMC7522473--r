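moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

central_diff <- function(y, t) {
  n <- length(y)
  d <- rep(NA_real_, n)
  if (n >= 3L)
    d[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  d
}

validate_timecourse <- function(time, min_points = 3L) {
  if (length(time) < min_points) stop("need at least ", min_points, " points")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
}

#' Specific growth rate from a biomass time course
#'
#' `mu(t) = d ln(OD) / dt` by central finite differences, after optional
#' 3-point (or wider) moving-average pre-smoothing of the OD series.
#' `mu_max` is the maximum over interior points. A regression mode
#' (`method = "regression"`) instead fits `ln(OD) ~ t` over the window of
#' points around the finite-difference maximum, for curves where a point
#' estimate is too noisy.
#'
#' @param time Time in hours, strictly increasing.
#' @param od OD600 values, all > 0 among the points used.
#' @param smoothing Moving-average window (default 1 = no smoothing).
#' @param method `"finite_difference"` (default) or `"regression"`.
#' @param reg_window Points on each side used by the regression mode
#'   (default 2).
#' @return List: `mu` (h^-1 series, `NA` at the ends), `mu_max`,
#'   `t_mu_max`.
#' @export
specific_growth_rate <- function(time, od, smoothing = 1L,
                                 method = c("finite_difference",
                                            "regression"),
                                 reg_window = 2L) {
  method <- match.arg(method)
  validate_timecourse(time)
  if (any(od <= 0)) stop("all OD values must be > 0")
  ods <- moving_average(od, smoothing)
  mu <- central_diff(log(ods), time)
  i <- which.max(mu)
  mu_max <- mu[i]; t_max <- time[i]
  if (method == "regression") {
    lo <- max(1L, i - reg_window); hi <- min(length(time), i + reg_window)
    fit <- lm(log(ods[lo:hi]) ~ time[lo:hi])
    mu_max <- unname(coef(fit)[2L])
  }
  list(mu = mu, mu_max = mu_max, t_mu_max = t_max)
}

#' Volumetric production rate from a product time course
#'
#' Central finite differences on the product concentration series; returns
#' the full rate series and its maximum with the time it occurs.
#'
#' @param time Time in hours, strictly increasing.
#' @param product Product concentration (e.g. riboflavin, ng mL^-1).
#' @param smoothing Moving-average window (default 1).
#' @return List: `rate` series (units of product per hour), `rate_max`,
#'   `t_rate_max`.
#' @export
production_rate <- function(time, product, smoothing = 1L) {
  validate_timecourse(time)
  p <- moving_average(product, smoothing)
  rate <- central_diff(p, time)
  i <- which.max(rate)
  list(rate = rate, rate_max = rate[i], t_rate_max = time[i])
}

#' Bioassay calibration curve
#'
#' Standards (concentration, growth response) for the microbiological
#' riboflavin assay; the fitted response is monotone piecewise-linear and
#' is inverted for quantification.
#'
#' @param concentration Standard concentrations (ng mL^-1), typically
#'   spanning 0-300.
#' @param response Growth responses of the test organism, non-decreasing in
#'   concentration.
#' @return Object of class `calibration_curve`.
#' @export
calibration_curve <- function(concentration, response) {
  o <- order(concentration)
  concentration <- concentration[o]; response <- response[o]
  if (any(diff(response) < 0))
    stop("response must be monotone non-decreasing in concentration")
  structure(list(concentration = concentration, response = response),
            class = "calibration_curve")
}

#' Quantify a sample against a bioassay calibration curve
#'
#' Inverse monotone piecewise-linear interpolation of the response, scaled
#' by the dilution factor. Responses below the span of the lowest standard
#' are flagged as below detection (carrying the detection limit, i.e. the
#' lowest positive standard concentration times the dilution); responses
#' above the top standard are an out-of-range error suggesting a higher
#' dilution.
#'
#' @param curve A [calibration_curve()].
#' @param response Measured growth response (finite scalar).
#' @param dilution Dilution factor applied to the sample (default 1).
#' @return List: `concentration` (or `NA`), `below_detection`,
#'   `detection_limit`.
#' @export
bioassay_quantify <- function(curve, response, dilution = 1) {
  if (!is.finite(response)) stop("response must be finite")
  conc <- curve$concentration; resp <- curve$response
  if (response > max(resp))
    stop("response above the top standard: dilute the sample further")
  pos <- conc[conc > 0]
  limit <- if (length(pos)) min(pos) * dilution else NA_real_
  if (response < min(resp) ||
      (response <= resp[1L] && conc[1L] == 0))
    return(list(concentration = NA_real_, below_detection = TRUE,
                detection_limit = limit))
  est <- approx(resp, conc, xout = response, ties = "ordered")$y
  list(concentration = est * dilution, below_detection = FALSE,
       detection_limit = limit)
}

#' Two-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Type-II sums of squares for the two main effects and their interaction,
#' with Tukey honest-significant-difference p-values (studentized range)
#' for all pairwise level comparisons of each factor and of the cells.
#' Significance is conventionally read at p < 0.05.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factors (or coercible), each with >= 2 levels.
#' @return List: `anova` (type-II table as `data.frame`), `tukey` (list of
#'   `data.frame`s of pairwise comparisons per factor and interaction).
#' @export
two_way_anova_tukey <- function(values, factor_a, factor_b) {
  factor_a <- factor(factor_a); factor_b <- factor(factor_b)
  if (nlevels(factor_a) < 2L || nlevels(factor_b) < 2L)
    stop("each factor needs at least 2 levels")
  dat <- data.frame(y = values, A = factor_a, B = factor_b)
  with_int <- min(table(dat$A, dat$B)) >= 2L
  form <- if (with_int) y ~ A * B else y ~ A + B
  fit <- lm(form, data = dat)
  # degenerate to numerical precision: all observations identical
  degenerate <- sum((dat$y - mean(dat$y))^2) <=
    1e-20 * (1 + mean(dat$y^2)) * length(dat$y)
  if (degenerate) {
    # F = 0, p = 1 by convention
    tab <- as.data.frame(summary(aov(form, data = dat))[[1L]])
    tab[["Sum Sq"]] <- 0
    tab[["Mean Sq"]] <- 0
    tab[[grep("F value", names(tab))]] <-
      c(rep(0, nrow(tab) - 1L), NA_real_)
    tab[[grep("Pr", names(tab))]] <- c(rep(1, nrow(tab) - 1L), NA_real_)
  } else {
    tab <- as.data.frame(car::Anova(fit, type = 2))
  }
  names(tab) <- sub("Pr\\(>F\\)", "p_value", names(tab))
  names(tab) <- sub("F value", "F", names(tab))
  av <- aov(form, data = dat)
  tk <- suppressWarnings(TukeyHSD(av))
  tukey <- lapply(tk, function(m) {
    df <- as.data.frame(m)
    df$comparison <- rownames(m)
    rownames(df) <- NULL
    names(df) <- c("diff", "lwr", "upr", "p_adj", "comparison")
    if (degenerate) { df$diff <- 0; df$lwr <- 0; df$upr <- 0; df$p_adj <- 1 }
    df$p_adj[!is.finite(df$p_adj) & df$diff == 0] <- 1
    df[, c("comparison", "diff", "lwr", "upr", "p_adj")]
  })
  list(anova = tab, tukey = tukey)
}

#' Summary statistics
#'
#' Mean, median (midpoint of the two central order statistics for even n),
#' minimum and maximum of a non-empty numeric vector.
#'
#' @param values Non-empty numeric vector.
#' @return Named list: `mean`, `median`, `min`, `max`, `n`.
#' @export
summary_stats <- function(values) {
  if (length(values) == 0L) stop("empty input")
  list(mean = mean(values), median = median(values),
       min = min(values), max = max(values), n = length(values))
}
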