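#' Magnitude scales for standardized differences and correlations
#'
#' Threshold scales used throughout the statistical layer: standardized
#' differences at 0.2 / 0.6 / 1.2 / 2.0 (trivial, small, moderate, large,
#' very large), correlations at 0.1 / 0.3 / 0.5 / 0.7 / 0.9 (trivial through
#' almost perfect), magnitude-based-inference probability bands at
#' 25 / 75 / 95 / 99 percent (possible, likely, very likely, most likely),
#' and the smallest worthwhile difference of 0.2 standardized units. A value
#' exactly at a threshold takes the lower band's label.
#'
#' @return Named list of thresholds.
#' @export
magnitude_scales <- function() {
  list(d_thresholds = c(0.2, 0.6, 1.2, 2.0),
       r_thresholds = c(0.1, 0.3, 0.5, 0.7, 0.9),
       mbi_bands = c(25, 75, 95, 99),
       swd_factor = 0.2)
}

#' Magnitude label for a standardized difference
#' @param d Standardized difference (sign ignored).
#' @return One of `"trivial"`, `"small"`, `"moderate"`, `"large"`,
#'   `"very large"`.
#' @export
magnitude_d <- function(d) {
  th <- magnitude_scales()$d_thresholds
  labs <- c("trivial", "small", "moderate", "large", "very large")
  labs[findInterval(abs(d), th, left.open = TRUE) + 1]
}

#' Magnitude label for a correlation coefficient
#' @param r Correlation (sign ignored).
#' @return One of `"trivial"`, `"small"`, `"moderate"`, `"large"`,
#'   `"very large"`, `"almost perfect"`.
#' @export
magnitude_r <- function(r) {
  th <- magnitude_scales()$r_thresholds
  labs <- c("trivial", "small", "moderate", "large", "very large",
            "almost perfect")
  labs[findInterval(abs(r), th, left.open = TRUE) + 1]
}

#' Pooled-variance standardized mean difference
#'
#' `d = (mean(B) - mean(A)) / s_pooled` with
#' `s_pooled^2 = ((nA-1) sA^2 + (nB-1) sB^2) / (nA + nB - 2)`, with 90%
#' confidence limits from the large-sample normal approximation on the
#' standard error `sqrt(1/nA + 1/nB + d^2 / (2 (nA + nB)))`, a magnitude
#' label, and a magnitude-based-inference label against the smallest
#' worthwhile difference of 0.2 standardized units.
#'
#' @param group_a,group_b Numeric vectors, each of length `>= 2`.
#' @param conf Confidence level (default 0.90).
#' @return An object of class `effect_result`: list with `d`, `se`, `lower`,
#'   `upper`, `n`, `magnitude`, `mbi`, `method`.
#' @export
cohen_d_pooled <- function(group_a, group_b, conf = 0.90) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2", call. = FALSE)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  md <- mean(b) - mean(a)
  if (sp2 == 0) {
    if (md != 0) {
      stop("infinite standardized difference: zero pooled variance with unequal means",
           call. = FALSE)
    }
    d <- 0
    se <- sqrt(1 / na + 1 / nb)
  } else {
    d <- md / sqrt(sp2)
    se <- sqrt(1 / na + 1 / nb + d^2 / (2 * (na + nb)))
  }
  z <- qnorm(1 - (1 - conf) / 2)
  lower <- d - z * se
  upper <- d + z * se
  structure(list(d = d, se = se, lower = lower, upper = upper,
                 n = c(na, nb), conf = conf,
                 magnitude = magnitude_d(d),
                 mbi = mbi_label(d, lower, upper,
                                 swd = magnitude_scales()$swd_factor,
                                 conf = conf),
                 method = "pooled-SD standardized difference, normal-approx CI"),
            class = "effect_result")
}

#' Percent difference between two groups of positive values
#'
#' Count-type measures are analysed on the natural-log scale: the point
#' estimate is the back-transformed difference of log means minus one, in
#' percent, with a pooled-variance t interval back-transformed the same way.
#' A raw-difference mode (`100 * (mean(B) - mean(A)) / mean(A)` with a
#' delta-method t interval) is provided for data containing zeros.
#'
#' @param group_a,group_b Numeric vectors (strictly positive in log mode).
#' @param conf Confidence level (default 0.90).
#' @param mode `"log"` (default) or `"raw"`.
#' @return An object of class `percent_result`: list with `pct`, `lower`,
#'   `upper`, `pm` (half-width), `mbi`, `method`.
#' @export
percent_difference <- function(group_a, group_b, conf = 0.90,
                               mode = c("log", "raw")) {
  mode <- match.arg(mode)
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2", call. = FALSE)
  df <- na + nb - 2
  crit <- qt(1 - (1 - conf) / 2, df)
  if (mode == "log") {
    if (any(a <= 0) || any(b <= 0)) {
      stop("non-positive values: use mode = \"raw\" for data with zeros",
           call. = FALSE)
    }
    la <- log(a); lb <- log(b)
    sp <- sqrt(((na - 1) * var(la) + (nb - 1) * var(lb)) / df)
    delta <- mean(lb) - mean(la)
    se <- sp * sqrt(1 / na + 1 / nb)
    pct <- 100 * (exp(delta) - 1)
    lower <- 100 * (exp(delta - crit * se) - 1)
    upper <- 100 * (exp(delta + crit * se) - 1)
    swd <- magnitude_scales()$swd_factor * sp
    mbi <- if (sp > 0) {
      mbi_label(delta, delta - crit * se, delta + crit * se, swd = swd,
                df = df, conf = conf)
    } else {
      list(label = "most likely", direction = "trivial", probabilities =
             c(positive = 0, trivial = 1, negative = 0))
    }
  } else {
    if (mean(a) == 0) stop("comparator group mean is zero", call. = FALSE)
    sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / df)
    delta <- mean(b) - mean(a)
    se <- sp * sqrt(1 / na + 1 / nb)
    pct <- 100 * delta / mean(a)
    lower <- 100 * (delta - crit * se) / mean(a)
    upper <- 100 * (delta + crit * se) / mean(a)
    swd <- magnitude_scales()$swd_factor * sp
    mbi <- if (sp > 0) {
      mbi_label(delta, delta - crit * se, delta + crit * se, swd = swd,
                df = df, conf = conf)
    } else {
      list(label = "most likely", direction = "trivial", probabilities =
             c(positive = 0, trivial = 1, negative = 0))
    }
  }
  structure(list(pct = pct, lower = lower, upper = upper,
                 pm = (upper - lower) / 2, conf = conf, mbi = mbi,
                 method = paste0(mode, "-scale percent difference, pooled t interval")),
            class = "percent_result")
}

#' Magnitude-based-inference label
#'
#' Computes the probabilities that the true effect is substantially positive
#' (`> +swd`), trivial (within `+/- swd`) or substantially negative
#' (`< -swd`) from the t (or normal) sampling distribution of the estimate,
#' and labels the most probable class with the qualitative probability bands
#' (25-75% possible, 75-95% likely, 95-99% very likely, >99% most likely).
#' When the confidence interval overlaps both `+swd` and `-swd` the effect
#' is `"unclear"`.
#'
#' @param est Point estimate (any effect scale).
#' @param lower,upper Confidence limits of the estimate at level `conf`.
#' @param swd Smallest worthwhile difference on the same scale (`> 0`).
#' @param df Degrees of freedom for the t distribution (`Inf` = normal).
#' @param conf Confidence level the limits were computed at.
#' @return List with `label`, `direction` (`"positive"`, `"trivial"`,
#'   `"negative"` or `"unclear"`), and the three `probabilities` (sum to 1).
#' @export
mbi_label <- function(est, lower, upper, swd = 0.2, df = Inf, conf = 0.90) {
  if (swd <= 0) stop("swd must be > 0", call. = FALSE)
  crit <- if (is.finite(df)) qt(1 - (1 - conf) / 2, df) else qnorm(1 - (1 - conf) / 2)
  se <- (upper - lower) / (2 * crit)
  if (se <= 0) {
    probs <- c(positive = as.numeric(est > swd),
               trivial = as.numeric(abs(est) <= swd),
               negative = as.numeric(est < -swd))
  } else {
    p_pos <- if (is.finite(df)) 1 - pt((swd - est) / se, df) else 1 - pnorm((swd - est) / se)
    p_neg <- if (is.finite(df)) pt((-swd - est) / se, df) else pnorm((-swd - est) / se)
    probs <- c(positive = p_pos, trivial = 1 - p_pos - p_neg, negative = p_neg)
  }
  if (lower < -swd && upper > swd) {
    return(list(label = "unclear", direction = "unclear",
                probabilities = probs))
  }
  k <- which.max(probs)
  p <- 100 * probs[k]
  bands <- magnitude_scales()$mbi_bands
  # a probability exactly at a band boundary takes the lower band's label;
  # the 1e-9 slack keeps that convention stable under floating point
  label <- if (p <= bands[2] + 1e-9) "possible"
           else if (p <= bands[3] + 1e-9) "likely"
           else if (p <= bands[4] + 1e-9) "very likely" else "most likely"
  list(label = label,
       direction = c("positive", "trivial", "negative")[k],
       probabilities = probs)
}

#' Pearson correlation with Fisher-z confidence limits
#'
#' Correlation over complete pairs, a 90% interval via the Fisher z
#' transform (`tanh(atanh(r) +/- z* / sqrt(n - 3))`), a magnitude label from
#' the correlation scale, and a clarity flag: the correlation is `"unclear"`
#' when the interval spans zero.
#'
#' @param x,y Numeric vectors.
#' @param conf Confidence level (default 0.90).
#' @return An object of class `correlation_result`: list with `r`, `lower`,
#'   `upper`, `n`, `magnitude`, `clarity`.
#' @export
pearson_ci <- function(x, y, conf = 0.90) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  r <- cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    lower <- upper <- r
  } else {
    half <- qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
    lower <- tanh(atanh(r) - half)
    upper <- tanh(atanh(r) + half)
  }
  structure(list(r = r, lower = lower, upper = upper, n = n, conf = conf,
                 magnitude = magnitude_r(r),
                 clarity = if (lower < 0 && upper > 0) "unclear" else "clear"),
            class = "correlation_result")
}

#' Shooting efficacy
#'
#' `goals * 100 / shots`, reported to one decimal place.
#'
#' @param goals,shots Non-negative integer counts, `shots >= 1`,
#'   `goals <= shots`.
#' @return Percentage, rounded to 1 decimal.
#' @export
efficacy <- function(goals, shots) {
  if (shots < 1) stop("efficacy undefined for shots < 1", call. = FALSE)
  if (goals < 0 || goals > shots) {
    stop("goals must satisfy 0 <= goals <= shots", call. = FALSE)
  }
  round(goals * 100 / shots, 1)
}

#' @export
print.effect_result <- function(x, ...) {
  inf <- if (x$mbi$label == "unclear") "unclear"
         else paste(x$mbi$label, x$mbi$direction)
  cat(sprintf("d = %.2f [%.0f%% CI %.2f; %.2f], %s, %s\n",
              x$d, 100 * x$conf, x$lower, x$upper, x$magnitude, inf))
  invisible(x)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.2f [%.0f%% CI %.2f; %.2f], %s (%s), n = %d\n",
              x$r, 100 * x$conf, x$lower, x$upper, x$magnitude, x$clarity,
              x$n))
  invisible(x)
}
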