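#' Convergence regression samples
#'
#' A `conv_sample` has one row per (country, base_year) interval with the
#' base-year fertility level, the growth ratio that forms the regression
#' outcome, and bookkeeping columns. Two constructors exist:
#' [build_time_sample()] for the classical growth-over-time statistic and
#' [build_edu_sample()] for growth-over-education, the statistic at the
#' heart of the package.
#' @name conv_sample
NULL

# Reshape one indicator of a long panel into a country x year matrix on the
# panel's lattice; fast path used by the sample builders and the simulator.
indicator_matrix <- function(panel, indicator) {
  sub <- panel[panel$indicator == indicator, , drop = FALSE]
  if (nrow(sub) == 0) {
    fc_abort(paste0("indicator '", indicator, "' not present in panel"),
             class = "fc_specification_error")
  }
  countries <- sort(unique(sub$country_id))
  years <- sort(unique(sub$year))
  m <- matrix(NA_real_, length(countries), length(years),
              dimnames = list(countries, as.character(years)))
  m[cbind(match(sub$country_id, countries), match(sub$year, years))] <- sub$value
  m
}

new_conv_sample <- function(df, counts = list()) {
  df <- tibble::as_tibble(df)
  class(df) <- c("conv_sample", class(tibble::tibble()))
  for (nm in names(counts)) attr(df, nm) <- counts[[nm]]
  df
}

#' Build the growth-over-time sample (classical beta-convergence)
#'
#' For every country and lattice base year `t` with an observation at
#' `t + horizon`, computes the annualized log growth rate
#' `(ln Y\[t+horizon\] - ln Y\[t\]) / horizon` and pairs it with the base
#' level `Y\[t\]`. Nonpositive fertility values make the log undefined; the
#' affected intervals are excluded and counted.
#'
#' @param panel a `conv_panel`.
#' @param fert name of the fertility indicator.
#' @param horizon interval length in years (a lattice multiple; default 5).
#' @return a `conv_sample` with columns `country_id`, `base_year`,
#'   `base_fertility`, `ratio`, `delta_edu` (NA here).
#' @export
build_time_sample <- function(panel, fert, horizon = 5L) {
  m <- indicator_matrix(panel, fert)
  years <- as.integer(colnames(m))
  tmat <- interval_table(m, years, horizon)
  ok_pos <- tmat$y1 > 0 & tmat$y2 > 0 & !is.na(tmat$y1) & !is.na(tmat$y2)
  n_nonpos <- sum(!is.na(tmat$y1) & !is.na(tmat$y2) & !(tmat$y1 > 0 & tmat$y2 > 0))
  if (n_nonpos > 0) {
    fc_log("build_time_sample: excluded ", n_nonpos,
           " interval(s) with nonpositive fertility")
  }
  keep <- ok_pos
  out <- tibble::tibble(
    country_id = tmat$country[keep],
    base_year = tmat$year[keep],
    base_fertility = tmat$y1[keep],
    ratio = (log(tmat$y2[keep]) - log(tmat$y1[keep])) / horizon,
    delta_edu = NA_real_
  )
  new_conv_sample(out, list(n_nonpositive = n_nonpos, horizon = horizon))
}

# Enumerate (country, t, t+horizon) value pairs from a country x year matrix.
interval_table <- function(m, years, horizon) {
  idx2 <- match(years + horizon, years)
  has <- which(!is.na(idx2))
  if (length(has) == 0) {
    fc_abort("no year pairs at the requested horizon", class = "fc_empty_sample_error")
  }
  country <- rep(rownames(m), times = length(has))
  year <- rep(years[has], each = nrow(m))
  y1 <- as.vector(m[, has, drop = FALSE])
  y2 <- as.vector(m[, idx2[has], drop = FALSE])
  list(country = country, year = year, y1 = y1, y2 = y2)
}

#' Build the growth-over-education sample
#'
#' The outcome is the change in log fertility divided by the contemporaneous
#' change in an education indicator:
#' `(ln FER\[t+h\] - ln FER\[t\]) / (EDU\[t+h\] - EDU\[t\])`,
#' regressed later on the base fertility level. Intervals with an education
#' change smaller than `tol` in absolute value are excluded (the statistic is
#' undefined at zero and explodes near it) and counted in the
#' `n_zero_delta` attribute; nonpositive fertility intervals are likewise
#' excluded and counted. Optional covariates are attached at their base-year
#' values; intervals missing a covariate are dropped with a logged count.
#'
#' @param panel a `conv_panel` holding both indicators on a common lattice.
#' @param fert,edu indicator names.
#' @param horizon interval length in years (default 5).
#' @param tol exclusion tolerance for `|delta_edu|`, in the education
#'   indicator's units (default 1e-9).
#' @param covariates character vector of indicator names to carry as
#'   base-year covariate columns.
#' @param drop_negative_delta exclude intervals where education declined?
#'   Default `FALSE`: small declines (e.g. cohort attrition) are retained and
#'   the outlier fence handles any extreme ratios they produce.
#' @return a `conv_sample`; attributes `n_zero_delta`, `n_nonpositive`,
#'   `n_missing_covariate` count exclusions.
#' @export
build_edu_sample <- function(panel, fert, edu, horizon = 5L, tol = 1e-9,
                             covariates = NULL, drop_negative_delta = FALSE) {
  mf <- indicator_matrix(panel, fert)
  me <- indicator_matrix(panel, edu)
  common <- intersect(rownames(mf), rownames(me))
  yrs <- intersect(colnames(mf), colnames(me))
  mf <- mf[common, yrs, drop = FALSE]
  me <- me[common, yrs, drop = FALSE]
  years <- as.integer(yrs)
  tf <- interval_table(mf, years, horizon)
  te <- interval_table(me, years, horizon)

  present <- !is.na(tf$y1) & !is.na(tf$y2) & !is.na(te$y1) & !is.na(te$y2)
  pos <- tf$y1 > 0 & tf$y2 > 0
  delta <- te$y2 - te$y1
  zero <- abs(delta) < tol
  neg <- delta < 0 & !zero

  n_nonpos <- sum(present & !pos)
  n_zero <- sum(present & pos & zero)
  n_neg_dropped <- 0L
  keep <- present & pos & !zero
  if (isTRUE(drop_negative_delta)) {
    n_neg_dropped <- sum(keep & neg)
    keep <- keep & !neg
  }
  if (n_nonpos > 0) fc_log("build_edu_sample: excluded ", n_nonpos,
                           " interval(s) with nonpositive fertility")
  if (n_zero > 0) fc_log("build_edu_sample: excluded ", n_zero,
                         " interval(s) with |delta_edu| < ", format(tol))
  if (n_neg_dropped > 0) fc_log("build_edu_sample: excluded ", n_neg_dropped,
                                " interval(s) with negative delta_edu")
  if (!any(keep)) {
    fc_abort("no usable intervals remain (all excluded)",
             class = "fc_empty_sample_error")
  }

  out <- tibble::tibble(
    country_id = tf$country[keep],
    base_year = tf$year[keep],
    base_fertility = tf$y1[keep],
    ratio = (log(tf$y2[keep]) - log(tf$y1[keep])) / delta[keep],
    delta_edu = delta[keep]
  )

  n_missing_cov <- 0L
  for (cv in covariates %||% character(0)) {
    mc <- indicator_matrix(panel, cv)
    val <- rep(NA_real_, nrow(out))
    ci <- match(out$country_id, rownames(mc))
    yi <- match(as.character(out$base_year), colnames(mc))
    okc <- !is.na(ci) & !is.na(yi)
    val[okc] <- mc[cbind(ci[okc], yi[okc])]
    out[[cv]] <- val
  }
  if (length(covariates %||% character(0)) > 0) {
    cc <- stats::complete.cases(out[, covariates, drop = FALSE])
    n_missing_cov <- sum(!cc)
    if (n_missing_cov > 0) {
      fc_log("build_edu_sample: dropped ", n_missing_cov,
             " interval(s) missing covariate values")
      out <- out[cc, , drop = FALSE]
    }
    if (nrow(out) == 0) {
      fc_abort("no intervals with complete covariates remain",
               class = "fc_empty_sample_error")
    }
  }

  new_conv_sample(out, list(
    n_zero_delta = n_zero, n_nonpositive = n_nonpos,
    n_negative_delta_dropped = n_neg_dropped,
    n_missing_covariate = n_missing_cov,
    horizon = horizon, covariates = covariates %||% character(0)
  ))
}

#' Trim extreme growth ratios with an interquartile-range fence
#'
#' Small education changes can make the growth-over-education ratio explode;
#' rows whose ratio falls outside
#' `\[Q1 - k * IQR, Q3 + k * IQR\]` are removed, with quartiles computed on
#' the input sample's ratio distribution (type-7 sample quantiles, R's
#' default). The default multiplier is `k = 3`. A degenerate sample with
#' IQR = 0 keeps exactly the rows lying in the (collapsed) quartile band.
#' Trimming is applied once per regression cell, before standardization.
#'
#' @param sample a `conv_sample`.
#' @param k fence multiplier (default 3).
#' @return the retained `conv_sample`; attributes `removed` (the trimmed
#'   rows), `n_trimmed` and `fences` record what was cut.
#' @export
trim_outliers <- function(sample, k = 3) {
  if (nrow(sample) == 0) {
    fc_abort("cannot trim an empty sample", class = "fc_empty_sample_error")
  }
  q <- stats::quantile(sample$ratio, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  keep <- sample$ratio >= lo & sample$ratio <= hi
  removed <- sample[!keep, , drop = FALSE]
  out <- sample[keep, , drop = FALSE]
  if (nrow(removed) > 0) {
    fc_log("trim_outliers: removed ", nrow(removed), " ratio outlier(s) outside [",
           format(lo), ", ", format(hi), "]")
  }
  counts <- attributes(sample)[c("n_zero_delta", "n_nonpositive",
                                 "n_missing_covariate", "horizon", "covariates")]
  counts <- counts[!vapply(counts, is.null, logical(1))]
  counts$removed <- removed
  counts$n_trimmed <- nrow(removed)
  counts$fences <- c(lower = lo, upper = hi)
  new_conv_sample(out, counts)
}

#' Z-score the estimation sample
#'
#' Replaces `ratio`, `base_fertility` and any covariate columns by
#' `(x - mean) / sd` (sample sd, n - 1 denominator), computed on the rows of
#' the sample as given — i.e. on the post-trimming estimation sample, so the
#' fitted slope is a standardized coefficient comparable across differently
#' scaled indicators. Zero variance in any standardized column is an error.
#'
#' @param sample a `conv_sample` (typically after [trim_outliers()]).
#' @param columns columns to standardize; defaults to `ratio`,
#'   `base_fertility` and the sample's covariate columns.
#' @return the standardized `conv_sample`; attribute `scaling` records the
#'   means and sds used.
#' @export
standardize_sample <- function(sample, columns = NULL) {
  columns <- columns %||% c("ratio", "base_fertility",
                            attr(sample, "covariates") %||% character(0))
  if (nrow(sample) < 2) {
    fc_abort("need at least 2 rows to standardize", class = "fc_degenerate_error")
  }
  scaling <- list()
  for (cl in columns) {
    x <- sample[[cl]]
    mu <- mean(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      fc_abort(paste0("column '", cl, "' has zero variance; cannot standardize"),
               class = "fc_degenerate_error")
    }
    sample[[cl]] <- (x - mu) / s
    scaling[[cl]] <- c(mean = mu, sd = s)
  }
  attr(sample, "scaling") <- scaling
  sample
}

#' Write a convergence sample to CSV
#'
#' Retained rows get `retained_flag = TRUE`; rows removed by
#' [trim_outliers()] (if the sample carries them) are appended with
#' `retained_flag = FALSE`.
#'
#' @param sample a `conv_sample`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample <- function(sample, path) {
  out <- tibble::as_tibble(sample)
  out$retained_flag <- TRUE
  removed <- attr(sample, "removed")
  if (!is.null(removed) && nrow(removed) > 0) {
    removed <- tibble::as_tibble(removed)
    removed$retained_flag <- FALSE
    out <- dplyr::bind_rows(out, removed)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.conv_sample <- function(x, ...) {
  cat("<conv_sample> ", nrow(x), " intervals, ",
      length(unique(x$country_id)), " countries\n", sep = "")
  NextMethod()
}
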