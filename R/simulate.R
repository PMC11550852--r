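#' Scenario configuration for the synthetic panel generator
#'
#' Describes a balanced quinquennial country panel whose fertility evolves
#' by the generative counterpart of the convergence model: per interval,
#' `ln FER\[t+step\] = ln FER\[t\] + (alpha + beta * FER\[t\] + gamma_i +
#' eps_it) * (EDU\[t+step\] - EDU\[t\])`, with country intercepts
#' `gamma_i ~ N(0, fe_sd^2)` and shocks `eps_it ~ N(0, noise_sd^2)`.
#' Education expands along per-country logistic paths. Because the
#' estimating equation is also the data-generating process, the planted
#' `true_beta` is the exact estimand and parameter recovery is testable.
#'
#' @param n_countries number of countries (default 146, the balanced-panel
#'   scale of the real linked data).
#' @param year_start,year_end,step lattice of observation years (default
#'   1950 to 2015 every 5 years, i.e. 14 points).
#' @param true_beta planted convergence coefficient on the unstandardized
#'   scale (growth-ratio units per fertility unit).
#' @param alpha baseline drift per education unit; negative for level-like
#'   indicators (fertility falls as education expands), positive for
#'   age-like ones (ages at childbearing rise).
#' @param fe_sd,noise_sd standard deviations of the country intercepts and
#'   the interval shocks, in drift units.
#' @param edu_init,edu_asymptote,edu_midpoint,edu_rate uniform ranges from
#'   which each country's logistic education path draws its start level,
#'   ceiling (years of schooling), midpoint year and rate per year.
#' @param fert_init uniform range of initial fertility.
#' @param indicator_kind `"level"` (TFR/NRR-like, declining) or `"age"`
#'   (MACB-like, rising). Chooses defaults for `alpha`, `true_beta`,
#'   `fert_init` and `clip` when those are not given.
#' @param indicator,edu_indicator names used in the emitted panels.
#' @param clip admissible fertility range; paths stepping outside are
#'   clipped with a warning (or re-drawn when `strict = TRUE`).
#' @param income_props named proportions for the four income groups (must
#'   sum to 1).
#' @param ssa_share share of countries labelled sub-Saharan African.
#' @param stall_share share of country-intervals whose education change is
#'   collapsed to (almost) zero, to exercise the exclusion path.
#' @param strict re-draw out-of-range fertility shocks instead of clipping.
#' @param seed integer seed; all draws are reproducible from it.
#' @return a `conv_scenario` list.
#' @export
scenario_config <- function(n_countries = 146L,
                            year_start = 1950L, year_end = 2015L, step = 5L,
                            true_beta = NULL, alpha = NULL,
                            fe_sd = 0.01, noise_sd = 0.02,
                            edu_init = c(0.5, 4),
                            edu_asymptote = c(8, 14),
                            edu_midpoint = c(1965, 2000),
                            edu_rate = c(0.04, 0.12),
                            fert_init = NULL,
                            indicator_kind = c("level", "age"),
                            indicator = "TFR", edu_indicator = "edu_years",
                            clip = NULL,
                            income_props = c(low = 0.25, `lower-middle` = 0.25,
                                             `upper-middle` = 0.25, high = 0.25),
                            ssa_share = 0.2,
                            stall_share = 0, strict = FALSE, seed = NULL) {
  indicator_kind <- match.arg(indicator_kind)
  if (indicator_kind == "level") {
    true_beta <- true_beta %||% -0.04
    alpha <- alpha %||% -0.02
    fert_init <- fert_init %||% c(1.5, 8)
    clip <- clip %||% c(0.5, 12)
  } else {
    true_beta <- true_beta %||% -0.008
    alpha <- alpha %||% 0.28
    fert_init <- fert_init %||% c(26, 34)
    clip <- clip %||% c(20, 48)
  }
  years <- seq.int(as.integer(year_start), as.integer(year_end), by = as.integer(step))
  if (length(years) < 3) {
    fc_abort("lattice must have at least 3 points", class = "fc_config_error")
  }
  if (n_countries < 2) {
    fc_abort("need at least 2 countries", class = "fc_config_error")
  }
  if (fe_sd < 0 || noise_sd < 0) {
    fc_abort("fe_sd and noise_sd must be nonnegative", class = "fc_config_error")
  }
  if (abs(sum(income_props) - 1) > 1e-8) {
    fc_abort("income_props must sum to 1", class = "fc_config_error")
  }
  structure(list(
    n_countries = as.integer(n_countries), years = years, step = as.integer(step),
    true_beta = true_beta, alpha = alpha, fe_sd = fe_sd, noise_sd = noise_sd,
    edu_init = edu_init, edu_asymptote = edu_asymptote,
    edu_midpoint = edu_midpoint, edu_rate = edu_rate,
    fert_init = fert_init, indicator_kind = indicator_kind,
    indicator = indicator, edu_indicator = edu_indicator, clip = clip,
    income_props = income_props, ssa_share = ssa_share,
    stall_share = stall_share, strict = strict,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "conv_scenario")
}

#' Canonical divergence scenario for sign-symmetry checks
#'
#' Planting a positive convergence coefficient makes the generative
#' recursion self-reinforcing: trajectories fan out, and with a wide initial
#' fertility band a tail of countries escapes the admissible range in finite
#' education change (the drift `alpha + beta * F` has an unstable fixed
#' point at `-alpha/beta`, and paths beyond it blow up). A well-posed
#' divergence experiment therefore starts from a compact initial band lying
#' entirely below the unstable point, so every trajectory declines — the
#' laggards decelerating, dispersion growing — and none reaches a boundary.
#' This helper encodes that design: `beta = +0.04`, `alpha = -0.18`
#' (unstable point at TFR 4.5, above the initial band of 2.5–4), and a
#' moderate education expansion.
#'
#' @param n_countries number of countries.
#' @param noise_sd,fe_sd shock and country-intercept sds.
#' @param seed integer seed.
#' @return a `conv_scenario`.
#' @export
divergence_scenario <- function(n_countries = 150L, noise_sd = 0.02,
                                fe_sd = 0.01, seed = NULL) {
  scenario_config(n_countries = n_countries, true_beta = 0.04, alpha = -0.18,
                  fert_init = c(2.5, 4), edu_init = c(0.5, 3),
                  edu_asymptote = c(6, 10),
                  noise_sd = noise_sd, fe_sd = fe_sd, seed = seed)
}

#' @export
print.conv_scenario <- function(x, ...) {
  cat("<conv_scenario> ", x$n_countries, " countries, years ",
      min(x$years), "-", max(x$years), " step ", x$step,
      "; beta = ", x$true_beta, ", alpha = ", x$alpha,
      ", fe_sd = ", x$fe_sd, ", noise_sd = ", x$noise_sd,
      ", seed = ", x$seed %||% NA, "\n", sep = "")
  invisible(x)
}

country_ids <- function(n) sprintf("C%03d", seq_len(n))

with_subseed <- function(seed, offset, expr) {
  if (!is.null(seed)) set.seed((seed + offset) %% .Machine$integer.max)
  force(expr)
}

# Logistic expansion re-anchored so the path starts exactly at the initial
# level: E(t) = e0 + (asym - e0) * (s(t) - s(t0)) / (1 - s(t0)) with
# s(t) = plogis(rate * (t - midpoint)). Monotone nondecreasing; flat in the
# rate -> 0 limit; never exceeds the asymptote.
edu_paths_matrix <- function(years, e0, asym, mid, rate) {
  n <- length(e0)
  tmat <- matrix(rep(years, each = n), n, length(years))
  s <- stats::plogis(rate * (tmat - mid))
  s0 <- stats::plogis(rate * (years[1] - mid))
  e0 + (asym - e0) * (s - s0) / (1 - s0)
}

#' Simulate education expansion paths
#'
#' Each country gets a logistic years-of-schooling trajectory on the
#' lattice: monotone nondecreasing, starting at a drawn initial level and
#' saturating toward a drawn asymptote (at most 16 years). With
#' `stall_share > 0`, a random subset of country-intervals has its education
#' increment collapsed to near zero to exercise the downstream exclusion
#' rule.
#'
#' @param config a `conv_scenario`.
#' @return a `conv_panel` of the education indicator; attribute `params`
#'   holds the per-country path parameters.
#' @export
simulate_education <- function(config) {
  n <- config$n_countries
  years <- config$years
  ids <- country_ids(n)
  with_subseed(config$seed, 1L, {
    e0 <- runif(n, config$edu_init[1], config$edu_init[2])
    asym <- pmin(runif(n, config$edu_asymptote[1], config$edu_asymptote[2]), 16)
    mid <- runif(n, config$edu_midpoint[1], config$edu_midpoint[2])
    rate <- runif(n, config$edu_rate[1], config$edu_rate[2])
    E <- edu_paths_matrix(years, e0, asym, mid, rate)
    if (config$stall_share > 0) {
      inc <- E[, -1, drop = FALSE] - E[, -ncol(E), drop = FALSE]
      stall <- matrix(runif(length(inc)) < config$stall_share,
                      nrow(inc), ncol(inc))
      inc[stall] <- inc[stall] * 1e-12
      E <- cbind(E[, 1], t(apply(inc, 1, cumsum)) + E[, 1])
    }
  })
  dimnames(E) <- list(ids, as.character(years))
  panel <- matrix_to_panel(E, config$edu_indicator)
  attr(panel, "params") <- tibble::tibble(
    country_id = ids, edu_init = e0, asymptote = asym, midpoint = mid, rate = rate
  )
  panel
}

matrix_to_panel <- function(M, indicator) {
  df <- tibble::tibble(
    country_id = rep(rownames(M), times = ncol(M)),
    year = rep(as.integer(colnames(M)), each = nrow(M)),
    indicator = indicator,
    value = as.vector(M)
  )
  conv_panel(df)
}

#' Simulate fertility paths driven by education change
#'
#' Runs the generative recursion (see [scenario_config()]) along the
#' education paths. Age-like indicators use a positive baseline drift so
#' trajectories rise; with a negative planted `true_beta`, countries with a
#' low mean age at childbearing then rise faster — the age-convergence sign
#' convention. Paths stepping outside the admissible `clip` range are
#' clipped with a warning; under `strict = TRUE` the offending shocks are
#' re-drawn (up to 100 attempts) instead.
#'
#' @param config a `conv_scenario`.
#' @param education education `conv_panel` from [simulate_education()].
#' @return a `conv_panel` of the fertility indicator; attribute `truth`
#'   holds `gamma`, initial values, and the realized path matrix.
#' @export
simulate_fertility <- function(config, education) {
  E <- indicator_matrix(education, config$edu_indicator)
  n <- nrow(E)
  Tn <- ncol(E)
  with_subseed(config$seed, 3L, {
    gamma <- rnorm(n, 0, config$fe_sd)
    f0 <- runif(n, config$fert_init[1], config$fert_init[2])
    Fm <- matrix(NA_real_, n, Tn, dimnames = dimnames(E))
    Fm[, 1] <- f0
    lnF <- log(f0)
    lo <- log(config$clip[1]); hi <- log(config$clip[2])
    n_clipped <- 0L
    for (t in seq_len(Tn - 1)) {
      dE <- E[, t + 1] - E[, t]
      eps <- rnorm(n, 0, config$noise_sd)
      cand <- lnF + (config$alpha + config$true_beta * Fm[, t] + gamma + eps) * dE
      if (isTRUE(config$strict) && config$noise_sd > 0) {
        bad <- which(cand < lo | cand > hi)
        tries <- 0L
        while (length(bad) > 0 && tries < 100L) {
          eps[bad] <- rnorm(length(bad), 0, config$noise_sd)
          cand[bad] <- lnF[bad] +
            (config$alpha + config$true_beta * Fm[bad, t] + gamma[bad] + eps[bad]) * dE[bad]
          bad <- bad[cand[bad] < lo | cand[bad] > hi]
          tries <- tries + 1L
        }
        if (length(bad) > 0) {
          fc_abort("could not keep fertility in range after 100 redraws",
                   class = "fc_simulation_error")
        }
      }
      out_of_range <- cand < lo | cand > hi
      n_clipped <- n_clipped + sum(out_of_range)
      lnF <- pmin(pmax(cand, lo), hi)
      Fm[, t + 1] <- exp(lnF)
    }
  })
  if (n_clipped > 0) {
    rlang::warn(paste0("simulate_fertility: clipped ", n_clipped,
                       " step(s) to the admissible range ",
                       "[", config$clip[1], ", ", config$clip[2], "]"),
                class = "fc_clip_warning")
  }
  panel <- matrix_to_panel(Fm, config$indicator)
  attr(panel, "truth") <- list(gamma = stats::setNames(gamma, rownames(E)),
                               fert_init = stats::setNames(f0, rownames(E)),
                               paths = Fm, n_clipped = n_clipped)
  panel
}

#' Generate per-country metadata labels
#'
#' Assigns income groups with exact stated proportions and a sub-Saharan
#' Africa flag. When initial fertility values are supplied, assignment is
#' rank-correlated with them (high-fertility countries lean low-income and
#' SSA), mimicking the regional structure that makes subgroup analyses
#' informative.
#'
#' @param config a `conv_scenario`.
#' @param fert_init optional named vector of initial fertility by country.
#' @return a tibble with `country_id`, `income_group`, `is_ssa`.
#' @export
make_metadata <- function(config, fert_init = NULL) {
  n <- config$n_countries
  ids <- country_ids(n)
  props <- config$income_props
  if (abs(sum(props) - 1) > 1e-8) {
    fc_abort("income_props must sum to 1", class = "fc_config_error")
  }
  counts <- diff(c(0, round(cumsum(props) * n)))
  with_subseed(config$seed, 2L, {
    if (is.null(fert_init)) {
      score <- runif(n)
    } else {
      # noisy rank: high fertility -> high score -> poorer group
      score <- rank(fert_init[ids]) + rnorm(n, 0, n / 10)
    }
    ord <- order(score, decreasing = TRUE)
    grp <- rep(names(props), times = counts)
    income <- character(n)
    income[ord] <- grp
    n_ssa <- round(config$ssa_share * n)
    is_ssa <- rep(FALSE, n)
    if (n_ssa > 0) is_ssa[order(score, decreasing = TRUE)[seq_len(n_ssa)]] <- TRUE
  })
  tibble::tibble(country_id = ids, income_group = income, is_ssa = is_ssa)
}

#' Run a full synthetic scenario
#'
#' Simulates education, fertility and metadata, links the panels on the
#' lattice, and returns everything together with the ground truth needed for
#' parameter-recovery checks.
#'
#' @param config a `conv_scenario`.
#' @return a `conv_simulation` list: `panel` (linked `conv_panel` with
#'   metadata columns), `metadata`, `truth` (planted `true_beta`, `alpha`,
#'   per-country `gamma`, paths), `config`.
#' @export
simulate_scenario <- function(config) {
  edu <- simulate_education(config)
  fert <- simulate_fertility(config, edu)
  truth <- attr(fert, "truth")
  meta <- make_metadata(config, fert_init = truth$fert_init)
  panel <- link_panels(fert, edu, step = config$step, require_balanced = TRUE)
  panel <- add_metadata(panel, meta)
  structure(list(
    panel = panel, metadata = meta,
    truth = list(true_beta = config$true_beta, alpha = config$alpha,
                 gamma = truth$gamma, fert_init = truth$fert_init,
                 fert_paths = truth$paths,
                 edu_params = attr(edu, "params"), n_clipped = truth$n_clipped),
    config = config
  ), class = "conv_simulation")
}

#' @export
print.conv_simulation <- function(x, ...) {
  cat("<conv_simulation> planted beta = ", x$truth$true_beta,
      "; panel: ", length(unique(x$panel$country_id)), " countries x ",
      length(unique(x$panel$year)), " years\n", sep = "")
  invisible(x)
}

#' Scenario with a planted educational gradient
#'
#' Builds a multi-measure scenario for exercising the full analysis grid:
#' three fertility indicators (TFR, MACB, NRR) driven by a common
#' years-of-schooling expansion, plus six attainment-share measures
#' (attended/completed x primary/secondary/tertiary) derived from the same
#' driver. The share measures are scaled so their planted raw convergence
#' slopes follow the stated level gradient (`betas`, strongest for tertiary)
#' with attendance at `attended_ratio` of the completed slope, and carry
#' measure-specific multiplicative lognormal jitter on their increments
#' (`jitter_sd`, mean-one). The jitter is what makes the *standardized*
#' gradient recoverable: z-scoring is affine-invariant, so pure rescaling
#' cannot order standardized slopes; noisier measures (primary, and
#' attended within each level) are attenuated more, ordering the
#' standardized coefficients the same way as the raw ones.
#'
#' @param n_countries,year_start,year_end,step lattice as in
#'   [scenario_config()].
#' @param betas named planted raw slopes for completed tertiary/secondary/
#'   primary (per share point).
#' @param attended_ratio attended slope as a fraction of completed.
#' @param jitter_sd named lognormal sd of the increment jitter per measure.
#' @param noise_sd,fe_sd shock and intercept sds of the fertility recursions.
#' @param seed integer seed.
#' @return a `conv_gradient_scenario` list.
#' @export
gradient_scenario <- function(n_countries = 146L, year_start = 1950L,
                              year_end = 2015L, step = 5L,
                              betas = c(tertiary = -0.06, secondary = -0.04,
                                        primary = -0.02),
                              attended_ratio = 0.8,
                              jitter_sd = c(primary_attended = 0.55,
                                            primary_completed = 0.40,
                                            secondary_attended = 0.35,
                                            secondary_completed = 0.20,
                                            tertiary_attended = 0.15,
                                            tertiary_completed = 0.05),
                              noise_sd = 0.02, fe_sd = 0.01, seed = NULL) {
  if (!all(c("tertiary", "secondary", "primary") %in% names(betas))) {
    fc_abort("betas must name tertiary, secondary and primary",
             class = "fc_config_error")
  }
  if (!all(betas < 0) || !(abs(betas["tertiary"]) > abs(betas["secondary"]) &&
                           abs(betas["secondary"]) > abs(betas["primary"]))) {
    fc_abort("planted betas must be negative and ordered |tertiary| > |secondary| > |primary|",
             class = "fc_config_error")
  }
  base <- scenario_config(n_countries = n_countries, year_start = year_start,
                          year_end = year_end, step = step,
                          true_beta = unname(betas["tertiary"]), alpha = -0.02,
                          fe_sd = fe_sd, noise_sd = noise_sd, seed = seed)
  structure(list(base = base, betas = betas, attended_ratio = attended_ratio,
                 jitter_sd = jitter_sd, seed = base$seed),
            class = "conv_gradient_scenario")
}

gradient_measures <- function(scn) {
  b <- scn$betas
  slopes <- c(primary_attended = unname(b["primary"]) * scn$attended_ratio,
              primary_completed = unname(b["primary"]),
              secondary_attended = unname(b["secondary"]) * scn$attended_ratio,
              secondary_completed = unname(b["secondary"]),
              tertiary_attended = unname(b["tertiary"]) * scn$attended_ratio,
              tertiary_completed = unname(b["tertiary"]))
  tibble::tibble(
    measure = names(slopes),
    slope = unname(slopes),
    scale = unname(b["tertiary"]) / unname(slopes),
    jitter = unname(scn$jitter_sd[names(slopes)]),
    init_lo = c(20, 12, 5, 2, 0, 0),
    init_hi = c(40, 30, 22, 16, 8, 5)
  )
}

#' Simulate the gradient scenario
#'
#' @param scn a `conv_gradient_scenario`.
#' @return a `conv_simulation` whose panel holds `TFR`, `MACB`, `NRR`,
#'   `edu_years` and the six attainment-share measures, with metadata
#'   joined; `truth` records planted slopes per measure.
#' @export
simulate_gradient <- function(scn) {
  base <- scn$base
  edu <- simulate_education(base)
  D <- indicator_matrix(edu, base$edu_indicator)
  years <- as.integer(colnames(D))
  n <- nrow(D)
  dD <- D[, -1, drop = FALSE] - D[, -ncol(D), drop = FALSE]
  meas <- gradient_measures(scn)

  panels <- list(edu)
  with_subseed(base$seed, 7L, {
    for (i in seq_len(nrow(meas))) {
      tau <- meas$jitter[i]
      jit <- matrix(exp(rnorm(length(dD), -tau^2 / 2, tau)), nrow(dD), ncol(dD))
      inc <- meas$scale[i] * dD * jit
      init <- runif(n, meas$init_lo[i], meas$init_hi[i])
      Em <- cbind(init, init + t(apply(inc, 1, cumsum)))
      Em <- pmin(Em, 100)  # shares cannot exceed 100; saturated steps are
                           # excluded downstream as zero-change intervals
      dimnames(Em) <- dimnames(D)
      panels[[length(panels) + 1]] <- matrix_to_panel(Em, meas$measure[i])
    }
  })

  fert_cfgs <- list(
    TFR = scenario_config(n_countries = n, year_start = years[1],
                          year_end = years[length(years)], step = base$step,
                          true_beta = unname(scn$betas["tertiary"]), alpha = -0.02,
                          fe_sd = base$fe_sd, noise_sd = base$noise_sd,
                          indicator = "TFR",
                          seed = if (is.null(base$seed)) NULL else base$seed + 100L),
    MACB = scenario_config(n_countries = n, year_start = years[1],
                           year_end = years[length(years)], step = base$step,
                           indicator_kind = "age", indicator = "MACB",
                           fe_sd = base$fe_sd, noise_sd = base$noise_sd,
                           seed = if (is.null(base$seed)) NULL else base$seed + 200L),
    NRR = scenario_config(n_countries = n, year_start = years[1],
                          year_end = years[length(years)], step = base$step,
                          true_beta = -0.05, alpha = -0.01,
                          fert_init = c(0.7, 3.5), clip = c(0.3, 4),
                          indicator = "NRR",
                          fe_sd = base$fe_sd, noise_sd = base$noise_sd,
                          seed = if (is.null(base$seed)) NULL else base$seed + 300L)
  )
  fert_truth <- list()
  for (nm in names(fert_cfgs)) {
    fp <- suppressWarnings(simulate_fertility(fert_cfgs[[nm]], edu))
    fert_truth[[nm]] <- attr(fp, "truth")
    panels[[length(panels) + 1]] <- fp
  }

  panel <- dplyr::bind_rows(lapply(panels, tibble::as_tibble))
  class(panel) <- c("conv_panel", class(tibble::tibble()))
  attr(panel, "lattice") <- years
  attr(panel, "step") <- base$step
  meta <- make_metadata(base, fert_init = fert_truth$TFR$fert_init)
  panel <- add_metadata(panel, meta)

  structure(list(
    panel = panel, metadata = meta,
    truth = list(measures = meas, betas = scn$betas,
                 fert_configs = fert_cfgs, fert_truth = fert_truth),
    config = scn
  ), class = "conv_simulation")
}

#' Read/write scenario configurations and simulation sidecars
#'
#' Scenarios serialize to a flat YAML key-value file;
#' [save_simulation()] writes the panel and metadata CSVs next to a sidecar
#' recording the configuration, seed and package version.
#'
#' @param config a `conv_scenario`.
#' @param path file path.
#' @return `read_scenario()` returns a `conv_scenario`; the writers return
#'   their path invisibly.
#' @export
write_scenario <- function(config, path) {
  obj <- unclass(config)
  obj$years <- NULL
  obj$year_start <- min(config$years)
  obj$year_end <- max(config$years)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$income_props <- unlist(obj$income_props)
  do.call(scenario_config, obj)
}

#' @rdname write_scenario
#' @param sim a `conv_simulation`.
#' @param dir output directory (created if needed).
#' @export
save_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_panel(sim$panel[, c("country_id", "year", "indicator", "value")],
              file.path(dir, "panel.csv"))
  readr::write_csv(sim$metadata, file.path(dir, "metadata.csv"), progress = FALSE)
  sidecar <- list(
    package = "fertconv",
    version = as.character(utils::packageVersion("fertconv")),
    seed = sim$config$seed %||% sim$config$base$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = if (inherits(sim$config, "conv_scenario")) {
      obj <- unclass(sim$config); obj$years <- NULL; obj
    } else "gradient_scenario"
  )
  yaml::write_yaml(sidecar, file.path(dir, "scenario.yaml"))
  invisible(dir)
}
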