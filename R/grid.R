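#' Specify an analysis grid
#'
#' The grid crosses fertility indicators, education measures and country
#' subgroups; each cell runs the full pipeline (subgroup filter, sample
#' construction, zero-change exclusion, outlier trimming, standardization,
#' fixed-effects fit). The default mirrors the standard design: 3 fertility
#' indicators x 7 education measures x 5 subgroups = 105 cells.
#'
#' @param fertility,education,subgroups character vectors of indicator names
#'   and subgroup rules.
#' @param covariates optional covariate indicator names added to every cell.
#' @return a `conv_grid_spec` list.
#' @export
grid_spec <- function(fertility = c("TFR", "MACB", "NRR"),
                      education = c("edu_years",
                                    "primary_attended", "primary_completed",
                                    "secondary_attended", "secondary_completed",
                                    "tertiary_attended", "tertiary_completed"),
                      subgroups = c("all", "exclude-high-income",
                                    "exclude-low-and-lower-middle-income",
                                    "exclude-ssa", "ssa-only"),
                      covariates = NULL) {
  structure(list(fertility = fertility, education = education,
                 subgroups = subgroups, covariates = covariates %||% character(0)),
            class = "conv_grid_spec")
}

#' Run the analysis grid
#'
#' Executes every (fertility, education, subgroup) cell of `spec` on the
#' panel. Per-cell failures (empty samples after exclusions, unidentified
#' designs, too few clusters) are recorded in the `error` column so the grid
#' always completes; referencing an indicator absent from the panel is a
#' specification error raised before any fitting. Results are deterministic
#' functions of the panel and spec — no randomness is involved — and
#' invariant to row order.
#'
#' @param panel a `conv_panel` (with metadata columns if subgroup rules need
#'   them; otherwise pass `metadata`).
#' @param spec a `conv_grid_spec` (default [grid_spec()]).
#' @param metadata optional per-country metadata to join first.
#' @param horizon,k,tol passed to [build_edu_sample()] and [trim_outliers()].
#' @param standardize z-score each cell's estimation sample (standardized
#'   coefficients, the reporting convention)? Default `TRUE`.
#' @param fixed_effects absorb country intercepts? Default `TRUE`.
#' @param keep_list optional data frame of (country_id, year) pairs to
#'   restrict the panel to before analysis (generic replication-subset hook).
#' @return a `conv_grid` tibble: one row per cell with the scalar fit fields,
#'   an `error` column, and a `fit` list-column; attributes record
#'   provenance (spec hash, timestamp, package version).
#' @export
run_grid <- function(panel, spec = grid_spec(), metadata = NULL,
                     horizon = 5L, k = 3, tol = 1e-9,
                     standardize = TRUE, fixed_effects = TRUE,
                     keep_list = NULL) {
  if (!is.null(metadata)) panel <- add_metadata(panel, metadata)
  present <- unique(panel$indicator)
  wanted <- unique(c(spec$fertility, spec$education, spec$covariates))
  absent <- setdiff(wanted, present)
  if (length(absent) > 0) {
    fc_abort(paste0("grid spec references indicator(s) absent from panel: ",
                    paste(absent, collapse = ", ")),
             class = "fc_specification_error")
  }
  if (!is.null(keep_list)) {
    keys <- paste(keep_list$country_id, keep_list$year)
    panel <- panel[paste(panel$country_id, panel$year) %in% keys, , drop = FALSE]
    class(panel) <- c("conv_panel", class(tibble::tibble()))
  }

  cells <- expand.grid(fertility = spec$fertility, education = spec$education,
                       subgroup = spec$subgroups, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    res <- run_cell(panel, cell$fertility, cell$education, cell$subgroup,
                    covariates = spec$covariates, horizon = horizon, k = k,
                    tol = tol, standardize = standardize,
                    fixed_effects = fixed_effects)
    rows[[i]] <- res
  }
  out <- tibble::as_tibble(cells)
  scalar <- dplyr::bind_rows(lapply(rows, function(r) r$row))
  out <- dplyr::bind_cols(out, scalar)
  out$fit <- lapply(rows, function(r) r$fit)
  class(out) <- c("conv_grid", class(tibble::tibble()))
  attr(out, "spec") <- spec
  attr(out, "provenance") <- list(
    spec_hash = rlang::hash(list(spec, horizon, k, tol, standardize, fixed_effects)),
    package_version = as.character(utils::packageVersion("fertconv")),
    timestamp = format(Sys.time(), tz = "UTC"),
    standardize = standardize, fixed_effects = fixed_effects,
    horizon = horizon, k = k, tol = tol
  )
  out
}

empty_cell_row <- function(reason) {
  tibble::tibble(beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p_value = NA_real_,
                 n_obs = NA_integer_, n_countries = NA_integer_,
                 n_trimmed = NA_integer_, n_zero_delta = NA_integer_,
                 converged_flag = NA_character_, error = reason)
}

run_cell <- function(panel, fert, edu, subgroup, covariates, horizon, k, tol,
                     standardize, fixed_effects) {
  fit <- NULL
  row <- tryCatch({
    sub <- filter_subgroup(panel, subgroup)
    smp <- build_edu_sample(sub, fert = fert, edu = edu, horizon = horizon,
                            tol = tol,
                            covariates = if (length(covariates)) covariates else NULL)
    smp <- trim_outliers(smp, k = k)
    if (standardize) smp <- standardize_sample(smp)
    f <- fit_convergence(smp, fixed_effects = fixed_effects,
                         covariates = covariates)
    fit <- f
    tibble::tibble(beta = f$beta, se = f$se, ci_low = f$ci_low,
                   ci_high = f$ci_high, p_value = f$p_value,
                   n_obs = f$n_obs, n_countries = f$n_countries,
                   n_trimmed = f$n_trimmed, n_zero_delta = f$n_zero_delta,
                   converged_flag = f$converged_flag, error = NA_character_)
  }, fertconv_error = function(e) empty_cell_row(conditionMessage(e)))
  list(row = row, fit = fit)
}

#' @export
print.conv_grid <- function(x, ...) {
  cat("<conv_grid> ", nrow(x), " cells (",
      sum(is.na(x$error)), " fitted, ", sum(!is.na(x$error)), " failed)\n",
      sep = "")
  NextMethod()
}

measure_level <- function(x) {
  lv <- rep(NA_character_, length(x))
  lv[grepl("primary", x)] <- "primary"
  lv[grepl("secondary", x)] <- "secondary"
  lv[grepl("tertiary", x)] <- "tertiary"
  lv
}

measure_status <- function(x) {
  st <- rep(NA_character_, length(x))
  st[grepl("attended", x)] <- "attended"
  st[grepl("completed", x)] <- "completed"
  st
}

#' Summarize the educational gradients in a fitted grid
#'
#' For each fertility indicator and subgroup, reports whether the fitted
#' coefficient magnitudes follow the two gradients of interest:
#' `|beta_tertiary| >= |beta_secondary| >= |beta_primary|` within each
#' attendance status, and `|beta_completed| >= |beta_attended|` within each
#' level. Exact equalities are reported as ties, not violations. Purely
#' descriptive: no new inference is performed, but a CI-overlap flag notes
#' when the compared intervals overlap. Missing or failed cells yield rows
#' flagged incomplete.
#'
#' @param grid a `conv_grid`.
#' @return a tibble with one row per (fertility, subgroup, comparison).
#' @export
gradient_summary <- function(grid) {
  g <- tibble::as_tibble(grid)
  g$level <- measure_level(g$education)
  g$status <- measure_status(g$education)
  out <- list()
  combos <- unique(g[, c("fertility", "subgroup")])
  for (i in seq_len(nrow(combos))) {
    fr <- combos$fertility[i]; sg <- combos$subgroup[i]
    sub <- g[g$fertility == fr & g$subgroup == sg & !is.na(g$level), , drop = FALSE]
    # level gradient within each status
    for (st in c("attended", "completed")) {
      s <- sub[sub$status %in% st, , drop = FALSE]
      b <- stats::setNames(s$beta[match(c("tertiary", "secondary", "primary"), s$level)],
                           c("tertiary", "secondary", "primary"))
      cil <- s$ci_low[match(c("tertiary", "secondary", "primary"), s$level)]
      cih <- s$ci_high[match(c("tertiary", "secondary", "primary"), s$level)]
      complete <- !anyNA(b)
      holds <- if (complete) {
        abs(b["tertiary"]) >= abs(b["secondary"]) &&
          abs(b["secondary"]) >= abs(b["primary"])
      } else NA
      tie <- if (complete) {
        abs(b["tertiary"]) == abs(b["secondary"]) ||
          abs(b["secondary"]) == abs(b["primary"])
      } else NA
      overlap <- if (complete) {
        (cil[1] <= cih[2] && cil[2] <= cih[1]) ||
          (cil[2] <= cih[3] && cil[3] <= cih[2])
      } else NA
      out[[length(out) + 1]] <- tibble::tibble(
        fertility = fr, subgroup = sg,
        comparison = paste0("level-gradient (", st, ")"),
        holds = holds, tie = tie, ci_overlap = overlap, complete = complete
      )
    }
    # completed vs attended within each level
    for (lv in c("primary", "secondary", "tertiary")) {
      s <- sub[sub$level %in% lv, , drop = FALSE]
      bc <- s$beta[match("completed", s$status)]
      ba <- s$beta[match("attended", s$status)]
      complete <- length(bc) == 1 && length(ba) == 1 && !is.na(bc) && !is.na(ba)
      holds <- if (complete) abs(bc) >= abs(ba) else NA
      tie <- if (complete) abs(bc) == abs(ba) else NA
      overlap <- if (complete) {
        s$ci_low[match("completed", s$status)] <= s$ci_high[match("attended", s$status)] &&
          s$ci_low[match("attended", s$status)] <= s$ci_high[match("completed", s$status)]
      } else NA
      out[[length(out) + 1]] <- tibble::tibble(
        fertility = fr, subgroup = sg,
        comparison = paste0("completed-vs-attended (", lv, ")"),
        holds = holds, tie = tie, ci_overlap = overlap, complete = complete
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Write grid results to disk
#'
#' Writes `cells.csv` (one row per cell, including failure reasons),
#' `provenance.json` (spec hash, parameters, package version, timestamp)
#' and, when `plot = TRUE` and ggplot2 is available, a best-effort forest
#' plot of coefficients per fertility indicator (`forest_<indicator>.pdf`);
#' plotting failures never fail the run. The CSV is byte-identical across
#' reruns of the same inputs (the timestamp lives only in the JSON).
#'
#' @param grid a `conv_grid`.
#' @param path output directory (created if needed).
#' @param plot also write coefficient plots? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
report_grid <- function(grid, path, plot = FALSE) {
  if (nrow(grid) == 0) {
    fc_abort("cannot report an empty grid", class = "fc_specification_error")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) {
    fc_abort(paste0("cannot create output directory: ", path), class = "fc_io_error")
  }
  flat <- tibble::as_tibble(grid)
  flat$fit <- NULL
  readr::write_csv(flat, file.path(path, "cells.csv"), progress = FALSE)
  jsonlite::write_json(attr(grid, "provenance"),
                       file.path(path, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(plot)) {
    tryCatch(write_forest_plots(flat, path), error = function(e) {
      fc_log("report_grid: plotting skipped (", conditionMessage(e), ")")
    })
  }
  invisible(path)
}

write_forest_plots <- function(flat, path) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    fc_log("report_grid: ggplot2 not available; skipping plots")
    return(invisible(NULL))
  }
  for (fr in unique(flat$fertility)) {
    sub <- flat[flat$fertility == fr & is.na(flat$error), , drop = FALSE]
    if (nrow(sub) == 0) next
    p <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$beta, y = .data$education)) +
      ggplot2::geom_point() +
      ggplot2::geom_errorbarh(
        ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
      ggplot2::geom_vline(xintercept = 0, linetype = 2) +
      ggplot2::facet_wrap(~subgroup) +
      ggplot2::labs(x = "convergence coefficient (95% CI)", y = NULL, title = fr)
    ggplot2::ggsave(file.path(path, paste0("forest_", fr, ".pdf")), p,
                    width = 9, height = 6)
  }
  invisible(NULL)
}
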