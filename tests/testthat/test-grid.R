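sim_for_grid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_gradient(gradient_scenario(n_countries = 60, seed = 31))
    }
    cache
  }
})

test_that("the default grid populates (or reasons about) every cell", {
  sim <- sim_for_grid()
  g <- run_grid(sim$panel, grid_spec())
  expect_equal(nrow(g), 3 * 7 * 5)
  expect_true(all(is.na(g$error) | nzchar(g$error)))
  expect_true(all(!is.na(g$beta) | !is.na(g$error)))
  # each requested cell appears exactly once
  expect_equal(anyDuplicated(g[, c("fertility", "education", "subgroup")]), 0)
})

test_that("a one-cell grid equals the manually composed pipeline", {
  sim <- sim_for_grid()
  g <- run_grid(sim$panel,
                grid_spec(fertility = "TFR", education = "secondary_completed",
                          subgroups = "exclude-high-income"))
  manual <- sim$panel |>
    filter_subgroup("exclude-high-income") |>
    build_edu_sample("TFR", "secondary_completed") |>
    trim_outliers() |>
    standardize_sample() |>
    fit_convergence(fixed_effects = TRUE)
  expect_equal(g$beta, manual$beta, tolerance = 1e-12)
  expect_equal(g$se, manual$se, tolerance = 1e-12)
  expect_equal(g$n_obs, manual$n_obs)
  expect_equal(g$fit[[1]]$beta, manual$beta)
})

test_that("unknown indicators fail before fitting; cell failures are recorded", {
  sim <- sim_for_grid()
  expect_error(run_grid(sim$panel, grid_spec(fertility = "no_such_indicator")),
               class = "fc_specification_error")

  # plant a failing cell: constant fertility has zero variance to standardize
  flat <- conv_panel(data.frame(
    country_id = rep(unique(sim$panel$country_id), each = 14),
    year = rep(sort(unique(sim$panel$year)), 60),
    indicator = "flat_index",
    value = 2
  ))
  p2 <- dplyr::bind_rows(tibble::as_tibble(sim$panel),
                         tibble::as_tibble(flat))
  class(p2) <- class(sim$panel)
  g <- run_grid(p2, grid_spec(fertility = c("TFR", "flat_index"),
                              education = "edu_years", subgroups = "all"))
  expect_equal(nrow(g), 2)
  failed <- g[g$fertility == "flat_index", ]
  expect_false(is.na(failed$error))
  expect_true(is.na(failed$beta))
  expect_true(is.na(g$error[g$fertility == "TFR"]))
})

test_that("grid results are invariant to panel row order and cell removal", {
  sim <- sim_for_grid()
  spec <- grid_spec(fertility = "TFR",
                    education = c("edu_years", "tertiary_completed"),
                    subgroups = c("all", "ssa-only"))
  g1 <- run_grid(sim$panel, spec)
  set.seed(1)
  shuffled <- sim$panel[sample(nrow(sim$panel)), ]
  class(shuffled) <- class(sim$panel)
  g2 <- run_grid(shuffled, spec)
  expect_equal(g1$beta, g2$beta, tolerance = 1e-12)
  expect_equal(g1$se, g2$se, tolerance = 1e-12)

  # dropping a subgroup leaves the other cells untouched
  g3 <- run_grid(sim$panel, grid_spec(fertility = "TFR",
                                      education = c("edu_years",
                                                    "tertiary_completed"),
                                      subgroups = "all"))
  expect_equal(g3$beta, g1$beta[g1$subgroup == "all"], tolerance = 1e-15)
})

test_that("keep-lists restrict the analysis to given country-years", {
  sim <- sim_for_grid()
  years <- sort(unique(sim$panel$year))
  keep <- expand.grid(country_id = unique(sim$panel$country_id)[1:20],
                      year = years, stringsAsFactors = FALSE)
  g <- run_grid(sim$panel, grid_spec(fertility = "TFR",
                                     education = "edu_years",
                                     subgroups = "all"),
                keep_list = keep)
  expect_equal(g$n_countries, 20)
})

test_that("gradient summaries report orderings, ties and gaps", {
  sim <- sim_for_grid()
  spec <- grid_spec(fertility = "TFR",
                    education = c("primary_attended", "primary_completed",
                                  "secondary_attended", "secondary_completed",
                                  "tertiary_attended", "tertiary_completed"),
                    subgroups = "all")
  g <- run_grid(sim$panel, spec)
  gs <- gradient_summary(g)
  expect_setequal(gs$comparison,
                  c("level-gradient (attended)", "level-gradient (completed)",
                    "completed-vs-attended (primary)",
                    "completed-vs-attended (secondary)",
                    "completed-vs-attended (tertiary)"))
  expect_true(all(gs$complete))

  # all-equal betas are ties, not violations
  g_tie <- g
  g_tie$beta <- -0.5
  gs_tie <- gradient_summary(g_tie)
  expect_true(all(gs_tie$holds))
  expect_true(all(gs_tie$tie))

  # missing cells are flagged incomplete
  g_miss <- g[!grepl("tertiary", g$education), ]
  class(g_miss) <- class(g)
  gs_miss <- gradient_summary(g_miss)
  expect_false(all(gs_miss$complete))
  expect_true(anyNA(gs_miss$holds))
})

test_that("reports conserve cells, record failures, and are reproducible", {
  sim <- sim_for_grid()
  spec <- grid_spec(fertility = "TFR",
                    education = c("edu_years", "primary_completed"),
                    subgroups = c("all", "ssa-only"))
  g <- run_grid(sim$panel, spec)
  d1 <- withr::local_tempdir()
  report_grid(g, d1)
  cells <- readr::read_csv(file.path(d1, "cells.csv"), show_col_types = FALSE)
  expect_equal(nrow(cells), nrow(g))
  prov <- jsonlite::fromJSON(file.path(d1, "provenance.json"))
  expect_true(nzchar(prov$spec_hash))

  # rerun: cells.csv is byte-identical (timestamp lives only in the JSON)
  d2 <- withr::local_tempdir()
  report_grid(run_grid(sim$panel, spec), d2)
  expect_identical(readLines(file.path(d1, "cells.csv")),
                   readLines(file.path(d2, "cells.csv")))

  # failure reasons travel into the CSV
  flat <- conv_panel(data.frame(
    country_id = rep(unique(sim$panel$country_id), each = 14),
    year = rep(sort(unique(sim$panel$year)), 60),
    indicator = "flat_index", value = 2))
  p2 <- dplyr::bind_rows(tibble::as_tibble(sim$panel), tibble::as_tibble(flat))
  class(p2) <- class(sim$panel)
  gf <- run_grid(p2, grid_spec(fertility = "flat_index",
                               education = "edu_years", subgroups = "all"))
  d3 <- withr::local_tempdir()
  report_grid(gf, d3)
  cells3 <- readr::read_csv(file.path(d3, "cells.csv"), show_col_types = FALSE)
  expect_true(any(nzchar(cells3$error)))
})
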