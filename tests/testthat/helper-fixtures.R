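# Silence drop/exclusion logging during tests; individual tests re-enable it
# when the logging itself is under test.
options(fertconv.quiet = TRUE)

# Long panel from a named list of country -> year -> value vectors.
make_panel <- function(values, indicator, years) {
  df <- do.call(rbind, lapply(names(values), function(cid) {
    data.frame(country_id = cid, year = years, indicator = indicator,
               value = values[[cid]])
  }))
  conv_panel(df)
}

# Small fertility+education panel on a 5-year lattice, linked.
make_linked_panel <- function(n_countries = 3, years = c(1950, 1955, 1960),
                              fert0 = NULL, edu_step = 1) {
  ids <- sprintf("C%02d", seq_len(n_countries))
  fert0 <- fert0 %||% seq(3, 6, length.out = n_countries)
  fvals <- lapply(seq_len(n_countries),
                  function(i) fert0[i] * 0.9^(seq_along(years) - 1))
  names(fvals) <- ids
  evals <- lapply(seq_len(n_countries),
                  function(i) 2 + edu_step * (seq_along(years) - 1))
  names(evals) <- ids
  f <- make_panel(fvals, "TFR", years)
  e <- make_panel(evals, "edu_years", years)
  link_panels(f, e, step = 5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random convergence sample with clustered structure, for estimator tests.
random_sample <- function(n_clusters, n_per, seed, beta = -0.05,
                          covariate = FALSE) {
  set.seed(seed)
  ids <- rep(sprintf("G%02d", seq_len(n_clusters)), each = n_per)
  n <- length(ids)
  base <- runif(n, 1, 8)
  gamma <- rep(rnorm(n_clusters, 0, 0.05), each = n_per)
  ratio <- -0.02 + beta * base + gamma + rnorm(n, 0, 0.03)
  df <- tibble::tibble(country_id = ids,
                       base_year = rep(seq_len(n_per) * 5 + 1945,
                                       times = n_clusters),
                       base_fertility = base, ratio = ratio,
                       delta_edu = runif(n, 0.2, 2))
  if (covariate) {
    df$cpr <- rnorm(n)
    df$ratio <- df$ratio + 0.01 * df$cpr
  }
  s <- df
  class(s) <- c("conv_sample", class(tibble::tibble()))
  if (covariate) attr(s, "covariates") <- "cpr"
  s
}
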