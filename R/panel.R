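#' Country-year indicator panels
#'
#' A `conv_panel` is a long-format tibble with one row per
#' (country, year, indicator) holding the indicator's value, optionally
#' carrying per-country metadata columns (`income_group`, `is_ssa`, ...).
#' It is the universal input to the convergence pipeline: fertility
#' indicators (TFR, MACB, NRR) and education indicators (years of schooling,
#' percentage attended/completed primary/secondary/tertiary) all travel in
#' this shape.
#'
#' Validation enforces: unique (country_id, year, indicator) keys; values in
#' the plausible range for the indicator kind (shares in \[0, 100\], years of
#' schooling >= 0, TFR/NRR > 0, MACB in (10, 60)); integer years.
#'
#' @param data a data frame with columns `country_id`, `year`, `indicator`,
#'   `value` (extra columns are kept as metadata).
#' @param kinds optional named character vector mapping indicator names to a
#'   kind in `c("tfr", "nrr", "macb", "years", "share", "none")`, overriding
#'   the name-based guess from [indicator_kind()].
#' @return a validated `conv_panel` tibble.
#' @export
conv_panel <- function(data, kinds = NULL) {
  required <- c("country_id", "year", "indicator", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    fc_abort(
      paste0("panel is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "fc_schema_error"
    )
  }
  data <- tibble::as_tibble(data)
  data$country_id <- as.character(data$country_id)
  data$year <- as.integer(data$year)
  data$indicator <- as.character(data$indicator)
  data$value <- as.double(data$value)

  dup <- duplicated(data[required[1:3]])
  if (any(dup)) {
    fc_abort(
      paste0("duplicate (country_id, year, indicator) keys: ",
             fc_key_preview(data[dup, , drop = FALSE], required[1:3])),
      class = "fc_integrity_error",
      keys = data[dup, required[1:3], drop = FALSE]
    )
  }

  bad <- !panel_value_ok(data$indicator, data$value, kinds = kinds)
  bad[is.na(data$value)] <- FALSE  # missing values are dropped later, at link time
  if (any(bad)) {
    off <- data[bad, required, drop = FALSE]
    fc_abort(
      paste0(sum(bad), " value(s) out of range for their indicator: ",
             fc_key_preview(off, required[1:3])),
      class = "fc_validation_error",
      offenders = off
    )
  }

  class(data) <- c("conv_panel", class(tibble::tibble()))
  data
}

#' Guess the kind of an indicator from its name
#'
#' Used for range validation. Matching is case-insensitive: `TFR`/`NRR` are
#' positive rates, `MACB` an age in (10, 60), names containing
#' `years`/`yrs`/`schooling` are nonnegative years, and names containing
#' `attended`, `completed`, `primary`, `secondary`, `tertiary`, `share` or
#' `pct` are percentages in \[0, 100\]. Anything else is unconstrained.
#'
#' @param name character vector of indicator names.
#' @return character vector of kinds.
#' @export
indicator_kind <- function(name) {
  lname <- tolower(name)
  kind <- rep("none", length(name))
  kind[grepl("attended|completed|primary|secondary|tertiary|share|pct", lname)] <- "share"
  kind[grepl("years|yrs|schooling", lname)] <- "years"
  kind[grepl("^tfr$|(^|_)tfr($|_)", lname)] <- "tfr"
  kind[grepl("^nrr$|(^|_)nrr($|_)", lname)] <- "nrr"
  kind[grepl("^macb$|(^|_)macb($|_)", lname)] <- "macb"
  kind
}

panel_value_ok <- function(indicator, value, kinds = NULL) {
  kind <- indicator_kind(indicator)
  if (!is.null(kinds)) {
    idx <- match(indicator, names(kinds))
    kind[!is.na(idx)] <- unname(kinds[idx[!is.na(idx)]])
  }
  ok <- rep(TRUE, length(value))
  ok[kind %in% c("tfr", "nrr")] <- value[kind %in% c("tfr", "nrr")] > 0
  ok[kind == "macb"] <- value[kind == "macb"] > 10 & value[kind == "macb"] < 60
  ok[kind == "years"] <- value[kind == "years"] >= 0
  ok[kind == "share"] <- value[kind == "share"] >= 0 & value[kind == "share"] <= 100
  ok
}

#' Read an indicator panel from CSV
#'
#' Accepts the long dialect (columns `country`/`country_id`, `year`,
#' `indicator`, `value`) or a wide dialect (one column per indicator), which
#' is pivoted to long. Validation is as in [conv_panel()]; offending rows are
#' reported, not silently dropped.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param schema optional named character vector renaming file indicator
#'   names to canonical ones, e.g. `c(tfr = "TFR")`.
#' @param kinds passed to [conv_panel()].
#' @return a `conv_panel`.
#' @export
read_panel <- function(path, schema = NULL, kinds = NULL) {
  if (!file.exists(path)) {
    fc_abort(paste0("file not found: ", path), class = "fc_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nm <- names(raw)
  if ("country" %in% nm && !"country_id" %in% nm) {
    names(raw)[nm == "country"] <- "country_id"
  }
  if (!"year" %in% names(raw) || !"country_id" %in% names(raw)) {
    fc_abort("CSV must contain 'country' (or 'country_id') and 'year' columns",
             class = "fc_schema_error")
  }
  if (!all(c("indicator", "value") %in% names(raw))) {
    # wide dialect: every non-key column is an indicator
    value_cols <- setdiff(names(raw), c("country_id", "year"))
    if (length(value_cols) == 0) {
      fc_abort("no indicator columns found in wide CSV", class = "fc_schema_error")
    }
    raw <- tidyr::pivot_longer(raw, cols = dplyr::all_of(value_cols),
                               names_to = "indicator", values_to = "value")
  }
  if (!is.null(schema)) {
    idx <- match(raw$indicator, names(schema))
    raw$indicator[!is.na(idx)] <- unname(schema[idx[!is.na(idx)]])
  }
  conv_panel(raw, kinds = kinds)
}

#' Write a panel to long-format CSV
#'
#' Round-trips exactly with [read_panel()] for finite values (full-precision
#' decimal serialization).
#'
#' @param panel a `conv_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel, path, progress = FALSE)
  invisible(path)
}

#' Attach per-country metadata to a panel
#'
#' Metadata (income group, sub-Saharan Africa flag, arbitrary extra columns)
#' is user-supplied and keyed by `country_id`; it is joined onto every row so
#' subgroup filters can reference it directly.
#'
#' @param panel a `conv_panel`.
#' @param metadata data frame keyed by `country_id` with metadata columns
#'   such as `income_group` (one of low, lower-middle, upper-middle, high)
#'   and logical `is_ssa`.
#' @return the panel with metadata columns joined.
#' @export
add_metadata <- function(panel, metadata) {
  if (!"country_id" %in% names(metadata)) {
    fc_abort("metadata must have a 'country_id' column", class = "fc_schema_error")
  }
  metadata <- tibble::as_tibble(metadata)
  metadata$country_id <- as.character(metadata$country_id)
  if (anyDuplicated(metadata$country_id)) {
    fc_abort("metadata has duplicated country_id rows", class = "fc_integrity_error")
  }
  if ("income_group" %in% names(metadata)) {
    lv <- c("low", "lower-middle", "upper-middle", "high")
    bad <- !is.na(metadata$income_group) & !metadata$income_group %in% lv
    if (any(bad)) {
      fc_abort(paste0("income_group outside {", paste(lv, collapse = ", "), "}"),
               class = "fc_validation_error")
    }
  }
  out <- dplyr::left_join(tibble::as_tibble(panel), metadata, by = "country_id")
  class(out) <- c("conv_panel", class(tibble::tibble()))
  out
}

#' Link fertility and education panels on a common year lattice
#'
#' Restricts both panels to (country, year) pairs present in both sources on
#' a `step`-year lattice anchored at the smallest year the two panels share,
#' then stacks them into one panel. Rows with missing values are dropped with
#' a logged count. With `require_balanced = TRUE` (the default, matching the
#' balanced quinquennial design), countries missing any lattice year for any
#' linked indicator are dropped and logged.
#'
#' @param fertility,education `conv_panel` objects.
#' @param step lattice spacing in years (default 5).
#' @param require_balanced drop countries not observed at every lattice year?
#' @return a linked `conv_panel`; attributes `dropped_countries` and
#'   `n_dropped_missing` record what was removed.
#' @export
link_panels <- function(fertility, education, step = 5L, require_balanced = TRUE) {
  if (nrow(fertility) == 0 || nrow(education) == 0) {
    fc_abort("both panels must be nonempty", class = "fc_linkage_error")
  }
  stopifnot(step > 0)
  anchor <- max(min(fertility$year), min(education$year))
  top <- min(max(fertility$year), max(education$year))
  if (top < anchor) {
    fc_abort("panels share no overlapping years", class = "fc_linkage_error")
  }
  lattice <- seq.int(anchor, top, by = step)
  lattice <- lattice[lattice %in% fertility$year & lattice %in% education$year]
  if (length(lattice) == 0) {
    fc_abort("no common years on the lattice", class = "fc_linkage_error")
  }

  f <- fertility[fertility$year %in% lattice, , drop = FALSE]
  e <- education[education$year %in% lattice, , drop = FALSE]
  keys_f <- unique(paste(f$country_id, f$year))
  keys_e <- unique(paste(e$country_id, e$year))
  keep <- intersect(keys_f, keys_e)
  if (length(keep) == 0) {
    fc_abort("fertility and education panels share no (country, year) pairs",
             class = "fc_linkage_error")
  }
  f <- f[paste(f$country_id, f$year) %in% keep, , drop = FALSE]
  e <- e[paste(e$country_id, e$year) %in% keep, , drop = FALSE]
  out <- dplyr::bind_rows(tibble::as_tibble(f), tibble::as_tibble(e))

  n_missing <- sum(is.na(out$value))
  if (n_missing > 0) {
    fc_log("link_panels: dropped ", n_missing, " row(s) with missing values")
    out <- out[!is.na(out$value), , drop = FALSE]
  }

  dropped_countries <- character(0)
  if (isTRUE(require_balanced)) {
    full <- length(lattice) * length(unique(out$indicator))
    cnt <- tapply(seq_len(nrow(out)), out$country_id, length)
    dropped_countries <- names(cnt)[cnt < full]
    if (length(dropped_countries) > 0) {
      fc_log("link_panels: dropped ", length(dropped_countries),
             " unbalanced country(ies): ",
             paste(utils::head(dropped_countries, 8), collapse = ", "))
      out <- out[!out$country_id %in% dropped_countries, , drop = FALSE]
    }
    if (nrow(out) == 0) {
      fc_abort("no balanced countries remain after linking", class = "fc_linkage_error")
    }
  }

  class(out) <- c("conv_panel", class(tibble::tibble()))
  attr(out, "lattice") <- lattice
  attr(out, "step") <- as.integer(step)
  attr(out, "dropped_countries") <- dropped_countries
  attr(out, "n_dropped_missing") <- n_missing
  out
}

#' Restrict a panel to a country subgroup
#'
#' Supported named rules mirror the usual subregional analyses:
#' `"all"` (no-op), `"exclude-high-income"`,
#' `"exclude-low-and-lower-middle-income"`, `"exclude-ssa"`, `"ssa-only"`.
#' A one-sided formula (evaluated against the panel's columns, kept rows
#' where `TRUE`) expresses arbitrary metadata predicates.
#'
#' @param panel a `conv_panel` carrying the metadata columns the rule needs.
#' @param rule a rule name or a one-sided formula, e.g. `~ !is_ssa`.
#' @return the filtered `conv_panel`.
#' @export
filter_subgroup <- function(panel, rule) {
  if (inherits(rule, "formula")) {
    keep <- rlang::eval_tidy(rule[[2]], data = panel)
    if (!is.logical(keep) || length(keep) != nrow(panel)) {
      fc_abort("subgroup formula must evaluate to a logical vector over rows",
               class = "fc_specification_error")
    }
    out <- panel[keep %in% TRUE, , drop = FALSE]
  } else if (is.character(rule) && length(rule) == 1) {
    needs <- switch(rule,
      "all" = character(0),
      "exclude-high-income" = "income_group",
      "exclude-low-and-lower-middle-income" = "income_group",
      "exclude-ssa" = "is_ssa",
      "ssa-only" = "is_ssa",
      fc_abort(paste0("unknown subgroup rule: '", rule, "'"),
               class = "fc_specification_error")
    )
    miss <- setdiff(needs, names(panel))
    if (length(miss) > 0) {
      fc_abort(paste0("subgroup rule '", rule, "' needs metadata column(s): ",
                      paste(miss, collapse = ", ")),
               class = "fc_specification_error")
    }
    keep <- switch(rule,
      "all" = rep(TRUE, nrow(panel)),
      "exclude-high-income" = panel$income_group != "high",
      "exclude-low-and-lower-middle-income" =
        !panel$income_group %in% c("low", "lower-middle"),
      "exclude-ssa" = !panel$is_ssa,
      "ssa-only" = panel$is_ssa
    )
    out <- panel[keep %in% TRUE, , drop = FALSE]
  } else {
    fc_abort("rule must be a single rule name or a one-sided formula",
             class = "fc_specification_error")
  }
  class(out) <- c("conv_panel", class(tibble::tibble()))
  for (a in c("lattice", "step")) attr(out, a) <- attr(panel, a)
  out
}

#' @export
print.conv_panel <- function(x, ...) {
  cat("<conv_panel> ", length(unique(x$country_id)), " countries, ",
      length(unique(x$year)), " years, indicators: ",
      paste(sort(unique(x$indicator)), collapse = ", "), "\n", sep = "")
  NextMethod()
}
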