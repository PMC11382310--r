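#' Canonical cohort schema
#'
#' One row per patient: baseline covariates, exposure (radiation modality,
#' `0` = IMRT photons, `1` = PBT protons), binary mediator (`g4ril`, grade 4
#' radiation-induced lymphopenia), and a right-censored overall-survival
#' outcome in months.
#'
#' @return a tibble with columns `column`, `type`, `levels` describing the
#'   canonical schema.
#' @export
cohort_schema <- function() {
  tibble::tribble(
    ~column,         ~type,         ~levels,
    "id",            "character",   NA_character_,
    "age",           "numeric",     NA_character_,
    "sex",           "factor",      "female|male",
    "baseline_alc",  "numeric",     NA_character_,
    "ptv",           "numeric",     NA_character_,
    "ecog",          "factor",      "0|1-2",
    "location",      "factor",      "upper-middle|lower",
    "stage",         "factor",      "I|II|III",
    "chemo_cycles",  "integer",     NA_character_,
    "barretts",      "integer",     "0|1",
    "histology",     "factor",      "adeno|scc",
    "surgery",       "integer",     "0|1",
    "modality",      "integer",     "0|1",
    "g4ril",         "integer",     "0|1",
    "os_months",     "numeric",     NA_character_,
    "event",         "integer",     "0|1"
  )
}

cohort_columns <- function() cohort_schema()$column

factor_levels <- function(col) {
  lv <- cohort_schema()$levels[match(col, cohort_schema()$column)]
  strsplit(lv, "|", fixed = TRUE)[[1]]
}

#' Validate a cohort table against the canonical schema
#'
#' Checks column presence and types, normalizes categorical labels to the
#' canonical levels, and drops rows with missing or out-of-domain values.
#' Row rejection mirrors the exclusion of patients with incomplete baseline
#' records in retrospective series: a record is either complete and valid or
#' it is excluded, with a count reported.
#'
#' @param data a data frame in the canonical schema (see [cohort_schema()]).
#' @param quiet suppress the rejected-row message.
#' @return a validated tibble with attributes `n_rejected` (count) and
#'   `provenance`.
#' @export
validate_cohort <- function(data, quiet = FALSE) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(cohort_columns(), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- data[, cohort_columns()]

  norm_factor <- function(x, col) {
    lev <- factor_levels(col)
    x <- trimws(tolower(as.character(x)))
    lookup <- setNames(lev, tolower(lev))
    # accept a few common synonyms
    extra <- switch(col,
      sex = c(f = "female", m = "male"),
      histology = c(adenocarcinoma = "adeno", "squamous cell carcinoma" = "scc",
                    squamous = "scc"),
      ecog = c("1" = "1-2", "2" = "1-2", "1 and 2" = "1-2"),
      location = c("upper" = "upper-middle", "middle" = "upper-middle",
                   "upper/middle" = "upper-middle"),
      stage = c("1" = "I", "2" = "II", "3" = "III"),
      NULL)
    lookup <- c(lookup, extra)
    factor(unname(lookup[x]), levels = lev)
  }
  as_binary <- function(x) {
    x <- suppressWarnings(as.numeric(as.character(x)))
    ifelse(!is.na(x) & x %in% c(0, 1), as.integer(x), NA_integer_)
  }
  as_num <- function(x) suppressWarnings(as.numeric(as.character(x)))

  out <- dplyr::mutate(data,
    id = as.character(.data$id),
    age = as_num(.data$age),
    sex = norm_factor(.data$sex, "sex"),
    baseline_alc = as_num(.data$baseline_alc),
    ptv = as_num(.data$ptv),
    ecog = norm_factor(.data$ecog, "ecog"),
    location = norm_factor(.data$location, "location"),
    stage = norm_factor(.data$stage, "stage"),
    chemo_cycles = {
      v <- as_num(.data$chemo_cycles)
      ifelse(!is.na(v) & v >= 1 & v == round(v), as.integer(v), NA_integer_)
    },
    barretts = as_binary(.data$barretts),
    histology = norm_factor(.data$histology, "histology"),
    surgery = as_binary(.data$surgery),
    modality = as_binary(.data$modality),
    g4ril = as_binary(.data$g4ril),
    os_months = {
      v <- as_num(.data$os_months)
      ifelse(!is.na(v) & v > 0, v, NA_real_)
    },
    event = as_binary(.data$event)
  )

  ok <- stats::complete.cases(out)
  n_rejected <- sum(!ok)
  out <- out[ok, ]
  if (anyDuplicated(out$id)) abort("duplicate patient ids after validation")
  if (!quiet && n_rejected > 0) {
    inform(sprintf("validate_cohort: rejected %d row(s) with missing or out-of-domain values", n_rejected))
  }
  attr(out, "n_rejected") <- n_rejected
  attr(out, "provenance") <- attr(data, "provenance") %||% "observed"
  out
}

#' Read a patient-level cohort CSV
#'
#' @param path CSV file with a header row, UTF-8, "." decimal separator.
#' @param col_map optional named character vector mapping canonical column
#'   names to the file's headers, e.g. `c(os_months = "OS_time")`.
#' @param quiet suppress the rejected-row message.
#' @return a validated cohort tibble (see [validate_cohort()]).
#' @export
read_cohort <- function(path, col_map = NULL, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      ext <- col_map[[canon]]
      if (!ext %in% names(raw)) abort(paste0("mapped column not in file: ", ext))
      names(raw)[names(raw) == ext] <- canon
    }
  }
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  validate_cohort(raw, quiet = quiet)
}

#' Write a cohort table to CSV
#'
#' Round-trips with [read_cohort()]: `read_cohort(write_cohort(x, p))` is
#' field-identical to `x`.
#'
#' @param data validated cohort tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Group-wise cohort summary with between-group tests
#'
#' Continuous fields are summarised as mean/SD/min/max with a Welch
#' (unequal-variance) two-sample t-test by default; categorical fields as
#' count/percent with a Pearson chi-squared test (continuity correction on
#' 2x2 tables by default). Mirrors the usual "Table 1" of a two-arm
#' observational comparison.
#'
#' @param data validated cohort tibble.
#' @param by grouping column name (character), e.g. `"modality"`.
#' @param welch use Welch's t (default) rather than the pooled-variance t.
#' @param correct apply the continuity correction to 2x2 chi-squared tables.
#' @return a tibble with one row per variable level and columns per group:
#'   `variable`, `level`, `stat_<group>` and `p_value` (repeated within a
#'   variable).
#' @export
summarize_cohort <- function(data, by = "modality", welch = TRUE, correct = TRUE) {
  if (!by %in% names(data)) abort(paste0("grouping column not found: ", by))
  g <- factor(data[[by]])
  groups <- levels(g)
  vars <- setdiff(cohort_columns(), c("id", by))
  vars <- intersect(vars, names(data))

  one_cont <- function(v) {
    x <- data[[v]]
    rows <- purrr::map(groups, function(lv) {
      xi <- x[g == lv]
      s <- if (length(xi) >= 2) sprintf("%.1f", sd(xi)) else "NA"
      tibble::tibble(group = lv,
                     stat = sprintf("%.1f, %s (%.1f-%.1f)", mean(xi), s, min(xi), max(xi)))
    })
    p <- NA_real_
    if (length(groups) == 2 && all(table(g) >= 2)) {
      p <- tryCatch(stats::t.test(x ~ g, var.equal = !welch)$p.value, error = function(e) NA_real_)
    } else if (length(groups) > 2) {
      p <- tryCatch(stats::oneway.test(x ~ g, var.equal = !welch)$p.value, error = function(e) NA_real_)
    }
    dplyr::bind_rows(rows) |>
      tidyr::pivot_wider(names_from = "group", values_from = "stat", names_prefix = "stat_") |>
      dplyr::mutate(variable = v, level = "mean, SD (min-max)", p_value = p, .before = 1)
  }

  one_cat <- function(v) {
    x <- factor(data[[v]])
    tab <- table(x, g)
    p <- NA_real_
    if (nrow(tab) >= 2 && ncol(tab) >= 2 && all(colSums(tab) > 0)) {
      use_cc <- correct && nrow(tab) == 2 && ncol(tab) == 2
      p <- tryCatch(suppressWarnings(stats::chisq.test(tab, correct = use_cc)$p.value),
                    error = function(e) NA_real_)
    }
    purrr::map_dfr(rownames(tab), function(lv) {
      row <- tibble::tibble(variable = v, level = lv, p_value = p)
      for (gp in groups) {
        n <- tab[lv, gp]
        pct <- 100 * n / sum(tab[, gp])
        row[[paste0("stat_", gp)]] <- sprintf("%d (%.1f)", n, pct)
      }
      row
    })
  }

  is_cont <- function(v) v %in% c("age", "baseline_alc", "ptv", "chemo_cycles", "os_months")
  out <- purrr::map_dfr(vars, function(v) if (is_cont(v)) one_cont(v) else one_cat(v))
  attr(out, "group_sizes") <- setNames(as.integer(table(g)), groups)
  out
}
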