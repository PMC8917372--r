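#' Pipeline run configuration
#'
#' One configuration object drives the whole analysis: simulate (or load)
#' microdata, build the analytic sample, score precarity, estimate
#' design-based distributions, fit the six nested models, and render the
#' report tables. Every threshold used downstream (salary multiple, workday
#' band, high-precarity cut, GOF groups) is explicit here and echoed into
#' the run metadata.
#'
#' @param input Optional path to a schema-conforming microdata CSV; if
#'   `NULL`, data are generated with `params`.
#' @param params [sim_params()] for synthetic generation.
#' @param nurse_codes Occupation codes treated as nurses.
#' @param required_fields Completeness rule for [build_analytic_sample()].
#' @param high_cut Precarity-level threshold, default 3.
#' @param salary_mw_multiple,hours_low,hours_high Precarity flag thresholds.
#' @param mw_table Optional per-year minimum-wage table for real-data runs
#'   (tibble: `year`, `minimum_wage`) applied when the input carries currency
#'   income instead of `income_mw`.
#' @param design_cols Names of the stratum/PSU/weight columns.
#' @param references Model reference categories, see [build_model_spec()].
#' @param gof_groups Groups for the goodness-of-fit test.
#' @param seed Overrides `params$seed` when not `NULL`.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL,
                       params = sim_params(),
                       nurse_codes = nurse_codes_synthetic(),
                       required_fields = default_required_fields(),
                       high_cut = 3L,
                       salary_mw_multiple = 2,
                       hours_low = 34, hours_high = 48,
                       mw_table = NULL,
                       design_cols = list(strata = "stratum_id", psu = "psu_id",
                                          weight = "weight"),
                       references = list(sector = "private", sex = "male",
                                         age_band = "25-54",
                                         marital = "married_union", n_jobs = "1",
                                         residence = "metropolitan", region = "1"),
                       gof_groups = 10L,
                       seed = NULL) {
  if (!is.null(input) && !file.exists(input)) {
    abort_config(sprintf("input file '%s' does not exist", input))
  }
  if (!is.null(seed)) params$seed <- as.integer(seed)
  structure(list(input = input, params = params, nurse_codes = nurse_codes,
                 required_fields = required_fields, high_cut = high_cut,
                 salary_mw_multiple = salary_mw_multiple,
                 hours_low = hours_low, hours_high = hours_high,
                 mw_table = mw_table, design_cols = design_cols,
                 references = references, gof_groups = gof_groups),
            class = "run_config")
}

five_group_labels <- function() {
  c("unemployed", "underemployed_nonprecarious", "underemployed_precarious",
    "employed_nonprecarious", "employed_precarious")
}

# five-way classification behind the characteristics cross-tabulation
five_group <- function(data) {
  out <- ifelse(data$labor_status == "unemployed", "unemployed",
         ifelse(data$labor_status == "underemployed",
                ifelse(data$score == 0L, "underemployed_nonprecarious",
                       "underemployed_precarious"),
                ifelse(data$score == 0L, "employed_nonprecarious",
                       "employed_precarious")))
  factor(out, levels = five_group_labels())
}

#' Weighted characteristics cross-tabulation
#'
#' For every category of every listed covariate, the design-based row
#' distribution across the five labor/precarity groups (unemployed;
#' underemployed non-precarious/precarious; health-sector employed
#' non-precarious/precarious), with 95% CIs. The first rows give the overall
#' weighted group sizes and shares.
#'
#' @param design A [svy_design()] over a scored analytic sample.
#' @param vars Covariates to tabulate.
#' @return A tidy tibble: `variable`, `category`, `group`, estimate columns.
#' @export
table1_crosstab <- function(design,
                            vars = c("sex", "age_band", "marital", "university",
                                     "sector", "n_jobs", "residence", "region")) {
  dat <- design$variables
  dat$group5 <- five_group(dat)
  d2 <- design
  d2$variables <- dat

  rows <- list()
  for (g in five_group_labels()) {
    est <- svy_prop(d2, dat$group5 == g)
    est$variable <- "overall"; est$category <- "all"; est$group <- g
    est$n_weighted_group <- sum(dat$weight[dat$group5 == g])
    rows[[length(rows) + 1]] <- est
  }
  for (v in vars) {
    col <- dat[[v]]
    cats <- if (is.factor(col)) levels(col) else sort(unique(col[!is.na(col)]), method = "radix")
    cats <- setdiff(as.character(cats), "none")
    for (ct in cats) {
      dom <- !is.na(col) & as.character(col) == ct
      if (!any(dom)) next
      for (g in five_group_labels()) {
        est <- svy_prop(d2, dat$group5 == g, domain = dom)
        est$variable <- v; est$category <- ct; est$group <- g
        est$n_weighted_group <- sum(dat$weight[dom & dat$group5 == g])
        rows[[length(rows) + 1]] <- est
      }
    }
  }
  dplyr::bind_rows(rows)[, c("variable", "category", "group", "estimate", "se",
                             "ci_low", "ci_high", "n_unweighted", "n_weighted",
                             "n_weighted_group")]
}

#' Precarity-level distribution by sector and period
#'
#' Among health-sector employees, the design-based share of each precarity
#' level (`non_or_low` vs `high`, cut at the configured score threshold) per
#' labor sector and government period.
#'
#' @param design A [svy_design()] over a scored analytic sample.
#' @return A tidy tibble with one row per (sector, period, level).
#' @export
precarity_level_distribution <- function(design) {
  dat <- design$variables
  emp <- dat$labor_status == "employed_health"
  rows <- list()
  for (s in c("private", "public")) {
    for (per in levels(dat$period)) {
      dom <- emp & dat$sector == s & dat$period == per
      if (!any(dom)) {
        warning(sprintf("no employed records for sector %s in %s; omitted", s, per))
        next
      }
      for (lv in c("non_or_low", "high")) {
        est <- svy_prop(design, !is.na(dat$level) & dat$level == lv, domain = dom)
        est$sector <- s; est$period <- per; est$level <- lv
        rows[[length(rows) + 1]] <- est
      }
    }
  }
  dplyr::bind_rows(rows)[, c("sector", "period", "level", "estimate", "se",
                             "ci_low", "ci_high", "n_unweighted", "n_weighted")]
}

headline_changes <- function(fig1, fig2) {
  pers <- unique(fig1$period)
  first <- pers[1]; last <- pers[length(pers)]
  pick1 <- function(st, per) {
    100 * fig1$estimate[fig1$period == per & fig1$labor_status == st]
  }
  pick2 <- function(sec, per) {
    100 * fig2$estimate[fig2$period == per & fig2$sector == sec &
                          fig2$level == "non_or_low"]
  }
  tibble::tibble(
    quantity = c("underemployment_share", "employment_share",
                 "private_non_or_low_precarious", "public_non_or_low_precarious"),
    p_start = c(pick1("underemployed", first), pick1("employed_health", first),
                pick2("private", first), pick2("public", first)),
    p_end = c(pick1("underemployed", last), pick1("employed_health", last),
              pick2("private", last), pick2("public", last)),
    relative_change = relative_change(
      c(pick1("underemployed", first), pick1("employed_health", first),
        pick2("private", first), pick2("public", first)),
      c(pick1("underemployed", last), pick1("employed_health", last),
        pick2("private", last), pick2("public", last)))
  )
}

#' Run the full analysis pipeline
#'
#' Composes simulate/load, cohort construction, precarity scoring,
#' design-based estimation, the six nested survey-weighted logistic models
#' with goodness-of-fit, adjusted prevalences by period and region, and the
#' headline relative changes. When `out_dir` is given, every table is
#' written as CSV with a metadata header (seed and configuration hash) via
#' [render_tables()].
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return (Invisibly) a `pipeline_result` list with all computed objects.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  say("stage simulate/load: %s",
      if (is.null(config$input)) "generating synthetic microdata" else config$input)
  records <- tryCatch({
    if (is.null(config$input)) simulate_enoe(config$params)
    else read_microdata(config$input)
  }, error = function(e) stop("stage simulate/load failed: ", conditionMessage(e)))

  say("stage classify: building analytic sample from %d records", nrow(records))
  built <- tryCatch(
    build_analytic_sample(records, config$nurse_codes, config$required_fields),
    error = function(e) stop("stage classify failed: ", conditionMessage(e)))

  say("stage score: precarity components (high_cut = %d)", config$high_cut)
  scored <- tryCatch(
    add_precarity(built$sample, config$high_cut, config$salary_mw_multiple,
                  config$hours_low, config$hours_high),
    error = function(e) stop("stage score failed: ", conditionMessage(e)))

  dcols <- config$design_cols
  design <- svy_design(scored, dcols$strata, dcols$psu, dcols$weight)

  say("stage estimate: status, characteristics and precarity-level tables")
  res <- tryCatch({
    fig1 <- labor_status_distribution(design)
    tab1 <- table1_crosstab(design)
    fig2 <- precarity_level_distribution(design)
    list(fig1 = fig1, tab1 = tab1, fig2 = fig2)
  }, error = function(e) stop("stage estimate failed: ", conditionMessage(e)))

  say("stage fit: six nested survey-weighted logistic models")
  models <- list()
  gof <- list()
  margins <- list()
  for (smp in c("underemployed_plus_employed", "employed_only")) {
    for (lvl in 1:3) {
      key <- sprintf("%s_m%d", smp, lvl)
      spec <- build_model_spec(smp, lvl, config$references)
      fit <- tryCatch(fit_model_spec(design, spec),
                      error = function(e) stop(sprintf(
                        "stage fit failed (%s): %s", key, conditionMessage(e))))
      models[[key]] <- fit
      gof[[key]] <- archer_lemeshow_gof(fit, config$gof_groups)
      if (lvl == 3) {
        margins[[smp]] <- adjusted_prevalence(fit, by = c("period", "region"))
      }
    }
  }

  say("stage report: headline relative changes")
  changes <- headline_changes(res$fig1, res$fig2)

  result <- structure(list(
    config = config, audit = built$audit, sample = scored, design = design,
    status_distribution = res$fig1, characteristics = res$tab1,
    precarity_levels = res$fig2, models = models, gof = gof,
    adjusted_prevalence = margins, headline_changes = changes
  ), class = "pipeline_result")

  if (!is.null(out_dir)) render_tables(result, out_dir)
  invisible(result)
}

model_summary_table <- function(result) {
  rows <- list()
  for (key in names(result$models)) {
    fit <- result$models[[key]]
    tab <- adjusted_odds_ratios(fit)
    tab$model <- key
    g <- result$gof[[key]]
    tab$gof_f <- g$f_statistic
    tab$gof_p <- g$p_value
    tab$n_obs <- fit$n_obs
    rows[[length(rows) + 1]] <- tab
  }
  dplyr::bind_rows(rows)[, c("model", "n_obs", "term", "beta", "se", "aor",
                             "ci_low", "ci_high", "p_value", "gof_f", "gof_p")]
}

#' Write the pipeline's report tables
#'
#' CSV always (full precision, one `#`-prefixed metadata line with seed and
#' configuration hash); `format = "text"` additionally writes a short
#' human-readable summary with percentages to one decimal.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @param format `"csv"` or `"text"` (text implies csv).
#' @return (Invisibly) the paths written.
#' @export
render_tables <- function(result, out_dir, format = c("csv", "text")) {
  stopifnot(inherits(result, "pipeline_result"))
  format <- match.arg(format)
  if (nrow(result$status_distribution) == 0) abort_validation("empty results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- sprintf("seed=%d config_hash=%s", result$config$params$seed,
                  rlang::hash(result$config))

  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    writeLines(paste0("# ", meta), path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
    path
  }
  paths <- c(
    emit(tibble::as_tibble(unclass(result$audit)), "audit.csv"),
    emit(result$status_distribution, "status_distribution.csv"),
    emit(result$characteristics, "characteristics_table.csv"),
    emit(result$precarity_levels, "precarity_levels.csv"),
    emit(model_summary_table(result), "model_results.csv"),
    emit(dplyr::bind_rows(result$adjusted_prevalence, .id = "sample"),
         "adjusted_prevalence.csv"),
    emit(result$headline_changes, "headline_changes.csv")
  )

  meta_path <- file.path(out_dir, "run_metadata.yaml")
  yaml::write_yaml(list(
    seed = result$config$params$seed,
    config_hash = rlang::hash(result$config),
    high_cut = result$config$high_cut,
    salary_mw_multiple = result$config$salary_mw_multiple,
    hours_band = c(result$config$hours_low, result$config$hours_high),
    gof_groups = result$config$gof_groups,
    audit = unclass(result$audit)
  ), meta_path)
  paths <- c(paths, meta_path)

  if (format == "text") {
    txt <- file.path(out_dir, "summary.txt")
    ch <- result$headline_changes
    lines <- c("Headline relative changes (first vs last period)",
               sprintf("  %-32s %6.1f%% -> %6.1f%%  (%+.1f%%)",
                       ch$quantity, round1(ch$p_start), round1(ch$p_end),
                       ch$relative_change))
    writeLines(lines, txt)
    paths <- c(paths, txt)
  }
  invisible(paths)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  print(x$audit)
  cat("\nHeadline relative changes:\n")
  print(x$headline_changes)
  invisible(x)
}
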