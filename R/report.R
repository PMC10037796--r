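#' Descriptive statistics by sex for one completed table
#'
#' Per-variable percentage (mediators) or mean (gender scores) by sex plus
#' the male-female gap, as a named vector keyed `desc|male|<var>`,
#' `desc|female|<var>`, `desc|gap|<var>` (and `score|<set>|<population>|...`
#' blocks when score sets are requested). Used as (part of) a bootstrap
#' estimator, so the descriptive table inherits percentile intervals.
#'
#' @param table Complete table.
#' @param varsets List of [variable_set()]s whose score models are fitted
#'   and summarized (empty list: mediator prevalences only).
#' @return Named numeric vector.
#' @export
compute_descriptives <- function(table, varsets = list()) {
  if (all(table$sex == 1) || all(table$sex == 0)) {
    stop("compute_descriptives: both sexes must be present", call. = FALSE)
  }
  out <- c()
  meds <- intersect(mediator_registry()$name, names(table))
  for (m in meds) {
    pm <- 100 * mean(table[[m]][table$sex == 1])
    pf <- 100 * mean(table[[m]][table$sex == 0])
    out[paste0("desc|male|", m)] <- pm
    out[paste0("desc|female|", m)] <- pf
    out[paste0("desc|gap|", m)] <- pm - pf
  }
  for (vs in varsets) {
    mod <- fit_gender_model(table, vs)
    sc <- predict_gender_score(mod, table)
    blocks <- describe_scores_by_group(sc, table$sex, table$deprived)
    for (i in seq_len(nrow(blocks))) {
      base <- paste0("score|", vs$name, "|", blocks$population[i])
      out[paste0(base, "|male")] <- blocks$mean_male[i]
      out[paste0(base, "|female")] <- blocks$mean_female[i]
      out[paste0(base, "|gap")] <- blocks$gap[i]
    }
  }
  out
}

#' Descriptive table by sex with bootstrap intervals
#'
#' Reshapes a [bootstrap_pipeline()] result whose estimator included
#' [compute_descriptives()] into the descriptive layout: one row per
#' variable (and per score set and population block) with the male and
#' female summaries, their percentile intervals and the male-female gap.
#'
#' @param boot A `bootstrap_result`.
#' @return Tibble with columns `variable`, `population`, `male`,
#'   `male_low`, `male_high`, `female`, `female_low`, `female_high`,
#'   `gap`, `gap_low`, `gap_high`.
#' @export
descriptives_by_sex <- function(boot) {
  stopifnot(inherits(boot, "bootstrap_result"))
  keys <- colnames(boot$estimates)
  desc <- grep("^desc\\|", keys, value = TRUE)
  score <- grep("^score\\|", keys, value = TRUE)
  if (length(desc) + length(score) == 0) {
    stop("descriptives_by_sex: bootstrap result carries no descriptive keys",
         call. = FALSE)
  }
  pull <- function(key) {
    c(boot$point[[key]], boot$ci["low", key], boot$ci["high", key])
  }
  rows <- list()
  vars <- unique(sub("^desc\\|[a-z]+\\|", "", desc))
  for (v in vars) {
    m <- pull(paste0("desc|male|", v))
    f <- pull(paste0("desc|female|", v))
    g <- pull(paste0("desc|gap|", v))
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = v, population = "total",
      male = m[1], male_low = m[2], male_high = m[3],
      female = f[1], female_low = f[2], female_high = f[3],
      gap = g[1], gap_low = g[2], gap_high = g[3])
  }
  score_base <- unique(sub("\\|(male|female|gap)$", "", score))
  for (b in score_base) {
    parts <- strsplit(b, "|", fixed = TRUE)[[1]]
    m <- pull(paste0(b, "|male"))
    f <- pull(paste0(b, "|female"))
    g <- pull(paste0(b, "|gap"))
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = paste0("gender_score_", parts[2]), population = parts[3],
      male = m[1], male_low = m[2], male_high = m[3],
      female = f[1], female_low = f[2], female_high = f[3],
      gap = g[1], gap_low = g[2], gap_high = g[3])
  }
  dplyr::bind_rows(rows)
}

fmt <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

fmt_ci <- function(lo, hi, digits) {
  ifelse(is.na(lo) | is.na(hi), "",
         paste0("[", fmt(lo, digits), " to ", fmt(hi, digits), "]"))
}

star <- function(lo, hi) {
  ifelse(!is.na(lo) & !is.na(hi) & (lo > 0 | hi < 0), "*", "")
}

#' Render estimand tables
#'
#' Renders a tidy estimand table into one of the paper-style layouts:
#' `"TE-table"` (one row per biomarker, original-scale and z-scale total
#' effects), `"EP-table"` (eliminated proportions in percent by strategy
#' and variable set), `"interaction-table"` (per biomarker and scale: four
#' cell means, stratum sex effects, deprivation effects by sex, additive
#' interaction). Output is a fixed-column tibble (full precision, for CSV)
#' plus markdown lines (journal-table decimal conventions: 1 decimal for percents,
#' 2 for effects; significance stars where the percentile interval
#' excludes zero). Missing cells render as explicit `NA` with a warning.
#'
#' @param estimates Tidy estimand tibble (with CI columns filled for
#'   starring).
#' @param layout One of `"TE-table"`, `"EP-table"`, `"interaction-table"`.
#' @return List with `csv` (tibble) and `markdown` (character vector).
#' @export
render_results <- function(estimates,
                           layout = c("TE-table", "EP-table",
                                      "interaction-table")) {
  layout <- match.arg(layout)
  if (nrow(estimates) == 0) {
    return(list(csv = tibble::tibble(), markdown = character(0)))
  }
  get1 <- function(est, out, sc, set = NA) {
    sel <- estimates$estimand == est & estimates$outcome == out &
      estimates$scale == sc &
      (is.na(set) | (!is.na(estimates$set) & estimates$set == set))
    row <- estimates[sel, , drop = FALSE]
    if (nrow(row) == 0) {
      warning("render_results: missing cell ", est, "/", out, "/", sc,
              if (!is.na(set)) paste0("/", set), call. = FALSE)
      return(tibble::tibble(point = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_))
    }
    row[1, c("point", "ci_low", "ci_high")]
  }
  outs <- intersect(biomarker_registry()$name, unique(estimates$outcome))

  if (layout == "TE-table") {
    scales <- intersect(c("original", "z"),
                        unique(estimates$scale[estimates$estimand == "TE"]))
    rows <- lapply(outs, function(o) {
      row <- tibble::tibble(outcome = o)
      for (sc in scales) {
        v <- get1("TE", o, sc)
        pre <- paste0("te_", sc)
        row[[pre]] <- v$point
        row[[paste0(pre, "_low")]] <- v$ci_low
        row[[paste0(pre, "_high")]] <- v$ci_high
      }
      row
    })
    csv <- dplyr::bind_rows(rows)
    hdr <- paste0("| Biomarker |",
                  paste(vapply(scales, function(sc)
                    paste0(" TE (", sc, ") | 95% CI |"), character(1)),
                    collapse = ""))
    md <- c(hdr,
            paste0("|", paste(rep("---|", 1 + 2 * length(scales)),
                              collapse = "")),
            vapply(seq_len(nrow(csv)), function(i) {
              r <- csv[i, ]
              cells <- vapply(scales, function(sc) {
                pre <- paste0("te_", sc)
                paste0(" ", fmt(r[[pre]], 2),
                       star(r[[paste0(pre, "_low")]],
                            r[[paste0(pre, "_high")]]), " | ",
                       fmt_ci(r[[paste0(pre, "_low")]],
                              r[[paste0(pre, "_high")]], 2), " |")
              }, character(1))
              paste0("| ", r$outcome, " |", paste(cells, collapse = ""))
            }, character(1)))
    return(list(csv = csv, markdown = md))
  }

  if (layout == "EP-table") {
    eps <- estimates[estimates$estimand %in%
                       c("EP_G", "EP_Sigma", "EP_E") &
                       estimates$scale == "z", , drop = FALSE]
    csv <- tibble::tibble(
      outcome = eps$outcome,
      strategy = c(EP_G = "a", EP_Sigma = "b", EP_E = "c")[eps$estimand],
      set = ifelse(is.na(eps$set) | eps$set == "", "-", eps$set),
      ep_pct = 100 * eps$point,
      ep_low_pct = 100 * eps$ci_low,
      ep_high_pct = 100 * eps$ci_high,
      unstable = eps$unstable)
    csv <- csv[order(match(csv$outcome, outs), csv$strategy, csv$set), ]
    md <- c("| Biomarker | Strategy | Set | EP (%) | 95% CI |",
            "|---|---|---|---|---|",
            vapply(seq_len(nrow(csv)), function(i) {
              r <- csv[i, ]
              paste0("| ", r$outcome, " | (", r$strategy, ") | ", r$set,
                     " | ", fmt(r$ep_pct, 1),
                     star(r$ep_low_pct, r$ep_high_pct),
                     ifelse(isTRUE(r$unstable), " (unstable)", ""), " | ",
                     fmt_ci(r$ep_low_pct, r$ep_high_pct, 1), " |")
            }, character(1)))
    return(list(csv = csv, markdown = md))
  }

  # interaction-table
  rows <- list()
  for (o in outs) {
    for (sc in intersect(c("original", "z"), unique(estimates$scale))) {
      vals <- list(
        mean_male_adv = get1("CellMean10", o, sc),
        mean_male_dep = get1("CellMean11", o, sc),
        mean_female_adv = get1("CellMean00", o, sc),
        mean_female_dep = get1("CellMean01", o, sc),
        te_advantaged = get1("TE0", o, sc),
        te_deprived = get1("TE1", o, sc),
        deprivation_effect_male = get1("DeprivationEffect1", o, sc),
        deprivation_effect_female = get1("DeprivationEffect0", o, sc),
        interaction = get1("IE", o, sc))
      row <- tibble::tibble(outcome = o, scale = sc)
      for (nm in names(vals)) {
        row[[nm]] <- vals[[nm]]$point
        row[[paste0(nm, "_low")]] <- vals[[nm]]$ci_low
        row[[paste0(nm, "_high")]] <- vals[[nm]]$ci_high
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  csv <- dplyr::bind_rows(rows)
  md <- c(paste("| Biomarker | Scale | M adv | M dep | F adv | F dep |",
                "TE adv | TE dep | DepEff M | DepEff F | IE |"),
          "|---|---|---|---|---|---|---|---|---|---|---|",
          vapply(seq_len(nrow(csv)), function(i) {
            r <- csv[i, ]
            cells <- vapply(
              c("mean_male_adv", "mean_male_dep", "mean_female_adv",
                "mean_female_dep", "te_advantaged", "te_deprived",
                "deprivation_effect_male", "deprivation_effect_female",
                "interaction"),
              function(nm) paste0(fmt(r[[nm]], 2),
                                  star(r[[paste0(nm, "_low")]],
                                       r[[paste0(nm, "_high")]])),
              character(1))
            paste0("| ", r$outcome, " | ", r$scale, " | ",
                   paste(cells, collapse = " | "), " |")
          }, character(1)))
  list(csv = csv, markdown = md)
}

#' Pipeline configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()];
#' accepts a YAML file path or a list of overrides on top of the defaults.
#'
#' @param config A YAML file path, a list of overrides, or `NULL` for the
#'   defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(config = NULL) {
  defaults <- list(
    data = list(source = "simulate", path = NULL, n = 4000, seed = 58,
                missingness = TRUE),
    outcomes = biomarker_registry()$name,
    strategies = c("a", "b", "c"),
    sets = "complete",
    scales = c("original", "z"),
    g0 = 0.5,
    ref_values = NULL,
    complete_cases = FALSE,
    bootstrap = list(B = 1000, seed = 1),
    imputation = list(cycles = 10),
    out_dir = NULL)
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    # YAML 1.1 reads a bare `n:` key as boolean FALSE; map it back
    if (!is.null(config$data) && "FALSE" %in% names(config$data)) {
      names(config$data)[names(config$data) == "FALSE"] <- "n"
    }
  }
  cfg <- utils::modifyList(defaults, config %||% list())
  stopifnot(cfg$data$source %in% c("simulate", "csv"),
            all(cfg$strategies %in% c("a", "b", "c")),
            all(cfg$outcomes %in% biomarker_registry()$name))
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, preprocessing, the bootstrap-then-impute loop
#' (descriptives, gender scores and all estimands inside each replicate)
#' and table rendering. With `complete_cases = TRUE` the analysis is
#' restricted to rows fully observed on all analysis variables and never
#' imputes (the sensitivity-analysis proxy).
#'
#' @param config See [pipeline_config()].
#' @return Invisibly, a list with `table` (analysed data), `boot`,
#'   `estimates` (tidy, with CIs), `descriptives`, the three rendered
#'   tables and `log` (character run log). When `out_dir` is set,
#'   everything is also written to disk as CSV/markdown/text.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  log_lines <- c(paste0("gendermech run, ", format(Sys.time(), "%Y-%m-%d")),
                 paste0("R ", getRversion()))
  stage <- function(msg) log_lines <<- c(log_lines, msg)

  tab <- tryCatch({
    if (cfg$data$source == "simulate") {
      p <- sim_params(seed = cfg$data$seed)
      t0 <- generate_cohort(p, n = cfg$data$n, seed = cfg$data$seed)
      if (isTRUE(cfg$data$missingness)) {
        t0 <- inject_missingness(t0, p, seed = cfg$data$seed)
      }
      stage(paste0("simulate: n = ", nrow(t0), ", seed = ", cfg$data$seed,
                   ", missingness = ", isTRUE(cfg$data$missingness)))
      t0
    } else {
      t0 <- read_cohort_csv(cfg$data$path)
      stage(paste0("ingest: ", cfg$data$path, ", n = ", nrow(t0)))
      t0
    }
  }, error = function(e) stop("[data] ", conditionMessage(e), call. = FALSE))

  tab <- tryCatch(transform_outcomes(tab),
                  error = function(e) stop("[preprocess] ",
                                           conditionMessage(e),
                                           call. = FALSE))
  varsets <- lapply(cfg$sets, function(s) variable_set(s))
  used_cols <- unique(c("sex", "deprived",
                        unlist(lapply(varsets, `[[`, "mediators")),
                        biomarker_registry()$analysis_col[
                          biomarker_registry()$name %in% cfg$outcomes]))
  if (isTRUE(cfg$complete_cases)) {
    keep <- stats::complete.cases(tab[, used_cols])
    # drop unused (possibly still incomplete) columns so the bootstrap sees
    # a fully observed table and never imputes
    breg_used <- biomarker_registry()[
      biomarker_registry()$name %in% cfg$outcomes, , drop = FALSE]
    tab <- tab[keep, unique(c(intersect(c("id", "sex",
                                          "mother_short_education",
                                          "parent_manual_class",
                                          "deprived"), names(tab)),
                              setdiff(used_cols, c("sex", "deprived")),
                              breg_used$name)), drop = FALSE]
    stage(paste0("complete cases: ", sum(keep), " rows retained"))
  }

  estimator <- function(completed, seed) {
    est <- compute_estimands(completed, outcomes = cfg$outcomes,
                             varsets = varsets,
                             strategies = cfg$strategies,
                             scales = cfg$scales, g0 = cfg$g0,
                             ref_values = cfg$ref_values)
    desc <- compute_descriptives(
      completed,
      varsets = if ("a" %in% cfg$strategies) varsets else list())
    c(stats::setNames(est$point, est$key), desc)
  }

  boot <- tryCatch(
    bootstrap_pipeline(tab, estimator, B = cfg$bootstrap$B,
                       master_seed = cfg$bootstrap$seed,
                       impute_spec = imputation_spec(
                         cycles = cfg$imputation$cycles)),
    error = function(e) stop("[bootstrap] ", conditionMessage(e),
                             call. = FALSE))
  stage(paste0("bootstrap: B = ", boot$B, ", failures = ", boot$failures,
               ", imputed replicates = ", boot$imputed_replicates))

  template <- tryCatch({
    completed <- if (anyNA(tab[, setdiff(names(tab), "id")])) {
      impute_stochastic(tab, imputation_spec(cfg$imputation$cycles),
                        seed = cfg$bootstrap$seed)
    } else {
      tab
    }
    compute_estimands(completed, outcomes = cfg$outcomes, varsets = varsets,
                      strategies = cfg$strategies, scales = cfg$scales,
                      g0 = cfg$g0, ref_values = cfg$ref_values)
  }, error = function(e) stop("[estimands] ", conditionMessage(e),
                              call. = FALSE))
  estimates <- summarize_bootstrap(boot, template)
  descriptives <- descriptives_by_sex(boot)

  tables <- list(
    te_table = render_results(estimates, "TE-table"),
    ep_table = if (length(intersect(cfg$strategies, c("a", "b", "c"))) > 0)
      render_results(estimates, "EP-table") else NULL,
    interaction_table = render_results(estimates, "interaction-table"))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(estimates, file.path(cfg$out_dir, "estimates.csv"),
                     progress = FALSE)
    readr::write_csv(descriptives,
                     file.path(cfg$out_dir, "descriptives.csv"),
                     progress = FALSE)
    for (nm in names(tables)) {
      if (is.null(tables[[nm]])) next
      readr::write_csv(tables[[nm]]$csv,
                       file.path(cfg$out_dir, paste0(nm, ".csv")),
                       progress = FALSE)
      writeLines(tables[[nm]]$markdown,
                 file.path(cfg$out_dir, paste0(nm, ".md")))
    }
    writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  }

  invisible(list(table = tab, boot = boot, estimates = estimates,
                 descriptives = descriptives, tables = tables,
                 config = cfg, log = log_lines))
}
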