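#' Build a 2x2 contingency table for one exposure contrast
#'
#' The exposed cells hold subjects in the contrast category at the
#' record's latency; the unexposed cells hold subjects never exposed over
#' the entire study period (the same referent for every contrast at a
#' latency). Subjects who were exposed but fail the latency induction
#' criterion belong to neither cell and are excluded, as are subjects
#' without an analyzable water-source history.
#'
#' @param subjects subject table with `subject_id` and `status`.
#' @param records exposure records from [compute_exposure()] at one
#'   latency and scenario.
#' @param contrast `"ever"`, `">0-5"`, `">5"` or `">10"`.
#' @return An object of class `contingency_table` with counts `a`
#'   (exposed cases), `b` (exposed controls), `c` (unexposed cases), `d`
#'   (unexposed controls).
#' @export
build_table <- function(subjects, records, contrast = "ever") {
  subjects <- as.data.frame(subjects)
  rec <- records[match(subjects$subject_id, records$subject_id), ]
  is_case <- subjects$status == "case"
  ana <- rec$analyzable
  exp_cell <- ana & rec$ever_exposed &
    in_duration_contrast(rec$duration, contrast)
  ref_cell <- ana & !rec$exposed_any
  if (!any(ref_cell)) stop("empty never-exposed referent group")
  contingency_table(a = sum(exp_cell & is_case),
                    b = sum(exp_cell & !is_case),
                    c = sum(ref_cell & is_case),
                    d = sum(ref_cell & !is_case),
                    contrast = contrast)
}

#' Construct a 2x2 table from counts
#'
#' @param a,b,c,d exposed cases, exposed controls, unexposed cases,
#'   unexposed controls.
#' @param contrast optional label.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, contrast = NULL) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be >= 0")
  structure(list(a = a, b = b, c = c, d = d, contrast = contrast),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<2x2> exposed %d/%d, unexposed %d/%d (cases/controls)\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Crude odds ratio with Woolf 95% confidence interval
#'
#' Point estimate `(a d)/(b c)`; the interval is
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. With any zero
#' cell the estimate is undefined (`defined = FALSE`), mirroring dash
#' entries in published tables; no continuity correction is applied.
#'
#' @param t a [contingency_table()].
#' @param conf_z normal quantile for the interval (default 1.96).
#' @return An object of class `or_result` with `point`, `ci_low`,
#'   `ci_high`, `method = "crude_woolf"` and `defined`.
#' @examples
#' crude_or(contingency_table(7, 2, 535, 704))  # 4.6 (1.0-22.3)
#' @export
crude_or <- function(t, conf_z = 1.96) {
  if (any(c(t$a, t$b, t$c, t$d) == 0)) {
    return(structure(list(point = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, method = "crude_woolf",
                          defined = FALSE), class = "or_result"))
  }
  point <- (t$a * t$d) / (t$b * t$c)
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  structure(list(point = point,
                 ci_low = exp(log(point) - conf_z * se),
                 ci_high = exp(log(point) + conf_z * se),
                 method = "crude_woolf", defined = TRUE),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("<or_result> %s [%s]\n", format_or(x), x$method))
  invisible(x)
}

#' Format an odds-ratio result for display
#'
#' One-decimal half-up rounding, `"-"` for undefined estimates, matching
#' the published table conventions.
#'
#' @param or an `or_result`.
#' @param digits decimals (default 1).
#' @return A string like `"4.6 (1.0-22.3)"`.
#' @export
format_or <- function(or, digits = 1) {
  if (!isTRUE(or$defined)) return("-")
  f <- function(v) sprintf(paste0("%.", digits, "f"),
                           round_half_up(v, digits))
  sprintf("%s (%s-%s)", f(or$point), f(or$ci_low), f(or$ci_high))
}

#' Adjusted odds ratio by multivariable logistic regression
#'
#' Fits case/control status on a binary exposure term plus categorical
#' covariates (dummy-encoded against their reference levels) by maximum
#' likelihood, and reports the adjusted OR as the antilog of the exposure
#' coefficient with a Wald 95% CI. Non-convergence or (quasi-)separation
#' flags the model and suppresses the estimate, mirroring missing
#' adjusted entries for sparse tables.
#'
#' @param data model data frame; must contain `status`
#'   (`case`/`control`) and the exposure column.
#' @param exposure name of the binary exposure column.
#' @param covariates character vector of covariate column names (factors
#'   or discrete vectors), possibly empty.
#' @param conf_z normal quantile for the Wald interval.
#' @return An object of class `logistic_model` with `coefficients`, the
#'   `or_result` for the exposure term, and `converged`/`separation`
#'   flags.
#' @export
fit_logistic <- function(data, exposure, covariates = character(0),
                         conf_z = 1.96) {
  data <- as.data.frame(data)
  data$.y <- as.integer(data$status == "case")
  data[[exposure]] <- as.numeric(data[[exposure]])
  for (cv in covariates) {
    if (!is.factor(data[[cv]])) data[[cv]] <- factor(data[[cv]])
  }
  fml <- stats::reformulate(c(exposure, covariates), response = ".y")
  fit <- suppressWarnings(glm(fml, data = data, family = binomial()))
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  separation <- !fit$converged || any(!is.finite(beta)) ||
    any(abs(beta) > 15) || any(!is.finite(se)) || any(se > 50)
  b <- beta[[exposure]]; s <- se[[exposure]]
  or <- if (separation) {
    structure(list(point = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, method = "adjusted_logistic",
                   defined = FALSE), class = "or_result")
  } else {
    structure(list(point = exp(b),
                   ci_low = exp(b - conf_z * s),
                   ci_high = exp(b + conf_z * s),
                   method = "adjusted_logistic", defined = TRUE),
              class = "or_result")
  }
  structure(list(coefficients = beta, se = se, or = or,
                 converged = fit$converged, separation = separation,
                 exposure = exposure, n = nrow(data)),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> n=%d, AOR(%s) = %s%s\n", x$n, x$exposure,
              format_or(x$or),
              if (x$separation) " [separation/non-convergence]" else ""))
  invisible(x)
}

# model data for one contrast: contrast subjects + never-exposed referent
analysis_data <- function(subjects, records, contrast = "ever") {
  subjects <- as.data.frame(subjects)
  rec <- records[match(subjects$subject_id, records$subject_id), ]
  keep <- rec$analyzable &
    ((rec$ever_exposed & in_duration_contrast(rec$duration, contrast)) |
       !rec$exposed_any)
  out <- subjects[keep, , drop = FALSE]
  out$exposed <- (rec$ever_exposed &
                    in_duration_contrast(rec$duration, contrast))[keep]
  out
}

#' Stratified odds ratios
#'
#' Computes the 2x2 table and crude (and optionally adjusted) OR
#' independently within each level of a subject-level stratifier such as
#' regular bottled-water use.
#'
#' @param subjects subject table.
#' @param records exposure records at one latency and scenario.
#' @param stratifier name of the subject column to stratify on.
#' @param contrast exposure contrast (see [build_table()]).
#' @param covariates covariates for an adjusted OR per stratum; `NULL`
#'   for crude-only.
#' @return Data frame with one row per stratum: sizes, counts, OR and CI
#'   (crude, plus adjusted when requested); undefined results for empty
#'   strata or zero cells.
#' @export
stratified_analysis <- function(subjects, records,
                                stratifier = "bottled_water_ever",
                                contrast = "ever", covariates = NULL) {
  subjects <- as.data.frame(subjects)
  lev <- sort(unique(subjects[[stratifier]]))
  rows <- lapply(lev, function(v) {
    sub <- subjects[subjects[[stratifier]] == v, , drop = FALSE]
    row <- data.frame(stratum = v, n = nrow(sub))
    tab <- try(build_table(sub, records, contrast), silent = TRUE)
    if (inherits(tab, "try-error")) {
      row$a <- row$b <- row$c <- row$d <- NA_integer_
      row$cor <- row$cor_low <- row$cor_high <- NA_real_
      row$cor_defined <- FALSE
      return(row)
    }
    or <- crude_or(tab)
    row$a <- tab$a; row$b <- tab$b; row$c <- tab$c; row$d <- tab$d
    row$cor <- or$point; row$cor_low <- or$ci_low
    row$cor_high <- or$ci_high; row$cor_defined <- or$defined
    if (!is.null(covariates)) {
      m <- fit_logistic(analysis_data(sub, records, contrast),
                        "exposed", covariates)
      row$aor <- m$or$point; row$aor_low <- m$or$ci_low
      row$aor_high <- m$or$ci_high; row$aor_defined <- m$or$defined
    }
    row
  })
  do.call(rbind, rows)
}

#' Full latency-by-scenario-by-contrast analysis grid
#'
#' One row per combination of pumping scenario, latency and exposure
#' contrast: cell counts, crude OR with Woolf CI, optionally the adjusted
#' OR, and display strings with one-decimal half-up rounding and `"-"`
#' for undefined entries.
#'
#' @param subjects subject table.
#' @param records_all exposure records stacked over scenarios and
#'   latencies (from repeated [compute_exposure()] calls).
#' @param contrasts exposure contrasts to tabulate.
#' @param covariates covariate names for adjusted ORs; `NULL` skips them.
#' @return A data frame, ordered by scenario, latency, contrast.
#' @export
run_analysis_grid <- function(subjects, records_all,
                              contrasts = c("ever", ">0-5", ">5", ">10"),
                              covariates = NULL) {
  combos <- unique(records_all[, c("scenario_id", "latency")])
  combos <- combos[order(combos$scenario_id, combos$latency), ]
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    rec <- records_all[records_all$scenario_id == combos$scenario_id[i] &
                         records_all$latency == combos$latency[i], ]
    for (ctr in contrasts) {
      tab <- build_table(subjects, rec, ctr)
      or <- crude_or(tab)
      row <- data.frame(
        scenario_id = combos$scenario_id[i],
        latency = combos$latency[i], contrast = ctr,
        cases_exposed = tab$a, controls_exposed = tab$b,
        cases_unexposed = tab$c, controls_unexposed = tab$d,
        cor = or$point, cor_low = or$ci_low, cor_high = or$ci_high,
        cor_defined = or$defined, cor_text = format_or(or),
        stringsAsFactors = FALSE)
      if (!is.null(covariates)) {
        m <- fit_logistic(analysis_data(subjects, rec, ctr),
                          "exposed", covariates)
        row$aor <- m$or$point; row$aor_low <- m$or$ci_low
        row$aor_high <- m$or$ci_high; row$aor_defined <- m$or$defined
        row$aor_text <- format_or(m$or)
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
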