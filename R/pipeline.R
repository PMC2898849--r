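#' Configuration for an end-to-end pipeline run
#'
#' Bundles everything a full reconstruction-and-analysis run needs.
#' Subjects and residences may be supplied as CSV paths or data frames;
#' when omitted, a synthetic cohort is generated from `cohort` (the
#' outcome is then simulated under the first scenario's schedule).
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed controlling every random draw of the run.
#' @param scenarios named numeric vector of pumping fractions.
#' @param latencies latency periods in years.
#' @param duration_mode `"occupancy"` or `"impacted-only"` (see
#'   [compute_exposure()]).
#' @param n_particles particles per source cell.
#' @param aquifer an `aquifer_model`, an [aquifer_scenario_config()], or
#'   a path to a config file readable by [read_aquifer_config()].
#' @param cohort a [cohort_config()] used when no subject data are given.
#' @param subjects,residences optional CSV paths or data frames.
#' @param systems optional list of [distribution_system()]s (required
#'   when subjects/residences are supplied).
#' @param covariates covariate columns for adjusted ORs (`NULL` = crude
#'   only).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            scenarios = c(low = 0.30, high = 0.75),
                            latencies = c(0, 10, 15, 20),
                            duration_mode = "occupancy",
                            n_particles = 25,
                            aquifer = aquifer_scenario_config(),
                            cohort = cohort_config(),
                            subjects = NULL, residences = NULL,
                            systems = NULL,
                            covariates = c("family_history", "age_cat")) {
  if (any(latencies < 0) || any(latencies != floor(latencies))) {
    stop("latency values must be nonnegative integers")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

load_frame <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("input file not found: ", x)
    read.csv(x, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
}

#' Validate pipeline inputs
#'
#' Checks the subject, residence and well tables against their schemas:
#' required columns, numeric year ranges, start/end ordering, category
#' domains, and overlapping occupancy intervals within a subject. Fatal
#' problems are reported with row numbers.
#'
#' @param cfg a [pipeline_config()], or a list with `subjects`,
#'   `residences` and optionally `wells` entries (paths or data frames).
#' @return An object of class `validation_report`: data frame of issues
#'   (zero rows when clean) with attribute `ok`.
#' @export
validate_inputs <- function(cfg) {
  issues <- data.frame(table = character(0), row = integer(0),
                       problem = character(0), stringsAsFactors = FALSE)
  add <- function(table, row, problem) {
    issues <<- rbind(issues,
                     data.frame(table = table, row = row,
                                problem = problem,
                                stringsAsFactors = FALSE))
  }
  check_cols <- function(df, need, table) {
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      add(table, NA_integer_,
          paste0("missing required column(s): ",
                 paste(miss, collapse = ", ")))
      return(FALSE)
    }
    TRUE
  }
  if (!is.null(cfg$wells)) {
    wells <- load_frame(cfg$wells)
    if (check_cols(wells, c("well_id", "layer", "row", "col",
                            "rated_capacity", "start_year", "end_year",
                            "role"), "wells")) {
      bad <- which(wells$start_year > wells$end_year)
      for (r in bad) add("wells", r, "start_year after end_year")
      bad <- which(wells$rated_capacity < 0)
      for (r in bad) add("wells", r, "negative rated_capacity")
    }
  }
  if (!is.null(cfg$subjects)) {
    subj <- load_frame(cfg$subjects)
    if (check_cols(subj, c("subject_id", "status", "index_year"),
                   "subjects")) {
      bad <- which(!subj$status %in% c("case", "control"))
      for (r in bad) add("subjects", r, "status not case/control")
      bad <- which(!is.finite(subj$index_year))
      for (r in bad) add("subjects", r, "non-numeric index_year")
      if (anyDuplicated(subj$subject_id)) {
        add("subjects", NA_integer_, "duplicated subject_id")
      }
    }
  }
  if (!is.null(cfg$residences)) {
    res <- load_frame(cfg$residences)
    if (check_cols(res, c("subject_id", "address_id", "start_year",
                          "end_year", "source"), "residences")) {
      bad <- which(!is.finite(res$start_year) | !is.finite(res$end_year))
      for (r in bad) add("residences", r, "non-numeric year")
      bad <- which(res$end_year < res$start_year)
      for (r in bad) add("residences", r, "end_year before start_year")
      bad <- which(!res$source %in% c("public", "private", "unknown"))
      for (r in bad) add("residences", r, "source not public/private/unknown")
      # overlapping occupancy intervals within a subject
      sp <- split(seq_len(nrow(res)), res$subject_id)
      for (rows in sp) {
        if (length(rows) < 2) next
        o <- rows[order(res$start_year[rows])]
        olap <- which(res$start_year[o][-1] <=
                        res$end_year[o][-length(o)])
        for (k in olap) {
          add("residences", o[k + 1],
              "occupancy interval overlaps the previous residence")
        }
      }
    }
  }
  structure(issues, class = c("validation_report", "data.frame"),
            ok = nrow(issues) == 0)
}

#' @export
print.validation_report <- function(x, ...) {
  if (isTRUE(attr(x, "ok"))) {
    cat("<validation_report> clean\n")
  } else {
    cat(sprintf("<validation_report> %d issue(s):\n", nrow(x)))
    print(as.data.frame(x))
  }
  invisible(x)
}

#' Run the full reconstruction and analysis pipeline
#'
#' Chains every stage for each pumping scenario: steady-state flow per
#' stress period, particle tracking and first-arrival detection,
#' residential exposure reconstruction at every latency, and the
#' odds-ratio analysis grid. Writes per-scenario impact schedules,
#' tracks, exposure records, head fields, the analysis grid and a
#' manifest with input parameters and MD5 hashes of every output; runs
#' are bit-reproducible for a fixed seed.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with `schedules`, `grids` (the analysis
#'   grid), `records`, `cohort`, `manifest_path`.
#' @export
run_pipeline <- function(cfg) {
  if (!dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }
  model <- if (inherits(cfg$aquifer, "aquifer_model")) {
    cfg$aquifer
  } else if (inherits(cfg$aquifer, "aquifer_scenario_config")) {
    generate_aquifer(cfg$aquifer)
  } else {
    ac <- read_aquifer_config(cfg$aquifer)
    structure(list(grid = ac$grid, props = ac$props, bc = ac$bc,
                   wells = ac$wells,
                   source_cells = ac$wells[ac$wells$role ==
                                             "effluent_source",
                                           c("layer", "row", "col")],
                   horizon = c(min(ac$wells$start_year),
                               max(ac$wells$end_year)),
                   scenario_fractions = cfg$scenarios,
                   config = NULL), class = "aquifer_model")
  }

  scen_results <- list()
  for (s in names(cfg$scenarios)) {
    scen_results[[s]] <- simulate_scenario(
      model, scenario_id = cfg$scenarios[[s]],
      n_particles = cfg$n_particles, seed = cfg$seed)
    scen_results[[s]]$schedule$scenario_id <- s
    scen_results[[s]]$scenario_id <- s
  }

  if (is.null(cfg$subjects)) {
    cc <- cfg$cohort
    cc$seed <- cfg$seed
    cohort <- generate_cohort(cc, model, scen_results[[1]])
    subjects <- cohort$subjects
    residences <- cohort$residences
    systems <- cohort$systems
  } else {
    cohort <- NULL
    subjects <- load_frame(cfg$subjects)
    residences <- load_frame(cfg$residences)
    systems <- cfg$systems
    if (is.null(systems)) {
      stop("distribution systems must be supplied with external cohort data")
    }
  }
  vrep <- validate_inputs(list(subjects = subjects,
                              residences = residences,
                              wells = model$wells))
  if (!isTRUE(attr(vrep, "ok"))) {
    print(vrep)
    stop("input validation failed")
  }

  residences <- assign_water_source(residences, systems)
  records <- list(); grids <- list(); schedules <- list()
  for (s in names(scen_results)) {
    sr <- scen_results[[s]]
    schedules[[s]] <- sr$schedule
    rec_s <- do.call(rbind, lapply(cfg$latencies, function(L) {
      compute_exposure(subjects, residences, sr$schedule, systems,
                       latency = L, scenario_id = s,
                       private_arrivals = sr$private_arrivals,
                       grid = model$grid,
                       duration_mode = cfg$duration_mode)
    }))
    records[[s]] <- rec_s
    grids[[s]] <- run_analysis_grid(subjects, rec_s,
                                    covariates = cfg$covariates)
    write.csv(sr$schedule,
              file.path(cfg$out_dir, sprintf("schedule_%s.csv", s)),
              row.names = FALSE)
    write_tracks_csv(sr$tracks,
                     file.path(cfg$out_dir, sprintf("tracks_%s.csv", s)))
    write.csv(rec_s,
              file.path(cfg$out_dir, sprintf("exposure_%s.csv", s)),
              row.names = FALSE)
    for (k in seq_along(sr$period_fields)) {
      pf <- sr$period_fields[[k]]
      write_field_csv(pf$heads$head,
                      file.path(cfg$out_dir,
                                sprintf("heads_%s_p%d_%d-%d.csv", s, k,
                                        pf$period$start_year,
                                        pf$period$end_year)))
    }
  }
  grid_all <- do.call(rbind, grids)
  rownames(grid_all) <- NULL
  write.csv(grid_all, file.path(cfg$out_dir, "analysis_grid.csv"),
            row.names = FALSE)
  write.csv(subjects, file.path(cfg$out_dir, "subjects.csv"),
            row.names = FALSE)
  write.csv(residences, file.path(cfg$out_dir, "residences.csv"),
            row.names = FALSE)

  outputs <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  hashes <- tools::md5sum(file.path(cfg$out_dir, outputs))
  manifest <- list(
    seed = cfg$seed,
    scenarios = as.list(cfg$scenarios),
    latencies = cfg$latencies,
    duration_mode = cfg$duration_mode,
    n_particles = cfg$n_particles,
    package_version = as.character(utils::packageVersion("plumetrace")),
    outputs = as.list(setNames(unname(hashes), outputs)))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(schedules = schedules, grids = grid_all,
                 records = records, cohort = cohort,
                 manifest_path = manifest_path))
}
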