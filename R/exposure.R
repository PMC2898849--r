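#' Define a public water distribution system
#'
#' A distribution system mixes water from its member wells (common
#' standpipe), so every served address shares one impact status per year:
#' the system is impacted from the earliest first-impact year of any of
#' its wells.
#'
#' @param supplier_id label.
#' @param wells character vector of well ids feeding the system.
#' @param member_addresses optional character vector of served address
#'   ids.
#' @param service_bbox optional planar service rectangle
#'   `c(xmin, xmax, ymin, ymax)` (feet) used when membership is resolved
#'   geographically.
#' @param mixing logical; `TRUE` (default) means common-standpipe mixing.
#' @return An object of class `distribution_system`.
#' @export
distribution_system <- function(supplier_id, wells,
                                member_addresses = NULL,
                                service_bbox = NULL, mixing = TRUE) {
  structure(list(supplier_id = supplier_id, wells = wells,
                 member_addresses = member_addresses,
                 service_bbox = service_bbox, mixing = mixing),
            class = "distribution_system")
}

system_contains <- function(sys, address_id, x, y) {
  if (!is.null(sys$member_addresses)) {
    address_id %in% sys$member_addresses
  } else if (!is.null(sys$service_bbox)) {
    bb <- sys$service_bbox
    !is.na(x) & !is.na(y) &
      x >= bb[1] & x <= bb[2] & y >= bb[3] & y <= bb[4]
  } else {
    rep(FALSE, length(address_id))
  }
}

#' Resolve the water source of each residence
#'
#' Self-reported public residences are matched to a supplier by address
#' membership or service polygon (first matching system wins); residences
#' on private wells are flagged for track-based impact testing; public
#' residences matching no supplier become `unknown` and are excluded from
#' analysis denominators downstream (with a logged count).
#'
#' @param residences data frame with columns `subject_id`, `address_id`,
#'   `x`, `y`, `start_year`, `end_year`, `source`
#'   (`public`/`private`/`unknown`) and optionally `supplier_id`.
#' @param systems list of [distribution_system()]s, in match priority
#'   order.
#' @return The residences with columns `resolved_source` and
#'   `supplier_id` filled in.
#' @export
assign_water_source <- function(residences, systems) {
  res <- as.data.frame(residences)
  res$resolved_source <- res$source
  if (!"supplier_id" %in% names(res)) res$supplier_id <- NA_character_
  pub <- which(res$source == "public")
  if (length(pub)) {
    matched <- rep(FALSE, length(pub))
    for (sys in systems) {
      hit <- !matched & system_contains(sys, res$address_id[pub],
                                        res$x[pub], res$y[pub])
      res$supplier_id[pub[hit]] <- sys$supplier_id
      matched <- matched | hit
    }
    if (any(!matched)) {
      res$resolved_source[pub[!matched]] <- "unknown"
      res$supplier_id[pub[!matched]] <- NA_character_
      verbose_msg(sprintf(
        "%d public residence(s) matched no supplier; set to unknown",
        sum(!matched)))
    }
  }
  res$supplier_id[res$resolved_source != "public"] <- NA_character_
  res
}

# first calendar year each system is impacted (mixing assumption:
# min over its wells' first-impact years); named numeric vector
system_first_impact <- function(systems, schedule) {
  out <- vapply(systems, function(sys) {
    yrs <- schedule$first_impact_year[match(sys$wells, schedule$well_id)]
    if (all(is.na(yrs))) NA_real_ else min(yrs, na.rm = TRUE)
  }, numeric(1))
  setNames(out, vapply(systems, `[[`, character(1), "supplier_id"))
}

# first impact year per residence (NA when never impacted)
residence_first_impact <- function(residences, schedule, systems,
                                   private_arrivals = NULL, grid = NULL) {
  res <- residences
  first <- rep(NA_real_, nrow(res))
  sf <- system_first_impact(systems, schedule)
  ispub <- res$resolved_source == "public" & !is.na(res$supplier_id)
  first[ispub] <- sf[res$supplier_id[ispub]]
  ispriv <- res$resolved_source == "private"
  if (any(ispriv) && !is.null(private_arrivals)) {
    pc <- locate_planar(grid, res$x[ispriv], res$y[ispriv])
    ok <- !is.na(pc[, 1]) & !is.na(pc[, 2])
    yr <- rep(NA_real_, sum(ispriv))
    yr[ok] <- private_arrivals[pc[ok, , drop = FALSE]]
    first[ispriv] <- yr
  }
  first
}

#' Calendar years a residence drew impacted water
#'
#' For a public residence these are the occupancy years from the
#' supplier's first impact year onward (common-standpipe mixing: all
#' member addresses share one impact status); for a private residence,
#' occupancy years from the year a track first passed beneath the
#' residence within the depth criterion. Year counting is inclusive of
#' both endpoints.
#'
#' @param residence one-row residence data frame (resolved; see
#'   [assign_water_source()]).
#' @param schedule a `well_impact_schedule`.
#' @param systems list of [distribution_system()]s.
#' @param private_arrivals matrix of earliest private-impact years per
#'   planar cell (from tracks), or `NULL`.
#' @param grid the [grid_spec()] (needed for private residences).
#' @return Integer vector of impacted calendar years (possibly empty).
#' @export
residence_impact_years <- function(residence, schedule, systems,
                                   private_arrivals = NULL, grid = NULL) {
  residence <- as.data.frame(residence)
  stopifnot(nrow(residence) == 1)
  if (!"resolved_source" %in% names(residence)) {
    residence <- assign_water_source(residence, systems)
  }
  first <- residence_first_impact(residence, schedule, systems,
                                  private_arrivals, grid)
  if (is.na(first) || first > residence$end_year) return(integer(0))
  seq.int(max(first, residence$start_year), residence$end_year)
}

#' Per-subject exposure metrics for a whole cohort
#'
#' Vectorised reconstruction of ever-exposure, first exposed year and
#' cumulative duration for every subject at one latency and pumping
#' scenario. A residence is ever-exposed when it has at least one
#' impacted occupancy year at or before the subject's index year. Under a
#' latency of `L` years a subject counts as exposed only when the first
#' exposed year is at or before `index_year - L` (an induction criterion;
#' the duration itself is not truncated by latency). Occupancy after the
#' index year never counts.
#'
#' @param subjects subject table with `subject_id`, `status`
#'   (`case`/`control`), `index_year` and covariate columns.
#' @param residences residence table (see [assign_water_source()]).
#' @param schedule a `well_impact_schedule` for the scenario.
#' @param systems list of [distribution_system()]s.
#' @param latency latency in years (single value).
#' @param scenario_id label copied into the records.
#' @param private_arrivals,grid private-well impact inputs (see
#'   [residence_impact_years()]).
#' @param duration_mode `"occupancy"` (default): duration is the total
#'   occupancy years at ever-exposed residences, truncated at the index
#'   year; `"impacted-only"`: only calendar years with well impact count.
#' @return A data frame of exposure records, one row per subject:
#'   `subject_id`, `scenario_id`, `latency`, `ever_exposed`, `duration`,
#'   `first_exposed_year`, `n_exposed_addresses`, `category`,
#'   `exposed_any` (exposure ignoring latency, defining the never-exposed
#'   referent) and `analyzable` (any residence with known water source).
#' @export
compute_exposure <- function(subjects, residences, schedule, systems,
                             latency = 0, scenario_id = "default",
                             private_arrivals = NULL, grid = NULL,
                             duration_mode = c("occupancy",
                                               "impacted-only")) {
  duration_mode <- match.arg(duration_mode)
  subjects <- as.data.frame(subjects)
  res <- as.data.frame(residences)
  if (!"resolved_source" %in% names(res)) {
    res <- assign_water_source(res, systems)
  }
  first_imp <- residence_first_impact(res, schedule, systems,
                                      private_arrivals, grid)
  sid <- factor(res$subject_id, levels = subjects$subject_id)
  index <- subjects$index_year[as.integer(sid)]
  occ_end <- pmin(res$end_year, index)
  n_trunc <- sum(res$end_year > index, na.rm = TRUE)
  if (n_trunc > 0) {
    verbose_msg(sprintf(
      "%d residence interval(s) extend past the index year; truncated",
      n_trunc))
  }
  valid <- res$start_year <= occ_end
  exposed_res <- valid & !is.na(first_imp) & first_imp <= occ_end
  res_first <- ifelse(exposed_res, pmax(first_imp, res$start_year), NA)
  res_dur <- rep(0, nrow(res))
  res_dur[exposed_res] <- if (duration_mode == "occupancy") {
    occ_end[exposed_res] - res$start_year[exposed_res] + 1
  } else {
    occ_end[exposed_res] - res_first[exposed_res] + 1
  }
  agg_min <- function(v) {
    out <- tapply(v, sid, function(z) {
      z <- z[!is.na(z)]
      if (length(z)) min(z) else NA_real_
    })
    as.numeric(out[subjects$subject_id])
  }
  agg_sum <- function(v) {
    out <- tapply(v, sid, sum)
    o <- as.numeric(out[subjects$subject_id])
    ifelse(is.na(o), 0, o)
  }
  first_exposed <- agg_min(res_first)
  duration <- agg_sum(res_dur)
  n_addr <- agg_sum(as.numeric(exposed_res))
  known <- res$resolved_source != "unknown"
  analyzable <- agg_sum(as.numeric(known & valid)) > 0
  exposed_any <- !is.na(first_exposed) &
    first_exposed <= subjects$index_year
  exposed_L <- exposed_any & first_exposed <= subjects$index_year - latency
  duration_L <- ifelse(exposed_L, duration, 0)
  data.frame(
    subject_id = subjects$subject_id,
    scenario_id = scenario_id,
    latency = latency,
    ever_exposed = exposed_L,
    duration = duration_L,
    first_exposed_year = ifelse(exposed_L, first_exposed, NA_real_),
    n_exposed_addresses = ifelse(exposed_L, n_addr, 0),
    category = categorize_duration(duration_L),
    exposed_any = exposed_any,
    analyzable = analyzable,
    stringsAsFactors = FALSE)
}

#' Exposure record for a single subject
#'
#' Reference implementation of the per-subject metrics from explicit
#' impact-year sets; [compute_exposure()] is the vectorised equivalent
#' used on whole cohorts.
#'
#' @param subject one-row subject data frame (needs `subject_id`,
#'   `index_year`).
#' @param residences this subject's residences.
#' @param impact_years_per_residence list of integer vectors, one per
#'   residence row: the calendar years that residence drew impacted water
#'   (see [residence_impact_years()]).
#' @param latency latency in years.
#' @param duration_mode see [compute_exposure()].
#' @return One-row exposure record data frame.
#' @export
subject_exposure <- function(subject, residences,
                             impact_years_per_residence, latency = 0,
                             duration_mode = c("occupancy",
                                               "impacted-only")) {
  duration_mode <- match.arg(duration_mode)
  subject <- as.data.frame(subject)
  res <- as.data.frame(residences)
  index <- subject$index_year
  first_exposed <- NA_real_; duration <- 0; n_addr <- 0
  for (i in seq_len(nrow(res))) {
    yrs <- impact_years_per_residence[[i]]
    yrs <- yrs[yrs <= index]
    occ_end <- min(res$end_year[i], index)
    if (res$start_year[i] > occ_end || length(yrs) == 0) next
    n_addr <- n_addr + 1
    first_exposed <- min(first_exposed, min(yrs), na.rm = TRUE)
    duration <- duration + if (duration_mode == "occupancy") {
      occ_end - res$start_year[i] + 1
    } else {
      length(yrs)
    }
  }
  exposed_any <- !is.na(first_exposed)
  exposed <- exposed_any && first_exposed <= index - latency
  data.frame(
    subject_id = subject$subject_id, scenario_id = "default",
    latency = latency, ever_exposed = exposed,
    duration = if (exposed) duration else 0,
    first_exposed_year = if (exposed) first_exposed else NA_real_,
    n_exposed_addresses = if (exposed) n_addr else 0,
    category = categorize_duration(if (exposed) duration else 0),
    exposed_any = exposed_any,
    analyzable = any(res$resolved_source != "unknown" &
                       res$start_year <= index),
    stringsAsFactors = FALSE)
}

#' Duration category of an exposure record
#'
#' Categories follow the analysis contrasts: `never` (0 years),
#' `>0-5` (up to and including 5), `>5-10`, and `>10`. Note the
#' published-style contrasts `>5` and `>10` overlap; use
#' [in_duration_contrast()] for contrast membership (a duration of 11
#' years belongs to both the `>5` and `>10` contrasts).
#'
#' @param duration numeric vector of cumulative exposure years (>= 0).
#' @return Character vector of categories.
#' @export
categorize_duration <- function(duration) {
  if (any(duration < 0)) stop("negative exposure duration")
  ifelse(duration == 0, "never",
         ifelse(duration <= 5, ">0-5",
                ifelse(duration <= 10, ">5-10", ">10")))
}

#' Membership of a duration in an analysis contrast
#'
#' @param duration numeric vector of exposure years.
#' @param contrast one of `"ever"`, `">0-5"`, `">5"`, `">10"`.
#' @return Logical vector.
#' @export
in_duration_contrast <- function(duration,
                                 contrast = c("ever", ">0-5", ">5",
                                              ">10")) {
  contrast <- match.arg(contrast)
  switch(contrast,
         "ever" = duration > 0,
         ">0-5" = duration > 0 & duration <= 5,
         ">5" = duration > 5,
         ">10" = duration > 10)
}

#' Concentration-weighted relative exposure score
#'
#' A scaled relative measure of exposure: for each subject, the sum over
#' exposed residence-years of the available nitrate-N concentrations at
#' the supply wells in that year (missing well-years contribute zero).
#' Quartiles are assigned among exposed subjects only.
#'
#' @param records exposure records from [compute_exposure()] (one
#'   latency/scenario).
#' @param subjects subject table.
#' @param residences resolved residence table.
#' @param schedule the scenario's `well_impact_schedule`.
#' @param systems list of [distribution_system()]s.
#' @param nitrate data frame `well_id`, `year`, `mg_l`.
#' @param private_arrivals,grid see [compute_exposure()].
#' @return Data frame `subject_id`, `score`, `quartile` (`NA` for
#'   unexposed subjects).
#' @export
nitrate_weighted_exposure <- function(records, subjects, residences,
                                      schedule, systems, nitrate,
                                      private_arrivals = NULL,
                                      grid = NULL) {
  res <- as.data.frame(residences)
  if (!"resolved_source" %in% names(res)) {
    res <- assign_water_source(res, systems)
  }
  first_imp <- residence_first_impact(res, schedule, systems,
                                      private_arrivals, grid)
  # total concentration across wells per calendar year
  conc <- rowsum(nitrate$mg_l, nitrate$year)
  conc_year <- as.numeric(rownames(conc))
  year_sum <- function(y1, y2) {
    k <- conc_year >= y1 & conc_year <= y2
    if (any(k)) sum(conc[k, 1]) else 0
  }
  sid <- factor(res$subject_id, levels = subjects$subject_id)
  index <- subjects$index_year[as.integer(sid)]
  occ_end <- pmin(res$end_year, index)
  exposed_res <- res$start_year <= occ_end & !is.na(first_imp) &
    first_imp <= occ_end
  score_res <- rep(0, nrow(res))
  miss <- 0
  for (i in which(exposed_res)) {
    y1 <- max(first_imp[i], res$start_year[i]); y2 <- occ_end[i]
    score_res[i] <- year_sum(y1, y2)
    miss <- miss + sum(!(y1:y2) %in% conc_year)
  }
  if (miss > 0) {
    verbose_msg(sprintf(
      "%d exposed residence-year(s) had no concentration record (count 0)",
      miss))
  }
  sc <- tapply(score_res, sid, sum)
  score <- ifelse(is.na(sc[subjects$subject_id]), 0,
                  as.numeric(sc[subjects$subject_id]))
  ever <- records$ever_exposed[match(subjects$subject_id,
                                     records$subject_id)]
  score[!ever] <- 0
  quart <- rep(NA_integer_, length(score))
  if (any(ever)) {
    qs <- quantile(score[ever], probs = c(0.25, 0.5, 0.75), names = FALSE)
    quart[ever] <- 1L + findInterval(score[ever], qs, left.open = TRUE)
  }
  data.frame(subject_id = subjects$subject_id, score = score,
             quartile = quart, stringsAsFactors = FALSE)
}
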