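#' Configuration for the synthetic aquifer fixture
#'
#' Describes a small stand-in aquifer with the same structure as the
#' study setting: a persistent effluent source upgradient of a cluster of
#' public supply wells in a permeable sand aquifer, with supply wells
#' coming online in 1953, 1961 (replaced 1984) and 1970, so that the
#' 1937-1993 horizon splits into five piecewise-steady pumping periods.
#' The well of uncertain pumping history is scenario-scaled between 30%,
#' 50% and 75% of its rated capacity of 96,250 ft^3/day (giving 28,875,
#' 48,125 and 72,188 ft^3/day); its neighbours pump at 30% and 50% of
#' the same rated capacity as their ordinary operating points.
#'
#' Default geometry and properties are typical of a shallow glacial
#' outwash sand aquifer: a single 140-ft layer, 250-ft cells, hydraulic
#' conductivity 200 ft/day, porosity 0.39, and a regional head gradient
#' of about 0.001 driving flow from the source toward the wells.
#'
#' @param n_rows,n_cols planar grid size (defaults 24 x 46).
#' @param dx,dy cell size (feet).
#' @param K,porosity aquifer properties (uniform; `K_sd_log > 0` makes
#'   conductivity lognormal around `K`).
#' @param K_sd_log standard deviation of log-conductivity (0 = uniform).
#' @param head_west,head_east constant heads on the west/east columns
#'   (feet).
#' @param recharge areal recharge (feet/day).
#' @param source_cell `(row, col)` of the effluent discharge.
#' @param source_rate effluent injection rate (feet^3/day).
#' @param rated_capacity supply-well rated capacity (feet^3/day).
#' @param scenario_fractions named pumping-scenario fractions of rated
#'   capacity for the uncertain well.
#' @param horizon calendar years covered.
#' @param seed RNG seed (used only when `K_sd_log > 0`).
#' @return A list of class `aquifer_scenario_config`.
#' @export
aquifer_scenario_config <- function(n_rows = 24, n_cols = 46,
                                    dx = 250, dy = 250,
                                    K = 200, porosity = 0.39,
                                    K_sd_log = 0,
                                    head_west = 21.5, head_east = 10,
                                    recharge = 0.001,
                                    source_cell = c(12, 7),
                                    source_rate = 130000,
                                    rated_capacity = 96250,
                                    scenario_fractions = c(low = 0.30,
                                                           mid = 0.50,
                                                           high = 0.75),
                                    horizon = c(1937, 1993),
                                    seed = 1L) {
  structure(as.list(environment()), class = "aquifer_scenario_config")
}

#' Generate the synthetic aquifer fixture
#'
#' Builds a solvable single-layer model with constant-head columns on the
#' west (upgradient) and east (downgradient) edges, areal recharge, one
#' effluent source cell active over the whole horizon, and four supply
#' wells whose start years (1953, 1961, 1970, 1984 replacement) create
#' five stress periods over 1937-1993. Reproducible given the seed.
#'
#' @param cfg an [aquifer_scenario_config()].
#' @return A list of class `aquifer_model` with elements `grid`, `props`,
#'   `bc`, `wells`, `source_cells`, `horizon`, `scenario_fractions` and
#'   `config`.
#' @export
generate_aquifer <- function(cfg = aquifer_scenario_config()) {
  grid <- grid_spec(n_rows = cfg$n_rows, n_cols = cfg$n_cols,
                    dx = cfg$dx, dy = cfg$dy,
                    layer_top = 20, layer_bottom = -120)
  dims <- c(1, cfg$n_rows, cfg$n_cols)
  K <- if (cfg$K_sd_log > 0) {
    with_seed(cfg$seed,
              array(exp(log(cfg$K) + stats::rnorm(prod(dims), 0,
                                                  cfg$K_sd_log)),
                    dim = dims))
  } else {
    array(cfg$K, dim = dims)
  }
  props <- aquifer_props(grid, K, cfg$porosity)
  ch <- rbind(
    data.frame(layer = 1, row = seq_len(cfg$n_rows), col = 1,
               head = cfg$head_west),
    data.frame(layer = 1, row = seq_len(cfg$n_rows), col = cfg$n_cols,
               head = cfg$head_east))
  bc <- boundary_conditions(constant_head = ch, recharge = cfg$recharge)
  src <- cfg$source_cell
  # supply wells clustered ~1.5 mi downgradient of the source
  wells <- rbind(
    well_spec("effluent_source", 1, src[1], src[2], cfg$source_rate,
              cfg$horizon[1], cfg$horizon[2], role = "effluent_source"),
    well_spec("hyannisport", 1, 16, 38, cfg$rated_capacity, 1953,
              cfg$horizon[2], base_fraction = 0.30),
    well_spec("straightway", 1, 12, 39, cfg$rated_capacity, 1961, 1984,
              scenario_scaled = TRUE),
    well_spec("simmons_pond", 1, 9, 39, cfg$rated_capacity, 1970,
              cfg$horizon[2], base_fraction = 0.50),
    well_spec("straightway_repl", 1, 12, 40, cfg$rated_capacity, 1984,
              cfg$horizon[2], scenario_scaled = TRUE))
  structure(list(grid = grid, props = props, bc = bc, wells = wells,
                 source_cells = data.frame(layer = 1, row = src[1],
                                           col = src[2]),
                 horizon = cfg$horizon,
                 scenario_fractions = cfg$scenario_fractions,
                 config = cfg),
            class = "aquifer_model")
}

#' @export
print.aquifer_model <- function(x, ...) {
  cat(sprintf("<aquifer_model> %d x %d cells, %d wells, horizon %d-%d\n",
              x$grid$n_rows, x$grid$n_cols, nrow(x$wells),
              x$horizon[1], x$horizon[2]))
  invisible(x)
}

#' Flow + tracking for one pumping scenario
#'
#' Builds the stress periods for the scenario fraction, solves each as an
#' independent steady state, releases particles at the effluent source at
#' the start of the horizon, tracks them through the per-period velocity
#' fields, and detects first arrivals at the supply wells.
#'
#' @param model an `aquifer_model` from [generate_aquifer()].
#' @param scenario_id name of a scenario in
#'   `model$scenario_fractions`, or a numeric fraction.
#' @param n_particles particles per source cell (default 25).
#' @param seed RNG seed for the within-stratum particle jitter.
#' @return A list of class `scenario_result` with `schedule`
#'   (`well_impact_schedule`), `tracks`, `period_fields`,
#'   `private_arrivals` (earliest year a track passes each planar cell
#'   within 100 ft of land surface) and `scenario_id`.
#' @export
simulate_scenario <- function(model, scenario_id = "high",
                              n_particles = 25, seed = 1L) {
  fraction <- if (is.numeric(scenario_id)) {
    scenario_id
  } else {
    model$scenario_fractions[[scenario_id]]
  }
  label <- if (is.numeric(scenario_id)) {
    sprintf("f%.2f", scenario_id)
  } else scenario_id
  periods <- build_stress_periods(model$wells, model$horizon,
                                  scenario_fraction = fraction)
  period_fields <- lapply(periods, function(p) {
    sys <- assemble_system(model$grid, model$props, model$bc, p)
    heads <- solve_steady_state(sys)
    list(period = p, field = cell_velocities(heads), heads = heads)
  })
  particles <- seed_particles(model$grid, model$source_cells,
                              n_per_cell = n_particles,
                              release_year = model$horizon[1],
                              rng_seed = seed)
  tracks <- lapply(particles, track_particle,
                   period_fields = period_fields)
  schedule <- detect_arrivals(tracks, model$wells, scenario_id = label)
  structure(list(schedule = schedule, tracks = tracks,
                 period_fields = period_fields,
                 private_arrivals = track_cell_arrivals(tracks,
                                                        model$grid, 100),
                 scenario_id = label, fraction = fraction),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s:\n", x$scenario_id))
  print(as.data.frame(x$schedule))
  invisible(x)
}

#' Configuration for the synthetic case-control cohort
#'
#' Defaults mirror the shape of the study population: 638 cases and 842
#' controls with index years 1983-1993; most subjects exposed (if at all)
#' at a single address, with a mobility mix of roughly 79% one address,
#' 18% two-three and 3% four-six; a public/private/unknown water-source
#' mix; about 23% ever-regular bottled-water users; and a configurable
#' true exposure log-odds effect plus one binary confounder associated
#' with both residential location (hence exposure) and outcome.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param index_years candidate diagnosis/index years.
#' @param true_or true exposure odds ratio on disease.
#' @param confounder_or confounder odds ratio on disease.
#' @param confounder_prev confounder prevalence.
#' @param p_service_conf,p_service_noconf probability that a subject's
#'   first residence (with/without the confounder) lies in the impacted
#'   supplier's service area.
#' @param p_stay probability that a move starting from a service-area
#'   residence stays inside the service area (residential persistence;
#'   moves are mostly local).
#' @param study_area_factor area of the whole study region as a multiple
#'   of the model footprint; residences outside the service area are
#'   drawn from the study region, so most lie beyond the modeled plume
#'   neighbourhood and cannot be privately impacted.
#' @param mobility probabilities of 1-6 addresses per subject.
#' @param p_public_in,p_private_in source mix inside the service area
#'   (remainder unknown).
#' @param p_public_out,p_private_out source mix outside it.
#' @param p_bottled probability of ever-regular bottled water use.
#' @param base_rate marginal case probability in the source population
#'   pool before case-control sampling.
#' @param pool_factor pool size as a multiple of the cohort size.
#' @param seed RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 638, n_controls = 842,
                          index_years = 1983:1993,
                          true_or = 1.5, confounder_or = 1.5,
                          confounder_prev = 0.30,
                          p_service_conf = 0.17,
                          p_service_noconf = 0.10,
                          p_stay = 0.65,
                          study_area_factor = 4,
                          mobility = c(0.79, 0.12, 0.06, 0.015, 0.010,
                                       0.005),
                          p_public_in = 0.85, p_private_in = 0.13,
                          p_public_out = 0.75, p_private_out = 0.23,
                          p_bottled = 0.231,
                          base_rate = 0.42, pool_factor = 2.4,
                          seed = 1L) {
  stopifnot(n_cases > 0, n_controls > 0,
            abs(sum(mobility) - 1) < 1e-6,
            p_public_in + p_private_in <= 1,
            p_public_out + p_private_out <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic case-control cohort with known ground truth
#'
#' Draws a source-population pool with the configured mobility,
#' residential geography and water-source mixture; reconstructs each pool
#' member's exposure through the package's own exposure machinery (the
#' supplied impact schedule plus, optionally, particle tracks for private
#' wells); assigns disease status from a logistic model with the
#' configured true exposure effect and confounder; and samples exactly
#' `n_cases` cases and `n_controls` controls. Control index years share
#' the case index-year distribution by construction. Case-control
#' sampling preserves the exposure odds ratio, so the fitted adjusted OR
#' estimates `true_or`.
#'
#' @param cfg a [cohort_config()].
#' @param model the `aquifer_model` (for grid geometry and well-supplier
#'   mapping).
#' @param scenario a `scenario_result` from [simulate_scenario()]; its
#'   schedule defines public-supply impact and its tracks private-well
#'   impact.
#' @return A list of class `synthetic_cohort` with `subjects`,
#'   `residences`, `systems` and the generating `config`.
#' @export
generate_cohort <- function(cfg, model, scenario) {
  with_seed(cfg$seed, {
    n_pool <- ceiling((cfg$n_cases + cfg$n_controls) * cfg$pool_factor)
    grid <- model$grid
    xe <- range(x_edges(grid)); ye <- range(y_edges(grid))
    # service area: eastern block around the supply wells
    bbox <- c(xe[1] + 0.62 * diff(xe), xe[2] - 0.02 * diff(xe),
              ye[1] + 0.08 * diff(ye), ye[2] - 0.08 * diff(ye))
    supply_ids <- model$wells$well_id[model$wells$role == "supply"]
    systems <- list(
      distribution_system("BWC", wells = supply_ids,
                          service_bbox = bbox),
      distribution_system("OUTLYING", wells = character(0),
                          service_bbox = c(xe[1], xe[2], ye[1], ye[2])))

    subj_id <- sprintf("S%05d", seq_len(n_pool))
    conf <- rbinom(n_pool, 1, cfg$confounder_prev)
    index_year <- sample(cfg$index_years, n_pool, replace = TRUE)
    n_addr <- sample(1:6, n_pool, replace = TRUE, prob = cfg$mobility)
    bottled <- rbinom(n_pool, 1, cfg$p_bottled) == 1
    age_cat <- sample(c("<50", "50-59", "60-69", "70-79", ">=80"),
                      n_pool, replace = TRUE,
                      prob = c(0.15, 0.20, 0.30, 0.25, 0.10))
    vital <- sample(c("alive", "deceased"), n_pool, replace = TRUE,
                    prob = c(0.65, 0.35))
    education <- sample(c("<12", "12", ">12"), n_pool, replace = TRUE,
                        prob = c(0.15, 0.35, 0.50))

    # residence histories: contiguous inclusive year intervals from the
    # history start to 1993, split at random into n_addr spells
    hist_start <- pmin(sample(1943:1970, n_pool, replace = TRUE),
                       1993 - (n_addr - 1))
    tot <- sum(n_addr)
    rsub <- rep(seq_len(n_pool), n_addr)
    ord <- sequence(n_addr)
    span <- (1993 - hist_start + 1)[rsub]
    w <- runif(tot, 0.2, 1)
    wsum <- ave(w, rsub, FUN = sum)
    cw <- ave(w, rsub, FUN = cumsum) / wsum
    endy <- hist_start[rsub] - 1 + pmax(floor(cw * span), ord)
    endy <- pmin(endy, 1993)
    last <- ave(ord, rsub, FUN = max) == ord
    endy[last] <- 1993
    starty <- hist_start[rsub]
    prev_end <- c(0, endy[-tot])
    starty[ord > 1] <- prev_end[ord > 1] + 1
    keep <- starty <= endy  # collapsed spells from rounding are dropped
    rsub <- rsub[keep]; starty <- starty[keep]; endy <- endy[keep]

    nres <- length(rsub)
    conf_res <- conf[rsub]
    p_in <- ifelse(conf_res == 1, cfg$p_service_conf,
                   cfg$p_service_noconf)
    # residential persistence: a move starting inside the service area
    # stays there with probability p_stay; first residences use p_in
    u_in <- runif(nres)
    in_service <- logical(nres)
    for (i in seq_len(nres)) {
      p <- if (ord[keep][i] > 1 && in_service[i - 1]) {
        cfg$p_stay
      } else {
        p_in[i]
      }
      in_service[i] <- u_in[i] < p
    }
    # the study region is study_area_factor times the model footprint;
    # non-service residences drawn beyond the footprint lie outside the
    # plume neighbourhood and can never be privately impacted
    sf <- sqrt(cfg$study_area_factor)
    rx <- numeric(nres); ry <- numeric(nres)
    rx[in_service] <- runif(sum(in_service), bbox[1], bbox[2])
    ry[in_service] <- runif(sum(in_service), bbox[3], bbox[4])
    n_out <- sum(!in_service)
    rx[!in_service] <- runif(n_out, xe[1], xe[1] + sf * diff(xe))
    ry[!in_service] <- runif(n_out, ye[1], ye[1] + sf * diff(ye))
    # reject out-draws that landed in the service box (they are not
    # service members): push them east of the footprint
    clash <- !in_service & rx >= bbox[1] & rx <= bbox[2] &
      ry >= bbox[3] & ry <= bbox[4]
    rx[clash] <- xe[2] + (rx[clash] - xe[1])
    u <- runif(nres)
    p_pub <- ifelse(in_service, cfg$p_public_in, cfg$p_public_out)
    p_priv <- ifelse(in_service, cfg$p_private_in, cfg$p_private_out)
    source <- ifelse(u < p_pub, "public",
                     ifelse(u < p_pub + p_priv, "private", "unknown"))
    residences <- data.frame(
      subject_id = subj_id[rsub],
      address_id = sprintf("A%06d", seq_len(nres)),
      x = rx, y = ry, start_year = starty, end_year = endy,
      source = source, supplier_id = NA_character_,
      stringsAsFactors = FALSE)

    pool <- data.frame(subject_id = subj_id, status = "control",
                       index_year = index_year,
                       family_history = conf,
                       age_cat = age_cat, vital_status = vital,
                       education = education,
                       bottled_water_ever = bottled,
                       stringsAsFactors = FALSE)
    rec <- compute_exposure(pool, residences, scenario$schedule, systems,
                            latency = 0,
                            private_arrivals = scenario$private_arrivals,
                            grid = grid)
    lin <- qlogis(cfg$base_rate) +
      log(cfg$true_or) * as.numeric(rec$ever_exposed) +
      log(cfg$confounder_or) * conf
    is_case <- rbinom(n_pool, 1, plogis(lin)) == 1
    if (sum(is_case) < cfg$n_cases || sum(!is_case) < cfg$n_controls) {
      stop("pool too small for requested cohort; raise pool_factor")
    }
    pick_cases <- sample(which(is_case), cfg$n_cases)
    pick_ctls <- sample(which(!is_case), cfg$n_controls)
    pool$status[is_case] <- "case"
    sel <- sort(c(pick_cases, pick_ctls))
    subjects <- pool[sel, , drop = FALSE]
    rownames(subjects) <- NULL
    residences <- residences[residences$subject_id %in%
                               subjects$subject_id, , drop = FALSE]
    rownames(residences) <- NULL
    structure(list(subjects = subjects, residences = residences,
                   systems = systems, config = cfg),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cases / %d controls, %d residences\n",
              sum(x$subjects$status == "case"),
              sum(x$subjects$status == "control"),
              nrow(x$residences)))
  invisible(x)
}
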