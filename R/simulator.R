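#' Phenotype preset for the fly simulator
#'
#' Parameters of the semi-Markov behavioural model underlying
#' [simulate_fly()]: how often climbs are initiated from rest, how fast and
#' how high the fly climbs, how it descends (drop versus controlled
#' descending climb), and how strongly it gravitates to the tube bottom.
#'
#' The bundled presets (see [preset_library()]) are calibrated only to the
#' directional group differences observed between control, parkin-mutant, and
#' nicotine-treated parkin-mutant flies (controls climb higher, reach the top
#' more, dwell less at the bottom, and perform more descending climbs), never
#' to measured group means. By default drops are near-instantaneous
#' (20-40 mm/s) and descending climbs move at 1-5 mm/s, so true labels fall
#' outside the classifier's excluded velocity band by construction.
#'
#' @param name preset label.
#' @param climb_initiation_rate_per_min rate of climb initiation from rest at
#'   the tube bottom (events/min); 0 gives a fly that rests forever.
#' @param ascent_speed_mean_mm_s,ascent_speed_sd_mm_s normal parameters of the
#'   climbing speed (truncated below at 0.5 mm/s).
#' @param peak_heights_mm,peak_height_probs categorical distribution of
#'   target peak heights (on the quantization grid).
#' @param prob_descent_is_drop probability a descent is a drop rather than a
#'   descending climb.
#' @param descclimb_speed_range_mm_s uniform range of descending-climb speed.
#' @param drop_speed_range_mm_s uniform range of drop speed.
#' @param rest_mean_s mean rest duration away from the bottom (exponential).
#' @param bottom_bias probability a descent targets the tube bottom.
#' @param peak_pause_range_s uniform range of the pause at a climb's peak.
#' @return Object of class `phenotype_preset`.
#' @export
phenotype_preset <- function(name = "custom",
                             climb_initiation_rate_per_min = 2,
                             ascent_speed_mean_mm_s = 12,
                             ascent_speed_sd_mm_s = 3,
                             peak_heights_mm = c(15, 27, 39, 51),
                             peak_height_probs = c(0.1, 0.15, 0.25, 0.5),
                             prob_descent_is_drop = 0.35,
                             descclimb_speed_range_mm_s = c(1, 5),
                             drop_speed_range_mm_s = c(20, 40),
                             rest_mean_s = 8,
                             bottom_bias = 0.6,
                             peak_pause_range_s = c(1, 3)) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1))
      stop("'", nm, "' must be probabilities in [0, 1]")
  }
  if (climb_initiation_rate_per_min < 0)
    stop("'climb_initiation_rate_per_min' must be non-negative")
  if (ascent_speed_mean_mm_s <= 0 || ascent_speed_sd_mm_s < 0)
    stop("ascent speed parameters must be positive")
  if (length(peak_heights_mm) != length(peak_height_probs))
    stop("'peak_heights_mm' and 'peak_height_probs' lengths differ")
  chk_prob(peak_height_probs, "peak_height_probs")
  if (abs(sum(peak_height_probs) - 1) > 1e-8)
    stop("'peak_height_probs' must sum to 1")
  chk_prob(prob_descent_is_drop, "prob_descent_is_drop")
  chk_prob(bottom_bias, "bottom_bias")
  rng_ok <- function(r) length(r) == 2 && r[1] > 0 && r[1] <= r[2]
  if (!rng_ok(descclimb_speed_range_mm_s) || !rng_ok(drop_speed_range_mm_s) ||
      !rng_ok(peak_pause_range_s))
    stop("speed/pause ranges must be positive increasing pairs")
  if (rest_mean_s <= 0) stop("'rest_mean_s' must be positive")
  structure(list(name = name,
                 climb_initiation_rate_per_min = climb_initiation_rate_per_min,
                 ascent_speed_mean_mm_s = ascent_speed_mean_mm_s,
                 ascent_speed_sd_mm_s = ascent_speed_sd_mm_s,
                 peak_heights_mm = peak_heights_mm,
                 peak_height_probs = peak_height_probs,
                 prob_descent_is_drop = prob_descent_is_drop,
                 descclimb_speed_range_mm_s = descclimb_speed_range_mm_s,
                 drop_speed_range_mm_s = drop_speed_range_mm_s,
                 rest_mean_s = rest_mean_s,
                 bottom_bias = bottom_bias,
                 peak_pause_range_s = peak_pause_range_s),
            class = "phenotype_preset")
}

#' Built-in phenotype presets
#'
#' Three presets encoding the directional phenotype orderings seen in
#' parkin-mutant climbing studies: `control` (frequent high climbs, more
#' descending climbs), `park25` (same climb initiation rate but lower peaks,
#' strong bottom bias, more drops), and `park25_nicotine` (partial rescue,
#' intermediate between the two).
#'
#' @return Named list of [phenotype_preset()] objects.
#' @export
preset_library <- function() {
  list(
    control = phenotype_preset(
      "control", climb_initiation_rate_per_min = 2, ascent_speed_mean_mm_s = 12,
      peak_height_probs = c(0.10, 0.15, 0.25, 0.50), prob_descent_is_drop = 0.35,
      rest_mean_s = 8, bottom_bias = 0.60),
    park25 = phenotype_preset(
      "park25", climb_initiation_rate_per_min = 2, ascent_speed_mean_mm_s = 10,
      peak_height_probs = c(0.45, 0.30, 0.15, 0.10), prob_descent_is_drop = 0.55,
      rest_mean_s = 12, bottom_bias = 0.85),
    park25_nicotine = phenotype_preset(
      "park25_nicotine", climb_initiation_rate_per_min = 2,
      ascent_speed_mean_mm_s = 11,
      peak_height_probs = c(0.20, 0.20, 0.25, 0.35), prob_descent_is_drop = 0.35,
      rest_mean_s = 9, bottom_bias = 0.65))
}

#' @rdname preset_library
#' @param name preset name.
#' @export
get_preset <- function(name) {
  lib <- preset_library()
  if (!name %in% names(lib)) stop("unknown preset: ", name)
  lib[[name]]
}

#' Simulate one fly with ground truth
#'
#' Continuous-time semi-Markov simulation of rest / ascent / descent episodes
#' with event durations on a 0.05 s grid and position clamped to the
#' detection zone. The piecewise-linear height path is sampled at 1 Hz and
#' quantized to the monitor's 3 mm bins (nearest bin), so sampled heights
#' never differ from the continuous truth by 3 mm or more. Identical
#' `(preset, duration_s, seed)` give bit-identical outputs.
#'
#' @param preset a [phenotype_preset()].
#' @param duration_s assay duration in seconds (default 1200, i.e. 20 min).
#' @param seed integer seed.
#' @param fly_id,genotype,age_days,dose_ug_per_ml,start_day metadata attached
#'   to the emitted trajectory.
#' @param geom an [assay_geometry()].
#' @return List with elements `trajectory` (a [trajectory()]) and `truth`
#'   (data frame of true events: `fly_id`, `type` in
#'   rest/ascent/drop/descending_climb, `t_start`, `t_end`, `h_start`,
#'   `h_end`, `true_velocity` in mm/s).
#' @export
simulate_fly <- function(preset, duration_s = 1200L, seed = 1L,
                         fly_id = "fly01", genotype = "control",
                         age_days = 20L, dose_ug_per_ml = 0,
                         start_day = NA_integer_, geom = assay_geometry()) {
  if (!inherits(preset, "phenotype_preset"))
    stop("'preset' must be a phenotype_preset")
  duration_s <- check_count(duration_s, "duration_s", min = 1L)
  step <- 0.05
  qd <- function(x) max(step, round(x / step) * step)
  env <- new.env(parent = emptyenv())
  env$t <- 0; env$y <- geom$increment_mm
  env$type <- character(0); env$t0 <- env$t1 <- env$h0 <- env$h1 <- numeric(0)
  emit <- function(type, dur, h_end) {
    t0 <- env$t; t1 <- t0 + dur; h0 <- env$y
    trunc <- t1 > duration_s
    if (trunc) {
      h_end <- h0 + (h_end - h0) * (duration_s - t0) / dur
      t1 <- duration_s
    }
    env$type <- c(env$type, type)
    env$t0 <- c(env$t0, t0); env$t1 <- c(env$t1, t1)
    env$h0 <- c(env$h0, h0); env$h1 <- c(env$h1, h_end)
    env$t <- t1; env$y <- h_end
    trunc
  }
  with_seed(seed, {
    pk <- preset$peak_heights_mm
    repeat {
      ## rest: climbs initiate from the bottom at the preset rate; mid-tube
      ## rests use the preset rest duration
      at_bottom <- env$y <= geom$increment_mm
      rate <- preset$climb_initiation_rate_per_min / 60
      rmean <- if (at_bottom) (if (rate > 0) 1 / rate else Inf) else preset$rest_mean_s
      r <- if (is.infinite(rmean)) duration_s - env$t else qd(stats::rexp(1, 1 / rmean))
      if (emit("rest", r, env$y)) break
      ## ascent toward a sampled peak (skip when already at/above all peaks)
      cand <- which(pk > env$y + 1e-9)
      if (length(cand)) {
        pr <- preset$peak_height_probs[cand]
        target <- pk[cand[sample.int(length(cand), 1, prob = pr)]]
        sp <- stats::rnorm(1, preset$ascent_speed_mean_mm_s,
                           preset$ascent_speed_sd_mm_s)
        sp <- max(sp, 0.5)
        if (emit("ascent", qd((target - env$y) / sp), target)) break
        pp <- preset$peak_pause_range_s
        if (emit("rest", qd(stats::runif(1, pp[1], pp[2])), env$y)) break
      }
      ## descent
      if (env$y > geom$increment_mm + 1e-9) {
        is_drop <- stats::runif(1) < preset$prob_descent_is_drop
        lowest <- geom$increment_mm
        if (stats::runif(1) < preset$bottom_bias || env$y - lowest <= 6) {
          target <- lowest
        } else {
          grid <- seq(lowest, env$y - 6, by = geom$increment_mm)
          target <- grid[sample.int(length(grid), 1)]
        }
        rng <- if (is_drop) preset$drop_speed_range_mm_s else preset$descclimb_speed_range_mm_s
        sp <- stats::runif(1, rng[1], rng[2])
        if (emit(if (is_drop) "drop" else "descending_climb",
                 qd((env$y - target) / sp), target)) break
      }
      if (env$t >= duration_s) break
    }
  })
  knots_t <- c(0, env$t1)
  knots_h <- c(geom$increment_mm, env$h1)
  hs <- stats::approx(knots_t, knots_h, xout = seq_len(duration_s) - 1,
                      rule = 2, ties = "ordered")$y
  pos <- pmin(geom$n_positions, pmax(1, round(hs / geom$increment_mm)))
  heights <- pos * geom$increment_mm
  truth <- data.frame(fly_id = fly_id, type = env$type,
                      t_start = env$t0, t_end = env$t1,
                      h_start = env$h0, h_end = env$h1,
                      true_velocity = ifelse(env$t1 > env$t0,
                                             abs(env$h1 - env$h0) / (env$t1 - env$t0), 0),
                      stringsAsFactors = FALSE)
  list(trajectory = trajectory(fly_id, heights, genotype, age_days,
                               dose_ug_per_ml, start_day, geom = geom),
       truth = truth)
}

#' Simulate a multi-group cohort
#'
#' Runs [simulate_fly()] for every fly of every design group. Per-fly seeds
#' are derived as `seed + running fly index`, so cohorts are reproducible
#' independent of iteration order.
#'
#' @param design named list; each element is a list with fields `preset`
#'   (preset name or [phenotype_preset()]), `n` (flies, >= 1), and optional
#'   metadata `genotype`, `age_days`, `dose_ug_per_ml`, `start_day`.
#' @param duration_s assay duration in seconds.
#' @param seed master integer seed.
#' @param geom an [assay_geometry()].
#' @return Object of class `sim_cohort`: list with `trajectories` (named list
#'   of [trajectory()]) and `truth` (row-bound ground-truth log with a
#'   `group` column).
#' @export
simulate_cohort <- function(design, duration_s = 1200L, seed = 1L,
                            geom = assay_geometry()) {
  if (!is.list(design) || !length(design)) stop("'design' must be a non-empty list")
  nm <- names(design)
  if (is.null(nm) || any(!nzchar(nm))) stop("design groups must be named")
  if (anyDuplicated(nm)) stop("duplicate group names in design: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  trajs <- list(); truth <- list(); idx <- 0L
  for (g in nm) {
    gs <- design[[g]]
    preset <- gs$preset
    if (is.character(preset)) preset <- get_preset(preset)
    n <- gs$n
    if (is.null(n) || !is_whole(n) || n < 1)
      stop("group '", g, "' must have n >= 1")
    for (i in seq_len(n)) {
      idx <- idx + 1L
      sim <- simulate_fly(preset, duration_s, seed = seed + idx,
                          fly_id = sprintf("%s_%03d", g, i),
                          genotype = gs$genotype %||% "control",
                          age_days = gs$age_days %||% 20L,
                          dose_ug_per_ml = gs$dose_ug_per_ml %||% 0,
                          start_day = gs$start_day %||% NA_integer_,
                          geom = geom)
      sim$truth$group <- g
      trajs[[sim$trajectory$fly_id]] <- sim$trajectory
      truth[[idx]] <- sim$truth
    }
  }
  structure(list(trajectories = trajs, truth = do.call(rbind, truth)),
            class = "sim_cohort")
}

#' Simulate binary flight outcomes
#'
#' Independent Bernoulli flight outcomes for one group, deterministic under a
#' fixed seed.
#'
#' @param fly_probability probability of flight in `[0, 1]`.
#' @param n number of flies.
#' @param seed integer seed.
#' @param genotype,dose_ug_per_ml,start_day group labels for the records.
#' @param id_prefix prefix for generated fly ids.
#' @return Data frame of flight records (see [read_flight_table()]).
#' @export
simulate_flight <- function(fly_probability, n, seed = 1L,
                            genotype = "control", dose_ug_per_ml = 0,
                            start_day = NA_integer_, id_prefix = "fly") {
  if (!is.numeric(fly_probability) || length(fly_probability) != 1 ||
      fly_probability < 0 || fly_probability > 1)
    stop("'fly_probability' must be a probability in [0, 1]")
  n <- check_count(n, "n", min = 1L)
  flew <- with_seed(seed, stats::runif(n) < fly_probability)
  data.frame(fly_id = sprintf("%s_%04d", id_prefix, seq_len(n)),
             genotype = genotype,
             dose_ug_per_ml = dose_ug_per_ml,
             start_day = if (is.na(start_day)) NA_integer_ else as.integer(start_day),
             flew = flew,
             stringsAsFactors = FALSE)
}

#' Evaluate descent-label recovery against simulator ground truth
#'
#' Matches each true descent event (drop or descending climb whose true
#' distance is at least `min_true_distance_mm`, so that its quantized trace
#' must exceed the classifier's minimum recordable distance) to the
#' overlapping segmented descent and compares labels.
#'
#' Accuracy follows the video-validation convention: it is computed over the
#' *classifiable* descents — those the classifier assigned a definite drop or
#' descending-climb label — because descents whose observed velocity falls in
#' the excluded band cannot be differentiated at 1 Hz / 3 mm resolution and
#' are excluded from both behavioural counts. (A short drop that straddles a
#' sample boundary is always observed at half its distance per second, which
#' can land in the band regardless of its true speed.) The fraction of true
#' descents that received a definite label is reported as `coverage`.
#'
#' @param sim output of [simulate_fly()] or [simulate_cohort()].
#' @param params a [classifier_params()].
#' @param min_true_distance_mm smallest true descent distance evaluated.
#' @return List with `n_true`, `n_classifiable`, `n_correct`, `accuracy`
#'   (correct / classifiable), `coverage` (classifiable / true), and a
#'   `detail` data frame (one row per evaluated true descent).
#' @export
evaluate_descent_recovery <- function(sim, params = classifier_params(),
                                      min_true_distance_mm = 7) {
  if (inherits(sim, "sim_cohort")) {
    sims <- lapply(names(sim$trajectories), function(id)
      list(trajectory = sim$trajectories[[id]],
           truth = sim$truth[sim$truth$fly_id == id, , drop = FALSE]))
  } else sims <- list(sim)
  details <- list()
  for (s in sims) {
    truth <- s$truth
    td <- truth[truth$type %in% c("drop", "descending_climb") &
                  (truth$h_start - truth$h_end) >= min_true_distance_mm, ,
                drop = FALSE]
    if (!nrow(td)) next
    seg <- classify_descents(segment_descents(s$trajectory, params), params)
    pred <- rep(NA_character_, nrow(td))
    if (nrow(seg)) {
      for (i in seq_len(nrow(td))) {
        w1 <- floor(td$t_start[i]); w2 <- ceiling(td$t_end[i])
        ov <- pmin(seg$end_t_s, w2) - pmax(seg$start_t_s, w1)
        j <- which.max(ov)
        if (ov[j] >= 0) pred[i] <- as.character(seg$label[j])
      }
    }
    details[[length(details) + 1L]] <- data.frame(
      fly_id = td$fly_id, type = td$type, t_start = td$t_start,
      t_end = td$t_end, true_velocity = td$true_velocity,
      predicted = pred,
      classifiable = !is.na(pred) & pred %in% c("drop", "descending_climb"),
      correct = !is.na(pred) & pred == td$type,
      stringsAsFactors = FALSE)
  }
  detail <- if (length(details)) do.call(rbind, details) else
    data.frame(fly_id = character(0), type = character(0),
               t_start = numeric(0), t_end = numeric(0),
               true_velocity = numeric(0), predicted = character(0),
               classifiable = logical(0), correct = logical(0))
  n_cls <- sum(detail$classifiable)
  list(n_true = nrow(detail),
       n_classifiable = n_cls,
       n_correct = sum(detail$correct),
       accuracy = if (n_cls) sum(detail$correct) / n_cls else NA_real_,
       coverage = if (nrow(detail)) n_cls / nrow(detail) else NA_real_,
       detail = detail)
}
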