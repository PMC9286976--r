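# Shared fixture builders: everything is generated in code, no binary files.

# Random valid height series: a clamped random walk on the 3 mm grid.
random_walk_heights <- function(n, geom = assay_geometry()) {
  steps <- sample(-2:2, n - 1, replace = TRUE)
  pos <- Reduce(function(p, s) min(geom$n_positions, max(1L, p + s)),
                steps, init = sample.int(geom$n_positions, 1),
                accumulate = TRUE)
  pos * geom$increment_mm
}

random_trajectory <- function(n = 60, id = "rw", geom = assay_geometry()) {
  trajectory(id, random_walk_heights(n, geom),
             genotype = sample(c("control", "park25"), 1),
             age_days = sample(0:20, 1),
             dose_ug_per_ml = sample(c(0, 3, 4.5, 6, 9), 1),
             geom = geom)
}

# Independent oracle for climbing-event counts: the number of up -> down sign
# reversals of the movement sequence (zeros dropped).
oracle_reversal_count <- function(h) {
  s <- sign(diff(h))
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-length(s)] == 1 & s[-1] == -1)
}

# Independent Fisher oracle: enumerate all 2x2 tables with the observed
# margins via binomial coefficients (no dhyper).
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  as <- max(0, k - n2):min(k, m)
  probs <- choose(m, as) * choose(n2, k - as) / choose(m + n2, k)
  p_obs <- probs[as == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Write a small multibeam fixture file and return its path.
write_multibeam_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("t_s\ttube_id\tposition_index", rows), path)
  path
}

# Flight-window stated world used by the window-recovery tests: park25 flies
# benefit from treatment started on days 0-5 (0.06 -> 0.40), controls are
# harmed through day 6 (0.88 -> 0.55). See the methods vignette.
simulate_window_cohort <- function(seed, n_per_group = 50L, days = 0:8,
                                   true_edge = 5L) {
  rows <- list()
  s <- seed
  for (d in days) {
    p_park_treated <- if (d <= true_edge) 0.40 else 0.06
    p_ctrl_treated <- if (d <= 6L) 0.55 else 0.88
    for (arm in list(
      list(g = "park25", dose = 4.5, p = p_park_treated),
      list(g = "park25", dose = 0, p = 0.06),
      list(g = "control", dose = 4.5, p = p_ctrl_treated),
      list(g = "control", dose = 0, p = 0.88))) {
      s <- s + 1L
      rows[[length(rows) + 1L]] <- simulate_flight(
        arm$p, n_per_group, seed = s, genotype = arm$g,
        dose_ug_per_ml = arm$dose, start_day = d,
        id_prefix = sprintf("%s_d%d_%g", arm$g, d, arm$dose))
    }
  }
  do.call(rbind, rows)
}
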