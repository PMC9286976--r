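#' Read a monitor recording into per-fly trajectories
#'
#' Supports two on-disk dialects:
#'
#' * `multibeam_tsv` — a reconstruction of a raw multibeam monitor export:
#'   tab-delimited columns `t_s` (seconds), `tube_id` (1-16) and
#'   `position_index` (1-17, empty or `NA` when no beam fired). Lines starting
#'   with `#` are comments. See `inst/extdata/multibeam_example.tsv` for an
#'   annotated example. Fly metadata is joined from a sidecar manifest (DCF
#'   key-value blocks mapping `tube_id` to `fly_id`, `genotype`, ...).
#' * `canonical_table` — the package's long-format trajectory table with
#'   columns `fly_id`, `t_s`, `height_mm`, `genotype`, `age_days`,
#'   `dose_ug_per_ml`, `start_day` (see [write_canonical()]).
#'
#' Gap policy: timestamps are normalized to t = 0 at each fly's first sample;
#' a missing second inherits the previous position (hold-last, with back-fill
#' at the head). Any gap longer than `max_gap_s` marks the trajectory as
#' `flagged`; flagged flies are excluded from metric tables by default but the
#' data are preserved.
#'
#' @param path file path.
#' @param dialect `"multibeam_tsv"` or `"canonical_table"`.
#' @param manifest optional path to a DCF manifest (multibeam dialect only).
#' @param assay_duration_s expected number of 1 Hz samples; `NULL` (default)
#'   infers each fly's duration from its last timestamp. The standard assay is
#'   1200 s.
#' @param max_gap_s longest tolerated gap, in seconds, before flagging.
#' @param geom an [assay_geometry()].
#' @return List of [trajectory()] objects.
#' @export
read_monitor_file <- function(path,
                              dialect = c("multibeam_tsv", "canonical_table"),
                              manifest = NULL,
                              assay_duration_s = NULL,
                              max_gap_s = 5L,
                              geom = assay_geometry()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         multibeam_tsv = read_multibeam(path, manifest, assay_duration_s, max_gap_s, geom),
         canonical_table = read_canonical(path, assay_duration_s, max_gap_s, geom))
}

canonical_columns <- c("fly_id", "t_s", "height_mm", "genotype", "age_days",
                       "dose_ug_per_ml", "start_day")

read_multibeam <- function(path, manifest, assay_duration_s, max_gap_s, geom) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lnos <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no data rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # optional header
  if (identical(tolower(trimws(fields[[1]])), c("t_s", "tube_id", "position_index"))) {
    fields <- fields[-1]; lnos <- lnos[-1]
  }
  if (!length(fields)) stop("no data rows in ", path)
  parse_int <- function(x) suppressWarnings(as.integer(x))
  n <- length(fields)
  t_s <- tube <- pos <- integer(n)
  for (i in seq_len(n)) {
    f <- trimws(fields[[i]])
    if (length(f) != 3)
      stop(sprintf("parse error at line %d of %s: expected 3 tab-delimited fields, got %d",
                   lnos[i], path, length(f)))
    ti <- parse_int(f[1]); tu <- parse_int(f[2])
    if (is.na(ti) || is.na(tu))
      stop(sprintf("parse error at line %d of %s: non-integer timestamp or tube id",
                   lnos[i], path))
    pi <- if (f[3] == "" || toupper(f[3]) == "NA") NA_integer_ else parse_int(f[3])
    if (!is.na(f[3]) && f[3] != "" && toupper(f[3]) != "NA" && is.na(pi))
      stop(sprintf("parse error at line %d of %s: malformed position index '%s'",
                   lnos[i], path, f[3]))
    if (tu < 1 || tu > 16)
      stop(sprintf("validation error at line %d of %s: tube_id %d outside 1-16",
                   lnos[i], path, tu))
    if (!is.na(pi) && (pi < 1 || pi > geom$n_positions))
      stop(sprintf("validation error at line %d of %s: position index %d outside 1-%d",
                   lnos[i], path, pi, geom$n_positions))
    t_s[i] <- ti; tube[i] <- tu; pos[i] <- pi
  }
  meta <- if (!is.null(manifest)) read_manifest(manifest) else NULL
  trajs <- list()
  for (tu in sort(unique(tube))) {
    sel <- tube == tu
    tt <- t_s[sel]; pp <- pos[sel]
    if (any(diff(tt) <= 0))
      stop(sprintf("validation error in %s: non-monotone timestamps for tube %d", path, tu))
    h <- position_to_height(pp[!is.na(pp)], geom)
    tt_obs <- tt[!is.na(pp)] - tt[1]
    if (!length(h))
      stop(sprintf("validation error in %s: tube %d has no beam readings", path, tu))
    dur <- assay_duration_s %||% (max(tt - tt[1]) + 1L)
    filled <- fill_gaps(tt_obs, h, dur, max_gap_s)
    m <- list(fly_id = sprintf("tube%02d", tu), genotype = "control",
              age_days = 20L, dose_ug_per_ml = 0, start_day = NA_integer_)
    if (!is.null(meta)) {
      row <- meta[meta$tube_id == tu, , drop = FALSE]
      if (nrow(row) == 1) {
        m$fly_id <- row$fly_id
        m$genotype <- row$genotype
        m$age_days <- row$age_days
        m$dose_ug_per_ml <- row$dose_ug_per_ml
        m$start_day <- row$start_day
      }
    }
    trajs[[m$fly_id]] <- trajectory(m$fly_id, filled$heights, m$genotype,
                                    m$age_days, m$dose_ug_per_ml, m$start_day,
                                    flagged = filled$flagged, geom = geom)
  }
  trajs
}

read_canonical <- function(path, assay_duration_s, max_gap_s, geom) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(canonical_columns, names(df))
  if (length(missing_cols))
    stop("canonical table ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(df)) return(list())
  trajs <- list()
  for (id in unique(df$fly_id)) {
    sub <- df[df$fly_id == id, , drop = FALSE]
    tt <- sub$t_s
    if (any(diff(tt) <= 0))
      stop(sprintf("validation error in %s: non-monotone timestamps for fly %s", path, id))
    p <- sub$height_mm / geom$increment_mm
    if (!all(is_whole(p)) || any(p < 1) || any(p > geom$n_positions))
      stop(sprintf("validation error in %s: fly %s has heights off the %g mm grid",
                   path, id, geom$increment_mm))
    dur <- assay_duration_s %||% (max(tt - tt[1]) + 1L)
    filled <- fill_gaps(tt - tt[1], sub$height_mm, dur, max_gap_s)
    sd1 <- sub$start_day[1]
    trajs[[id]] <- trajectory(as.character(id), filled$heights,
                              genotype = as.character(sub$genotype[1]),
                              age_days = as.integer(sub$age_days[1]),
                              dose_ug_per_ml = as.numeric(sub$dose_ug_per_ml[1]),
                              start_day = if (is.na(sd1)) NA_integer_ else as.integer(sd1),
                              flagged = filled$flagged, geom = geom)
  }
  trajs
}

# Hold-last imputation onto a 0..(duration-1) grid. Returns the filled height
# vector and whether any gap run exceeded max_gap_s.
fill_gaps <- function(t_obs, h_obs, duration_s, max_gap_s) {
  duration_s <- check_count(duration_s, "assay_duration_s", min = 1L)
  keep <- t_obs >= 0 & t_obs < duration_s
  t_obs <- t_obs[keep]; h_obs <- h_obs[keep]
  h <- rep(NA_real_, duration_s)
  h[t_obs + 1L] <- h_obs
  flagged <- FALSE
  if (anyNA(h)) {
    runs <- rle(is.na(h))
    flagged <- any(runs$lengths[runs$values] > max_gap_s)
    idx <- cumsum(!is.na(h))
    first <- which(!is.na(h))[1]
    idx[idx == 0] <- NA
    filled <- h[!is.na(h)][idx]
    filled[is.na(filled)] <- h[first]  # back-fill a leading gap
    h <- filled
  }
  list(heights = h, flagged = flagged)
}

#' Write trajectories to the canonical long table
#'
#' Tab-delimited UTF-8 with the fixed header `fly_id, t_s, height_mm,
#' genotype, age_days, dose_ug_per_ml, start_day`; lossless with respect to
#' `read_monitor_file(dialect = "canonical_table")`.
#'
#' @param trajs a [trajectory()] or list of them (may be empty).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_canonical <- function(trajs, path) {
  if (is.null(trajs) || (is.list(trajs) && !length(trajs) &&
                         !inherits(trajs, "fly_trajectory"))) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(canonical_columns)),
                                 canonical_columns))
  } else {
    trajs <- as_trajectory_list(trajs)
    df <- do.call(rbind, lapply(trajs, as.data.frame))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tube-to-fly manifest
#'
#' DCF key-value blocks, one per tube, with fields `tube_id`, `fly_id`,
#' `genotype`, and optional `age_days`, `dose_ug_per_ml`, `start_day`.
#'
#' @param path manifest file path.
#' @return Data frame, one row per tube.
#' @export
read_manifest <- function(path) {
  m <- read.dcf(path)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  if (!all(c("tube_id", "fly_id") %in% names(df)))
    stop("manifest ", path, " must contain fields 'tube_id' and 'fly_id'")
  df$tube_id <- as.integer(df$tube_id)
  df$genotype <- if ("genotype" %in% names(df)) df$genotype else "control"
  df$age_days <- if ("age_days" %in% names(df)) as.integer(df$age_days) else 20L
  df$dose_ug_per_ml <- if ("dose_ug_per_ml" %in% names(df)) as.numeric(df$dose_ug_per_ml) else 0
  df$start_day <- if ("start_day" %in% names(df)) as.integer(df$start_day) else NA_integer_
  df
}

#' Read a binary flight-outcome table
#'
#' Expects columns `fly_id`, `genotype`, `dose_ug_per_ml`, `start_day`,
#' `flew`; tab-delimited unless the path ends in `.csv`. The `flew` column is
#' parsed strictly from `0/1/yes/no/true/false` (case-insensitive); anything
#' else is a parse error.
#'
#' @param path file path.
#' @return Data frame of flight records with logical `flew`.
#' @export
read_flight_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("fly_id", "genotype", "dose_ug_per_ml", "start_day", "flew")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("flight table ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(df)) {
    df$flew <- logical(0)
    df$dose_ug_per_ml <- numeric(0)
    df$start_day <- integer(0)
    return(df[needed])
  }
  key <- tolower(trimws(df$flew))
  truth <- c("1" = TRUE, "yes" = TRUE, "true" = TRUE,
             "0" = FALSE, "no" = FALSE, "false" = FALSE)
  bad <- !(key %in% names(truth))
  if (any(bad))
    stop(sprintf("parse error in %s: ambiguous flight value '%s' at row %d",
                 path, df$flew[which(bad)[1]], which(bad)[1]))
  out <- data.frame(fly_id = df$fly_id,
                    genotype = df$genotype,
                    dose_ug_per_ml = as.numeric(df$dose_ug_per_ml),
                    start_day = suppressWarnings(as.integer(df$start_day)),
                    flew = unname(truth[key]),
                    stringsAsFactors = FALSE)
  out
}

#' Write a flight-outcome table
#'
#' Inverse of [read_flight_table()]; `flew` is written as 0/1.
#'
#' @param flight data frame with the flight-table columns.
#' @param path output path (`.csv` for comma-separated, otherwise TSV).
#' @return `path`, invisibly.
#' @export
write_flight_table <- function(flight, path) {
  out <- flight[c("fly_id", "genotype", "dose_ug_per_ml", "start_day", "flew")]
  out$flew <- as.integer(out$flew)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
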