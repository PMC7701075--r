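## CSV / YAML readers and writers for the package's table schemas. Writers
## emit a commented metadata header (tool version, seed, weighting basis);
## readers validate schemas and report offending rows.

meta_header <- function(extra = list()) {
  meta <- c(list(tool = paste0("fibrilhydro ",
                               as.character(utils::packageVersion("fibrilhydro"))),
                 written = format(Sys.time(), "%Y-%m-%d")),
            extra)
  sprintf("# %s: %s", names(meta), vapply(meta, function(v)
    paste(format(v), collapse = " "), character(1)))
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  df
}

check_numeric_column <- function(df, col, path) {
  v <- df[[col]]
  bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
  if (length(bad))
    stop(sprintf("%s: non-numeric value in column '%s' at data row %d",
                 path, col, bad[1]))
  as.numeric(v)
}

#' Read an AFM fibril-length table
#'
#' CSV with a `length_nm` column (optional `height_nm`), `#`-prefixed
#' metadata lines allowed.
#'
#' @param path CSV file path.
#' @return Data frame with `length_nm` (and `height_nm` if present).
#' @export
read_afm_table <- function(path) {
  df <- read_table_checked(path, "length_nm")
  df$length_nm <- check_numeric_column(df, "length_nm", path)
  if ("height_nm" %in% names(df))
    df$height_nm <- check_numeric_column(df, "height_nm", path)
  df
}

#' Write an AFM fibril-length table
#'
#' @param df Data frame with `length_nm` (optional `height_nm`).
#' @param path Output CSV path.
#' @param metadata Named list added to the commented header.
#' @return `path`, invisibly.
#' @export
write_afm_table <- function(df, path, metadata = list()) {
  stopifnot("length_nm" %in% names(df))
  writeLines(c(meta_header(metadata),
               paste(names(df), collapse = ",")), path)
  utils::write.table(df, path, append = TRUE, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a sedimentation-coefficient distribution
#'
#' CSV with `s_svedberg` and either `density` or `cumulative`. A cumulative
#' input is differentiated (central differences) to a density on ingest and
#' flagged in the metadata.
#'
#' @param path CSV file path.
#' @param weighting Weighting basis tag of the stored distribution.
#' @return A [weighted_distribution()] over s.
#' @export
read_s_distribution <- function(path, weighting = "extinction") {
  df <- read_table_checked(path, "s_svedberg")
  s <- check_numeric_column(df, "s_svedberg", path)
  if ("density" %in% names(df)) {
    dens <- check_numeric_column(df, "density", path)
    from_cumulative <- FALSE
  } else if ("cumulative" %in% names(df)) {
    cum <- check_numeric_column(df, "cumulative", path)
    if (is.unsorted(cum)) stop(path, ": cumulative column must be non-decreasing")
    n <- length(s)
    dens <- numeric(n)
    dens[2:(n - 1)] <- (cum[3:n] - cum[1:(n - 2)]) / (s[3:n] - s[1:(n - 2)])
    dens[1] <- (cum[2] - cum[1]) / (s[2] - s[1])
    dens[n] <- (cum[n] - cum[n - 1]) / (s[n] - s[n - 1])
    dens[dens < 0] <- 0
    from_cumulative <- TRUE
  } else {
    stop(path, ": need a 'density' or 'cumulative' column alongside 's_svedberg'")
  }
  weighted_distribution(s, dens, axis = "s", weighting = weighting,
                        metadata = list(source = path,
                                        from_cumulative = from_cumulative))
}

#' Write a weighted distribution as CSV
#'
#' Columns mirror the input schemas: `length_nm`/`s_svedberg` plus `density`
#' (and `cumulative`); the weighting basis goes into the metadata header.
#'
#' @param dist A [weighted_distribution()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "weighted_distribution"))
  axis_col <- if (dist$axis == "length") "length_nm" else "s_svedberg"
  df <- data.frame(dist$grid, density = dist$density,
                   cumulative = cumulative_weight(dist))
  names(df)[1] <- axis_col
  writeLines(c(meta_header(list(weighting = dist$weighting, axis = dist$axis)),
               paste(names(df), collapse = ",")), path)
  utils::write.table(df, path, append = TRUE, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a distribution written by [write_distribution()]
#'
#' @param path CSV file path.
#' @return A [weighted_distribution()].
#' @export
read_distribution <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- grep("^#", readLines(path, n = 20), value = TRUE)
  wt <- sub("^# weighting: ", "", grep("^# weighting: ", header, value = TRUE))
  df <- utils::read.csv(path, comment.char = "#")
  axis <- if ("length_nm" %in% names(df)) "length" else "s"
  grid <- if (axis == "length") df$length_nm else df$s_svedberg
  if (is.null(grid)) stop(path, ": no length_nm or s_svedberg column")
  weighted_distribution(grid, check_numeric_column(df, "density", path),
                        axis = axis,
                        weighting = if (length(wt)) wt else "number",
                        metadata = list(source = path), normalize = FALSE)
}

#' Read a gravitational-sweep run configuration (YAML)
#'
#' Keys: `rotor_rpm, meniscus_cm, bottom_cm, detector_cm, duration_s, dt_s,
#' n_particles, seed, cutoff_svedberg` and a `species` list of
#' `{s_svedberg, ffo, density_kg_m3, abundance}`.
#'
#' @param path YAML file path.
#' @return A list with `config` ([sweep_config()]), `species` (list of
#'   [species_spec()]) and `cutoff`.
#' @export
read_sweep_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  need <- c("rotor_rpm", "meniscus_cm", "bottom_cm", "detector_cm",
            "duration_s", "dt_s", "n_particles", "seed", "species")
  missing <- setdiff(need, names(y))
  if (length(missing))
    stop(path, ": missing key(s): ", paste(missing, collapse = ", "))
  config <- sweep_config(rotor_rpm = y$rotor_rpm, meniscus_cm = y$meniscus_cm,
                         bottom_cm = y$bottom_cm, detector_cm = y$detector_cm,
                         duration_s = y$duration_s, dt_s = y$dt_s,
                         n_particles = y$n_particles, seed = y$seed)
  ab <- vapply(y$species, function(sp) {
    need_sp <- c("s_svedberg", "ffo", "density_kg_m3", "abundance")
    if (!all(need_sp %in% names(sp)))
      stop(path, ": each species needs ", paste(need_sp, collapse = ", "))
    sp$abundance
  }, numeric(1))
  species <- mapply(function(sp, a)
    species_spec(sp$s_svedberg, sp$ffo, sp$density_kg_m3, a / sum(ab)),
    y$species, ab, SIMPLIFY = FALSE)
  list(config = config, species = species,
       cutoff = if (is.null(y$cutoff_svedberg)) 10 else y$cutoff_svedberg)
}

#' Write a gravitational-sweep run configuration (YAML)
#'
#' @param config A [sweep_config()].
#' @param species List of [species_spec()].
#' @param path Output YAML path.
#' @param cutoff Analysis cutoff in Svedberg.
#' @return `path`, invisibly.
#' @export
write_sweep_config <- function(config, species, path, cutoff = 10) {
  stopifnot(inherits(config, "sweep_config"))
  y <- list(rotor_rpm = config$rotor_rpm,
            meniscus_cm = config$meniscus * 100,
            bottom_cm = config$bottom * 100,
            detector_cm = config$detector * 100,
            duration_s = config$duration, dt_s = config$dt,
            n_particles = config$n_particles, seed = config$seed,
            cutoff_svedberg = cutoff,
            species = lapply(species, function(sp)
              list(s_svedberg = sp$s, ffo = sp$ffo,
                   density_kg_m3 = sp$density, abundance = sp$abundance)))
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}

#' Write a detector trace as CSV
#'
#' @param trace A [simulate_sweep()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_s = trace$time, signal = trace$signal)
  writeLines(c(meta_header(list(seed = trace$config$seed,
                                rotor_rpm = trace$config$rotor_rpm)),
               "time_s,signal"), path)
  utils::write.table(df, path, append = TRUE, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a comminution series CSV
#'
#' Columns `rpm, seconds, length_nm` and optionally `statistic, source`.
#'
#' @param path CSV file path.
#' @return A [comminution_series()].
#' @export
read_comminution_series <- function(path) {
  df <- read_table_checked(path, c("rpm", "seconds", "length_nm"))
  comminution_series(check_numeric_column(df, "rpm", path),
                     check_numeric_column(df, "seconds", path),
                     check_numeric_column(df, "length_nm", path),
                     statistic = if ("statistic" %in% names(df)) df$statistic else "mean",
                     source = if ("source" %in% names(df)) df$source else "AFM")
}
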