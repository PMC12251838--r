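#' File formats and session configuration
#'
#' Streams are exchanged as one CSV per sensor with a mandatory unit
#' header line (`# units: t=s gyro=rad/s accel=m/s2`), columns
#' `t,gx,gy,gz,ax,ay,az`. Gyro may be declared in `rad/s` or `deg/s`,
#' accel in `m/s2` or `g`; values are normalized on read. Parameter
#' tables are written as tidy CSV and JSON; cluster results and truth
#' records as JSON.
#'
#' @name io
NULL

#' Write sensor streams to a directory
#'
#' @param streams named list of [sensor_stream()]s.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_streams <- function(streams, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(streams), function(nm) {
    s <- streams[[nm]]
    path <- file.path(dir, paste0(nm, ".csv"))
    con <- file(path, "w")
    writeLines("# units: t=s gyro=rad/s accel=m/s2", con)
    utils::write.csv(data.frame(
      t = s$t,
      gx = s$gyro[, 1], gy = s$gyro[, 2], gz = s$gyro[, 3],
      ax = s$accel[, 1], ay = s$accel[, 2], az = s$accel[, 3]),
      con, row.names = FALSE)
    close(con)
    path
  }, character(1))
  invisible(paths)
}

parse_unit_header <- function(line, path) {
  if (!grepl("^#\\s*units:", line))
    stop("missing unit header line in ", path)
  units <- list(gyro = "rad/s", accel = "m/s2")
  for (part in strsplit(sub("^#\\s*units:\\s*", "", line), "\\s+")[[1]]) {
    kv <- strsplit(part, "=")[[1]]
    if (length(kv) == 2) units[[kv[1]]] <- kv[2]
  }
  if (!units$gyro %in% c("rad/s", "deg/s"))
    stop("unsupported gyro unit '", units$gyro, "' in ", path)
  if (!units$accel %in% c("m/s2", "g"))
    stop("unsupported accel unit '", units$accel, "' in ", path)
  units
}

#' Read sensor streams from a directory
#'
#' Each `<sensor>.csv` must carry the unit header line; the sensor name
#' maps to a placement either directly or through `config$sensors`
#' (named list `sensor_id = placement`). Units are normalized to rad/s
#' and m/s^2, gaps larger than 2/rate are an error (naming the sensor
#' and time), and cross-sensor start-time alignment is verified to
#' within 5 ms.
#'
#' @param dir directory of stream CSVs.
#' @param config optional session config list ([read_session_config()]).
#' @return named list of [sensor_stream()]s (by placement).
#' @export
read_streams <- function(dir, config = NULL) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no stream CSVs found in ", dir)
  rate <- if (!is.null(config$rate)) config$rate else 200
  streams <- list()
  for (path in files) {
    sensor_id <- sub("\\.csv$", "", basename(path))
    placement <- if (!is.null(config$sensors))
      config$sensors[[sensor_id]] else sensor_id
    if (is.null(placement) || !placement %in% swim_placements()) {
      if (!is.null(config$sensors)) stop("unmapped sensor: ", sensor_id)
      next
    }
    if (placement %in% names(streams))
      stop("placement mapped twice: ", placement)
    units <- parse_unit_header(readLines(path, n = 1), path)
    df <- utils::read.csv(path, comment.char = "#")
    need <- c("t", "gx", "gy", "gz", "ax", "ay", "az")
    if (!all(need %in% names(df)))
      stop("missing column(s) ", paste(setdiff(need, names(df)), collapse = ","),
           " in ", path)
    gyro <- as.matrix(df[, c("gx", "gy", "gz")])
    accel <- as.matrix(df[, c("ax", "ay", "az")])
    if (units$gyro == "deg/s") gyro <- gyro * pi / 180
    if (units$accel == "g") accel <- accel * GRAVITY
    streams[[placement]] <- sensor_stream(placement, df$t, gyro, accel,
                                          rate = rate)
  }
  starts <- vapply(streams, function(s) s$t[1], numeric(1))
  if (diff(range(starts)) > 0.005)
    stop(sprintf("cross-sensor time misalignment of %.1f ms exceeds 5 ms",
                 diff(range(starts)) * 1000))
  streams
}

#' Read a YAML session configuration
#'
#' Values in the file override [default_config()]; unknown keys are kept
#' (e.g. `sensors`, `n_laps`, threshold overrides).
#'
#' @param path YAML file.
#' @return merged config list.
#' @export
read_session_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

#' Write a parameter table as tidy CSV and JSON
#'
#' One row per subject x parameter in the CSV; the JSON mirrors the
#' named vectors.
#'
#' @param params named numeric vector, or subjects x parameters matrix.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the tidy data frame.
#' @export
write_parameter_table <- function(params, csv_path = NULL, json_path = NULL) {
  if (is.null(dim(params))) params <- t(as.matrix(params))
  if (is.null(rownames(params)))
    rownames(params) <- sprintf("S%02d", seq_len(nrow(params)))
  tidy <- data.frame(
    subject = rep(rownames(params), each = ncol(params)),
    parameter = rep(colnames(params), nrow(params)),
    value = as.numeric(t(params)))
  if (!is.null(csv_path)) utils::write.csv(tidy, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(apply(params, 1, as.list), json_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tidy)
}
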