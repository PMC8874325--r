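## Plain-text readers/writers for the sensor formats.

#' Write an inertial stream as tidy CSV
#'
#' Columns: time_s, acc_ap, acc_si, acc_ml, gyro_sag, gyro_front,
#' gyro_trans.
#'
#' @param imu an [imu_stream()].
#' @param path output file.
#' @export
write_imu_csv <- function(imu, path) {
  d <- data.frame(time_s = imu$time,
                  acc_ap = imu$acc[, 1L], acc_si = imu$acc[, 2L],
                  acc_ml = imu$acc[, 3L],
                  gyro_sag = imu$gyro[, 1L], gyro_front = imu$gyro[, 2L],
                  gyro_trans = imu$gyro[, 3L])
  utils::write.csv(d, path, row.names = FALSE)
}

#' Read an inertial stream CSV written by [write_imu_csv()]
#'
#' @param path input file.
#' @param fs sampling rate (Hz); inferred from the time column when NULL.
#' @return an [imu_stream()].
#' @export
read_imu_csv <- function(path, fs = NULL) {
  d <- utils::read.csv(path)
  if (is.null(fs)) fs <- 1 / stats::median(diff(d$time_s))
  imu_stream(d$time_s,
             acc = cbind(AP = d$acc_ap, SI = d$acc_si, ML = d$acc_ml),
             gyro = cbind(sagittal = d$gyro_sag, frontal = d$gyro_front,
                          transverse = d$gyro_trans),
             fs = fs)
}

#' Write an ECG stream as CSV (time_s, mv)
#' @param ecg an `ecg_stream`.
#' @param path output file.
#' @export
write_ecg_csv <- function(ecg, path) {
  utils::write.csv(data.frame(time_s = ecg$time, mv = ecg$mv), path,
                   row.names = FALSE)
}

#' Read an ECG stream CSV
#' @param path input file.
#' @return an `ecg_stream`.
#' @export
read_ecg_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(list(time = d$time_s, mv = d$mv,
                 fs = 1 / stats::median(diff(d$time_s))),
            class = "ecg_stream")
}

#' Write a GNSS track as CSV (time_s, lat, lon, ele_m, speed_mps)
#' @param track a [generate_gnss_track()] result.
#' @param path output file.
#' @export
write_gnss_csv <- function(track, path) {
  utils::write.csv(data.frame(time_s = track$time, lat = track$lat,
                              lon = track$lon, ele_m = track$ele,
                              speed_mps = track$speed),
                   path, row.names = FALSE)
}

#' Read a GNSS track CSV
#' @param path input file.
#' @return a `gnss_track` data.frame.
#' @export
read_gnss_csv <- function(path) {
  d <- utils::read.csv(path)
  track <- data.frame(time = d$time_s, lat = d$lat, lon = d$lon,
                      ele = d$ele_m, speed = d$speed_mps)
  attr(track, "fs") <- 1 / stats::median(diff(track$time))
  class(track) <- c("gnss_track", "data.frame")
  track
}

#' Write a GNSS track as GPX 1.1
#'
#' One track with one segment; elevation in <ele>, per-point speed as a
#' GPX extension.
#'
#' @param track a [generate_gnss_track()] result.
#' @param path output file.
#' @param t0 POSIXct origin for the absolute timestamps.
#' @export
write_gpx <- function(track, path, t0 = as.POSIXct("2019-10-27 09:00:00",
                                                   tz = "UTC")) {
  ## the document is assembled as text (vectorised) because per-node
  ## insertion is too slow for 10 Hz race-length tracks
  stamps <- format(t0 + track$time, "%Y-%m-%dT%H:%M:%OS2Z", tz = "UTC")
  pts <- sprintf(paste0(
    '<trkpt lat="%.8f" lon="%.8f"><ele>%.3f</ele><time>%s</time>',
    '<extensions><speed>%.4f</speed></extensions></trkpt>'),
    track$lat, track$lon, track$ele, stamps, track$speed)
  txt <- c('<?xml version="1.0" encoding="UTF-8"?>',
           paste0('<gpx version="1.1" creator="runfatigue" ',
                  'xmlns="http://www.topografix.com/GPX/1/1">'),
           "<trk><trkseg>", pts, "</trkseg></trk></gpx>")
  writeLines(txt, path)
}

#' Read a GPX 1.1 track
#'
#' @param path input file.
#' @return a `gnss_track` data.frame (time in seconds from the first
#'   point).
#' @export
read_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  ele <- as.numeric(xml2::xml_text(xml2::xml_find_first(pts, "./ele")))
  tim <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
  tim <- as.POSIXct(tim, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  sp <- suppressWarnings(as.numeric(
    xml2::xml_text(xml2::xml_find_first(pts, "./extensions/speed"))))
  track <- data.frame(time = as.numeric(difftime(tim, tim[1L], units = "secs")),
                      lat = lat, lon = lon, ele = ele, speed = sp)
  attr(track, "fs") <- 1 / stats::median(diff(track$time))
  class(track) <- c("gnss_track", "data.frame")
  track
}

#' Write / read a rating-of-fatigue log CSV (time_s, rof)
#' @param rof data.frame(time, rof).
#' @param path file path.
#' @export
write_rof_csv <- function(rof, path) {
  utils::write.csv(data.frame(time_s = rof$time, rof = rof$rof), path,
                   row.names = FALSE)
}

#' @rdname write_rof_csv
#' @export
read_rof_csv <- function(path) {
  d <- utils::read.csv(path)
  data.frame(time = d$time_s, rof = as.integer(d$rof))
}

#' Write ground truth as JSON
#' @param truth the `truth` component of [simulate_subject()].
#' @param path output file.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
}
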