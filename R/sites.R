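#' Canonical sensor sites
#'
#' The eight body-worn sensor sites used throughout the package, in the
#' canonical order in which their channels are stacked: chest (sternum),
#' lower back (third lumbar vertebra), left/right wrist, left/right thigh,
#' left/right ankle.
#'
#' @return Character vector of the 8 site names, in canonical order.
#' @export
#' @examples
#' sensor_sites()
sensor_sites <- function() {
  c("chest", "lower_back", "left_wrist", "right_wrist",
    "left_thigh", "right_thigh", "left_ankle", "right_ankle")
}

#' Per-site channel names
#'
#' Each sensor records three acceleration axes (X anterior-posterior,
#' Y mediolateral, Z vertical, in g) and three angular-velocity axes
#' (roll about X, pitch about Y, yaw about Z, in deg/s).
#'
#' @return Character vector of the 6 channel names, in canonical order.
#' @export
sensor_channels <- function() {
  c("acc_x", "acc_y", "acc_z", "gyr_roll", "gyr_pitch", "gyr_yaw")
}

#' Canonical 48-channel column names
#'
#' Site-major stacking: the 6 channels of the first site, then the 6 channels
#' of the second site, and so on. This is the column order of every gait-cycle
#' window and model input matrix in the package.
#'
#' @return Character vector of length 48, `<site>.<channel>`.
#' @export
channel_names <- function() {
  as.vector(t(outer(sensor_sites(), sensor_channels(), paste, sep = ".")))
}

#' Column indices of a site's channels in the 48-channel layout
#'
#' @param sites character vector of site names.
#' @return Integer vector of column indices (6 per site).
#' @export
site_columns <- function(sites) {
  sites <- match.arg(sites, sensor_sites(), several.ok = TRUE)
  idx <- match(sites, sensor_sites())
  as.vector(vapply(idx, function(i) (i - 1L) * 6L + 1:6, integer(6)))
}

#' Column indices of one modality/axis channel group
#'
#' A channel group is one of the 6 modality-axis combinations (acc X/Y/Z,
#' gyro roll/pitch/yaw) taken across all 8 sensors; normalization operates
#' per group.
#'
#' @param channel one of the names returned by [sensor_channels()].
#' @return Integer vector of 8 column indices.
#' @export
channel_group_columns <- function(channel) {
  j <- match(match.arg(channel, sensor_channels()), sensor_channels())
  seq(j, by = 6L, length.out = 8L)
}

# sensor hardware range (Xsens DOT class device): |acc| <= 16 g, |gyro| <= 2000 deg/s
.ACC_RANGE_G <- 16
.GYR_RANGE_DPS <- 2000
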