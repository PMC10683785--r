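#' Platform motion profile
#'
#' Describes the support-surface translation kinematics: a rapid translation
#' of `target_displacement` metres with peak acceleration `peak_acceleration`
#' and a requested peak velocity. The stock protocol uses 20 cm displacement,
#' 100 cm/s velocity and 0.2 g acceleration. That triple is not jointly
#' realizable by an accelerate-cruise-decelerate profile (reaching 1 m/s at
#' 0.2 g alone covers ~25.5 cm), so the profile honours acceleration and
#' displacement exactly and caps the achieved peak velocity at
#' `min(target_peak_velocity, sqrt(a * d))`, i.e. a triangular velocity
#' profile when the cap binds. A warning is raised at construction when the
#' cap binds; downstream analysis depends only on acceleration onset and
#' displacement, not on peak velocity.
#'
#' @param sampling_rate Accelerometer sampling rate in Hz.
#' @param peak_acceleration Peak platform acceleration, m/s^2 (0.2 g default).
#' @param target_displacement Translation distance, m.
#' @param target_peak_velocity Requested peak velocity, m/s.
#' @return A list of class `platform_profile`, including the achieved
#'   `peak_velocity` after the feasibility rule.
#' @export
platform_profile <- function(sampling_rate = 150,
                             peak_acceleration = 0.2 * 9.81,
                             target_displacement = 0.20,
                             target_peak_velocity = 1.0) {
  stopifnot(sampling_rate > 0, peak_acceleration > 0,
            target_displacement >= 0, target_peak_velocity > 0)
  v_cap <- sqrt(peak_acceleration * target_displacement)
  v_peak <- min(target_peak_velocity, v_cap)
  if (v_cap < target_peak_velocity && target_displacement > 0) {
    warning(sprintf(paste0(
      "requested peak velocity %.3g m/s is not reachable at %.3g m/s^2 over ",
      "%.3g m; using triangular velocity profile with peak %.3g m/s"),
      target_peak_velocity, peak_acceleration, target_displacement, v_peak),
      call. = FALSE)
  }
  structure(list(sampling_rate = sampling_rate,
                 peak_acceleration = peak_acceleration,
                 target_displacement = target_displacement,
                 target_peak_velocity = target_peak_velocity,
                 peak_velocity = v_peak),
            class = "platform_profile")
}

#' Simulate a platform-translation acceleration trace
#'
#' Emits the sampled platform acceleration for one translation, starting at
#' motion onset (time zero). The continuous-time design is the trapezoidal
#' velocity family: accelerate at `peak_acceleration`, cruise at the achieved
#' peak velocity (the cruise phase vanishes when the feasibility cap binds,
#' giving a triangular velocity profile), then decelerate. The sampled trace
#' is amplitude-rescaled by a sub-percent factor so that cumulative-trapezoid
#' double integration of the emitted samples reproduces `target_displacement`
#' to machine precision; this pins the discretized trace, which is what onset
#' detection and any re-integration consume, to the nominal kinematics.
#'
#' Sign convention: posterior translations are negative, anterior positive.
#'
#' @param profile A [platform_profile].
#' @param direction `"posterior"` or `"anterior"`.
#' @return Numeric vector of acceleration samples (m/s^2) at
#'   `profile$sampling_rate`, zero-valued after motion end.
#' @examples
#' a <- simulate_platform_motion(platform_profile(), "posterior")
#' abs(platform_displacement(a, 150))  # 0.20 m
#' @export
simulate_platform_motion <- function(profile, direction = c("posterior", "anterior")) {
  stopifnot(inherits(profile, "platform_profile"))
  direction <- match.arg(direction)
  d <- profile$target_displacement
  if (d == 0) return(numeric(2L))
  a <- profile$peak_acceleration
  vp <- profile$peak_velocity
  t_acc <- vp / a
  t_cruise <- max(0, (d - vp^2 / a) / vp)
  t_total <- 2 * t_acc + t_cruise
  fs <- profile$sampling_rate
  tt <- seq(0, ceiling(t_total * fs) / fs + 1 / fs, by = 1 / fs)
  pos <- as.numeric(tt < t_acc) * a
  neg <- -as.numeric(tt >= t_acc + t_cruise & tt < t_total) * a
  # Rescale the two phases (sub-percent) so the sampled trace ends with
  # exactly zero velocity and exactly the nominal displacement under
  # trapezoid integration -- the discretized trace is what detection and
  # re-integration consume.
  vp <- cumtrapz(pos, 1 / fs); vn <- cumtrapz(neg, 1 / fs)
  xp <- cumtrapz(vp, 1 / fs); xn <- cumtrapz(vn, 1 / fs)
  k <- length(tt)
  s <- solve(matrix(c(vp[k], vn[k], xp[k], xn[k]), 2, 2, byrow = TRUE),
             c(0, d))
  acc <- s[1] * pos + s[2] * neg
  if (direction == "posterior") acc <- -acc
  acc
}

#' Displacement and peak velocity from an acceleration trace
#'
#' Double (respectively single) cumulative-trapezoid integration of a sampled
#' acceleration trace.
#'
#' @param acceleration Numeric acceleration samples, m/s^2.
#' @param sampling_rate Sampling rate, Hz.
#' @return `platform_displacement`: net displacement in metres;
#'   `platform_peak_velocity`: maximum absolute velocity in m/s.
#' @export
platform_displacement <- function(acceleration, sampling_rate) {
  v <- cumtrapz(acceleration, 1 / sampling_rate)
  x <- cumtrapz(v, 1 / sampling_rate)
  x[length(x)]
}

#' @rdname platform_displacement
#' @export
platform_peak_velocity <- function(acceleration, sampling_rate) {
  max(abs(cumtrapz(acceleration, 1 / sampling_rate)))
}

# cumulative trapezoid with uniform step
cumtrapz <- function(x, dx) {
  if (length(x) < 2L) return(numeric(length(x)))
  dx * (cumsum(x) - (x + x[1]) / 2)
}
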