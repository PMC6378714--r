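#' Specification of a synthetic plate video
#'
#' Describes a backlit plate recording: dark worm-shaped blobs (capsules)
#' performing a persistent random walk over a static bright background, with
#' additive Gaussian pixel noise, imaged at 1 Hz.
#'
#' @param n_frames Number of frames.
#' @param height,width Frame size in pixels.
#' @param n_worms Number of animals.
#' @param worm_length_px,worm_width_px Capsule dimensions in pixels.
#' @param step_sigma Per-frame displacement (pixels/frame) of the persistent
#'   walk; agitated animals move roughly their body length over the
#'   15-frame background window, which is what makes movement-based
#'   detection work.
#' @param turn_sigma SD (radians/frame) of heading changes.
#' @param background_level,worm_level Background and worm intensities
#'   (arbitrary units); worms must be darker than the background.
#' @param noise_sigma SD of additive Gaussian pixel noise.
#' @param seed Integer seed.
#' @return A list of class `video_spec`.
#' @export
video_spec <- function(n_frames = 25, height = 320, width = 320,
                       n_worms = 10, worm_length_px = 12, worm_width_px = 3,
                       step_sigma = 3, turn_sigma = 0.25,
                       background_level = 200, worm_level = 60,
                       noise_sigma = 4, seed = 1) {
  stopifnot(
    n_frames >= 1, height >= 32, width >= 32, n_worms >= 0,
    worm_level < background_level,
    worm_length_px >= worm_width_px, worm_width_px >= 1
  )
  worm_area <- worm_length_px * worm_width_px
  if (n_worms * worm_area > 0.5 * height * width) {
    stop("capacity error: ", n_worms, " worms would cover more than half the arena")
  }
  structure(as.list(environment()), class = "video_spec")
}

## linear pixel indices (column-major, H rows) covered by a capsule
## (segment of half-length hl, radius r) centered at (cx, cy)
capsule_pixels <- function(cx, cy, theta, hl, r, H, W) {
  pad <- ceiling(hl + r + 1)
  x0 <- max(1L, floor(cx - pad)); x1 <- min(W, ceiling(cx + pad))
  y0 <- max(1L, floor(cy - pad)); y1 <- min(H, ceiling(cy + pad))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys)) - cx
  py <- rep(ys, times = length(xs)) - cy
  ## distance from pixel to the central segment
  ux <- cos(theta); uy <- sin(theta)
  t <- pmin(pmax(px * ux + py * uy, -hl), hl)
  d2 <- (px - t * ux)^2 + (py - t * uy)^2
  hit <- which(d2 <= r^2)
  iy <- rep(ys, times = length(xs))[hit]
  ix <- rep(xs, each = length(ys))[hit]
  (ix - 1L) * H + iy
}

## paint one capsule into a frame matrix (used directly in tests)
paint_capsule <- function(frame, cx, cy, theta, hl, r, level) {
  idx <- capsule_pixels(cx, cy, theta, hl, r, nrow(frame), ncol(frame))
  frame[idx] <- level
  frame
}

#' Generate a synthetic plate video with known animal positions
#'
#' Renders `n_worms` dark capsules on a bright background, each performing a
#' persistent random walk (constant speed `step_sigma` pixels/frame, heading
#' diffusing with SD `turn_sigma`, reflecting at the arena walls), and adds
#' Gaussian pixel noise. The ground truth needed by counting and tracking
#' tests is returned alongside the frames.
#'
#' @param spec A [video_spec()].
#' @return A list with:
#' \describe{
#'   \item{frames}{numeric array `height x width x n_frames`}
#'   \item{timestamps}{seconds, 1 Hz from 0}
#'   \item{true_count}{`n_worms`}
#'   \item{truth}{data frame `frame, animal, x, y, theta` of true positions}
#' }
#' @export
gen_video <- function(spec = video_spec()) {
  stopifnot(inherits(spec, "video_spec"))
  set.seed(child_seed(spec$seed, "video"))
  H <- spec$height; W <- spec$width; Tn <- spec$n_frames; n <- spec$n_worms
  margin <- spec$worm_length_px
  hl <- max(0, spec$worm_length_px / 2 - spec$worm_width_px / 2)
  r <- spec$worm_width_px / 2

  x <- stats::runif(n, margin, W - margin)
  y <- stats::runif(n, margin, H - margin)
  theta <- stats::runif(n, 0, 2 * pi)

  frames <- array(
    stats::rnorm(H * W * Tn, spec$background_level, spec$noise_sigma),
    dim = c(H, W, Tn)
  )
  truth <- vector("list", Tn)
  npix <- H * W
  drop_level <- spec$worm_level - spec$background_level
  for (f in seq_len(Tn)) {
    if (n > 0) {
      idx <- unique(unlist(lapply(seq_len(n), function(k) {
        capsule_pixels(x[k], y[k], theta[k], hl, r, H, W)
      })))
      frames[(f - 1L) * npix + idx] <- frames[(f - 1L) * npix + idx] + drop_level
    }
    truth[[f]] <- if (n > 0) {
      data.frame(frame = f, animal = seq_len(n), x = x, y = y, theta = theta)
    } else {
      data.frame(frame = integer(0), animal = integer(0),
                 x = numeric(0), y = numeric(0), theta = numeric(0))
    }
    ## advance the walk
    if (n > 0) {
      theta <- theta + stats::rnorm(n, 0, spec$turn_sigma)
      x <- x + spec$step_sigma * cos(theta)
      y <- y + spec$step_sigma * sin(theta)
      ## reflect at walls
      for (k in seq_len(n)) {
        if (x[k] < margin || x[k] > W - margin) {
          theta[k] <- pi - theta[k]
          x[k] <- min(max(x[k], margin), W - margin)
        }
        if (y[k] < margin || y[k] > H - margin) {
          theta[k] <- -theta[k]
          y[k] <- min(max(y[k], margin), H - margin)
        }
      }
    }
  }
  list(
    frames = frames,
    timestamps = as.numeric(seq_len(Tn) - 1),
    true_count = n,
    truth = do.call(rbind, truth)
  )
}

#' Simulate logistic growth trajectories for a cohort of strains
#'
#' Emulates long-term developmental imaging: per-animal projected area grows
#' logistically, `A(t) = K / (1 + exp(-rate (t - t_mid)))`, with per-animal
#' variation in asymptote and midpoint and multiplicative observation noise;
#' length is proportional to the square root of area (fixed shape factor), as
#' for an elongating animal of roughly constant aspect ratio.
#'
#' @param strains Data frame with columns `name`, `growth_rate` (per hour)
#'   and `asymptote` (px^2); one row per strain.
#' @param n_animals Animals per strain.
#' @param obs_noise SD of multiplicative log-normal observation noise
#'   (0 = noiseless).
#' @param t_max Recording length in seconds (default 65 h).
#' @param dt Sampling interval in seconds.
#' @param t_mid Mean logistic midpoint in seconds (default 30 h).
#' @param animal_cv Between-animal coefficient of variation of the asymptote
#'   and midpoint.
#' @param shape_factor Length = `shape_factor * sqrt(area)`.
#' @param seed Integer seed.
#' @return A data frame `strain, animal, t, area, length`; `animal` is unique
#'   within strain.
#' @export
gen_growth_cohort <- function(strains, n_animals = 40, obs_noise = 0.05,
                              t_max = 65 * 3600, dt = 60,
                              t_mid = 30 * 3600, animal_cv = 0.05,
                              shape_factor = 3.5, seed = 1) {
  stopifnot(all(c("name", "growth_rate", "asymptote") %in% names(strains)))
  set.seed(child_seed(seed, "growth"))
  tt <- seq(0, t_max, by = dt)
  out <- vector("list", nrow(strains) * n_animals)
  idx <- 0L
  for (s in seq_len(nrow(strains))) {
    rate <- strains$growth_rate[s] / 3600 # per second
    for (a in seq_len(n_animals)) {
      K <- strains$asymptote[s] * exp(stats::rnorm(1, 0, animal_cv))
      tm <- t_mid * exp(stats::rnorm(1, 0, animal_cv))
      area <- K / (1 + exp(-rate * (tt - tm)))
      if (obs_noise > 0) {
        area <- area * exp(stats::rnorm(length(tt), 0, obs_noise))
      }
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        strain = strains$name[s], animal = a, t = tt,
        area = area, length = shape_factor * sqrt(area),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Simulate a brood-size table
#'
#' Draws daily progeny counts over three 24-h laying intervals from a
#' negative-binomial model (variance `mu + phi mu^2`; `overdispersion = 0`
#' recovers Poisson), splitting each strain's mean brood across days with the
#' typical early-peaked laying profile, and flags animals as censored
#' (crawled off the plate) with probability `censor_prob`.
#'
#' @param strains Data frame with columns `name` and `mean_brood`.
#' @param n_animals Animals per strain.
#' @param overdispersion Negative-binomial dispersion `phi` (>= 0).
#' @param censor_prob Per-animal probability of censoring.
#' @param day_split Fractions of the mean brood laid on days 1-3.
#' @param seed Integer seed.
#' @return A data frame `strain, animal, day1, day2, day3, censored`.
#' @export
gen_brood <- function(strains, n_animals = 15, overdispersion = 0.05,
                      censor_prob = 0.1, day_split = c(0.45, 0.40, 0.15),
                      seed = 1) {
  stopifnot(
    all(c("name", "mean_brood") %in% names(strains)),
    overdispersion >= 0, abs(sum(day_split) - 1) < 1e-8
  )
  set.seed(child_seed(seed, "brood"))
  if (n_animals == 0 || nrow(strains) == 0) {
    return(data.frame(
      strain = character(0), animal = integer(0), day1 = integer(0),
      day2 = integer(0), day3 = integer(0), censored = logical(0)
    ))
  }
  draw_day <- function(mu, n) {
    if (overdispersion == 0) {
      stats::rpois(n, mu)
    } else {
      stats::rnbinom(n, size = 1 / overdispersion, mu = mu)
    }
  }
  out <- vector("list", nrow(strains))
  for (s in seq_len(nrow(strains))) {
    mu <- strains$mean_brood[s] * day_split
    out[[s]] <- data.frame(
      strain = strains$name[s], animal = seq_len(n_animals),
      day1 = draw_day(mu[1], n_animals),
      day2 = draw_day(mu[2], n_animals),
      day3 = draw_day(mu[3], n_animals),
      censored = stats::runif(n_animals) < censor_prob,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
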