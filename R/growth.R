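#' Windowed population growth curve
#'
#' Implements the windowed growth-curve estimator used for long-term plate
#' recordings: each animal's attribute is averaged within consecutive
#' non-overlapping windows of length `w` (per-animal mean of the samples
#' available in the window, `A_n(s)`); the population value in a window is
#' the unweighted ensemble mean across animals contributing to it,
#' `A(s) = <A_n(s)>`, with the standard error of the mean across animals.
#'
#' @param trajectories Data frame with columns `animal`, `t` (seconds) and
#'   the chosen `value` column (from [link_tracks()] joined with detection
#'   attributes, or [gen_growth_cohort()]).
#' @param w Window length in seconds, default 1200 (20 min).
#' @param value Attribute column to average, default `"area"`.
#' @param t_range Recording interval covered by the windows; defaults to
#'   the data range.
#' @return An object of class `growth_curve`: a data frame `s, mean, sem,
#'   n_animals` (window start times `s`; windows with no animal are `NA`)
#'   with the per-animal window means in `attr(, "per_animal")` and the
#'   window length in `attr(, "w")`.
#' @export
growth_curve <- function(trajectories, w = 1200, value = "area",
                         t_range = NULL) {
  stopifnot(all(c("animal", "t", value) %in% names(trajectories)))
  if (nrow(trajectories) == 0) stop("no trajectory samples")
  if (is.null(t_range)) t_range <- range(trajectories$t)
  breaks <- seq(t_range[1], t_range[2] + w, by = w)
  s <- breaks[-length(breaks)]
  win <- findInterval(trajectories$t, breaks,
    rightmost.closed = FALSE, left.open = FALSE
  )
  ok <- win >= 1 & win <= length(s)
  animals <- sort(unique(trajectories$animal))
  per <- matrix(NA_real_, length(animals), length(s),
    dimnames = list(as.character(animals), NULL)
  )
  agg <- tapply(
    trajectories[[value]][ok],
    list(
      factor(trajectories$animal[ok], levels = animals),
      factor(win[ok], levels = seq_along(s))
    ),
    mean
  )
  per[] <- agg
  n <- colSums(!is.na(per))
  mu <- ifelse(n > 0, colMeans(per, na.rm = TRUE), NA_real_)
  sem <- vapply(seq_along(s), function(j) {
    v <- per[!is.na(per[, j]), j]
    if (length(v) >= 2) sd(v) / sqrt(length(v)) else if (length(v) == 1) 0 else NA_real_
  }, numeric(1))
  out <- data.frame(s = s, mean = mu, sem = sem, n_animals = n)
  structure(out,
    class = c("growth_curve", "data.frame"),
    per_animal = per, w = w, value = value
  )
}

#' Combine growth curves that match a standard curve
#'
#' Reproduces the presentation rule for cohort growth curves: any strain
#' whose curve lies within the confidence band of the designated standard
#' curve at every shared window is pooled into a combined ensemble (reported
#' as the mean across member strains with the between-strain SEM); the rest
#' are reported individually.
#'
#' @param curves Named list of `growth_curve` objects on the same window
#'   grid, including the standard.
#' @param standard_name Name of the standard curve in `curves`.
#' @param alpha Band level, default 0.01 (a 99% confidence band,
#'   `mean +/- z(1 - alpha/2) * SEM`).
#' @param criterion `"pointwise"` (default: inside the standard's band at
#'   every window) or `"ztest"` (per-window two-sample z test on the two
#'   curves' SEMs, Bonferroni-corrected across windows; a strain combines
#'   when no window rejects).
#' @return A list with `combined` (member names, always including the
#'   standard), `individual` (the rest), and `combined_curve` (data frame
#'   `s, mean, sem` across member strains).
#' @export
combine_curves <- function(curves, standard_name, alpha = 0.01,
                           criterion = c("pointwise", "ztest")) {
  criterion <- match.arg(criterion)
  stopifnot(standard_name %in% names(curves))
  std <- curves[[standard_name]]
  z <- stats::qnorm(1 - alpha / 2)
  others <- setdiff(names(curves), standard_name)
  ok <- logical(length(others))
  names(ok) <- others
  for (nm in others) {
    cv <- curves[[nm]]
    if (nrow(cv) != nrow(std) || any(abs(cv$s - std$s) > 1e-9)) {
      stop("curve '", nm, "' is not on the standard's window grid")
    }
    shared <- which(!is.na(cv$mean) & !is.na(std$mean))
    if (criterion == "pointwise") {
      ok[nm] <- all(
        abs(cv$mean[shared] - std$mean[shared]) <= z * std$sem[shared]
      )
    } else {
      se <- sqrt(cv$sem[shared]^2 + std$sem[shared]^2)
      pvals <- 2 * stats::pnorm(-abs(cv$mean[shared] - std$mean[shared]) / se)
      ok[nm] <- all(pmin(1, pvals * length(shared)) > alpha)
    }
  }
  members <- c(standard_name, others[ok])
  mats <- vapply(members, function(nm) curves[[nm]]$mean, std$mean)
  if (is.null(dim(mats))) mats <- matrix(mats, nrow = 1)
  k <- rowSums(!is.na(mats))
  combined_curve <- data.frame(
    s = std$s,
    mean = rowMeans(mats, na.rm = TRUE),
    sem = apply(mats, 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r) >= 2) sd(r) / sqrt(length(r)) else 0
    }),
    n_strains = k
  )
  list(
    combined = members,
    individual = others[!ok],
    combined_curve = combined_curve
  )
}

#' Attribute ratio to control at a given time
#'
#' For each strain, the windowed mean of an attribute (length by default) in
#' the window containing time `t`, divided by the control strain's value in
#' that window. The 95% confidence interval comes from the per-animal
#' ratios (each animal's window mean divided by the control mean) via the t
#' distribution.
#'
#' @param curves Named list of `growth_curve` objects (built on the
#'   attribute of interest) on a shared window grid.
#' @param t Time (seconds) at which to compare, default 50 h.
#' @param control_name Name of the control curve.
#' @param conf_level Confidence level, default 0.95.
#' @return Data frame `strain, ratio, ci_low, ci_high, n_animals`.
#' @export
length_ratio_at <- function(curves, t = 50 * 3600, control_name,
                            conf_level = 0.95) {
  stopifnot(control_name %in% names(curves))
  ctrl <- curves[[control_name]]
  j <- findInterval(t, c(ctrl$s, ctrl$s[length(ctrl$s)] + attr(ctrl, "w")))
  if (j < 1 || j > nrow(ctrl)) stop("time ", t, " outside the window grid")
  ref <- ctrl$mean[j]
  if (!is.finite(ref) || ref == 0) stop("control has no value at time ", t)
  rows <- lapply(names(curves), function(nm) {
    per <- attr(curves[[nm]], "per_animal")[, j]
    per <- per[!is.na(per)]
    ratios <- per / ref
    n <- length(ratios)
    if (n >= 2 && stats::sd(ratios) > 0) {
      ci <- stats::t.test(ratios, conf.level = conf_level)$conf.int
    } else if (n >= 2) {
      ci <- rep(mean(ratios), 2) # zero spread: degenerate interval
    } else {
      ci <- c(NA_real_, NA_real_)
    }
    data.frame(
      strain = nm, ratio = mean(ratios), ci_low = ci[1], ci_high = ci[2],
      n_animals = n, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
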