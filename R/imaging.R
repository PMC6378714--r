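#' Maximum-projection background image
#'
#' Pixelwise maximum over a stack of frames. With dark animals on a bright
#' backlit field, any pixel an animal vacates at least once during the stack
#' takes its bright background value, so moving animals are erased.
#'
#' @param frames Numeric array `H x W x T` (or a matrix for T = 1).
#' @return An `H x W` matrix.
#' @export
max_projection <- function(frames) {
  if (is.matrix(frames)) return(frames)
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 1)
  out <- frames[, , 1]
  for (f in seq_len(dim(frames)[3])[-1]) out <- pmax(out, frames[, , f])
  out
}

#' Label connected components of a binary mask
#'
#' 8-connected labeling (default), built on `EBImage::bwlabel` (4-connected)
#' followed by a union of 4-connected labels that touch diagonally.
#'
#' @param mask Logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (connectivity == 4 || nlab <= 1) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  ## diagonal neighbor label pairs
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1] # down-right
  a2 <- lab[-H, -1]; b2 <- lab[-1, -W] # down-left
  pairs <- rbind(
    cbind(as.vector(a1), as.vector(b1)),
    cbind(as.vector(a2), as.vector(b2))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
    drop = FALSE
  ]
  if (nrow(pairs) == 0) return(lab)
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nlab - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  ## renumber components consecutively
  new_id <- match(memb, sort(unique(memb)))
  out <- lab
  out[lab > 0] <- new_id[lab[lab > 0]]
  out
}

#' Otsu threshold of a numeric image
#'
#' Thin wrapper around `EBImage::otsu` operating on arbitrary intensity
#' ranges (EBImage expects `[0, 1]`).
#'
#' @param x Numeric matrix or vector of intensities.
#' @param levels Histogram bins, default 256.
#' @return The threshold on the scale of `x`.
#' @export
otsu_threshold <- function(x, levels = 256) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) return(rng[1])
  xn <- (x - rng[1]) / diff(rng)
  if (!is.matrix(xn)) xn <- matrix(xn, nrow = 1)
  th <- EBImage::otsu(EBImage::Image(xn), levels = levels)
  rng[1] + th * diff(rng)
}

#' Difference image between a frame and its background
#' @noRd
difference_image <- function(frame, background, mode = c("clip", "abs")) {
  mode <- match.arg(mode)
  if (!all(dim(frame) == dim(background))) {
    stop("frame and background dimensions differ")
  }
  d <- background - frame
  if (mode == "clip") pmax(d, 0) else abs(d)
}

#' Count animals in one frame by movement
#'
#' Computes the difference image `background - frame` (clipped at zero: dark
#' animals on a bright field), thresholds it, labels connected components
#' (8-connectivity) and counts components of at least `min_area` pixels.
#'
#' @param frame,background `H x W` matrices of equal shape.
#' @param diff_threshold Threshold on the difference image; `NULL` uses the
#'   Otsu threshold of this frame's difference image.
#' @param min_area Minimum component area (px^2), default 10.
#' @param mode `"clip"` (default) or `"abs"` for the difference definition.
#' @return Integer count.
#' @export
count_frame <- function(frame, background, diff_threshold = NULL,
                        min_area = 10, mode = c("clip", "abs")) {
  d <- difference_image(frame, background, match.arg(mode))
  if (is.null(diff_threshold)) diff_threshold <- otsu_threshold(d)
  lab <- label_components(d > diff_threshold)
  if (max(lab) == 0) return(0L)
  areas <- tabulate(lab[lab > 0])
  sum(areas >= min_area)
}

#' Count animals on a plate from a short video
#'
#' The brood-size counting procedure: the background is the maximum
#' projection of the first `n_background` frames (default 15, imaged at
#' 1 Hz after agitating the plate); animals are then detected by movement on
#' the next `n_count` frames (default 10) via difference images, and the
#' final count is the statistical mode of the per-frame counts, ties broken
#' to the larger count.
#'
#' @param video A `FrameStack` list with `frames` (`H x W x T` array), e.g.
#'   from [gen_video()], or the bare array.
#' @param n_background,n_count Frames used for the background / counting.
#' @param diff_threshold Fixed difference threshold; `NULL` (default) uses
#'   the Otsu threshold of the pooled difference images of the counting
#'   frames.
#' @param min_area Minimum component area (px^2), default 10.
#' @param background_frames,count_frames Optional explicit frame indices
#'   overriding the first-`n_background` / next-`n_count` policy.
#' @return Integer count.
#' @export
count_plate <- function(video, n_background = 15, n_count = 10,
                        diff_threshold = NULL, min_area = 10,
                        background_frames = NULL, count_frames = NULL) {
  frames <- if (is.list(video)) video$frames else video
  Tn <- dim(frames)[3]
  if (is.null(background_frames)) background_frames <- seq_len(n_background)
  if (is.null(count_frames)) {
    count_frames <- seq(max(background_frames) + 1, length.out = n_count)
  }
  need <- max(count_frames)
  if (Tn < need) {
    stop("video has ", Tn, " frames; at least ", need,
         " required (", length(background_frames), " background + ",
         length(count_frames), " counting)")
  }
  background <- max_projection(frames[, , background_frames, drop = FALSE])
  if (is.null(diff_threshold)) {
    pooled <- vapply(
      count_frames,
      function(f) difference_image(frames[, , f], background),
      background
    )
    diff_threshold <- otsu_threshold(pooled)
  }
  counts <- vapply(
    count_frames,
    function(f) {
      count_frame(frames[, , f], background,
        diff_threshold = diff_threshold, min_area = min_area
      )
    },
    integer(1)
  )
  mode_count(counts)
}

## statistical mode, ties broken to the larger value
mode_count <- function(counts) {
  tab <- table(counts)
  modes <- as.integer(names(tab)[tab == max(tab)])
  max(modes)
}

#' Detect animals in every frame
#'
#' Runs the same difference/threshold/label pipeline as [count_frame()] on
#' each frame, emitting per-component centroid, area and length. The
#' background is either static (maximum projection of `background_frames`)
#' or rolling (maximum projection of the `bg_window` frames preceding each
#' frame).
#'
#' @param video `FrameStack` list or `H x W x T` array.
#' @param background_frames Frames for the static background (default the
#'   first 15).
#' @param policy `"static"` (default) or `"rolling"`.
#' @param bg_window Window length for the rolling background.
#' @param diff_threshold Fixed threshold; `NULL` pools the detection frames'
#'   difference images and applies Otsu once.
#' @param min_area Minimum component area (px^2).
#' @param frames_to_scan Frames to detect on (default: all frames after the
#'   static background window, or all frames for rolling).
#' @return Data frame `frame, t, x, y, area, length`, one row per detection.
#'   Length is the extent of the component along its principal axis.
#' @export
detect_all <- function(video, background_frames = 1:15,
                       policy = c("static", "rolling"), bg_window = 15,
                       diff_threshold = NULL, min_area = 10,
                       frames_to_scan = NULL) {
  policy <- match.arg(policy)
  frames <- if (is.list(video)) video$frames else video
  ts <- if (is.list(video) && !is.null(video$timestamps)) {
    video$timestamps
  } else {
    seq_len(dim(frames)[3]) - 1
  }
  Tn <- dim(frames)[3]
  if (is.null(frames_to_scan)) {
    frames_to_scan <- if (policy == "static") {
      setdiff(seq_len(Tn), background_frames)
    } else {
      seq_len(Tn)[-seq_len(min(bg_window, Tn - 1))]
    }
  }
  static_bg <- if (policy == "static") {
    max_projection(frames[, , background_frames, drop = FALSE])
  }
  get_bg <- function(f) {
    if (policy == "static") return(static_bg)
    lo <- max(1, f - bg_window)
    max_projection(frames[, , lo:max(lo, f - 1), drop = FALSE])
  }
  if (is.null(diff_threshold)) {
    pooled <- vapply(
      frames_to_scan,
      function(f) difference_image(frames[, , f], get_bg(f)),
      frames[, , 1]
    )
    diff_threshold <- otsu_threshold(pooled)
  }
  rows <- lapply(frames_to_scan, function(f) {
    d <- difference_image(frames[, , f], get_bg(f))
    lab <- label_components(d > diff_threshold)
    if (max(lab) == 0) {
      return(data.frame(
        frame = integer(0), t = numeric(0), x = numeric(0),
        y = numeric(0), area = numeric(0), length = numeric(0)
      ))
    }
    comp_stats(lab, min_area, f, ts[f])
  })
  do.call(rbind, rows)
}

## centroid/area/principal-axis length per labeled component
comp_stats <- function(lab, min_area, frame, t) {
  idx <- which(lab > 0)
  labs <- lab[idx]
  areas <- tabulate(labs)
  keep <- which(areas >= min_area)
  if (length(keep) == 0) {
    return(data.frame(
      frame = integer(0), t = numeric(0), x = numeric(0),
      y = numeric(0), area = numeric(0), length = numeric(0)
    ))
  }
  ys <- (idx - 1) %% nrow(lab) + 1
  xs <- (idx - 1) %/% nrow(lab) + 1
  out <- lapply(keep, function(k) {
    sel <- labs == k
    px <- xs[sel]; py <- ys[sel]
    cx <- mean(px); cy <- mean(py)
    n <- length(px)
    if (n == 1) {
      len <- 1
    } else {
      cv <- stats::cov(cbind(px, py))
      ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
      proj <- (px - cx) * ev[1] + (py - cy) * ev[2]
      len <- diff(range(proj)) + 1
    }
    data.frame(frame = frame, t = t, x = cx, y = cy, area = n, length = len)
  })
  do.call(rbind, out)
}
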