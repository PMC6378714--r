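#' Solve the linear assignment problem
#'
#' Exact minimum-cost assignment of rows to columns of a cost matrix by the
#' Hungarian method in its shortest-augmenting-path (Jonker-Volkgenant style)
#' form, O(n^3). Rectangular matrices are handled by assigning every row
#' when `nrow <= ncol` (and symmetrically otherwise, leaving surplus
#' columns/rows unassigned).
#'
#' @param cost Numeric cost matrix; `Inf` forbids a pairing (at least one
#'   finite entry per row is required when rows must all be assigned).
#' @return A list with `assignment` (for each row, the assigned column or
#'   `NA`) and `cost` (total cost of the assignment).
#' @export
lap_solve <- function(cost) {
  cost <- as.matrix(cost)
  if (length(cost) == 0 || nrow(cost) == 0 || ncol(cost) == 0) {
    return(list(assignment = rep(NA_integer_, nrow(cost)), cost = 0))
  }
  transposed <- nrow(cost) > ncol(cost)
  if (transposed) cost <- t(cost)
  n <- nrow(cost); m <- ncol(cost)

  ## potentials u (rows), v (columns, slot m+1 = virtual column)
  u <- numeric(n)
  v <- numeric(m + 1)
  p <- integer(m + 1) # p[j] = row matched to column j (0 = free); p[m+1] = row being inserted
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(m)])
      if (length(free) == 0) stop("infeasible assignment: no admissible column")
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd]] <- j0
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      if (!is.finite(delta)) stop("infeasible assignment: all remaining costs Inf")
      usedj <- which(used)
      u[p[usedj]] <- u[p[usedj]] + delta
      v[usedj] <- v[usedj] - delta
      minv[!used[seq_len(m)]] <- minv[!used[seq_len(m)]] - delta
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1) break
    }
  }
  assignment <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j] > 0) assignment[p[j]] <- j
  total <- sum(cost[cbind(seq_len(n), assignment)])
  if (transposed) {
    back <- rep(NA_integer_, m)
    back[assignment] <- seq_len(n)
    assignment <- back
  }
  list(assignment = assignment, cost = total)
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame data association by minimum-cost linear assignment on
#' centroid distances ([lap_solve()]). Pairings farther than
#' `max_link_dist` are forbidden via dummy nodes: a detection that cannot be
#' linked starts a new trajectory, and a trajectory unmatched for more than
#' `max_gap_frames` consecutive frames is closed (so a short disappearance
#' leaves a gap rather than splitting the track).
#'
#' @param detections Data frame from [detect_all()] (`frame, t, x, y, area,
#'   length`).
#' @param max_link_dist Maximum centroid displacement (px) linkable between
#'   consecutive observations.
#' @param max_gap_frames Frames a trajectory may remain undetected before it
#'   is closed, default 0.
#' @return Data frame `animal, frame, t, x, y, area, length`, one row per
#'   detection; every input detection belongs to exactly one trajectory.
#' @export
link_tracks <- function(detections, max_link_dist = 20, max_gap_frames = 0) {
  cols <- c("frame", "t", "x", "y", "area", "length")
  missing_cols <- setdiff(c("frame", "x", "y"), names(detections))
  if (length(missing_cols)) {
    stop("detections lack columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"t" %in% names(detections)) detections$t <- detections$frame
  nr <- nrow(detections)
  if (!"area" %in% names(detections)) detections$area <- rep(NA_real_, nr)
  if (!"length" %in% names(detections)) detections$length <- rep(NA_real_, nr)
  if (nrow(detections) == 0) {
    return(cbind(data.frame(animal = integer(0)), detections[cols]))
  }

  frames <- sort(unique(detections$frame))
  next_id <- 0L
  ## active tracks: id, x, y, last frame seen
  act <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    last = integer(0))
  out_id <- integer(nrow(detections))

  for (f in frames) {
    rows <- which(detections$frame == f)
    det <- detections[rows, ]
    ## drop stale tracks
    act <- act[f - act$last <= max_gap_frames + 1L, , drop = FALSE]
    assigned <- rep(NA_integer_, nrow(det))
    if (nrow(act) > 0 && nrow(det) > 0) {
      cost <- outer(seq_len(nrow(act)), seq_len(nrow(det)),
        function(i, j) sqrt((act$x[i] - det$x[j])^2 + (act$y[i] - det$y[j])^2)
      )
      ## pad to square with dummy rows/columns at max_link_dist so that any
      ## pairing costing more than a new-track/missed-track pair is refused
      k <- max(nrow(cost), ncol(cost))
      pad <- matrix(max_link_dist, k, k)
      pad[seq_len(nrow(cost)), seq_len(ncol(cost))] <- cost
      sol <- lap_solve(pad)
      for (i in seq_len(nrow(act))) {
        j <- sol$assignment[i]
        if (!is.na(j) && j <= nrow(det) && pad[i, j] < max_link_dist) {
          assigned[j] <- i
        }
      }
    }
    for (j in seq_len(nrow(det))) {
      if (!is.na(assigned[j])) {
        i <- assigned[j]
        out_id[rows[j]] <- act$id[i]
        act$x[i] <- det$x[j]; act$y[i] <- det$y[j]; act$last[i] <- f
      } else {
        next_id <- next_id + 1L
        out_id[rows[j]] <- next_id
        act <- rbind(act, data.frame(id = next_id, x = det$x[j],
                                     y = det$y[j], last = f))
      }
    }
  }
  res <- cbind(data.frame(animal = out_id), detections[cols])
  res[order(res$animal, res$frame), , drop = FALSE]
}
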