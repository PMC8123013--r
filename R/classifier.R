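#' Extract the graph representation of one heartbeat
#'
#' All samples falling in the window from 200 ms before to 400 ms after the
#' detection point become graph nodes `(tau, value)` with `tau` relative to
#' the detection point.  Beats truncated by a record edge are flagged by
#' returning `NULL` (they are excluded from clustering).
#'
#' @param nu an [nu_signal()]
#' @param lead lead index
#' @param detection_time detection point (ms)
#' @param window window around the detection point (ms)
#' @param baseline_correct subtract the median node value, removing the
#'   beat-local baseline offset (wander) before amplitudes are compared
#' @return a `beat_graph` (list `tau`, `value`) or `NULL`
#' @export
extract_beat_graph <- function(nu, lead = 1, detection_time,
                               window = c(-200, 400),
                               baseline_correct = TRUE) {
  stopifnot(inherits(nu, "nu_signal"))
  lo <- detection_time + window[1]
  hi <- detection_time + window[2]
  if (lo < nu$times[1] - 1e-9 || hi > nu$times[length(nu$times)] + 1e-9)
    return(NULL)
  i1 <- findInterval(lo - 1e-9, nu$times) + 1L
  i2 <- findInterval(hi + 1e-9, nu$times)
  value <- as.numeric(nu$values[[lead]][i1:i2])
  if (baseline_correct) value <- value - stats::median(value)
  structure(list(tau = nu$times[i1:i2] - detection_time, value = value),
            class = "beat_graph")
}

#' The beat-independent class-kernel quantization pattern
#'
#' Class kernels live on a fixed arbitrary grid whose density next to the
#' fiducial point is 8x the maximum signal sampling density (0.25 ms for
#' 500 Hz sources) and decays monotonically with distance: 0.25 ms spacing
#' for `|tau| <= 50` ms, 1 ms to 100 ms, 2 ms to 200 ms, 4 ms beyond.
#'
#' @param window window around the fiducial (ms)
#' @export
kernel_grid <- function(window = c(-200, 400)) {
  brk <- c(50, 100, 200)
  sp <- c(0.25, 1, 2, 4)
  pos <- c(seq(0, brk[1], by = sp[1]),
           seq(brk[1] + sp[2], brk[2], by = sp[2]),
           seq(brk[2] + sp[3], brk[3], by = sp[3]),
           seq(brk[3] + sp[4], 400, by = sp[4]))
  neg <- -rev(pos[pos > 0 & pos <= -window[1]])
  g <- c(neg, pos[pos <= window[2]])
  g[g >= window[1] & g <= window[2]]
}

#' Time weighting of the similarity score
#'
#' The weight of a node is proportional to the kernel-grid sampling density
#' at its `tau`, normalized to mean 1 over the beat window, so that samples
#' near the fiducial point dominate the likelihood assessment.
#'
#' @param tau node times relative to the detection point (ms)
#' @param weighting `"density"` (default) or `"flat"` (unit weights)
#' @export
time_weight <- function(tau, weighting = "density") {
  if (weighting == "flat") return(rep(1, length(tau)))
  dens <- ifelse(abs(tau) <= 50, 4,
          ifelse(abs(tau) <= 100, 1,
          ifelse(abs(tau) <= 200, 0.5, 0.25)))
  # mean density over the [-200, 400] window
  dens / (650 / 600)
}

#' Graph distance between two heartbeat representations
#'
#' For each node of either graph the counterpart value is linearly
#' interpolated in the other graph at the same `tau` (the one-to-many /
#' many-to-one node assignment); elementary distances are absolute value
#' differences modulated by the time weight; the similarity score `s` is
#' their sum (averaged over the two directions, making the distance
#' symmetric), normalized by the mean absolute amplitude of the two graphs.
#'
#' @param ga,gb `beat_graph` objects
#' @param weighting see [time_weight()]
#' @param abort_above stop accumulating once the cumulative normalized score
#'   exceeds this value and return `Inf` (first-pass shortcut)
#' @return dimensionless distance, `>= 0`, 0 for identical graphs
#' @export
graph_distance <- function(ga, gb, weighting = "density",
                           abort_above = NULL) {
  lo <- max(min(ga$tau), min(gb$tau))
  hi <- min(max(ga$tau), max(gb$tau))
  if (lo >= hi) stop("beat graphs do not overlap in time")
  amp <- mean(abs(c(ga$value, gb$value)))
  if (amp == 0) return(0)
  d_dir <- function(gx, gy) {
    sel <- gx$tau >= lo & gx$tau <= hi
    tau <- gx$tau[sel]
    other <- stats::approx(gy$tau, gy$value, xout = tau, rule = 2)$y
    abs(gx$value[sel] - other) * time_weight(tau, weighting)
  }
  d <- c(d_dir(ga, gb), d_dir(gb, ga)) / 2
  if (!is.null(abort_above)) {
    cs <- cumsum(d) / amp
    if (any(cs > abort_above)) return(Inf)
    return(cs[length(cs)])
  }
  sum(d) / amp
}

#' Create or update a class kernel with a newly accepted beat
#'
#' The kernel holds running means of member-beat values at the fixed
#' quantization pattern ([kernel_grid()]).  A new beat contributes its
#' linearly interpolated values at every grid point inside its time span,
#' weighted by the per-point member count.
#'
#' @param kernel a `class_kernel` or `NULL` (the founding beat becomes the
#'   kernel)
#' @param beat a `beat_graph`
#' @return a `class_kernel`: list `grid`, `value`, `count` (per grid point)
#' @export
update_kernel <- function(kernel, beat) {
  if (is.null(kernel)) {
    grid <- kernel_grid()
    kernel <- structure(list(grid = grid,
                             value = rep(NA_real_, length(grid)),
                             count = rep(0L, length(grid))),
                        class = "class_kernel")
  }
  sel <- kernel$grid >= min(beat$tau) & kernel$grid <= max(beat$tau)
  vals <- stats::approx(beat$tau, beat$value, xout = kernel$grid[sel])$y
  cnt <- kernel$count[sel]
  old <- kernel$value[sel]
  old[cnt == 0L] <- 0
  kernel$value[sel] <- (old * cnt + vals) / (cnt + 1L)
  kernel$count[sel] <- cnt + 1L
  kernel
}

# a kernel viewed as a beat graph (only populated grid points)
kernel_as_graph <- function(kernel) {
  has <- kernel$count > 0L
  structure(list(tau = kernel$grid[has], value = kernel$value[has]),
            class = "beat_graph")
}

#' Clustering configuration
#'
#' @param new_class_threshold first-pass distance threshold above which a
#'   beat founds a new class.  The default was calibrated once on the
#'   synthetic suite -- midway between the upper envelope of intra-class
#'   beat-to-kernel distances and the lower envelope of cross-class ones --
#'   and frozen.
#' @param max_iter maximum number of passes
#' @param weighting time weighting of the distance ([time_weight()])
#' @export
cluster_config <- function(new_class_threshold = 850, max_iter = 10,
                           weighting = "density") {
  stopifnot(new_class_threshold > 0, max_iter >= 1)
  structure(list(new_class_threshold = new_class_threshold,
                 max_iter = max_iter, weighting = weighting),
            class = "cluster_config")
}

#' Multipass clustering of heartbeats
#'
#' First pass: each beat joins (and updates) the nearest class kernel if its
#' distance is within the threshold, otherwise founds a new class.
#' Subsequent passes: kernels are frozen, every beat is assigned to the
#' nearest kernel, then kernels are recomputed from their members.  The
#' process stops when two consecutive passes agree or `max_iter` is
#' reached.  Multilead beats use the sum of per-lead distances.
#'
#' @param beats list of beats; each beat is a list of `beat_graph`s (one per
#'   lead) or a single `beat_graph`
#' @param config a [cluster_config()]
#' @return list: `assignments` (class index per beat, `NA` for excluded
#'   beats), `kernels` (per class, list of per-lead kernels), `n_pass`,
#'   `converged`
#' @export
cluster_beats <- function(beats, config = cluster_config()) {
  stopifnot(length(beats) >= 1)
  beats <- lapply(beats, function(b)
    if (inherits(b, "beat_graph")) list(b) else b)
  usable <- !vapply(beats, function(b) any(vapply(b, is.null, TRUE)), TRUE)
  idx_use <- which(usable)
  nlead <- length(beats[[idx_use[1]]])
  beat_dist <- function(beat, kern, abort_above = NULL) {
    tot <- 0
    for (l in seq_len(nlead)) {
      d <- graph_distance(beat[[l]], kernel_as_graph(kern[[l]]),
                          config$weighting,
                          abort_above = if (is.null(abort_above)) NULL
                                        else abort_above - tot)
      tot <- tot + d
      if (is.infinite(tot)) return(Inf)
    }
    tot
  }
  kernels <- list()
  assign_vec <- rep(NA_integer_, length(beats))
  # --- pass 1: threshold rule
  for (i in idx_use) {
    b <- beats[[i]]
    best <- Inf; best_k <- 0L
    for (k in seq_along(kernels)) {
      d <- beat_dist(b, kernels[[k]], abort_above = config$new_class_threshold)
      if (d < best) { best <- d; best_k <- k }
    }
    if (best <= config$new_class_threshold) {
      assign_vec[i] <- best_k
      kernels[[best_k]] <- lapply(seq_len(nlead), function(l)
        update_kernel(kernels[[best_k]][[l]], b[[l]]))
    } else {
      kernels[[length(kernels) + 1L]] <- lapply(seq_len(nlead), function(l)
        update_kernel(NULL, b[[l]]))
      assign_vec[i] <- length(kernels)
    }
  }
  n_pass <- 1L
  converged <- FALSE
  # --- passes >= 2: nearest kernel, kernels frozen within a pass
  while (n_pass < config$max_iter) {
    n_pass <- n_pass + 1L
    new_assign <- rep(NA_integer_, length(beats))
    for (i in idx_use) {
      d <- vapply(kernels, function(kern) beat_dist(beats[[i]], kern),
                  numeric(1))
      new_assign[i] <- which.min(d)   # ties resolve to the lowest index
    }
    if (identical(new_assign, assign_vec)) {
      assign_vec <- new_assign
      converged <- TRUE
      break
    }
    assign_vec <- new_assign
    # rebuild kernels from members
    keep <- sort(unique(assign_vec[!is.na(assign_vec)]))
    remap <- match(assign_vec, keep)
    kernels <- lapply(keep, function(k) {
      kern <- NULL
      for (i in idx_use[which(remap[idx_use] == match(k, keep))]) {
        kern <- if (is.null(kern))
          lapply(seq_len(nlead), function(l) update_kernel(NULL, beats[[i]][[l]]))
        else lapply(seq_len(nlead), function(l)
          update_kernel(kern[[l]], beats[[i]][[l]]))
      }
      kern
    })
    assign_vec <- remap
  }
  list(assignments = assign_vec, kernels = kernels,
       n_pass = n_pass, converged = converged)
}

#' Beat graphs of a whole record
#'
#' Convenience wrapper extracting all leads of all detected beats.
#' @param nu an [nu_signal()]
#' @param detections detection times (ms)
#' @param window window around each detection point (ms)
#' @param baseline_correct see [extract_beat_graph()]
#' @export
record_beat_graphs <- function(nu, detections, window = c(-200, 400),
                               baseline_correct = TRUE) {
  lapply(detections, function(d)
    lapply(seq_along(nu$values), function(l)
      extract_beat_graph(nu, l, d, window, baseline_correct)))
}
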