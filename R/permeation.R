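#' Tabular ion trajectory
#'
#' Validates and annotates a table of ion positions over time: columns
#' `time` (ps), `ion` (id), `x`, `y`, `z` (Angstrom). The pore axis is z.
#'
#' @param x Data frame or path to a delimited text file with those columns.
#' @param frame_interval_ps Sampling interval; inferred from the data when
#'   `NULL`.
#' @param box_z Periodic box height along z, Angstrom; when supplied, z is
#'   unwrapped across jumps larger than `box_z / 2` before crossing
#'   classification.
#' @return An object of class `trajectory_table` (a data frame with
#'   attributes `frame_interval_ps`, `box_z`).
#' @export
trajectory_table <- function(x, frame_interval_ps = NULL, box_z = NULL) {
  if (is.character(x)) {
    first <- readLines(x, n = 1)
    sep <- if (grepl(",", first)) "," else ""
    x <- read.table(x, header = TRUE, sep = sep)
  }
  req <- c("time", "ion", "x", "y", "z")
  if (!all(req %in% names(x)))
    stop_ionspike(paste("trajectory must have columns:",
                        paste(req, collapse = ", ")),
                  "ionspike_validation_error")
  x <- as.data.frame(x)[, req]
  for (id in unique(x$ion)) {
    tt <- x$time[x$ion == id]
    if (is.unsorted(tt, strictly = FALSE))
      stop_ionspike(sprintf("times for ion %s are not sorted", id),
                    "ionspike_validation_error")
  }
  if (is.null(frame_interval_ps)) {
    dtv <- diff(sort(unique(x$time)))
    frame_interval_ps <- if (length(dtv) > 0) median(dtv) else 1
  }
  if (frame_interval_ps <= 0)
    stop_ionspike("frame interval must be positive",
                  "ionspike_validation_error")
  if (!is.null(box_z) && !is.finite(box_z)) box_z <- NULL
  structure(x, class = c("trajectory_table", "data.frame"),
            frame_interval_ps = frame_interval_ps, box_z = box_z)
}

#' Geometric pore definition for permeation counting
#'
#' Two z planes bound the pore slab; optionally a lateral radius around the
#' pore axis gates what counts as "inside" (set `radius = Inf` for a pure
#' slab criterion).
#'
#' @param z_lower,z_upper Pore mouth planes, Angstrom (`z_upper > z_lower`).
#' @param axis_x,axis_y Pore axis coordinates, Angstrom.
#' @param radius Lateral gate radius, Angstrom.
#' @param ion_charge Ion charge in units of e0.
#' @return An object of class `pore_definition`.
#' @export
pore_definition <- function(z_lower, z_upper, axis_x = 0, axis_y = 0,
                            radius = Inf, ion_charge = 1) {
  if (z_upper <= z_lower)
    stop_ionspike("`z_upper` must exceed `z_lower`", "ionspike_domain_error")
  if (radius <= 0)
    stop_ionspike("`radius` must be positive", "ionspike_domain_error")
  structure(list(z_lower = z_lower, z_upper = z_upper, axis_x = axis_x,
                 axis_y = axis_y, radius = radius, ion_charge = ion_charge),
            class = "pore_definition")
}

# unwrap a z series across periodic jumps > box_z / 2
unwrap_z <- function(z, box_z) {
  if (is.null(box_z) || !is.finite(box_z) || length(z) < 2) return(z)
  dz <- diff(z)
  shift <- -box_z * cumsum(round(dz / box_z))
  z + c(0, shift)
}

# region code per frame: 0 below, 1 inside (lateral ok), 2 above,
# 3 inside slab but laterally outside the gate
classify_region <- function(x, y, z, pore) {
  r <- ifelse(z < pore$z_lower, 0L, ifelse(z > pore$z_upper, 2L, 1L))
  if (is.finite(pore$radius)) {
    lat2 <- (x - pore$axis_x)^2 + (y - pore$axis_y)^2
    r[r == 1L & lat2 > pore$radius^2] <- 3L
  }
  r
}

#' Count complete ion permeation events
#'
#' A per-ion three-state machine over the pore regions: a completed
#' up-crossing is below -> inside -> above without an intervening exit back
#' below or a lateral excursion beyond the gate radius while inside
#' (symmetric for down-crossings). An observed inside sample is required, so
#' a single-frame jump across the whole slab does not count; missing frames
#' are otherwise tolerated (the machine advances on available samples).
#' z is unwrapped across periodic jumps larger than `box_z / 2` before
#' classification when the trajectory carries a box height.
#'
#' Runs are collapsed per ion (run-length encoding over region codes), so
#' cost scales with the number of region changes rather than frames.
#'
#' @param traj A [trajectory_table()].
#' @param pore A [pore_definition()].
#' @return Data frame of crossing events: `ion`, `direction` ("up"/"down"),
#'   `entry_time`, `exit_time` (ps).
#' @export
count_crossings <- function(traj, pore) {
  stopifnot(inherits(traj, "trajectory_table"),
            inherits(pore, "pore_definition"))
  box_z <- attr(traj, "box_z")
  events <- list()
  for (id in unique(traj$ion)) {
    sub <- traj[traj$ion == id, ]
    z <- unwrap_z(sub$z, box_z)
    reg <- classify_region(sub$x, sub$y, z, pore)
    rl <- rle(reg)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    state <- 0L   # 0 none, 1 below, 2 above, 3 in-from-below, 4 in-from-above
    entry <- NA_real_
    for (k in seq_along(rl$values)) {
      rg <- rl$values[k]
      tfirst <- sub$time[starts[k]]
      if (rg == 0L) {                 # below
        if (state == 4L)
          events[[length(events) + 1]] <- data.frame(
            ion = id, direction = "down", entry_time = entry,
            exit_time = tfirst)
        state <- 1L
      } else if (rg == 2L) {          # above
        if (state == 3L)
          events[[length(events) + 1]] <- data.frame(
            ion = id, direction = "up", entry_time = entry,
            exit_time = tfirst)
        state <- 2L
      } else if (rg == 1L) {          # inside
        if (state == 1L) { state <- 3L; entry <- tfirst }
        else if (state == 2L) { state <- 4L; entry <- tfirst }
      } else {                        # inside slab, laterally outside
        state <- 0L
      }
    }
  }
  if (length(events) == 0)
    return(data.frame(ion = character(0), direction = character(0),
                      entry_time = numeric(0), exit_time = numeric(0)))
  do.call(rbind, events)
}

#' Current and single-channel conductance from crossing events
#'
#' Net flux `n_net = n_up - n_down` (positive along +z), current
#' `I = n_net * ion_charge * e / duration` and conductance `g = I / v_m`,
#' with `e = 1.602176634e-19` C handled exactly.
#'
#' @param events Event data frame from [count_crossings()].
#' @param duration_ns Observation span, ns.
#' @param v_m_mV Transmembrane voltage, mV (nonzero).
#' @param ion_charge Ion charge, e0 units.
#' @return List with `n_up`, `n_down`, `n_net`, `current_pA`, `g_pS`.
#' @examples
#' ev <- data.frame(ion = 1:19, direction = "up", entry_time = 1,
#'                  exit_time = 2)
#' crossing_conductance(ev, duration_ns = 500, v_m_mV = 600)$g_pS # ~10.15
#' @export
crossing_conductance <- function(events, duration_ns, v_m_mV, ion_charge = 1) {
  check_scalar(duration_ns, "duration_ns", lower = 1e-300)
  if (!is.numeric(v_m_mV) || length(v_m_mV) != 1 || v_m_mV == 0)
    stop_ionspike(
      "`v_m_mV` must be nonzero: conductance g = I / V_m is undefined at V_m = 0",
      "ionspike_domain_error")
  n_up <- sum(events$direction == "up")
  n_down <- sum(events$direction == "down")
  n_net <- n_up - n_down
  current_A <- n_net * ion_charge * .E_CHARGE / (duration_ns * 1e-9)
  current_pA <- current_A * 1e12
  g_pS <- current_pA / (v_m_mV * 1e-3)  # 1 pA per volt = 1 pS
  list(n_up = n_up, n_down = n_down, n_net = n_net,
       current_pA = current_pA, g_pS = g_pS)
}

#' Block-averaged conductance with standard error
#'
#' Splits the trajectory time span into `n_blocks` equal blocks, computes
#' the conductance per block (events assigned by exit time, so passages
#' spanning a block boundary are kept) and returns the mean and standard
#' error of the mean.
#'
#' @param traj A [trajectory_table()].
#' @param pore A [pore_definition()].
#' @param n_blocks Number of blocks (>= 2).
#' @param v_m_mV Transmembrane voltage, mV.
#' @return List with `g_mean_pS`, `g_se_pS`, `g_blocks_pS`.
#' @export
block_errors <- function(traj, pore, n_blocks, v_m_mV) {
  if (!is_count(n_blocks) || n_blocks < 2)
    stop_ionspike("`n_blocks` must be an integer >= 2",
                  "ionspike_domain_error")
  span <- range(traj$time)
  fi <- attr(traj, "frame_interval_ps")
  block_ps <- (span[2] - span[1]) / n_blocks
  if (block_ps < 2 * fi)
    stop_ionspike("blocks shorter than 2 frames", "ionspike_domain_error")
  ev <- count_crossings(traj, pore)
  edges <- seq(span[1], span[2], length.out = n_blocks + 1)
  g <- vapply(seq_len(n_blocks), function(b) {
    inb <- ev$exit_time > edges[b] & ev$exit_time <= edges[b + 1] |
      (b == 1 & ev$exit_time == edges[1])
    sub <- ev[inb, , drop = FALSE]
    crossing_conductance(sub, duration_ns = block_ps / 1000,
                         v_m_mV = v_m_mV,
                         ion_charge = pore$ion_charge)$g_pS
  }, numeric(1))
  list(g_mean_pS = mean(g),
       g_se_pS = stats::sd(g) / sqrt(n_blocks),
       g_blocks_pS = g)
}
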