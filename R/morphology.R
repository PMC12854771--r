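#' Construct a neuron morphology from a segment table
#'
#' A morphology is a tree of cylindrical/frustum segments. Each row gives a
#' segment id, its parent id (`-1` for the root), proximal and distal 3D
#' coordinates (um), proximal and distal diameters (um) and a region label
#' (`soma`, `dendrite` or `axon`).
#'
#' @param segments Data frame with columns `id`, `parent`, `x0,y0,z0`,
#'   `x1,y1,z1`, `d0`, `d1`, `region`.
#' @return An object of class `morphology` (a validated data frame).
#' @export
morphology <- function(segments) {
  req <- c("id", "parent", "x0", "y0", "z0", "x1", "y1", "z1", "d0", "d1",
           "region")
  if (!all(req %in% names(segments)))
    stop_ionspike(paste("missing columns:",
                        paste(setdiff(req, names(segments)), collapse = ", ")),
                  "ionspike_validation_error")
  segments <- as.data.frame(segments)[, req]
  segments$region <- as.character(segments$region)
  m <- structure(segments, class = c("morphology", "data.frame"))
  validate_morphology(m)
  m
}

segment_lengths <- function(m) {
  sqrt((m$x1 - m$x0)^2 + (m$y1 - m$y0)^2 + (m$z1 - m$z0)^2)
}

validate_morphology <- function(m) {
  if (nrow(m) < 1)
    stop_ionspike("morphology has no segments", "ionspike_validation_error")
  roots <- which(m$parent == -1)
  if (length(roots) != 1)
    stop_ionspike("morphology must have exactly one root segment",
                  "ionspike_validation_error")
  if (any(duplicated(m$id)))
    stop_ionspike("duplicate segment ids", "ionspike_validation_error")
  if (!all(m$parent[-roots] %in% m$id))
    stop_ionspike("parent ids must reference existing segments",
                  "ionspike_validation_error")
  if (any(m$d0 <= 0 | m$d1 <= 0))
    stop_ionspike("segment diameters must be positive",
                  "ionspike_validation_error")
  if (any(segment_lengths(m) <= 0))
    stop_ionspike("segment lengths must be positive",
                  "ionspike_validation_error")
  if (!all(m$region %in% c("soma", "dendrite", "axon")))
    stop_ionspike("region must be one of soma/dendrite/axon",
                  "ionspike_validation_error")
  # acyclic: walk each segment to the root
  byid <- setNames(m$parent, m$id)
  for (i in m$id) {
    seen <- character(0)
    j <- i
    while (j != -1) {
      if (j %in% seen)
        stop_ionspike("cycle detected in morphology tree",
                      "ionspike_validation_error")
      seen <- c(seen, j)
      j <- byid[[as.character(j)]]
    }
  }
  invisible(m)
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("Morphology: %d segments (%s); total length %.1f um\n",
              nrow(x),
              paste(sprintf("%d %s", table(x$region),
                            names(table(x$region))), collapse = ", "),
              sum(segment_lengths(x))))
  invisible(x)
}

#' Ball-and-stick morphology
#'
#' A spherical-equivalent cylindrical soma (length = diameter, so the lateral
#' area equals the sphere area `pi * d^2`) with a single dendrite attached to
#' its distal end.
#'
#' @param soma_diam Soma diameter (= soma cylinder length), um.
#' @param dend_len Dendrite length, um.
#' @param dend_diam Dendrite diameter, um.
#' @return A `morphology` with one soma and one dendrite segment.
#' @examples
#' make_ball_and_stick(20, 200, 2)
#' @export
make_ball_and_stick <- function(soma_diam = 20, dend_len = 200, dend_diam = 2) {
  check_scalar(soma_diam, "soma_diam", lower = 1e-9)
  check_scalar(dend_len, "dend_len", lower = 1e-9)
  check_scalar(dend_diam, "dend_diam", lower = 1e-9)
  morphology(data.frame(
    id = c(1L, 2L), parent = c(-1L, 1L),
    x0 = c(0, soma_diam), y0 = 0, z0 = 0,
    x1 = c(soma_diam, soma_diam + dend_len), y1 = 0, z1 = 0,
    d0 = c(soma_diam, dend_diam), d1 = c(soma_diam, dend_diam),
    region = c("soma", "dendrite")))
}

#' Specification for a random dendritic tree
#'
#' @param depth Maximum branching depth.
#' @param branch_prob Probability of each of the two candidate daughter
#'   branches beyond the fully-branched levels.
#' @param min_full_depth Levels that always produce two daughters (guarantees
#'   a minimum dendritic segment count for synapse placement).
#' @param len_range Segment length range, um.
#' @param taper Diameter ratio per generation.
#' @param diam0 Trunk diameter, um.
#' @param diam_min Diameter floor, um.
#' @param soma_height Soma cylinder height (= diameter), um; default 20.
#' @param axon_len Length of the single axonal segment, um.
#' @return An object of class `tree_spec`.
#' @export
tree_spec <- function(depth = 5, branch_prob = 0.7, min_full_depth = 3,
                      len_range = c(30, 60), taper = 0.8, diam0 = 2.5,
                      diam_min = 0.3, soma_height = 20, axon_len = 300) {
  stopifnot(depth >= 1, branch_prob >= 0, branch_prob <= 1,
            length(len_range) == 2, len_range[1] > 0,
            len_range[2] >= len_range[1], taper > 0, taper <= 1,
            diam0 > 0, soma_height > 0, axon_len > 0)
  structure(list(depth = depth, branch_prob = branch_prob,
                 min_full_depth = min_full_depth, len_range = len_range,
                 taper = taper, diam0 = diam0, diam_min = diam_min,
                 soma_height = soma_height, axon_len = axon_len),
            class = "tree_spec")
}

#' Generate a random branched dendritic morphology
#'
#' Grows a binary dendritic tree from the distal end of a cylindrical soma.
#' Levels up to `min_full_depth` always branch into two daughters so the
#' default spec is guaranteed at least `2^min_full_depth + ...` dendritic
#' segments (>= 10 for the default); deeper levels branch with
#' `branch_prob` per candidate daughter. Daughter directions are random in
#' 3D with an outward bias; diameters taper by `taper` per generation. One
#' axonal segment leaves the proximal soma pole. Deterministic per seed.
#'
#' @param spec A [tree_spec()].
#' @param seed Integer seed.
#' @return A `morphology`.
#' @examples
#' m <- make_random_tree(tree_spec(), seed = 1)
#' sum(m$region == "dendrite")
#' @export
make_random_tree <- function(spec = tree_spec(), seed = 1) {
  stopifnot(inherits(spec, "tree_spec"))
  rows <- with_seed(seed, {
    soma <- data.frame(id = 1L, parent = -1L,
                       x0 = 0, y0 = 0, z0 = 0,
                       x1 = spec$soma_height, y1 = 0, z1 = 0,
                       d0 = spec$soma_height, d1 = spec$soma_height,
                       region = "soma")
    axon <- data.frame(id = 2L, parent = 1L,
                       x0 = 0, y0 = 0, z0 = 0,
                       x1 = -spec$axon_len, y1 = 0, z1 = 0,
                       d0 = 1, d1 = 1, region = "axon")
    out <- rbind(soma, axon)
    nid <- 2L
    # stack of (parent id, tip coords, direction, diameter, level)
    grow <- list(list(parent = 1L,
                      tip = c(spec$soma_height, 0, 0),
                      dir = c(1, 0, 0), diam = spec$diam0, level = 1L))
    while (length(grow) > 0) {
      node <- grow[[1]]
      grow <- grow[-1]
      len <- runif(1, spec$len_range[1], spec$len_range[2])
      # jitter direction, keep outward bias
      dir <- node$dir + rnorm(3, sd = 0.4)
      dir <- dir / sqrt(sum(dir^2))
      tip <- node$tip + dir * len
      nid <- nid + 1L
      out <- rbind(out, data.frame(
        id = nid, parent = node$parent,
        x0 = node$tip[1], y0 = node$tip[2], z0 = node$tip[3],
        x1 = tip[1], y1 = tip[2], z1 = tip[3],
        d0 = node$diam, d1 = node$diam, region = "dendrite"))
      if (node$level < spec$depth) {
        ndaughter <- if (node$level <= spec$min_full_depth) 2L
                     else sum(runif(2) < spec$branch_prob)
        d_next <- max(node$diam * spec$taper, spec$diam_min)
        if (ndaughter >= 1)
          grow <- c(grow, list(list(parent = nid, tip = tip, dir = dir,
                                    diam = d_next, level = node$level + 1L)))
        if (ndaughter == 2)
          grow <- c(grow, list(list(parent = nid, tip = tip, dir = dir,
                                    diam = d_next, level = node$level + 1L)))
      }
    }
    out
  })
  if (sum(rows$region == "dendrite") < 1)
    stop_ionspike("tree spec produced no dendritic segments",
                  "ionspike_validation_error")
  morphology(rows)
}

#' Read / write morphologies in SWC format
#'
#' Standard 7-column SWC (`index type x y z radius parent`); type codes 1 =
#' soma, 2 = axon, 3 = dendrite. On write, each segment contributes its
#' distal point, with proximal points emitted for root segments; on read,
#' every point with a parent becomes a segment from the parent point to the
#' point, with the region taken from the child's type code and diameters from
#' the two point radii.
#'
#' @param path File path.
#' @param morph A `morphology` (for writing).
#' @return `read_swc` returns a `morphology`; `write_swc` returns `path`
#'   invisibly.
#' @export
read_swc <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("index", "type", "x", "y", "z", "radius",
                                  "parent"))
  type_region <- c("1" = "soma", "2" = "axon", "3" = "dendrite")
  pts <- tab[order(tab$index), ]
  rownames(pts) <- NULL
  idx <- setNames(seq_len(nrow(pts)), pts$index)
  segs <- pts[pts$parent != -1, ]
  if (nrow(segs) < 1)
    stop_ionspike("SWC file contains no edges", "ionspike_validation_error")
  par <- pts[idx[as.character(segs$parent)], ]
  # segment parent: the edge ending at our proximal point; edges hanging off
  # the root point share the first such edge as their parent (the root edge)
  edge_id <- setNames(seq_len(nrow(segs)), segs$index)
  seg_parent <- ifelse(segs$parent %in% segs$index,
                       edge_id[as.character(segs$parent)], NA_integer_)
  off_root <- which(is.na(seg_parent))
  if (length(off_root) > 0) {
    seg_parent[off_root[1]] <- -1L
    if (length(off_root) > 1) seg_parent[off_root[-1]] <- off_root[1]
  }
  # each edge is read as a cylinder of the child point's radius; this makes
  # write/read a lossless round trip for the package's generators (which emit
  # constant-diameter segments) and sidesteps the radius ambiguity at region
  # boundaries inherent to point-based SWC
  morphology(data.frame(
    id = seq_len(nrow(segs)), parent = as.integer(seg_parent),
    x0 = par$x, y0 = par$y, z0 = par$z,
    x1 = segs$x, y1 = segs$y, z1 = segs$z,
    d0 = 2 * segs$radius, d1 = 2 * segs$radius,
    region = unname(type_region[as.character(segs$type)])))
}

#' @rdname read_swc
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "morphology"))
  region_type <- c(soma = 1L, axon = 2L, dendrite = 3L)
  # point for each segment's distal end; root gets an extra proximal point
  root <- which(morph$parent == -1)
  npt <- nrow(morph) + 1L
  pts <- data.frame(index = seq_len(npt), type = 0L, x = 0, y = 0, z = 0,
                    radius = 0, parent = -1L)
  pts[1, ] <- list(1L, region_type[[morph$region[root]]],
                   morph$x0[root], morph$y0[root], morph$z0[root],
                   morph$d0[root] / 2, -1L)
  seg_pt <- integer(nrow(morph)) # point index of each segment's distal end
  remaining <- setdiff(seq_len(nrow(morph)), root)
  done <- c(root)
  seg_pt[root] <- 2L
  pts[2, ] <- list(2L, region_type[[morph$region[root]]],
                   morph$x1[root], morph$y1[root], morph$z1[root],
                   morph$d1[root] / 2, 1L)
  nxt <- 3L
  while (length(remaining) > 0) {
    for (i in remaining) {
      pseg <- which(morph$id == morph$parent[i])
      if (pseg %in% done) {
        # attach to the parent's distal point, or to the root's proximal
        # point when the child branches from the proximal pole (e.g. an axon
        # leaving the soma opposite the dendrites)
        at_prox <- pseg == root &&
          isTRUE(all.equal(c(morph$x0[i], morph$y0[i], morph$z0[i]),
                           c(morph$x0[root], morph$y0[root], morph$z0[root]),
                           tolerance = 1e-9))
        ppt <- if (at_prox) 1L else seg_pt[pseg]
        pts[nxt, ] <- list(nxt, region_type[[morph$region[i]]],
                           morph$x1[i], morph$y1[i], morph$z1[i],
                           morph$d1[i] / 2, ppt)
        seg_pt[i] <- nxt
        nxt <- nxt + 1L
        done <- c(done, i)
      }
    }
    remaining <- setdiff(remaining, done)
  }
  lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d", pts$index, pts$type,
                   pts$x, pts$y, pts$z, pts$radius, pts$parent)
  writeLines(c("# SWC export", lines), path)
  invisible(path)
}
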