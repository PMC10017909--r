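#' Per-atom Voronoi cell volumes under periodic boundary conditions
#'
#' Partitions the orthorhombic box among atomic sites by an ordinary
#' (unweighted) Voronoi tessellation with full periodic images, and returns
#' each site's cell volume. Cell volumes sum to the box volume by
#' construction (conservation is the key invariant the compressibility
#' estimate relies on).
#'
#' @param frame an [md_frame()]; coordinates are wrapped into the box.
#' @param sites optional integer vector of atom ids to report (the
#'   tessellation is always computed over all atoms in the frame).
#' @return Numeric vector of cell volumes (Angstrom^3), one per atom of the
#'   frame (or per requested site).
#' @export
voronoi_cell_volumes <- function(frame, sites = NULL) {
  stopifnot(inherits(frame, "md_frame"))
  n <- nrow(frame$xyz)
  if (n > 1 && n <= 2000) {
    # warn when some site's nearest neighbour is further than half a box
    # edge: its cell then presses against the site's own periodic images
    nn <- vapply(seq_len(n), function(i) {
      sqrt(min(.min_image_dist2(frame$xyz[-i, , drop = FALSE],
                                frame$xyz[i, ], frame$box)))
    }, numeric(1))
    if (any(frame$box < 2 * max(nn))) {
      warning("box edge below twice the largest nearest-site spacing; ",
              "cells are bounded by their own periodic images")
    }
  }
  vols <- voronoi_volumes_cpp(frame$xyz, frame$box)
  if (!is.null(sites)) vols <- vols[sites]
  vols
}

#' Construct a region volume time series
#'
#' @param region_name name of the region the volumes belong to.
#' @param times sample times (ns), strictly increasing.
#' @param volumes region volumes (Angstrom^3), positive.
#' @param condition a [condition()] describing pressure / ethanol fraction /
#'   temperature, or NULL.
#' @return A list of class `"volume_series"`.
#' @export
volume_series <- function(region_name, times, volumes, condition = NULL) {
  stopifnot(length(times) == length(volumes))
  if (any(volumes <= 0)) stop("volumes must be positive")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  structure(list(region = region_name, times = as.numeric(times),
                 volumes = as.numeric(volumes), condition = condition),
            class = "volume_series")
}

#' Region volume time series from a trajectory
#'
#' For each sampled frame the whole system (protein plus solvent) is
#' tessellated, so protein-solvent boundaries are physical, and the region
#' volume is the sum of the Voronoi cell volumes of the region's heavy
#' atoms.
#'
#' @param traj an [md_trajectory()].
#' @param partition a [region_partition()].
#' @param region_name region to measure.
#' @param sample_interval sampling interval in ns; must be at least the
#'   frame spacing. Frames at times that are (approximate) multiples of the
#'   interval are used.
#' @param condition optional [condition()] attached to the series.
#' @param scope atom scope for the region sum, default heavy atoms.
#' @return A [volume_series()].
#' @export
region_volume_series <- function(traj, partition, region_name,
                                 sample_interval = 1, condition = NULL,
                                 scope = "heavy-atom") {
  ids <- region_atoms(partition, traj$topology, region_name, scope = scope)
  times <- vapply(traj$frames, `[[`, numeric(1), "time")
  if (length(times) > 1) {
    dt <- min(diff(times))
    if (sample_interval < dt - 1e-9) {
      stop("sample_interval (", sample_interval,
           " ns) is below the frame spacing (", dt, " ns)")
    }
  }
  keep <- which(abs(times / sample_interval -
                    round(times / sample_interval)) < 1e-6)
  if (length(keep) == 0) stop("no frames fall on the sampling grid")
  vols <- vapply(keep, function(k) {
    sum(voronoi_cell_volumes(traj$frames[[k]], sites = ids))
  }, numeric(1))
  volume_series(region_name, times[keep], vols, condition)
}
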