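# Selectivity observables on molecular trajectories: selections,
# distance series, two-state occupancy with hysteresis, hydration
# numbers, contact occupancy and site-binding events.

#' Trajectory bundle: atom table plus coordinate frames
#'
#' @param atoms data.frame with columns `index`, `name`, `resname`,
#'   `resno`, `chain`, `element` (1-based residue numbers, PDB
#'   convention).
#' @param coords Numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param dt_ps Optional frame interval (ps).
#' @return An object of class `trajectory_bundle`.
#' @export
trajectory_bundle <- function(atoms, coords, dt_ps = NULL) {
  need <- c("index", "name", "resname", "resno", "chain", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  if (dim(coords)[1] != nrow(atoms) || dim(coords)[2] != 3)
    stop("coords must be n_atoms x 3 x n_frames", call. = FALSE)
  if (any(!is.finite(coords)))
    stop("coordinates must be finite", call. = FALSE)
  # periodic imaging is unsupported: warn when the coordinate spread looks
  # like a wrapped box (all coordinates inside one octant of a large cube
  # with atoms hugging opposite faces)
  span <- apply(coords, 2, function(m) diff(range(m)))
  if (any(span > 500))
    warning("coordinate span > 500 A; wrapped periodic boxes are not ",
            "supported", call. = FALSE)
  structure(list(atoms = atoms, coords = coords, dt_ps = dt_ps,
                 n_frames = dim(coords)[3]),
            class = "trajectory_bundle")
}

#' Resolve an atom selection
#'
#' Selections are either integer atom indices or a string of
#' `and`-joined clauses over atom-table columns, e.g.
#' `"resi 222 and name OH"`.  Clause keys: `resi` (residue number),
#' `resn` (residue name), `name` (atom name), `chain`, `elem`; each key
#' may list several space-separated values (OR within a clause).
#'
#' @param traj A [trajectory_bundle()].
#' @param sel Selection string or integer vector.
#' @return Integer vector of atom row indices (>= 1 atom).
#' @export
select_atoms <- function(traj, sel) {
  stopifnot(inherits(traj, "trajectory_bundle"))
  at <- traj$atoms
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (any(idx < 1 | idx > nrow(at)))
      stop("atom indices out of range", call. = FALSE)
    return(idx)
  }
  keep <- rep(TRUE, nrow(at))
  for (clause in strsplit(sel, "\\s+and\\s+")[[1]]) {
    tok <- strsplit(trimws(clause), "\\s+")[[1]]
    if (length(tok) < 2)
      stop("malformed selection clause: '", clause, "'", call. = FALSE)
    key <- tok[1]; vals <- tok[-1]
    col <- switch(key,
                  resi = as.character(at$resno),
                  resn = at$resname,
                  name = at$name,
                  chain = at$chain,
                  elem = at$element,
                  stop("unknown selection key '", key,
                       "' (use resi/resn/name/chain/elem)", call. = FALSE))
    keep <- keep & col %in% vals
  }
  idx <- which(keep)
  if (!length(idx))
    stop("selection '", sel, "' matches no atoms", call. = FALSE)
  idx
}

# per-frame coordinates of a selection: n_sel x 3 matrix
.frame_xyz <- function(traj, idx, frame) {
  matrix(traj$coords[idx, , frame], ncol = 3)
}

#' Per-frame distance between two selections
#'
#' Euclidean distance between the unweighted centroids of the two
#' selections, or the minimum inter-atom pair distance, per frame.
#' Distances are computed on raw (unwrapped) coordinates.
#'
#' @param traj A [trajectory_bundle()].
#' @param sel_a,sel_b Selections (see [select_atoms()]).
#' @param mode `"centroid"` or `"min_pair"`.
#' @return Numeric vector, one distance (Angstrom) per frame.
#' @export
distance_series <- function(traj, sel_a, sel_b,
                            mode = c("centroid", "min_pair")) {
  mode <- match.arg(mode)
  ia <- select_atoms(traj, sel_a)
  ib <- select_atoms(traj, sel_b)
  vapply(seq_len(traj$n_frames), function(f) {
    xa <- .frame_xyz(traj, ia, f)
    xb <- .frame_xyz(traj, ib, f)
    if (mode == "centroid") {
      sqrt(sum((colMeans(xa) - colMeans(xb))^2))
    } else {
      d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
      sqrt(max(0, min(d2)))
    }
  }, numeric(1))
}

#' Histogram of a distance series
#'
#' @param distances Numeric vector (Angstrom).
#' @param bin_width Bin width in Angstrom (default 0.1).
#' @return data.frame with `mid_a` (bin centers) and `count`.
#' @export
distance_histogram <- function(distances, bin_width = 0.1) {
  lo <- floor(min(distances) / bin_width) * bin_width
  hi <- ceiling(max(distances) / bin_width) * bin_width
  br <- seq(lo, hi + bin_width / 2, by = bin_width)
  if (length(br) < 2) br <- c(lo, lo + bin_width)
  idx <- findInterval(distances, br, rightmost.closed = TRUE,
                      all.inside = TRUE)
  data.frame(mid_a = br[-length(br)] + bin_width / 2,
             count = tabulate(idx, nbins = length(br) - 1))
}

#' Two-state (tight/loose) classification with hysteresis
#'
#' Frames enter the tight state when the distance drops below
#' `low_threshold` and the loose state when it rises above
#' `high_threshold`; inside the band the previous label is kept, so
#' chatter within the band produces no spurious transitions.  Frames
#' before the first crossing are `undefined` and excluded from the
#' occupancy fractions.
#'
#' @param distances Per-frame distance series (Angstrom).
#' @param low_threshold,high_threshold Hysteresis thresholds,
#'   `low_threshold < high_threshold`.
#' @return List of class `state_series`: `states` (factor tight / loose
#'   / undefined), `occupancy` (named fractions over defined frames),
#'   `transitions` (count).
#' @export
classify_two_state <- function(distances, low_threshold, high_threshold) {
  if (low_threshold >= high_threshold)
    stop("low_threshold must be below high_threshold", call. = FALSE)
  n <- length(distances)
  states <- character(n)
  cur <- "undefined"
  trans <- 0L
  for (i in seq_len(n)) {
    nxt <- if (distances[i] < low_threshold) "tight"
           else if (distances[i] > high_threshold) "loose"
           else cur
    if (cur != "undefined" && nxt != cur) trans <- trans + 1L
    cur <- nxt
    states[i] <- cur
  }
  defined <- states != "undefined"
  occ <- if (any(defined)) {
    tab <- table(factor(states[defined], levels = c("tight", "loose")))
    as.numeric(tab) / sum(tab)
  } else c(NA_real_, NA_real_)
  names(occ) <- c("tight", "loose")
  structure(list(states = factor(states,
                                 levels = c("tight", "loose", "undefined")),
                 occupancy = occ, transitions = trans),
            class = "state_series")
}

#' First-shell hydration number of an ion
#'
#' Counts, per frame, the water oxygen atoms within `cutoff_a`
#' (inclusive) of a single-atom ion selection.
#'
#' @param traj A [trajectory_bundle()].
#' @param ion Selection resolving to exactly one atom.
#' @param waters Selection of water oxygen atoms.
#' @param cutoff_a First-shell cutoff (default 3.5 Angstrom, the
#'   conventional K+-water-oxygen first minimum).
#' @return List: `counts` (per frame), `mean`.
#' @export
hydration_number <- function(traj, ion, waters, cutoff_a = 3.5) {
  ii <- select_atoms(traj, ion)
  if (length(ii) != 1)
    stop("ion selection must resolve to exactly one atom (got ",
         length(ii), ")", call. = FALSE)
  iw <- select_atoms(traj, waters)
  counts <- vapply(seq_len(traj$n_frames), function(f) {
    xi <- traj$coords[ii, , f]
    xw <- .frame_xyz(traj, iw, f)
    d <- sqrt(rowSums(sweep(xw, 2, xi)^2))
    sum(d <= cutoff_a)
  }, numeric(1))
  list(counts = counts, mean = mean(counts))
}

#' Contact (e.g. salt-bridge) occupancy between two selections
#'
#' A frame is "in contact" when the minimum inter-atom distance between
#' the selections is at or below `cutoff_a`.
#'
#' @param traj A [trajectory_bundle()].
#' @param sel_a,sel_b Selections.
#' @param cutoff_a Contact cutoff (default 4.0 Angstrom, the usual
#'   side-chain N/O salt-bridge criterion).
#' @return List: `fraction` (bound fraction of frames), `in_contact`
#'   (logical per frame), `distances` (per-frame min-pair distance).
#' @export
contact_occupancy <- function(traj, sel_a, sel_b, cutoff_a = 4.0) {
  d <- distance_series(traj, sel_a, sel_b, mode = "min_pair")
  inc <- d <= cutoff_a
  list(fraction = mean(inc), in_contact = inc, distances = d)
}

#' Detect transient binding events from an ion-site distance series
#'
#' Maximal runs of consecutive frames with distance at or below
#' `cutoff_a`; runs shorter than `min_dwell` frames are discarded.  With
#' `min_dwell = 1` the total bound fraction equals the contact
#' occupancy.
#'
#' @param distances Per-frame ion-site distance series (Angstrom).
#' @param cutoff_a Binding cutoff (default 5.0 Angstrom).
#' @param min_dwell Minimum event length in frames (default 1).
#' @return List of class `binding_events`: `events` (data.frame
#'   start_frame / end_frame / mean_distance_a), `bound_fraction`.
#' @export
detect_binding_events <- function(distances, cutoff_a = 5.0, min_dwell = 1) {
  if (min_dwell < 1) stop("min_dwell must be >= 1", call. = FALSE)
  inb <- distances <= cutoff_a
  r <- rle(inb)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_dwell
  ev <- data.frame(start_frame = starts[keep], end_frame = ends[keep])
  ev$mean_distance_a <- vapply(seq_len(nrow(ev)), function(i)
    mean(distances[ev$start_frame[i]:ev$end_frame[i]]), numeric(1))
  structure(list(events = ev,
                 bound_fraction = sum(ev$end_frame - ev$start_frame + 1) /
                   length(distances)),
            class = "binding_events")
}
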