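# Step labeling (B / Z / junction), Z-segment tracking, and dynamic event
# detection: hydrogen-bond registry, base flipping, base extrusion and
# intercalated stacking.

.default_thresholds <- list(
  t_z_deg = 15, hbond_cutoff_A = 3.4, flip_min_deg = 100,
  extrusion_dwell = 5, extrusion_disp_A = 2.5,
  stack_dist_A = 4.5, stack_angle_deg = 30, perp_angle_deg = 60,
  min_z = 1)

#' Label dinucleotide steps as B, Z or junction
#'
#' A step is `Z` when its twist is below `t_z` AND its backbone or glycosyl
#' state is Z-like (a ZI/ZII/ZIII signature, a BIII family, or a step purine
#' in the minus_syn/plus_syn/high_anti chi class); otherwise `B`.  After run
#' formation the boundary step of every maximal B-run adjacent to a Z-run is
#' relabeled `junction`.
#'
#' @param steps data.frame with columns `twist` (deg), `z_signature`,
#'   `b_family` (see [classify_step_backbone()]) and `purine_chi` (a list
#'   column, chi classes of the step's purines; or a character column).
#' @param t_z Twist threshold in degrees (default 15).
#' @return The input with a `label` factor column (B/Z/junction) added.
#' @export
label_steps <- function(steps, t_z = .default_thresholds$t_z_deg) {
  need <- c("twist", "z_signature", "b_family", "purine_chi")
  if (!all(need %in% names(steps))) {
    stop("alignment error: steps must carry ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(steps)
  z_chi <- c("minus_syn", "plus_syn", "high_anti")
  lab <- rep("B", n)
  for (k in seq_len(n)) {
    chis <- unlist(steps$purine_chi[k])
    z_like <- (!is.na(steps$z_signature[k]) &&
                 as.character(steps$z_signature[k]) %in% c("ZI", "ZII", "ZIII")) ||
      (!is.na(steps$b_family[k]) && as.character(steps$b_family[k]) == "BIII") ||
      any(chis %in% z_chi)
    if (!is.na(steps$twist[k]) && steps$twist[k] < t_z && z_like) lab[k] <- "Z"
  }
  # relabel boundary B steps adjacent to a Z run
  for (k in seq_len(n)) {
    if (lab[k] == "B" &&
        ((k > 1 && lab[k - 1] == "Z") || (k < n && lab[k + 1] == "Z"))) {
      lab[k] <- "junction"
    }
  }
  steps$label <- factor(lab, levels = c("B", "Z", "junction"))
  steps
}

#' Z-segments and their flanking junctions
#'
#' @param labels Factor/character vector of step labels (from
#'   [label_steps()]).
#' @param min_z Minimum Z-run length kept (default 1).
#' @return data.frame: start, end (step indices of the Z run), length,
#'   junction_5p, junction_3p (step index or NA).
#' @export
detect_junctions <- function(labels, min_z = .default_thresholds$min_z) {
  lab <- as.character(labels)
  n <- length(lab)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  zi <- which(r$values == "Z" & r$lengths >= min_z)
  if (length(zi) == 0) {
    return(data.frame(start = integer(0), end = integer(0), length = integer(0),
                      junction_5p = integer(0), junction_3p = integer(0)))
  }
  data.frame(
    start = starts[zi], end = ends[zi], length = r$lengths[zi],
    junction_5p = ifelse(starts[zi] > 1 & lab[pmax(1, starts[zi] - 1)] == "junction",
                         starts[zi] - 1, NA),
    junction_3p = ifelse(ends[zi] < n & lab[pmin(n, ends[zi] + 1)] == "junction",
                         ends[zi] + 1, NA))
}

#' Z-stretch growth profile over trajectory windows
#'
#' @param window_labels List (one per window) of step label vectors.
#' @param window_twists Optional list of per-step twists (deg) matching
#'   `window_labels`; used for the unwinding score
#'   `sum(max(0, 36 - twist))`.
#' @return data.frame: window, z_steps, unwinding.
#' @export
track_z_stretch <- function(window_labels, window_twists = NULL) {
  if (length(window_labels) < 2) {
    stop("track_z_stretch needs at least two windows", call. = FALSE)
  }
  nz <- vapply(window_labels, function(l) sum(as.character(l) == "Z"), 0L)
  unw <- if (is.null(window_twists)) {
    rep(NA_real_, length(window_labels))
  } else {
    vapply(window_twists, function(tw) sum(pmax(0, 36 - tw), na.rm = TRUE), 0)
  }
  data.frame(window = seq_along(window_labels), z_steps = nz, unwinding = unw)
}

# candidate donor...acceptor atom-name sets; first atom on base 1, second on
# base 2
.registry_candidates <- list(
  "A.A" = list(c("N1", "N6"), c("N6", "N1"), c("N6", "N7"), c("N7", "N6"),
               c("N3", "N6"), c("N6", "N3")),
  "C.G" = list(c("O2", "N2"), c("N3", "N1"), c("N4", "O6")),
  "G.C" = list(c("N2", "O2"), c("N1", "N3"), c("O6", "N4")),
  "A.T" = list(c("N6", "O4"), c("N1", "N3")),
  "T.A" = list(c("O4", "N6"), c("N3", "N1")))

#' Hydrogen-bond registry of a base pair
#'
#' Evaluates the candidate donor-acceptor atom sets of the pair type and
#' returns those with a heavy-atom distance at or below the cutoff
#' (3.4 A by default, no angle term).
#'
#' @param pair A `base_pair`, or a `duplex` together with `pos`.
#' @param pos Strand-1 position identifying the pair when `pair` is a
#'   duplex.
#' @param frame Optional frame index for trajectories.
#' @param cutoff Heavy-atom distance cutoff (A).
#' @return Character vector of registry labels such as `"N6...N1"`, or
#'   `"none"`; attribute `"distances"` carries all candidate distances.
#' @export
classify_hbond_registry <- function(pair, pos = NULL, frame = NULL,
                                    cutoff = .default_thresholds$hbond_cutoff_A) {
  if (inherits(pair, "duplex") && !is.null(pos)) {
    d <- pair
    xyz <- if (is.null(frame)) d$xyz else d$frames[[frame]]
    p2 <- d$pairing$pos2[d$pairing$pos1 == pos]
    rt <- residue_table(d)
    r1 <- rt$resid[rt$strand == 1 & rt$pos == pos]
    r2 <- rt$resid[rt$strand == 2 & rt$pos == p2]
    get1 <- function(at) atom_xyz(d, 1, pos, at, xyz)
    get2 <- function(at) atom_xyz(d, 2, p2, at, xyz)
  } else {
    r1 <- pair$resid1
    r2 <- pair$resid2
    get1 <- function(at) if (at %in% rownames(pair$base1)) pair$base1[at, ] else NULL
    get2 <- function(at) if (at %in% rownames(pair$base2)) pair$base2[at, ] else NULL
  }
  key <- paste(r1, r2, sep = ".")
  cand <- .registry_candidates[[key]]
  if (is.null(cand)) {
    stop("type error: no registry candidates for pair ", r1, "...", r2,
         call. = FALSE)
  }
  dists <- vapply(cand, function(b) {
    a1 <- get1(b[1]); a2 <- get2(b[2])
    if (is.null(a1) || is.null(a2)) NA_real_ else vnorm(a1 - a2)
  }, 0)
  names(dists) <- vapply(cand, function(b) paste0(b[1], "...", b[2]), "")
  hit <- names(dists)[!is.na(dists) & dists <= cutoff]
  out <- if (length(hit) == 0) "none" else hit
  attr(out, "distances") <- dists
  out
}

# circular unwrap: cumulative series with minimal angular increments
unwrap_angles <- function(x) {
  d <- diff(x)
  d <- ((d + 180) %% 360) - 180
  cumsum(c(x[1], d))
}

#' Detect a glycosyl base flip in a chi time series
#'
#' The series is unwrapped on the circle; a flip is a net unwrapped change
#' of at least `min_deg` between the stable start and end.  The pathway is
#' `cis_path` when the unwrapped trajectory crosses 0 deg (mod 360) and
#' `trans_path` when it crosses 180 deg.
#'
#' @param chi Numeric chi series (degrees).
#' @param times Optional frame times (ps) used in the returned span.
#' @param min_deg Flip magnitude threshold (default 100).
#' @return `NULL` when no flip; else list: kind = "flip", pathway, from, to,
#'   net (deg), span (index or time range).
#' @export
detect_flip <- function(chi, times = NULL,
                        min_deg = .default_thresholds$flip_min_deg) {
  if (length(chi) < 3) stop("chi series too short", call. = FALSE)
  u <- unwrap_angles(chi)
  k <- max(1, min(3, floor(length(u) / 5)))
  start <- mean(u[seq_len(k)])
  end <- mean(u[seq(length(u) - k + 1, length(u))])
  net <- end - start
  if (abs(net) < min_deg) return(NULL)
  crossed <- function(mark) {
    marks <- mark + 360 * (-3:3)
    lo <- min(start, end); hi <- max(start, end)
    any(marks > lo & marks < hi)
  }
  pathway <- if (crossed(0)) "cis_path" else if (crossed(180)) "trans_path" else NA
  span <- if (is.null(times)) c(1, length(chi)) else range(times)
  list(kind = "flip", pathway = pathway, from = chi[1] %% 360,
       to = chi[length(chi)] %% 360, net = net, span = span)
}

#' Lateral displacement of a partner base from the helical stack
#'
#' Distance of the strand-2 base centroid (ring atoms) from the line
#' joining the midpoints of the two flanking pairs.  For trajectories the
#' excursion is reported relative to a reference frame (default the first),
#' since even an intact stacked base sits at some distance from that line;
#' set `reference = NULL` for the raw distance.
#'
#' @param d A `duplex` (or trajectory with `frame`).
#' @param pos Strand-1 position of the pair of interest (not terminal).
#' @param frame Optional frame index.
#' @param reference Reference frame index subtracted from the raw distance
#'   (trajectories only; `NULL` for raw).
#' @return Displacement in Angstrom (raw, or excursion floored at 0).
#' @export
lateral_displacement <- function(d, pos, frame = NULL, reference = 1) {
  raw <- function(xyz) {
    m1 <- colMeans(pair_c1_matrix(d, pos - 1, xyz))
    m2 <- colMeans(pair_c1_matrix(d, pos + 1, xyz))
    p2 <- d$pairing$pos2[d$pairing$pos1 == pos]
    rt <- residue_table(d)
    base2 <- rt$resid[rt$strand == 2 & rt$pos == p2]
    idx <- vapply(.ring_atoms[[base2]], function(at) atom_index(d, 2, p2, at), 1L)
    cen <- colMeans(xyz[idx, , drop = FALSE])
    axis <- vunit(m2 - m1)
    v <- cen - m1
    vnorm(v - sum(v * axis) * axis)
  }
  if (pos <= 1 || pos >= d$n) {
    stop("boundary error: flanking pairs unavailable", call. = FALSE)
  }
  xyz <- if (is.null(frame)) d$xyz else d$frames[[frame]]
  out <- raw(xyz)
  if (!is.null(frame) && !is.null(reference) && inherits(d, "duplex_trajectory")) {
    out <- max(0, out - raw(d$frames[[reference]]))
  }
  out
}

#' Detect base extrusion events
#'
#' Extrusion requires, simultaneously and for at least `dwell` consecutive
#' frames, a lost hydrogen-bond registry (`"none"`) and a base-centroid
#' lateral displacement above `disp_min`.
#'
#' @param registry Character vector per frame (`"none"` or a registry
#'   label; multi-bond frames may be collapsed to any non-"none" value).
#' @param displacement Numeric lateral displacements (A) per frame.
#' @param times Optional frame times (ps).
#' @param dwell Minimum run length in frames (default 5).
#' @param disp_min Displacement threshold in A (default 2.5).
#' @return data.frame of events: frame_start, frame_end (and time_start /
#'   time_end when `times` given); zero rows when none.
#' @export
detect_extrusion <- function(registry, displacement, times = NULL,
                             dwell = .default_thresholds$extrusion_dwell,
                             disp_min = .default_thresholds$extrusion_disp_A) {
  if (length(registry) != length(displacement)) {
    stop("alignment error: series lengths differ", call. = FALSE)
  }
  hit <- registry == "none" & displacement > disp_min
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= dwell)
  out <- data.frame(kind = rep("extrusion", length(keep)),
                    frame_start = starts[keep], frame_end = ends[keep])
  if (!is.null(times) && nrow(out) > 0) {
    out$time_start <- times[out$frame_start]
    out$time_end <- times[out$frame_end]
  }
  out
}

base_plane_normal <- function(xyz, idx) {
  M <- sweep(xyz[idx, , drop = FALSE], 2, colMeans(xyz[idx, , drop = FALSE]))
  svd(M)$v[, 3]
}

#' Detect intercalated stacking of a mismatched pair
#'
#' TRUE when the two mismatched bases are near-parallel (interplanar angle
#' below `stack_angle`), stacked (centroid separation below `stack_dist`),
#' and the mismatch C1'...C1' vector is rotated away from the mean flanking
#' C1'...C1' vector by more than `perp_angle`.
#'
#' @param d A `duplex` (or trajectory with `frame`).
#' @param pos Strand-1 position of the mismatched pair (not terminal).
#' @param frame Optional frame index.
#' @param stack_angle,stack_dist,perp_angle Thresholds (deg, A, deg).
#' @return Logical; attributes carry the three measured quantities.
#' @export
detect_intercalation <- function(d, pos, frame = NULL,
                                 stack_angle = .default_thresholds$stack_angle_deg,
                                 stack_dist = .default_thresholds$stack_dist_A,
                                 perp_angle = .default_thresholds$perp_angle_deg) {
  xyz <- if (is.null(frame)) d$xyz else d$frames[[frame]]
  if (pos <= 1 || pos >= d$n) {
    stop("boundary error: flanking pairs unavailable", call. = FALSE)
  }
  p2 <- d$pairing$pos2[d$pairing$pos1 == pos]
  rt <- residue_table(d)
  b1 <- rt$resid[rt$strand == 1 & rt$pos == pos]
  b2 <- rt$resid[rt$strand == 2 & rt$pos == p2]
  i1 <- vapply(.ring_atoms[[b1]], function(at) atom_index(d, 1, pos, at), 1L)
  i2 <- vapply(.ring_atoms[[b2]], function(at) atom_index(d, 2, p2, at), 1L)
  n1 <- base_plane_normal(xyz, i1)
  n2 <- base_plane_normal(xyz, i2)
  inter <- acos(pmin(1, abs(sum(n1 * n2)))) * 180 / pi
  sep <- vnorm(colMeans(xyz[i1, , drop = FALSE]) - colMeans(xyz[i2, , drop = FALSE]))
  vm <- pair_c1_matrix(d, pos, xyz)
  vf1 <- pair_c1_matrix(d, pos - 1, xyz)
  vf2 <- pair_c1_matrix(d, pos + 1, xyz)
  v <- vm[2, ] - vm[1, ]
  vf <- (vf1[2, ] - vf1[1, ]) + (vf2[2, ] - vf2[1, ])
  rot <- acos(pmin(1, abs(sum(vunit(v) * vunit(vf))))) * 180 / pi
  out <- inter < stack_angle && sep < stack_dist && rot > perp_angle
  attr(out, "interplanar_deg") <- inter
  attr(out, "centroid_sep_A") <- sep
  attr(out, "vector_rotation_deg") <- rot
  out
}
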