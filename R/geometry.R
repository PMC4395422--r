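# Core geometric observables: dihedrals, per-residue torsion sets,
# C1'...C1'-vector helical twist, groove widths, hydrogen-bond distances,
# RMSD and windowed average structures, plus RMSD ensemble segmentation.

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention (clockwise positive looking from p2 to p3), mapped
#' to \code{[0, 360)} degrees.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees in `[0, 360)`.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-10 || vnorm(b2) < 1e-10 || vnorm(b3) < 1e-10) {
    stop("undefined dihedral: consecutive points coincide", call. = FALSE)
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-8 || vnorm(n2) < 1e-8) {
    stop("undefined dihedral: three consecutive points are colinear",
         call. = FALSE)
  }
  y <- sum(cross3(n1, n2) * vunit(b2))
  ang <- atan2(y, sum(n1 * n2)) * 180 / pi
  ang %% 360
}

# torsion atom chains; i-1 / i+1 refer to the preceding / following residue
# on the same strand (5'->3')
.torsion_defs <- list(
  alpha = list(c(-1, "O3'"), c(0, "P"), c(0, "O5'"), c(0, "C5'")),
  beta  = list(c(0, "P"), c(0, "O5'"), c(0, "C5'"), c(0, "C4'")),
  gamma = list(c(0, "O5'"), c(0, "C5'"), c(0, "C4'"), c(0, "C3'")),
  delta = list(c(0, "C5'"), c(0, "C4'"), c(0, "C3'"), c(0, "O3'")),
  epsilon = list(c(0, "C4'"), c(0, "C3'"), c(0, "O3'"), c(1, "P")),
  zeta  = list(c(0, "C3'"), c(0, "O3'"), c(1, "P"), c(1, "O5'"))
)

#' Backbone and glycosyl torsions of every residue
#'
#' Standard nucleic-acid definitions: alpha O3'(i-1)-P-O5'-C5';
#' beta P-O5'-C5'-C4'; gamma O5'-C5'-C4'-C3'; delta C5'-C4'-C3'-O3';
#' epsilon C4'-C3'-O3'-P(i+1); zeta C3'-O3'-P(i+1)-O5'(i+1); chi
#' O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2 for pyrimidines.  Angles in
#' degrees in `[0, 360)`; entries involving atoms beyond the chain termini
#' (or missing atoms, which additionally warn) are `NA`.
#'
#' @param x A `duplex` (or trajectory; see `frame`).
#' @param frame Frame index when `x` is a trajectory; default the stored
#'   coordinates.
#' @return data.frame: strand, pos, label, resid, alpha ... zeta, chi.
#' @export
compute_torsions <- function(x, frame = NULL) {
  xyz <- if (is.null(frame)) x$xyz else x$frames[[frame]]
  rt <- residue_table(x)
  out <- rt[, c("strand", "pos", "label", "resid")]
  for (nm in c(names(.torsion_defs), "chi")) out[[nm]] <- NA_real_
  warned <- character(0)
  for (r in seq_len(nrow(rt))) {
    s <- rt$strand[r]; p <- rt$pos[r]; base <- rt$resid[r]
    nmax <- max(rt$pos[rt$strand == s])
    for (nm in names(.torsion_defs)) {
      def <- .torsion_defs[[nm]]
      pts <- vector("list", 4)
      ok <- TRUE
      terminal <- FALSE
      for (k in 1:4) {
        off <- as.integer(def[[k]][1])
        pp <- p + off
        if (pp < 1 || pp > nmax) { terminal <- TRUE; ok <- FALSE; break }
        v <- atom_xyz(x, s, pp, def[[k]][2], xyz)
        if (is.null(v)) { ok <- FALSE; break }
        pts[[k]] <- v
      }
      if (ok) {
        out[[nm]][r] <- dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
      } else if (!terminal) {
        warned <- c(warned, paste0(rt$label[r], ":", nm))
      }
    }
    ch <- list(atom_xyz(x, s, p, "O4'", xyz), atom_xyz(x, s, p, "C1'", xyz),
               atom_xyz(x, s, p, .glyco_n[[base]], xyz),
               atom_xyz(x, s, p, .chi_ref[[base]], xyz))
    if (!any(vapply(ch, is.null, TRUE))) {
      out$chi[r] <- dihedral(ch[[1]], ch[[2]], ch[[3]], ch[[4]])
    } else {
      warned <- c(warned, paste0(rt$label[r], ":chi"))
    }
  }
  if (length(warned) > 0) {
    warning("torsions skipped for missing atoms: ",
            paste(warned, collapse = ", "), call. = FALSE)
  }
  out
}

#' Helical twist between two base pairs from their C1' atoms
#'
#' For each pair the in-pair vector runs from the strand-1 C1' to the
#' strand-2 C1'.  The local step axis `h` is the unit vector joining the two
#' pair midpoints; the twist is the signed angle from the projection of the
#' first pair vector onto the plane perpendicular to `h` to the projection
#' of the second, positive for a right-handed rotation about `h`.
#'
#' The step axis flips direction when the arguments are swapped, so the
#' twist of a step is the same seen from either end (a screw's handedness
#' does not depend on the viewing direction).  To compare steps traversed
#' in opposite directions against one fixed reference, pass an explicit
#' `axis`; with a fixed axis, swapping the pairs negates the twist.
#'
#' @param pair_i,pair_j 2 x 3 matrices; row 1 the strand-1 C1', row 2 the
#'   strand-2 C1'.
#' @param axis Optional fixed axis direction overriding the
#'   midpoint-to-midpoint default.
#' @return Signed twist in degrees in `(-180, 180]`.
#' @export
c1c1_twist <- function(pair_i, pair_j, axis = NULL) {
  mi <- colMeans(pair_i)
  mj <- colMeans(pair_j)
  h <- if (is.null(axis)) mj - mi else axis
  if (vnorm(mj - mi) < 1e-8) {
    stop("undefined twist: coincident pair midpoints", call. = FALSE)
  }
  h <- vunit(h)
  vi <- pair_i[2, ] - pair_i[1, ]
  vj <- pair_j[2, ] - pair_j[1, ]
  pi_ <- vi - sum(vi * h) * h
  pj_ <- vj - sum(vj * h) * h
  if (vnorm(pi_) < 1e-8 || vnorm(pj_) < 1e-8) {
    stop("undefined twist: pair vector parallel to the step axis", call. = FALSE)
  }
  ang <- atan2(sum(cross3(pi_, pj_) * h), sum(pi_ * pj_)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

pair_c1_matrix <- function(x, k, xyz = x$xyz) {
  pr <- x$pairing
  p2 <- pr$pos2[pr$pos1 == k]
  a <- atom_xyz(x, 1, k, "C1'", xyz)
  b <- atom_xyz(x, 2, p2, "C1'", xyz)
  if (is.null(a) || is.null(b)) return(NULL)
  rbind(a, b)
}

#' Per-step C1'...C1' twist along a duplex
#'
#' @param x A `duplex`.
#' @param frame Optional frame index for trajectories.
#' @return data.frame: step (1-based index of the 5' pair), step_label
#'   (e.g. "C_7A_8"), twist (deg), rise (A, midpoint separation),
#'   c1c1_i / c1c1_j (C1'...C1' distances of the flanking pairs, A).
#' @export
step_twists <- function(x, frame = NULL) {
  xyz <- if (is.null(frame)) x$xyz else x$frames[[frame]]
  rt <- residue_table(x)
  lab1 <- rt$label[rt$strand == 1][order(rt$pos[rt$strand == 1])]
  n <- x$n
  out <- data.frame(step = seq_len(n - 1),
                    step_label = paste0(lab1[-n], lab1[-1]),
                    twist = NA_real_, rise = NA_real_,
                    c1c1_i = NA_real_, c1c1_j = NA_real_)
  for (k in seq_len(n - 1)) {
    pi_ <- pair_c1_matrix(x, k, xyz)
    pj_ <- pair_c1_matrix(x, k + 1, xyz)
    if (is.null(pi_) || is.null(pj_)) next
    out$twist[k] <- c1c1_twist(pi_, pj_)
    out$rise[k] <- vnorm(colMeans(pj_) - colMeans(pi_))
    out$c1c1_i[k] <- vnorm(pi_[2, ] - pi_[1, ])
    out$c1c1_j[k] <- vnorm(pj_[2, ] - pj_[1, ])
  }
  out
}

#' Minor and major groove widths from cross-strand phosphate distances
#'
#' Raw P-P distances (no van der Waals subtraction):
#' `minor(i) = |P(s1, i) - P(s2, partner(i) - 3)|` and
#' `major(i) = |P(s1, i) - P(s2, partner(i) + 4)|`, with entries absent
#' where the offset runs off the chain.  The offsets are a declared
#' convention of this package.
#'
#' @param x A `duplex`.
#' @param frame Optional frame index.
#' @return data.frame: pos, label, minor, major (Angstrom, `NA` if absent).
#' @export
groove_widths <- function(x, frame = NULL) {
  xyz <- if (is.null(frame)) x$xyz else x$frames[[frame]]
  rt <- residue_table(x)
  lab1 <- rt$label[rt$strand == 1][order(rt$pos[rt$strand == 1])]
  pr <- x$pairing
  out <- data.frame(pos = seq_len(x$n), label = lab1,
                    minor = NA_real_, major = NA_real_)
  for (i in seq_len(x$n)) {
    p1 <- atom_xyz(x, 1, i, "P", xyz)
    if (is.null(p1)) next
    partner <- pr$pos2[pr$pos1 == i]
    for (side in c("minor", "major")) {
      off <- if (side == "minor") -3L else 4L
      j <- partner + off
      if (j < 1 || j > x$n) next
      p2 <- atom_xyz(x, 2, j, "P", xyz)
      if (is.null(p2)) next
      out[[side]][i] <- vnorm(p1 - p2)
    }
  }
  out
}

#' Hydrogen-bond (donor...acceptor) distance profiles
#'
#' @param x A `duplex` or `duplex_trajectory`.
#' @param specs Character vector of atom-pair specs,
#'   `"donor(LABEL)-acceptor(LABEL)"`, e.g. `"O2(C_7)-N2(G_24)"`.
#' @return data.frame with one row per (spec, frame): spec, time_ps,
#'   distance (A).
#' @export
hbond_distances <- function(x, specs) {
  frames <- if (inherits(x, "duplex_trajectory")) x$frames else list(x$xyz)
  times <- if (inherits(x, "duplex_trajectory")) x$times else 0
  parsed <- lapply(specs, function(sp) {
    halves <- strsplit(sp, "(?<=\\))\\s*-\\s*", perl = TRUE)[[1]]
    if (length(halves) != 2) {
      stop("cannot parse hydrogen-bond spec '", sp, "'", call. = FALSE)
    }
    c(resolve_spec(x, halves[1]), resolve_spec(x, halves[2]))
  })
  out <- expand.grid(spec = specs, time_ps = times, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$distance <- NA_real_
  row <- 0L
  for (t in seq_along(frames)) {
    for (s in seq_along(specs)) {
      idx <- parsed[[s]]
      d <- vnorm(frames[[t]][idx[1], ] - frames[[t]][idx[2], ])
      out$distance[out$spec == specs[s] & out$time_ps == times[t]] <- d
      row <- row + 1L
    }
  }
  out[order(match(out$spec, specs), out$time_ps), c("spec", "time_ps", "distance")]
}

#' Least-squares superposed RMSD
#'
#' Optimal rotation/translation (Kabsch) of `frame` onto `reference` over
#' the selected atoms, then root-mean-square deviation.
#'
#' @param frame,reference n x 3 coordinate matrices.
#' @param sel Optional integer vector of row indices used both for fitting
#'   and for the deviation (default: all rows).
#' @return RMSD in Angstrom.
#' @export
rmsd_fit <- function(frame, reference, sel = NULL) {
  if (is.null(sel)) sel <- seq_len(nrow(reference))
  if (nrow(frame) != nrow(reference)) {
    stop("selection error: coordinate sets differ in size", call. = FALSE)
  }
  P <- frame[sel, , drop = FALSE]
  Q <- reference[sel, , drop = FALSE]
  if (nrow(P) != nrow(Q)) {
    stop("selection error: selections differ in size", call. = FALSE)
  }
  tr <- kabsch(P, Q)
  Pf <- xform(P, tr$R, tr$t)
  sqrt(mean(rowSums((Pf - Q)^2)))
}

# default heavy-atom selection excluding `exclude_termini` pairs at each end
rmsd_selection <- function(x, exclude_termini = 0) {
  a <- x$atoms
  keep <- a$pos > exclude_termini & a$pos <= (x$n - exclude_termini)
  which(keep)
}

#' Time vs RMSD profile of a trajectory
#'
#' @param traj A `duplex_trajectory`.
#' @param reference Reference xyz matrix (default: first frame).
#' @param exclude_termini Number of base pairs ignored at each duplex end
#'   (default 0; set 2 to suppress end fraying).
#' @return data.frame: time_ps, rmsd.
#' @export
rmsd_profile <- function(traj, reference = NULL, exclude_termini = 0) {
  if (is.null(reference)) reference <- traj$frames[[1]]
  sel <- rmsd_selection(traj, exclude_termini)
  data.frame(
    time_ps = traj$times,
    rmsd = vapply(traj$frames, rmsd_fit, 0, reference = reference, sel = sel))
}

#' Average structure over a time window
#'
#' Frames with `start <= t < end` (half-open, ps) are superposed onto the
#' first frame in the window and averaged.
#'
#' @param traj A `duplex_trajectory`.
#' @param window Numeric length-2, `c(start, end)` in ps.
#' @return xyz coordinate matrix.
#' @export
average_structure <- function(traj, window) {
  sel <- which(traj$times >= window[1] & traj$times < window[2])
  if (length(sel) == 0) {
    stop("window error: no frames in [", window[1], ", ", window[2], ") ps",
         call. = FALSE)
  }
  ref <- traj$frames[[sel[1]]]
  acc <- matrix(0, nrow(ref), 3)
  for (k in sel) {
    f <- traj$frames[[k]]
    tr <- kabsch(f, ref)
    acc <- acc + xform(f, tr$R, tr$t)
  }
  acc / length(sel)
}

#' Segment an RMSD series into ensembles by greedy change-point splitting
#'
#' Recursively splits at the point maximizing the between-segment mean
#' separation; a split is accepted when `|delta mean|` exceeds
#' `max(0.5, pooled sd)`.  Segments shorter than `min_dwell` are merged into
#' their closer neighbour.
#'
#' @param series Numeric RMSD series (A).
#' @param min_dwell Minimum segment length in samples (default 10).
#' @return data.frame: start, end (inclusive indices), mean, sd.
#' @export
segment_rmsd_ensembles <- function(series, min_dwell = 10) {
  n <- length(series)
  split_rec <- function(lo, hi) {
    len <- hi - lo + 1
    if (len < 2 * min_dwell) return(c(lo))
    best <- NULL
    for (cut in (lo + min_dwell - 1):(hi - min_dwell)) {
      a <- series[lo:cut]
      b <- series[(cut + 1):hi]
      dm <- abs(mean(a) - mean(b))
      if (is.null(best) || dm > best$dm) best <- list(cut = cut, dm = dm, a = a, b = b)
    }
    pooled <- sqrt(((length(best$a) - 1) * stats::var(best$a) +
                    (length(best$b) - 1) * stats::var(best$b)) /
                   (length(best$a) + length(best$b) - 2))
    if (best$dm > max(0.5, pooled)) {
      c(split_rec(lo, best$cut), split_rec(best$cut + 1, hi))
    } else {
      c(lo)
    }
  }
  starts <- split_rec(1, n)
  ends <- c(starts[-1] - 1, n)
  # merge short segments into the neighbour with the closer mean
  repeat {
    lens <- ends - starts + 1
    short <- which(lens < min_dwell)
    if (length(short) == 0 || length(starts) == 1) break
    k <- short[1]
    if (k == 1) {
      starts <- starts[-2]; ends <- ends[-1]
    } else if (k == length(starts)) {
      starts <- starts[-k]; ends <- ends[-(k - 1)]
    } else {
      m <- mean(series[starts[k]:ends[k]])
      prev_m <- mean(series[starts[k - 1]:ends[k - 1]])
      next_m <- mean(series[starts[k + 1]:ends[k + 1]])
      if (abs(m - prev_m) <= abs(m - next_m)) {
        starts <- starts[-k]; ends <- ends[-(k - 1)]
      } else {
        starts <- starts[-(k + 1)]; ends <- ends[-k]
      }
    }
  }
  data.frame(
    start = starts, end = ends,
    mean = vapply(seq_along(starts), function(k) mean(series[starts[k]:ends[k]]), 0),
    sd = vapply(seq_along(starts), function(k) stats::sd(series[starts[k]:ends[k]]), 0))
}
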