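# Idealized planar nucleobase templates and small geometric utilities.
#
# Base heavy-atom coordinates follow the standard nucleic-acid reference
# frame: the base lies in the xy-plane (z = 0) with its Watson-Crick edge
# facing -y; a Watson-Crick partner is generated by a 180 deg rotation about
# the x-axis.  Ring bond lengths come out at 1.31-1.46 A and the WC
# donor-acceptor distances of pairs built from these templates fall in
# 2.8-3.0 A, which is what downstream hydrogen-bond checks assume.

.base_templates <- local({
  mk <- function(m) {
    out <- cbind(m, 0)
    colnames(out) <- c("x", "y", "z")
    out
  }
  list(
    A = mk(rbind(
      "C1'" = c(-2.479, 5.346),
      N9 = c(-1.291, 4.498), C8 = c(0.024, 4.897), N7 = c(0.877, 3.902),
      C5 = c(0.071, 2.771), C6 = c(0.369, 1.398), N6 = c(1.611, 0.909),
      N1 = c(-0.668, 0.532), C2 = c(-1.912, 1.023), N3 = c(-2.320, 2.290),
      C4 = c(-1.267, 3.124))),
    G = mk(rbind(
      "C1'" = c(-2.477, 5.399),
      N9 = c(-1.289, 4.551), C8 = c(0.023, 4.962), N7 = c(0.870, 3.969),
      C5 = c(0.071, 2.833), C6 = c(0.424, 1.460), O6 = c(1.554, 0.955),
      N1 = c(-0.700, 0.641), C2 = c(-1.999, 1.087), N2 = c(-2.949, 0.139),
      N3 = c(-2.342, 2.364), C4 = c(-1.265, 3.177))),
    C = mk(rbind(
      "C1'" = c(-2.477, 5.402),
      N1 = c(-1.285, 4.542), C2 = c(-1.472, 3.158), O2 = c(-2.628, 2.709),
      N3 = c(-0.391, 2.344), C4 = c(0.837, 2.868), N4 = c(1.875, 2.027),
      C5 = c(1.056, 4.275), C6 = c(-0.023, 5.068))),
    T = mk(rbind(
      "C1'" = c(-2.481, 5.354),
      N1 = c(-1.284, 4.500), C2 = c(-1.462, 3.135), O2 = c(-2.562, 2.608),
      N3 = c(-0.298, 2.407), C4 = c(0.994, 2.897), O4 = c(1.944, 2.119),
      C5 = c(1.106, 4.338), C7 = c(2.466, 4.961), C6 = c(-0.024, 5.057)))
  )
})

.purines <- c("A", "G")
.pyrimidines <- c("C", "T")
.complement <- c(A = "T", T = "A", G = "C", C = "G")

# glycosyl nitrogen and the chi reference atom on the base side
.glyco_n <- c(A = "N9", G = "N9", C = "N1", T = "N1")
.chi_ref <- c(A = "C4", G = "C4", C = "C2", T = "C2")

# per-pair y-shift (A) tightening WC donor-acceptor distances into 2.8-3.0
.wc_shift <- c(A = 0.07, T = 0.07, G = 0.05, C = 0.05)

.ring_atoms <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6")
)

.vdw_radius <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80)

#' Idealized planar base template
#'
#' Returns heavy-atom coordinates (base ring plus exocyclic hydrogen-bonding
#' atoms and C1') of one nucleobase in the standard reference frame: base in
#' the xy-plane, Watson-Crick edge toward -y.
#'
#' @param base One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return Numeric matrix with rownames giving atom names and columns
#'   `x`, `y`, `z` in Angstrom.
#' @export
base_template <- function(base) {
  base <- normalize_residue_name(base)
  .base_templates[[base]]
}

#' Map residue name dialects to one-letter nucleotide codes
#'
#' Accepts both `A/C/G/T` and the PDB deoxy names `DA/DC/DG/DT`.
#'
#' @param x Character vector of residue names.
#' @return Character vector of one-letter codes.
#' @export
normalize_residue_name <- function(x) {
  up <- toupper(trimws(x))
  up <- sub("^D", "", up)
  bad <- !(up %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    stop("unsupported residue name(s): ", paste(unique(x[bad]), collapse = ", "),
         " (only A/C/G/T and DA/DC/DG/DT nucleotides are handled)",
         call. = FALSE)
  }
  up
}

## ---- small vector helpers (internal) --------------------------------------

vnorm <- function(v) sqrt(sum(v * v))
vunit <- function(v) v / vnorm(v)

rot_z <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         nrow = 3, byrow = TRUE)
}

# rotation matrix about arbitrary axis (Rodrigues)
rot_axis <- function(axis, theta_deg) {
  u <- vunit(axis)
  th <- theta_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# apply rotation R (about origin) then translation t to an n x 3 matrix
xform <- function(m, R = diag(3), t = c(0, 0, 0)) {
  out <- m %*% t(R)
  out[, 1] <- out[, 1] + t[1]
  out[, 2] <- out[, 2] + t[2]
  out[, 3] <- out[, 3] + t[3]
  out
}

# 180 deg rotation about x: maps a base template to its Watson-Crick partner
# orientation (proper rotation in 3D)
flip_x <- function(m) {
  m[, 2] <- -m[, 2]
  m[, 3] <- -m[, 3]
  m
}

# in-plane reflection of the base across its glycosidic C1'-N bond: the
# planar idealization of rotating the base ~180 deg about the glycosidic
# bond (anti <-> syn).  C1' is on the axis and does not move.
glyco_flip <- function(m, base) {
  p0 <- m["C1'", ]
  ax <- vunit(m[.glyco_n[[base]], ] - p0)
  idx <- setdiff(rownames(m), "C1'")
  for (i in idx) {
    v <- m[i, ] - p0
    m[i, ] <- 2 * sum(v * ax) * ax - v + p0
  }
  m
}

# Kabsch least-squares superposition: rotation R and translation t mapping
# point set P onto Q (rows are corresponding atoms)
kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cq - c(R %*% cp))
}

# NeRF atom placement: position atom D given bonded chain C-B-A with bond
# length |DC|, angle D-C-B (deg) and dihedral D-C-B-A (deg)
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  bc <- vunit(c - b)
  n <- vunit(cross3(b - a, bc))
  m <- cross3(n, bc)
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
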