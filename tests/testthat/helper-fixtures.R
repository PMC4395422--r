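# Shared fixtures and independent oracles for the test suite.

# independent dihedral oracle: explicit plane-normal arithmetic, written
# without reference to the package implementation
oracle_dihedral <- function(p1, p2, p3, p4) {
  n1 <- pracma_cross_(p2 - p1, p3 - p2)   # normal of plane (p1,p2,p3)
  n2 <- pracma_cross_(p3 - p2, p4 - p3)   # normal of plane (p2,p3,p4)
  axis <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  x <- sum(n1 * n2)
  y <- sum(pracma_cross_(n1, n2) * axis)
  (atan2(y, x) * 180 / pi) %% 360
}
pracma_cross_ <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# place a 4th point realizing a chosen dihedral by explicit axis rotation
# (inverse-rotation construction, independent of the package's NeRF code)
oracle_place_dihedral <- function(p1, p2, p3, target_deg, bond = 1.5,
                                  angle_deg = 110) {
  axis <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  # reference direction: p2 -> p1 component perpendicular to the axis
  ref <- (p1 - p2) - sum((p1 - p2) * axis) * axis
  ref <- ref / sqrt(sum(ref^2))
  th <- target_deg * pi / 180       # sign chosen to realize the IUPAC sense
  perp <- pracma_cross_(axis, ref)
  dir_ <- cos(th) * ref + sin(th) * perp
  ang <- angle_deg * pi / 180
  p3 + bond * (-cos(ang) * axis + sin(ang) * dir_)
}

random_rigid_motion <- function() {
  ax <- stats::rnorm(3)
  R <- rotation_about_(ax, stats::runif(1, 0, 360))
  list(R = R, t = stats::rnorm(3, 0, 10))
}
rotation_about_ <- function(axis, theta_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- theta_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
apply_motion <- function(m, mo) {
  out <- m %*% t(mo$R)
  sweep(out, 2, -mo$t)
}

# cached expensive fixtures (built once per test run)
fixture_env <- new.env()
fx <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}
fx_b15 <- function() fx("b15", function() build_b_duplex("CTGCTGCAGCTGCTG"))
fx_b15_mm <- function() fx("b15mm", function()
  build_b_duplex("CTGCTGCAGCTGCTG", mismatch = 8))
fx_zcg <- function() fx("zcg", function() build_z_duplex("CGCGCGCGCGCG"))
fx_gc <- function() fx("gc", function() build_wc_pair("G"))
fx_aa <- function() fx("aa", function() build_mismatch_pair("anti_anti"))
fx_sa <- function() fx("sa", function() build_mismatch_pair("syn_anti"))
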