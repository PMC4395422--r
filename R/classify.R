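# Conformer classification: glycosyl (chi) classes, gauche/trans wells,
# BI/BII/BIII backbone families and Z-form signatures, and occupancy
# fractions over trajectory windows.
#
# All bins are half-open [lo, hi) on the circle.  The chi bin edges beyond
# the classical anti range are a declared calibration of this package: every
# representative value used in the CAG-mismatch literature (250 anti,
# 79 +syn, 309 -syn, 287 high-anti) must land in its named class.  The anti
# lower edge sits at 170 deg (rather than 180) to tolerate thermal
# fluctuation of anti populations centred near 250.

.chi_bins_default <- list(
  cis = c(345, 15), plus_syn = c(15, 100), unassigned = c(100, 170),
  anti = c(170, 260), high_anti = c(260, 290), minus_syn = c(290, 345))

.well_bins_default <- list(
  g_plus = c(0, 120), trans = c(120, 240), g_minus = c(240, 360))

in_circular_bin <- function(angle, lo, hi) {
  a <- angle %% 360
  if (lo <= hi) a >= lo & a < hi else a >= lo | a < hi
}

#' Classify a glycosyl (chi) torsion
#'
#' Bins (half-open, degrees): cis \[345, 15), +syn \[15, 100),
#' unassigned \[100, 170), anti \[170, 260), high-anti \[260, 290),
#' -syn \[290, 345).
#'
#' @param chi Numeric vector of angles in degrees (any real; reduced mod
#'   360, so the negative notation -38 == 322 is accepted).
#' @param bins Optional named list overriding the bin edges.
#' @return factor with levels cis, plus_syn, anti, high_anti, minus_syn,
#'   unassigned.
#' @export
classify_chi <- function(chi, bins = .chi_bins_default) {
  lv <- c("cis", "plus_syn", "anti", "high_anti", "minus_syn", "unassigned")
  out <- rep("unassigned", length(chi))
  for (nm in names(bins)) {
    hit <- !is.na(chi) & in_circular_bin(chi, bins[[nm]][1], bins[[nm]][2])
    out[hit] <- nm
  }
  out[is.na(chi)] <- NA
  factor(out, levels = lv)
}

#' Classify a backbone torsion into gauche/trans wells
#'
#' g+ \[0, 120), trans \[120, 240), g- \[240, 360); half-open, so exact
#' multiples of 120 fall in the higher bin.
#'
#' @param angle Numeric vector, degrees (reduced mod 360).
#' @param bins Optional named list overriding the well edges.
#' @return factor with levels g_plus, trans, g_minus.
#' @export
classify_well <- function(angle, bins = .well_bins_default) {
  out <- rep(NA_character_, length(angle))
  for (nm in names(bins)) {
    hit <- !is.na(angle) & in_circular_bin(angle, bins[[nm]][1], bins[[nm]][2])
    out[hit] <- nm
  }
  factor(out, levels = c("g_plus", "trans", "g_minus"))
}

.b_families <- list(BI = c("trans", "g_minus", "g_minus"),
                    BII = c("g_minus", "trans", "g_minus"),
                    BIII = c("g_minus", "g_minus", "g_minus"))
.z_signatures <- list(ZI = c("g_minus", "g_plus", "g_plus", "trans"),
                      ZII = c("g_minus", "g_minus", "g_plus", "trans"),
                      ZIII = c("g_minus", "g_minus", "g_minus", "g_plus"))

#' Classify a dinucleotide-step backbone
#'
#' Step convention: epsilon and zeta come from residue i, alpha and gamma
#' from residue i+1 (step labels such as A_8G_9 attach alpha/gamma to G_9).
#' The B family is read from the (epsilon, zeta, alpha) well triple:
#' (t, g-, g-) BI, (g-, t, g-) BII, (g-, g-, g-) BIII, anything else
#' `other`.  The Z signature is read independently from the
#' (epsilon, zeta, alpha, gamma) quadruple: (g-, g+, g+, t) ZI,
#' (g-, g-, g+, t) ZII, (g-, g-, g-, g+) ZIII, else `none`.  BIII and ZIII
#' may co-occur.
#'
#' @param epsilon,zeta,alpha,gamma Angles in degrees; `NA` at chain termini.
#' @param bins Optional well bins (see [classify_well()]).
#' @return data.frame: b_family (BI/BII/BIII/other/unassigned) and
#'   z_signature (ZI/ZII/ZIII/none/unassigned).
#' @export
classify_step_backbone <- function(epsilon, zeta, alpha, gamma,
                                   bins = .well_bins_default) {
  n <- max(length(epsilon), length(zeta), length(alpha), length(gamma))
  epsilon <- rep_len(epsilon, n); zeta <- rep_len(zeta, n)
  alpha <- rep_len(alpha, n); gamma <- rep_len(gamma, n)
  we <- classify_well(epsilon, bins); wz <- classify_well(zeta, bins)
  wa <- classify_well(alpha, bins); wg <- classify_well(gamma, bins)
  b_family <- rep("other", n)
  z_signature <- rep("none", n)
  for (k in seq_len(n)) {
    if (anyNA(c(epsilon[k], zeta[k], alpha[k]))) {
      b_family[k] <- "unassigned"
    } else {
      tri <- c(as.character(we[k]), as.character(wz[k]), as.character(wa[k]))
      for (nm in names(.b_families)) {
        if (identical(tri, .b_families[[nm]])) b_family[k] <- nm
      }
    }
    if (anyNA(c(epsilon[k], zeta[k], alpha[k], gamma[k]))) {
      z_signature[k] <- "unassigned"
    } else {
      quad <- c(as.character(we[k]), as.character(wz[k]),
                as.character(wa[k]), as.character(wg[k]))
      for (nm in names(.z_signatures)) {
        if (identical(quad, .z_signatures[[nm]])) z_signature[k] <- nm
      }
    }
  }
  data.frame(
    b_family = factor(b_family, levels = c("BI", "BII", "BIII", "other", "unassigned")),
    z_signature = factor(z_signature, levels = c("ZI", "ZII", "ZIII", "none", "unassigned")))
}

#' Occupancy fractions of conformer classes
#'
#' Applies a classifier to every observation (residue x frame) and returns
#' the fraction of observations per class; fractions sum to 1 including the
#' unassigned class.
#'
#' @param values Numeric vector (or matrix, residues x frames) of angles.
#' @param classifier Classification function, default [classify_chi()].
#' @return data.frame: class, fraction.
#' @export
class_fractions <- function(values, classifier = classify_chi) {
  v <- as.numeric(values)
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    stop("selection error: no observations to classify", call. = FALSE)
  }
  cl <- classifier(v)
  tab <- table(cl) / length(v)
  data.frame(class = names(tab), fraction = as.numeric(tab))
}

#' Circular mean of angles in degrees
#'
#' @param x Angles in degrees (NA dropped).
#' @return Mean direction in `[0, 360)`, or `NA` if empty.
#' @export
circular_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  th <- x * pi / 180
  (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi) %% 360
}
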