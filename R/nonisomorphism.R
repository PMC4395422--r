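# Base-pair nonisomorphism: modeled pairs, anchored superposition, residual
# twist and radial difference.
#
# A `base_pair` holds two planar bases with named heavy atoms (ring atoms,
# exocyclic donors/acceptors, C1', and O4' so that chi is measurable):
#   $base1, $base2  coordinate matrices (rownames = atom names)
#   $resid1, $resid2  one-letter codes
#   $glycosyl  character(2), e.g. c("anti", "anti")
#   $hbonds    list of c(donor_atom_on_base2, acceptor_atom_on_base1)
#
# Mismatch construction.  The A...A pair cannot adopt Watson-Crick geometry
# (two purines overlap), so the modeled pair is produced by a small
# restrained minimization that mirrors restrained model building: both
# bases start at the canonical WC scaffold, each base may swing in-plane
# about its glycosidic nitrogen (C1' fixed), and the partner residue frame
# may rotate/translate against a harmonic restraint; the energy combines
# the declared hydrogen-bond distance (2.9 A), a soft per-element van der
# Waals exclusion (0.93 x radius sum) and the swing/frame restraints.
# Stiffnesses are package constants; results move by <2 deg / <0.2 A across
# a four-fold stiffness range, so the construction is effectively pinned by
# the clash geometry itself.

.pair_energy_k <- c(bond = 100, vdw = 100, swing = 0.02, frame_t = 2,
                    frame_r = 0.02, vdw_soft = 0.93)

# 1-3 neighbours used to exempt atoms adjacent to a declared hydrogen bond
# from the vdW exclusion
.hb_neighbours <- list(N1 = c("C2", "C6"), N6 = "C6", N7 = c("C5", "C8"),
                       N3 = c("C2", "C4"), O6 = "C6", N2 = "C2",
                       O2 = "C2", N4 = "C4", O4 = "C4")

chi_rep_value <- c(anti = 250, plus_syn = 79, minus_syn = 320)

# attach O4' realizing the requested chi (torsion O4'-C1'-N-Cref)
attach_o4p <- function(atoms, base, chi) {
  gn <- .glyco_n[[base]]
  cr <- .chi_ref[[base]]
  o4 <- place_atom(atoms[cr, ], atoms[gn, ], atoms["C1'", ],
                   bond = 1.42, angle_deg = 108, dihedral_deg = chi)
  rbind(atoms, "O4'" = o4)
}

new_base_pair <- function(base1, base2, resid1, resid2, glycosyl, hbonds) {
  obj <- list(base1 = base1, base2 = base2, resid1 = resid1, resid2 = resid2,
              glycosyl = glycosyl, hbonds = hbonds)
  class(obj) <- "base_pair"
  obj
}

#' @export
print.base_pair <- function(x, ...) {
  cat(x$resid1, "...", x$resid2, " pair (", paste(x$glycosyl, collapse = "..."),
      "), H-bonds: ",
      paste(vapply(x$hbonds, function(b) paste0(b[1], "...", b[2]), ""),
            collapse = ", "),
      "; C1'...C1' = ", round(pair_c1c1(x), 2), " A\n", sep = "")
  invisible(x)
}

pair_c1c1 <- function(pair) {
  vnorm(pair$base1["C1'", ] - pair$base2["C1'", ])
}

#' Idealized Watson-Crick base pair
#'
#' Base 1 in the standard reference frame, the complementary base flipped
#' 180 deg about x with a small pair-specific shift tightening the
#' donor-acceptor distances into 2.8-3.0 A.  Both glycosyls are anti
#' (chi 250 deg).
#'
#' @param base Base of strand 1, one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return A `base_pair`.
#' @export
build_wc_pair <- function(base) {
  base <- normalize_residue_name(base)
  comp <- .complement[[base]]
  b1 <- .base_templates[[base]]
  b2 <- flip_x(.base_templates[[comp]])
  b2[, 2] <- b2[, 2] + .wc_shift[[base]]
  b1 <- attach_o4p(b1, base, chi_rep_value[["anti"]])
  b2 <- attach_o4p(b2, comp, chi_rep_value[["anti"]])
  hb <- switch(base,
    G = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")),
    C = list(c("N4", "O6"), c("N3", "N1"), c("O2", "N2")),
    A = list(c("N6", "O4"), c("N1", "N3")),
    T = list(c("O4", "N6"), c("N3", "N1")))
  new_base_pair(b1, b2, base, comp, c("anti", "anti"), hb)
}

# vectorized restrained energy for the in-plane pair placement
pair_energy_fn <- function(b1_0, b2_0, bonds, k = .pair_energy_k) {
  an1 <- rownames(b1_0)
  an2 <- rownames(b2_0)
  pr <- expand.grid(i = an2, j = an1, stringsAsFactors = FALSE)
  drop <- rep(FALSE, nrow(pr))
  for (b in bonds) {
    drop <- drop |
      (pr$i %in% c(b[1], .hb_neighbours[[b[1]]]) &
       pr$j %in% c(b[2], .hb_neighbours[[b[2]]]))
  }
  pr <- pr[!drop, ]
  lim <- k[["vdw_soft"]] *
    (.vdw_radius[substr(pr$i, 1, 1)] + .vdw_radius[substr(pr$j, 1, 1)])
  i2 <- match(pr$i, an2)
  j1 <- match(pr$j, an1)
  bi <- match(vapply(bonds, `[`, "", 1), an2)
  bj <- match(vapply(bonds, `[`, "", 2), an1)
  function(p, b1_gn, b2_gn) {
    # p = (swing1, swing2, frame_rot_deg, tx, ty)
    sw <- function(b, gn, s) {
      piv <- b[gn, ]
      R <- rot_z(s)
      idx <- setdiff(rownames(b), c("C1'", gn))
      b[idx, ] <- xform(sweep(b[idx, , drop = FALSE], 2, piv), R, piv)
      b
    }
    b1 <- sw(b1_0, b1_gn, p[1])
    b2 <- sw(b2_0, b2_gn, p[2])
    b2 <- xform(b2, rot_z(p[3]), c(p[4], p[5], 0))
    e <- k[["swing"]] * (p[1]^2 + p[2]^2) + k[["frame_r"]] * p[3]^2 +
      k[["frame_t"]] * (p[4]^2 + p[5]^2)
    db <- sqrt(rowSums((b2[bi, , drop = FALSE] - b1[bj, , drop = FALSE])^2))
    e <- e + k[["bond"]] * sum((db - 2.9)^2)
    dd <- sqrt(rowSums((b2[i2, ] - b1[j1, ])^2))
    v <- lim - dd
    e + k[["vdw"]] * sum(v[v > 0]^2)
  }
}

#' Modeled A...A mismatch pair
#'
#' Builds an adenine-adenine pair in a chosen glycosyl configuration with a
#' declared hydrogen-bond registry (donor on base 2, acceptor on base 1) at
#' 2.9 A, bases coplanar, by restrained in-plane minimization from the
#' Watson-Crick scaffold (see the package vignette for the construction).
#' Glycosyl chi values are class-representative: anti 250, +syn 79,
#' -syn 320 deg.
#'
#' @param config `"anti_anti"`, `"syn_anti"` (base 2 +syn) or
#'   `"minus_syn_minus_syn"`.
#' @param hbond Registry as `"N6...N1"` (donor atom of base 2 first).
#'   `"N6...N7"` is only compatible with syn-containing configurations.
#' @return A `base_pair`.
#' @export
build_mismatch_pair <- function(config = c("anti_anti", "syn_anti",
                                           "minus_syn_minus_syn"),
                                hbond = "N6...N1") {
  config <- match.arg(config)
  hb <- strsplit(gsub("\\s", "", hbond), "\\.{3}")[[1]]
  if (length(hb) != 2) {
    stop("config error: cannot parse hbond spec '", hbond, "'", call. = FALSE)
  }
  syn2 <- config %in% c("syn_anti", "minus_syn_minus_syn")
  syn1 <- config == "minus_syn_minus_syn"
  if (any(hb %in% "N7") && !syn2) {
    stop("config error: the N6...N7 registry requires a syn-configured base",
         call. = FALSE)
  }
  glyco <- switch(config,
    anti_anti = c("anti", "anti"),
    syn_anti = c("anti", "plus_syn"),
    minus_syn_minus_syn = c("minus_syn", "minus_syn"))

  b1 <- .base_templates[["A"]]
  b2 <- flip_x(.base_templates[["A"]])
  if (syn1) b1 <- glyco_flip(b1, "A")
  if (syn2) b2 <- glyco_flip(b2, "A")

  # orient the declared bond across the two bases: in syn-containing
  # configurations the amino/Hoogsteen atoms (N6, N7) can only meet the
  # partner from the syn base, so they are assigned to base 2; in symmetric
  # configurations the first-listed atom sits on base 1
  if (config == "syn_anti") {
    bonds <- list(c(hb[hb %in% c("N6", "N7")][1], hb[!(hb %in% c("N6", "N7"))][1]))
    if (anyNA(bonds[[1]])) bonds <- list(c(hb[2], hb[1]))
  } else {
    bonds <- list(c(hb[2], hb[1]))
  }
  en <- pair_energy_fn(b1, b2, bonds)
  best <- NULL
  for (s in c(-12, 0, 12)) {
    f <- stats::optim(c(s, -s, 0, 0, -0.5), en, b1_gn = "N9", b2_gn = "N9",
                      method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-13))
    f <- stats::optim(f$par, en, b1_gn = "N9", b2_gn = "N9",
                      method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-13))
    if (is.null(best) || f$value < best$value) best <- f
  }
  p <- best$par
  sw <- function(b, s) {
    piv <- b["N9", ]
    idx <- setdiff(rownames(b), c("C1'", "N9"))
    b[idx, ] <- xform(sweep(b[idx, , drop = FALSE], 2, piv), rot_z(s), piv)
    b
  }
  b1 <- sw(b1, p[1])
  b2 <- sw(b2, p[2])
  b2 <- xform(b2, rot_z(p[3]), c(p[4], p[5], 0))
  b1 <- attach_o4p(b1, "A", chi_rep_value[[glyco[1]]])
  b2 <- attach_o4p(b2, "A", chi_rep_value[[glyco[2]]])
  new_base_pair(b1, b2, "A", "A", glyco, list(hb))
}

## ---- superposition and the two nonisomorphism measures --------------------

pair_base <- function(pair, which) if (which == 1) pair$base1 else pair$base2

resolve_anchor <- function(pairA, pairB, anchor) {
  if (is.numeric(anchor)) return(as.integer(anchor))
  if (anchor != "auto") stop("anchor must be 1, 2 or 'auto'", call. = FALSE)
  if (pairA$resid1 == pairB$resid1) return(1L)
  if (pairA$resid2 == pairB$resid2) return(2L)
  # default: the strand-1 purine side
  if (pairA$resid1 %in% .purines && pairB$resid1 %in% .purines) return(1L)
  if (pairA$resid2 %in% .purines && pairB$resid2 %in% .purines) return(2L)
  1L
}

#' Superpose one pair's anchor base onto another's
#'
#' Least-squares (Kabsch) superposition of pair B's anchor base onto pair
#' A's anchor base over their shared named atoms (ring atoms plus C1').
#'
#' @param pairA,pairB `base_pair` objects.
#' @param anchor 1, 2, or `"auto"` (same nucleotide type where possible,
#'   else the strand-1 purine).
#' @return list: `R`, `t` (transform taking pair B onto pair A), `anchor`,
#'   `atoms` used, and `rmsd` of the anchor fit.
#' @export
superpose_on_anchor <- function(pairA, pairB, anchor = "auto") {
  anchor <- resolve_anchor(pairA, pairB, anchor)
  bA <- pair_base(pairA, anchor)
  bB <- pair_base(pairB, anchor)
  common <- intersect(rownames(bA), rownames(bB))
  common <- common[common %in% c(unique(unlist(.ring_atoms)), "C1'")]
  if (length(common) < 3) {
    stop("superposition error: fewer than 3 shared anchor atoms", call. = FALSE)
  }
  tr <- kabsch(bB[common, , drop = FALSE], bA[common, , drop = FALSE])
  fitted <- xform(bB[common, , drop = FALSE], tr$R, tr$t)
  list(R = tr$R, t = tr$t, anchor = anchor, atoms = common,
       rmsd = sqrt(mean(rowSums((fitted - bA[common, , drop = FALSE])^2))))
}

#' Radial difference between two base pairs
#'
#' Absolute difference of the two pairs' C1'...C1' distances.
#'
#' @param pairA,pairB `base_pair` objects.
#' @return Difference in Angstrom (>= 0).
#' @export
radial_difference <- function(pairA, pairB) {
  for (p in list(pairA, pairB)) {
    if (!("C1'" %in% rownames(p$base1)) || !("C1'" %in% rownames(p$base2))) {
      stop("atom error: C1' missing from a pair", call. = FALSE)
    }
  }
  abs(pair_c1c1(pairA) - pair_c1c1(pairB))
}

#' Residual twist between two base pairs
#'
#' After superposing pair B's anchor base onto pair A's, both pairs'
#' C1'(anchor) -> C1'(other) vectors are projected onto the anchor base
#' plane (fitted to pair A's anchor ring atoms) and the unsigned angle
#' between the projections is returned.
#'
#' @inheritParams superpose_on_anchor
#' @return Angle in degrees in `[0, 180]`.
#' @export
residual_twist <- function(pairA, pairB, anchor = "auto") {
  tr <- superpose_on_anchor(pairA, pairB, anchor)
  a <- tr$anchor
  o <- 3L - a
  vA <- pair_base(pairA, o)["C1'", ] - pair_base(pairA, a)["C1'", ]
  bB_anchor <- xform(pair_base(pairB, a), tr$R, tr$t)
  bB_other <- xform(pair_base(pairB, o), tr$R, tr$t)
  vB <- bB_other["C1'", ] - bB_anchor["C1'", ]
  # anchor base plane normal from pair A's anchor ring
  ringA <- pair_base(pairA, a)
  ring_names <- intersect(rownames(ringA), unique(unlist(.ring_atoms)))
  M <- sweep(ringA[ring_names, ], 2, colMeans(ringA[ring_names, ]))
  n <- svd(M)$v[, 3]
  pA <- vA - sum(vA * n) * n
  pB <- vB - sum(vB * n) * n
  if (vnorm(pA) < 1e-8 || vnorm(pB) < 1e-8) {
    stop("undefined residual twist: pair vector perpendicular to the anchor plane",
         call. = FALSE)
  }
  acos(pmin(1, pmax(-1, sum(vunit(pA) * vunit(pB))))) * 180 / pi
}

#' Nonisomorphism summary of two base pairs
#'
#' @inheritParams superpose_on_anchor
#' @return data.frame: residual_twist (deg), radial_difference (A), and the
#'   two pairs' C1'...C1' distances (A).
#' @export
nonisomorphism <- function(pairA, pairB, anchor = "auto") {
  data.frame(
    residual_twist = residual_twist(pairA, pairB, anchor),
    radial_difference = radial_difference(pairA, pairB),
    c1c1_A = pair_c1c1(pairA),
    c1c1_B = pair_c1c1(pairB))
}
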