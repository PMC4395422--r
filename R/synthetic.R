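# Synthetic structure and trajectory generation: idealized B-form and
# Z-form duplex builders, mismatch embedding, and seeded mock trajectories
# with planted B->Z windows, scripted base flips and extrusions.
#
# Construction scheme.  Each residue is built in a local pair frame: the
# base is an idealized planar template (harmonized so that C1' and the
# glycosidic nitrogen coincide across bases), the sugar-phosphate atoms
# O4', C4', C3', C5', O3', O5', P are grown from the base by internal
# coordinates (NeRF), with chi, beta, gamma, delta prescribed exactly and
# three sugar-orientation torsions chosen once, per helix type, by a small
# deterministic least squares so that the emergent inter-residue torsions
# (alpha, epsilon, zeta) land in the intended wells and the O3'-P virtual
# bond closes near 1.6 A.  Pairs are centred so their C1'...C1' midpoint
# sits on the helix axis, which makes the C1'...C1'-vector twist of the
# built helix exactly equal to the step twist parameter.
#
# B-form: 36 deg twist / 3.38 A rise per step, all-anti.
# Z-form: dinucleotide repeat, -9 deg into-purine and -51 deg
# into-pyrimidine steps, 3.7 A rise, purines syn (chi 60 deg), backbone
# aimed at the ZI (g-, g+, g+, t) well targets.  These are standard fiber
# values serving as classification targets.

.helix_params <- list(
  B = list(twist = 36, rise = 3.38,
           torsions = list(pur = c(chi = 250, beta = 176, gamma = 48, delta = 128),
                           pyr = c(chi = 250, beta = 176, gamma = 48, delta = 128)),
           targets = c(alpha = 300, epsilon = 184, zeta = 265)),
  Z = list(twist_into_pur = -9, twist_into_pyr = -51, rise = 3.7,
           torsions = list(pur = c(chi = 60, beta = 215, gamma = 181, delta = 95),
                           pyr = c(chi = 210, beta = 215, gamma = 181, delta = 138)),
           targets = c(alpha = 99, epsilon = 283, zeta = 83))
)

.sugar_geom <- list(
  o4 = c(bond = 1.42, angle = 108),   # O4'-C1', O4'-C1'-N
  c4 = c(bond = 1.45, angle = 110),   # C4'-O4', C4'-O4'-C1'
  c3 = c(bond = 1.53, angle = 106),   # C3'-C4', C3'-C4'-O4'
  c5 = c(bond = 1.51, angle = 109),   # C5'-C4', C5'-C4'-O4'
  o3 = c(bond = 1.42, angle = 110),   # O3'-C3', O3'-C3'-C4'
  o5 = c(bond = 1.44, angle = 110),   # O5'-C5', O5'-C5'-C4'
  p  = c(bond = 1.59, angle = 120)    # P-O5',  P-O5'-C5'
)

.builder_cache <- new.env(parent = emptyenv())

# harmonize base templates: rigidly move each so C1' and the C1'->N
# direction coincide with the adenine template's
harmonized_templates <- function() {
  if (!is.null(.builder_cache$templates)) return(.builder_cache$templates)
  ref <- .base_templates[["A"]]
  refc <- ref["C1'", ]
  refdir <- vunit(ref["N9", ] - refc)
  out <- list()
  for (b in names(.base_templates)) {
    m <- .base_templates[[b]]
    gn <- .glyco_n[[b]]
    dir <- vunit(m[gn, ] - m["C1'", ])
    ang <- atan2(dir[1] * refdir[2] - dir[2] * refdir[1],
                 sum(dir * refdir)) * 180 / pi
    m <- xform(sweep(m, 2, m["C1'", ]), rot_z(ang), refc)
    out[[b]] <- m
  }
  .builder_cache$templates <- out
  out
}

# grow sugar-phosphate atoms from a placed base by internal coordinates
grow_backbone <- function(base_atoms, base, tors, t3par) {
  g <- .sugar_geom
  gn <- .glyco_n[[base]]
  cr <- .chi_ref[[base]]
  o4 <- place_atom(base_atoms[cr, ], base_atoms[gn, ], base_atoms["C1'", ],
                   g$o4[["bond"]], g$o4[["angle"]], tors[["chi"]])
  c4 <- place_atom(base_atoms[gn, ], base_atoms["C1'", ], o4,
                   g$c4[["bond"]], g$c4[["angle"]], t3par[1])
  c3 <- place_atom(base_atoms["C1'", ], o4, c4,
                   g$c3[["bond"]], g$c3[["angle"]], t3par[2])
  c5 <- place_atom(base_atoms["C1'", ], o4, c4,
                   g$c5[["bond"]], g$c5[["angle"]], t3par[3])
  o3 <- place_atom(c5, c4, c3, g$o3[["bond"]], g$o3[["angle"]], tors[["delta"]])
  o5 <- place_atom(c3, c4, c5, g$o5[["bond"]], g$o5[["angle"]], tors[["gamma"]])
  p <- place_atom(c4, c5, o5, g$p[["bond"]], g$p[["angle"]], tors[["beta"]])
  rbind(base_atoms,
        "O4'" = o4, "C4'" = c4, "C3'" = c3, "C5'" = c5,
        "O3'" = o3, "O5'" = o5, P = p)
}

# local-frame residue: harmonized base (optionally glycosyl-flipped and/or
# WC-flipped about x) centred on the common pair midpoint, plus backbone
local_residue <- function(base, helix, strand2 = FALSE, syn = FALSE,
                          t3par) {
  tmpl <- harmonized_templates()[[base]]
  if (strand2) {
    tmpl <- flip_x(tmpl)
    # pair-specific tightening shift keeping donor-acceptor distances in
    # 2.8-3.0 A (G.C pairs sit slightly closer than A.T in the templates)
    tmpl[, 2] <- tmpl[, 2] + if (base %in% c("G", "C")) -0.04 else 0.06
  }
  if (syn) tmpl <- glyco_flip(tmpl, base)
  cls <- if (base %in% .purines) "pur" else "pyr"
  tors <- .helix_params[[helix]]$torsions[[cls]]
  off <- pair_center_offset()
  atoms <- grow_backbone(tmpl, base, tors, t3par)
  sweep(atoms, 2, off)
}

# common C1'...C1' midpoint of a harmonized WC pair (identical for all pair
# types by construction)
pair_center_offset <- function() {
  tmpl <- harmonized_templates()[["A"]]
  c1a <- tmpl["C1'", ]
  part <- flip_x(tmpl)
  part[, 2] <- part[, 2] + 0.06
  (c1a + part["C1'", ]) / 2
}

# deterministic least squares for the three sugar-orientation torsions of a
# helix class: emergent alpha/epsilon/zeta near targets, O3'-P closure 1.6 A
solve_sugar_torsions <- function(helix) {
  key <- paste0("t3_", helix)
  if (!is.null(.builder_cache[[key]])) return(.builder_cache[[key]])
  hp <- .helix_params[[helix]]
  circ_err <- function(a, b) {
    d <- (a - b) %% 360
    pmin(d, 360 - d)
  }
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  if (helix == "B") {
    step <- function(m) xform(m, rot_z(hp$twist), c(0, 0, hp$rise))
    obj <- function(t3par) {
      v <- safe({
        r0 <- local_residue("A", "B", t3par = t3par)
        r1 <- step(r0)
        cl <- vnorm(r0["O3'", ] - r1["P", ])
        eps <- dihedral(r0["C4'", ], r0["C3'", ], r0["O3'", ], r1["P", ])
        zet <- dihedral(r0["C3'", ], r0["O3'", ], r1["P", ], r1["O5'", ])
        alp <- dihedral(r0["O3'", ], r1["P", ], r1["O5'", ], r1["C5'", ])
        100 * (cl - 1.60)^2 +
          (circ_err(alp, hp$targets[["alpha"]]) / 15)^2 +
          (circ_err(eps, hp$targets[["epsilon"]]) / 15)^2 +
          (circ_err(zet, hp$targets[["zeta"]]) / 15)^2
      })
      if (is.null(v)) 1e6 else v
    }
    fit <- stats::optim(c(140, 260, 140), obj, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-12))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-12))
    sol <- list(pur = fit$par, pyr = fit$par, value = fit$value)
  } else {
    step_a <- function(m) xform(m, rot_z(hp$twist_into_pyr), c(0, 0, hp$rise))
    step_b <- function(m) xform(m, rot_z(hp$twist_into_pur), c(0, 0, hp$rise))
    obj <- function(par) {
      v <- safe({
        tp <- par[1:3]; ty <- par[4:6]
        pu <- local_residue("G", "Z", syn = TRUE, t3par = tp)
        py <- local_residue("C", "Z", t3par = ty)
        pu_py <- step_a(py)   # purine -> pyrimidine step (-51)
        py_pu <- step_b(pu)   # pyrimidine -> purine step (-9)
        e <- 0
        for (pairres in list(list(pu, pu_py), list(py, py_pu))) {
          r0 <- pairres[[1]]; r1 <- pairres[[2]]
          cl <- vnorm(r0["O3'", ] - r1["P", ])
          eps <- dihedral(r0["C4'", ], r0["C3'", ], r0["O3'", ], r1["P", ])
          zet <- dihedral(r0["C3'", ], r0["O3'", ], r1["P", ], r1["O5'", ])
          alp <- dihedral(r0["O3'", ], r1["P", ], r1["O5'", ], r1["C5'", ])
          e <- e + 100 * (cl - 1.60)^2 +
            (circ_err(alp, hp$targets[["alpha"]]) / 15)^2 +
            (circ_err(eps, hp$targets[["epsilon"]]) / 15)^2 +
            (circ_err(zet, hp$targets[["zeta"]]) / 15)^2
        }
        e
      })
      if (is.null(v)) 1e6 else v
    }
    # multi-start: the landscape has several sugar-orientation basins
    starts <- expand.grid(a = c(60, 140, 220, 300), b = c(80, 180, 280),
                          c = c(60, 180, 300))
    fit <- NULL
    for (k in seq_len(nrow(starts))) {
      s0 <- as.numeric(starts[k, ])
      f <- stats::optim(c(s0, s0), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
      if (is.null(fit) || f$value < fit$value) fit <- f
    }
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 6000, reltol = 1e-12))
    sol <- list(pur = fit$par[1:3], pyr = fit$par[4:6], value = fit$value)
  }
  .builder_cache[[key]] <- sol
  sol
}

# per-step transforms for a mixed B/Z build; step j carries pairs j -> j+1
step_transform <- function(helix, base_to) {
  hp <- .helix_params[[helix]]
  if (helix == "B") {
    list(R = rot_z(hp$twist), t = c(0, 0, hp$rise), twist = hp$twist)
  } else {
    tw <- if (base_to %in% .purines) hp$twist_into_pur else hp$twist_into_pyr
    list(R = rot_z(tw), t = c(0, 0, hp$rise), twist = tw)
  }
}

parse_sequence <- function(sequence) {
  s <- toupper(gsub("\\s", "", paste(sequence, collapse = "")))
  ch <- strsplit(s, "")[[1]]
  if (length(ch) == 0 || !all(ch %in% c("A", "C", "G", "T"))) {
    stop("sequence error: expected a nonempty string over A/C/G/T",
         call. = FALSE)
  }
  ch
}

# core builder: place residues of both strands under cumulative step
# transforms; `helix_of_step` gives "B"/"Z" per step, `syn_map`/`resid2`
# control per-residue state
build_duplex_core <- function(seq1, seq2, helix_of_step, syn2_map = NULL,
                              syn1_map = NULL) {
  n <- length(seq1)
  sol_b <- solve_sugar_torsions("B")
  sol_z <- if (any(helix_of_step == "Z")) solve_sugar_torsions("Z") else NULL
  # residue-level helix state: Z if an adjacent step is Z
  helix_of_res <- vapply(seq_len(n), function(i) {
    adj <- helix_of_step[intersect(c(i - 1, i), seq_len(n - 1))]
    if (any(adj == "Z")) "Z" else "B"
  }, "")
  # cumulative transforms
  Ts <- vector("list", n)
  Ts[[1]] <- list(R = diag(3), t = c(0, 0, 0))
  for (j in seq_len(n - 1)) {
    st <- step_transform(helix_of_step[j], seq1[j + 1])
    Ts[[j + 1]] <- list(R = st$R %*% Ts[[j]]$R,
                        t = c(st$R %*% Ts[[j]]$t) + st$t)
  }
  res_list <- list()
  for (i in seq_len(n)) {
    hx <- helix_of_res[i]
    sol <- if (hx == "Z") sol_z else sol_b
    for (s in 1:2) {
      base <- if (s == 1) seq1[i] else seq2[n + 1 - i]
      syn_default <- hx == "Z" && base %in% .purines
      syn <- if (s == 1 && !is.null(syn1_map)) syn1_map[i]
             else if (s == 2 && !is.null(syn2_map)) syn2_map[n + 1 - i]
             else syn_default
      cls <- if (base %in% .purines) "pur" else "pyr"
      loc <- local_residue(base, hx, strand2 = s == 2, syn = isTRUE(syn),
                           t3par = sol[[cls]])
      placed <- xform(loc, Ts[[i]]$R, Ts[[i]]$t)
      res_list[[length(res_list) + 1]] <- list(
        strand = s, pos = if (s == 1) i else n + 1 - i,
        resid = base, atoms = placed)
    }
  }
  # order: strand1 5'->3', then strand2 5'->3'
  ord <- order(vapply(res_list, function(r) r$strand * 1000 + r$pos, 0))
  parts <- make_atoms(res_list[ord])
  d <- new_duplex(parts$atoms, parts$xyz)
  d$helix_of_step <- helix_of_step
  d
}

#' Idealized B-form duplex
#'
#' Builds a fiber-model B-DNA duplex (36 deg/step, 3.38 A rise, all-anti)
#' from the strand-1 sequence; the complementary strand is generated
#' antiparallel with Watson-Crick pairing.  Optional A...A mismatches
#' replace the strand-2 partner with an adenine whose base is placed by the
#' modeled mismatch-pair geometry (see [build_mismatch_pair()]).
#'
#' @param sequence Strand-1 sequence 5'->3' (string or character vector).
#' @param mismatch Optional integer vector of strand-1 positions carrying an
#'   A...A mismatch (the strand-1 base there must be A).
#' @param mismatch_config Glycosyl configuration for mismatched pairs.
#' @return A `duplex`; `$torsion_targets` records the prescribed and
#'   emergent backbone torsion values of the construction.
#' @export
build_b_duplex <- function(sequence, mismatch = integer(0),
                           mismatch_config = "anti_anti") {
  seq1 <- parse_sequence(sequence)
  n <- length(seq1)
  seq2 <- rev(vapply(seq1, function(b) .complement[[b]], ""))
  if (length(mismatch) > 0) {
    if (any(mismatch < 1 | mismatch > n)) {
      stop("mismatch position out of range", call. = FALSE)
    }
    if (any(seq1[mismatch] != "A")) {
      stop("A...A mismatches require adenine on strand 1", call. = FALSE)
    }
    seq2[n + 1 - mismatch] <- "A"
  }
  d <- build_duplex_core(seq1, seq2, rep("B", n - 1))
  if (length(mismatch) > 0) {
    d <- embed_mismatch(d, mismatch, mismatch_config)
  }
  d$helix <- "B"
  d$torsion_targets <- builder_torsion_targets("B")
  d
}

#' Idealized Z-form duplex
#'
#' Dinucleotide-repeat left-handed helix: -9 deg steps into purines and
#' -51 deg into pyrimidines, 3.7 A rise, purines syn (chi 60 deg), backbone
#' aimed at the ZI well targets.
#'
#' @inheritParams build_b_duplex
#' @return A `duplex` with `$torsion_targets`.
#' @export
build_z_duplex <- function(sequence) {
  seq1 <- parse_sequence(sequence)
  n <- length(seq1)
  seq2 <- rev(vapply(seq1, function(b) .complement[[b]], ""))
  d <- build_duplex_core(seq1, seq2, rep("Z", n - 1))
  d$helix <- "Z"
  d$torsion_targets <- builder_torsion_targets("Z")
  d
}

# measured construction constants: prescribed intra-residue torsions plus
# the emergent alpha/epsilon/zeta achieved by the solved templates
builder_torsion_targets <- function(helix) {
  sol <- solve_sugar_torsions(helix)
  hp <- .helix_params[[helix]]
  list(prescribed = hp$torsions, aimed_wells = hp$targets, solver = sol)
}

# replace strand-2 base atoms at mismatch sites with the modeled A...A pair
# geometry expressed in the strand-1 residue's frame
embed_mismatch <- function(d, mismatch, config) {
  pair <- build_mismatch_pair(config)
  tmplA <- harmonized_templates()[["A"]]
  off <- pair_center_offset()
  ringA <- .ring_atoms$A
  for (mp in mismatch) {
    # frame of the strand-1 adenine as built
    idx1 <- vapply(c(ringA, "C1'"), function(at) atom_index(d, 1, mp, at), 1L)
    tr <- kabsch(pair$base1[c(ringA, "C1'"), ], d$xyz[idx1, ])
    p2 <- d$pairing$pos2[d$pairing$pos1 == mp]
    # rebuild strand-2 residue: mismatch base + backbone grown on it
    base2 <- xform(pair$base2[c(ringA, "C1'"), ], tr$R, tr$t)
    tors <- .helix_params$B$torsions$pur
    tors[["chi"]] <- chi_rep_value[[pair$glycosyl[2]]]
    sol <- solve_sugar_torsions("B")
    atoms <- grow_backbone(base2, "A", tors, sol$pur)
    # overwrite coordinates of existing strand-2 residue atoms
    for (at in rownames(atoms)) {
      i <- atom_index(d, 2, p2, at)
      if (!is.na(i)) d$xyz[i, ] <- atoms[at, ]
    }
  }
  d
}

## ---- trajectories ---------------------------------------------------------

#' Mock trajectory with a planted B-to-Z window
#'
#' Generates frames of a duplex in which a contiguous window of steps
#' switches from B-form to Z-form geometry in stages, with optional scripted
#' base-flip and base-extrusion events and i.i.d. Gaussian coordinate noise.
#' Ground truth (per-frame step labels and event table) is returned
#' alongside and can be written as a JSON sidecar.
#'
#' @param sequence Strand-1 sequence 5'->3'.
#' @param z_window Integer range of steps (e.g. `6:9`) that reach Z form.
#' @param n_frames Number of frames.
#' @param stages Number of growth stages (default 1: the full window
#'   switches at once; k stages grow the Z stretch outward from the window
#'   centre in k increments).
#' @param noise_sigma Gaussian noise sd per coordinate (A), default 0.
#' @param seed Integer seed; all randomness derives from it.
#' @param events Optional list of event scripts, each a list with `kind`
#'   (`"flip"` or `"extrusion"`), `pos` (strand-1 pair position; the event
#'   applies to the strand-2 partner base), `frames` (integer span),
#'   and for flips `from`, `to`, `direction` (`"cis"`/`"trans"`), for
#'   extrusions `displacement` (A, default 4).
#' @param dt_ps Frame spacing (ps), default 100.
#' @param mismatch,mismatch_config Passed to [build_b_duplex()].
#' @return list: `trajectory` (a `duplex_trajectory`), `truth`
#'   (list: labels matrix frames x steps, events data.frame, noise_sigma,
#'   seed).
#' @export
make_bz_trajectory <- function(sequence, z_window = NULL, n_frames = 10,
                               stages = 1, noise_sigma = 0, seed = 1,
                               events = list(), dt_ps = 100,
                               mismatch = integer(0),
                               mismatch_config = "anti_anti") {
  seq1 <- parse_sequence(sequence)
  n <- length(seq1)
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  if (!is.null(z_window)) {
    if (min(z_window) < 1 || max(z_window) > n - 1) {
      stop("range error: z_window outside the step axis", call. = FALSE)
    }
  }
  seq2 <- rev(vapply(seq1, function(b) .complement[[b]], ""))
  if (length(mismatch) > 0) seq2[n + 1 - mismatch] <- "A"

  set.seed(as.integer(seed))
  # stage schedule: which steps are Z in each frame; `stages` may be an
  # explicit list of step vectors (one per stage) instead of a count
  n_stages <- if (is.list(stages)) length(stages) else stages
  frame_stage <- if ((is.null(z_window) && !is.list(stages)) || n_stages < 1) {
    rep(0L, n_frames)
  } else if (n_stages == 1) {
    rep(1L, n_frames)
  } else {
    as.integer(cut(seq_len(n_frames), breaks = n_stages, labels = FALSE))
  }
  stage_steps <- function(stg) {
    if (stg < 1) return(integer(0))
    if (is.list(stages)) return(sort(as.integer(stages[[stg]])))
    if (is.null(z_window)) return(integer(0))
    w <- sort(z_window)
    k <- ceiling(length(w) * stg / max(1, n_stages))
    mid <- ceiling(length(w) / 2)
    lo <- max(1, mid - floor((k - 1) / 2))
    w[seq(lo, min(length(w), lo + k - 1))]
  }

  frames <- vector("list", n_frames)
  labels <- matrix("B", n_frames, n - 1)
  base_cache <- list()
  for (f in seq_len(n_frames)) {
    zsteps <- stage_steps(frame_stage[f])
    key <- paste0("k", paste(zsteps, collapse = ","))
    if (is.null(base_cache[[key]])) {
      hos <- rep("B", n - 1)
      hos[zsteps] <- "Z"
      base_cache[[key]] <- build_duplex_core(seq1, seq2, hos)
    }
    d <- base_cache[[key]]
    xyz <- d$xyz
    # truth labels: Z inside the window, junction at B steps adjacent to Z
    if (length(zsteps) > 0) {
      labels[f, zsteps] <- "Z"
      for (b in c(min(zsteps) - 1, max(zsteps) + 1)) {
        if (b >= 1 && b <= n - 1) labels[f, b] <- "junction"
      }
    }
    # scripted events modify strand-2 partner bases
    for (ev in events) {
      # flips persist once complete; extrusions are excursions that revert
      last <- ev$frames[length(ev$frames)]
      if (f < ev$frames[1] || (ev$kind != "flip" && f > last)) next
      frac <- if (f > last || length(ev$frames) == 1 || isFALSE(ev$ramp)) 1 else
        (f - ev$frames[1]) / (last - ev$frames[1])
      p2 <- n + 1 - ev$pos
      base2 <- seq2[n + 1 - ev$pos]
      bi <- which(d$atoms$strand == 2 & d$atoms$pos == p2 &
                  d$atoms$atom %in% c(.ring_atoms[[base2]],
                                      setdiff(rownames(.base_templates[[base2]]),
                                              "C1'")))
      if (ev$kind == "flip") {
        delta <- flip_path_delta(ev$from, ev$to, ev$direction) * frac
        c1 <- d$xyz[atom_index(d, 2, p2, "C1'"), ]
        gn <- d$xyz[atom_index(d, 2, p2, .glyco_n[[base2]]), ]
        # rotating the base by +delta about the glycosidic axis moves chi
        # (measured through the fixed O4') by -delta
        R <- rot_axis(gn - c1, -delta)
        bi2 <- setdiff(bi, atom_index(d, 2, p2, .glyco_n[[base2]]))
        xyz[bi2, ] <- xform(sweep(xyz[bi2, , drop = FALSE], 2, gn), R, gn)
      } else if (ev$kind == "extrusion") {
        disp <- if (is.null(ev$displacement)) 4 else ev$displacement
        pm <- pair_c1_matrix(d, ev$pos)
        dir <- vunit(pm[2, ] - pm[1, ])
        bi3 <- which(d$atoms$strand == 2 & d$atoms$pos == p2)
        xyz[bi3, ] <- sweep(xyz[bi3, , drop = FALSE], 2, -dir * disp * frac)
      } else {
        stop("unknown scripted event kind '", ev$kind, "'", call. = FALSE)
      }
    }
    if (noise_sigma > 0) {
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_sigma),
                          nrow(xyz), 3)
    }
    frames[[f]] <- xyz
  }

  d0 <- base_cache[[paste0("k", paste(stage_steps(frame_stage[1]), collapse = ","))]]
  traj <- d0
  traj$xyz <- frames[[1]]
  traj$frames <- frames
  traj$times <- (seq_len(n_frames) - 1) * dt_ps
  class(traj) <- c("duplex_trajectory", "duplex")

  ev_df <- if (length(events) > 0) {
    do.call(rbind, lapply(events, function(ev) data.frame(
      kind = ev$kind, pos = ev$pos,
      frame_start = ev$frames[1], frame_end = ev$frames[length(ev$frames)],
      direction = if (!is.null(ev$direction)) ev$direction else NA,
      stringsAsFactors = FALSE)))
  } else {
    data.frame(kind = character(0), pos = integer(0),
               frame_start = integer(0), frame_end = integer(0),
               direction = character(0))
  }
  list(trajectory = traj,
       truth = list(labels = labels, events = ev_df,
                    noise_sigma = noise_sigma, seed = seed))
}

# signed total rotation from `from` to `to` passing through 0 (cis) or 180
# (trans); degrees
flip_path_delta <- function(from, to, direction) {
  from <- from %% 360
  to <- to %% 360
  d_up <- (to - from) %% 360     # counterclockwise (increasing)
  d_dn <- d_up - 360             # clockwise (decreasing)
  crosses <- function(delta, mark) {
    # does from + t*delta pass mark (mod 360) for t in (0, 1)?
    span <- sort(c(0, delta))
    any((mark - from + c(-360, 0, 360)) > span[1] &
        (mark - from + c(-360, 0, 360)) < span[2])
  }
  if (direction == "cis") {
    if (crosses(d_up, 0)) d_up else d_dn
  } else {
    if (crosses(d_up, 180)) d_up else d_dn
  }
}

#' Scripted glycosyl flip time series
#'
#' Generates a chi time series rotating from `from` to `to` along the cis
#' (through 0 deg) or trans (through 180 deg) pathway with stable plateaus
#' at the two ends, plus Gaussian angular noise.
#'
#' @param n_frames Series length (default 40).
#' @param from,to Start/end chi (degrees).
#' @param direction `"cis"` or `"trans"`.
#' @param noise_sd Angular noise sd (degrees), default 3.
#' @param seed Integer seed.
#' @return list: `chi` (numeric series, degrees in `[0, 360)`),
#'   `direction`, `from`, `to`.
#' @export
make_flip_series <- function(n_frames = 40, from = 79, to = 320,
                             direction = c("cis", "trans"), noise_sd = 3,
                             seed = 1) {
  direction <- match.arg(direction)
  set.seed(as.integer(seed))
  delta <- flip_path_delta(from, to, direction)
  plateau <- max(3, floor(n_frames / 4))
  nmid <- n_frames - 2 * plateau
  path <- c(rep(0, plateau), seq(0, 1, length.out = nmid), rep(1, plateau))
  chi <- (from + path * delta + stats::rnorm(n_frames, 0, noise_sd)) %% 360
  list(chi = chi, direction = direction, from = from, to = to)
}
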