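# Pipeline orchestration: configuration, per-window step classification and
# CSV report generation.

#' Pipeline configuration
#'
#' Builds a validated configuration list.  Unknown keys are rejected;
#' thresholds must lie in their valid ranges.
#'
#' @param ... Overrides of the defaults: `t_z_deg`, `hbond_cutoff_A`,
#'   `flip_min_deg`, `extrusion_dwell`, `extrusion_disp_A`, `stack_dist_A`,
#'   `stack_angle_deg`, `perp_angle_deg`, `min_z`, `dt_ps`,
#'   `exclude_termini`, `window_frames`, `seed`, `chi_bins`, `well_bins`.
#' @return Named list of settings, class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- c(.default_thresholds,
           list(dt_ps = 100, exclude_termini = 0, window_frames = 5,
                seed = 1, chi_bins = .chi_bins_default,
                well_bins = .well_bins_default))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  num_pos <- c("hbond_cutoff_A", "extrusion_disp_A", "stack_dist_A", "dt_ps")
  for (k in num_pos) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      stop("config error: ", k, " must be positive", call. = FALSE)
    }
  }
  for (k in c("t_z_deg", "flip_min_deg", "stack_angle_deg", "perp_angle_deg")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < -180 || cfg[[k]] > 360) {
      stop("config error: ", k, " must be an angle in degrees", call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

# step table of one frame set: twists and backbone/chi classes, averaged
# over the frames with circular means before classification
step_classification <- function(d, frames = NULL, config = pipeline_config()) {
  use_frames <- if (is.null(frames)) list(d$xyz) else lapply(frames, function(f) d$frames[[f]])
  tor_list <- lapply(seq_along(use_frames), function(k) {
    dd <- d
    dd$xyz <- use_frames[[k]]
    compute_torsions(dd)
  })
  tw_list <- lapply(seq_along(use_frames), function(k) {
    dd <- d
    dd$xyz <- use_frames[[k]]
    step_twists(dd)
  })
  tor <- tor_list[[1]]
  ang_cols <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")
  for (cc in ang_cols) {
    m <- sapply(tor_list, function(t) t[[cc]])
    tor[[cc]] <- apply(as.matrix(m), 1, circular_mean)
  }
  tw <- tw_list[[1]]
  tw$twist <- rowMeans(sapply(tw_list, function(t) t$twist))

  rt <- residue_table(d)
  n <- d$n
  s1 <- function(p, col) tor[[col]][tor$strand == 1 & tor$pos == p]
  steps <- tw
  eps <- vapply(seq_len(n - 1), function(i) s1(i, "epsilon"), 0)
  zet <- vapply(seq_len(n - 1), function(i) s1(i, "zeta"), 0)
  alp <- vapply(seq_len(n - 1), function(i) s1(i + 1, "alpha"), 0)
  gam <- vapply(seq_len(n - 1), function(i) s1(i + 1, "gamma"), 0)
  bk <- classify_step_backbone(eps, zet, alp, gam, bins = config$well_bins)
  steps$epsilon <- eps
  steps$zeta <- zet
  steps$alpha <- alp
  steps$gamma <- gam
  steps$b_family <- bk$b_family
  steps$z_signature <- bk$z_signature
  pairing <- d$pairing
  steps$purine_chi <- lapply(seq_len(n - 1), function(i) {
    members <- list(c(1, i), c(1, i + 1),
                    c(2, pairing$pos2[pairing$pos1 == i]),
                    c(2, pairing$pos2[pairing$pos1 == i + 1]))
    out <- character(0)
    for (m in members) {
      res <- rt$resid[rt$strand == m[1] & rt$pos == m[2]]
      if (res %in% .purines) {
        ch <- tor$chi[tor$strand == m[1] & tor$pos == m[2]]
        out <- c(out, as.character(classify_chi(ch, bins = config$chi_bins)))
      }
    }
    out
  })
  steps
}

csv_with_header <- function(df, file, header_lines) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' Run the full analysis pipeline
#'
#' Reads a structure or multi-model trajectory, computes torsions,
#' conformer classes, C1'...C1' twists, step labels, junctions, Z-stretch
#' profile and dynamic events, and writes the CSV report bundle to
#' `out_dir`.
#'
#' @param input Path to a PDB file, or a `duplex` / `duplex_trajectory`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the computed tables and the summary.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = ".") {
  if (is.character(input)) {
    if (!file.exists(input)) {
      stop("input file not found: ", input, call. = FALSE)
    }
    n_models <- length(grep("^MODEL", readLines(input)))
    input <- if (n_models > 1) {
      read_trajectory(input, dt_ps = config$dt_ps)
    } else {
      read_structure(input)
    }
  }
  d <- input
  is_traj <- inherits(d, "duplex_trajectory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  conv <- c(paste0("angle bins: chi ",
                   paste(vapply(names(config$chi_bins), function(nm)
                     paste0(nm, "[", config$chi_bins[[nm]][1], ",",
                            config$chi_bins[[nm]][2], ")"), ""),
                     collapse = " ")),
            paste0("t_z_deg: ", config$t_z_deg,
                   "; hbond_cutoff_A: ", config$hbond_cutoff_A),
            "groove offsets: minor partner-3, major partner+4, raw P-P (A)",
            "units: angles deg in [0,360); distances A; time ps")

  tor <- compute_torsions(d)
  tor_out <- tor
  tor_out$chi_class <- as.character(classify_chi(tor$chi, bins = config$chi_bins))
  csv_with_header(tor_out, file.path(out_dir, "torsions.csv"), conv)

  grooves <- groove_widths(d)
  csv_with_header(grooves, file.path(out_dir, "grooves.csv"), conv)

  windows <- if (is_traj) {
    split(seq_along(d$frames),
          ceiling(seq_along(d$frames) / config$window_frames))
  } else {
    list(NULL)
  }
  win_steps <- lapply(windows, function(w) step_classification(d, w, config))
  steps0 <- win_steps[[1]]
  csv_with_header(steps0[, c("step", "step_label", "twist", "rise",
                             "c1c1_i", "c1c1_j")],
                  file.path(out_dir, "steps.csv"), conv)

  labeled <- lapply(win_steps, label_steps, t_z = config$t_z_deg)
  lab_df <- do.call(rbind, lapply(seq_along(labeled), function(w) {
    x <- labeled[[w]]
    data.frame(window = w, step = x$step, step_label = x$step_label,
               twist = x$twist, b_family = as.character(x$b_family),
               z_signature = as.character(x$z_signature),
               label = as.character(x$label))
  }))
  csv_with_header(lab_df, file.path(out_dir, "labels.csv"), conv)

  segs <- detect_junctions(labeled[[length(labeled)]]$label, min_z = config$min_z)
  csv_with_header(segs, file.path(out_dir, "segments.csv"), conv)

  events <- data.frame(kind = character(0), residue = character(0),
                       t_start = numeric(0), t_end = numeric(0),
                       attributes = character(0))
  rmsd_df <- NULL
  stretch <- NULL
  if (is_traj) {
    rmsd_df <- rmsd_profile(d, exclude_termini = config$exclude_termini)
    csv_with_header(rmsd_df, file.path(out_dir, "rmsd.csv"), conv)
    stretch <- if (length(labeled) >= 2) {
      track_z_stretch(lapply(labeled, `[[`, "label"),
                      lapply(labeled, `[[`, "twist"))
    }
    # per-residue flip scan
    rt <- residue_table(d)
    chi_series <- lapply(seq_len(nrow(rt)), function(r) {
      vapply(seq_along(d$frames), function(f) {
        tt <- compute_torsions_residue(d, rt$strand[r], rt$pos[r], f)
        tt
      }, 0)
    })
    for (r in seq_len(nrow(rt))) {
      fl <- tryCatch(detect_flip(chi_series[[r]], times = d$times,
                                 min_deg = config$flip_min_deg),
                     error = function(e) NULL)
      if (!is.null(fl)) {
        events <- rbind(events, data.frame(
          kind = "flip", residue = rt$label[r],
          t_start = fl$span[1], t_end = fl$span[2],
          attributes = paste0("pathway=", fl$pathway)))
      }
    }
    # extrusion scan over A...A pairs
    pr <- d$pairing
    for (i in seq_len(nrow(pr))) {
      r1 <- rt$resid[rt$strand == 1 & rt$pos == pr$pos1[i]]
      r2 <- rt$resid[rt$strand == 2 & rt$pos == pr$pos2[i]]
      if (!(r1 == "A" && r2 == "A")) next
      if (pr$pos1[i] <= 1 || pr$pos1[i] >= d$n) next
      reg <- vapply(seq_along(d$frames), function(f) {
        classify_hbond_registry(d, pos = pr$pos1[i], frame = f,
                                cutoff = config$hbond_cutoff_A)[1]
      }, "")
      disp <- vapply(seq_along(d$frames), function(f) {
        lateral_displacement(d, pr$pos1[i], f)
      }, 0)
      ex <- detect_extrusion(reg, disp, times = d$times,
                             dwell = config$extrusion_dwell,
                             disp_min = config$extrusion_disp_A)
      if (nrow(ex) > 0) {
        events <- rbind(events, data.frame(
          kind = "extrusion", residue = rt$label[rt$strand == 2 &
                                                   rt$pos == pr$pos2[i]],
          t_start = ex$time_start, t_end = ex$time_end,
          attributes = ""))
      }
    }
  }
  csv_with_header(events, file.path(out_dir, "events.csv"), conv)

  final_labels <- labeled[[length(labeled)]]$label
  summary <- list(
    n_bp = d$n,
    n_frames = if (is_traj) length(d$frames) else 1L,
    z_steps = sum(as.character(final_labels) == "Z"),
    junctions = sum(as.character(final_labels) == "junction"),
    n_events = nrow(events),
    z_segments = segs,
    z_stretch = stretch)
  invisible(list(torsions = tor_out, steps = steps0, grooves = grooves,
                 labels = lab_df, segments = segs, events = events,
                 rmsd = rmsd_df, summary = summary))
}

# chi of one residue in one frame (lightweight; avoids recomputing the
# whole torsion table per frame)
compute_torsions_residue <- function(d, strand, pos, frame) {
  xyz <- d$frames[[frame]]
  rt <- residue_table(d)
  base <- rt$resid[rt$strand == strand & rt$pos == pos]
  pts <- list(atom_xyz(d, strand, pos, "O4'", xyz),
              atom_xyz(d, strand, pos, "C1'", xyz),
              atom_xyz(d, strand, pos, .glyco_n[[base]], xyz),
              atom_xyz(d, strand, pos, .chi_ref[[base]], xyz))
  if (any(vapply(pts, is.null, TRUE))) return(NA_real_)
  dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
}
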