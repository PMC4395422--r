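# Structure and trajectory I/O plus duplex topology.
#
# A `duplex` object holds one DNA duplex:
#   $atoms  data.frame: serial, atom, resid (one-letter), chain, resno
#           (as in the file), strand (1 or 2), pos (1-based 5'->3' within
#           the strand), number (continuous numbering across both strands,
#           C_1 ... G_36 style), label ("A_8")
#   $xyz    n_atoms x 3 coordinate matrix (Angstrom)
#   $pairing data.frame(pos1, pos2): strand-1 position paired with strand-2
#           position (both 1-based 5'->3'); mismatches are retained
#   $n      strand length
#
# A `duplex_trajectory` adds $frames (list of xyz matrices) and $times (ps).
# Single-model I/O is delegated to bio3d; multi-model files additionally get
# a light MODEL-block scan so that inconsistent models are reported as
# format errors rather than silently merged.

new_duplex <- function(atoms, xyz, pairing = NULL) {
  stopifnot(nrow(atoms) == nrow(xyz))
  n <- max(atoms$pos[atoms$strand == 1L])
  obj <- list(atoms = atoms, xyz = xyz, pairing = pairing, n = n)
  class(obj) <- "duplex"
  if (is.null(pairing)) obj$pairing <- infer_pairing(obj)
  obj
}

#' @export
print.duplex <- function(x, ...) {
  s1 <- paste(residue_table(x)$resid[residue_table(x)$strand == 1], collapse = "")
  s2 <- paste(residue_table(x)$resid[residue_table(x)$strand == 2], collapse = "")
  cat("DNA duplex, ", x$n, " bp\n", sep = "")
  cat("  strand1 5'-", s1, "-3'\n", sep = "")
  cat("  strand2 5'-", s2, "-3'\n", sep = "")
  cat("  ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Residue-level view of a duplex
#'
#' @param x A `duplex`.
#' @return data.frame with one row per residue: strand, pos, resid, number
#'   (continuous numbering across both strands) and label.
#' @export
residue_table <- function(x) {
  a <- x$atoms
  unique(a[, c("strand", "pos", "resid", "number", "label")])
}

# index of one atom; NA if absent
atom_index <- function(x, strand, pos, atom) {
  a <- x$atoms
  w <- which(a$strand == strand & a$pos == pos & a$atom == atom)
  if (length(w) == 0) NA_integer_ else w[1]
}

atom_xyz <- function(x, strand, pos, atom, xyz = x$xyz) {
  i <- atom_index(x, strand, pos, atom)
  if (is.na(i)) return(NULL)
  xyz[i, ]
}

# resolve a "ATOM(LABEL)" spec such as "N2(G_24)" to an atom index
resolve_spec <- function(x, spec) {
  m <- regmatches(spec, regexec("^\\s*([A-Za-z0-9']+)\\s*\\(\\s*([A-Za-z]_?[0-9]+)\\s*\\)\\s*$",
                                spec))[[1]]
  if (length(m) != 3) {
    stop("cannot parse atom spec '", spec, "'; expected e.g. \"N2(G_24)\"",
         call. = FALSE)
  }
  atom <- m[2]
  lab <- sub("^([A-Za-z])([0-9]+)$", "\\1_\\2", m[3])
  a <- x$atoms
  w <- which(a$label == lab & a$atom == atom)
  if (length(w) == 0) {
    stop("atom spec '", spec, "' does not resolve in this topology",
         call. = FALSE)
  }
  w[1]
}

#' Infer the base-pairing map of an antiparallel duplex
#'
#' Default pairing is position `i` on strand 1 with position `N + 1 - i` on
#' strand 2 (both 1-based, 5'->3').  Mismatched pairs (such as A...A) are
#' retained, not rejected.
#'
#' @param x A `duplex`, or a list with elements `strand1`/`strand2` giving
#'   the two sequences 5'->3'.
#' @return data.frame with columns `pos1`, `pos2`.
#' @export
infer_pairing <- function(x) {
  if (inherits(x, "duplex")) {
    rt <- residue_table(x)
    n1 <- sum(rt$strand == 1)
    n2 <- sum(rt$strand == 2)
  } else {
    n1 <- length(strsplit(paste(x$strand1, collapse = ""), "")[[1]])
    n2 <- length(strsplit(paste(x$strand2, collapse = ""), "")[[1]])
  }
  if (n1 != n2) {
    stop("pairing error: strands have unequal lengths (", n1, " vs ", n2, ")",
         call. = FALSE)
  }
  data.frame(pos1 = seq_len(n1), pos2 = n1 + 1L - seq_len(n1))
}

# assemble the atoms table for a strand-organised coordinate build
make_atoms <- function(res_list) {
  # res_list: list of list(strand, pos, resid, atoms = matrix with rownames)
  rows <- list()
  serial <- 0L
  n1 <- sum(vapply(res_list, function(r) r$strand == 1L, TRUE))
  for (r in res_list) {
    number <- if (r$strand == 1L) r$pos else n1 + r$pos
    for (an in rownames(r$atoms)) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, atom = an, resid = r$resid,
        chain = if (r$strand == 1L) "A" else "B",
        resno = number, strand = r$strand, pos = r$pos,
        number = number, label = paste0(r$resid, "_", number),
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  xyz <- do.call(rbind, lapply(res_list, function(r) r$atoms))
  rownames(xyz) <- NULL
  colnames(xyz) <- c("x", "y", "z")
  list(atoms = atoms, xyz = xyz)
}

## ---- reading --------------------------------------------------------------

#' Read a DNA duplex structure from PDB
#'
#' Accepts a path to a PDB file with exactly two DNA chains (or one chain
#' split at a TER record).  Non-nucleic residues raise an error; solvent and
#' ions (HOH, WAT, NA, CL, MG, K) are stripped with a message.  Missing
#' backbone atoms are flagged per residue with a warning, not an error.
#'
#' @param source Path to a PDB file.
#' @return A `duplex` object.
#' @export
read_structure <- function(source) {
  pdb <- bio3d::read.pdb(source, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), ]
  solvent <- c("HOH", "WAT", "NA", "CL", "MG", "K", "SPM")
  ns <- at$resid %in% solvent
  if (any(ns)) {
    message("stripped ", sum(ns), " solvent/ion atoms")
    at <- at[!ns, ]
  }
  known <- c("A", "C", "G", "T", "DA", "DC", "DG", "DT")
  if (!all(at$resid %in% known)) {
    bad <- setdiff(unique(at$resid), known)
    stop("unsupported residue(s) in PDB: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  at <- at[substr(at$elety, 1, 1) != "H", ]

  chains <- unique(at$chain)
  if (length(chains) == 1) {
    # single chain: split at the largest residue-number gap or TER handled
    # by bio3d as same chain; fall back to halving
    res_ids <- unique(at$resno)
    if (length(res_ids) %% 2 != 0) {
      stop("cannot split single chain with odd residue count into a duplex",
           call. = FALSE)
    }
    half <- res_ids[length(res_ids) / 2]
    strand <- ifelse(at$resno <= half, 1L, 2L)
  } else if (length(chains) == 2) {
    strand <- ifelse(at$chain == chains[1], 1L, 2L)
  } else {
    stop("expected one or two DNA chains, found ", length(chains), call. = FALSE)
  }

  res_list <- list()
  for (s in 1:2) {
    sel <- strand == s
    resnos <- unique(at$resno[sel])
    for (k in seq_along(resnos)) {
      rows <- which(sel & at$resno == resnos[k])
      m <- as.matrix(at[rows, c("x", "y", "z")])
      rownames(m) <- at$elety[rows]
      res_list[[length(res_list) + 1]] <- list(
        strand = s, pos = k,
        resid = normalize_residue_name(at$resid[rows[1]]),
        atoms = m)
    }
  }
  parts <- make_atoms(res_list)
  bb <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'", "O4'", "C1'")
  for (r in res_list) {
    missing <- setdiff(setdiff(bb, c("P")), rownames(r$atoms))
    if (length(missing) > 0) {
      warning("residue strand", r$strand, ":", r$pos, " missing backbone atom(s): ",
              paste(missing, collapse = ","), call. = FALSE)
    }
  }
  new_duplex(parts$atoms, parts$xyz)
}

#' Write a duplex (optionally with trajectory frames) to PDB
#'
#' Coordinates are written at the standard PDB 3-decimal precision; residue
#' names use the DA/DC/DG/DT dialect.  When `frames` is supplied each frame
#' becomes one MODEL block.
#'
#' @param x A `duplex`.
#' @param file Output path.
#' @param frames Optional list of xyz matrices (multi-model output).
#' @return `file`, invisibly.
#' @export
write_structure <- function(x, file, frames = NULL) {
  a <- x$atoms
  fmt_atom <- function(i, xyz, serial) {
    name <- a$atom[i]
    name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %4s %-3s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            serial, name_fmt, paste0("D", a$resid[i]), a$chain[i], a$resno[i],
            xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0)
  }
  write_model <- function(con, xyz) {
    serial <- 0L
    for (s in 1:2) {
      idx <- which(a$strand == s)
      for (i in idx) {
        serial <- serial + 1L
        writeLines(fmt_atom(i, xyz, serial), con)
      }
      writeLines("TER", con)
    }
  }
  con <- file(file, "w")
  on.exit(close(con))
  if (is.null(frames)) {
    write_model(con, x$xyz)
  } else {
    for (k in seq_along(frames)) {
      writeLines(sprintf("MODEL     %4d", k), con)
      write_model(con, frames[[k]])
      writeLines("ENDMDL", con)
    }
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a multi-model PDB as a trajectory
#'
#' One frame per MODEL block.  All models must share one atom ordering;
#' otherwise a format error is raised.  Frame times come from a sidecar file
#' (`frame_index<TAB>time_ps`) when given, else uniform spacing.
#'
#' @param source Path to a (multi-model) PDB file.
#' @param dt_ps Frame spacing in ps used when no sidecar is given
#'   (default 100 ps = 0.1 ns).
#' @param times_file Optional path to a two-column tab-separated sidecar.
#' @return A `duplex_trajectory`: a `duplex` plus `$frames` and `$times`.
#' @export
read_trajectory <- function(source, dt_ps = 100, times_file = NULL) {
  lines <- readLines(source)
  model_starts <- grep("^MODEL", lines)
  n_models <- max(1L, length(model_starts))

  # validate per-model atom ordering before handing off to bio3d
  if (length(model_starts) > 0) {
    sig <- NULL
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts)) {
      stop("format error: unbalanced MODEL/ENDMDL records", call. = FALSE)
    }
    for (k in seq_along(model_starts)) {
      blk <- lines[model_starts[k]:model_ends[k]]
      atoms <- blk[grepl("^(ATOM|HETATM)", blk)]
      this_sig <- paste(substr(atoms, 13, 27), collapse = "\n")
      if (is.null(sig)) {
        sig <- this_sig
      } else if (!identical(sig, this_sig)) {
        stop("format error: model ", k,
             " has a different atom count or ordering", call. = FALSE)
      }
    }
  }

  pdb <- bio3d::read.pdb(source, multi = n_models > 1, verbose = FALSE)
  first <- read_structure_from_lines(lines, model_starts)
  frames <- vector("list", n_models)
  if (n_models > 1) {
    for (k in seq_len(n_models)) {
      frames[[k]] <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
    }
  } else {
    frames[[1]] <- matrix(as.numeric(pdb$xyz), ncol = 3, byrow = TRUE)
  }
  # align frame atom order with the duplex atom table (file order is kept,
  # so this is one-to-one already)
  times <- if (!is.null(times_file)) {
    tt <- utils::read.table(times_file, sep = "\t", header = FALSE)
    as.numeric(tt[[2]])[seq_len(n_models)]
  } else {
    (seq_len(n_models) - 1) * dt_ps
  }
  if (any(diff(times) <= 0)) {
    stop("trajectory times must be strictly increasing", call. = FALSE)
  }
  out <- first
  out$xyz <- frames[[1]]
  out$frames <- frames
  out$times <- times
  class(out) <- c("duplex_trajectory", "duplex")
  out
}

# parse the first model with read_structure semantics (via a temp file so the
# same validation applies)
read_structure_from_lines <- function(lines, model_starts) {
  if (length(model_starts) > 0) {
    ends <- grep("^ENDMDL", lines)
    lines <- lines[(model_starts[1] + 1):(ends[1] - 1)]
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(c(lines, "END"), tf)
  read_structure(tf)
}

#' @export
print.duplex_trajectory <- function(x, ...) {
  cat("DNA duplex trajectory: ", length(x$frames), " frames, ",
      x$n, " bp, t = ", x$times[1], "..", x$times[length(x$times)], " ps\n",
      sep = "")
  invisible(x)
}
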