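# Multi-frame analyses: backbone RMSD stability, hydrogen-bond occupancy and
# angle statistics, per-frame triage timelines, and window slicing.

# materialise frame f of a trajectory as list(protein, ligand)
frame_complex <- function(traj, f, ligand_resname = NULL) {
  topo <- traj$topology
  xyz <- traj$frames[[f]]
  if (inherits(topo, "pf_protein")) {
    prot <- topo
    prot$atoms[, c("x", "y", "z")] <- xyz
    lig <- NULL
    if (!is.null(ligand_resname)) {
      lig <- extract_ligand(prot, ligand_resname)
    }
    return(list(protein = prot, ligand = lig))
  }
  np <- nrow(topo$protein$atoms)
  prot <- topo$protein
  prot$atoms[, c("x", "y", "z")] <- xyz[seq_len(np), , drop = FALSE]
  lig <- topo$ligand
  if (!is.null(lig))
    lig$conformers[[1]] <- xyz[np + seq_len(n_atoms(lig)), , drop = FALSE]
  list(protein = prot, ligand = lig)
}

traj_protein <- function(traj) {
  if (inherits(traj$topology, "pf_protein")) traj$topology
  else traj$topology$protein
}

#' Backbone RMSD time series of a trajectory
#'
#' Each frame is superposed (Kabsch) onto the reference frame on the protein
#' backbone atoms (names N, CA, C, O; HETATM excluded) before the RMSD is
#' measured over those same atoms.
#'
#' @param traj a \code{pf_traj}.
#' @param reference_frame index of the reference frame (default 1).
#' @return data.frame of class \code{pf_rmsd_series} with columns
#'   \code{time} (ns) and \code{rmsd} (A); attribute \code{reference}
#'   describes the reference.
#' @export
backbone_rmsd <- function(traj, reference_frame = 1L) {
  prot <- traj_protein(traj)
  bb <- which(!prot$atoms$het & prot$atoms$name %in% BACKBONE_NAMES &
                prot$atoms$element != "H")
  if (!length(bb)) stopf("backbone_rmsd: no backbone atoms (N, CA, C, O)")
  ref <- traj$frames[[reference_frame]][bb, , drop = FALSE]
  vals <- vapply(traj$frames, function(fr)
    kabsch_fit(fr[bb, , drop = FALSE], ref)$rmsd, 1)
  out <- data.frame(time = traj$times, rmsd = vals)
  attr(out, "reference") <- sprintf("frame %d (t = %.3f ns), %d backbone atoms",
                                    reference_frame,
                                    traj$times[reference_frame], length(bb))
  class(out) <- c("pf_rmsd_series", "data.frame")
  out
}

#' @export
plot.pf_rmsd_series <- function(x, threshold = 2.5, ...) {
  graphics::plot(x$time, x$rmsd, type = "l", xlab = "time (ns)",
                 ylab = "backbone RMSD (A)", ...)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Trajectory stability flag
#'
#' A system is called stable iff the maximum backbone RMSD stays strictly
#' below the threshold (default 2.5 A): max 2.49 is stable, max 2.50 is not.
#'
#' @param rmsd_series a \code{pf_rmsd_series} or numeric vector of RMSD
#'   values in Angstrom.
#' @param threshold strict upper bound in Angstrom (default 2.5).
#' @return Logical flag.
#' @export
is_stable <- function(rmsd_series, threshold = 2.5) {
  vals <- if (is.data.frame(rmsd_series)) rmsd_series$rmsd else rmsd_series
  if (!length(vals)) stopf("is_stable: empty RMSD series")
  max(vals) < threshold
}

#' Hydrogen-bond occupancy over a trajectory window
#'
#' Presence is evaluated per frame with \code{\link{detect_hbonds}}
#' restricted to the specified protein residue; occupancy is the fraction of
#' in-window frames where at least one such bond exists. Angle statistics are
#' computed over the present frames that carry an explicit hydrogen.
#'
#' @param traj a \code{pf_traj} whose topology includes the ligand (either a
#'   \code{list(protein, ligand)} topology or HETATM rows plus
#'   \code{ligand_resname}).
#' @param residue protein residue key, e.g. \code{"Gln421"}.
#' @param window numeric \code{c(t_start, t_end)} in ns (default
#'   \code{c(0, 20)}, the early-trajectory convention); must overlap the
#'   trajectory time range.
#' @param dist_max,angle_min H-bond criteria (see
#'   \code{\link{detect_hbonds}}).
#' @param ligand_resname het residue name when the ligand lives in the
#'   topology's atom table.
#' @return A list of class \code{pf_occupancy}: \code{residue},
#'   \code{window}, \code{frames_in_window}, \code{frames_with_contact},
#'   \code{occupancy}, \code{mean_angle}, \code{sd_angle},
#'   \code{present} (per-in-window-frame logical).
#' @export
hbond_occupancy <- function(traj, residue, window = c(0, 20),
                            dist_max = 3.5, angle_min = 120,
                            ligand_resname = NULL) {
  if (window[1] >= window[2])
    stopf("hbond_occupancy: empty window [%g, %g]", window[1], window[2])
  if (window[1] > max(traj$times) || window[2] < min(traj$times))
    stopf("hbond_occupancy: window [%g, %g] ns outside trajectory range [%g, %g]",
          window[1], window[2], min(traj$times), max(traj$times))
  in_win <- which(traj$times >= window[1] & traj$times <= window[2])
  present <- logical(length(in_win))
  angles <- numeric(0)
  for (k in seq_along(in_win)) {
    cx <- frame_complex(traj, in_win[k], ligand_resname)
    if (is.null(cx$ligand))
      stopf("hbond_occupancy: trajectory topology has no ligand")
    hb <- detect_hbonds(cx$protein, cx$ligand, dist_max, angle_min,
                        residues = residue)
    present[k] <- nrow(hb) > 0L
    if (present[k]) {
      a <- hb$angle[!is.na(hb$angle)]
      if (length(a)) angles <- c(angles, max(a))
    }
  }
  structure(list(residue = residue, window = window,
                 frames_in_window = length(in_win),
                 frames_with_contact = sum(present),
                 occupancy = sum(present) / length(in_win),
                 mean_angle = if (length(angles)) mean(angles) else NA_real_,
                 sd_angle = if (length(angles) > 1) stats::sd(angles)
                            else NA_real_,
                 present = present),
            class = "pf_occupancy")
}

#' @export
print.pf_occupancy <- function(x, ...) {
  cat(sprintf("<pf_occupancy> %s over [%g, %g] ns: %d/%d frames (%.1f%%)",
              x$residue, x$window[1], x$window[2], x$frames_with_contact,
              x$frames_in_window, 100 * x$occupancy))
  if (!is.na(x$mean_angle))
    cat(sprintf(", mean angle %.1f deg (sd %.1f)", x$mean_angle,
                x$sd_angle %||% NA))
  cat("\n")
  invisible(x)
}

#' Per-frame triage timeline of a trajectory
#'
#' Applies \code{\link{triage_pose}} to every frame and summarises the
#' fraction of frames passing round 1.
#'
#' @param traj a \code{pf_traj} including the ligand.
#' @param config a \code{\link{triage_config}}.
#' @param ligand_resname het residue name when the ligand lives in the
#'   topology's atom table.
#' @return data.frame with columns \code{time}, \code{round1_pass},
#'   \code{round2_preferred}, \code{clash_count}; attribute
#'   \code{fraction_round1}.
#' @export
contact_timeline <- function(traj, config = triage_config(),
                             ligand_resname = NULL) {
  if (!length(traj$frames)) stopf("contact_timeline: empty trajectory")
  rows <- lapply(seq_along(traj$frames), function(f) {
    cx <- frame_complex(traj, f, ligand_resname)
    if (is.null(cx$ligand))
      stopf("contact_timeline: trajectory topology has no ligand")
    td <- triage_pose(cx$protein, cx$ligand, config)
    data.frame(time = traj$times[f], round1_pass = td$round1_pass,
               round2_preferred = td$round2_preferred,
               clash_count = td$clash_count)
  })
  out <- do.call(rbind, rows)
  attr(out, "fraction_round1") <- mean(out$round1_pass)
  out
}

#' Slice a trajectory to a time window
#'
#' Utility backing windowed conventions such as snapshot extraction over the
#' final nanoseconds of a production run.
#'
#' @param traj a \code{pf_traj}.
#' @param window numeric \code{c(t_start, t_end)} in ns, inclusive.
#' @return A \code{pf_traj} restricted to the in-window frames.
#' @export
slice_window <- function(traj, window) {
  keep <- which(traj$times >= window[1] & traj$times <= window[2])
  if (!length(keep))
    stopf("slice_window: no frames in [%g, %g] ns", window[1], window[2])
  trajectory(traj$topology, traj$frames[keep], traj$times[keep])
}
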