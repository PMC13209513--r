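# End-to-end funnel driver: pharmacophore screen -> pose triage ->
# stability filter -> energy ranking -> energy-window enrichment. Stages
# with missing inputs are skipped and logged, never silently; survivor
# counts are monotone non-increasing.

#' Funnel configuration
#'
#' All stage thresholds in one declarative object. Defaults follow the
#' screening campaign conventions: strict backbone-RMSD stability below
#' 2.5 A, activity beyond 50 percent inhibition at 10 uM, energy windows at
#' -40/-30/-20 kcal/mol.
#'
#' @param triage a \code{\link{triage_config}}.
#' @param stability_threshold strict backbone RMSD bound in A (default 2.5).
#' @param activity_concentration assay concentration in uM (default 10).
#' @param activity_threshold strict percent-inhibition threshold
#'   (default 50).
#' @param energy_boundaries energy window boundaries in kcal/mol
#'   (default -40, -30, -20).
#' @param occupancy_window H-bond occupancy window in ns (default 0-20).
#' @param seed integer seed recorded in reports.
#' @return A named list of class \code{pf_funnel_config}.
#' @export
funnel_config <- function(triage = triage_config(),
                          stability_threshold = 2.5,
                          activity_concentration = 10,
                          activity_threshold = 50,
                          energy_boundaries = c(-40, -30, -20),
                          occupancy_window = c(0, 20),
                          seed = 17L) {
  structure(list(triage = triage,
                 stability_threshold = stability_threshold,
                 activity_concentration = activity_concentration,
                 activity_threshold = activity_threshold,
                 energy_boundaries = energy_boundaries,
                 occupancy_window = occupancy_window,
                 seed = as.integer(seed)),
            class = "pf_funnel_config")
}

#' Run the virtual-screening funnel
#'
#' Executes the available stages in order on whatever inputs are supplied:
#' \enumerate{
#'   \item pharmacophore screen (\code{model} + \code{molecules});
#'   \item pose triage (\code{poses}: named list of
#'     \code{list(protein, ligand)} complexes, names = compound ids);
#'   \item backbone-RMSD stability filter (\code{trajectories}: named list
#'     of \code{pf_traj});
#'   \item energy ranking and \item energy-window enrichment
#'     (\code{records}: a \code{pf_screening} table).
#' }
#' A compound survives a stage only if it also survived the previous ones;
#' stages without inputs are marked skipped and filter nothing.
#'
#' @param config a \code{\link{funnel_config}}.
#' @param model optional \code{pf_model}.
#' @param molecules optional list of \code{pf_mol}.
#' @param poses optional named list of complexes.
#' @param trajectories optional named list of \code{pf_traj}.
#' @param records optional \code{pf_screening} data.frame.
#' @return A list of class \code{pf_funnel_report}: \code{stages}
#'   (data.frame of per-stage counts and status), \code{survivors},
#'   \code{ranking}, \code{windows}, \code{details}.
#' @export
run_funnel <- function(config = funnel_config(), model = NULL,
                       molecules = NULL, poses = NULL, trajectories = NULL,
                       records = NULL) {
  stages <- data.frame(stage = character(0), status = character(0),
                       n_in = integer(0), n_out = integer(0))
  details <- list()
  survivors <- NULL   # NULL = universe not yet constrained
  note <- function(stage, status, n_in, n_out) {
    stages <<- rbind(stages, data.frame(stage = stage, status = status,
                                        n_in = n_in, n_out = n_out))
  }
  restrict <- function(ids) {
    if (is.null(survivors)) ids else intersect(survivors, ids)
  }

  if (!is.null(model) && !is.null(molecules)) {
    scr <- screen_library(model, molecules)
    survivors <- attr(scr, "hits")
    details$screen <- scr
    note("pharmacophore_screen", "run", nrow(scr), length(survivors))
  } else {
    note("pharmacophore_screen", "skipped", NA, NA)
    message("funnel: pharmacophore screen skipped (no model or molecules)")
  }

  if (!is.null(poses)) {
    cand <- restrict(names(poses))
    dec <- lapply(poses[cand], function(px)
      triage_pose(px$protein, px$ligand, config$triage))
    keep <- cand[vapply(dec, `[[`, TRUE, "round1_pass")]
    details$triage <- dec
    n_in <- if (is.null(survivors)) length(cand) else length(survivors)
    survivors <- if (is.null(survivors)) keep else intersect(survivors, keep)
    note("pose_triage", "run", n_in, length(survivors))
  } else {
    note("pose_triage", "skipped", NA, NA)
    message("funnel: pose triage skipped (no poses)")
  }

  if (!is.null(trajectories)) {
    cand <- restrict(names(trajectories))
    stab <- vapply(trajectories[cand], function(tr)
      is_stable(backbone_rmsd(tr), config$stability_threshold), TRUE)
    keep <- cand[stab]
    details$stability <- stab
    n_in <- if (is.null(survivors)) length(cand) else length(survivors)
    survivors <- if (is.null(survivors)) keep else intersect(survivors, keep)
    note("stability_filter", "run", n_in, length(survivors))
  } else {
    note("stability_filter", "skipped", NA, NA)
    message("funnel: stability filter skipped (no trajectories)")
  }

  ranking <- NULL; windows <- NULL
  if (!is.null(records)) {
    sel <- if (is.null(survivors)) records else
      records[records$id %in% survivors, , drop = FALSE]
    ranking <- rank_by_energy(sel)
    windows <- energy_window_enrichment(
      sel, config$energy_boundaries,
      concentration = config$activity_concentration,
      threshold_pct = config$activity_threshold)
    n_in <- if (is.null(survivors)) nrow(records) else length(survivors)
    survivors <- ranking
    note("energy_ranking", "run", n_in, length(ranking))
    note("window_enrichment", "run", length(ranking), length(ranking))
  } else {
    note("energy_ranking", "skipped", NA, NA)
    note("window_enrichment", "skipped", NA, NA)
    message("funnel: energy stages skipped (no records)")
  }

  structure(list(stages = stages,
                 survivors = survivors %||% character(0),
                 ranking = ranking, windows = windows,
                 config = config, details = details),
            class = "pf_funnel_report")
}

#' @export
print.pf_funnel_report <- function(x, ...) {
  cat("<pf_funnel_report>\n")
  for (r in seq_len(nrow(x$stages))) {
    s <- x$stages[r, ]
    if (s$status == "run") {
      cat(sprintf("  %-20s %4d -> %4d\n", s$stage, s$n_in, s$n_out))
    } else {
      cat(sprintf("  %-20s skipped\n", s$stage))
    }
  }
  cat(sprintf("  survivors: %d\n", length(x$survivors)))
  invisible(x)
}
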