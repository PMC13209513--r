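# Screening validation metrics and activity/energy analyses: enrichment
# factor, Goodness-of-Hit, TPR/FPR, activity-threshold filtering,
# binding-energy-window enrichment, energy ranking, per-residue
# decomposition summaries, selectivity classification.

#' Confusion counts of a screening test set
#'
#' @param D total number of compounds in the test set.
#' @param A total number of active compounds.
#' @param Ht total number of hit compounds.
#' @param Ha number of known actives among the hits.
#' @return A validated list of class \code{pf_counts}.
#' @export
confusion_counts <- function(D, A, Ht, Ha) {
  D <- as.integer(D); A <- as.integer(A)
  Ht <- as.integer(Ht); Ha <- as.integer(Ha)
  if (A > D) stopf("confusion_counts: A (%d) > D (%d)", A, D)
  if (Ht > D) stopf("confusion_counts: Ht (%d) > D (%d)", Ht, D)
  if (Ha > min(A, Ht) || Ha < 0L)
    stopf("confusion_counts: need 0 <= Ha <= min(A, Ht)")
  structure(list(D = D, A = A, Ht = Ht, Ha = Ha), class = "pf_counts")
}

#' Enrichment factor
#'
#' EF = (Ha/Ht) x (D/A): the concentration of actives among the hits
#' relative to the whole library.
#'
#' @param counts a \code{\link{confusion_counts}} object.
#' @return Numeric EF (report to 2 decimals in summaries).
#' @export
enrichment_factor <- function(counts) {
  if (counts$Ht == 0L || counts$A == 0L)
    stopf("enrichment_factor: undefined for Ht = 0 or A = 0")
  (counts$Ha / counts$Ht) * (counts$D / counts$A)
}

#' Goodness-of-Hit score
#'
#' GH = (Ha/A) x [(3A + Ht)/(4 Ht)] x [1 - (Ht - Ha)/(D - A)]; a composite
#' of recall and precision, with > 0.5 conventionally deemed acceptable
#' model quality.
#'
#' @param counts a \code{\link{confusion_counts}} object.
#' @return Numeric GH score (report to 2 decimals in summaries).
#' @export
gh_score <- function(counts) {
  if (counts$Ht == 0L || counts$A == 0L)
    stopf("gh_score: undefined for Ht = 0 or A = 0")
  if (counts$D == counts$A) stopf("gh_score: undefined for D = A")
  (counts$Ha / counts$A) *
    ((3 * counts$A + counts$Ht) / (4 * counts$Ht)) *
    (1 - (counts$Ht - counts$Ha) / (counts$D - counts$A))
}

#' True and false positive rates
#'
#' TPR = Ha/A; FPR = (Ht - Ha)/(D - A).
#'
#' @param counts a \code{\link{confusion_counts}} object.
#' @return Named numeric vector \code{c(tpr, fpr)}.
#' @export
rates <- function(counts) {
  if (counts$A == 0L) stopf("rates: undefined for A = 0")
  if (counts$D == counts$A) stopf("rates: undefined for D = A")
  c(tpr = counts$Ha / counts$A,
    fpr = (counts$Ht - counts$Ha) / (counts$D - counts$A))
}

#' Filter screening records by inhibition at a concentration
#'
#' A record is a hit iff its inhibition at the given concentration is
#' strictly greater than the threshold. Records without a measurement at
#' that concentration (n.d.) are excluded from both numerator and
#' denominator.
#'
#' @param records a \code{pf_screening} data.frame
#'   (see \code{\link{read_screening_csv}}).
#' @param concentration assay concentration in micromolar (default 10).
#' @param threshold_pct strict percent-inhibition threshold (default 50).
#' @return List: \code{hits} (ids), \code{n_evaluated},
#'   \code{hit_rate} (percent, rounded half away from zero).
#' @export
activity_filter <- function(records, concentration = 10, threshold_pct = 50) {
  inh <- inh_column(records, concentration)
  have <- !is.na(inh)
  if (!any(have))
    stopf("activity_filter: no record carries a %g uM measurement",
          concentration)
  hits <- records$id[have & inh > threshold_pct]
  list(hits = hits, n_evaluated = sum(have),
       hit_rate = round_half_up(100 * length(hits) / sum(have)))
}

#' Binding-energy-window enrichment
#'
#' Partitions the records by predicted binding free energy into
#' right-open windows \code{(-Inf, b1), [b1, b2), ..., [bk, Inf)} and
#' reports, per window, the count and percentage of active compounds
#' (activity by \code{\link{activity_filter}} criteria; records without the
#' activity measurement count toward the window total but not the actives).
#'
#' @param records a \code{pf_screening} data.frame.
#' @param boundaries increasing window boundaries in kcal/mol
#'   (default -40, -30, -20).
#' @param concentration,threshold_pct activity criteria (default 10 uM,
#'   > 50 percent).
#' @return data.frame: \code{lower}, \code{upper}, \code{n_total},
#'   \code{n_active}, \code{percent_active} (rounded half away from zero,
#'   NA when the window is empty).
#' @export
energy_window_enrichment <- function(records, boundaries = c(-40, -30, -20),
                                     concentration = 10, threshold_pct = 50) {
  if (is.unsorted(boundaries, strictly = TRUE))
    stopf("energy_window_enrichment: boundaries must be strictly increasing")
  inh <- inh_column(records, concentration)
  active <- !is.na(inh) & inh > threshold_pct
  edges <- c(-Inf, boundaries, Inf)
  out <- data.frame(lower = edges[-length(edges)], upper = edges[-1],
                    n_total = 0L, n_active = 0L, percent_active = NA_real_)
  for (w in seq_len(nrow(out))) {
    in_w <- records$dg_mean >= out$lower[w] & records$dg_mean < out$upper[w]
    out$n_total[w] <- sum(in_w)
    out$n_active[w] <- sum(in_w & active)
    if (out$n_total[w] > 0)
      out$percent_active[w] <-
        round_half_up(100 * out$n_active[w] / out$n_total[w])
  }
  out
}

#' Rank screening records by predicted binding energy
#'
#' @param records a \code{pf_screening} data.frame.
#' @param ascending sort most negative (most favorable) first
#'   (default TRUE). Ties broken by id, lexicographically.
#' @return Character vector of ids in rank order.
#' @export
rank_by_energy <- function(records, ascending = TRUE) {
  ord <- order(if (ascending) records$dg_mean else -records$dg_mean,
               records$id)
  records$id[ord]
}

#' Residues contributing significantly to binding
#'
#' From a per-residue energy decomposition table (one row per residue, one
#' numeric column per complex, kcal/mol), selects residues whose
#' contribution is strictly below the cutoff in at least one complex,
#' sorted by their most favorable (lowest) energy.
#'
#' @param decomposition data.frame: first column \code{residue}, remaining
#'   numeric columns one per complex.
#' @param cutoff strict upper bound in kcal/mol (default -1.0).
#' @return data.frame \code{residue}, \code{best_energy}, sorted; possibly
#'   zero rows.
#' @export
significant_residues <- function(decomposition, cutoff = -1.0) {
  if (!nrow(decomposition)) stopf("significant_residues: empty table")
  vals <- as.matrix(decomposition[, -1, drop = FALSE])
  best <- apply(vals, 1, min, na.rm = TRUE)
  keep <- apply(vals, 1, function(v) any(v < cutoff, na.rm = TRUE))
  out <- data.frame(residue = decomposition[[1]][keep],
                    best_energy = best[keep], stringsAsFactors = FALSE)
  out[order(out$best_energy), , drop = FALSE]
}

#' Classify on-target vs off-target selectivity of a compound
#'
#' Selective iff active on-target (> threshold percent inhibition at
#' \code{conc_on}) and inactive off-target (<= threshold at
#' \code{conc_off}); the selectivity fold is \code{conc_off / conc_on}.
#' Missing measurements yield "undetermined".
#'
#' @param record one-row \code{pf_screening} data.frame (on-target).
#' @param off_record one-row \code{pf_screening} data.frame for the same
#'   compound against the off-target.
#' @param conc_on on-target assay concentration in uM (default 10).
#' @param conc_off off-target assay concentration in uM (default 50).
#' @param threshold_pct percent threshold (default 50).
#' @return List: \code{class} in \{"selective", "non_selective",
#'   "undetermined"\} and \code{fold}.
#' @export
selectivity_class <- function(record, off_record, conc_on = 10,
                              conc_off = 50, threshold_pct = 50) {
  fold <- conc_off / conc_on
  on <- tryCatch(inh_column(record, conc_on), error = function(e) NA_real_)
  off <- tryCatch(inh_column(off_record, conc_off),
                  error = function(e) NA_real_)
  if (length(on) != 1L || length(off) != 1L)
    stopf("selectivity_class: expects one-row records")
  if (is.na(on) || is.na(off))
    return(list(class = "undetermined", fold = fold))
  if (on > threshold_pct && off <= threshold_pct)
    list(class = "selective", fold = fold)
  else if (on > threshold_pct && off > threshold_pct)
    list(class = "non_selective", fold = fold)
  else list(class = "undetermined", fold = fold)
}
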