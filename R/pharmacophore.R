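# Pharmacophore models as tolerance spheres; matching by correspondence-graph
# clique search verified with Kabsch superposition; consensus construction
# from overlaid ligands; radius refinement against a labelled test set.

#' Construct a pharmacophore model
#'
#' A model is an ordered list of tolerance spheres: each feature has a kind,
#' a center (Angstrom, common 3D frame) and a radius. A conformer matches the
#' model when all features can be satisfied simultaneously after an optimal
#' rigid-body superposition.
#'
#' @param features data.frame with columns \code{label}, \code{kind},
#'   \code{x}, \code{y}, \code{z}, \code{radius}.
#' @param name model name.
#' @param provenance free-text provenance note.
#' @return An object of class \code{pf_model}.
#' @export
pharmacophore_model <- function(features, name = "model", provenance = "") {
  need <- c("label", "kind", "x", "y", "z", "radius")
  if (!all(need %in% names(features)))
    stopf("pharmacophore_model: features need columns %s",
          paste(need, collapse = ", "))
  if (nrow(features) < 3L)
    stopf("pharmacophore_model: needs >= 3 features")
  if (!all(features$kind %in% FEATURE_KINDS))
    stopf("pharmacophore_model: unknown kind(s): %s",
          paste(setdiff(features$kind, FEATURE_KINDS), collapse = ", "))
  if (any(!is.finite(features$radius) | features$radius <= 0 |
            features$radius > 3))
    stopf("pharmacophore_model: radii must lie in (0, 3] Angstrom")
  if (!all(is.finite(as.matrix(features[, c("x", "y", "z")]))))
    stopf("pharmacophore_model: non-finite feature centers")
  rownames(features) <- NULL
  structure(list(name = name, provenance = provenance,
                 features = features[, need]),
            class = "pf_model")
}

#' @export
print.pf_model <- function(x, ...) {
  cat(sprintf("<pf_model> %s: %d features\n", x$name, nrow(x$features)))
  f <- x$features
  for (k in seq_len(nrow(f)))
    cat(sprintf("  %-4s %-13s (%7.2f,%7.2f,%7.2f)  r=%.2f\n",
                f$label[k], f$kind[k], f$x[k], f$y[k], f$z[k], f$radius[k]))
  invisible(x)
}

model_centers <- function(model) as.matrix(model$features[, c("x", "y", "z")])

#' Read a pharmacophore model from JSON
#'
#' Schema: \code{{name, provenance?, features: [{label, kind,
#' center:[x,y,z], radius}]}}.
#'
#' @param path JSON file path.
#' @return A \code{pf_model}.
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- do.call(rbind, lapply(j$features, function(f) {
    data.frame(label = f$label, kind = f$kind,
               x = f$center[[1]], y = f$center[[2]], z = f$center[[3]],
               radius = f$radius, stringsAsFactors = FALSE)
  }))
  pharmacophore_model(feats, name = j$name %||% "model",
                      provenance = j$provenance %||% "")
}

#' Write a pharmacophore model to JSON
#'
#' @param model a \code{pf_model}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_model_json <- function(model, path) {
  f <- model$features
  obj <- list(name = model$name, provenance = model$provenance,
              features = lapply(seq_len(nrow(f)), function(k) {
                list(label = f$label[k], kind = f$kind[k],
                     center = c(f$x[k], f$y[k], f$z[k]),
                     radius = f$radius[k])
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The packaged refined PDE1 pharmacophore model
#'
#' Seven tolerance spheres: two aromatic ring centers (1.0 A radius), two
#' hydrogen-bond acceptors (0.7 A), a linking atom (0.7 A), an
#' aromatic/hydrophobic ring center (1.0 A) and a hydrophobic center
#' (1.0 A). Feature kinds and radii follow the refined model reported for
#' PDE1 inhibitors; the 3D centers are a synthetic overlay constructed for
#' this package (the original coordinates were never published), hence the
#' asset name.
#'
#' @return A \code{pf_model} with features F1-F7.
#' @export
default_pde1_model <- function() {
  read_model_json(system.file("extdata", "pde1_model_synthetic.json",
                              package = "pharmfunnel", mustWork = TRUE))
}

# feature/point kind compatibility; LINKER features accept any single-atom
# heavy point
kind_compatible <- function(feature_kind, point_kinds, point_n_atoms) {
  feature_kind %in% point_kinds ||
    (feature_kind == "LINKER" && point_n_atoms == 1L)
}

# Verify an ordered assignment (point row per feature): the assignment is
# valid iff some rigid transform places every point inside its tolerance
# sphere. The unweighted Kabsch optimum is tried first; if it leaves a point
# outside its sphere, a tolerance-weighted Kabsch iteration (weights
# escalating on the worst residual/radius ratios) searches for a feasible
# transform -- the least-squares optimum minimises the total, not the
# maximum, residual, so feasible assignments can otherwise be missed.
verify_assignment <- function(P, model, max_iter = 60L) {
  Q <- model_centers(model)
  radius <- model$features$radius
  fit <- kabsch_fit(P, Q)
  residuals <- sqrt(rowSums((fit$fitted - Q)^2))
  if (all(residuals <= radius + 1e-9))
    return(list(ok = TRUE, fit = fit, residuals = residuals))
  w <- rep(1, nrow(P))
  for (it in seq_len(max_iter)) {
    ratio <- residuals / radius
    w <- w * pmax(ratio, 0.2)^2
    w <- w / sum(w)
    wfit <- kabsch_fit(P, Q, weights = w)
    residuals <- sqrt(rowSums((wfit$fitted - Q)^2))
    if (all(residuals <= radius + 1e-9))
      return(list(ok = TRUE, fit = wfit, residuals = residuals))
  }
  list(ok = FALSE, fit = fit,
       residuals = sqrt(rowSums((fit$fitted - Q)^2)))
}

match_conformer <- function(model, points) {
  K <- nrow(model$features)
  npt <- nrow(points)
  if (npt < K) return(NULL)
  radius <- model$features$radius
  # correspondence graph: node = kind-compatible (point, feature) pair
  nodes <- list()
  for (p in seq_len(npt)) for (f in seq_len(K)) {
    if (kind_compatible(model$features$kind[f], points$kinds[[p]],
                        points$n_atoms[p]))
      nodes[[length(nodes) + 1L]] <- c(p, f)
  }
  if (length(nodes) < K) return(NULL)
  nd <- do.call(rbind, nodes)
  P <- feature_coords(points)
  dpt <- cross_dist(P, P)
  dft <- cross_dist(model_centers(model), model_centers(model))
  nn <- nrow(nd)
  edges <- list()
  for (u in seq_len(nn - 1L)) for (v in (u + 1L):nn) {
    if (nd[u, 1] == nd[v, 1] || nd[u, 2] == nd[v, 2]) next
    tol <- radius[nd[u, 2]] + radius[nd[v, 2]]
    if (abs(dpt[nd[u, 1], nd[v, 1]] - dft[nd[u, 2], nd[v, 2]]) <= tol)
      edges[[length(edges) + 1L]] <- c(u, v)
  }
  if (!length(edges)) return(NULL)
  g <- igraph::make_empty_graph(n = nn, directed = FALSE)
  g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  cl <- igraph::cliques(g, min = K, max = K)
  if (!length(cl)) return(NULL)
  best <- NULL
  for (c_ in cl) {
    sel <- nd[as.integer(c_), , drop = FALSE]
    ord <- order(sel[, 2])
    assignment <- sel[ord, 1]           # point index per feature, model order
    chk <- verify_assignment(P[assignment, , drop = FALSE], model)
    if (!chk$ok) next
    cand <- list(assignment = assignment, fit = chk$fit,
                 residuals = chk$residuals, fit_rmsd = chk$fit$rmsd)
    if (is.null(best) || cand$fit_rmsd < best$fit_rmsd - 1e-12 ||
        (abs(cand$fit_rmsd - best$fit_rmsd) <= 1e-12 &&
           paste(cand$assignment, collapse = ",") <
             paste(best$assignment, collapse = ","))) best <- cand
  }
  best
}

#' Match a perceived point set against a pharmacophore model
#'
#' Low-level single-conformer interface behind
#' \code{\link{match_pharmacophore}}: takes an already-perceived
#' \code{pf_features} point set instead of a molecule.
#'
#' @param model a \code{pf_model}.
#' @param points a \code{pf_features} data.frame
#'   (see \code{\link{perceive_features}}).
#' @return \code{NULL} when no valid assignment exists, else a list with
#'   \code{assignment}, \code{fit}, \code{residuals}, \code{fit_rmsd}.
#' @export
match_points <- function(model, points) {
  if (!nrow(points)) return(NULL)
  match_conformer(model, points)
}

#' Match a molecule against a pharmacophore model
#'
#' A conformer matches iff there is an injective, kind-compatible assignment
#' of its perceived feature points to all model features such that, after
#' optimal rigid-body (Kabsch) superposition of the assigned points onto the
#' feature centers, every point lies within its feature's tolerance radius.
#' Candidate assignments are enumerated as maximum cliques of the
#' correspondence graph (nodes: compatible point/feature pairs; edges between
#' pairs whose point-point and feature-feature distances agree within the sum
#' of the two radii). The best verified assignment over all conformers (by
#' fit RMSD, ties broken lexicographically) is returned.
#'
#' @param model a \code{pf_model}.
#' @param mol a \code{pf_mol} with >= 1 conformer.
#' @return A list of class \code{pf_match}: \code{matched} flag and, when
#'   matched, \code{conformer}, \code{assignment} (named integer: feature
#'   label -> point row), \code{rotation}, \code{translation},
#'   \code{fit_rmsd}, \code{residuals} (named, per feature).
#' @export
match_pharmacophore <- function(model, mol) {
  best <- NULL; best_cf <- NA_integer_
  for (cf in seq_len(n_conformers(mol))) {
    pts <- perceive_features(mol, cf)
    cand <- if (nrow(pts)) match_conformer(model, pts) else NULL
    if (!is.null(cand) &&
        (is.null(best) || cand$fit_rmsd < best$fit_rmsd)) {
      best <- cand; best_cf <- cf
    }
  }
  if (is.null(best)) {
    return(structure(list(matched = FALSE, id = mol$id,
                          n_conformers = n_conformers(mol)),
                     class = "pf_match"))
  }
  labels <- model$features$label
  structure(list(matched = TRUE, id = mol$id,
                 n_conformers = n_conformers(mol),
                 conformer = best_cf,
                 assignment = stats::setNames(best$assignment, labels),
                 rotation = best$fit$rotation,
                 translation = best$fit$translation,
                 fit_rmsd = best$fit_rmsd,
                 residuals = stats::setNames(best$residuals, labels)),
            class = "pf_match")
}

#' @export
print.pf_match <- function(x, ...) {
  if (x$matched) {
    cat(sprintf("<pf_match> %s: MATCH (conformer %d/%d, fit RMSD %.3f A)\n",
                x$id, x$conformer, x$n_conformers, x$fit_rmsd))
  } else {
    cat(sprintf("<pf_match> %s: no match (%d conformer(s))\n",
                x$id, x$n_conformers))
  }
  invisible(x)
}

#' Screen a library against a pharmacophore model
#'
#' A compound is a hit iff any of its conformers matches (see
#' \code{\link{match_pharmacophore}}). Input order is preserved.
#'
#' @param model a \code{pf_model}.
#' @param mols list of \code{pf_mol}.
#' @param verbose log each decision to the console.
#' @return data.frame with one row per compound: \code{id},
#'   \code{n_conformers}, \code{matched}, \code{best_conformer},
#'   \code{fit_rmsd}; attribute \code{hits} gives the hit ids in order.
#' @export
screen_library <- function(model, mols, verbose = FALSE) {
  rows <- lapply(mols, function(mol) {
    m <- match_pharmacophore(model, mol)
    if (verbose)
      message(sprintf("%s: %d conformers -> %s", mol$id, m$n_conformers,
                      if (m$matched) "hit" else "miss"))
    data.frame(id = mol$id, n_conformers = m$n_conformers,
               matched = m$matched,
               best_conformer = if (m$matched) m$conformer else NA_integer_,
               fit_rmsd = if (m$matched) m$fit_rmsd else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(id = character(0), n_conformers = integer(0),
               matched = logical(0), best_conformer = integer(0),
               fit_rmsd = numeric(0))
  attr(out, "hits") <- out$id[out$matched]
  out
}

#' Build a consensus pharmacophore model from overlaid ligands
#'
#' Feature points of identical kind across the (pre-superposed,
#' single-conformer) ligands are single-linkage clustered; clusters supported
#' by at least \code{min_support} distinct ligands become model features at
#' the cluster centroid, with a common initial radius. Co-located clusters of
#' different kinds arising from the same source points (e.g. an all-carbon
#' aromatic ring, which is both AROMATIC_RING and HYDROPHOBIC) are merged
#' into one feature, keeping the most specific kind
#' (AROMATIC_RING > HBA > HBD > HYDROPHOBIC > LINKER).
#'
#' @param ligands list of single-conformer \code{pf_mol}, all in one frame.
#' @param cluster_radius single-linkage cut height in Angstrom (default 1.5).
#' @param min_support minimum number of distinct supporting ligands
#'   (default: all of them).
#' @param initial_radius tolerance radius assigned to every feature
#'   (default 1.0 A).
#' @param name model name.
#' @return A \code{pf_model}; features ordered by descending support, then
#'   kind name, and labelled F1, F2, ...
#' @export
build_consensus_model <- function(ligands, cluster_radius = 1.5,
                                  min_support = length(ligands),
                                  initial_radius = 1.0,
                                  name = "consensus") {
  if (length(ligands) < 2L)
    stopf("build_consensus_model: needs >= 2 overlaid ligands")
  if (any(vapply(ligands, n_conformers, 1L) != 1L))
    stopf("build_consensus_model: ligands must be single-conformer")
  pts <- list()
  for (li in seq_along(ligands)) {
    f <- perceive_features(ligands[[li]], 1L)
    for (r in seq_len(nrow(f))) {
      for (kind in f$kinds[[r]]) {
        pts[[length(pts) + 1L]] <- list(
          kind = kind, ligand = li, xyz = c(f$x[r], f$y[r], f$z[r]),
          point_id = paste(li, r, sep = "."))
      }
    }
  }
  kinds <- vapply(pts, `[[`, "", "kind")
  clusters <- list()
  for (kind in unique(kinds)) {
    sel <- which(kinds == kind)
    X <- do.call(rbind, lapply(pts[sel], `[[`, "xyz"))
    member <- if (length(sel) == 1L) 1L else {
      hc <- stats::hclust(stats::dist(X), method = "single")
      stats::cutree(hc, h = cluster_radius)
    }
    for (cid in unique(member)) {
      rows <- sel[member == cid]
      clusters[[length(clusters) + 1L]] <- list(
        kind = kind,
        support = length(unique(vapply(pts[rows], `[[`, 1L, "ligand"))),
        center = colMeans(do.call(rbind, lapply(pts[rows], `[[`, "xyz"))),
        points = sort(vapply(pts[rows], `[[`, "", "point_id")))
    }
  }
  keep <- Filter(function(cl) cl$support >= min_support, clusters)
  if (!length(keep))
    stopf("build_consensus_model: no feature cluster reaches support %d",
          min_support)
  # merge clusters of different kinds built from the same source points
  prio <- stats::setNames(seq_along(FEATURE_KINDS), FEATURE_KINDS)
  keys <- vapply(keep, function(cl) paste(cl$points, collapse = "|"), "")
  merged <- lapply(unique(keys), function(k) {
    grp <- keep[keys == k]
    grp[[which.min(vapply(grp, function(cl) prio[[cl$kind]], 1))]]
  })
  ord <- order(-vapply(merged, `[[`, 1L, "support"),
               vapply(merged, `[[`, "", "kind"))
  merged <- merged[ord]
  feats <- data.frame(
    label = paste0("F", seq_along(merged)),
    kind = vapply(merged, `[[`, "", "kind"),
    x = vapply(merged, function(cl) cl$center[1], 1),
    y = vapply(merged, function(cl) cl$center[2], 1),
    z = vapply(merged, function(cl) cl$center[3], 1),
    radius = initial_radius,
    stringsAsFactors = FALSE)
  model <- pharmacophore_model(feats, name = name,
                               provenance = sprintf(
                                 "consensus of %d overlaid ligands",
                                 length(ligands)))
  attr(model, "support") <- vapply(merged, `[[`, 1L, "support")
  model
}

# GH of a model on a labelled test set. Degenerate cases only arise inside
# refinement sweeps: Ht = 0 scores 0; with no decoys (D = A) the
# false-positive factor is taken as 1 (no false positive is possible).
model_gh <- function(model, actives, decoys) {
  ha <- sum(vapply(actives, function(m) match_pharmacophore(model, m)$matched,
                   TRUE))
  hi <- sum(vapply(decoys, function(m) match_pharmacophore(model, m)$matched,
                   TRUE))
  counts <- confusion_counts(D = length(actives) + length(decoys),
                             A = length(actives), Ht = ha + hi, Ha = ha)
  if (counts$Ht == 0L) return(list(gh = 0, counts = counts))
  gh <- if (counts$D == counts$A) {
    (counts$Ha / counts$A) * ((3 * counts$A + counts$Ht) / (4 * counts$Ht))
  } else gh_score(counts)
  list(gh = gh, counts = counts)
}

#' Refine a pharmacophore model's radii against a labelled test set
#'
#' One sweep of coordinate descent over the features in order: for each
#' feature, the candidate radius (the grid plus the incumbent value)
#' maximising the Goodness-of-Hit score on the test set is kept; exact ties
#' go to the smaller (stricter) radius. Because the incumbent is always a
#' candidate, the refined model's GH is never below the input model's.
#'
#' @param model a \code{pf_model}.
#' @param test_actives,test_decoys lists of labelled \code{pf_mol}.
#' @param radius_grid candidate radii in Angstrom
#'   (default 0.5, 0.7, 1.0, 1.2).
#' @return List with \code{model} (refined) and \code{trace} (data.frame of
#'   the per-feature decisions with the GH after each step).
#' @export
refine_model <- function(model, test_actives, test_decoys,
                         radius_grid = c(0.5, 0.7, 1.0, 1.2)) {
  if (!length(test_actives))
    stopf("refine_model: degenerate test set (no actives)")
  current <- model
  gh_now <- model_gh(current, test_actives, test_decoys)$gh
  trace <- data.frame(feature = character(0), radius = numeric(0),
                      gh = numeric(0))
  for (f in seq_len(nrow(current$features))) {
    cand_r <- sort(unique(c(radius_grid, current$features$radius[f])))
    best_r <- current$features$radius[f]; best_gh <- -Inf
    for (r in cand_r) {
      trial <- current
      trial$features$radius[f] <- r
      gh <- model_gh(trial, test_actives, test_decoys)$gh
      if (gh > best_gh + 1e-12 ||
          (abs(gh - best_gh) <= 1e-12 && r < best_r)) {
        best_gh <- gh; best_r <- r
      }
    }
    current$features$radius[f] <- best_r
    gh_now <- best_gh
    trace <- rbind(trace, data.frame(feature = current$features$label[f],
                                     radius = best_r, gh = gh_now))
  }
  list(model = current, trace = trace)
}
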