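# Independent oracles.
#
# The brute-force matcher enumerates ALL injective kind-compatible
# assignments (no correspondence-graph pruning) and verifies each with a
# superposition computed by Horn's quaternion method -- a different optimal-
# rotation algorithm from the SVD-based Kabsch fit inside the package. The
# feasibility search (tolerance-weighted refit when the unweighted optimum
# leaves a point outside its sphere) follows the same schedule, since it is
# part of the match definition.

horn_superpose <- function(P, Q, w = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  w <- if (is.null(w)) rep(1, nrow(P)) else w
  w <- w / sum(w)
  cp <- colSums(P * w); cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  S <- t(Pc * w) %*% Qc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  R <- rbind(
    c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
    c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
    c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2))
  fitted <- sweep(Pc %*% t(R), 2, cq, "+")
  list(fitted = fitted, rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

oracle_verify <- function(P, centers, radii, max_iter = 60L) {
  fit <- horn_superpose(P, centers)
  res <- sqrt(rowSums((fit$fitted - centers)^2))
  if (all(res <= radii + 1e-9)) return(list(ok = TRUE, rmsd = fit$rmsd))
  w <- rep(1, nrow(P))
  for (it in seq_len(max_iter)) {
    w <- w * pmax(res / radii, 0.2)^2
    w <- w / sum(w)
    wfit <- horn_superpose(P, centers, w)
    res <- sqrt(rowSums((wfit$fitted - centers)^2))
    if (all(res <= radii + 1e-9)) return(list(ok = TRUE, rmsd = wfit$rmsd))
  }
  list(ok = FALSE, rmsd = NA_real_)
}

oracle_compatible <- function(kind, point_kinds, point_n_atoms) {
  kind %in% point_kinds || (kind == "LINKER" && point_n_atoms == 1L)
}

# exhaustive injective assignment search; returns list(matched, fit_rmsd)
brute_force_match <- function(model, points) {
  K <- nrow(model$features)
  centers <- as.matrix(model$features[, c("x", "y", "z")])
  radii <- model$features$radius
  P <- as.matrix(points[, c("x", "y", "z")])
  best <- Inf; matched <- FALSE
  assign_next <- function(f, used, chosen) {
    if (f > K) {
      v <- oracle_verify(P[chosen, , drop = FALSE], centers, radii)
      if (v$ok) {
        matched <<- TRUE
        if (v$rmsd < best) best <<- v$rmsd
      }
      return(invisible(NULL))
    }
    for (p in seq_len(nrow(points))) {
      if (used[p]) next
      if (!oracle_compatible(model$features$kind[f], points$kinds[[p]],
                             points$n_atoms[p])) next
      used[p] <- TRUE
      assign_next(f + 1L, used, c(chosen, p))
      used[p] <- FALSE
    }
    invisible(NULL)
  }
  assign_next(1L, rep(FALSE, nrow(points)), integer(0))
  list(matched = matched, fit_rmsd = if (matched) best else NA_real_)
}

# random matcher test instance: a small model plus a point set that is a
# jittered+transformed copy (likely feasible), a scattered set (infeasible),
# or a fully random set, optionally with distractor points
random_match_instance <- function() {
  K <- sample(3:5, 1)
  repeat {
    centers <- matrix(runif(3 * K, -4, 4), K, 3)
    if (K < 2 || min(dist(centers)) > 2.5) break
  }
  kinds <- sample(c("AROMATIC_RING", "HBA", "HBD", "HYDROPHOBIC"), K,
                  replace = TRUE)
  radii <- sample(c(0.5, 0.7, 1.0, 1.2), K, replace = TRUE)
  model <- make_model(centers, kinds, radii)
  kind_pool <- c("AROMATIC_RING", "HBA", "HBD", "HYDROPHOBIC")
  type <- sample(c("planted", "scattered", "random"), 1,
                 prob = c(0.45, 0.3, 0.25))
  if (type == "planted") {
    jit <- runif(1, 0, 0.8)
    pts <- centers + t(sapply(radii, function(r) {
      repeat { v <- runif(3, -1, 1); if (sum(v^2) <= 1) break }
      jit * r * v
    }))
    pkinds <- as.list(kinds)
    n_extra <- sample(0:(8 - K), 1)
    if (n_extra > 0) {
      pts <- rbind(pts, matrix(runif(3 * n_extra, -12, 12), n_extra, 3))
      pkinds <- c(pkinds, as.list(sample(kind_pool, n_extra, replace = TRUE)))
    }
    pts <- random_rigid(pts)
  } else if (type == "scattered") {
    n <- sample(K:8, 1)
    spread <- max(dist(centers)) + 2 * max(radii) + 5
    pts <- t(sapply(seq_len(n), function(k)
      c(k * spread, 0, 0) + rnorm(3, 0, 0.5)))
    pkinds <- as.list(sample(kinds, n, replace = TRUE))
  } else {
    n <- sample(K:8, 1)
    pts <- matrix(runif(3 * n, -6, 6), n, 3)
    pkinds <- as.list(sample(kind_pool, n, replace = TRUE))
  }
  list(model = model, points = make_points(pts, pkinds))
}
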