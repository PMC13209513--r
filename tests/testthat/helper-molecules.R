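# small molecule builders used across tests

hexagon_xyz <- function(ctr = c(0, 0, 0), radius = 1.39, normal = c(0, 0, 1)) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- ref - sum(ref * n) * n; p1 <- p1 / sqrt(sum(p1^2))
  p2 <- c(n[2] * p1[3] - n[3] * p1[2], n[3] * p1[1] - n[1] * p1[3],
          n[1] * p1[2] - n[2] * p1[1])
  t(sapply(seq(0, 300, 60) * pi / 180, function(a)
    ctr + radius * (cos(a) * p1 + sin(a) * p2)))
}

make_benzene <- function(id = "benzene", ctr = c(0, 0, 0),
                         normal = c(0, 0, 1)) {
  molecule(id, rep("C", 6), data.frame(i = 1:6, j = c(2:6, 1), order = 4L),
           list(hexagon_xyz(ctr, normal = normal)))
}

make_acetone <- function() {
  molecule("acetone", c("C", "C", "O", "C"),
           data.frame(i = c(1, 2, 2), j = c(2, 3, 4), order = c(1L, 2L, 1L)),
           list(rbind(c(-1.5, 0, 0), c(0, 0, 0), c(0, 1.22, 0),
                      c(1.5, 0, 0))))
}

make_biphenyl <- function() {
  molecule("biphenyl", rep("C", 12),
           rbind(data.frame(i = 1:6, j = c(2:6, 1), order = 4L),
                 data.frame(i = 7:12, j = c(8:12, 7), order = 4L),
                 data.frame(i = 1L, j = 7L, order = 1L)),
           list(rbind(hexagon_xyz(c(0, 0, 0)), hexagon_xyz(c(4.2, 0, 0)))))
}

make_diphenylmethane <- function() {
  molecule("diphenylmethane", c(rep("C", 12), "C"),
           rbind(data.frame(i = 1:6, j = c(2:6, 1), order = 4L),
                 data.frame(i = 7:12, j = c(8:12, 7), order = 4L),
                 data.frame(i = c(13L, 13L), j = c(1L, 7L), order = 1L)),
           list(rbind(hexagon_xyz(c(0, 0, 0)), hexagon_xyz(c(5.2, 0, 0)),
                      matrix(c(2.6, 1.4, 0), 1))))
}

# a bare pf_features point set for low-level matcher tests
make_points <- function(coords, kinds, n_atoms = NULL) {
  coords <- as.matrix(coords)
  df <- data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   n_atoms = n_atoms %||% rep(1L, nrow(coords)))
  df$kinds <- if (is.list(kinds)) kinds else as.list(kinds)
  df$atoms <- lapply(seq_len(nrow(coords)), function(i) i)
  class(df) <- c("pf_features", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_model <- function(coords, kinds, radii, name = "test-model") {
  coords <- as.matrix(coords)
  pharmacophore_model(data.frame(
    label = paste0("F", seq_len(nrow(coords))), kind = kinds,
    x = coords[, 1], y = coords[, 2], z = coords[, 3], radius = radii),
    name = name)
}

# minimal one-residue protein: a GLN with its acceptor OE1 at `acc`
gln_protein <- function(acc = c(0, 0, 0)) {
  base <- rbind(N = c(-6, 0, 0), CA = c(-4.9, 0.9, 0), C = c(-4.2, 2.1, 0),
                O = c(-4.8, 3.2, 0), CB = c(-3.6, 0, 0.8),
                CG = c(-2.4, 0, 0.4), CD = c(-1.2, 0, 0.2),
                NE2 = c(-0.9, 1.2, 0.2))
  xyz <- rbind(base, OE1 = acc)
  protein_structure("gln", data.frame(
    eleno = seq_len(nrow(xyz)), name = rownames(xyz),
    element = substr(rownames(xyz), 1, 1), resname = "GLN", chain = "A",
    resno = 421L, het = FALSE, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

# ligand amine donor: N at `npos`, H placed to realise the D-H...A angle
donor_ligand <- function(npos, acc, angle) {
  u <- (acc - npos) / sqrt(sum((acc - npos)^2))
  perp <- c(-u[2], u[1], 0); perp <- perp / sqrt(sum(perp^2))
  f <- function(alpha) {
    h <- npos + 1.0 * (cos(alpha) * u + sin(alpha) * perp)
    v1 <- npos - h; v2 <- acc - h
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi - angle
  }
  alpha <- if (abs(f(0)) < 1e-9) 0 else
    uniroot(f, c(1e-6, 3), tol = 1e-12)$root
  h <- npos + 1.0 * (cos(alpha) * u + sin(alpha) * perp)
  molecule("don", c("N", "H", "C"),
           data.frame(i = c(1, 1), j = c(2, 3), order = 1L),
           list(rbind(npos, h, npos + c(0, 0, 1.5))))
}

random_rigid <- function(xyz) {
  M <- matrix(rnorm(9), 3, 3)
  R <- qr.Q(qr(M))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(xyz %*% t(R), 2, runif(3, -10, 10), "+")
}
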