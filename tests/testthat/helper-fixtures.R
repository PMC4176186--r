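# Shared fixture builders for the test suite. Everything is generated in
# code; no files are shipped.

# quick ladder structure
ladder <- function(seq = "GACU", ...) make_fixture(fixture_spec(seq, ...))

# a minimal synthetic chemical-group row for direct score arithmetic
make_group <- function(role, pos, dirs) {
  g <- data.frame(chain = "A", resno = 1, base = "G", atom = "O6",
                  role = role, x = pos[1], y = pos[2], z = pos[3],
                  area = 1, stringsAsFactors = FALSE)
  g$dirs <- list(matrix(dirs, ncol = 3, byrow = TRUE))
  class(g) <- c("chem_groups", "data.frame")
  g
}

# Two pyrimidines facing each other across their Watson-Crick edges, the gap
# sized for a pyrimidine:pyrimidine pair: residue 2 is residue 1 rotated 180
# degrees about the ring normal through a point 1.4 A beyond N3. Substituting
# either side to a purine overfills the gap (the junction scenario).
wc_facing_pair <- function() {
  s <- make_fixture(fixture_spec("CC"))
  a <- s$atoms
  ring <- c("N1", "C2", "N3", "C4", "C5", "C6")
  rc <- as.matrix(a[a$resno == 1 & a$atom %in% ring, c("x", "y", "z")])
  ctr <- colMeans(rc)
  n <- svd(sweep(rc, 2, ctr))$v[, 3]
  n3 <- unlist(a[a$resno == 1 & a$atom == "N3", c("x", "y", "z")])
  w <- n3 - ctr; w <- w - n * sum(w * n); w <- w / sqrt(sum(w^2))
  p <- n3 + 1.4 * w
  r1 <- which(a$resno == 1); r2 <- which(a$resno == 2)
  X <- sweep(as.matrix(a[r1, c("x", "y", "z")]), 2, p)
  Xr <- -X + 2 * outer(as.numeric(X %*% n), n)     # pi rotation about n
  a[r2, c("x", "y", "z")] <- sweep(Xr, 2, p, "+")[match(a$atom[r2], a$atom[r1]), ]
  rna_structure("wc-facing-pair", a)
}

# rigid-body transform of a whole structure (rotation about z + translation)
rigid_move <- function(s, deg = 35, shift = c(3, -2, 1)) {
  t <- deg * pi / 180
  R <- matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}

# one residue's atom table with rownames normalized, for exact comparison
res_df <- function(s, rn, cols = c("atom", "x", "y", "z")) {
  d <- s$atoms[s$atoms$resno == rn & !s$atoms$occluder, cols]
  rownames(d) <- NULL
  d
}

# per-atom coordinate comparison keyed by (chain, resno, atom), robust to
# atom-order changes
max_atom_shift <- function(s1, s2) {
  k1 <- paste(s1$atoms$chain, s1$atoms$resno, s1$atoms$atom)
  k2 <- paste(s2$atoms$chain, s2$atoms$resno, s2$atoms$atom)
  stopifnot(setequal(k1, k2))
  m <- match(k1, k2)
  max(sqrt(rowSums((as.matrix(s1$atoms[, c("x", "y", "z")]) -
                      as.matrix(s2$atoms[m, c("x", "y", "z")]))^2)))
}
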