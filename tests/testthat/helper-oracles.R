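# Independent oracles used to check the package's algorithms. Each one is a
# from-scratch implementation (different algorithm or closed form) and must
# never call the code path it validates.

# Horn's closed-form quaternion absolute-orientation solution: the largest
# eigenvalue of the 4x4 matrix built from the covariance of the centered
# point sets gives the optimal rotation as a unit quaternion.
horn_fit <- function(mobile, reference) {
  mc <- colMeans(mobile); rc <- colMeans(reference)
  x <- sweep(mobile, 2, mc); y <- sweep(reference, 2, rc)
  S <- t(x) %*% y
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1L]
  w <- q[1]; xq <- q[2]; yq <- q[3]; zq <- q[4]
  R <- matrix(c(
    1 - 2 * (yq^2 + zq^2), 2 * (xq * yq - w * zq), 2 * (xq * zq + w * yq),
    2 * (xq * yq + w * zq), 1 - 2 * (xq^2 + zq^2), 2 * (yq * zq - w * xq),
    2 * (xq * zq - w * yq), 2 * (yq * zq + w * xq), 1 - 2 * (xq^2 + yq^2)),
    3, 3, byrow = TRUE)
  list(rotation = R, translation = rc - as.numeric(R %*% mc))
}

# Closed-form accessible area of two intersecting spheres of radii R1, R2
# (probe-expanded) at center distance d: each sphere loses the spherical
# cap cut off by the radical plane.
two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  a1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  a2 <- (d^2 + R2^2 - R1^2) / (2 * d)
  2 * pi * R1 * (R1 + a1) + 2 * pi * R2 * (R2 + a2)
}

# Plain-loop neighbor-counting clustering, written independently from the
# package implementation (no vectorized shortcuts, no relabeling logic):
# returns the membership list in formation order.
gromos_oracle <- function(m, cutoff) {
  n <- nrow(m)
  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining) > 0L) {
    best <- -1L; seed <- remaining[1L]
    for (i in remaining) {
      cnt <- 0L
      for (j in remaining) if (i != j && m[i, j] <= cutoff) cnt <- cnt + 1L
      if (cnt > best) { best <- cnt; seed <- i }
    }
    members <- integer(0)
    for (j in remaining) if (m[seed, j] <= cutoff) members <- c(members, j)
    clusters[[length(clusters) + 1L]] <- list(seed = seed, members = members)
    remaining <- setdiff(remaining, members)
  }
  clusters
}

# direct coordinate arithmetic for the triangle statistic
triangle_oracle <- function(model, chain, ser, his, donor_res, donor_atom) {
  g <- function(res, at) {
    a <- model$atoms
    i <- which(a$chain == chain & a$resseq == res & a$atom == at)
    c(a$x[i], a$y[i], a$z[i])
  }
  d <- function(p, q) sqrt(sum((p - q)^2))
  c(d1 = d(g(ser, "CA"), g(his, "CA")),
    d2 = d(g(ser, "CA"), g(donor_res, donor_atom)),
    d3 = d(g(donor_res, donor_atom), g(his, "CA")))
}

# tiny model builder for hand-planted coordinate tests
tiny_model <- function(coords, atoms = NULL, resseq = NULL, chain = "A",
                       resname = "GLY", element = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(atoms)) atoms <- sprintf("X%d", seq_len(n))
  if (is.null(resseq)) resseq <- seq_len(n)
  if (is.null(element)) element <- rep("C", n)
  structure_model(data.frame(
    chain = chain, resseq = resseq, icode = "", resname = resname,
    atom = atoms, altloc = "", x = coords[, 1], y = coords[, 2],
    z = coords[, 3], occ = 1, b = 0, element = element, het = FALSE,
    hydrogen = FALSE, water = FALSE, stringsAsFactors = FALSE),
    id = "tiny")
}
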