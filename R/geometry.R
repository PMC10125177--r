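# Small 3D geometry kernel: rotations, internal-coordinate placement,
# dihedral measurement/setting, and pairwise minimum distances.

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of `angle` degrees
#' about the direction `axis`.
#'
#' @param axis numeric length-3 direction (need not be unit length).
#' @param angle rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- unit(axis)
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy,
                uz, 0, -ux,
                -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# rotate rows of an n x 3 matrix about a line (point `origin`, direction
# `axis`) by `angle` degrees
rotate_about <- function(xyz, origin, axis, angle) {
  R <- rotation_matrix(axis, angle)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, "+")
}

# align rotation: minimal rotation taking unit vector `from` onto `to`
align_rotation <- function(from, to) {
  f <- unit(from); t_ <- unit(to)
  d <- sum(f * t_)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    # pick any perpendicular axis for a 180 degree flip
    perp <- if (abs(f[1]) < 0.9) cross3(f, c(1, 0, 0)) else cross3(f, c(0, 1, 0))
    return(rotation_matrix(perp, 180))
  }
  axis <- cross3(f, t_)
  rotation_matrix(axis, acos(d) * 180 / pi)
}

# random (Haar-uniform) rotation matrix, for invariance tests
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vec_norm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF) placement: returns the position of an atom at
#' distance `bond` from `a`, forming angle `angle` (degrees) with `b`-`a`,
#' and dihedral `dihedral` (degrees) about the `b`-`a` axis relative to `c`.
#'
#' @param a,b,c positions of the three reference atoms (`a` bonded to the new
#'   atom, `b` bonded to `a`, `c` bonded to `b`).
#' @param bond bond length in Angstrom.
#' @param angle bond angle `new`-`a`-`b` in degrees.
#' @param dihedral torsion `new`-`a`-`b`-`c` in degrees.
#' @return numeric length-3 position.
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  d2 <- c(bond * cos(pi - th),
          bond * sin(pi - th) * cos(ph),
          bond * sin(pi - th) * sin(ph))
  bc <- unit(a - b)
  n <- unit(cross3(b - c, bc))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(a + m %*% d2)
}

#' Measure a torsion angle
#'
#' @param p1,p2,p3,p4 atom positions; the torsion is about the `p2`-`p3` bond.
#' @return dihedral angle in degrees in (-180, 180].
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# minimum distance between two point sets (n x 3, m x 3), brute force but
# vectorized; optionally early-exits once a pair below `below` is found
min_cross_distance <- function(xyz_a, xyz_b, below = NULL) {
  if (nrow(xyz_a) == 0 || nrow(xyz_b) == 0) return(Inf)
  # process in row blocks to bound memory on large sets
  best <- Inf
  block <- max(1L, floor(4e6 / nrow(xyz_b)))
  i <- 1L
  n <- nrow(xyz_a)
  bb <- rowSums(xyz_b^2)
  while (i <= n) {
    j <- min(n, i + block - 1L)
    a <- xyz_a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(a^2), bb, "+") - 2 * a %*% t(xyz_b)
    m <- min(d2)
    if (m < best^2) best <- sqrt(max(m, 0))
    if (!is.null(below) && best < below) return(best)
    i <- j + 1L
  }
  best
}

# all pairwise distances below cutoff between rows of xyz; returns a 2-col
# index matrix (i < j). Simple cell-list implementation.
pairs_within <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), 0, 2))
  cell <- pmax(cutoff, 1e-6)
  key <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  id <- key[, 1] * 73856093 + key[, 2] * 19349663 + key[, 3] * 83492791
  out_i <- integer(0); out_j <- integer(0)
  split_idx <- split(seq_len(n), id)
  # neighbor cell offsets
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  keymap <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(split_idx)) assign(k, split_idx[[k]], envir = keymap)
  hash_of <- function(kx, ky, kz) kx * 73856093 + ky * 19349663 + kz * 83492791
  for (k in seq_along(split_idx)) {
    ii <- split_idx[[k]]
    k0 <- key[ii[1], ]
    cand <- integer(0)
    for (o in seq_len(nrow(offs))) {
      h <- as.character(hash_of(k0[1] + offs[o, 1], k0[2] + offs[o, 2],
                                k0[3] + offs[o, 3]))
      if (!is.null(keymap[[h]])) cand <- c(cand, keymap[[h]])
    }
    for (a in ii) {
      cb <- cand[cand > a]
      if (length(cb) == 0) next
      d2 <- (xyz[cb, 1] - xyz[a, 1])^2 + (xyz[cb, 2] - xyz[a, 2])^2 +
        (xyz[cb, 3] - xyz[a, 3])^2
      hit <- cb[d2 <= cutoff^2]
      if (length(hit) > 0) {
        out_i <- c(out_i, rep.int(a, length(hit)))
        out_j <- c(out_j, hit)
      }
    }
  }
  cbind(i = out_i, j = out_j)
}

# run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# quasi-uniform points on the unit sphere (golden-spiral / Fibonacci set)
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}
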