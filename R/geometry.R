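# ---------------------------------------------------------------------------
# Cartesian geometry: dihedral measurement, internal-coordinate atom
# placement (NeRF), torsion driving, and Kabsch superposition.
# ---------------------------------------------------------------------------

#' Measure a dihedral angle
#'
#' Standard signed dihedral about the j--k axis, mapped from the signed
#' (-180, 180] convention into [0, 360) by adding 360 to negatives.  All
#' bin arithmetic in the package uses the [0, 360) convention.
#'
#' @param conf n x 3 coordinate matrix.
#' @param quad integer vector (i, j, k, l) of 1-based atom indices.
#' @return angle in degrees in [0, 360).
#' @export
measure_dihedral <- function(conf, quad) {
  p <- conf[quad, , drop = FALSE]
  if (any(!is.finite(p))) stop("non-finite coordinates in dihedral quadruple")
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stop("undefined dihedral: three consecutive atoms are collinear")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  ang <- -ang                      # IUPAC sign convention (i->l clockwise positive)
  if (ang < 0) ang <- ang + 360
  if (ang >= 360) ang <- ang - 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural extension reference frame: place D given A, B, C and internal
# coordinates (bond CD, angle BCD in degrees, dihedral ABCD in degrees).
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  d2 <- c(bond * cos(pi - th),
          bond * sin(pi - th) * cos(ph),
          bond * sin(pi - th) * sin(ph))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cbind(bc, cross3(n, bc), n)
  as.vector(m %*% d2) + c
}

# Rotate the l-side fragment about the j-k axis so that dihedral(i,j,k,l)
# becomes `target` degrees.  Acyclic bonds only: the fragment is the
# connected component containing k after deleting bond (j,k).
set_torsion <- function(mol, conf, quad, target) {
  j <- quad[2]; k <- quad[3]
  cur <- measure_dihedral(conf, quad)
  delta <- (target - cur) * pi / 180
  if (abs(delta) < 1e-12) return(conf)
  side <- component_after_cut(mol, j, k)
  axis <- conf[k, ] - conf[j, ]
  axis <- axis / sqrt(sum(axis^2))
  rot <- rotation_matrix(axis, delta)
  moved <- conf
  idx <- setdiff(side, k)
  shifted <- sweep(conf[side, , drop = FALSE], 2, conf[k, ])
  moved[side, ] <- sweep(shifted %*% t(rot), 2, conf[k, ], "+")
  moved
}

component_after_cut <- function(mol, j, k) {
  adj <- adjacency(mol)
  seen <- logical(n_atoms(mol))
  seen[j] <- TRUE
  stack <- k
  comp <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    comp <- c(comp, v)
    stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
  }
  if (j %in% comp) stop("bond (", j, ",", k, ") is in a ring; cannot drive torsion")
  comp
}

rotation_matrix <- function(axis, theta) {
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  c0 <- cos(theta); s0 <- sin(theta); C <- 1 - c0
  matrix(c(c0 + x * x * C,     x * y * C - z * s0, x * z * C + y * s0,
           y * x * C + z * s0, c0 + y * y * C,     y * z * C - x * s0,
           z * x * C - y * s0, z * y * C + x * s0, c0 + z * z * C),
         3, 3, byrow = TRUE)
}

# Kabsch RMSD between two coordinate sets under a fixed correspondence.
kabsch_rmsd <- function(x, y) {
  stopifnot(nrow(x) == nrow(y))
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(t(yc) %*% xc)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  diff <- xc - yc %*% rot
  sqrt(sum(diff^2) / nrow(x))
}

# Embed an acyclic molecule (tree graph) from idealized internal
# coordinates: bond lengths by element pair, bond angles 111 deg,
# dihedrals staggered (180, shifted by 120 deg per extra sibling).
# Torsions of interest are driven to exact values afterwards with
# set_torsion(), so only connectivity-consistent geometry matters here.
embed_tree <- function(mol, dihedral_default = 180) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  conf <- matrix(NA_real_, n, 3)
  parent <- integer(n)
  order <- integer(0)
  seen <- logical(n)
  stack <- 1L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    order <- c(order, v)
    kids <- sort(adj[[v]][!seen[adj[[v]]]])
    for (w in rev(kids)) { parent[w] <- v; stack <- c(stack, w) }
  }
  if (length(order) < n) stop("embed_tree: molecule is disconnected")
  placed <- logical(n)
  n_placed_kids <- integer(n)   # per parent: how many children already placed
  for (v in order) {
    p1 <- parent[v]
    if (p1 == 0L) { conf[v, ] <- c(0, 0, 0); placed[v] <- TRUE; next }
    blen <- bond_length_guess(mol$elements[v], mol$elements[p1])
    p2 <- parent[p1]
    if (p2 == 0L) {
      # child of the root: first goes on +x, later ones at 111 deg off
      k <- n_placed_kids[p1]
      if (k == 0L) {
        conf[v, ] <- conf[p1, ] + c(blen, 0, 0)
      } else {
        th <- (180 - 111) * pi / 180
        ph <- (k - 1L) * 2 * pi / 3
        conf[v, ] <- conf[p1, ] + blen * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
      }
    } else {
      p3 <- parent[p2]
      a_ref <- if (p3 != 0L) conf[p3, ] else conf[p2, ] + c(0, 1, 0)
      dih <- dihedral_default + 120 * n_placed_kids[p1]
      conf[v, ] <- nerf_place(a_ref, conf[p2, ], conf[p1, ], blen, 111, dih)
    }
    n_placed_kids[p1] <- n_placed_kids[p1] + 1L
    placed[v] <- TRUE
  }
  conf
}

bond_length_guess <- function(e1, e2) {
  r <- c(C = 0.77, N = 0.74, O = 0.74, S = 1.04, F = 0.72, Cl = 0.99,
         Br = 1.14, I = 1.33, P = 1.10, B = 0.82, Si = 1.11)
  r1 <- if (e1 %in% names(r)) r[[e1]] else 0.77
  r2 <- if (e2 %in% names(r)) r[[e2]] else 0.77
  r1 + r2
}
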