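# Pose degrees of freedom: rigid translation, orientation as a unit
# quaternion (renormalized after every update; gradients live in the 3-D
# tangent space, avoiding Euler-angle singularities), and one torsion angle
# per rotatable bond. Torsions are applied root-outward, then the whole
# ligand is rotated about its reference centroid and translated.

quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("zero quaternion", call. = FALSE)
  q / n
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# rotation vector (axis * angle) -> unit quaternion
quat_from_rotvec <- function(v) {
  angle <- sqrt(sum(v^2))
  if (angle < 1e-12) return(c(1, v / 2))
  c(cos(angle / 2), sin(angle / 2) * v / angle)
}

random_unit_quaternion <- function() {
  quat_normalize(stats::rnorm(4))
}

# Rodrigues rotation of points (rows of x) about the axis through `point`
# with unit direction `u`, right-handed by angle theta
rotate_about_axis <- function(x, point, u, theta) {
  p <- sweep(x, 2, point)
  ct <- cos(theta); st <- sin(theta)
  cross <- cbind(u[2] * p[, 3] - u[3] * p[, 2],
                 u[3] * p[, 1] - u[1] * p[, 3],
                 u[1] * p[, 2] - u[2] * p[, 1])
  dotu <- p %*% u
  rot <- ct * p + st * cross + (1 - ct) * (dotu %*% t(u))
  sweep(rot, 2, point, `+`)
}

#' Pose degrees of freedom
#'
#' Bundles the minimization variables of a ligand pose: a rigid translation
#' (Angstrom), an orientation as a unit quaternion `(w, x, y, z)`, and one
#' torsion angle (radians) per rotatable bond. The zero DOF (zero
#' translation, identity quaternion, zero torsions) reproduces the input
#' conformation exactly.
#'
#' @param translation length-3 numeric.
#' @param orientation length-4 quaternion; normalized on construction.
#' @param torsions numeric vector, one angle per rotatable bond.
#' @return an object of class `pose_dof`.
#' @export
pose_dof <- function(translation = c(0, 0, 0),
                     orientation = c(1, 0, 0, 0),
                     torsions = numeric(0)) {
  stopifnot(length(translation) == 3, length(orientation) == 4)
  structure(list(translation = as.numeric(translation),
                 orientation = quat_normalize(as.numeric(orientation)),
                 torsions = as.numeric(torsions)),
            class = "pose_dof")
}

#' @export
print.pose_dof <- function(x, ...) {
  cat("<pose_dof> t = (", paste(sprintf("%.3f", x$translation),
                                collapse = ", "),
      "), |q| = 1, ", length(x$torsions), " torsion(s)\n", sep = "")
  invisible(x)
}

n_dof <- function(dof) 6L + length(dof$torsions)

# compose a tangent-space step (dt[1:3] translation, dt[4:6] rotation
# vector applied on the left, dt[7:] torsion increments) onto a pose
compose_dof_step <- function(dof, step) {
  dof$translation <- dof$translation + step[1:3]
  dof$orientation <- quat_normalize(
    quat_multiply(quat_from_rotvec(step[4:6]), dof$orientation))
  if (length(dof$torsions)) {
    th <- dof$torsions + step[-(1:6)]
    dof$torsions <- ((th + pi) %% (2 * pi)) - pi
  }
  dof
}

ligand_centroid <- function(model) colMeans(model$xyz)

#' Apply pose degrees of freedom to a ligand
#'
#' Rebuilds ligand coordinates from the stored reference conformation:
#' torsion rotations are applied root-outward about each rotatable bond
#' (each affecting exactly its moved-atom subtree), then the whole molecule
#' is rotated about the reference centroid by the orientation quaternion and
#' translated. Rigid fragments move rigidly; internal bond lengths and
#' angles are preserved.
#'
#' @param model a `ligand_model`.
#' @param dof a `pose_dof` whose torsion count matches the model.
#' @return n_atoms x 3 coordinate matrix.
#' @export
apply_dof <- function(model, dof) {
  stopifnot(inherits(model, "ligand_model"), inherits(dof, "pose_dof"))
  if (length(dof$torsions) != model$n_rot) {
    stop("torsion count mismatch: model has ", model$n_rot,
         " rotatable bond(s), dof has ", length(dof$torsions), call. = FALSE)
  }
  x <- model$xyz
  for (k in seq_along(model$torsions)) {
    tr <- model$torsions[[k]]
    a <- x[tr$axis[1], ]
    b <- x[tr$axis[2], ]
    u <- b - a
    nu <- sqrt(sum(u^2))
    if (nu < 1e-12) stop("degenerate torsion axis", call. = FALSE)
    u <- u / nu
    x[tr$moved, ] <- rotate_about_axis(x[tr$moved, , drop = FALSE], a, u,
                                       dof$torsions[k])
  }
  c0 <- ligand_centroid(model)
  rot <- quat_to_matrix(dof$orientation)
  x <- sweep(x, 2, c0)
  x <- x %*% t(rot)
  sweep(x, 2, c0 + dof$translation, `+`)
}
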