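# Synthetic SMPL-compatible body model: a 24-joint kinematic tree with
# shape-conditioned rest offsets, linear blend skinning onto a scattered
# vertex cloud, and fixed linear regressors to the 24-joint and 14-joint
# evaluation sets.  The template mirrors the SMPL interface (beta in R^10,
# 24 joint rotations, vertices -> joints regression) without the licensed
# asset; pose-corrective blendshapes are intentionally absent.

# Parent of each joint, 1-indexed, root sentinel 0.  Children always have
# larger indices than their parents (required by the FK sweeps).
.SMPL_PARENTS <- c(0L, 1L, 1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L,
                   10L, 10L, 10L, 13L, 14L, 15L, 17L, 18L, 19L, 20L, 21L, 22L)

.JOINT_NAMES <- c("pelvis", "hip.L", "hip.R", "spine1", "knee.L", "knee.R",
                  "spine2", "ankle.L", "ankle.R", "spine3", "foot.L", "foot.R",
                  "neck", "collar.L", "collar.R", "head", "shoulder.L",
                  "shoulder.R", "elbow.L", "elbow.R", "wrist.L", "wrist.R",
                  "hand.L", "hand.R")

# Base parent-relative rest offsets in mm (y up); total stature ~1.7 m.
.BASE_OFFSETS <- matrix(c(
     0,    0,   0,
    90,  -60,   0,
   -90,  -60,   0,
     0,  100,   0,
     0, -400,   0,
     0, -400,   0,
     0,  120,   0,
     0, -420,   0,
     0, -420,   0,
     0,  120,   0,
     0,  -60, 130,
     0,  -60, 130,
     0,  150,   0,
    45,  110,   0,
   -45,  110,   0,
     0,  110,   0,
   115,   30,   0,
  -115,   30,   0,
   260,    0,   0,
  -260,    0,   0,
   250,    0,   0,
  -250,    0,   0,
    80,    0,   0,
   -80,    0,   0), ncol = 3L, byrow = TRUE)

# H3.6M-style 14-joint evaluation set, as indices into the 24 SMPL joints:
# R ankle, R knee, R hip, L hip, L knee, L ankle, R wrist, R elbow,
# R shoulder, L shoulder, L elbow, L wrist, neck, head.
.JOINTS14 <- c(9L, 6L, 3L, 2L, 5L, 8L, 22L, 20L, 18L, 17L, 19L, 21L, 13L, 16L)

# Run expr with a fixed seed, restoring the caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a synthetic SMPL-compatible body template
#'
#' Constructs a deterministic articulated body: the standard 24-joint SMPL
#' kinematic tree with humanoid-proportioned rest offsets (slightly perturbed
#' per seed), a random linear shape basis mapping a 10-vector identity
#' parameter to offset perturbations, `n_vertices` vertices scattered around
#' the bones with distance-decayed skinning weights (3 nearest joints, rows
#' summing to 1), a distance-weighted vertices-to-24-joints regressor, and a
#' fixed 24-to-14 joint selection matrix in the Human3.6M-style order
#' (R/L ankles, knees, hips, wrists, elbows, shoulders, neck, head).
#'
#' This is a synthetic stand-in exposing the SMPL module interface; it is not
#' the licensed SMPL asset and carries no pose-corrective blendshapes.
#'
#' @param seed Integer seed; the template is a pure function of it.
#' @param n_vertices Number of mesh vertices (default 500).
#' @return A `body_template` object (list) with fields `parent_index`,
#'   `rest_offsets` (24 x 3 mm), `shape_basis` (72 x 10), `vertex_template`
#'   (V x 3 mm), `skinning_weights` (V x 24), `joint_regressor_24` (24 x V),
#'   `joint_regressor_14` (14 x 24), `joint_names`, `n_vertices`, `seed`.
#' @export
build_synthetic_template <- function(seed = 1L, n_vertices = 500L) {
  stopifnot(n_vertices >= 24L)
  .with_seed(seed, {
    scale <- 1 + 0.03 * stats::runif(24L, -1, 1)
    offsets <- .BASE_OFFSETS * scale
    shape_basis <- matrix(stats::rnorm(72L * 10L, sd = 4), nrow = 72L)
    shape_basis[c(1L, 25L, 49L), ] <- 0  # root offset stays pinned
    jr <- .cumulative_offsets(offsets)
    bone <- sample.int(24L, n_vertices, replace = TRUE)
    s <- stats::runif(n_vertices)
    verts <- matrix(0, n_vertices, 3L)
    for (v in seq_len(n_vertices)) {
      j <- bone[v]
      base <- if (j == 1L) jr[1L, ] else jr[.SMPL_PARENTS[j], ] + s[v] * (jr[j, ] - jr[.SMPL_PARENTS[j], ])
      verts[v, ] <- base + stats::rnorm(3L, sd = 25)
    }
    d2 <- outer(rowSums(verts^2), rowSums(jr^2), "+") - 2 * verts %*% t(jr)
    d2[d2 < 0] <- 0
    W <- exp(-d2 / (2 * 80^2))
    for (v in seq_len(n_vertices)) {
      keep <- order(W[v, ], decreasing = TRUE)[1:3]
      w <- numeric(24L); w[keep] <- W[v, keep]
      W[v, ] <- w / sum(w)
    }
    A <- exp(-d2 / (2 * 60^2))
    reg24 <- sweep(t(A), 1L, colSums(A), "/")
    reg14 <- matrix(0, 14L, 24L)
    reg14[cbind(1:14, .JOINTS14)] <- 1
    structure(list(
      parent_index = .SMPL_PARENTS,
      rest_offsets = offsets,
      shape_basis = shape_basis,
      vertex_template = verts,
      skinning_weights = W,
      joint_regressor_24 = reg24,
      joint_regressor_14 = reg14,
      joint_names = .JOINT_NAMES,
      n_vertices = as.integer(n_vertices),
      seed = as.integer(seed)
    ), class = "body_template")
  })
}

#' Assemble a body template from raw arrays
#'
#' Builds a `body_template` from externally supplied arrays, e.g. a real SMPL
#' model exported from its native container to plain matrices (vertex
#' template, blend weights, joint regressor).  All invariants are validated:
#' tree shape, skinning rows summing to 1, regressor dimensions.  When a real
#' model is loaded this way `n_vertices` is typically 6890 and the native
#' vertices-to-joints regressor replaces the synthetic one.  No model file
#' ships with this package.
#'
#' @param parent_index 24 parents (1-indexed, root sentinel 0).
#' @param rest_offsets 24 x 3 parent-relative offsets (mm).
#' @param vertex_template V x 3 rest vertices (mm).
#' @param skinning_weights V x 24 nonnegative weights, rows summing to 1.
#' @param joint_regressor_24 24 x V linear map from vertices to joints.
#' @param shape_basis 72 x 10 linear shape basis (default zero: rigid shape).
#' @param joint_regressor_14 14 x 24 evaluation-joint map (default: the
#'   package's Human3.6M-style selection matrix).
#' @param joint_names Optional 24 joint names.
#' @return A validated `body_template`.
#' @export
body_template_from_arrays <- function(parent_index, rest_offsets,
                                      vertex_template, skinning_weights,
                                      joint_regressor_24,
                                      shape_basis = matrix(0, 72L, 10L),
                                      joint_regressor_14 = NULL,
                                      joint_names = .JOINT_NAMES) {
  if (is.null(joint_regressor_14)) {
    joint_regressor_14 <- matrix(0, 14L, 24L)
    joint_regressor_14[cbind(1:14, .JOINTS14)] <- 1
  }
  stopifnot(identical(dim(as.matrix(rest_offsets)), c(24L, 3L)),
            ncol(vertex_template) == 3L,
            identical(dim(skinning_weights),
                      c(nrow(vertex_template), 24L)),
            all(skinning_weights >= 0),
            identical(dim(joint_regressor_24),
                      c(24L, nrow(vertex_template))),
            identical(dim(as.matrix(shape_basis)), c(72L, 10L)),
            identical(dim(as.matrix(joint_regressor_14)), c(14L, 24L)))
  if (max(abs(rowSums(skinning_weights) - 1)) > 1e-6) {
    stop("skinning weight rows must sum to 1", call. = FALSE)
  }
  tpl <- structure(list(
    parent_index = as.integer(parent_index),
    rest_offsets = as.matrix(rest_offsets),
    shape_basis = as.matrix(shape_basis),
    vertex_template = as.matrix(vertex_template),
    skinning_weights = as.matrix(skinning_weights),
    joint_regressor_24 = as.matrix(joint_regressor_24),
    joint_regressor_14 = as.matrix(joint_regressor_14),
    joint_names = joint_names,
    n_vertices = nrow(vertex_template),
    seed = NA_integer_
  ), class = "body_template")
  .validate_template(tpl)
  tpl
}

.cumulative_offsets <- function(offsets) {
  jr <- matrix(0, 24L, 3L)
  jr[1L, ] <- offsets[1L, ]
  for (j in 2:24) jr[j, ] <- jr[.SMPL_PARENTS[j], ] + offsets[j, ]
  jr
}

.validate_template <- function(template) {
  if (!inherits(template, "body_template")) stop("not a body_template", call. = FALSE)
  p <- template$parent_index
  if (length(p) != 24L || p[1L] != 0L || any(p[-1L] >= seq(2L, 24L)) || any(p[-1L] < 1L)) {
    stop("parent_index does not define a valid single-rooted tree", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.body_template <- function(x, ...) {
  cat(sprintf("Synthetic body template: 24 joints, %d vertices (seed %d)\n",
              x$n_vertices, x$seed))
  jr <- .cumulative_offsets(x$rest_offsets)
  cat(sprintf("  rest stature: %.0f mm (y extent)\n", diff(range(jr[, 2]))))
  invisible(x)
}

#' Shape-conditioned rest offsets
#'
#' Applies the linear shape basis: `rest_offsets + shape_basis %*% beta`
#' (the 72-vector perturbation is the column-major layout of a 24 x 3 matrix).
#'
#' @param template A `body_template`.
#' @param beta Length-10 identity/shape vector.
#' @return 24 x 3 matrix of parent-relative rest offsets (mm).
#' @export
shape_skeleton <- function(template, beta = rep(0, 10)) {
  .validate_template(template)
  stopifnot(length(beta) == 10L, all(is.finite(beta)))
  template$rest_offsets + matrix(template$shape_basis %*% beta, 24L, 3L)
}

#' Rest joint positions for a given shape
#'
#' Joint positions of the identity pose (cumulative shaped offsets), root at
#' the origin.
#'
#' @inheritParams shape_skeleton
#' @return 24 x 3 matrix of joint positions (mm).
#' @export
rest_joints <- function(template, beta = rep(0, 10)) {
  .cumulative_offsets(shape_skeleton(template, beta))
}

#' Forward kinematics over the 24-joint tree
#'
#' Each joint's position is its parent's position plus the parent's global
#' rotation applied to the shaped rest offset; its global rotation is the
#' parent's global rotation composed with the joint-local rotation.  The root
#' sits at the origin.
#'
#' @param pose 24 x 4 matrix of joint-local unit quaternions (scalar-first).
#' @param template A `body_template`.
#' @param beta Length-10 shape vector.
#' @return List with `joints` (24 x 3 mm) and `rotations` (3 x 3 x 24 array of
#'   global rotation matrices).
#' @export
forward_kinematics <- function(pose, template, beta = rep(0, 10)) {
  .validate_template(template)
  pose <- .as_rows(pose, 4L, "pose")
  if (nrow(pose) != 24L) stop("pose must have 24 joint rotations", call. = FALSE)
  .check_unit_quat(pose)
  offs <- shape_skeleton(template, beta)
  fwd <- .fk_batch(array(t(pose), c(4L, 24L, 1L)),
                   array(t(offs), c(3L, 24L, 1L)),
                   template$parent_index)
  G <- array(0, c(3L, 3L, 24L))
  for (j in 1:24) G[, , j] <- fwd$G[[j]][, , 1L]
  list(joints = t(matrix(fwd$X, 3L, 24L)), rotations = G)
}

#' Linear blend skinning
#'
#' Deforms the vertex template by the skinning-weighted sum of per-joint rigid
#' transforms from the forward-kinematics output: vertex `v` maps to
#' `sum_j W[v, j] * (G_j (t_v - r_j) + x_j)` with `r_j` the shaped rest joint
#' positions.  With the identity pose the template is reproduced exactly
#' (shape affects the skeleton only).
#'
#' @param fk Output of [forward_kinematics()].
#' @param template A `body_template`.
#' @param beta Length-10 shape vector (must match the one used for `fk`).
#' @return V x 3 matrix of posed vertex positions (mm).
#' @export
skin_vertices <- function(fk, template, beta = rep(0, 10)) {
  .validate_template(template)
  jr <- rest_joints(template, beta)
  D <- t(template$vertex_template)           # 3 x V
  W <- template$skinning_weights             # V x 24
  V <- nrow(template$vertex_template)
  Gcat <- matrix(0, 3L, 72L)
  Dstack <- matrix(0, 72L, V)
  for (j in 1:24) {
    rows <- (3L * j - 2L):(3L * j)
    Gcat[, rows] <- fk$rotations[, , j]
    Dstack[rows, ] <- (D - jr[j, ]) * rep(W[, j], each = 3L)
  }
  t(Gcat %*% Dstack + t(fk$joints) %*% t(W))
}

#' Regress the 14-joint evaluation set
#'
#' Applies the template's fixed linear maps: a V x 3 vertex matrix is first
#' regressed to 24 joints, a 24 x 3 joint matrix is mapped directly to the
#' 14-joint Human3.6M-style set.
#'
#' @param x V x 3 posed vertices or 24 x 3 joint positions.
#' @param template A `body_template`.
#' @return 14 x 3 matrix of evaluation joints (mm).
#' @export
regress_joints <- function(x, template) {
  .validate_template(template)
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("expected a 3-column coordinate matrix", call. = FALSE)
  if (nrow(x) == 24L) {
    template$joint_regressor_14 %*% x
  } else if (nrow(x) == template$n_vertices) {
    template$joint_regressor_14 %*% (template$joint_regressor_24 %*% x)
  } else {
    stop("input must have 24 rows (joints) or n_vertices rows", call. = FALSE)
  }
}
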