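#' Synthetic specimen with known landmarks
#'
#' The synthetic test bed stands in for real skull samples: closed
#' "skull-like" meshes (a subdivided icosphere stretched to a 3:2:1.5
#' ellipsoid with an anterior bump for asymmetry, plus random surface
#' bumps), ground-truth landmarks tied to the generating process, and
#' optional group structure, smooth individual variation, and random pose
#' and scale. Everything is reproducible from a seed.
#'
#' @name synthetic_specimen
NULL

# icosahedron subdivided s times and projected to the unit sphere;
# 10 * 4^s + 2 vertices
icosphere <- function(subdivisions) {
  phi <- (1 + sqrt(5)) / 2
  v <- matrix(c(-1, phi, 0,  1, phi, 0,  -1, -phi, 0,  1, -phi, 0,
                0, -1, phi,  0, 1, phi,  0, -1, -phi,  0, 1, -phi,
                phi, 0, -1,  phi, 0, 1,  -phi, 0, -1,  -phi, 0, 1),
              ncol = 3, byrow = TRUE)
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(1, 12, 6,  1, 6, 2,  1, 2, 8,  1, 8, 11,  1, 11, 12,
                2, 6, 10,  6, 12, 5,  12, 11, 3,  11, 8, 7,  8, 2, 9,
                4, 10, 5,  4, 5, 3,  4, 3, 7,  4, 7, 9,  4, 9, 10,
                5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,  10, 9, 2),
              ncol = 3, byrow = TRUE)
  for (s in seq_len(subdivisions)) {
    cache <- new.env(parent = emptyenv())
    vlist <- v
    nf <- matrix(0L, 0, 3)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (vlist[i, ] + vlist[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      vlist <<- rbind(vlist, m)
      idx <- nrow(vlist)
      cache[[key]] <- idx
      idx
    }
    newf <- vector("list", nrow(f))
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[[t]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                         c(ab, bc, ca))
    }
    v <- vlist
    f <- do.call(rbind, newf)
  }
  list(vertices = v, faces = f)
}

#' Generate the base synthetic shape
#'
#' Subdivided icosphere stretched to a 3 x 2 x 1.5 ellipsoid (mm), with one
#' fixed anterior bump (making the shape asymmetric, as a skull is) and
#' `n_bumps` seeded random radial Gaussian bumps. Landmarks are the apex
#' vertex of each bump plus the six axis-extremal vertices, labeled
#' deterministically; they are exact mesh vertices, so they lie on the
#' surface by construction.
#'
#' @param subdivisions icosphere subdivision level (>= 2); level 3 gives 642
#'   vertices.
#' @param n_bumps number of random surface bumps (and bump landmarks).
#' @param seed RNG seed.
#' @return an object of class `synthetic_specimen` with fields `mesh`,
#'   `true_landmarks`, `group`, `generating_params`.
#' @export
make_base_shape <- function(subdivisions = 3, n_bumps = 10, seed = 1) {
  if (subdivisions < 2) stopf("subdivisions must be >= 2")
  ico <- icosphere(subdivisions)
  u <- ico$vertices                        # unit directions
  axes <- c(3, 2, 1.5)

  withr::with_seed(seed, {
    dirs <- matrix(stats::rnorm(3 * n_bumps), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    amps <- stats::runif(n_bumps, 0.12, 0.3)
  })
  bump_width <- 0.45
  # radial bump field on the unit sphere: an egg-like taper along +x
  # (anterior end fuller, as a braincase vs snout), a fixed anterior
  # "snout" bump and a dorsal "vault" bump, then seeded random bumps.
  # Together with the parabolic dorsal arch applied below these make the
  # shape strongly asymmetric, as a skull is, so that its pose is
  # geometrically unambiguous under the ellipsoid's near-symmetries.
  rfac <- 1 + 0.3 * u[, 1] +
    0.8 * exp(-rowSums(sweep(u, 2, c(1, 0, 0))^2) / (2 * 0.8^2)) +
    0.5 * exp(-rowSums(sweep(u, 2, c(0.287, 0, 0.958))^2) / (2 * 0.55^2))
  for (j in seq_len(n_bumps)) {
    rfac <- rfac + amps[j] * exp(-rowSums(sweep(u, 2, dirs[j, ])^2) /
                                   (2 * bump_width^2))
  }
  verts <- (u * rfac) %*% diag(axes)
  verts[, 3] <- verts[, 3] + 0.5 * (verts[, 1] / axes[1])^2  # dorsal arch
  mesh <- triangle_mesh(verts, ico$faces, name = "base")

  used <- integer(0)
  pick <- function(score) {
    ord <- order(score, decreasing = TRUE)
    i <- ord[which(!(ord %in% used))[1]]
    used <<- c(used, i)
    i
  }
  bump_idx <- vapply(seq_len(n_bumps), function(j)
    pick(u %*% dirs[j, ]), 1L)
  ext_idx <- c(pick(verts[, 1]), pick(-verts[, 1]),
               pick(verts[, 2]), pick(-verts[, 2]),
               pick(verts[, 3]), pick(-verts[, 3]))
  idx <- c(bump_idx, ext_idx)
  labels <- c(sprintf("bump%02d", seq_len(n_bumps)),
              "xmax", "xmin", "ymax", "ymin", "zmax", "zmin")
  lms <- landmark_set(verts[idx, , drop = FALSE], labels, specimen = "base")

  structure(list(mesh = mesh, true_landmarks = lms, group = NA_character_,
                 generating_params = list(subdivisions = subdivisions,
                                          n_bumps = n_bumps, seed = seed,
                                          bump_dirs = dirs, bump_amps = amps,
                                          landmark_vertex_idx = idx,
                                          warps = list(), pose = NULL)),
            class = "synthetic_specimen")
}

#' @export
print.synthetic_specimen <- function(x, ...) {
  cat(sprintf("<synthetic_specimen '%s'%s: %d vertices, %d landmarks>\n",
              x$mesh$name,
              if (is.na(x$group)) "" else sprintf(" (group %s)", x$group),
              nrow(x$mesh$vertices), nrow(x$true_landmarks$coords)))
  invisible(x)
}

#' Build a Gaussian radial-basis warp
#'
#' A smooth analytic displacement field
#' `d(x) = sum_j a_j exp(-||x - c_j||^2 / (2 w^2))` used to plant known
#' deformations: it is evaluated identically on vertices and landmarks, so
#' the warped landmarks are the exact ground truth for registration
#' recovery.
#'
#' @param centers k x 3 matrix of warp centers (mm).
#' @param amplitudes k x 3 matrix of displacement vectors a_j (mm).
#' @param width common Gaussian width w (mm).
#' @return a list of class `rbf_warp`.
#' @export
rbf_warp <- function(centers, amplitudes, width) {
  centers <- as.matrix(centers)
  amplitudes <- as.matrix(amplitudes)
  if (!all(dim(centers) == dim(amplitudes)) || ncol(centers) != 3)
    stopf("centers and amplitudes must be matching k x 3 matrices")
  if (width <= 0) stopf("width must be positive")
  structure(list(centers = centers, amplitudes = amplitudes, width = width),
            class = "rbf_warp")
}

#' Evaluate the displacement of an RBF warp at points
#' @param warp an [rbf_warp()].
#' @param pts P x 3 matrix.
#' @return P x 3 matrix of displacements (mm).
#' @export
warp_displacement <- function(warp, pts) {
  K <- exp(-pdist2(as_points(pts), warp$centers) / (2 * warp$width^2))
  K %*% warp$amplitudes
}

#' Draw a random RBF warp inside a shape's bounding box
#'
#' @param spec a `synthetic_specimen` giving the support region.
#' @param n_centers number of Gaussian centers.
#' @param amplitude scale of the displacement vectors (mm); each center's
#'   vector has norm between 0.5 and 1 times this.
#' @param width Gaussian width (mm).
#' @param seed RNG seed.
#' @return an [rbf_warp()].
#' @export
random_warp <- function(spec, n_centers = 4, amplitude = 0.15, width = 1.2,
                        seed = 1) {
  v <- spec$mesh$vertices
  lo <- apply(v, 2, min)
  hi <- apply(v, 2, max)
  withr::with_seed(seed, {
    ctrs <- sapply(1:3, function(d)
      stats::runif(n_centers, lo[d] + 0.1 * (hi[d] - lo[d]),
                   hi[d] - 0.1 * (hi[d] - lo[d])))
    dirs <- matrix(stats::rnorm(3 * n_centers), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    mags <- stats::runif(n_centers, 0.5, 1) * amplitude
  })
  rbf_warp(matrix(ctrs, ncol = 3), dirs * mags, width)
}

#' Apply a smooth warp to a synthetic specimen
#'
#' Displaces mesh vertices and true landmarks identically through the
#' analytic warp, keeping the landmark ground truth exact. Errors out if the
#' warp is aggressive enough to risk a fold/self-intersection (Lipschitz
#' bound of the displacement field >= 1) or if amplitudes exceed 15% of the
#' shape diameter.
#'
#' @param spec a `synthetic_specimen`.
#' @param warp an [rbf_warp()].
#' @return the warped `synthetic_specimen` (warp appended to its
#'   `generating_params$warps`).
#' @export
apply_smooth_warp <- function(spec, warp) {
  stopifnot(inherits(spec, "synthetic_specimen"), inherits(warp, "rbf_warp"))
  diam <- bbox_diagonal(spec$mesh$vertices)
  amp_norms <- row_norms(warp$amplitudes)
  if (max(amp_norms) > 0.15 * diam)
    stopf("warp amplitude %.3g mm exceeds 15%% of the shape diameter (%.3g mm)",
          max(amp_norms), diam)
  # sup |grad d| <= sum_j ||a_j|| * exp(-1/2) / width; < 1 keeps the map
  # invertible (no folding)
  lip <- sum(amp_norms) * exp(-0.5) / warp$width
  if (lip >= 1)
    stopf("warp too aggressive (Lipschitz bound %.2f >= 1): self-intersection risk",
          lip)
  mesh <- spec$mesh
  mesh$vertices <- mesh$vertices + warp_displacement(warp, mesh$vertices)
  lms <- spec$true_landmarks
  lms <- landmark_set(lms$coords + warp_displacement(warp, lms$coords),
                      lms$labels, specimen = lms$specimen)
  spec$mesh <- mesh
  spec$true_landmarks <- lms
  spec$generating_params$warps <-
    c(spec$generating_params$warps, list(warp))
  spec
}

# derived sub-stream seeds, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset)) %% 2147483629)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a synthetic specimen population
#'
#' Emulates a study sample of one anatomical object: a common base shape, a
#' fixed group-mean warp per group (amplitude `between_group_amp`), an
#' individual warp per specimen (amplitude `within_amp`, smaller than the
#' group amplitude), and optionally a random rigid pose and uniform scale
#' per specimen. True landmarks are carried through every step. With
#' `n_groups = 1` this mimics a single-population sample; with several
#' groups, a multi-species sample.
#'
#' @param n number of specimens (>= n_groups).
#' @param n_groups number of planted shape groups.
#' @param between_group_amp amplitude of the group-mean warps (mm).
#' @param within_amp amplitude of the individual warps (mm).
#' @param pose apply a random rigid pose (rotation + translation) per
#'   specimen.
#' @param scale_range uniform-scale range per specimen, e.g. `c(0.9, 1.1)`;
#'   `c(1, 1)` disables size variation.
#' @param translation_range half-width (mm) of the uniform translation cube
#'   when `pose` is on.
#' @param seed master RNG seed; the population is byte-identical for a
#'   given seed.
#' @param subdivisions,n_bumps base-shape controls (see
#'   [make_base_shape()]).
#' @return a named list of `synthetic_specimen` objects with `group` set
#'   and names `spec01, spec02, ...`.
#' @export
make_population <- function(n = 12, n_groups = 3, between_group_amp = 0.9,
                            within_amp = 0.15, pose = TRUE,
                            scale_range = c(0.9, 1.1),
                            translation_range = 5, seed = 1,
                            subdivisions = 3, n_bumps = 10) {
  if (n < n_groups || n_groups < 1)
    stopf("need n >= n_groups >= 1 (got n = %d, n_groups = %d)", n, n_groups)
  base <- make_base_shape(subdivisions, n_bumps, seed = seed)
  group_of <- rep(seq_len(n_groups), length.out = n)
  # group differences are broad, species-scale warps; individual variation
  # is finer-grained and much smaller
  group_warps <- lapply(seq_len(n_groups), function(g)
    if (between_group_amp > 0)
      random_warp(base, n_centers = 3, amplitude = between_group_amp,
                  width = 1.8, seed = derive_seed(seed, g))
    else NULL)
  pop <- vector("list", n)
  ids <- sprintf("spec%02d", seq_len(n))
  for (i in seq_len(n)) {
    sp <- base
    g <- group_of[i]
    if (!is.null(group_warps[[g]])) sp <- apply_smooth_warp(sp, group_warps[[g]])
    if (within_amp > 0)
      sp <- apply_smooth_warp(sp, random_warp(base, n_centers = 4,
                                              amplitude = within_amp,
                                              width = 1.2,
                                              seed = derive_seed(seed, 100L + i)))
    prms <- withr::with_seed(derive_seed(seed, 500L + i), {
      list(R = if (pose) random_rotation() else diag(3),
           t = if (pose) stats::runif(3, -translation_range,
                                      translation_range) else c(0, 0, 0),
           s = stats::runif(1, scale_range[1], scale_range[2]))
    })
    sp$mesh$vertices <- sweep(prms$s * (sp$mesh$vertices %*% t(prms$R)), 2,
                              prms$t, "+")
    sp$true_landmarks <- landmark_set(
      sweep(prms$s * (sp$true_landmarks$coords %*% t(prms$R)), 2, prms$t, "+"),
      sp$true_landmarks$labels, specimen = ids[i])
    sp$mesh$name <- ids[i]
    sp$group <- sprintf("g%d", g)
    sp$generating_params$pose <- prms
    sp$generating_params$specimen <- ids[i]
    pop[[i]] <- sp
  }
  names(pop) <- ids
  pop
}

#' Extract the meshes / true landmarks / group labels of a population
#' @param pop a list of `synthetic_specimen` objects.
#' @return named list of meshes, named list of landmark sets, or named
#'   character vector of group labels.
#' @export
population_meshes <- function(pop) lapply(pop, function(s) s$mesh)

#' @rdname population_meshes
#' @export
population_landmarks <- function(pop) lapply(pop, function(s) s$true_landmarks)

#' @rdname population_meshes
#' @export
population_groups <- function(pop)
  vapply(pop, function(s) s$group, "")

#' Corrupt one template's slice of an estimate stack
#'
#' Displaces every landmark estimate of one template by a random-direction
#' offset of the given magnitude — a fixture for gross registration failure
#' (e.g. a template far in form from the target, as a juvenile template
#' against adults).
#'
#' @param stack an [estimate_stack()].
#' @param template_id which slice to corrupt.
#' @param magnitude offset length (mm); 0 leaves the stack unchanged.
#' @param seed RNG seed.
#' @return the corrupted [estimate_stack()].
#' @export
corrupt_template_slice <- function(stack, template_id, magnitude, seed = 1) {
  stopifnot(inherits(stack, "estimate_stack"))
  idx <- match(template_id, stack$template_ids)
  if (is.na(idx)) stopf("unknown template id '%s'", template_id)
  if (magnitude == 0) return(stack)
  L <- dim(stack$estimates)[2]
  offs <- withr::with_seed(seed, {
    d <- matrix(stats::rnorm(3 * L), ncol = 3)
    d / sqrt(rowSums(d^2)) * magnitude
  })
  est <- stack$estimates
  est[idx, , ] <- est[idx, , ] + offs
  estimate_stack(est, stack$template_ids, stack$labels, stack$target_id)
}
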