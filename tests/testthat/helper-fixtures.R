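# shared fixtures (built once per run) and independent brute-force oracles

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

fixture_base <- function(seed = 1) {
  cached(paste0("base", seed), make_base_shape(3, 10, seed = seed))
}

fixture_population <- function(seed = 2) {
  cached(paste0("pop", seed), make_population(n = 12, n_groups = 3, seed = seed))
}

# a small tetrahedron mesh for I/O and validation tests
tetra_mesh <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                rbind(c(1, 2, 3), c(1, 2, 4)), name = "tetra")
}

random_landmarks <- function(L, seed, scale = 10) {
  withr::with_seed(seed,
    landmark_set(matrix(runif(3 * L, -scale, scale), ncol = 3),
                 specimen = paste0("rand", seed)))
}

random_stack <- function(Tn, L, seed, target_id = "tgt") {
  withr::with_seed(seed,
    estimate_stack(array(rnorm(Tn * L * 3, sd = 5), c(Tn, L, 3)),
                   paste0("tpl", seq_len(Tn)), paste0("lm", seq_len(L)),
                   target_id))
}

# --- independent oracles -------------------------------------------------

# Eq-style RMSE by explicit per-landmark summation
bf_rmse <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  total <- 0
  for (i in seq_len(nrow(A))) {
    total <- total + (A[i, 1] - B[i, 1])^2 + (A[i, 2] - B[i, 2])^2 +
      (A[i, 3] - B[i, 3])^2
  }
  sqrt(total / nrow(A))
}

# per-coordinate sort-based median over template slices
bf_median_stack <- function(est) {
  Tn <- dim(est)[1]; L <- dim(est)[2]
  out <- matrix(NA_real_, L, 3)
  for (l in seq_len(L)) for (d in 1:3) {
    v <- sort(est[, l, d])
    n <- length(v)
    out[l, d] <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  out
}

# exhaustive nearest neighbour (loops, no matrix tricks)
bf_nearest <- function(p, pts) {
  best <- 1L; bd <- Inf
  for (i in seq_len(nrow(pts))) {
    d <- sum((p - pts[i, ])^2)
    if (d < bd) { bd <- d; best <- i }
  }
  best
}

# two-shape ordinary Procrustes distance (center, unit-size, best rotation)
bf_opa_distance <- function(A, B) {
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  A <- A / sqrt(sum(A^2));      B <- B / sqrt(sum(B^2))
  sv <- svd(crossprod(A, B))
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sqrt(sum((A %*% R - B)^2))
}

rigid_move_lms <- function(coords, R, t, s = 1) {
  sweep(s * (coords %*% t(R)), 2, t, "+")
}

random_rotation_seeded <- function(seed) {
  withr::with_seed(seed, {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  })
}

# templates/targets split of a population given template ids
population_split <- function(pop, tpl_ids) {
  templates <- lapply(tpl_ids, function(id)
    list(mesh = pop[[id]]$mesh, landmarks = pop[[id]]$true_landmarks))
  names(templates) <- tpl_ids
  tgt_ids <- setdiff(names(pop), tpl_ids)
  list(templates = templates,
       targets = population_meshes(pop)[tgt_ids],
       tgt_ids = tgt_ids)
}

# per-template mean RMSE matrix (targets x templates) and median RMSEs
malpaca_rmse_summary <- function(res, truth, tgt_ids) {
  med <- vapply(tgt_ids, function(id)
    rmse(res$targets[[id]]$median, truth[[id]]), 1)
  Tn <- length(res$template_ids)
  per_tpl <- sapply(seq_len(Tn), function(ti)
    vapply(tgt_ids, function(id)
      rmse(res$targets[[id]]$stack$estimates[ti, , ],
           truth[[id]]$coords), 1))
  list(median_rmse = med, template_rmse = per_tpl)
}
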