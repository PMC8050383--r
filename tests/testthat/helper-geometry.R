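# shared geometry fixtures and brute-force oracles, all built in code

# axis-aligned cube as a 12-triangle watertight mesh (outward winding)
cube_mesh <- function(side = 1, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  v <- sweep(v, 2, origin, `+`)
  f <- matrix(c(1,3,4, 1,4,2, 5,6,8, 5,8,7, 1,2,6, 1,6,5,
                3,7,8, 3,8,4, 1,5,7, 1,7,3, 2,4,8, 2,8,6),
              ncol = 3, byrow = TRUE)
  surface_mesh(v, f)
}

# voxelized ball mask, radius r mm at given spacing
ball_mask <- function(r = 10, spacing = 0.6, margin = 4) {
  n <- ceiling(2 * (r + margin) / spacing)
  cc <- (n + 1) / 2
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  occ <- array(rowSums((sweep(idx, 2, cc) * spacing)^2) <= r^2, c(n, n, n))
  binary_mask(occ, spacing = rep(spacing, 3))
}

# hollow spherical shell mask (outer/inner radii, mm)
shell_mask <- function(outer = 10, inner = 8, spacing = 0.5, margin = 3) {
  n <- ceiling(2 * (outer + margin) / spacing)
  cc <- (n + 1) / 2
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  r2 <- rowSums((sweep(idx, 2, cc) * spacing)^2)
  occ <- array(r2 <= outer^2 & r2 >= inner^2, c(n, n, n))
  binary_mask(occ, spacing = rep(spacing, 3))
}

# brute-force 3D flood fill from the border (6-connectivity); fills cavities
oracle_fill_3d <- function(occ) {
  d <- dim(occ)
  reach <- array(FALSE, d)
  queue <- matrix(0L, 0, 3)
  push_if <- function(q, i, j, k) {
    if (!occ[i, j, k] && !reach[i, j, k]) {
      reach[i, j, k] <<- TRUE
      rbind(q, c(i, j, k))
    } else q
  }
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in c(1, d[3])) queue <- push_if(queue, i, j, k)
  for (i in 1:d[1]) for (k in 1:d[3]) for (j in c(1, d[2])) queue <- push_if(queue, i, j, k)
  for (j in 1:d[2]) for (k in 1:d[3]) for (i in c(1, d[1])) queue <- push_if(queue, i, j, k)
  while (nrow(queue) > 0) {
    p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    for (dd in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      q <- p + dd
      if (all(q >= 1) && all(q <= d)) queue <- push_if(queue, q[1], q[2], q[3])
    }
  }
  occ | !reach
}

# brute-force component labelling (26-connectivity), first-seen order
oracle_label_26 <- function(occ) {
  d <- dim(occ)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (s in which(occ)) {
    if (lab[s] > 0L) next
    nxt <- nxt + 1L
    k0 <- (s - 1) %/% (d[1] * d[2]) + 1
    j0 <- ((s - 1) %/% d[1]) %% d[2] + 1
    i0 <- (s - 1) %% d[1] + 1
    stack <- matrix(c(i0, j0, k0), 1)
    lab[i0, j0, k0] <- nxt
    while (nrow(stack) > 0) {
      p <- stack[nrow(stack), ]; stack <- stack[-nrow(stack), , drop = FALSE]
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (all(q >= 1) && all(q <= d) && occ[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nxt
          stack <- rbind(stack, q)
        }
      }
    }
  }
  lab
}

# nearest-neighbour distances with plain double arithmetic (bit-compatible
# with the packaged kernel): for each row of A, min over B of
# sqrt(dx^2 + dy^2 + dz^2)
oracle_nn <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i) {
    sqrt(min((A[i, 1] - B[, 1])^2 + (A[i, 2] - B[, 2])^2 + (A[i, 3] - B[, 3])^2))
  }, numeric(1))
}

# small phantom spec for unit tests (same structure, smaller and faster)
small_phantom_spec <- function(...) {
  phantom_spec(body_size = c(30, 22, 18), pmma_semiaxes = c(9, 6, 1.6), ...)
}

# geodesic sphere: subdivided icosahedron projected to radius r
icosphere <- function(r = 10, subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- matrix(c(1,12,6, 1,6,2, 1,2,8, 1,8,11, 1,11,12, 2,6,10, 6,12,5,
                12,11,3, 11,8,7, 8,2,9, 4,10,5, 4,5,3, 4,3,7, 4,7,9,
                4,9,10, 5,10,6, 3,5,12, 7,3,11, 9,7,8, 10,9,2),
              ncol = 3, byrow = TRUE)
  for (s in seq_len(subdivisions)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    edges <- unique(key(rep(f, 3)[1:(3 * nrow(f))],
                        c(f[, 2], f[, 3], f[, 1])))
    mids <- new.env()
    for (e in edges) {
      ab <- as.integer(strsplit(e, " ")[[1]])
      v <- rbind(v, (v[ab[1], ] + v[ab[2], ]) / 2)
      assign(e, nrow(v), envir = mids)
    }
    mid <- function(a, b) get(key(a, b), envir = mids)
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- mid(a, b); bc <- mid(b, c3); ca <- mid(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(ab, b, bc), c(ca, bc, c3), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v * r / sqrt(rowSums(v^2))
  surface_mesh(v, f)
}

# deterministic pseudo-random rigid transform
random_rigid <- function(seed) {
  set.seed(seed)
  rigid_transform(canal3d:::rotation_about_axis(rnorm(3), runif(1, 0.1, 1.2)),
                  runif(3, -10, 10))
}
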