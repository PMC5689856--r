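# Independent R-language oracles. These deliberately re-derive results by
# direct summation/sampling so the compiled engine paths are checked
# against a second route.

# dense-sampling line integral of ED (0.01 mm steps), the brute-force
# counterpart of the Siddon radiological path
rad_path_oracle <- function(density, src, dst, step = 0.01) {
  g <- density$grid
  L <- sqrt(sum((dst - src)^2))
  if (L == 0) return(0)
  t <- seq(step / 2, L, by = step)
  u <- (dst - src) / L
  pts <- cbind(src[1] + t * u[1], src[2] + t * u[2], src[3] + t * u[3])
  lo <- g$origin - g$spacing / 2
  idx <- sapply(1:3, function(a)
    floor((pts[, a] - lo[a]) / g$spacing[a]) + 1L)
  n <- dim(g$values)
  inside <- idx[, 1] >= 1 & idx[, 1] <= n[1] & idx[, 2] >= 1 &
    idx[, 2] <= n[2] & idx[, 3] >= 1 & idx[, 3] <= n[3]
  sum(g$values[idx[inside, , drop = FALSE]]) * step
}

# direct collapsed-cone collection in plain R: walks every cone of every
# dose voxel exactly like the definition (nearest-voxel sampling, CK
# interval differences over radiological steps)
superpose_oracle <- function(terma, density, cck, step_mm) {
  g <- terma$grid
  n <- dim(g$values)
  # kernel-frame templates mapped to the world frame of an untilted
  # gantry-0 beam (forward +z of the kernel becomes world -z)
  dirs <- cck$cones$directions %*% diag(c(1, -1, -1))
  edges <- cck$radii_mm
  rmax <- max(edges)
  lo <- g$origin - g$spacing / 2
  hi <- g$origin + (n - 0.5) * g$spacing
  ck_at <- function(row, r)
    stats::approx(edges, cck$CK[row, ], xout = min(r, rmax), rule = 2)$y
  dose <- array(0, n)
  for (kz in seq_len(n[3])) for (jy in seq_len(n[2])) for (ix in seq_len(n[1])) {
    x <- g$origin + (c(ix, jy, kz) - 1) * g$spacing
    acc <- 0
    for (m in seq_len(nrow(dirs))) {
      u <- dirs[m, ]
      racc <- 0; ckp <- 0; s <- 0
      repeat {
        p <- x - (s + step_mm / 2) * u
        if (any(p < lo) || any(p > hi) || racc >= rmax) break
        i <- pmin(pmax(floor((p - lo) / g$spacing) + 1L, 1L), n)
        ed <- density$grid$values[i[1], i[2], i[3]]
        rnew <- racc + ed * step_mm
        if (ed > 0) {
          ckn <- ck_at(m, rnew)
          acc <- acc + terma$grid$values[i[1], i[2], i[3]] * (ckn - ckp)
          ckp <- ckn
        }
        racc <- rnew; s <- s + step_mm
      }
    }
    dose[ix, jy, kz] <- acc
  }
  dose
}

# numeric chord-length model of a rounded leaf end: fraction of leaf
# thickness traversed at penetration u, computed by direct geometry
chord_fraction_oracle <- function(u, R, t) {
  if (u <= 0) return(0)
  if (u >= R) return(1)
  min(2 * sqrt(u * (2 * R - u)) / t, 1)
}
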