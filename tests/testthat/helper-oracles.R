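# Independent brute-force oracles, deliberately written without reusing the
# package's internals: plain-R flood fill, pairwise-distance inscribed-sphere
# search, and dense line-casting MIL.  All operate in voxel units.

# 26-connected component labeling by breadth-first search over an R array
label_oracle <- function(fg) {
  d <- dim(fg)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  cur <- 0L
  for (start in which(fg & lab == 0)) {
    if (lab[start] != 0) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- arrayInd(queue[1], d)
      queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > d)) next
        qi <- q[1] + d[1] * (q[2] - 1 + d[2] * (q[3] - 1))
        if (fg[qi] && lab[qi] == 0) {
          lab[qi] <- cur
          queue <- c(queue, qi)
        }
      }
    }
  }
  lab
}

# Largest-inscribed-sphere local thickness, from the definition: for each
# phase voxel p, the largest r^2(c) over phase centres c whose sphere
# (radius^2 = min squared distance to a complement voxel centre, strict
# containment) contains p.  O(n^2); volumes must be small.
thickness_oracle_sq <- function(fg) {
  d <- dim(fg)
  P <- arrayInd(which(fg), d)
  B <- arrayInd(which(!fg), d)
  stopifnot(nrow(P) > 0, nrow(B) > 0)
  r2 <- vapply(seq_len(nrow(P)), function(i)
    min(colSums((t(B) - P[i, ])^2)), numeric(1))
  out <- numeric(nrow(P))
  for (i in seq_len(nrow(P))) {
    d2 <- colSums((t(P) - P[i, ])^2)
    cover <- d2 < r2[i]
    out[cover] <- pmax(out[cover], r2[i])
  }
  map <- array(0, d)
  map[which(fg)] <- out
  map
}

# Dense line-casting MIL oracle: lines on a 1-voxel grid, 0.25-voxel steps,
# no random offsets; same MIL definition (bone length / crossings) and
# quadric fit, coded independently and vectorised per direction.
mil_oracle <- function(fg, spacing_mm, dirs) {
  d <- dim(fg)
  ctr <- (d - 1) / 2
  Rad <- sqrt(sum(d^2)) / 2 + 1
  step <- 0.25
  out <- matrix(0, nrow(dirs), 2)
  for (q in seq_len(nrow(dirs))) {
    w <- dirs[q, ]
    a <- if (abs(w[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
    e1 <- c(w[2] * a[3] - w[3] * a[2], w[3] * a[1] - w[1] * a[3],
            w[1] * a[2] - w[2] * a[1])
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(w[2] * e1[3] - w[3] * e1[2], w[3] * e1[1] - w[1] * e1[3],
            w[1] * e1[2] - w[2] * e1[1])
    uv <- as.matrix(expand.grid(u = seq(-Rad, Rad, by = 1),
                                v = seq(-Rad, Rad, by = 1)))
    orig <- cbind(ctr[1] + uv[, 1] * e1[1] + uv[, 2] * e2[1] - Rad * w[1],
                  ctr[2] + uv[, 1] * e1[2] + uv[, 2] * e2[2] - Rad * w[2],
                  ctr[3] + uv[, 1] * e1[3] + uv[, 2] * e2[3] - Rad * w[3])
    ts <- seq(0, 2 * Rad, by = step)
    len <- 0
    crossings <- 0
    state <- matrix(-1L, nrow(orig), length(ts)) # -1 invalid, 0 marrow, 1 bone
    for (axis in 1:1) {} # (positions computed per coordinate below)
    ix <- round(outer(orig[, 1], ts * w[1], "+"))
    iy <- round(outer(orig[, 2], ts * w[2], "+"))
    iz <- round(outer(orig[, 3], ts * w[3], "+"))
    valid <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3]
    lin <- ix + d[1] * (iy + d[2] * iz) + 1
    lin[!valid] <- 1L
    bone <- matrix(fg[lin], nrow(orig), length(ts))
    state[valid & bone] <- 1L
    state[valid & !bone] <- 0L
    len <- sum(state == 1L) * step
    s1 <- state[, -ncol(state), drop = FALSE]
    s2 <- state[, -1, drop = FALSE]
    crossings <- sum(s1 >= 0 & s2 >= 0 & s1 != s2)
    out[q, ] <- c(len, crossings)
  }
  mil <- out[, 1] * spacing_mm / out[, 2]
  A <- cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
             2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
             2 * dirs[, 2] * dirs[, 3])
  h <- solve(crossprod(A), crossprod(A, 1 / mil^2))
  H <- matrix(c(h[1], h[4], h[5], h[4], h[2], h[6], h[5], h[6], h[3]), 3, 3)
  ev <- eigen(H, symmetric = TRUE)$values
  sort(1 / sqrt(ev), decreasing = TRUE)
}

# Boolean-sphere near-isotropic test volume
boolean_spheres <- function(shape = c(48, 48, 48), n = 260, seed = 2,
                            spacing_mm = 0.05) {
  set.seed(seed)
  a <- array(0, shape)
  for (q in seq_len(n)) {
    c0 <- runif(3, 5, shape - 5)
    r <- runif(1, 2.5, 4.5)
    lo <- pmax(1, floor(c0 - r))
    hi <- pmin(shape, ceiling(c0 + r))
    g <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    sel <- rowSums(sweep(g, 2, c0)^2) <= r^2
    a[g[sel, , drop = FALSE]] <- 1
  }
  voxel_volume(a, spacing_mm)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
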