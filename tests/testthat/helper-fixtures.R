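# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env()

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

ball_mask <- function(r, n = 2 * r + 14) {
  cc <- (n - 1) / 2
  x <- seq_len(n) - 1
  d2 <- outer(outer((x - cc)^2, (x - cc)^2, `+`), (x - cc)^2, `+`)
  array(d2 <= r^2, dim = c(n, n, n))
}

# small guard-compliant folded phantom (1 mm voxels, gyral spacing 8.4 mm)
small_folded_spec <- function(a = 2, lobe_amplitude = c(1, 1, 1, 1),
                              voxel = 1, grid = 80) {
  folded_brain_spec(base_radius_mm = 30, fold_amplitude_mm = a,
                    fold_frequency = 12, cortical_thickness_mm = 2,
                    voxel_size_mm = voxel, grid_shape = rep(grid, 3),
                    lobe_amplitude = lobe_amplitude)
}

small_folded_lv <- function(a = 2, ...) {
  key <- paste0("lv_", a, "_", paste(c(...), collapse = "_"))
  memo(key, make_folded_brain(small_folded_spec(a, ...)))
}

# independent reference morphology on small grids: direct neighbourhood
# scan, no shared code with the package implementation
ref_dilate <- function(mask, steps = 1) {
  d <- dim(mask)
  for (s in seq_len(steps)) {
    out <- mask
    idx <- which(mask, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      for (ax in 1:3) {
        for (dd in c(-1, 1)) {
          p <- idx[k, ]
          p[ax] <- p[ax] + dd
          if (p[ax] >= 1 && p[ax] <= d[ax]) out[p[1], p[2], p[3]] <- TRUE
        }
      }
    }
    mask <- out
  }
  mask
}

ref_erode <- function(mask, steps = 1) {
  d <- dim(mask)
  for (s in seq_len(steps)) {
    out <- mask
    idx <- which(mask, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      keep <- TRUE
      for (ax in 1:3) {
        for (dd in c(-1, 1)) {
          p <- idx[k, ]
          p[ax] <- p[ax] + dd
          if (p[ax] < 1 || p[ax] > d[ax] || !mask[p[1], p[2], p[3]]) keep <- FALSE
        }
      }
      if (!keep) out[idx[k, 1], idx[k, 2], idx[k, 3]] <- FALSE
    }
    mask <- out
  }
  mask
}

# all injective assignments of n cases to m pool slots (n <= m), as a
# matrix with one assignment per row
all_assignments <- function(n, m) {
  if (n == 1) return(matrix(seq_len(m), ncol = 1))
  out <- NULL
  for (j in seq_len(m)) {
    rest <- all_assignments(n - 1, m - 1)
    remaining <- setdiff(seq_len(m), j)
    out <- rbind(out, cbind(j, matrix(remaining[rest], nrow = nrow(rest))))
  }
  out
}

brute_force_match <- function(cost) {
  asg <- all_assignments(nrow(cost), ncol(cost))
  totals <- apply(asg, 1, function(a) sum(cost[cbind(seq_len(nrow(cost)), a)]))
  list(total = min(totals), assignment = asg[which.min(totals), ])
}

# watertightness: every undirected mesh edge borders exactly two faces
edge_face_counts <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(table(key))
}
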