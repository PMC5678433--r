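# Derivation of the 256-case iso-surface triangulation table.
#
# Cube corners are indexed 0..7 by coordinate bits (x, y, z); edges are the 12
# corner pairs differing in one bit. For a binary field sampled at voxel
# centres and iso-level 0.5, every surface vertex lies at a cube-edge
# midpoint. Each of the 256 corner-sign cases is triangulated by running
# marching squares on the six cube faces and linking the resulting segments
# into closed loops. Face saddles (two diagonally opposite inside corners)
# are resolved by always isolating the inside corners; because a shared face
# is seen with identical corner values from both adjacent cells, this rule is
# globally consistent and the extracted surface is watertight.

mc_corner_coords <- function() {
  t(vapply(0:7, function(i) {
    c(bitwAnd(i, 1L), bitwAnd(bitwShiftR(i, 1L), 1L), bitwAnd(bitwShiftR(i, 2L), 1L))
  }, numeric(3)))
}

mc_edges <- function() {
  e <- list()
  for (i in 0:7) {
    for (ax in 0:2) {
      if (bitwAnd(i, bitwShiftL(1L, ax)) == 0L) {
        e[[length(e) + 1L]] <- c(i, bitwOr(i, bitwShiftL(1L, ax)))
      }
    }
  }
  do.call(rbind, e[order(vapply(e, function(p) p[1] * 8 + p[2], numeric(1)))])
}

# six faces, each as 4 corner ids in cyclic order
mc_faces <- function() {
  faces <- list()
  for (ax in 0:2) {
    for (side in 0:1) {
      corners <- Filter(function(i) bitwAnd(bitwShiftR(i, ax), 1L) == side, 0:7)
      others <- setdiff(0:2, ax)
      key <- function(i) {
        c(bitwAnd(bitwShiftR(i, others[1]), 1L), bitwAnd(bitwShiftR(i, others[2]), 1L))
      }
      km <- vapply(corners, key, numeric(2))
      pick <- function(a, b) corners[which(km[1, ] == a & km[2, ] == b)]
      faces[[length(faces) + 1L]] <- c(pick(0, 0), pick(1, 0), pick(1, 1), pick(0, 1))
    }
  }
  faces
}

# marching-squares segments for one face of one case, as pairs of edge ids
mc_face_segments <- function(case, cyc, edge_id) {
  v <- vapply(cyc, function(cn) bitwAnd(bitwShiftR(case, cn), 1L), integer(1))
  eid <- vapply(1:4, function(i) {
    p <- sort(c(cyc[i], cyc[i %% 4 + 1]))
    edge_id[[paste(p, collapse = "-")]]
  }, integer(1))
  cut <- which(v != v[c(2, 3, 4, 1)])
  if (length(cut) == 0) return(NULL)
  if (length(cut) == 2) return(list(c(eid[cut[1]], eid[cut[2]])))
  # saddle: isolate each inside corner between its two adjacent cut edges
  segs <- list()
  for (i in 1:4) {
    ip <- i %% 4 + 1
    im <- (i - 2) %% 4 + 1
    if (v[i] == 1 && v[ip] == 0 && v[im] == 0) {
      segs[[length(segs) + 1L]] <- c(eid[im], eid[i])
    }
  }
  segs
}

mc_build_table <- function() {
  edges <- mc_edges()
  edge_id <- stats::setNames(
    as.list(seq_len(nrow(edges)) - 1L),
    apply(edges, 1, paste, collapse = "-")
  )
  faces <- mc_faces()
  loops_by_case <- vector("list", 256)
  for (case in 0:255) {
    segs <- list()
    for (cyc in faces) {
      segs <- c(segs, mc_face_segments(case, cyc, edge_id))
    }
    loops <- list()
    if (length(segs) > 0) {
      used <- rep(FALSE, length(segs))
      seg_mat <- do.call(rbind, segs)
      while (any(!used)) {
        s0 <- which(!used)[1]
        used[s0] <- TRUE
        loop <- seg_mat[s0, ]
        repeat {
          cur <- loop[length(loop)]
          nxt <- which(!used & (seg_mat[, 1] == cur | seg_mat[, 2] == cur))
          if (length(nxt) == 0) break
          nxt <- nxt[1]
          used[nxt] <- TRUE
          other <- if (seg_mat[nxt, 1] == cur) seg_mat[nxt, 2] else seg_mat[nxt, 1]
          if (other == loop[1]) break
          loop <- c(loop, other)
        }
        loops[[length(loops) + 1L]] <- loop
      }
    }
    loops_by_case[[case + 1L]] <- loops
  }

  loop_edges <- integer(0)
  loop_start <- integer(0)
  loop_case <- integer(0)
  for (case in 0:255) {
    for (loop in loops_by_case[[case + 1L]]) {
      loop_start <- c(loop_start, length(loop_edges))
      loop_case <- c(loop_case, case)
      loop_edges <- c(loop_edges, loop)
    }
  }
  corner <- mc_corner_coords()
  edge_mid <- (corner[edges[, 1] + 1L, ] + corner[edges[, 2] + 1L, ]) / 2
  list(
    loop_edges = as.integer(loop_edges),
    loop_start = as.integer(loop_start),
    loop_case = as.integer(loop_case),
    edge_mid = edge_mid
  )
}

.gyriflow_env <- new.env(parent = emptyenv())

mc_table <- function() {
  if (is.null(.gyriflow_env$mc_table)) {
    .gyriflow_env$mc_table <- mc_build_table()
  }
  .gyriflow_env$mc_table
}
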