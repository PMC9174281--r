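# fixture builders shared across tests; everything is generated in code.

# k nucleus positions inside the embryo sphere with a minimum pairwise
# separation (micrometres), returned in isotropic units on the volume
placeSeparated <- function(k, cfg, minSepUm = 12) {
  ctr <- cfg@volumeDim * cfg@voxelSpacing / 2
  rIn <- cfg@embryoRadius - cfg@nucleusRadius
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < k) {
    p <- runif(3, -1, 1) * rIn
    if (sqrt(sum(p^2)) > rIn) next
    if (nrow(pts) && min(sqrt(rowSums(sweep(pts, 2, p)^2))) < minSepUm) next
    pts <- rbind(pts, p)
  }
  pts <- sweep(pts, 2, ctr, `+`) / cfg@voxelSpacing[1]
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

# paint a voxelized ball into a logical array (1-based center, voxel units)
addBall <- function(arr, center, radius) {
  d <- dim(arr)
  xs <- max(1, floor(center[1] - radius)):min(d[1], ceiling(center[1] + radius))
  ys <- max(1, floor(center[2] - radius)):min(d[2], ceiling(center[2] + radius))
  zs <- max(1, floor(center[3] - radius)):min(d[3], ceiling(center[3] + radius))
  for (z in zs) for (y in ys) for (x in xs)
    if ((x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2 <= radius^2)
      arr[x, y, z] <- TRUE
  arr
}

# observation table for hand-built per-frame counts at 1 h spacing
obsFromCounts <- function(counts, dt = 1) {
  do.call(rbind, lapply(seq_along(counts), function(f) {
    n <- counts[f]
    data.frame(embryo_id = "e1", frame = f, time_h = (f - 1) * dt,
               x = seq_len(n) * 10, y = 0, z = 0)
  }))
}

# small deterministic lineage tree built by hand: root divides at t1, the two
# blastomeres divide at the given times, etc.
handTree <- function(divTimes2 = c(10, 11), birth1 = 0, div1 = 5) {
  nodes <- data.frame(
    node_id = 1:7,
    parent_id = c(NA, 1L, 1L, 2L, 2L, 3L, 3L),
    round_index = c(1L, 2L, 2L, 3L, 3L, 3L, 3L),
    birth_time = c(birth1, div1, div1, div1 + divTimes2[1], div1 + divTimes2[1],
                   div1 + divTimes2[2], div1 + divTimes2[2]),
    division_time = c(div1, div1 + divTimes2[1], div1 + divTimes2[2],
                      NA, NA, NA, NA))
  lineageTree("hand", nodes)
}
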