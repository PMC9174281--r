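## shape and motility descriptors computed from barycentric coordinates.

#' Coefficient of variation of nucleus-to-barycenter distances
#'
#' Sample CV of the Euclidean distances from each nucleus centroid to the
#' unweighted barycenter of the frame; a scale- and rigid-motion-invariant
#' roundness descriptor. Defined as 0 when all points coincide.
#'
#' @param points numeric matrix (n >= 2 rows, 3 columns).
#' @return unitless CV.
#' @examples
#' distanceCV(rbind(c(0,0,0), c(1,0,0), c(3,0,0)))
#' @export
distanceCV <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  ctr <- colMeans(points)
  d <- sqrt(rowSums(sweep(points, 2, ctr)^2))
  m <- mean(d)
  if (m == 0) return(0)
  sd(d) / m
}

#' Embryo motility between two frames
#'
#' Optimal one-to-one matching between the two point sets; the sum of the
#' matched displacement magnitudes divided by the elapsed time. Unmatched
#' points (count changes across a division) are excluded by default; with
#' \code{splitUnmatched = TRUE} every unmatched point instead contributes
#' the distance to its nearest counterpart, sharing a division displacement
#' between daughters.
#'
#' @param pointsA,pointsB numeric matrices (rows = nuclei, 3 columns).
#' @param dt elapsed time, hours (> 0).
#' @param splitUnmatched include nearest-counterpart distances of unmatched
#'   points.
#' @return displacement sum per hour (isotropic units / h).
#' @export
motility <- function(pointsA, pointsB, dt, splitUnmatched = FALSE) {
  if (dt <= 0) stop("dt must be > 0")
  pointsA <- as.matrix(pointsA); pointsB <- as.matrix(pointsB)
  if (nrow(pointsA) == 0L || nrow(pointsB) == 0L)
    stop("both frames must contain at least one point")
  pairs <- matchPoints(pointsA, pointsB)
  dists <- sqrt(rowSums((pointsA[pairs[, 1], , drop = FALSE] -
                           pointsB[pairs[, 2], , drop = FALSE])^2))
  total <- sum(dists)
  if (splitUnmatched) {
    if (nrow(pointsB) > nrow(pointsA)) {
      um <- setdiff(seq_len(nrow(pointsB)), pairs[, 2])
      for (u in um)
        total <- total + min(sqrt(rowSums(sweep(pointsA, 2, pointsB[u, ])^2)))
    } else if (nrow(pointsA) > nrow(pointsB)) {
      um <- setdiff(seq_len(nrow(pointsA)), pairs[, 1])
      for (u in um)
        total <- total + min(sqrt(rowSums(sweep(pointsB, 2, pointsA[u, ])^2)))
    }
  }
  total / dt
}

# center and scale to unit centroid size; errors on degenerate shapes
preshape <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  s <- sqrt(sum(x^2))
  if (s < 1e-12) stop("degenerate (all-coincident) shape")
  x / s
}

# full Procrustes distance for corresponded landmarks, rotation restricted
# to proper rotations (no reflection)
procrustesCorresponded <- function(a, b) {
  sv <- svd(crossprod(preshape(a), preshape(b)))
  d <- sign(det(sv$u %*% t(sv$v)))
  lam <- sv$d
  lam[length(lam)] <- lam[length(lam)] * d
  s <- sum(lam)
  sqrt(max(0, 1 - s^2))
}

#' Full Procrustes distance between two landmark configurations
#'
#' Residual shape distance after optimal translation, uniform scaling and
#' proper rotation (reflections excluded: embryos are chiral). Nuclei are
#' unlabeled landmarks, so when no correspondence is supplied it is resolved
#' by exhaustive minimization over landmark permutations for n <= 8, and by
#' greedy nearest-landmark initialization for larger sets.
#'
#' @param shapeA,shapeB numeric matrices (n >= 3 rows, 3 columns, equal n).
#' @param corresponded landmarks already correspond row-by-row.
#' @return unitless distance in [0, 1]; 0 exactly for similarity-equivalent
#'   shapes.
#' @examples
#' sq <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0))
#' procrustesDistance(sq, 2 * sq, corresponded = TRUE)  # 0
#' @export
procrustesDistance <- function(shapeA, shapeB, corresponded = FALSE) {
  a <- as.matrix(shapeA); b <- as.matrix(shapeB)
  if (nrow(a) != nrow(b)) stop("shapes must have equal point counts")
  if (nrow(a) < 3L) stop("need at least 3 landmarks")
  if (corresponded) return(procrustesCorresponded(a, b))
  n <- nrow(a)
  if (n <= 8L) {
    perms <- permutations(n)
    best <- Inf
    for (i in seq_len(nrow(perms))) {
      d <- procrustesCorresponded(a, b[perms[i, ], , drop = FALSE])
      if (d < best) best <- d
    }
    return(best)
  }
  # greedy nearest-landmark correspondence on the pre-shapes
  pa <- preshape(a); pb <- preshape(b)
  perm <- integer(n)
  free <- rep(TRUE, n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(pb) - pa[i, ])^2)
    d2[!free] <- Inf
    j <- which.min(d2)
    perm[i] <- j
    free[j] <- FALSE
  }
  procrustesCorresponded(a, b[perm, , drop = FALSE])
}

# all permutations of 1..n (n small)
permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Per-frame morphometric series of an embryo
#'
#' For each frame: the barycenter, the distance CV, the motility relative to
#' the previous frame and the Procrustes distance to the previous frame's
#' configuration (NA when the point counts differ or either frame has fewer
#' than 3 nuclei).
#'
#' @param observations nucleus-observation data.frame of one embryo.
#' @return data.frame with one row per frame: embryo_id, frame, time_h,
#'   bary_x, bary_y, bary_z, distance_cv, motility, procrustes_distance.
#' @export
morphometricSeries <- function(observations) {
  obs <- asObservations(observations)
  ids <- unique(obs$embryo_id)
  if (length(ids) != 1L) stop("expected a single embryo")
  frames <- split(obs, obs$frame)
  prev <- NULL; prevT <- NA_real_
  rows <- lapply(frames, function(f) {
    pts <- as.matrix(f[, c("x", "y", "z")])
    ctr <- colMeans(pts)
    dcv <- if (nrow(pts) >= 2) distanceCV(pts) else NA_real_
    mot <- NA_real_; pd <- NA_real_
    if (!is.null(prev)) {
      dt <- f$time_h[1] - prevT
      if (dt > 0) mot <- motility(prev, pts, dt)
      if (nrow(prev) == nrow(pts) && nrow(pts) >= 3) {
        # consecutive frames: nuclei barely move, so the optimal position
        # assignment fixes the landmark correspondence directly
        pr <- matchPoints(prev, pts)
        pd <- procrustesDistance(prev[pr[, 1], , drop = FALSE],
                                 pts[pr[, 2], , drop = FALSE],
                                 corresponded = TRUE)
      }
    }
    prev <<- pts; prevT <<- f$time_h[1]
    data.frame(embryo_id = ids, frame = f$frame[1], time_h = f$time_h[1],
               bary_x = ctr[1], bary_y = ctr[2], bary_z = ctr[3],
               distance_cv = dcv, motility = mot, procrustes_distance = pd)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
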