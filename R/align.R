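## Kabsch: proper rotation R minimizing || (A - centroid) R - (B - centroid) ||
## for row-vector coordinate matrices. Returns the rotation acting on the
## *mobile* set so that mobile %*% R best matches the reference.
kabsch_rotation <- function(mobile, reference) {
  H <- crossprod(mobile, reference)            # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  s$u %*% D %*% t(s$v)
}

rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Align an ensemble to a reference frame by C-alpha RMSD superposition
#'
#' Every frame is rigidly transformed (Kabsch algorithm on the alpha-carbon
#' atoms; translation + proper rotation applied to all atoms) so that its
#' C-alpha centroid coincides with the reference C-alpha centroid and the
#' C-alpha RMSD to the reference is minimized.  By default the reference is
#' the first frame of class 0 (class A).
#'
#' @param ensemble a `dect_ensemble` or list of `dect_frame`.
#' @param reference a `dect_frame`; default: first class-0 frame (first
#'   frame overall if there is none).
#' @return The ensemble with transformed coordinates; frame order, labels and
#'   annotations untouched.
#' @export
align_rmsd <- function(ensemble, reference = NULL) {
  frames <- if (inherits(ensemble, "dect_ensemble")) ensemble$frames
            else ensemble
  if (is.null(reference)) {
    first_a <- which(vapply(frames, function(f) f$class_label, 0L) == 0L)[1L]
    reference <- frames[[if (is.na(first_a)) 1L else first_a]]
  }
  ref_ca <- reference$coords[ca_indices(reference), , drop = FALSE]
  ref_cen <- colMeans(ref_ca)
  ref_ca <- sweep(ref_ca, 2, ref_cen)
  aligned <- lapply(frames, function(fr) {
    ca_idx <- ca_indices(fr)
    if (length(ca_idx) != nrow(ref_ca))
      stop_("C-alpha count mismatch: %d vs reference %d",
            length(ca_idx), nrow(ref_ca))
    mob_ca <- fr$coords[ca_idx, , drop = FALSE]
    cen <- colMeans(mob_ca)
    mob_ca <- sweep(mob_ca, 2, cen)
    if (qr(mob_ca)$rank < 3L)
      warning("degenerate (collinear) C-alpha set; best-fit rotation used")
    R <- kabsch_rotation(mob_ca, ref_ca)
    fr$coords <- sweep(sweep(fr$coords, 2, cen) %*% R, 2, ref_cen, "+")
    fr
  })
  if (inherits(ensemble, "dect_ensemble")) {
    ensemble$frames <- aligned
    ensemble
  } else aligned
}

## spherical Fibonacci lattice: n near-uniform unit vectors
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

## Rodrigues rotation of vectors v (rows) about unit axis k by angle a
rodrigues <- function(v, k, a) {
  k <- k / sqrt(sum(k^2))
  cs <- cos(a); sn <- sin(a)
  kv <- v %*% k
  cross <- cbind(k[2] * v[, 3] - k[3] * v[, 2],
                 k[3] * v[, 1] - k[1] * v[, 3],
                 k[1] * v[, 2] - k[2] * v[, 1])
  v * cs + cross * sn + outer(drop(kv), k) * (1 - cs)
}

#' Correspondence-free rotational alignment of two frames
#'
#' Aligns `frame_b` to `frame_a` by matching their topological summaries
#' instead of atom pairs: Euler characteristic curves are computed for
#' `n_dirs` near-uniform sphere directions on each frame's radius-cutoff
#' mesh, each direction of A is paired with the direction of B whose curve
#' is closest in squared Euclidean distance, and RANSAC over minimal
#' 3-pair samples finds the proper rotation with the largest consensus
#' (a pair is an inlier when `dot(dir_A, R dir_B) > dot_threshold`).
#'
#' Both frames are centered on their C-alpha centroids first.  The cost
#' curves use the same mesh radius `r` and filtration length `l` as the
#' main analysis.
#'
#' @param frame_a,frame_b `dect_frame` objects.
#' @param n_dirs number of summary directions (>= 3).
#' @param dot_threshold RANSAC inlier rule on the direction dot product.
#' @param r mesh radius cutoff in Angstroms.
#' @param l number of filtration steps.
#' @param iterations RANSAC iterations.
#' @param seed integer seed for the RANSAC sampling.
#' @return 3x3 proper rotation matrix (apply as `coords %*% t(R)`), with
#'   attribute `consensus` = inlier count.
#' @export
align_topological <- function(frame_a, frame_b, n_dirs = 500,
                              dot_threshold = 0.9, r = 6, l = 30,
                              iterations = 1000, seed = 1) {
  n_dirs <- check_count(n_dirs, "n_dirs", 3)
  dirs <- fibonacci_sphere(n_dirs)
  curves_for <- function(frame) {
    cen <- colMeans(frame$coords[ca_indices(frame), , drop = FALSE])
    fr <- frame
    fr$coords <- sweep(fr$coords, 2, cen)
    mesh <- build_mesh(fr, r = r)
    mesh <- normalize_meshes(list(mesh))[[1L]]
    filt <- filtration_spec(l)
    t(vapply(seq_len(n_dirs),
             function(i) ec_curve(mesh, dirs[i, ], filt)$values,
             numeric(l)))
  }
  ca_ <- curves_for(frame_a)
  cb_ <- curves_for(frame_b)
  ## pair each A-direction with its nearest B-direction in summary space
  best_b <- integer(n_dirs)
  for (i in seq_len(n_dirs)) {
    d2 <- colSums((t(cb_) - ca_[i, ])^2)
    best_b[i] <- which.min(d2)
  }
  pa <- dirs                 # directions on frame A
  pb <- dirs[best_b, , drop = FALSE]
  set.seed(seed)
  best_R <- NULL
  best_inl <- -1L
  for (it in seq_len(iterations)) {
    s <- sample.int(n_dirs, 3L)
    R <- kabsch_rotation(pb[s, , drop = FALSE], pa[s, , drop = FALSE])
    inl <- sum(rowSums((pb %*% R) * pa) > dot_threshold)
    if (inl > best_inl) {
      best_inl <- inl
      best_R <- R
    }
  }
  if (best_inl < 3L) stop_("no stable topological alignment")
  ## refit on the consensus set
  ok <- rowSums((pb %*% best_R) * pa) > dot_threshold
  if (sum(ok) >= 3L)
    best_R <- kabsch_rotation(pb[ok, , drop = FALSE], pa[ok, , drop = FALSE])
  R <- t(best_R)             # so that new_b = b %*% t(R) ... see below
  structure(R, consensus = as.integer(max(best_inl, sum(ok))))
}
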