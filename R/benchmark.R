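#' Generate a protein-backbone-like base chain
#'
#' Smooth self-avoiding 3D chain with ~3.8 Angstrom consecutive spacing
#' (alpha-carbon-like): step directions follow a persistent random walk,
#' a step is retried while it lands within 3.0 Angstroms of any earlier
#' non-adjacent atom, and the chain is confined to a sphere of radius
#' `3.2 * n_atoms^(1/3)` Angstroms so the fold is globular — matching the
#' packing density of real single-domain proteins (about one residue per
#' 130 cubic Angstroms), which is what makes the contact topology at
#' alpha-carbon resolution realistic.  The chain restarts (up to 1000
#' times) if a step cannot be placed.
#'
#' @param n_atoms chain length (>= 50).
#' @param seed integer seed.
#' @param spacing consecutive spacing in Angstroms.
#' @param persistence direction-persistence weight in [0, 1); larger is
#'   straighter.
#' @param confine_radius confinement sphere radius in Angstroms
#'   (default `3.2 * n_atoms^(1/3)`).
#' @return n_atoms x 3 coordinate matrix.
#' @export
synth_chain <- function(n_atoms, seed = 1, spacing = 3.8,
                        persistence = 0.55,
                        confine_radius = 3.2 * n_atoms^(1 / 3)) {
  n_atoms <- check_count(n_atoms, "n_atoms", 50)
  set.seed(child_seed(seed, 1L))
  for (restart in seq_len(1000L)) {
    x <- matrix(0, n_atoms, 3)
    x[1, ] <- stats::rnorm(3) * confine_radius / 4
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    ok <- TRUE
    for (i in 2:n_atoms) {
      placed <- FALSE
      for (try in seq_len(100L)) {
        ## persistent steps first; fall back to fully random wiggles when
        ## boxed in near the wall or earlier chain segments
        w <- if (try <= 30L) persistence else 0
        nd <- w * dir + (1 - w) * stats::rnorm(3)
        nd <- nd / sqrt(sum(nd^2))
        cand <- x[i - 1L, ] + spacing * nd
        if (sqrt(sum(cand^2)) > confine_radius) next
        if (i > 2L) {
          d2 <- rowSums(sweep(x[seq_len(i - 2L), , drop = FALSE], 2,
                              cand)^2)
          if (min(d2) < 3.0^2) next
        }
        x[i, ] <- cand
        dir <- nd
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(x)
  }
  stop_("chain self-intersection persisted after 1000 restarts")
}

#' Most compact contiguous window of a chain
#'
#' Scans every contiguous window of `width` atoms and returns the one
#' with the smallest radius of gyration — a localized, loop-like region
#' of the fold, analogous to the surface loops used as ground-truth
#' regions in controlled perturbation studies.
#'
#' @param coords chain coordinates (n x 3) or a `dect_frame`.
#' @param width window width in atoms.
#' @return A [roi_spec()] over the selected atom indices.
#' @export
compact_roi_window <- function(coords, width = 40) {
  if (inherits(coords, "dect_frame")) coords <- coords$coords
  n <- nrow(coords)
  if (n < width) stop_("chain shorter than the window")
  rg <- vapply(seq_len(n - width + 1L), function(i) {
    w <- coords[i:(i + width - 1L), , drop = FALSE]
    sum(sweep(w, 2, colMeans(w))^2)
  }, 0)
  start <- which.min(rg)
  roi_spec(atoms = start:(start + width - 1L))
}

#' Synthetic thermal ensemble around a base conformation
#'
#' Emulates post-alignment molecular-dynamics fluctuation: every frame is
#' the base chain plus a spatially correlated Gaussian displacement field
#' (squared-exponential correlation over inter-atom distance, length
#' `corr_length`; per-atom displacement-norm SD `thermal_sigma`, i.e.
#' per-coordinate SD `thermal_sigma / sqrt(3)`), plus a small random
#' global rotation (up to `max_rot_deg` degrees) that downstream
#' [align_rmsd()] removes again.
#'
#' @param n_frames number of frames (>= 10).
#' @param base base conformation (from [synth_chain()]), or `NULL` to
#'   generate one from `n_atoms` and `seed`.
#' @param n_atoms chain length when `base` is NULL.
#' @param thermal_sigma per-atom RMS displacement in Angstroms.
#' @param corr_length correlation length of the displacement field (Å).
#' @param seed integer seed.
#' @param class_label label attached to all frames.
#' @param times optional frame times in ns (length `n_frames`).
#' @param max_rot_deg maximum random global rotation, degrees.
#' @return list of `dect_frame` (atom names "CA", one residue per atom).
#' @export
synth_ensemble <- function(n_frames, base = NULL, n_atoms = 400,
                           thermal_sigma = 0.4, corr_length = 5,
                           seed = 1, class_label = 0L, times = NULL,
                           max_rot_deg = 2) {
  n_frames <- check_count(n_frames, "n_frames", 10)
  if (is.null(base)) base <- synth_chain(n_atoms, seed)
  n <- nrow(base)
  sd_c <- thermal_sigma / sqrt(3)
  set.seed(child_seed(seed, 2L))
  Lc <- NULL
  if (thermal_sigma > 0) {
    D2 <- as.matrix(stats::dist(base))^2
    C <- sd_c^2 * exp(-D2 / (2 * corr_length^2))
    Lc <- chol(C + diag(1e-10 * max(sd_c^2, 1), n))
  }
  if (is.null(times)) times <- seq_len(n_frames) - 1
  lapply(seq_len(n_frames), function(i) {
    x <- base
    if (!is.null(Lc))
      x <- x + crossprod(Lc, matrix(stats::rnorm(3 * n), n, 3))
    if (max_rot_deg > 0) {
      axis <- stats::rnorm(3)
      ang <- stats::runif(1, 0, max_rot_deg * pi / 180)
      cen <- colMeans(x)
      x <- sweep(rodrigues(sweep(x, 2, cen), axis, ang), 2, cen, "+")
    }
    structure_frame(x, class_label = class_label, frame_time = times[i])
  })
}

#' Perturbation specification for the controlled benchmark
#'
#' @param mode "constant" (same fixed vector for every ROI atom in every
#'   frame) or "spherical" (independent standard-normal vector per ROI
#'   atom per frame, normalized to `magnitude`).
#' @param magnitude displacement scale in Angstroms; in constant mode each
#'   Cartesian component equals `magnitude` (total length
#'   `magnitude * sqrt(3)`) unless `total_length_mode` rescales the vector
#'   to total length `magnitude`.
#' @param roi a [roi_spec()] naming the perturbed atoms.
#' @param seed integer seed (spherical draws).
#' @param total_length_mode see `magnitude`.
#' @return A `dect_perturbation` list.
#' @export
perturbation_spec <- function(mode = c("constant", "spherical"),
                              magnitude = 1, roi, seed = 1,
                              total_length_mode = FALSE) {
  mode <- match.arg(mode)
  if (magnitude <= 0) stop_("magnitude must be > 0")
  structure(list(mode = mode, magnitude = magnitude, roi = roi,
                 seed = seed, total_length_mode = isTRUE(total_length_mode)),
            class = "dect_perturbation")
}

#' Displace ROI atoms of every frame
#'
#' Non-ROI atoms are untouched, and the frames are deliberately NOT
#' re-aligned afterwards: re-aligning a perturbed ensemble drags the
#' unperturbed body against the displacement and smears the ground truth.
#'
#' @param frames list of `dect_frame`.
#' @param spec a [perturbation_spec()].
#' @return the perturbed frames.
#' @export
perturb_roi <- function(frames, spec) {
  ridx <- roi_atoms(frames[[1L]], spec$roi)
  m <- spec$magnitude
  if (spec$mode == "constant") {
    v <- c(m, m, m)
    if (spec$total_length_mode) v <- v / sqrt(3)
    return(lapply(frames, function(fr) {
      fr$coords[ridx, ] <- sweep(fr$coords[ridx, , drop = FALSE], 2, v, "+")
      fr
    }))
  }
  set.seed(child_seed(spec$seed, 3L))
  lapply(frames, function(fr) {
    g <- matrix(stats::rnorm(3 * length(ridx)), length(ridx), 3)
    g <- g * (m / sqrt(rowSums(g^2)))
    fr$coords[ridx, ] <- fr$coords[ridx, , drop = FALSE] + g
    fr
  })
}

frames_to_matrix <- function(frames)
  t(vapply(frames, function(fr) as.numeric(t(fr$coords)),
           numeric(3 * n_atoms(frames[[1L]]))))

#' RMSF-difference baseline
#'
#' Per class and atom, the root-mean-square (over frames) of the distance
#' to the atom's mean position; the score is the absolute between-class
#' difference.  Exactly shift-invariant, so purely static (constant-
#' vector) displacements are invisible to it.
#'
#' @param frames_a,frames_b frame lists with identical atom counts.
#' @return per-atom score vector.
#' @export
rmsf_baseline <- function(frames_a, frames_b) {
  if (n_atoms(frames_a[[1L]]) != n_atoms(frames_b[[1L]]))
    stop_("RMSF baseline requires atom correspondence between classes")
  rmsf <- function(frames) {
    arr <- vapply(frames, function(fr) fr$coords,
                  frames[[1L]]$coords)            # n x 3 x n_frames
    mu <- apply(arr, c(1, 2), mean)
    sqrt(apply((arr - as.vector(mu))^2, 3, rowSums) |> rowMeans())
  }
  unname(abs(rmsf(frames_a) - rmsf(frames_b)))
}

#' PCA baseline
#'
#' Flattens each class to frames x 3n, centers, takes the top
#' `n_components` right singular vectors weighted by their singular
#' values, sums them into one coordinate-space vector per class, and
#' scores each atom by the Euclidean norm (over its 3 coordinates) of the
#' between-class difference of those vectors.
#'
#' @inheritParams rmsf_baseline
#' @param n_components number of principal components (clipped with a
#'   warning if larger than the data admit).
#' @return per-atom score vector.
#' @export
pca_baseline <- function(frames_a, frames_b, n_components = 10) {
  if (n_atoms(frames_a[[1L]]) != n_atoms(frames_b[[1L]]))
    stop_("PCA baseline requires atom correspondence between classes")
  comp_sum <- function(frames) {
    M <- frames_to_matrix(frames)
    M <- sweep(M, 2, colMeans(M))
    k <- min(n_components, nrow(M), ncol(M))
    if (k < n_components)
      warning(sprintf("n_components clipped to %d", k))
    sv <- svd(M, nu = 0, nv = k)
    colSums(t(sv$v) * sv$d[seq_len(k)])
  }
  dv <- comp_sum(frames_a) - comp_sum(frames_b)
  sqrt(colSums(matrix(dv^2, nrow = 3)))
}

#' Elastic-net classification baseline
#'
#' Concatenated atomic coordinates are features of an L1+L2-penalized
#' linear (binomial) classifier.  The penalty strength is selected on a
#' stratified 90/10 train/validation split by validation accuracy over a
#' log-spaced grid (1e-5..1e-1, 7 points; ties resolved toward the
#' stronger penalty), at mixing ratio `alpha`.  Each atom is scored by
#' the sum of absolute coefficients over its 3 coordinates.
#'
#' @inheritParams rmsf_baseline
#' @param seed integer seed for the split.
#' @param alpha elastic-net mixing ratio (1 = lasso).
#' @param lambda_grid penalty grid (descending order recommended).
#' @return per-atom score vector with attribute `validation_accuracy`.
#' @export
elasticnet_baseline <- function(frames_a, frames_b, seed = 1, alpha = 0.15,
                                lambda_grid = 10^seq(-1, -5,
                                                     length.out = 7)) {
  if (n_atoms(frames_a[[1L]]) != n_atoms(frames_b[[1L]]))
    stop_("elastic net requires atom correspondence between classes")
  X <- rbind(frames_to_matrix(frames_a), frames_to_matrix(frames_b))
  y <- c(rep(0L, length(frames_a)), rep(1L, length(frames_b)))
  set.seed(child_seed(seed, 4L))
  val <- c(sample(which(y == 0L), max(1L, round(0.1 * sum(y == 0L)))),
           sample(which(y == 1L), max(1L, round(0.1 * sum(y == 1L)))))
  fit <- glmnet::glmnet(X[-val, , drop = FALSE], y[-val],
                        family = "binomial", alpha = alpha,
                        lambda = sort(lambda_grid, decreasing = TRUE),
                        standardize = FALSE)
  pred <- predict(fit, X[val, , drop = FALSE], type = "class")
  acc <- colMeans(pred == as.character(y[val]))
  best <- which.max(acc)     # first max = largest lambda = strongest penalty
  beta <- abs(as.numeric(fit$beta[, best]))
  score <- colSums(matrix(beta, nrow = 3))
  attr(score, "validation_accuracy") <- unname(acc[best])
  attr(score, "lambda") <- fit$lambda[best]
  score
}

#' Cone-wise detection scores from feature associations
#'
#' Closed form of the sorted-threshold detection sweep: an atom is
#' detected by a cone once every one of that cone's directions selects the
#' atom's sublevel feature, so thresholding
#' `score(atom) = max over cones of (min over the cone's directions of the
#' atom's gamma)` reproduces the swept detected sets exactly.
#'
#' @param design a `dect_design`.
#' @param scores a `dect_scores` (or plain gamma vector).
#' @param frame_index which meshes' atom maps to score.  A single index
#'   gives the literal single-frame sweep statistic; a vector of indices
#'   averages the statistic over those frames (the same across-frame
#'   averaging convention the evidence scores use), which smooths the
#'   sublevel-bin quantization of any one conformation.
#' @return per-atom score vector.
#' @export
detection_scores <- function(design, scores, frame_index = 1L) {
  gamma <- if (inherits(scores, "dect_scores")) scores$gamma else scores
  cone_of <- design$dirs$cone_of
  one <- function(idx) {
    map <- design$atom_feature_map[[idx]]
    G <- matrix(gamma[map], nrow(map), ncol(map))
    out <- rep(-Inf, nrow(G))
    for (k in seq_len(design$dirs$c)) {
      cols <- which(cone_of == k)
      m_k <- do.call(pmin, as.data.frame(G[, cols, drop = FALSE]))
      out <- pmax(out, m_k)
    }
    out
  }
  unname(Reduce(`+`, lapply(frame_index, one)) / length(frame_index))
}

#' ROC curve and AUC against ground-truth labels (Mann-Whitney-consistent)
#'
#' Sweeps the distinct score values as descending thresholds (ties
#' grouped), accumulating TPR = TP/P and FPR = FP/N, and integrates by the
#' trapezoid rule.  All-constant scores give the single diagonal step,
#' AUC 0.5.
#'
#' @param scores per-atom scores (larger = more likely positive).
#' @param truth logical (or 0/1) ground-truth labels.
#' @return A `dect_roc` list: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  P <- sum(truth)
  N <- sum(!truth)
  if (P == 0L || N == 0L) stop_("need both positive and negative labels")
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t_ <- truth[ord]
  idx <- cumsum(rle(s)$lengths)       # last position of each tie group
  tpr <- c(0, cumsum(t_)[idx] / P)
  fpr <- c(0, cumsum(!t_)[idx] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "dect_roc")
}

#' @method print dect_roc
#' @export
print.dect_roc <- function(x, ...) {
  cat(sprintf("<dect_roc> AUC = %.4f over %d thresholds\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Run the controlled perturbation benchmark
#'
#' Generates one synthetic thermal ensemble per class around a shared base
#' chain (class A at integer-ns times, class B interleaved at +0.5 ns,
#' both split across the requested offset series), aligns everything to
#' the first class-A frame, perturbs the ROI atoms of class B (no
#' re-alignment afterwards), runs the requested scoring methods and
#' returns the AUC of each at recovering the ROI atoms.
#'
#' @param n_atoms,n_frames,thermal_sigma,corr_length see [synth_ensemble()];
#'   `n_frames` is per class.
#' @param roi a [roi_spec()]; `NULL` (the default) picks the spatially
#'   most compact contiguous 40-atom window of the base chain (see
#'   [compact_roi_window()]) — a localized, loop-like region, which is
#'   what the perturbation scenarios emulate.
#' @param mode,magnitude see [perturbation_spec()].
#' @param offsets offset-series time shifts in ns.
#' @param methods subset of "rmsf", "pca", "elasticnet", "dect".
#' @param c,d,theta,l,r transform parameters for the "dect" method;
#'   `r = NULL` picks the radius for mean vertex degree 10 on the
#'   reference frame.
#' @param n_iter,burn_in,thin sampler settings passed to [dect()].
#' @param seed master seed.
#' @return data.frame (method, mode, magnitude, auc, seed) with the
#'   per-method score vectors in attribute `scores` and the fitted
#'   [dect()] object (if run) in attribute `fit`.
#' @export
run_benchmark <- function(n_atoms = 400, n_frames = 100,
                          thermal_sigma = 0.4, corr_length = 5,
                          roi = NULL,
                          mode = "spherical", magnitude = 2,
                          offsets = seq(0, 0.4, by = 0.1),
                          methods = base::c("rmsf", "pca", "elasticnet",
                                      "dect"),
                          c = 10, d = 4, theta = 0.8, l = 60, r = NULL,
                          n_iter = 10000, burn_in = n_iter / 2, thin = 10,
                          seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  base <- synth_chain(n_atoms, seed)
  if (is.null(roi)) roi <- compact_roi_window(base)
  per_series <- max(1L, n_frames %/% length(offsets))
  times_a <- as.numeric(outer(seq_len(per_series) - 1, offsets, "+"))
  frames_a <- synth_ensemble(n_frames, base = base,
                             thermal_sigma = thermal_sigma,
                             corr_length = corr_length,
                             seed = child_seed(seed, 10L), class_label = 0L,
                             times = times_a[seq_len(n_frames)])
  frames_b <- synth_ensemble(n_frames, base = base,
                             thermal_sigma = thermal_sigma,
                             corr_length = corr_length,
                             seed = child_seed(seed, 20L), class_label = 1L,
                             times = times_a[seq_len(n_frames)] + 0.5)
  aligned <- align_rmsd(base::c(frames_a, frames_b), reference = frames_a[[1L]])
  frames_a <- aligned[seq_len(n_frames)]
  frames_b <- perturb_roi(aligned[n_frames + seq_len(n_frames)],
                          perturbation_spec(mode, magnitude, roi,
                                            seed = child_seed(seed, 30L)))
  truth <- seq_len(n_atoms) %in% roi_atoms(frames_a[[1L]], roi)
  scores <- list()
  fit <- NULL
  for (mth in methods) {
    scores[[mth]] <- switch(mth,
      rmsf = rmsf_baseline(frames_a, frames_b),
      pca = pca_baseline(frames_a, frames_b),
      elasticnet = elasticnet_baseline(frames_a, frames_b,
                                       seed = child_seed(seed, 40L)),
      dect = {
        fit <- dect(frames_a, frames_b, r = r, c = c, d = d,
                     theta = theta, l = l, n_iter = n_iter,
                     burn_in = burn_in, thin = thin,
                     seed = child_seed(seed, 50L), align = FALSE)
        detection_scores(fit$design, fit$scores,
                                 frame_index = seq_along(aligned))
      })
  }
  out <- data.frame(method = names(scores), mode = mode,
                    magnitude = magnitude,
                    auc = vapply(scores, function(s) roc_auc(s, truth)$auc,
                                 0),
                    seed = seed, row.names = NULL)
  attr(out, "scores") <- scores
  attr(out, "truth") <- truth
  attr(out, "fit") <- fit
  out
}
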