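#' Region-of-interest specification
#'
#' @param residues integer vector of residue ids, and/or
#' @param atoms explicit atom indices (into the representative frame).
#' @return A `dect_roi` list.
#' @export
roi_spec <- function(residues = NULL, atoms = NULL) {
  if (is.null(residues) && is.null(atoms))
    stop_("give residues and/or atoms")
  structure(list(residues = residues, atoms = atoms), class = "dect_roi")
}

roi_atoms <- function(frame, roi) {
  idx <- integer(0)
  if (!is.null(roi$residues))
    idx <- which(frame$residue_ids %in% roi$residues)
  if (!is.null(roi$atoms)) idx <- sort(unique(c(idx, as.integer(roi$atoms))))
  if (length(idx) == 0L) stop_("ROI matches no atoms in this frame")
  idx
}

#' ROI test statistic: summed per-atom association score
#'
#' @param scores per-atom association values (one per atom of the frame).
#' @param atoms atom indices of the region.
#' @return scalar sum.
#' @export
roi_statistic <- function(scores, atoms) {
  if (any(atoms < 1L | atoms > length(scores)))
    stop_("region atoms outside the score vector")
  if (any(is.na(scores[atoms]))) stop_("missing scores on region atoms")
  sum(scores[atoms])
}

#' K-nearest-neighbour null regions
#'
#' Draws `T` seed atoms uniformly without replacement from outside the ROI
#' and grows each into a K-atom region (the seed plus its K-1 nearest
#' atoms by Euclidean distance).  Regions sharing any atom with the ROI
#' are rejected and redrawn, up to `100 * T` total draws.
#'
#' @param frame representative `dect_frame`.
#' @param roi a [roi_spec()].
#' @param n_regions number of null regions T.
#' @param seed integer seed.
#' @return list of `T` integer atom-index vectors, each of length K
#'   (= ROI size) and disjoint from the ROI.
#' @export
knn_null_regions <- function(frame, roi, n_regions = 500, seed = 1) {
  n_regions <- check_count(n_regions, "n_regions")
  ridx <- roi_atoms(frame, roi)
  K <- length(ridx)
  outside <- setdiff(seq_len(n_atoms(frame)), ridx)
  if (length(outside) < K) stop_("fewer than K atoms outside the ROI")
  D <- as.matrix(stats::dist(frame$coords))
  set.seed(seed)
  pool <- sample(outside)          # uniform order, no replacement
  regions <- vector("list", n_regions)
  got <- 0L
  draws <- 0L
  i <- 0L
  while (got < n_regions) {
    i <- i + 1L
    if (i > length(pool)) {        # pool exhausted: reshuffle (with cap)
      pool <- sample(outside)
      i <- 1L
    }
    draws <- draws + 1L
    if (draws > 100L * n_regions)
      stop_("could not place %d null regions disjoint from the ROI",
            n_regions)
    seed_atom <- pool[i]
    region <- order(D[seed_atom, ])[seq_len(K)]   # includes the seed (d=0)
    if (length(intersect(region, ridx)) > 0L) next
    got <- got + 1L
    regions[[got]] <- sort(region)
  }
  regions
}

#' Null-region P-value
#'
#' `P = (1 / (T + 1)) * #\{t : tau_star <= tau_t\}` — the fraction (out of
#' T + 1) of null statistics at least as large as the observed one, ties
#' counted.  Note the granularity: P takes values in
#' `\{0, 1/(T+1), ..., T/(T+1)\}`.  With `add_one_numerator = TRUE` the
#' conventional permutation estimator `(1 + #) / (T + 1)` is used instead.
#'
#' @param tau_star observed ROI statistic.
#' @param tau_null numeric vector of T null statistics.
#' @param add_one_numerator use the +1 numerator convention?
#' @return P-value in `[0, 1]`.
#' @export
roi_pvalue <- function(tau_star, tau_null, add_one_numerator = FALSE) {
  T_ <- length(tau_null)
  if (T_ < 1L) stop_("need at least one null statistic")
  (sum(tau_star <= tau_null) + as.integer(add_one_numerator)) / (T_ + 1)
}

#' Calibrated Bayes factor from a P-value
#'
#' `BF(P) = 1 / (-e * P * ln P)`, an evidence ratio for the alternative
#' over the null, defined for `P < 1/e`.  `P = 0` maps to `Inf`;
#' `P >= 1/e` returns `NA` (reported as an em dash in tables).
#'
#' @param p P-value(s).
#' @return Bayes factor(s); `NA` where undefined.
#' @export
calibrated_bf <- function(p) {
  out <- rep(NA_real_, length(p))
  out[!is.na(p) & p == 0] <- Inf
  ok <- !is.na(p) & p > 0 & p < exp(-1)
  out[ok] <- 1 / (-exp(1) * p[ok] * log(p[ok]))
  boundary <- !is.na(p) & p == exp(-1)
  out[boundary] <- 1
  out
}

#' Run the ROI null test on one structure's per-atom scores
#'
#' @param frame representative `dect_frame`.
#' @param scores per-atom association values (e.g. `gamma_hat` from
#'   [scale_scores()]).
#' @param roi a [roi_spec()].
#' @param n_regions number of null regions T.
#' @param seed integer seed.
#' @inheritParams roi_pvalue
#' @return list with `tau_star`, `tau_null`, `p`, `bf`.
#' @export
roi_null_test <- function(frame, scores, roi, n_regions = 500, seed = 1,
                          add_one_numerator = FALSE) {
  ridx <- roi_atoms(frame, roi)
  tau_star <- roi_statistic(scores, ridx)
  regions <- knn_null_regions(frame, roi, n_regions, seed)
  tau_null <- vapply(regions, function(rg) roi_statistic(scores, rg), 0)
  p <- roi_pvalue(tau_star, tau_null, add_one_numerator)
  list(tau_star = tau_star, tau_null = tau_null, p = p,
       bf = calibrated_bf(p))
}

#' Aggregate null-test results across structures
#'
#' Median P and median calibrated Bayes factor (over defined BFs only).
#'
#' @param results list of [roi_null_test()] results.
#' @return list with `p_values`, `bf_values`, `p_median`, `bf_median`.
#' @export
aggregate_null_test <- function(results) {
  if (length(results) < 1L) stop_("no results")
  p <- vapply(results, function(r) r$p, 0)
  bf <- vapply(results, function(r) r$bf, 0)
  list(p_values = p, bf_values = bf,
       p_median = stats::median(p),
       bf_median = if (any(!is.na(bf))) stats::median(bf[!is.na(bf)])
                   else NA_real_)
}
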