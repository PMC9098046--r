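#' Per-atom minimum association value (evidence score before scaling)
#'
#' In the threshold-sweep reconstruction an atom stays "alive" while all of
#' its m per-direction gamma values exceed a rising threshold, and is
#' assigned the value at which it dies.  That sweep has a closed form: the
#' atom's minimum gamma over its m associated features.
#'
#' @param map n_atoms x m integer matrix of feature columns (one per
#'   direction), from `atom_feature_map`.
#' @param gamma length-J association vector (or a `dect_scores`).
#' @return length n_atoms vector of per-atom minimum gamma.
#' @export
atom_gamma_hat <- function(map, gamma) {
  if (inherits(gamma, "dect_scores")) gamma <- gamma$gamma
  if (any(is.na(map)) || any(map < 1L) || any(map > length(gamma)))
    stop_("atom feature map has columns outside the gamma vector")
  matrix(gamma[map], nrow(map), ncol(map)) |> apply(1, min)
}

## 0..100 rank scaling with average ranks for ties
rank_scale <- function(x) {
  n <- length(x)
  if (n == 1L) return(100)
  100 * (rank(x, ties.method = "average") - 1) / (n - 1)
}

#' Evidence scores on atoms and residues
#'
#' Per-frame minimum-gamma values are averaged over frames per atom, then
#' rank-scaled to `[0, 100]` (average ranks for ties).  Residue scores are
#' the mean per-atom value within each residue, rank-scaled over residues.
#' When `series` assigns frames to offset series, per-residue means and
#' standard errors across series are attached.
#'
#' @param gamma_hat_frames matrix (n_frames x n_atoms) of per-frame
#'   minimum-gamma values, or a single vector.
#' @param residue_ids integer residue id per atom (representative frame).
#' @param series optional factor of length n_frames grouping frames into
#'   offset series.
#' @return A `dect_evidence` list: `gamma_hat` (per-atom mean), `atom_score`,
#'   `residue_ids`, `residue_score` (named by residue), and optionally
#'   `residue_series` (mean and standard error per residue across series).
#' @export
scale_scores <- function(gamma_hat_frames, residue_ids, series = NULL) {
  if (is.null(dim(gamma_hat_frames)))
    gamma_hat_frames <- matrix(gamma_hat_frames, nrow = 1L)
  gh <- colMeans(gamma_hat_frames)
  if (length(residue_ids) != length(gh))
    stop_("residue_ids length does not match atoms")
  atom_score <- rank_scale(gh)
  res_mean <- tapply(gh, residue_ids, mean)
  residue_score <- rank_scale(as.numeric(res_mean))
  names(residue_score) <- names(res_mean)
  out <- list(gamma_hat = gh, atom_score = atom_score,
              residue_ids = residue_ids, residue_score = residue_score)
  if (!is.null(series)) {
    series <- as.factor(series)
    per_series <- vapply(levels(series), function(sl) {
      g <- colMeans(gamma_hat_frames[series == sl, , drop = FALSE])
      as.numeric(tapply(g, residue_ids, mean))
    }, numeric(length(res_mean)))
    if (is.null(dim(per_series)))
      per_series <- matrix(per_series, nrow = 1L)
    out$residue_series <- data.frame(
      residue = as.integer(names(res_mean)),
      mean = rowMeans(per_series),
      se = apply(per_series, 1, stats::sd) / sqrt(ncol(per_series)))
  }
  structure(out, class = "dect_evidence")
}

#' Write a representative structure with evidence scores as B-factors
#'
#' @param frame representative `dect_frame`.
#' @param evidence a `dect_evidence` (atom scores clamped to 99.99).
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
export_scored_pdb <- function(frame, evidence, path) {
  if (n_atoms(frame) != length(evidence$atom_score))
    stop_("atom count mismatch between frame and scores")
  write_frames(frame, path, b_factors = evidence$atom_score)
}
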