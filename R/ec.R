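## index of the first threshold a_k with h <= a_k (l+1 if h is above them all)
entry_index <- function(h, thresholds)
  findInterval(h, thresholds, left.open = TRUE) + 1L

## per-step cumulative counts of simplices whose max vertex height has
## entered by each threshold
cum_counts <- function(h, l, thresholds) {
  k <- entry_index(h, thresholds)
  k[k > l] <- l + 1L
  cumsum(tabulate(k, nbins = l + 1L))[seq_len(l)]
}

## max vertex height per edge / face, given vertex heights hv
simplex_heights <- function(mesh, hv) {
  eh <- if (nrow(mesh$edges)) pmax(hv[mesh$edges[, 1]], hv[mesh$edges[, 2]])
        else numeric(0)
  fh <- if (nrow(mesh$faces)) pmax(hv[mesh$faces[, 1]], hv[mesh$faces[, 2]],
                                   hv[mesh$faces[, 3]])
        else numeric(0)
  list(edges = eh, faces = fh)
}

#' Euler characteristic curve of a mesh along one direction
#'
#' Heights are `h(x) = x . nu`; the k-th sublevel complex contains a vertex
#' iff its height is `<= a_k` and an edge/face iff all its vertices are in
#' (max-vertex-height convention).  The curve value at step k is
#' `V_k - E_k + F_k`.
#'
#' @param mesh a normalized `dect_mesh` (vertex norms <= 1).
#' @param nu unit direction (normalized with a warning otherwise).
#' @param filt a [filtration_spec()].
#' @return A `dect_ec_curve`: integer `values` (length l), per-step counts
#'   `V`, `E`, `F`, and `nu`.
#' @export
ec_curve <- function(mesh, nu, filt) {
  nu <- as.numeric(nu)
  nn <- sqrt(sum(nu^2))
  if (abs(nn - 1) > 1e-8) {
    warning("direction not unit norm; normalizing")
    nu <- nu / nn
  }
  l <- filt$l
  a <- filt$thresholds
  hv <- drop(mesh$vertices %*% nu)
  sh <- simplex_heights(mesh, hv)
  V <- cum_counts(hv, l, a)
  E <- cum_counts(sh$edges, l, a)
  F_ <- cum_counts(sh$faces, l, a)
  structure(list(values = V - E + F_, V = V, E = E, F = F_, nu = nu),
            class = "dect_ec_curve")
}

#' Differential Euler characteristic curve
#'
#' Step-to-step change of the EC counts with lag `t`:
#' `value_k = chi_k - chi_(k-t)`, where the complex at step `k - t < 1` is
#' empty, so for `t = 1` the curve telescopes exactly back to the EC curve.
#'
#' @inheritParams ec_curve
#' @param t lag, `1 <= t < l`.
#' @return A `dect_dec_curve` with integer `values` and the lagged count
#'   differences `dV`, `dE`, `dF`.
#' @export
dec_curve <- function(mesh, nu, filt, t = 1) {
  t <- check_count(t, "t")
  if (t >= filt$l) stop_("lag t must be < l")
  ec <- ec_curve(mesh, nu, filt)
  lagged <- function(x) x - c(rep(0L, t), x[seq_len(filt$l - t)])
  structure(list(values = lagged(ec$values), dV = lagged(ec$V),
                 dE = lagged(ec$E), dF = lagged(ec$F), nu = ec$nu, t = t),
            class = "dect_dec_curve")
}

#' Assemble the topology design matrix
#'
#' Row i concatenates the DEC curves of mesh i over all directions in the
#' fixed column order: cones outer, directions within cone middle, sublevel
#' index inner, so column `j` decodes uniquely to
#' `(cone, direction, sublevel)` (see the returned `provenance`).
#' For every mesh, `atom_feature_map[[i]]` records, per atom and direction,
#' the column of the smallest threshold at which that atom enters the
#' filtration — the hook used later to project feature importances back
#' onto atoms.
#'
#' @param meshes list of `dect_mesh` sharing one normalization.
#' @param dirs a [generate_cones()] object.
#' @param filt a [filtration_spec()].
#' @param t DEC lag.
#' @return A `dect_design`: `X` (N x J), `provenance` data.frame
#'   (column, cone, direction, sublevel), `atom_feature_map` (list of
#'   n_atoms x m integer matrices of column indices), `y` class labels,
#'   plus `dirs`, `filt`, `t`.
#' @export
build_design_matrix <- function(meshes, dirs, filt, t = 1) {
  if (length(meshes) < 1L) stop_("no meshes")
  scales <- vapply(meshes, function(m) m$scale_factor, 0)
  if (max(scales) - min(scales) > 1e-12 * max(scales))
    stop_("meshes do not share one normalization")
  m <- dirs$c * dirs$d
  l <- filt$l
  J <- m * l
  N <- length(meshes)
  X <- matrix(0, N, J)
  afm <- vector("list", N)
  tdirs <- t(dirs$directions)
  for (i in seq_len(N)) {
    mesh <- meshes[[i]]
    H <- mesh$vertices %*% tdirs            # n_atoms x m heights
    row <- numeric(J)
    for (v in seq_len(m)) {
      hv <- H[, v]
      sh <- simplex_heights(mesh, hv)
      V <- cum_counts(hv, l, filt$thresholds)
      E <- cum_counts(sh$edges, l, filt$thresholds)
      F_ <- cum_counts(sh$faces, l, filt$thresholds)
      chi <- V - E + F_
      row[(v - 1L) * l + seq_len(l)] <-
        chi - c(rep(0L, t), chi[seq_len(l - t)])
    }
    X[i, ] <- row
    k_entry <- entry_index(H, filt$thresholds)
    k_entry[k_entry > l] <- l
    afm[[i]] <- matrix((rep(seq_len(m) - 1L, each = nrow(H)) * l) +
                         as.integer(k_entry), nrow(H), m)
    ## map mesh vertex rows back to source atoms
    rownames(afm[[i]]) <- NULL
  }
  provenance <- data.frame(
    column = seq_len(J),
    cone = rep(seq_len(dirs$c), each = dirs$d * l),
    direction = rep(rep(seq_len(dirs$d), each = l), times = dirs$c),
    sublevel = rep(seq_len(l), times = m))
  y <- vapply(meshes, function(mm) mm$class_label %||% 0L, 0L)
  structure(list(X = X, provenance = provenance, atom_feature_map = afm,
                 y = as.integer(y), dirs = dirs, filt = filt, t = t),
            class = "dect_design")
}

#' @method print dect_design
#' @export
print.dect_design <- function(x, ...) {
  cat(sprintf("<dect_design> N=%d frames x J=%d features (c=%d d=%d l=%d)\n",
              nrow(x$X), ncol(x$X), x$dirs$c, x$dirs$d, x$filt$l))
  invisible(x)
}
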