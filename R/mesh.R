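#' Build a radius-cutoff simplicial complex from a frame
#'
#' Vertices are the atoms; an edge joins every atom pair whose Euclidean
#' distance is strictly smaller than `r`; a face fills every atom triple
#' whose three pairwise edges are present.  Isolated vertices are retained.
#' Tetrahedra and higher simplices are never enumerated — the Euler
#' characteristic here uses only V, E and F.
#'
#' @param frame a `dect_frame`.
#' @param r radius cutoff in Angstroms (> 0); ties at exactly `r` are
#'   excluded.
#' @return A `dect_mesh`: `vertices` (n x 3), `edges` (|E| x 2, i < j),
#'   `faces` (|F| x 3, i < j < k), `r_cutoff`, `scale_factor` (1 until
#'   [normalize_meshes()] is applied), `atom_index_map` (mesh vertex ->
#'   source atom row) and the source frame's annotations.
#' @export
build_mesh <- function(frame, r) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stop_("r must be > 0")
  x <- frame$coords
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  adj <- d < r
  diag(adj) <- FALSE
  ## edges with i < j
  eidx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- eidx[order(eidx[, 1], eidx[, 2]), , drop = FALSE]
  dimnames(edges) <- NULL
  ## faces: for each edge (i,j), common neighbours k > j
  faces <- matrix(integer(0), 0L, 3L)
  if (nrow(edges) > 0L) {
    fl <- vector("list", nrow(edges))
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      k <- which(adj[i, ] & adj[j, ])
      k <- k[k > j]
      if (length(k))
        fl[[e]] <- cbind(i, j, k, deparse.level = 0)
    }
    fl <- fl[!vapply(fl, is.null, TRUE)]
    if (length(fl)) faces <- do.call(rbind, fl)
  }
  structure(list(vertices = x, edges = edges, faces = faces,
                 r_cutoff = r, scale_factor = 1,
                 atom_index_map = seq_len(n),
                 residue_ids = frame$residue_ids,
                 atom_names = frame$atom_names,
                 class_label = frame$class_label),
            class = "dect_mesh")
}

#' @method print dect_mesh
#' @export
print.dect_mesh <- function(x, ...) {
  cat(sprintf(
    "<dect_mesh> V=%d E=%d F=%d (chi=%d), r=%.3g, scale=%.4g\n",
    nrow(x$vertices), nrow(x$edges), nrow(x$faces),
    euler_characteristic(x), x$r_cutoff, x$scale_factor))
  invisible(x)
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh a `dect_mesh`.
#' @return integer.
#' @export
euler_characteristic <- function(mesh)
  nrow(mesh$vertices) - nrow(mesh$edges) + nrow(mesh$faces)

#' Normalize a set of meshes to the unit ball with one common scale
#'
#' All vertex coordinates are divided by a single dataset-wide scale
#' factor: the largest vertex distance from `origin` over every mesh.
#' Using one common scale (rather than per-mesh scaling) keeps the
#' topological summary statistics comparable across frames.  Connectivity
#' is untouched.
#'
#' @param meshes list of `dect_mesh` built from frames sharing one
#'   alignment.
#' @param origin common origin; default the centroid of the first mesh's
#'   vertices (the reference frame's atoms after alignment).
#' @return The meshes, recentered on `origin` and scaled; `scale_factor`
#'   records the normalizing radius in Angstroms.
#' @export
normalize_meshes <- function(meshes, origin = NULL) {
  if (length(meshes) == 0L) stop_("empty mesh list")
  if (is.null(origin)) origin <- colMeans(meshes[[1L]]$vertices)
  radius <- max(vapply(meshes, function(m)
    sqrt(max(rowSums(sweep(m$vertices, 2, origin)^2))), 0))
  if (radius <= 0) stop_("degenerate meshes: zero radius")
  lapply(meshes, function(m) {
    m$vertices <- sweep(m$vertices, 2, origin) / radius
    m$scale_factor <- radius
    m
  })
}

#' Pick a mesh radius from a target mean vertex degree
#'
#' Bisection on `r` so that the mean number of neighbours per atom (edges
#' counted twice over atoms) on the given frame hits `target_degree`.
#'
#' @param frame a representative `dect_frame`.
#' @param target_degree desired mean degree (default 10, well inside the
#'   useful 4-20 band for protein-scale point clouds).
#' @return radius in Angstroms.
#' @export
radius_for_degree <- function(frame, target_degree = 10) {
  d <- stats::dist(frame$coords)
  n <- n_atoms(frame)
  deg <- function(r) 2 * sum(d < r) / n
  lo <- 0.1; hi <- max(d)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (deg(mid) < target_degree) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Export a mesh in OFF format (debugging aid)
#' @param mesh a `dect_mesh`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  utils::write.table(format(mesh$vertices, digits = 9), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (nrow(mesh$faces))
    utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  invisible(path)
}
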