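## Independent brute-force oracles used across the suite.  These deliberately
## re-derive quantities from first principles (exhaustive enumeration, literal
## re-simulation) and share no code with the implementation paths they check.

random_frame <- function(n = 30, box = 10, seed = 1, ...) {
  set.seed(seed)
  structure_frame(matrix(runif(n * 3, 0, box), n, 3), ...)
}

## exhaustive pair/triple enumeration mesh
brute_mesh <- function(coords, r) {
  n <- nrow(coords)
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < r)
      edges <- rbind(edges, c(i, j))
  has_edge <- function(i, j)
    !is.null(edges) && any(edges[, 1] == min(i, j) & edges[, 2] == max(i, j))
  faces <- NULL
  if (n >= 3) for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1))
    for (k in (j + 1):n)
      if (has_edge(i, j) && has_edge(i, k) && has_edge(j, k))
        faces <- rbind(faces, c(i, j, k))
  list(edges = edges, faces = faces)
}

## EC curve by rebuilding every sublevel complex from scratch
brute_ec_curve <- function(mesh, nu, thresholds) {
  hv <- drop(mesh$vertices %*% nu)
  vapply(thresholds, function(a) {
    vin <- which(hv <= a)
    ein <- if (nrow(mesh$edges)) sum(mesh$edges[, 1] %in% vin &
                                       mesh$edges[, 2] %in% vin) else 0L
    fin <- if (nrow(mesh$faces)) sum(mesh$faces[, 1] %in% vin &
                                       mesh$faces[, 2] %in% vin &
                                       mesh$faces[, 3] %in% vin) else 0L
    length(vin) - ein + fin
  }, 0)
}

## literal threshold-sweep reconstruction: raise the threshold through the
## sorted gamma values; an atom dies when any of its values falls at or
## below the threshold, and is assigned the largest of its values not
## exceeding that threshold (= the value that killed it)
sweep_gamma_hat <- function(map, gamma) {
  n <- nrow(map)
  out <- rep(NA_real_, n)
  alive <- rep(TRUE, n)
  for (thr in sort(unique(gamma[as.vector(map)]))) {
    for (a in which(alive)) {
      g <- gamma[map[a, ]]
      if (any(g <= thr)) {
        alive[a] <- FALSE
        out[a] <- max(g[g <= thr])
      }
    }
  }
  out
}

## literal detection sweep: features with gamma >= T selected; an atom is
## detected when some cone has all its directions' features selected
sweep_detected <- function(map, gamma, cone_of, T_) {
  sel <- gamma >= T_
  vapply(seq_len(nrow(map)), function(a) {
    any(vapply(unique(cone_of), function(k)
      all(sel[map[a, cone_of == k]]), TRUE))
  }, TRUE)
}

## AUC as the Mann-Whitney pairwise probability
mw_auc <- function(scores, truth) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!as.logical(truth)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

make_multimodel_pdb <- function(path, frames) {
  write_frames(frames, path)
  path
}
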