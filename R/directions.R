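#' Generate cones of filtration directions
#'
#' Cone centers are placed by a deterministic spherical Fibonacci lattice
#' (near-uniform coverage of the unit sphere); the whole set is then rotated
#' by a seed-controlled random rotation so different seeds explore different
#' orientations while the layout stays reproducible.  Within each cone,
#' `d` directions are placed equidistantly on the circle of angular radius
#' `theta` about the center (Rodrigues' rotation formula); `d = 1` uses the
#' center itself.
#'
#' @param c number of cones (>= 1).
#' @param d directions per cone (>= 1).
#' @param theta cap radius in radians, in (0, 2*pi].
#' @param seed integer seed for the global random rotation.
#' @return A `dect_directions` object: `centers` (c x 3), `directions`
#'   (c*d x 3, grouped by cone: cone index outer, direction index inner),
#'   `cone_of` (length c*d), and the parameters.
#' @export
generate_cones <- function(c = 10, d = 4, theta = 0.8, seed = 1) {
  c <- check_count(c, "c"); d <- check_count(d, "d")
  if (!is.numeric(theta) || theta <= 0 || theta > 2 * pi)
    stop_("theta must be in (0, 2*pi]")
  centers <- fibonacci_sphere(c)
  ## seed-controlled random rotation of the whole lattice
  set.seed(child_seed(seed, 17L))
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  centers <- centers %*% Q
  dirs <- matrix(0, c * d, 3)
  for (k in seq_len(c)) {
    mu <- centers[k, ]
    if (d == 1L) {
      dirs[k, ] <- mu
      next
    }
    ## an arbitrary unit vector orthogonal to mu
    ref <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * mu) * mu
    u <- u / sqrt(sum(u^2))
    ## tilt mu by theta towards u, then spin equidistantly about mu
    tilted <- drop(rodrigues(matrix(mu, 1), u, theta))
    ang <- 2 * pi * (seq_len(d) - 1) / d
    for (i in seq_len(d))
      dirs[(k - 1L) * d + i, ] <- drop(rodrigues(matrix(tilted, 1), mu,
                                                 ang[i]))
  }
  dirs <- dirs / sqrt(rowSums(dirs^2))
  structure(list(centers = centers, directions = dirs,
                 cone_of = rep(seq_len(c), each = d),
                 c = c, d = d, theta = theta, seed = seed),
            class = "dect_directions")
}

#' @method print dect_directions
#' @export
print.dect_directions <- function(x, ...) {
  cat(sprintf("<dect_directions> %d cones x %d directions (m=%d), theta=%.3g\n",
              x$c, x$d, x$c * x$d, x$theta))
  invisible(x)
}

#' Sublevel-set filtration thresholds
#'
#' `l` thresholds equally spaced on `range` inclusive.  After unit-ball
#' normalization every vertex height lies in `[-1, 1]`, so the default
#' range is exhaustive.
#'
#' @param l number of sublevel sets (>= 2).
#' @param range filtration range, default `c(-1, 1)`.
#' @return A `dect_filtration`: `l`, `thresholds` (strictly increasing).
#' @export
filtration_spec <- function(l = 60, range = c(-1, 1)) {
  l <- check_count(l, "l", 2)
  if (range[1] >= range[2]) stop_("invalid filtration range")
  structure(list(l = l, thresholds = seq(range[1], range[2], length.out = l)),
            class = "dect_filtration")
}
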