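test_that("the base chain is backbone-like, self-avoiding and globular", {
  ch <- synth_chain(120, seed = 1)
  steps <- sqrt(rowSums(diff(ch)^2))
  expect_true(all(steps > 3.0 & steps < 4.6))
  D <- as.matrix(dist(ch))
  diag(D) <- Inf
  D[cbind(1:119, 2:120)] <- Inf
  D[cbind(2:120, 1:119)] <- Inf
  expect_gte(min(D), 3.0)                       # non-adjacent clash cutoff
  expect_lte(max(sqrt(rowSums(ch^2))), 3.2 * 120^(1 / 3) + 1e-9)
})

test_that("zero thermal noise reproduces the base exactly; RMSF matches sigma", {
  base <- synth_chain(60, seed = 2)
  frames0 <- synth_ensemble(10, base = base, thermal_sigma = 0,
                            max_rot_deg = 0, seed = 3)
  for (fr in frames0) expect_equal(fr$coords, base, ignore_attr = TRUE)

  ## generator contract: per-atom RMSF ~ thermal_sigma within 10%
  frames <- synth_ensemble(500, base = base, thermal_sigma = 0.5,
                           corr_length = 4, max_rot_deg = 0, seed = 4)
  arr <- vapply(frames, function(fr) fr$coords, base)
  mu <- apply(arr, c(1, 2), mean)
  rmsf <- sqrt(rowMeans(apply((arr - as.vector(mu))^2, 3, rowSums)))
  expect_lt(max(abs(rmsf - 0.5)), 0.05)
})

test_that("perturbations displace exactly the ROI in the stated way", {
  base <- synth_chain(60, seed = 5)
  frames <- synth_ensemble(10, base = base, thermal_sigma = 0.2, seed = 6)
  roi <- roi_spec(atoms = 11:18)
  const <- perturb_roi(frames, perturbation_spec("constant", 1.0, roi))
  for (i in seq_along(frames)) {
    delta <- const[[i]]$coords - frames[[i]]$coords
    expect_equal(delta[11:18, ], matrix(1, 8, 3), ignore_attr = TRUE)
    expect_equal(delta[-(11:18), ], matrix(0, 52, 3), ignore_attr = TRUE)
  }
  sph <- perturb_roi(frames, perturbation_spec("spherical", 2.0, roi,
                                               seed = 7))
  lens <- unlist(lapply(seq_along(frames), function(i)
    sqrt(rowSums((sph[[i]]$coords - frames[[i]]$coords)[11:18, ]^2))))
  expect_equal(lens, rep(2, length(lens)), tolerance = 1e-12)
  ## per-frame redraws differ
  d1 <- sph[[1]]$coords[11, ] - frames[[1]]$coords[11, ]
  d2 <- sph[[2]]$coords[11, ] - frames[[2]]$coords[11, ]
  expect_gt(max(abs(d1 - d2)), 1e-6)
  ## total-length option
  tl <- perturb_roi(frames, perturbation_spec("constant", 1.0, roi,
                                              total_length_mode = TRUE))
  expect_equal(sqrt(sum((tl[[1]]$coords[11, ] -
                           frames[[1]]$coords[11, ])^2)), 1)
})

test_that("RMSF difference is exactly shift-invariant and oracle-exact", {
  base <- synth_chain(50, seed = 8)
  fa <- synth_ensemble(12, base = base, thermal_sigma = 0.3, seed = 9,
                       max_rot_deg = 0)
  expect_equal(rmsf_baseline(fa, fa), rep(0, 50))
  shifted <- lapply(fa, function(fr) {
    fr$coords <- fr$coords + rep(c(5, -2, 1), each = 50)
    fr
  })
  expect_equal(rmsf_baseline(fa, shifted), rep(0, 50))

  fb <- synth_ensemble(12, base = base, thermal_sigma = 0.6, seed = 10,
                       max_rot_deg = 0)
  sc <- rmsf_baseline(fa, fb)
  ## brute-force per-atom recomputation
  for (atom in c(1, 25, 50)) {
    per_class <- function(frames) {
      xs <- t(vapply(frames, function(fr) fr$coords[atom, ], numeric(3)))
      sqrt(mean(rowSums(sweep(xs, 2, colMeans(xs))^2)))
    }
    expect_equal(sc[atom], abs(per_class(fa) - per_class(fb)),
                 tolerance = 1e-12)
  }
})

test_that("PCA baseline matches an independent SVD recomputation", {
  base <- synth_chain(50, seed = 11)
  fa <- synth_ensemble(15, base = base, thermal_sigma = 0.3, seed = 12)
  fb <- synth_ensemble(15, base = base, thermal_sigma = 0.3, seed = 13)
  expect_equal(pca_baseline(fa, fa), rep(0, 50))
  sc <- pca_baseline(fa, fb, n_components = 5)
  oracle <- function(frames, k) {
    M <- t(sapply(frames, function(fr) as.numeric(t(fr$coords))))
    M <- scale(M, scale = FALSE)
    sv <- svd(M)
    colSums(t(sv$v[, 1:k]) * sv$d[1:k])
  }
  dv <- oracle(fa, 5) - oracle(fb, 5)
  expect_equal(sc, sqrt(colSums(matrix(dv^2, 3))), tolerance = 1e-8)
  expect_warning(expect_warning(pca_baseline(fa, fb, n_components = 99),
                                "clipped"), "clipped")  # once per class
})

test_that("elastic net finds a hugely displaced atom and reports accuracy", {
  base <- synth_chain(50, seed = 14)
  fa <- synth_ensemble(30, base = base, thermal_sigma = 0.2, seed = 15,
                       max_rot_deg = 0)
  fb <- lapply(synth_ensemble(30, base = base, thermal_sigma = 0.2,
                              seed = 16, max_rot_deg = 0), function(fr) {
    fr$coords[7, ] <- fr$coords[7, ] + 25
    fr
  })
  sc <- elasticnet_baseline(fa, fb, seed = 17)
  expect_equal(which.max(sc), 7L)
  expect_equal(attr(sc, "validation_accuracy"), 1)
  ## identical classes: nothing separates, accuracy near chance
  sc0 <- elasticnet_baseline(fa, fa, seed = 18)
  expect_lt(attr(sc0, "validation_accuracy"), 0.9)
})

test_that("detection scores collapse correctly and match the literal sweep", {
  filt <- filtration_spec(6)
  dirs <- generate_cones(2, 2, 0.5, seed = 19)
  fr <- random_frame(12, box = 4, seed = 20)
  meshes <- normalize_meshes(list(build_mesh(fr, 2)))
  des <- build_design_matrix(meshes, dirs, filt)
  set.seed(21)
  gamma <- runif(ncol(des$X))
  sc <- detection_scores(des, gamma)
  map <- des$atom_feature_map[[1]]
  ## closed form by hand
  by_hand <- vapply(seq_len(12), function(a) {
    g <- gamma[map[a, ]]
    max(min(g[1:2]), min(g[3:4]))
  }, 0)
  expect_equal(sc, by_hand)
  ## thresholding the score reproduces the literal sweep at every level
  for (T_ in sort(unique(gamma[as.vector(map)]))) {
    expect_equal(sc >= T_, sweep_detected(map, gamma, dirs$cone_of, T_))
  }
  ## single cone degenerates to the plain min over its directions
  dirs1 <- generate_cones(1, 3, 0.5, seed = 22)
  des1 <- build_design_matrix(meshes, dirs1, filt)
  g1 <- runif(ncol(des1$X))
  m1 <- des1$atom_feature_map[[1]]
  expect_equal(detection_scores(des1, g1),
               apply(matrix(g1[m1], 12, 3), 1, min))
})

test_that("ROC/AUC matches the Mann-Whitney oracle and edge cases", {
  truth <- c(rep(TRUE, 4), rep(FALSE, 6))
  expect_equal(roc_auc(c(4, 3.5, 3, 2.9, 1, 1, 0.5, 0.2, 0.1, 0), truth)$auc,
               1)
  expect_equal(roc_auc(c(0, 0.1, 0.2, 0.3, 1, 2, 3, 4, 5, 6), truth)$auc, 0)
  expect_equal(roc_auc(rep(1, 10), truth)$auc, 0.5)
  set.seed(23)
  for (rep_ in 1:5) {
    sc <- sample(seq(0, 1, by = 0.05), 200, replace = TRUE)  # many ties
    tr <- runif(200) < 0.3
    if (!any(tr) || all(tr)) next
    r <- roc_auc(sc, tr)
    expect_equal(r$auc, mw_auc(sc, tr), tolerance = 1e-12)
    expect_true(all(diff(r$tpr) >= 0))
    expect_true(all(diff(r$fpr) >= 0))
  }
  skip_if_not_installed("pROC")
  sc <- runif(100); tr <- runif(100) < 0.4
  expect_equal(roc_auc(sc, tr)$auc,
               as.numeric(pROC::auc(pROC::roc(tr, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("a null benchmark run is seed-deterministic and near chance", {
  res1 <- run_benchmark(n_atoms = 80, n_frames = 10, magnitude = 1e-9,
                        mode = "spherical", roi = roi_spec(atoms = 31:40),
                        methods = c("rmsf", "pca"),
                        offsets = c(0, 0.1), seed = 24)
  res2 <- run_benchmark(n_atoms = 80, n_frames = 10, magnitude = 1e-9,
                        mode = "spherical", roi = roi_spec(atoms = 31:40),
                        methods = c("rmsf", "pca"),
                        offsets = c(0, 0.1), seed = 24)
  expect_identical(res1$auc, res2$auc)
  expect_true(all(abs(res1$auc - 0.5) < 0.35))   # no signal, noisy n=80
  expect_equal(nrow(res1), 2L)
})
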