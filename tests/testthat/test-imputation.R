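# Mirror-imaging and thin-plate-spline estimation of missing landmarks.

sym_config <- function(k = 18, seed = 1, cs = 10) {
  sch <- default_scheme(k)
  list(scheme = sch, X = make_template(k, sch, seed = seed, cs = cs))
}

test_that("midsagittal plane is exact on symmetric data and rotation-equivariant", {
  fx <- sym_config()
  set <- landmark_set(fx$X, "sym")
  pl <- fit_midsagittal_plane(set, fx$scheme)
  expect_equal(abs(pl$normal), c(0, 1, 0), tolerance = 1e-10)
  expect_equal(pl$offset, 0, tolerance = 1e-10)

  set.seed(21)
  for (i in 1:5) {
    R <- rand_rotation()
    plR <- fit_midsagittal_plane(landmark_set(fx$X %*% R, "rot"), fx$scheme)
    align <- abs(sum(plR$normal * drop(c(0, 1, 0) %*% R)))
    expect_equal(align, 1, tolerance = 1e-9)
  }
})

test_that("midsagittal plane is within 1 degree of truth under noise", {
  fx <- sym_config(cs = 10)
  set.seed(31)
  angles <- replicate(100, {
    pl <- fit_midsagittal_plane(
      landmark_set(fx$X + matrix(stats::rnorm(nrow(fx$X) * 3, sd = 0.01),
                                 ncol = 3), "noisy"), fx$scheme)
    acos(min(abs(pl$normal[2]), 1)) * 180 / pi
  })
  expect_lt(stats::median(angles), 1)
  expect_lt(mean(angles < 1), 1 + 1e-9)  # all angles finite
  expect_gt(mean(angles < 1), 0.95)
})

test_that("mirror imputation recovers deleted bilateral landmarks", {
  fx <- sym_config()
  sch <- fx$scheme
  # exact symmetry: deleted left landmark recovered exactly
  miss <- rep(FALSE, sch$k); miss[sch$paired[1, 1]] <- TRUE
  X <- fx$X; X[miss, ] <- NA
  out <- impute_mirror(landmark_set(X, "m1", missing = miss), sch)
  expect_false(any(out$missing))
  expect_equal(out$coords, fx$X, tolerance = 1e-10)
  expect_equal(attr(out, "imputed")$method, "mirror")

  # both sides missing: untouched, passed through for the TPS stage
  miss2 <- rep(FALSE, sch$k); miss2[sch$paired[2, ]] <- TRUE
  X2 <- fx$X; X2[miss2, ] <- NA
  out2 <- impute_mirror(landmark_set(X2, "m2", missing = miss2), sch)
  expect_identical(out2$missing, miss2)

  # asymmetric noise sigma = 0.5 mm: recovery error comparable to 2 sigma
  set.seed(41)
  fx2 <- sym_config(k = 18, cs = 150)
  sigma <- 0.5
  errs <- replicate(200, {
    Xn <- fx2$X + matrix(stats::rnorm(18 * 3, sd = sigma), ncol = 3)
    tgt <- fx2$scheme$paired[3, 1]
    truth <- Xn[tgt, ]
    Xn[tgt, ] <- NA
    miss <- rep(FALSE, 18); miss[tgt] <- TRUE
    out <- impute_mirror(landmark_set(Xn, "n", missing = miss), fx2$scheme)
    sqrt(sum((out$coords[tgt, ] - truth)^2))
  })
  expect_lt(mean(errs), 2.5 * sigma)
  expect_gt(mean(errs), 0.5 * sigma)
})

test_that("TPS interpolates exactly and is exact for affine maps", {
  set.seed(51)
  ref <- rand_config(10, scale = 5)
  # identity
  m <- fit_tps(ref, ref)
  expect_equal(m$bending_energy, 0, tolerance = 1e-8)
  expect_lt(max(abs(m$weights)), 1e-8)
  expect_equal(m$affine[, 1:3], diag(3), tolerance = 1e-8)
  # affine target: zero bending energy, affine recovered
  A <- matrix(stats::rnorm(9, sd = 0.5), 3, 3) + diag(3)
  b <- stats::rnorm(3)
  tgt <- ref %*% t(A) + rep(1, 10) %o% b
  m <- fit_tps(ref, tgt)
  expect_equal(m$bending_energy, 0, tolerance = 1e-7)
  expect_lt(max(abs(m$weights)), 1e-7)
  expect_equal(m$affine[, 1:3], A, tolerance = 1e-9)
  expect_equal(m$affine[, 4], b, tolerance = 1e-9)
  probe <- rand_config(6, 5)
  expect_equal(predict(m, probe), probe %*% t(A) + rep(1, 6) %o% b,
               tolerance = 1e-8)
  # interpolation property at constraint points
  tgt2 <- ref + rand_config(10, 0.3)
  m2 <- fit_tps(ref, tgt2)
  expect_lt(max(abs(predict(m2, ref) - tgt2)), 1e-8)
  expect_gte(m2$bending_energy, 0)
  # coincident reference points named in the error
  refdup <- ref; refdup[7, ] <- refdup[2, ]
  expect_error(fit_tps(refdup, tgt2), "coincident")
})

test_that("TPS bending energy is invariant to rigid motion of the target", {
  set.seed(52)
  ref <- rand_config(12, 5)
  tgt <- ref + rand_config(12, 0.4)
  be0 <- fit_tps(ref, tgt)$bending_energy
  for (i in 1:3) {
    be <- fit_tps(ref, apply_rigid(tgt, s = 1))$bending_energy
    expect_equal(be, be0, tolerance = 1e-6 * max(be0, 1))
  }
})

test_that("TPS imputation recovers deleted landmarks from a reference", {
  fx <- sym_config(k = 21, seed = 7, cs = 100)
  ref <- fx$X
  # specimen equal to reference: exact recovery of a midline landmark
  tgt_i <- fx$scheme$midline[2]
  miss <- rep(FALSE, 21); miss[tgt_i] <- TRUE
  X <- ref; X[tgt_i, ] <- NA
  out <- impute_tps(landmark_set(X, "t1", missing = miss), ref)
  expect_equal(out$coords, ref, tolerance = 1e-8)
  # affine deformation, 3 landmarks deleted: exact recovery
  set.seed(61)
  A <- diag(3) + matrix(stats::rnorm(9, sd = 0.2), 3, 3)
  spec <- ref %*% t(A) + rep(1, 21) %o% stats::rnorm(3, sd = 10)
  del <- c(2, 9, 15)
  X2 <- spec; X2[del, ] <- NA
  miss2 <- rep(FALSE, 21); miss2[del] <- TRUE
  out2 <- impute_tps(landmark_set(X2, "t2", missing = miss2), ref)
  expect_equal(out2$coords, spec, tolerance = 1e-7)
})

test_that("leave-one-landmark-out TPS error stays below the generating noise", {
  fx <- sym_config(k = 30, seed = 3, cs = 100)
  ref <- fx$X
  set.seed(71)
  # smooth nonlinear deformation (low-energy TPS warp) plus landmark noise
  ctrl <- rand_config(6, 60)
  warp <- fit_tps(ctrl, ctrl + rand_config(6, 4))
  sigma <- 0.8
  spec <- predict(warp, ref) + matrix(stats::rnorm(30 * 3, sd = sigma),
                                      ncol = 3)
  errs <- vapply(seq_len(30), function(j) {
    X <- spec; X[j, ] <- NA
    miss <- rep(FALSE, 30); miss[j] <- TRUE
    out <- impute_tps(landmark_set(X, "loo", missing = miss), ref)
    sqrt(sum((out$coords[j, ] - spec[j, ])^2))
  }, numeric(1))
  expect_lt(stats::median(errs), 2 * sigma)
})

test_that("the mirror-then-TPS orchestrator completes every specimen", {
  d <- synthetic_design(k = 21L, scheme = default_scheme(21L),
                        missing_rate = 0.08, seed = 5)
  sim <- simulate_dataset(d)
  n_missing_before <- sum(vapply(sim$sets, function(s) sum(s$missing),
                                 numeric(1)))
  expect_gt(n_missing_before, 0)
  out <- impute_missing(sim$sets, d$scheme)
  expect_true(all(!vapply(out, function(s) any(s$missing), logical(1))))
  prov <- imputation_provenance(out)
  expect_equal(nrow(prov), n_missing_before)
  expect_true(all(prov$method %in% c("mirror", "tps")))
  # imputed landmarks land near their generating positions
  errs <- unlist(lapply(out, function(s) {
    truth <- sim$truth$masked_coordinates[[s$specimen_id]]
    if (is.null(truth)) return(NULL)
    idx <- sort(attr(s, "imputed")$landmark)  # truth rows are in index order
    sqrt(rowSums((s$coords[idx, , drop = FALSE] - truth)^2))
  }))
  # generating noise: shape_noise_sd in Procrustes units at CS ~ 150 mm
  scale_mm <- exp(mean(d$group_size_means))
  expect_lt(stats::median(errs), 3 * d$shape_noise_sd * scale_mm)
})

test_that("intra-observer error matches the chi-distribution closed form", {
  fx <- sym_config(k = 12, cs = 150)
  reps <- lapply(1:4, function(r) landmark_set(fx$X, "s1"))
  res <- intra_observer_error(reps)
  expect_equal(res$per_landmark, rep(0, 12))
  expect_equal(res$grand_mean, 0)

  set.seed(81)
  r <- 6L; sigma <- 0.5
  reps <- unlist(lapply(1:10, function(sp) {
    lapply(1:r, function(j)
      landmark_set(fx$X + matrix(stats::rnorm(36, sd = sigma), ncol = 3),
                   paste0("sp", sp)))
  }), recursive = FALSE)
  res <- intra_observer_error(reps)
  # replicate deviation ~ N3(0, sigma^2 (1 - 1/r) I); E|.| = 2 sqrt(2/pi) s
  expected <- 2 * sqrt(2 / pi) * sigma * sqrt(1 - 1 / r)
  expect_equal(res$grand_mean, expected, tolerance = 0.08)

  # sigma tuned so the grand mean sits at the 0.8 mm repeatability scale
  sigma08 <- 0.8 / (2 * sqrt(2 / pi) * sqrt(1 - 1 / r))
  reps <- unlist(lapply(1:10, function(sp) {
    lapply(1:r, function(j)
      landmark_set(fx$X + matrix(stats::rnorm(36, sd = sigma08), ncol = 3),
                   paste0("sp", sp)))
  }), recursive = FALSE)
  expect_equal(intra_observer_error(reps)$grand_mean, 0.8, tolerance = 0.08)
  expect_error(intra_observer_error(list(landmark_set(fx$X, "x"))),
               "fewer than 2")
})
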