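## Synthetic landmark data with known ground truth: a bilaterally symmetric
## template, group-specific mean-shape displacements and size differences,
## symmetric individual variation, fluctuating asymmetry, digitization
## noise, random rigid motions and MCAR missingness capped below 20%.

#' A generic bilateral symmetry scheme for k landmarks
#'
#' Convenience constructor used by the simulator: roughly one third of the
#' landmarks are midline, the rest form left/right pairs. The conventional
#' cranial (k = 39) and mandibular (k = 33) schemes ship as editable YAML
#' files under \code{inst/extdata} (synthetic stand-ins: they carry the
#' counts and pairing structure, not real anatomical definitions).
#'
#' @param k landmark count.
#' @return a \code{symmetry_scheme} with midline landmarks first.
#' @export
default_scheme <- function(k) {
  n_pairs <- floor(k / 3)
  n_mid <- k - 2L * n_pairs
  symmetry_scheme(
    paired = cbind(n_mid + seq_len(n_pairs),
                   n_mid + n_pairs + seq_len(n_pairs)),
    midline = seq_len(n_mid), k = k)
}

## Evaluate and restore RNG state so generator calls are reproducible given
## their seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Symmetric template configuration
#'
#' Places midline landmarks on the y = 0 plane and pair landmarks mirrored
#' across it, all on a half-ellipsoid surface (a schematic vault, not real
#' anatomy), centered at the origin and scaled to a stated centroid size.
#' Deterministic given the seed; the output is exactly symmetric under the
#' scheme's reflection-relabel map.
#'
#' @param k landmark count.
#' @param scheme a \code{symmetry_scheme} partitioning \code{1:k}.
#' @param seed integer seed.
#' @param cs centroid size of the template, mm (default 150, cranial scale).
#' @return k x 3 configuration.
#' @export
make_template <- function(k, scheme = default_scheme(k), seed = 1L,
                          cs = 150) {
  stopifnot(scheme$k == k)
  with_seed(seed, {
    axes <- c(1, 0.8, 0.7)
    X <- matrix(0, k, 3)
    n_mid <- length(scheme$midline)
    # midline: arc in the xz-plane
    th <- seq(-0.45 * pi, 0.45 * pi, length.out = max(n_mid, 2L)) +
      stats::runif(max(n_mid, 2L), -0.03, 0.03)
    X[scheme$midline, ] <- cbind(axes[1] * sin(th[seq_len(n_mid)]), 0,
                                 axes[3] * cos(th[seq_len(n_mid)]))
    # right-side points on the y > 0 half-ellipsoid, mirrored to the left
    n_pairs <- nrow(scheme$paired)
    u <- stats::runif(n_pairs, -0.4 * pi, 0.4 * pi)
    v <- stats::runif(n_pairs, 0.15 * pi, 0.85 * pi)
    right <- cbind(axes[1] * cos(v),
                   axes[2] * sin(v) * abs(cos(u)),   # y > 0 half
                   axes[3] * sin(v) * sin(u))
    X[scheme$paired[, 2], ] <- right
    X[scheme$paired[, 1], ] <- right %*% diag(c(1, -1, 1))
    X <- center_config(X)
    # re-zero the midline y (centering preserves it; guard numerically)
    X[scheme$midline, 2] <- 0
    X * (cs / centroid_size(X))
  })
}

## Symmetric part of a tangent perturbation under the scheme, orthogonalized
## against translation and the template direction so that effects live in
## the symmetric tangent subspace and generating Mahalanobis distances stay
## available in closed form.
symmetrize_vector <- function(E, scheme, template_unit) {
  Es <- (E + reflect_relabel(E, scheme)) / 2
  Es <- center_config(Es)
  Es - sum(Es * template_unit) * template_unit
}

#' Specify a synthetic study design
#'
#' Defaults emulate the cranial sample structure of a five-horizon
#' Nile-valley study: group sizes 8/10/28/13/10 (Mesolithic, A-group,
#' C-group, Pharaonic, Meroitic), a strongly displaced Mesolithic mean
#' shape, a larger Mesolithic mean size, and digitization-scale noise of
#' about 0.8 mm mean landmark deviation at a 150 mm centroid size.
#'
#' @param k landmark count (default 39).
#' @param scheme \code{symmetry_scheme} (default \code{default_scheme(k)}).
#' @param n_per_group named integer vector of group sizes.
#' @param effect_sizes named per-group magnitudes of the mean-shape
#'   displacement, Procrustes units. Displacement directions are drawn
#'   deterministically from the seed, symmetrized and orthogonalized.
#' @param group_size_means named per-group mean log centroid size.
#' @param shape_noise_sd per-coordinate SD of symmetric individual shape
#'   variation, Procrustes units.
#' @param asymmetry_sd per-coordinate SD of fluctuating asymmetry,
#'   Procrustes units.
#' @param size_noise_sd SD of log centroid size within groups.
#' @param missing_rate per-landmark MCAR missingness probability, in
#'   [0, 0.2); specimens are redrawn until below the 20\% cap.
#' @param diet named per-group dietary labels.
#' @param seed integer seed; the design (template, effect directions) and
#'   the dataset drawn from it are both reproducible.
#' @return object of class \code{synthetic_design}.
#' @export
synthetic_design <- function(
    k = 39L, scheme = default_scheme(k),
    n_per_group = c(Mesolithic = 8L, `A-group` = 10L, `C-group` = 28L,
                    Pharaonic = 13L, Meroitic = 10L),
    effect_sizes = c(Mesolithic = 0.06, `A-group` = 0.012, `C-group` = 0.008,
                     Pharaonic = 0.012, Meroitic = 0.015),
    group_size_means = c(Mesolithic = log(158), `A-group` = log(150),
                         `C-group` = log(150), Pharaonic = log(149),
                         Meroitic = log(149)),
    shape_noise_sd = 0.01, asymmetry_sd = 0.004, size_noise_sd = 0.03,
    missing_rate = 0.05,
    diet = c(Mesolithic = "HG", `A-group` = "EF", `C-group` = "EF",
             Pharaonic = "F", Meroitic = "F"),
    seed = 1L) {
  stopifnot(scheme$k == k, missing_rate >= 0, missing_rate < 0.20,
            shape_noise_sd > 0)
  groups <- names(n_per_group)
  stopifnot(!is.null(groups), setequal(groups, names(effect_sizes)),
            setequal(groups, names(group_size_means)))
  template <- make_template(k, scheme, seed = seed)
  template_unit <- template / sqrt(sum(center_config(template)^2))
  effects <- with_seed(seed + 1L, {
    lapply(stats::setNames(groups, groups), function(g) {
      E <- symmetrize_vector(matrix(stats::rnorm(3L * k), k, 3),
                             scheme, template_unit)
      E * (effect_sizes[[g]] / sqrt(sum(E^2)))
    })
  })
  structure(list(k = k, scheme = scheme, n_per_group = n_per_group,
                 group_shape_effects = effects,
                 group_size_means = group_size_means,
                 shape_noise_sd = shape_noise_sd,
                 asymmetry_sd = asymmetry_sd, size_noise_sd = size_noise_sd,
                 missing_rate = missing_rate, diet = diet[groups],
                 template = template, seed = as.integer(seed)),
            class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf("synthetic_design: k = %d, %d groups, n = %s (seed %d)\n",
              x$k, length(x$n_per_group),
              paste(x$n_per_group, collapse = "/"), x$seed))
  cat(sprintf("  shape noise %.4g, asymmetry %.4g, size noise %.4g, missing %.0f%%\n",
              x$shape_noise_sd, x$asymmetry_sd, x$size_noise_sd,
              100 * x$missing_rate))
  invisible(x)
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generating (true) Mahalanobis distances of a design
#'
#' Under the generator the symmetric tangent perturbation is isotropic with
#' per-coordinate SD \code{shape_noise_sd}, so the Mahalanobis distance
#' between groups g and h is \code{||effect_g - effect_h|| /
#' shape_noise_sd}, available in closed form.
#'
#' @param design a \code{synthetic_design}.
#' @return symmetric matrix of generating distances.
#' @export
true_mahalanobis <- function(design) {
  groups <- names(design$n_per_group)
  g <- length(groups)
  D <- matrix(0, g, g, dimnames = list(groups, groups))
  for (i in seq_len(g - 1L)) for (j in (i + 1L):g) {
    d <- design$group_shape_effects[[i]] - design$group_shape_effects[[j]]
    D[i, j] <- D[j, i] <- sqrt(sum(d^2)) / design$shape_noise_sd
  }
  D
}

#' Simulate a landmark dataset from a design
#'
#' Each specimen is built as size x rotation(unit template + group effect +
#' symmetric noise + asymmetric noise) + translation, with log-normal size,
#' isotropic Gaussian tangent noise (symmetric component at
#' \code{shape_noise_sd}, asymmetric component at \code{asymmetry_sd} per
#' coordinate), a random rigid motion per specimen, and MCAR missingness
#' below the 20\% cap. Bit-reproducible given the design seed.
#'
#' @param design a \code{synthetic_design}.
#' @param seed optional seed overriding \code{design$seed + 2}.
#' @return list with \code{sets} (list of \code{landmark_set}) and
#'   \code{truth}: generating Mahalanobis distances, true group mean log
#'   sizes, true allometric slope (0), and per-specimen true coordinates of
#'   masked landmarks.
#' @export
simulate_dataset <- function(design, seed = NULL) {
  if (is.null(seed)) seed <- design$seed + 2L
  scheme <- design$scheme
  k <- design$k
  unit_template <- design$template / centroid_size(design$template)
  template_unit <- unit_template / sqrt(sum(center_config(unit_template)^2))
  with_seed(seed, {
    sets <- list()
    targets <- list()
    for (g in names(design$n_per_group)) {
      for (i in seq_len(design$n_per_group[[g]])) {
        # projecting an isotropic draw onto the symmetric (or asymmetric)
        # subspace keeps the per-direction SD, so the nominal SDs apply
        # directly within each subspace
        Es <- symmetrize_vector(
          matrix(stats::rnorm(3L * k, sd = design$shape_noise_sd), k, 3),
          scheme, template_unit)
        Ea <- matrix(stats::rnorm(3L * k, sd = design$asymmetry_sd), k, 3)
        Ea <- center_config((Ea - reflect_relabel(Ea, scheme)) / 2)
        shape <- unit_template + design$group_shape_effects[[g]] + Es + Ea
        cs_i <- exp(stats::rnorm(1, design$group_size_means[[g]],
                                 design$size_noise_sd))
        X <- cs_i * (shape %*% random_rotation())
        X <- sweep(X, 2L, stats::runif(3, -100, 100), `+`)
        repeat {
          miss <- stats::runif(k) < design$missing_rate
          if (mean(miss) < 0.20) break
        }
        id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", g), i)
        Xm <- X
        Xm[miss, ] <- NA_real_
        sets[[length(sets) + 1L]] <- landmark_set(
          Xm, specimen_id = id, missing = miss, group = g,
          diet = design$diet[[g]], sex = sample(c("m", "f"), 1))
        if (any(miss))
          targets[[id]] <- X[miss, , drop = FALSE]
      }
    }
    list(sets = sets,
         truth = list(mahalanobis = true_mahalanobis(design),
                      group_log_size_means = design$group_size_means,
                      allometric_slope = 0,
                      masked_coordinates = targets))
  })
}

#' Simulate a dataset with no group structure
#'
#' Zero shape effects and equal size means: group labels carry no
#' information. Used for type-I-error calibration of the group statistics.
#'
#' @param design a \code{synthetic_design}; effects and size differences
#'   are zeroed out.
#' @param seed optional seed passed to \code{\link{simulate_dataset}}.
#' @return as \code{\link{simulate_dataset}}.
#' @export
null_dataset <- function(design, seed = NULL) {
  design$group_shape_effects <- lapply(design$group_shape_effects,
                                       function(E) E * 0)
  design$group_size_means[] <- mean(design$group_size_means)
  simulate_dataset(design, seed = seed)
}
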