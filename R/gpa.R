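## Generalized Procrustes analysis with unit-centroid-size scaling, tangent
## projection, and the symmetric component of shape for object symmetry.

as_config_array <- function(configs) {
  if (is.array(configs) && length(dim(configs)) == 3L) {
    stopifnot(dim(configs)[2] == 3L)
    return(configs)
  }
  if (is.list(configs)) {
    configs <- lapply(configs, function(x)
      if (inherits(x, "landmark_set")) x$coords else as.matrix(x))
    ks <- vapply(configs, nrow, integer(1))
    if (length(unique(ks)) != 1L)
      stop("configurations have differing landmark counts")
    return(simplify2array(configs))
  }
  stop("configs must be a k x 3 x n array or a list of k x 3 matrices")
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks from
#' their centroid; the standard geometric measure of size, in the units of
#' the input coordinates (mm).
#'
#' @param config k x 3 coordinate matrix with no missing values.
#' @return positive scalar.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (anyNA(config)) stop("centroid size is undefined with missing landmarks")
  cs <- sqrt(sum(sweep(config, 2L, colMeans(config))^2))
  if (cs < .Machine$double.eps^0.5)
    stop("degenerate configuration: all landmarks coincide")
  cs
}

## Orthogonal Procrustes: the orthogonal matrix H with det(H) = det_sign
## minimizing ||source H - target||_F, via SVD with sign correction on the
## smallest singular value (deterministic tie-break).
orth_fit <- function(source, target, det_sign = 1) {
  sv <- svd(crossprod(source, target))
  H <- tcrossprod(sv$u, sv$v)
  if (sign(det(H)) != det_sign) {
    u <- sv$u
    u[, 3L] <- -u[, 3L]                 # flip the smallest singular axis
    H <- tcrossprod(u, sv$v)
  }
  H
}

#' Ordinary Procrustes rotation between two configurations
#'
#' Finds the rotation minimizing the Frobenius distance
#' \code{||source \%*\% rotation - target||}. Both configurations should be
#' centered (and for shape comparison, scaled to unit centroid size).
#' Reflections are excluded unless \code{allow_reflection = TRUE}; with a
#' rank-deficient cross-covariance the sign ambiguity is resolved by flipping
#' the axis with the smallest singular value.
#'
#' @param source,target k x 3 matrices.
#' @param allow_reflection permit improper rotations (default FALSE).
#' @return list with \code{rotation} (3 x 3) and \code{residual}, the
#'   minimized Frobenius distance.
#' @export
opa_fit <- function(source, target, allow_reflection = FALSE) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (allow_reflection) {
    sv <- svd(crossprod(source, target))
    R <- tcrossprod(sv$u, sv$v)
  } else {
    R <- orth_fit(source, target, det_sign = 1)
  }
  list(rotation = R, residual = sqrt(sum((source %*% R - target)^2)))
}

center_config <- function(X) sweep(X, 2L, colMeans(X))

## Deterministic canonical orientation: principal axes of the mean shape,
## signs fixed by third moments (skewness) along each axis, det +1. Makes
## GPA output invariant to rigid motion of the inputs and to input order.
canonical_rotation <- function(M) {
  V <- eigen(crossprod(M), symmetric = TRUE)$vectors
  if (det(V) < 0) V[, 3L] <- -V[, 3L]
  A <- M %*% V
  s <- numeric(2)
  for (j in 1:2) {
    m3 <- sum(A[, j]^3)
    s[j] <- if (abs(m3) > 1e-9) sign(m3)
            else sign(A[which.max(abs(A[, j])), j])
  }
  V %*% diag(c(s[1], s[2], s[1] * s[2]))
}

#' Generalized Procrustes analysis
#'
#' Translates each configuration to a common centroid, scales it to unit
#' centroid size, and iteratively rotates all configurations to the evolving
#' mean shape by least squares until the decrease in the total Procrustes sum
#' of squares falls below \code{tol}. Aligned shapes are then brought into a
#' deterministic canonical orientation and projected into the tangent space
#' at the mean.
#'
#' @param configs k x 3 x n array, or list of k x 3 matrices or
#'   \code{landmark_set}s (complete; run imputation first).
#' @param tol convergence tolerance on the decrease of the total Procrustes
#'   sum of squares.
#' @param max_iter maximum number of alignment sweeps.
#' @return object of class \code{gpa}: \code{aligned} (k x 3 x n),
#'   \code{mean_shape} (k x 3, unit centroid size), \code{centroid_sizes}
#'   (mm), \code{tangent} (n x 3k), \code{ss} (total Procrustes SS per
#'   iteration), \code{iterations}, \code{converged}.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 200L) {
  A <- as_config_array(configs)
  k <- dim(A)[1]; n <- dim(A)[3]
  if (n < 2L) stop("generalized Procrustes analysis needs at least 2 configurations")
  ids <- dimnames(A)[[3]]
  if (is.list(configs) && is.null(ids) &&
      all(vapply(configs, inherits, logical(1), "landmark_set")))
    ids <- vapply(configs, function(s) s$specimen_id, character(1))
  cs <- numeric(n)
  for (i in seq_len(n)) {
    X <- center_config(A[, , i])
    cs[i] <- centroid_size(A[, , i])
    A[, , i] <- X / cs[i]
  }
  mean_shape <- A[, , 1L]
  ss <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n))
      A[, , i] <- A[, , i] %*% orth_fit(A[, , i], mean_shape)
    mean_shape <- apply(A, c(1, 2), mean)
    mean_shape <- center_config(mean_shape)
    mean_shape <- mean_shape / sqrt(sum(mean_shape^2))
    ss_now <- sum(apply(A, 3L, function(X) sum((X - mean_shape)^2)))
    ss <- c(ss, ss_now)
    if (iter > 1L && (ss[iter - 1L] - ss_now) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  V <- canonical_rotation(mean_shape)
  mean_shape <- mean_shape %*% V
  for (i in seq_len(n)) A[, , i] <- A[, , i] %*% V
  dimnames(A)[[3]] <- ids
  res <- structure(list(aligned = A, mean_shape = mean_shape,
                        centroid_sizes = cs,
                        tangent = NULL, ss = ss, iterations = iter,
                        converged = converged),
                   class = "gpa")
  res$tangent <- tangent_project(A, mean_shape)
  rownames(res$tangent) <- ids
  res
}

#' @export
print.gpa <- function(x, ...) {
  d <- dim(x$aligned)
  cat(sprintf("gpa: %d configurations, %d landmarks; %d iterations (%s)\n",
              d[3], d[1], x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  total Procrustes SS: %.6g; centroid size %.1f-%.1f mm\n",
              x$ss[length(x$ss)], min(x$centroid_sizes),
              max(x$centroid_sizes)))
  invisible(x)
}

#' @export
summary.gpa <- function(object, ...) {
  print(object)
  cat(sprintf("  mean centroid size: %.2f mm (sd %.2f)\n",
              mean(object$centroid_sizes), stats::sd(object$centroid_sizes)))
  invisible(object)
}

## Flatten a k x 3 configuration row-major: (x1, y1, z1, x2, ...)
flatten_config <- function(X) as.vector(t(X))
unflatten_config <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' Project aligned shapes into the tangent space at the mean
#'
#' Orthogonal projection of each aligned shape vector onto the linear
#' subspace orthogonal to the mean-shape direction (the linearization of
#' shape space at the mean). The projection is idempotent.
#'
#' @param aligned k x 3 x n array of Procrustes-aligned shapes (or a
#'   \code{gpa} object).
#' @param mean_shape k x 3 mean shape; taken from the \code{gpa} object when
#'   one is supplied.
#' @return n x 3k matrix of tangent coordinates, row-major per landmark
#'   (x1, y1, z1, x2, ...).
#' @export
tangent_project <- function(aligned, mean_shape = NULL) {
  if (inherits(aligned, "gpa")) {
    mean_shape <- aligned$mean_shape
    aligned <- aligned$aligned
  }
  m <- flatten_config(mean_shape)
  m <- m / sqrt(sum(m^2))
  X <- t(apply(aligned, 3L, flatten_config))
  X - (X %*% m) %*% t(m)
}

## Reflect + relabel a configuration under a symmetry scheme: mirror in the
## xz-plane and swap the left/right labels. Any fixed reflection works here;
## the subsequent orthogonal alignment absorbs the choice.
reflect_relabel <- function(X, scheme) {
  Y <- X %*% diag(c(1, -1, 1))
  perm <- seq_len(nrow(X))
  perm[scheme$paired[, 1]] <- scheme$paired[, 2]
  perm[scheme$paired[, 2]] <- scheme$paired[, 1]
  Y[perm, , drop = FALSE]
}

#' Residual asymmetry of a configuration
#'
#' Frobenius distance between a configuration and its optimally aligned
#' reflected-relabeled copy; zero for an exactly symmetric object.
#'
#' @param X centered k x 3 configuration.
#' @param scheme a \code{symmetry_scheme}.
#' @return nonnegative scalar.
#' @export
asymmetry_residual <- function(X, scheme) {
  M <- reflect_relabel(X, scheme)
  H <- orth_fit(M, X, det_sign = 1)    # rotation only: exactly one reflection
  sqrt(sum((M %*% H - X)^2))
}

#' Symmetric component of Procrustes-aligned shapes
#'
#' For each specimen, the reflected and relabeled copy is superimposed onto
#' the original by least squares and the two are averaged, removing
#' asymmetric shape variation. The output is exactly symmetric under the
#' scheme's reflection-relabel map.
#'
#' @param aligned k x 3 x n array of aligned shapes, or a \code{gpa} object.
#' @param scheme a \code{symmetry_scheme} with the same k.
#' @return k x 3 x n array of symmetric shapes. Typically followed by a
#'   fresh \code{\link{gpa}} on the symmetric shapes.
#' @export
symmetrize <- function(aligned, scheme) {
  if (inherits(aligned, "gpa")) aligned <- aligned$aligned
  stopifnot(dim(aligned)[1] == scheme$k)
  out <- aligned
  for (i in seq_len(dim(aligned)[3])) {
    X <- aligned[, , i]
    M <- reflect_relabel(X, scheme)
    H <- orth_fit(M, X, det_sign = 1)
    out[, , i] <- (X + M %*% H) / 2
  }
  out
}
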