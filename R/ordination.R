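## Ordination of tangent-space shape coordinates: total-variance PCA,
## between-group PCA, axis-extreme shape reconstruction, and allometric
## regression of PC scores on centroid size.

new_shape_ordination <- function(scores, eigenvectors, eigenvalues,
                                 variance_fraction, kind, mean_vector,
                                 groups = NULL, extra = list()) {
  structure(c(list(scores = scores, eigenvectors = eigenvectors,
                   eigenvalues = eigenvalues,
                   variance_fraction = variance_fraction,
                   kind = kind, mean_vector = mean_vector, groups = groups),
              extra),
            class = "shape_ordination")
}

## Reproducible sign convention: the largest-magnitude loading of each
## eigenvector is made positive.
fix_eigen_signs <- function(vectors, scores) {
  for (j in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) {
      vectors[, j] <- -vectors[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(vectors = vectors, scores = scores)
}

#' Principal component analysis of shape coordinates
#'
#' Eigen-decomposition of the sample covariance of tangent coordinates
#' (total variance-covariance PCA). Scores are mean-centered projections.
#'
#' @param tangent n x 3k matrix of tangent coordinates (rows = specimens).
#' @return object of class \code{shape_ordination} with \code{kind =
#'   "total"}: \code{scores} (n x p), orthonormal \code{eigenvectors}
#'   (3k x p), \code{eigenvalues} (descending), \code{variance_fraction} and
#'   \code{mean_vector}.
#' @export
total_pca <- function(tangent) {
  tangent <- as.matrix(tangent)
  n <- nrow(tangent)
  if (n < 2L) stop("PCA needs at least 2 specimens")
  pc <- stats::prcomp(tangent, center = TRUE, scale. = FALSE)
  eigenvalues <- pc$sdev^2
  p <- min(n - 1L, ncol(tangent))
  eigenvalues <- eigenvalues[seq_len(p)]
  fx <- fix_eigen_signs(pc$rotation[, seq_len(p), drop = FALSE],
                        pc$x[, seq_len(p), drop = FALSE])
  new_shape_ordination(scores = fx$scores, eigenvectors = fx$vectors,
                       eigenvalues = eigenvalues,
                       variance_fraction = eigenvalues / sum(eigenvalues),
                       kind = "total", mean_vector = pc$center)
}

#' Retain leading components up to a cumulative variance threshold
#'
#' @param ord a \code{shape_ordination}.
#' @param threshold cumulative variance fraction in (0, 1]; the default 0.95
#'   retains the smallest q axes jointly accounting for 95\% of the
#'   variance.
#' @return n x q matrix of retained scores.
#' @export
retain_for_variance <- function(ord, threshold = 0.95) {
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  q <- which(cumsum(ord$variance_fraction) >= threshold - 1e-12)[1]
  if (is.na(q)) q <- length(ord$variance_fraction)
  ord$scores[, seq_len(q), drop = FALSE]
}

#' Between-group principal component analysis
#'
#' Ordination on the eigenvectors of the covariance matrix of group mean
#' shape vectors (by default weighted by group size), emphasizing among-group
#' differences. All specimens are projected onto these axes; at most g - 1
#' eigenvalues are nonzero for g groups.
#'
#' @param tangent n x 3k matrix of tangent coordinates.
#' @param groups group labels of length n.
#' @param weighted weight group means by group size (default TRUE); when
#'   FALSE all groups count equally.
#' @return a \code{shape_ordination} with \code{kind = "between_group"};
#'   \code{variance_fraction} is relative to the between-group variance and
#'   \code{total_variance_fraction} gives each axis' share of the total
#'   specimen variance.
#' @export
between_group_pca <- function(tangent, groups, weighted = TRUE) {
  tangent <- as.matrix(tangent)
  groups <- as.character(groups)
  if (length(groups) != nrow(tangent))
    stop("groups length must match rows of tangent")
  glev <- unique(groups)
  if (length(glev) < 2L) stop("need at least 2 groups")
  ng <- table(factor(groups, levels = glev))
  if (any(ng == 0L)) stop("empty group")
  means <- t(vapply(glev, function(g)
    colMeans(tangent[groups == g, , drop = FALSE]), numeric(ncol(tangent))))
  w <- if (weighted) as.numeric(ng) / nrow(tangent)
       else rep(1 / length(glev), length(glev))
  grand <- colSums(means * w)
  C <- sweep(means, 2L, grand) * sqrt(w)   # B = C'C is the weighted
  sv <- svd(C, nu = 0)                     # between-group covariance
  p <- min(length(glev) - 1L, ncol(sv$v), ncol(tangent))
  eigenvalues <- sv$d[seq_len(p)]^2
  vectors <- sv$v[, seq_len(p), drop = FALSE]
  scores <- sweep(tangent, 2L, grand) %*% vectors
  fx <- fix_eigen_signs(vectors, scores)
  total_var <- sum(apply(sweep(tangent, 2L, colMeans(tangent)), 2L,
                         function(x) sum(x^2))) / (nrow(tangent) - 1L)
  axis_var <- apply(fx$scores, 2L, stats::var)
  new_shape_ordination(scores = fx$scores, eigenvectors = fx$vectors,
                       eigenvalues = eigenvalues,
                       variance_fraction = eigenvalues / sum(eigenvalues),
                       kind = "between_group", mean_vector = grand,
                       groups = groups,
                       extra = list(group_means = means,
                                    total_variance_fraction =
                                      axis_var / total_var))
}

#' @export
print.shape_ordination <- function(x, ...) {
  cat(sprintf("shape_ordination (%s PCA): %d specimens, %d axes\n",
              x$kind, nrow(x$scores), length(x$eigenvalues)))
  vf <- utils::head(x$variance_fraction, 5)
  cat("  variance fraction:", paste(sprintf("%.1f%%", 100 * vf),
                                    collapse = " "), "\n")
  if (!is.null(x$total_variance_fraction))
    cat("  share of total variance:",
        paste(sprintf("%.1f%%", 100 * utils::head(
          x$total_variance_fraction, 5)), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.shape_ordination <- function(x, axes = c(1, 2), ...) {
  s <- x$scores[, axes, drop = FALSE]
  grp <- if (is.null(x$groups)) factor(rep(1, nrow(s))) else factor(x$groups)
  graphics::plot(s, col = as.integer(grp), pch = 19,
                 xlab = sprintf("axis %d (%.1f%%)", axes[1],
                                100 * x$variance_fraction[axes[1]]),
                 ylab = sprintf("axis %d (%.1f%%)", axes[2],
                                100 * x$variance_fraction[axes[2]]), ...)
  if (nlevels(grp) > 1L)
    graphics::legend("topright", legend = levels(grp), col =
                       seq_len(nlevels(grp)), pch = 19, cex = 0.8)
  invisible(x)
}

#' Reconstruct the configuration at a score along an ordination axis
#'
#' Linear shape model: mean vector plus \code{score} times the axis
#' eigenvector, folded back to a k x 3 configuration. Used to visualize
#' shape change along PCA or between-group PCA axes.
#'
#' @param ord a \code{shape_ordination}.
#' @param axis axis number.
#' @param score position along the axis (0 gives the mean shape).
#' @param k landmark count.
#' @return k x 3 configuration.
#' @export
shape_at_score <- function(ord, axis, score, k) {
  if (axis > ncol(ord$eigenvectors)) stop("axis out of range")
  v <- ord$mean_vector + score * ord$eigenvectors[, axis]
  if (length(v) != 3L * k) stop("k inconsistent with ordination dimension")
  unflatten_config(v)
}

#' Allometric regression of shape scores on centroid size
#'
#' Ordinary least squares of each retained PC score on centroid size
#' (optionally log centroid size), with a multivariate summary: the trace of
#' the predicted-score covariance over the trace of the total score
#' covariance.
#'
#' @param scores n x q matrix of PC scores.
#' @param centroid_sizes length-n centroid sizes (mm).
#' @param log_cs regress on log centroid size instead (default FALSE).
#' @return object of class \code{allometry}: per-axis data frame
#'   (slope, r_squared, p_value) and \code{multivariate_r_squared}.
#' @export
allometry_regression <- function(scores, centroid_sizes, log_cs = FALSE) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 3L) stop("need at least 3 specimens")
  if (length(centroid_sizes) != n)
    stop("centroid_sizes length must match scores")
  x <- if (log_cs) log(centroid_sizes) else centroid_sizes
  if (stats::var(x) < .Machine$double.eps)
    stop("centroid size has zero variance")
  per_axis <- do.call(rbind, lapply(seq_len(ncol(scores)), function(j) {
    fit <- stats::lm(scores[, j] ~ x)
    sm <- summary(fit)
    p <- if (nrow(sm$coefficients) > 1L) sm$coefficients[2L, 4L] else NA_real_
    data.frame(axis = j, slope = stats::coef(fit)[[2L]],
               r_squared = sm$r.squared, p_value = p)
  }))
  fitted <- cbind(1, x) %*% rbind(colMeans(scores) -
                                    per_axis$slope * mean(x),
                                  per_axis$slope)
  mv <- sum(apply(fitted, 2L, stats::var)) /
    sum(apply(scores, 2L, stats::var))
  structure(list(per_axis = per_axis, multivariate_r_squared = mv,
                 predictor = if (log_cs) "log(centroid size)"
                             else "centroid size"),
            class = "allometry")
}

#' @export
print.allometry <- function(x, ...) {
  cat(sprintf("allometry_regression on %s: multivariate R^2 = %.4f\n",
              x$predictor, x$multivariate_r_squared))
  print(utils::head(x$per_axis, 10), row.names = FALSE)
  invisible(x)
}
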