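## Group comparisons: one-way ANOVA and Tukey HSD on centroid size, MANOVA
## (Wilks' lambda) on retained PC scores with a trace-based effect size, and
## among-group Mahalanobis distances from the pooled within-group covariance.

check_groups <- function(groups, n, min_size = 2L) {
  groups <- factor(as.character(groups))
  if (length(groups) != n) stop("groups length mismatch")
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  small <- table(groups) < min_size
  if (any(small))
    stop("group(s) with fewer than ", min_size, " members: ",
         paste(names(small)[small], collapse = ", "))
  groups
}

#' One-way ANOVA of centroid size on group
#'
#' @param cs numeric vector of centroid sizes (mm).
#' @param groups group labels; every group needs at least 2 members.
#' @return list with \code{F}, \code{p}, \code{df} and the underlying
#'   \code{aov} fit.
#' @export
size_anova <- function(cs, groups) {
  g <- check_groups(groups, length(cs))
  fit <- stats::aov(cs ~ g)
  tab <- summary(fit)[[1]]
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df = c(tab$Df[1], tab$Df[2]), fit = fit)
}

#' Tukey honestly-significant-difference test on centroid size
#'
#' All pairwise group comparisons with studentized-range-adjusted p-values;
#' unbalanced designs are handled by the Tukey-Kramer procedure.
#'
#' @param cs numeric vector of centroid sizes (mm).
#' @param groups group labels.
#' @param conf_level confidence level of the intervals (default 0.95).
#' @return data frame with columns pair, diff, lwr, upr, p_adj.
#' @export
tukey_hsd <- function(cs, groups, conf_level = 0.95) {
  g <- check_groups(groups, length(cs))
  fit <- stats::aov(cs ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$g
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

group_scatter_matrices <- function(scores, groups) {
  grand <- colMeans(scores)
  Tm <- crossprod(sweep(scores, 2L, grand))
  W <- matrix(0, ncol(scores), ncol(scores))
  for (g in levels(groups)) {
    Xg <- scores[groups == g, , drop = FALSE]
    W <- W + crossprod(sweep(Xg, 2L, colMeans(Xg)))
  }
  list(total = Tm, within = W, between = Tm - W)
}

#' MANOVA on retained PC scores
#'
#' Tests for group differences in multivariate shape scores using Wilks'
#' lambda with Rao's F approximation, and reports an effect size: by default
#' the trace-based coefficient of determination trace(B)/trace(T), where B
#' and T are the between-group and total sums-of-squares-and-cross-products
#' matrices of the scores; \code{r2_method = "wilks"} reports 1 - lambda
#' instead. When the within-group degrees of freedom cannot support the
#' requested dimensionality (n - g <= q), the leading n - g - 1 score
#' columns are used with a warning.
#'
#' @param scores n x q matrix of PC scores.
#' @param groups group labels.
#' @param r2_method \code{"trace"} (default) or \code{"wilks"}.
#' @return object of class \code{shape_manova}: \code{wilks_lambda},
#'   \code{F_approx}, \code{df} (numerator, denominator), \code{p_value},
#'   \code{r_squared}, \code{q_used}.
#' @export
shape_manova <- function(scores, groups, r2_method = c("trace", "wilks")) {
  r2_method <- match.arg(r2_method)
  scores <- as.matrix(scores)
  g <- check_groups(groups, nrow(scores))
  n <- nrow(scores); ng <- nlevels(g)
  q <- ncol(scores)
  if (n - ng <= q) {
    q_new <- n - ng - 1L
    if (q_new < 1L) stop("too few specimens for any MANOVA dimension")
    warning("reducing score dimension from ", q, " to ", q_new,
            " so the within-group covariance is invertible")
    scores <- scores[, seq_len(q_new), drop = FALSE]
    q <- q_new
  }
  sc <- group_scatter_matrices(scores, g)
  if (q == 1L) {
    # univariate reduction: Wilks' lambda is SSW/SST and F is the ANOVA F
    lambda <- sc$within[1L, 1L] / sc$total[1L, 1L]
    df1 <- ng - 1L; df2 <- n - ng
    Fstat <- (1 - lambda) / lambda * df2 / df1
    sm <- matrix(c(lambda, Fstat, df1, df2,
                   stats::pf(Fstat, df1, df2, lower.tail = FALSE)),
                 nrow = 1,
                 dimnames = list(NULL, c("Wilks", "approx F", "num Df",
                                         "den Df", "Pr(>F)")))
  } else {
    fit <- stats::manova(scores ~ g)
    sm <- summary(fit, test = "Wilks")$stats
  }
  if (min(eigen(sc$within, symmetric = TRUE, only.values = TRUE)$values) <=
      .Machine$double.eps * q)
    stop("singular within-group covariance; retain fewer PCs")
  r2 <- switch(r2_method,
               trace = sum(diag(sc$between)) / sum(diag(sc$total)),
               wilks = 1 - sm[1L, "Wilks"])
  structure(list(wilks_lambda = unname(sm[1L, "Wilks"]),
                 F_approx = unname(sm[1L, "approx F"]),
                 df = unname(c(sm[1L, "num Df"], sm[1L, "den Df"])),
                 p_value = unname(sm[1L, "Pr(>F)"]),
                 r_squared = unname(r2),
                 r2_method = r2_method, q_used = q,
                 groups = levels(g)),
            class = "shape_manova")
}

#' @export
print.shape_manova <- function(x, ...) {
  cat(sprintf(
    "MANOVA (%d groups, %d dims): Wilks lambda = %.4f, F(%g, %g) = %.3f, p = %.4g\n",
    length(x$groups), x$q_used, x$wilks_lambda, x$df[1], x$df[2],
    x$F_approx, x$p_value))
  cat(sprintf("  R^2 (%s) = %.4f\n", x$r2_method, x$r_squared))
  invisible(x)
}

#' Among-group Mahalanobis distance matrix
#'
#' Distances between group mean score vectors standardized by the pooled
#' within-group covariance W (divisor n - g):
#' D(i, j) = sqrt((mi - mj)' W^-1 (mi - mj)). Reported unsquared.
#'
#' @param scores n x q matrix of PC scores.
#' @param groups group labels.
#' @return symmetric g x g matrix with zero diagonal and group labels as
#'   dimnames.
#' @export
mahalanobis_matrix <- function(scores, groups) {
  scores <- as.matrix(scores)
  g <- check_groups(groups, nrow(scores))
  n <- nrow(scores); ng <- nlevels(g); q <- ncol(scores)
  if (n - ng <= q)
    stop("pooled within-group covariance is singular (n - g <= q); ",
         "retain fewer PCs")
  sc <- group_scatter_matrices(scores, g)
  W <- sc$within / (n - ng)
  Winv <- tryCatch(solve(W), error = function(e)
    stop("pooled within-group covariance is singular; retain fewer PCs"))
  means <- do.call(rbind, lapply(levels(g), function(lev)
    colMeans(scores[g == lev, , drop = FALSE])))
  D <- matrix(0, ng, ng, dimnames = list(levels(g), levels(g)))
  for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
    d <- means[i, ] - means[j, ]
    D[i, j] <- D[j, i] <- sqrt(drop(t(d) %*% Winv %*% d))
  }
  D
}
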