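## Missing-landmark estimation: mirror-imaging across the midsagittal plane
## for bilateral landmarks whose antimere is present, then thin-plate-spline
## interpolation from a complete reference for everything else (midline
## landmarks and pairs missing on both sides).

#' Fit the midsagittal plane of a bilaterally symmetric configuration
#'
#' The plane is fitted by total least squares to the landmarks that must lie
#' on it: present midline landmarks and the midpoints of complete bilateral
#' pairs. When those constraint points do not span a plane (fewer than three,
#' or nearly collinear) the normal falls back to the principal axis of the
#' left-right difference vectors of complete pairs, which is parallel to the
#' plane normal for a symmetric configuration.
#'
#' @param set a \code{landmark_set}.
#' @param scheme a \code{symmetry_scheme} consistent with the set.
#' @return object of class \code{midsagittal_plane}: list with unit
#'   \code{normal} and scalar \code{offset}; the plane is
#'   \{x : normal . x = offset\}.
#' @export
fit_midsagittal_plane <- function(set, scheme) {
  stopifnot(inherits(scheme, "symmetry_scheme"))
  X <- set$coords
  miss <- set$missing
  mid_ok <- scheme$midline[!miss[scheme$midline]]
  pair_ok <- scheme$paired[!miss[scheme$paired[, 1]] &
                           !miss[scheme$paired[, 2]], , drop = FALSE]
  pts <- rbind(X[mid_ok, , drop = FALSE],
               if (nrow(pair_ok))
                 (X[pair_ok[, 1], , drop = FALSE] +
                  X[pair_ok[, 2], , drop = FALSE]) / 2)
  diffs <- if (nrow(pair_ok))
    X[pair_ok[, 2], , drop = FALSE] - X[pair_ok[, 1], , drop = FALSE]
  else matrix(0, 0, 3)
  if (length(mid_ok) < 3L && nrow(pair_ok) < 2L)
    stop("insufficient constraints to fit a midsagittal plane; ",
         "consider thin-plate-spline imputation instead")
  ctr <- colMeans(pts)
  S <- crossprod(sweep(pts, 2L, ctr))
  ev <- eigen(S, symmetric = TRUE)
  # plane is well determined by the points when their scatter has rank >= 2
  planar_ok <- nrow(pts) >= 3L && ev$values[2] > 1e-10 * max(ev$values[1], 1)
  if (planar_ok) {
    normal <- ev$vectors[, 3L]
  } else {
    dn <- diffs / sqrt(rowSums(diffs^2))
    normal <- eigen(crossprod(dn), symmetric = TRUE)$vectors[, 1L]
  }
  # deterministic sign: largest-magnitude component positive
  j <- which.max(abs(normal))
  if (normal[j] < 0) normal <- -normal
  normal <- normal / sqrt(sum(normal^2))
  structure(list(normal = normal, offset = sum(normal * ctr)),
            class = "midsagittal_plane")
}

#' @export
print.midsagittal_plane <- function(x, ...) {
  cat(sprintf("midsagittal_plane: normal (%.4f, %.4f, %.4f), offset %.4f\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

#' Reflect points across a plane
#' @param X n x 3 matrix of points.
#' @param plane a \code{midsagittal_plane}.
#' @return n x 3 matrix of reflected points.
#' @export
reflect_across_plane <- function(X, plane) {
  X <- rbind(X)
  d <- drop(X %*% plane$normal) - plane$offset
  X - 2 * outer(d, plane$normal)
}

#' Estimate missing bilateral landmarks by mirror-imaging
#'
#' Every missing bilateral landmark whose antimere is present is replaced by
#' the reflection of the antimere across the specimen's midsagittal plane.
#' Landmarks missing on both sides, and missing midline landmarks, are left
#' untouched (the thin-plate-spline stage handles them).
#'
#' @param set a \code{landmark_set}.
#' @param scheme a \code{symmetry_scheme}.
#' @param plane optional precomputed \code{midsagittal_plane}.
#' @return the \code{landmark_set} with recovered landmarks filled in and the
#'   mask updated; imputed landmark indices recorded in
#'   \code{attr(, "imputed")}.
#' @export
impute_mirror <- function(set, scheme, plane = NULL) {
  targets <- integer(0)
  sources <- integer(0)
  for (r in seq_len(nrow(scheme$paired))) {
    l <- scheme$paired[r, 1]; rr <- scheme$paired[r, 2]
    if (set$missing[l] && !set$missing[rr]) {
      targets <- c(targets, l); sources <- c(sources, rr)
    } else if (set$missing[rr] && !set$missing[l]) {
      targets <- c(targets, rr); sources <- c(sources, l)
    }
  }
  if (!length(targets)) return(set)
  if (is.null(plane)) plane <- fit_midsagittal_plane(set, scheme)
  set$coords[targets, ] <- reflect_across_plane(
    set$coords[sources, , drop = FALSE], plane)
  set$missing[targets] <- FALSE
  prov <- rbind(attr(set, "imputed"),
                data.frame(landmark = targets, method = "mirror",
                           stringsAsFactors = FALSE))
  attr(set, "imputed") <- prov
  set
}

## --- thin-plate spline (3D) -----------------------------------------------
## Kernel U(r) = -r: Euclidean distance is conditionally negative definite,
## so -r is conditionally positive definite on the subspace orthogonal to
## affine functions, making the bending energy w' K w nonnegative under the
## side conditions P'w = 0.

tps_kernel <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  -sqrt(pmax(d2, 0))
}

#' Fit a 3D thin-plate-spline interpolant
#'
#' Solves the TPS system mapping \code{reference} landmarks exactly onto
#' \code{target} landmarks while minimizing bending energy, with kernel
#' U(r) = -r and side conditions forcing the non-affine weights to be
#' orthogonal to \{1, x, y, z\} of the reference.
#'
#' @param reference m x 3 matrix of source landmarks (no duplicates).
#' @param target m x 3 matrix of corresponding destination landmarks.
#' @return object of class \code{tps_model} with fields
#'   \code{reference_points}, \code{affine} (3 x 4 matrix \code{[A | b]}),
#'   \code{weights} (m x 3) and \code{bending_energy}.
#' @export
fit_tps <- function(reference, target) {
  reference <- as.matrix(reference); target <- as.matrix(target)
  m <- nrow(reference)
  if (m < 5L) stop("need at least 5 landmarks to fit a 3D thin-plate spline")
  if (nrow(target) != m) stop("reference and target landmark counts differ")
  dd <- as.matrix(stats::dist(reference))
  dup <- which(dd < 1e-9 & upper.tri(dd), arr.ind = TRUE)
  if (nrow(dup))
    stop("coincident reference landmarks make the TPS system singular: ",
         paste(apply(dup, 1L, paste, collapse = "/"), collapse = ", "))
  K <- tps_kernel(reference, reference)
  P <- cbind(1, reference)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(target, matrix(0, 4, 3))
  sol <- solve(L, rhs)
  W <- sol[seq_len(m), , drop = FALSE]
  A <- sol[m + 1:4, , drop = FALSE]        # 4 x 3: rows = (1, x, y, z) coefs
  be <- sum(diag(t(W) %*% K %*% W))
  if (be < 0 && be > -1e-8) be <- 0
  structure(list(reference_points = reference,
                 affine = t(A)[, c(2:4, 1), drop = FALSE],  # 3 x 4 [A | b]
                 weights = W, bending_energy = be,
                 .coefs = sol),
            class = "tps_model")
}

#' Evaluate a fitted thin-plate spline at new points
#' @param object a \code{tps_model}.
#' @param newdata n x 3 matrix of points to map.
#' @param ... unused.
#' @return n x 3 matrix of mapped points.
#' @export
predict.tps_model <- function(object, newdata, ...) {
  newdata <- rbind(newdata)
  U <- tps_kernel(newdata, object$reference_points)
  cbind(U, 1, newdata) %*% object$.coefs
}

#' @export
print.tps_model <- function(x, ...) {
  cat(sprintf("tps_model: %d reference landmarks, bending energy %.3g\n",
              nrow(x$reference_points), x$bending_energy))
  invisible(x)
}

#' Estimate remaining missing landmarks by thin-plate-spline interpolation
#'
#' Fits a TPS from the present landmarks of a complete \code{reference}
#' configuration onto the specimen's present landmarks, and maps the
#' reference positions of the missing landmarks through it.
#'
#' @param set a \code{landmark_set} with at least 80\% of landmarks present.
#' @param reference complete k x 3 matrix (e.g. a Procrustes mean shape).
#' @return the completed \code{landmark_set}; imputed landmarks recorded in
#'   \code{attr(, "imputed")}.
#' @export
impute_tps <- function(set, reference) {
  reference <- as.matrix(reference)
  if (nrow(reference) != nrow(set$coords))
    stop("reference landmark count differs from specimen")
  if (anyNA(reference)) stop("reference must be complete")
  if (missing_fraction(set) > 0.20)
    stop("specimen has more than 20% missing landmarks")
  todo <- which(set$missing)
  if (!length(todo)) return(set)
  present <- which(!set$missing)
  model <- fit_tps(reference[present, , drop = FALSE],
                   set$coords[present, , drop = FALSE])
  set$coords[todo, ] <- predict(model, reference[todo, , drop = FALSE])
  set$missing[todo] <- FALSE
  prov <- rbind(attr(set, "imputed"),
                data.frame(landmark = todo, method = "tps",
                           stringsAsFactors = FALSE))
  attr(set, "imputed") <- prov
  set
}

#' Impute all missing landmarks across a sample
#'
#' Orchestrates the two estimation stages in order: mirror-imaging for
#' bilateral landmarks with a present antimere, then TPS interpolation for
#' midline landmarks and pairs missing on both sides. The TPS reference is
#' the Procrustes mean of fully complete specimens in the same group
#' (when at least \code{min_group_complete} are available) or of all
#' complete specimens otherwise; one single pass, no iteration.
#'
#' @param sets list of \code{landmark_set} objects with identical k.
#' @param scheme a \code{symmetry_scheme}.
#' @param min_group_complete minimum complete specimens per group before a
#'   group-specific reference is used (default 3).
#' @return list of completed \code{landmark_set} objects; per-specimen
#'   provenance retained in \code{attr(, "imputed")} of each element.
#' @export
impute_missing <- function(sets, scheme, min_group_complete = 3L) {
  sets <- lapply(sets, function(s) {
    if (any(s$missing)) impute_mirror(s, scheme) else s
  })
  still <- vapply(sets, function(s) any(s$missing), logical(1))
  if (!any(still)) return(sets)
  complete <- sets[!vapply(sets, function(s) any(s$missing), logical(1))]
  if (length(complete) < 2L)
    stop("fewer than 2 complete specimens available as TPS reference")
  groups <- vapply(complete, function(s) s$group, character(1))
  ref_for <- function(g) {
    pool <- complete[groups == g]
    if (length(pool) < min_group_complete) pool <- complete
    fit <- gpa(lapply(pool, function(s) s$coords))
    # rescale the unit-size mean back to the pool's average centroid size so
    # the reference lives at anatomical scale (TPS is scale-adaptive anyway)
    fit$mean_shape * mean(fit$centroid_sizes)
  }
  refs <- new.env()
  for (i in which(still)) {
    g <- sets[[i]]$group
    key <- if (is.na(g)) ".na" else g
    if (is.null(refs[[key]])) refs[[key]] <- ref_for(g)
    sets[[i]] <- impute_tps(sets[[i]], refs[[key]])
  }
  sets
}

#' Imputation provenance of a sample
#' @param sets list of \code{landmark_set} objects (after imputation).
#' @return data frame with columns specimen_id, landmark, method.
#' @export
imputation_provenance <- function(sets) {
  out <- lapply(sets, function(s) {
    p <- attr(s, "imputed")
    if (is.null(p)) return(NULL)
    cbind(specimen_id = s$specimen_id, p)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(specimen_id = character(0), landmark = integer(0),
                      method = character(0))
  out
}

#' Intra-observer landmarking error
#'
#' Given repeated digitizations of the same specimens, computes for each
#' landmark the mean Euclidean deviation of the replicates from the
#' specimen-wise replicate centroid, averaged over specimens, plus the grand
#' mean over landmarks (mm).
#'
#' @param repeats list of \code{landmark_set} replicates; replicates of the
#'   same specimen share \code{specimen_id}. At least 2 replicates per
#'   specimen, identical k throughout, no missing landmarks.
#' @return list with \code{per_landmark} (length-k mean deviations, mm) and
#'   \code{grand_mean}.
#' @export
intra_observer_error <- function(repeats) {
  ks <- vapply(repeats, function(s) nrow(s$coords), integer(1))
  if (length(unique(ks)) != 1L)
    stop("replicates have mismatched landmark counts")
  k <- ks[1]
  ids <- vapply(repeats, function(s) s$specimen_id, character(1))
  per_spec <- lapply(unique(ids), function(id) {
    reps <- repeats[ids == id]
    if (length(reps) < 2L)
      stop("specimen ", id, " has fewer than 2 replicates")
    arr <- simplify2array(lapply(reps, function(s) s$coords))  # k x 3 x r
    ctr <- apply(arr, c(1, 2), mean)
    devs <- apply(arr, 3L, function(X) sqrt(rowSums((X - ctr)^2)))
    rowMeans(devs)
  })
  per_landmark <- rowMeans(do.call(cbind, per_spec))
  list(per_landmark = per_landmark, grand_mean = mean(per_landmark))
}
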