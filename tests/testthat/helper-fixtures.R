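# Shared fixtures and independent oracles. Everything is generated in code;
# the only literal data are the published group distance matrices used as a
# fixed input for the tree module.

rand_config <- function(k, scale = 1) matrix(stats::rnorm(k * 3), k, 3) * scale

rand_rotation <- function() {
  qd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qd) %*% diag(sign(diag(qr.R(qd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(X, R = rand_rotation(), s = exp(stats::rnorm(1, 0, 0.3)),
                        t = stats::runif(3, -50, 50)) {
  sweep(s * X %*% R, 2L, t, `+`)
}

# Published among-group Mahalanobis distance matrices (cranium and mandible)
# used as a fixed 5-group input fixture for the tree module.
nubian_labels <- c("A-group", "C-group", "Meroitic", "Pharaonic", "Mesolithic")

cranial_distance_fixture <- function() {
  D <- matrix(0, 5, 5, dimnames = list(nubian_labels, nubian_labels))
  D["A-group", "C-group"] <- 2.942074
  D["A-group", "Meroitic"] <- 3.142982
  D["A-group", "Pharaonic"] <- 3.346135
  D["A-group", "Mesolithic"] <- 6.408830
  D["C-group", "Meroitic"] <- 2.477643
  D["C-group", "Pharaonic"] <- 3.060727
  D["C-group", "Mesolithic"] <- 6.016817
  D["Meroitic", "Pharaonic"] <- 2.922747
  D["Meroitic", "Mesolithic"] <- 5.738018
  D["Pharaonic", "Mesolithic"] <- 7.414554
  D + t(D)
}

mandibular_distance_fixture <- function() {
  D <- matrix(0, 5, 5, dimnames = list(nubian_labels, nubian_labels))
  D["C-group", "A-group"] <- 1.738055
  D["Meroitic", "A-group"] <- 2.519526
  D["Meroitic", "C-group"] <- 2.727493
  D["Pharaonic", "A-group"] <- 2.451742
  D["Pharaonic", "C-group"] <- 2.069805
  D["Pharaonic", "Meroitic"] <- 2.346177
  D["Mesolithic", "A-group"] <- 4.448209
  D["Mesolithic", "C-group"] <- 3.766902
  D["Mesolithic", "Meroitic"] <- 5.189174
  D["Mesolithic", "Pharaonic"] <- 4.030918
  D + t(D)
}

# Nonnegative least squares by exhaustive active-set enumeration: small
# enough here (7 edges) that trying every subset of zeroed coefficients is
# a fully independent oracle.
nnls_brute <- function(X, d) {
  p <- ncol(X)
  best <- NULL
  for (mask in 0:(2^p - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) == 0)
    if (!length(free)) next
    beta <- rep(0, p)
    b <- tryCatch(qr.solve(X[, free, drop = FALSE], d),
                  error = function(e) NULL)
    if (is.null(b) || any(b < -1e-12)) next
    beta[free] <- pmax(b, 0)
    rss <- sum((X %*% beta - d)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(beta = beta, rss = rss)
  }
  best
}

# Brute-force oracle for 5-taxon trees: enumerate all 15 unrooted binary
# topologies (two cherries + one middle taxon), fit the 7 edge lengths by
# nonnegative least squares on the 10 pairwise distances, and return the
# best-fitting tree with its terminal branch lengths and path metric.
enumerate_five_taxon_ls <- function(D) {
  labs <- rownames(D)
  stopifnot(length(labs) == 5L)
  pairs_of <- function(v) utils::combn(v, 2, simplify = FALSE)
  seen <- character(0)
  best <- NULL
  for (p1 in pairs_of(labs)) {
    rest <- setdiff(labs, p1)
    for (p2 in pairs_of(rest)) {
      e <- setdiff(rest, p2)
      key <- paste(sort(c(paste(sort(p1), collapse = ","),
                          paste(sort(p2), collapse = ","))), collapse = ";")
      if (key %in% seen) next
      seen <- c(seen, key)
      # edges: p1[1], p1[2], p2[1], p2[2], e (terminals), u-w, w-v (internal)
      edge_names <- c(p1, p2, e, "uw", "wv")
      side <- function(t) if (t %in% p1) "u" else if (t %in% p2) "v" else "w"
      path_edges <- function(x, y) {
        s <- sort(c(side(x), side(y)))
        inner <- if (identical(s, c("u", "v"))) c("uw", "wv")
                 else if (identical(s, c("u", "w"))) "uw"
                 else if (identical(s, c("v", "w"))) "wv"
                 else character(0)
        c(x, y, inner)
      }
      combs <- pairs_of(labs)
      X <- t(vapply(combs, function(pr) {
        as.numeric(edge_names %in% path_edges(pr[1], pr[2]))
      }, numeric(7)))
      d <- vapply(combs, function(pr) D[pr[1], pr[2]], numeric(1))
      fit <- nnls_brute(X, d)
      beta <- fit$beta
      rss <- fit$rss
      if (is.null(best) || rss < best$rss) {
        path <- matrix(0, 5, 5, dimnames = list(labs, labs))
        for (i in seq_along(combs))
          path[combs[[i]][1], combs[[i]][2]] <-
            path[combs[[i]][2], combs[[i]][1]] <- sum(beta * X[i, ])
        best <- list(cherries = list(sort(p1), sort(p2)), middle = e,
                     terminal = stats::setNames(beta[1:5], edge_names[1:5]),
                     internal = beta[6:7], rss = rss, path = path)
      }
    }
  }
  best
}

# Additive distance matrix from an ape tree (independent path-length oracle).
additive_matrix <- function(phy) ape::cophenetic.phylo(phy)
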