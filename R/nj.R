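## Neighbor-Joining from a group distance matrix, with specimen-level
## bootstrap supports. The agglomeration is written out here (Saitou-Nei
## Q-criterion, deterministic lexicographic tie-break, negative branch
## lengths reported as-is); ape supplies the phylo container and Newick
## round-trips.

fmt_len <- function(x) sprintf("%.15g", x)

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q-criterion. Ties in Q are broken by the
#' lexicographically smallest index pair, so the result is deterministic.
#' On an additive matrix the tree metric reproduces the input exactly.
#' Negative branch lengths arising from non-additive input are kept as-is
#' and flagged.
#'
#' @param D symmetric distance matrix with zero diagonal; dimnames provide
#'   leaf labels.
#' @param labels optional leaf labels overriding dimnames.
#' @return object of class \code{nj_tree}: \code{phylo} (ape tree),
#'   \code{newick}, \code{labels}, \code{negative_lengths} flag, and
#'   \code{supports} (NULL until \code{\link{bootstrap_supports}}).
#' @export
neighbor_joining <- function(D, labels = NULL) {
  D <- as.matrix(D)
  if (is.null(labels)) labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(D)))
  g <- nrow(D)
  if (g != ncol(D) || max(abs(D - t(D))) > 1e-8 || any(diag(D) != 0))
    stop("D must be a symmetric matrix with zero diagonal")
  if (any(D < 0)) stop("negative distances")
  if (g < 2L) stop("need at least 2 taxa")
  if (g == 2L) {
    warning("only 2 taxa: returning the single-edge tree")
    nwk <- sprintf("(%s:%s,%s:%s);", labels[1], fmt_len(D[1, 2] / 2),
                   labels[2], fmt_len(D[1, 2] / 2))
    return(as_nj_tree(nwk, labels))
  }
  nodes <- labels
  Dw <- D
  while (length(nodes) > 3L) {
    r <- length(nodes)
    Rs <- rowSums(Dw)
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(r - 1L)) for (j in (i + 1L):r) {
      q <- (r - 2) * Dw[i, j] - Rs[i] - Rs[j]
      if (q < bestq - 1e-12) {          # strict improvement keeps the
        bestq <- q; best <- c(i, j)     # lexicographically smallest pair
      }
    }
    i <- best[1]; j <- best[2]
    bi <- Dw[i, j] / 2 + (Rs[i] - Rs[j]) / (2 * (r - 2))
    bj <- Dw[i, j] - bi
    newlab <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt_len(bi),
                      nodes[j], fmt_len(bj))
    dnew <- (Dw[i, ] + Dw[j, ] - Dw[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    Dw <- rbind(cbind(Dw[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], newlab)
  }
  ba <- (Dw[1, 2] + Dw[1, 3] - Dw[2, 3]) / 2
  bb <- (Dw[1, 2] + Dw[2, 3] - Dw[1, 3]) / 2
  bc <- (Dw[1, 3] + Dw[2, 3] - Dw[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt_len(ba),
                 nodes[2], fmt_len(bb), nodes[3], fmt_len(bc))
  as_nj_tree(nwk, labels)
}

as_nj_tree <- function(newick, labels) {
  phy <- ape::read.tree(text = newick)
  structure(list(phylo = phy, newick = newick, labels = labels,
                 negative_lengths = any(phy$edge.length < 0),
                 supports = NULL),
            class = "nj_tree")
}

#' @export
print.nj_tree <- function(x, ...) {
  cat(sprintf("nj_tree: %d leaves%s\n", length(x$labels),
              if (x$negative_lengths) " (contains negative branch lengths)"
              else ""))
  cat(" ", to_newick(x, digits = 6), "\n")
  invisible(x)
}

#' @export
plot.nj_tree <- function(x, ...) {
  phy <- x$phylo
  if (!is.null(x$supports)) phy <- annotate_supports(x)$phylo
  ape::plot.phylo(ape::unroot(phy), type = "unrooted",
                  show.node.label = TRUE, ...)
  invisible(x)
}

tips_under <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_under, phy = phy))
}

## Canonical key of the bipartition induced by the edge above `node`:
## sorted labels of the side not containing the alphabetically first leaf.
bipartition_key <- function(side, all_labels) {
  first <- sort(all_labels)[1]
  if (first %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "|")
}

#' Internal-edge bipartitions of a tree
#' @param tree an \code{nj_tree} or ape \code{phylo}.
#' @return character vector of canonical bipartition keys (sorted leaf
#'   labels of one side, pipe-separated), one per internal edge.
#' @export
tree_bipartitions <- function(tree) {
  phy <- if (inherits(tree, "nj_tree")) tree$phylo else tree
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  internal_children <- setdiff(phy$edge[, 2][phy$edge[, 2] > ntip], root)
  vapply(internal_children, function(nd)
    bipartition_key(tips_under(phy, nd), phy$tip.label), character(1))
}

## Attach supports as internal-node labels for Newick export / plotting.
annotate_supports <- function(tree) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  labs <- rep("", nnode)
  for (nd in (ntip + 2L):(ntip + nnode)) {
    key <- bipartition_key(tips_under(phy, nd), phy$tip.label)
    if (key %in% names(tree$supports))
      labs[nd - ntip] <- as.character(round(tree$supports[[key]]))
  }
  phy$node.label <- labs
  tree$phylo <- phy
  tree
}

#' Newick serialization of an NJ tree
#'
#' Branch lengths are written in full precision by default; bootstrap
#' supports, when present, appear as internal-node labels (integer
#' percentages), never on terminal edges.
#'
#' @param tree an \code{nj_tree}.
#' @param file optional path; when given the string is also written there.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when writing to file.
#' @export
to_newick <- function(tree, file = NULL, digits = 15L) {
  phy <- if (is.null(tree$supports)) tree$phylo
         else annotate_supports(tree)$phylo
  s <- ape::write.tree(phy, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Path-length (cophenetic) distances of an NJ tree
#' @param tree an \code{nj_tree}.
#' @return symmetric matrix of leaf-to-leaf path lengths.
#' @export
tree_distances <- function(tree) {
  stats::cophenetic(tree$phylo)[tree$labels, tree$labels]
}

#' Bootstrap supports for an NJ tree by stratified specimen resampling
#'
#' Resamples specimens with replacement within each group, reruns the score
#' pipeline (total PCA, retention at the variance threshold, Mahalanobis
#' distances) and Neighbor-Joining per replicate, and scores each internal
#' edge of the observed tree by the percentage of replicate trees containing
#' the same leaf bipartition. GPA is treated as fixed preprocessing and not
#' rerun per replicate. Replicates with a singular within-group covariance
#' are skipped and counted; a warning is raised when more than 5\% are
#' skipped.
#'
#' @param tangent n x 3k tangent coordinates (post-GPA, post-symmetrization).
#' @param groups group labels of length n.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed integer seed making the supports reproducible.
#' @param variance_threshold cumulative variance retained per replicate
#'   (default 0.95).
#' @param resampler optional function(rep) returning a replicate distance
#'   matrix directly (used for diagnostics and testing); when supplied the
#'   tangent/groups resampling machinery is bypassed.
#' @param observed optional precomputed observed \code{nj_tree}.
#' @return the observed \code{nj_tree} with \code{supports} filled in
#'   (named percentage per internal-edge bipartition) plus
#'   \code{n_valid_replicates} and \code{n_skipped}.
#' @export
bootstrap_supports <- function(tangent, groups, n_reps = 1000L, seed = NULL,
                               variance_threshold = 0.95, resampler = NULL,
                               observed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dist_from_data <- function(tg, gr) {
    ord <- total_pca(tg)
    sc <- retain_for_variance(ord, variance_threshold)
    q_max <- length(gr) - length(unique(gr)) - 1L
    if (ncol(sc) > q_max) sc <- sc[, seq_len(q_max), drop = FALSE]
    mahalanobis_matrix(sc, gr)
  }
  if (is.null(observed)) {
    if (is.null(tangent)) stop("need tangent coordinates or an observed tree")
    observed <- neighbor_joining(dist_from_data(as.matrix(tangent),
                                                as.character(groups)))
  }
  obs_bip <- tree_bipartitions(observed)
  counts <- stats::setNames(numeric(length(obs_bip)), obs_bip)
  if (is.null(resampler)) {
    tangent <- as.matrix(tangent)
    groups <- as.character(groups)
    idx_by_group <- split(seq_along(groups), groups)
    resampler <- function(rep) {
      idx <- unlist(lapply(idx_by_group, function(ii)
        sample(ii, length(ii), replace = TRUE)), use.names = FALSE)
      dist_from_data(tangent[idx, , drop = FALSE], groups[idx])
    }
  }
  skipped <- 0L
  for (rep in seq_len(n_reps)) {
    Drep <- tryCatch(resampler(rep), error = function(e) NULL)
    if (is.null(Drep)) { skipped <- skipped + 1L; next }
    bip <- tree_bipartitions(neighbor_joining(Drep))
    hit <- obs_bip %in% bip
    counts[hit] <- counts[hit] + 1
  }
  valid <- n_reps - skipped
  if (valid < 1L) stop("all bootstrap replicates failed")
  if (skipped > 0.05 * n_reps)
    warning(skipped, " of ", n_reps, " bootstrap replicates skipped ",
            "(singular covariance)")
  observed$supports <- 100 * counts / valid
  observed$n_valid_replicates <- valid
  observed$n_skipped <- skipped
  observed
}
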