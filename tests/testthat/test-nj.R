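# Neighbor-Joining, Newick round-trips, bootstrap supports.

test_that("NJ recovers the generating 4-taxon tree exactly", {
  phy <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  D <- additive_matrix(phy)
  tree <- neighbor_joining(D)
  expect_setequal(tree_bipartitions(tree), tree_bipartitions(phy))
  expect_lt(max(abs(tree_distances(tree)[rownames(D), rownames(D)] - D)),
            1e-9)
})

test_that("3-taxon branch lengths follow the three-point formulas", {
  D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(D)
  pd <- tree_distances(tree)
  expect_equal(pd, D, tolerance = 1e-12)
  # three-point formulas: a = (dAB + dAC - dBC)/2 = 1, b = 2, c = 4
  expect_equal(sort(tree$phylo$edge.length), c(1, 2, 4), tolerance = 1e-12)
})

test_that("NJ is consistent on additive matrices up to 8 taxa", {
  set.seed(1)
  for (n in c(5, 6, 8)) for (rep in 1:5) {
    phy <- ape::rtree(n, rooted = FALSE)
    phy$edge.length <- stats::runif(length(phy$edge.length), 0.5, 3)
    D <- additive_matrix(phy)
    tree <- neighbor_joining(D)
    expect_setequal(tree_bipartitions(tree), tree_bipartitions(phy))
    expect_lt(max(abs(tree_distances(tree)[rownames(D), rownames(D)] - D)),
              1e-9)
  }
})

test_that("NJ agrees with the independent ape implementation", {
  set.seed(2)
  for (rep in 1:8) {
    n <- sample(4:9, 1)
    X <- matrix(stats::rnorm(n * 4), n, 4,
                dimnames = list(paste0("t", 1:n), NULL))
    D <- as.matrix(stats::dist(X))  # metric but generally non-additive
    mine <- neighbor_joining(D)
    theirs <- ape::nj(as.dist(D))
    expect_setequal(tree_bipartitions(mine), tree_bipartitions(theirs))
    expect_lt(max(abs(tree_distances(mine)[rownames(D), rownames(D)] -
                        ape::cophenetic.phylo(theirs)[rownames(D),
                                                      rownames(D)])), 1e-8)
  }
})

test_that("NJ is deterministic and equivariant under label permutation", {
  set.seed(3)
  X <- matrix(stats::rnorm(24), 6, 4, dimnames = list(LETTERS[1:6], NULL))
  D <- as.matrix(stats::dist(X))
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D)
  expect_identical(t1$newick, t2$newick)
  perm <- sample(6)
  t3 <- neighbor_joining(D[perm, perm])
  expect_setequal(tree_bipartitions(t3), tree_bipartitions(t1))
  expect_lt(max(abs(tree_distances(t3)[LETTERS[1:6], LETTERS[1:6]] -
                      tree_distances(t1)[LETTERS[1:6], LETTERS[1:6]])),
            1e-10)
  # exact ties resolved to the lexicographically smallest pair: on a star
  # matrix every Q is equal and the first pair is joined
  Ds <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(Ds) <- 0
  ts <- neighbor_joining(Ds)
  # joining (a, b) first induces the ab|cd split, canonically keyed "c|d"
  expect_identical(tree_bipartitions(ts), "c|d")
  expect_warning(neighbor_joining(matrix(c(0, 1, 1, 0), 2, 2,
                                         dimnames = list(c("x", "y"),
                                                         c("x", "y")))),
                 "2 taxa")
})

test_that("Newick output round-trips and carries supports only on internal edges", {
  set.seed(4)
  X <- matrix(stats::rnorm(35), 7, 5, dimnames = list(paste0("g", 1:7), NULL))
  D <- as.matrix(stats::dist(X))
  tree <- neighbor_joining(D)
  back <- ape::read.tree(text = to_newick(tree))
  expect_setequal(tree_bipartitions(back), tree_bipartitions(tree))
  expect_lt(max(abs(ape::cophenetic.phylo(back)[rownames(D), rownames(D)] -
                      tree_distances(tree)[rownames(D), rownames(D)])),
            1e-10)
  # with supports: internal-node labels only, tips unchanged
  tree$supports <- stats::setNames(rep(87, length(tree_bipartitions(tree))),
                                   tree_bipartitions(tree))
  s <- to_newick(tree)
  withsup <- ape::read.tree(text = s)
  expect_setequal(withsup$tip.label, rownames(D))
  expect_true(any(withsup$node.label == "87"))
  f <- withr::local_tempfile(fileext = ".nwk")
  to_newick(tree, file = f)
  expect_identical(readLines(f), s)
})

test_that("bootstrap supports saturate, reproduce, and collapse correctly", {
  set.seed(5)
  q <- 3
  mk_groups <- function(sep) {
    do.call(rbind, lapply(0:3, function(i)
      matrix(stats::rnorm(20 * q), 20, q) + i * sep))
  }
  g <- rep(paste0("grp", 1:4), each = 20)

  # degenerate resampler returning the same matrix: supports exactly 100
  X <- mk_groups(2)
  D <- mahalanobis_matrix(X, g)
  tree <- bootstrap_supports(resampler = function(i) D, n_reps = 50,
                             observed = neighbor_joining(D),
                             tangent = NULL, groups = NULL, seed = 1)
  expect_true(all(tree$supports == 100))

  # enormous separation: all supports 100 under real resampling
  Xs <- mk_groups(20)
  ts <- bootstrap_supports(Xs, g, n_reps = 100, seed = 2)
  expect_true(all(ts$supports == 100))

  # reproducible given seed
  t1 <- bootstrap_supports(X, g, n_reps = 100, seed = 7)
  t2 <- bootstrap_supports(X, g, n_reps = 100, seed = 7)
  expect_identical(t1$supports, t2$supports)

  # homogeneous cloud with arbitrary labels: weak internal support
  med <- stats::median(vapply(1:5, function(s) {
    X0 <- matrix(stats::rnorm(80 * q), 80, q)
    t0 <- bootstrap_supports(X0, g, n_reps = 60, seed = s)
    stats::median(t0$supports)
  }, numeric(1)))
  expect_lt(med, 70)
})

test_that("the published cranial matrix yields the expected tree structure", {
  D <- cranial_distance_fixture()
  tree <- neighbor_joining(D)
  phy <- tree$phylo
  term <- stats::setNames(
    phy$edge.length[match(seq_along(phy$tip.label), phy$edge[, 2])],
    phy$tip.label)
  expect_equal(names(which.max(term)), "Mesolithic")
  pd <- tree_distances(tree)
  farmers <- setdiff(nubian_labels, "Mesolithic")
  # A-group sits closest to C-group among all farmer groups, on the tree
  # metric as in the input matrix
  expect_equal(names(which.min(pd["A-group", setdiff(farmers, "A-group")])),
               "C-group")
  # brute-force nonnegative-least-squares enumeration of all 15 topologies
  # lands on the same topology and the same structural conclusions
  ls_best <- enumerate_five_taxon_ls(D)
  expect_setequal(tree_bipartitions(tree),
                  vapply(ls_best$cherries, function(ch)
                    skullmorph:::bipartition_key(ch, nubian_labels),
                    character(1)))
  expect_equal(names(which.max(ls_best$terminal)), "Mesolithic")
  expect_equal(names(which.min(ls_best$path["A-group",
                                            setdiff(farmers, "A-group")])),
               "C-group")

  # mandibular matrix: Mesolithic likewise carries the longest terminal
  Dm <- mandibular_distance_fixture()
  tm <- neighbor_joining(Dm)
  termm <- stats::setNames(
    tm$phylo$edge.length[match(seq_along(tm$phylo$tip.label),
                               tm$phylo$edge[, 2])],
    tm$phylo$tip.label)
  expect_equal(names(which.max(termm)), "Mesolithic")
})
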