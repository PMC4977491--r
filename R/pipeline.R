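## End-to-end orchestration: imputation -> missingness filter -> GPA ->
## symmetric component -> size statistics -> PCA / between-group PCA ->
## MANOVA rows over the grouping schemes -> Mahalanobis distances -> NJ with
## bootstrap supports -> allometric regression, with optional on-disk report
## bundle (TSV / Newick / TPS / JSON run log).

numeric_signature <- function(x) {
  v <- suppressWarnings(as.numeric(unlist(x)))
  v <- v[is.finite(v)]
  sprintf("%.10e", sum(v^2))
}

#' Read a pipeline configuration from YAML
#'
#' Recognized fields: \code{input} (TPS or CSV landmark file),
#' \code{scheme} (YAML symmetry scheme), \code{anatomical_unit},
#' \code{variance_threshold} (default 0.95), \code{bootstrap_reps}
#' (default 1000), \code{seed}, \code{exclude_group},
#' \code{output_dir}.
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("input", "scheme"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured ", f, " file does not exist: ", cfg[[f]])
  if (!is.null(cfg$variance_threshold) &&
      !(cfg$variance_threshold > 0 && cfg$variance_threshold <= 1))
    stop("variance_threshold must be in (0, 1]")
  if (!is.null(cfg$bootstrap_reps) && cfg$bootstrap_reps < 1)
    stop("bootstrap_reps must be >= 1")
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full shape-analysis pipeline
#'
#' Crania and mandibles are intended to be run as separate invocations;
#' nothing here ever merges anatomical units.
#'
#' @param sets list of \code{landmark_set} objects (or NULL when
#'   \code{config} supplies an input path).
#' @param scheme a \code{symmetry_scheme} (or NULL with \code{config}).
#' @param variance_threshold cumulative variance retained for MANOVA /
#'   Mahalanobis / allometry (default 0.95).
#' @param bootstrap_reps NJ bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param exclude_group group dropped in the sensitivity MANOVA row
#'   (default \code{"Mesolithic"} when present).
#' @param output_dir optional directory for the report bundle.
#' @param config optional list or YAML path; fields override the defaults
#'   above and may supply \code{input} / \code{scheme} paths.
#' @return object of class \code{pipeline_result} collecting every stage
#'   output.
#' @export
run_pipeline <- function(sets = NULL, scheme = NULL,
                         variance_threshold = 0.95, bootstrap_reps = 1000L,
                         seed = NULL, exclude_group = "Mesolithic",
                         output_dir = NULL, config = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(config)) {
    if (!is.null(config$input)) {
      sets <- if (grepl("\\.csv$", config$input, ignore.case = TRUE))
        read_landmark_csv(config$input) else read_tps(config$input)
    }
    if (!is.null(config$scheme)) scheme <- read_symmetry_scheme(config$scheme)
    if (!is.null(config$variance_threshold))
      variance_threshold <- config$variance_threshold
    if (!is.null(config$bootstrap_reps))
      bootstrap_reps <- config$bootstrap_reps
    if (!is.null(config$seed)) seed <- config$seed
    if (!is.null(config$exclude_group)) exclude_group <- config$exclude_group
    if (!is.null(config$output_dir)) output_dir <- config$output_dir
  }
  if (is.null(sets) || is.null(scheme))
    stop("need landmark sets and a symmetry scheme")

  orig_frac <- vapply(sets, missing_fraction, numeric(1))
  flt <- stage("filter", filter_missingness(sets))
  excluded <- flt$excluded
  sets <- stage("imputation", impute_missing(flt$kept, scheme))

  groups <- vapply(sets, function(s) s$group, character(1))
  diets <- vapply(sets, function(s) s$diet, character(1))

  fit0 <- stage("gpa", gpa(sets))
  sym <- stage("symmetrize", symmetrize(fit0, scheme))
  fit <- stage("gpa_symmetric", gpa(sym))
  fit$centroid_sizes <- fit0$centroid_sizes   # sizes are pre-scaling facts
  cs <- fit0$centroid_sizes

  anova_res <- stage("size_anova", size_anova(cs, groups))
  tukey_res <- stage("tukey_hsd", tukey_hsd(cs, groups))

  pca <- stage("total_pca", total_pca(fit$tangent))
  scores <- retain_for_variance(pca, variance_threshold)
  bg <- stage("between_group_pca", between_group_pca(fit$tangent, groups))

  manova_rows <- stage("manova", {
    rows <- list()
    add_row <- function(grouping, subset, keep, labels) {
      lev <- unique(labels[keep])
      if (length(lev) < 2L) return()
      q_max <- sum(keep) - length(lev) - 1L
      sc <- scores[keep, seq_len(min(ncol(scores), q_max)), drop = FALSE]
      m <- shape_manova(sc, labels[keep])
      rows[[length(rows) + 1L]] <<- data.frame(
        grouping = grouping, subset = subset, n = sum(keep),
        q = m$q_used, wilks_lambda = m$wilks_lambda, F = m$F_approx,
        r_squared = m$r_squared, p_value = m$p_value,
        stringsAsFactors = FALSE)
    }
    all <- rep(TRUE, length(groups))
    add_row("cultural", "all samples", all, groups)
    if (exclude_group %in% groups)
      add_row("cultural", paste("without", exclude_group),
              groups != exclude_group, groups)
    if (!all(is.na(diets)) && length(unique(stats::na.omit(diets))) >= 2L) {
      add_row("dietary", "all groups (HG, EF, F)", all, diets)
      combined <- ifelse(diets == "HG", "HG", "F")
      add_row("dietary", "farmers combined (HG, F)", all, combined)
      add_row("dietary", "without HG sample (EF, F)", diets != "HG", diets)
    }
    do.call(rbind, rows)
  })

  D <- stage("mahalanobis", {
    q_max <- length(groups) - length(unique(groups)) - 1L
    sc <- scores[, seq_len(min(ncol(scores), q_max)), drop = FALSE]
    mahalanobis_matrix(sc, groups)
  })

  tree <- stage("nj_bootstrap", {
    obs <- neighbor_joining(D)
    if (bootstrap_reps >= 1L)
      bootstrap_supports(fit$tangent, groups, n_reps = bootstrap_reps,
                         seed = seed,
                         variance_threshold = variance_threshold,
                         observed = obs)
    else obs
  })

  allom <- stage("allometry", allometry_regression(scores, cs))

  res <- structure(list(
    n = length(sets), excluded = excluded, sets = sets,
    groups = groups, diets = diets, centroid_sizes = cs,
    gpa = fit, pca = pca, scores = scores, bgpca = bg,
    size_anova = anova_res, tukey = tukey_res, manova = manova_rows,
    mahalanobis = D, tree = tree, allometry = allom,
    variance_threshold = variance_threshold,
    bootstrap_reps = bootstrap_reps, seed = seed),
    class = "pipeline_result")
  if (!is.null(output_dir)) write_report_bundle(res, output_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d specimens (%d excluded for missingness), %d groups\n",
              x$n, length(x$excluded), length(unique(x$groups))))
  cat(sprintf("  size ANOVA: F = %.3f, p = %.4g\n", x$size_anova$F,
              x$size_anova$p))
  cat(sprintf("  PCs retained at %.0f%% variance: %d\n",
              100 * x$variance_threshold, ncol(x$scores)))
  cat(sprintf("  bgPC1: %.1f%% of between-group, %.1f%% of total variance\n",
              100 * x$bgpca$variance_fraction[1],
              100 * x$bgpca$total_variance_fraction[1]))
  cat("  MANOVA:\n")
  print(x$manova[, c("grouping", "subset", "r_squared", "p_value")],
        row.names = FALSE)
  cat("  Mahalanobis distances:\n")
  print(round(x$mahalanobis, 3))
  cat("  NJ tree:", to_newick(x$tree, digits = 4), "\n")
  cat(sprintf("  allometry: multivariate R^2 = %.4f\n",
              x$allometry$multivariate_r_squared))
  invisible(x)
}

#' Write the pipeline report bundle to a directory
#'
#' Emits TSV tables (Mahalanobis matrix, MANOVA rows, Tukey HSD, PC scores,
#' eigenvalues, allometry), the bootstrapped Newick tree, the mean shape as
#' TPS, aligned coordinates as CSV, and a machine-readable JSON run log with
#' seed, package version and per-stage numeric checksums.
#'
#' @param res a \code{pipeline_result}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report_bundle <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$mahalanobis, file.path(dir, "mahalanobis.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(res$manova, file.path(dir, "manova.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$tukey, file.path(dir, "tukey_hsd.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$allometry$per_axis,
                     file.path(dir, "allometry.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sc <- data.frame(specimen_id = vapply(res$sets, `[[`, "", "specimen_id"),
                   group = res$groups, diet = res$diets,
                   centroid_size = res$centroid_sizes,
                   res$scores, check.names = FALSE)
  utils::write.table(sc, file.path(dir, "pc_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bg <- data.frame(axis1 = res$bgpca$scores[, 1],
                   axis2 = res$bgpca$scores[, min(2, ncol(res$bgpca$scores))],
                   group = res$groups)
  utils::write.table(bg, file.path(dir, "bgpca_scatter.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(axis = seq_along(res$pca$eigenvalues),
               eigenvalue = res$pca$eigenvalues,
               variance_fraction = res$pca$variance_fraction),
    file.path(dir, "eigenvalues.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  to_newick(res$tree, file = file.path(dir, "nj_tree.nwk"))
  write_tps(list(landmark_set(res$gpa$mean_shape,
                              specimen_id = "mean_shape")),
            file.path(dir, "mean_shape.tps"))
  aligned_sets <- lapply(seq_len(res$n), function(i)
    landmark_set(res$gpa$aligned[, , i],
                 specimen_id = res$sets[[i]]$specimen_id,
                 group = res$groups[i], diet = res$diets[i]))
  write_landmark_csv(aligned_sets, file.path(dir, "aligned.csv"))
  log <- list(
    package = "skullmorph",
    version = as.character(utils::packageVersion("skullmorph")),
    seed = res$seed, n = res$n,
    n_excluded = length(res$excluded),
    variance_threshold = res$variance_threshold,
    bootstrap_reps = res$bootstrap_reps,
    retained_pcs = ncol(res$scores),
    stage_checksums = list(
      gpa = numeric_signature(res$gpa$tangent),
      scores = numeric_signature(res$scores),
      mahalanobis = numeric_signature(res$mahalanobis),
      manova = numeric_signature(res$manova$r_squared),
      tree = numeric_signature(res$tree$phylo$edge.length)))
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
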