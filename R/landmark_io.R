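#' Construct a landmark set
#'
#' A landmark set holds one specimen's 3D landmark configuration together
#' with a missingness mask and archaeological metadata. Coordinates are in
#' millimetres throughout; no unit conversion is attempted anywhere in the
#' package.
#'
#' @param coords numeric k x 3 matrix of landmark coordinates (mm). Rows
#'   flagged missing may contain \code{NA}.
#' @param specimen_id character scalar identifying the specimen.
#' @param missing logical vector of length k; \code{TRUE} marks a landmark
#'   whose coordinates are unknown. Defaults to rows containing \code{NA}.
#' @param anatomical_unit \code{"cranium"}, \code{"mandible"}, or \code{NA}
#'   for generic configurations. When set, the conventional landmark counts
#'   (39 for crania, 33 for mandibles) are checked unless \code{strict_k}
#'   is \code{FALSE}.
#' @param group group label (e.g. a cultural horizon such as
#'   \code{"Mesolithic"}); any character label is accepted.
#' @param diet dietary group: \code{"HG"} (hunter-gatherers), \code{"EF"}
#'   (early farmers), \code{"F"} (farmers), or \code{NA}.
#' @param sex \code{"m"}, \code{"f"} or \code{"u"} (unknown).
#' @param strict_k enforce k = 39/33 when \code{anatomical_unit} is set.
#' @return an object of class \code{landmark_set}.
#' @export
landmark_set <- function(coords, specimen_id = "specimen", missing = NULL,
                         anatomical_unit = NA_character_, group = NA_character_,
                         diet = NA_character_, sex = "u", strict_k = FALSE) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must be a k x 3 matrix")
  storage.mode(coords) <- "double"
  k <- nrow(coords)
  if (is.null(missing)) missing <- apply(coords, 1L, function(r) anyNA(r))
  missing <- as.logical(missing)
  if (length(missing) != k)
    stop("missing mask length must equal number of landmarks")
  if (any(!is.finite(coords[!missing, , drop = FALSE])))
    stop("non-missing coordinates must be finite (specimen ", specimen_id, ")")
  if (!is.na(anatomical_unit)) {
    anatomical_unit <- match.arg(anatomical_unit, c("cranium", "mandible"))
    expected <- c(cranium = 39L, mandible = 33L)[[anatomical_unit]]
    if (strict_k && k != expected)
      stop(anatomical_unit, " configurations use ", expected,
           " landmarks, got ", k)
  }
  if (!is.na(sex)) sex <- match.arg(sex, c("m", "f", "u"))
  structure(list(specimen_id = as.character(specimen_id),
                 anatomical_unit = anatomical_unit,
                 group = as.character(group), diet = as.character(diet),
                 sex = sex, coords = coords, missing = missing),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  k <- nrow(x$coords)
  cat(sprintf("landmark_set '%s': %d landmarks (%d missing)%s\n",
              x$specimen_id, k, sum(x$missing),
              if (!is.na(x$anatomical_unit)) paste0(", ", x$anatomical_unit)
              else ""))
  cat(sprintf("  group: %s  diet: %s  sex: %s\n", x$group, x$diet, x$sex))
  invisible(x)
}

#' Fraction of missing landmarks
#' @param set a \code{landmark_set}.
#' @return scalar in [0, 1].
#' @export
missing_fraction <- function(set) mean(set$missing)

#' Define a bilateral symmetry scheme
#'
#' Partitions the landmarks of a bilaterally symmetric structure into
#' left/right pairs and midline (midsagittal) landmarks. Indices are 1-based,
#' following R convention; scheme files on disk also use 1-based indices.
#'
#' @param paired integer matrix or two-column structure of (left, right)
#'   landmark index pairs.
#' @param midline integer vector of midline landmark indices.
#' @param k total landmark count; paired and midline indices must partition
#'   \code{1:k} with no overlap.
#' @return an object of class \code{symmetry_scheme}.
#' @export
symmetry_scheme <- function(paired, midline, k) {
  paired <- matrix(as.integer(paired), ncol = 2L,
                   dimnames = list(NULL, c("left", "right")))
  midline <- as.integer(midline)
  all_idx <- c(paired, midline)
  if (length(all_idx) != k || anyDuplicated(all_idx) ||
      !setequal(all_idx, seq_len(k)))
    stop("paired and midline indices must partition 1:", k,
         " with no index used twice")
  structure(list(paired = paired, midline = midline, k = as.integer(k)),
            class = "symmetry_scheme")
}

#' @export
print.symmetry_scheme <- function(x, ...) {
  cat(sprintf("symmetry_scheme: %d landmarks = %d bilateral pairs + %d midline\n",
              x$k, nrow(x$paired), length(x$midline)))
  invisible(x)
}

#' Read a symmetry scheme from a YAML file
#'
#' The file lists \code{paired} as a sequence of two-element (left, right)
#' index pairs and \code{midline} as a sequence of indices, all 1-based.
#'
#' @param path path to a YAML scheme file.
#' @return a \code{symmetry_scheme}.
#' @export
read_symmetry_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$paired) || is.null(y$midline))
    stop("scheme file must contain 'paired' and 'midline' entries: ", path)
  paired <- do.call(rbind, lapply(y$paired, as.integer))
  midline <- as.integer(unlist(y$midline))
  symmetry_scheme(paired, midline, k = 2L * nrow(paired) + length(midline))
}

#' Write a symmetry scheme to YAML
#' @param scheme a \code{symmetry_scheme}.
#' @param path output path.
#' @export
write_symmetry_scheme <- function(scheme, path) {
  yaml::write_yaml(list(
    paired = lapply(seq_len(nrow(scheme$paired)),
                    function(i) as.integer(scheme$paired[i, ])),
    midline = as.integer(scheme$midline)), path)
  invisible(path)
}

## TPS landmark file dialect: blocks of "LM3=<k>" followed by k coordinate
## lines, an optional "ID=<name>" line per block. Missing landmarks are
## written as "NA NA NA"; the -9999 sentinel is also accepted on read.

#' Read a TPS landmark file
#'
#' Parses the common TPS dialect for 3D data: each specimen is a block
#' starting with \code{LM3=k}, followed by k lines of three
#' whitespace-separated coordinates, optionally followed by \code{ID=name}.
#' Landmarks whose line is \code{NA NA NA} (or all -9999) are flagged
#' missing.
#'
#' @param path path to a TPS file.
#' @return a list of \code{landmark_set} objects.
#' @export
read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sets <- list()
  i <- 1L
  block <- 0L
  while (i <= length(lines)) {
    if (!grepl("^LM3=", lines[i], ignore.case = TRUE))
      stop("expected LM3= record at line ", i, " of ", path)
    block <- block + 1L
    k <- as.integer(sub("^LM3=", "", lines[i], ignore.case = TRUE))
    if (is.na(k) || k < 1L)
      stop("malformed LM3= count in block ", block, " of ", path)
    i <- i + 1L
    coord_lines <- character(0)
    while (i <= length(lines) && length(coord_lines) < k &&
           !grepl("^(LM3|ID)=", lines[i], ignore.case = TRUE)) {
      coord_lines <- c(coord_lines, lines[i])
      i <- i + 1L
    }
    if (length(coord_lines) != k)
      stop("block ", block, " of ", path, ": LM3=", k, " but read ",
           length(coord_lines), " coordinate lines")
    coords <- t(vapply(coord_lines, function(l) {
      toks <- strsplit(l, "[[:space:]]+")[[1]]
      if (length(toks) != 3L)
        stop("block ", block, " of ", path,
             ": coordinate line does not have 3 fields: '", l, "'")
      suppressWarnings(as.numeric(toks))
    }, numeric(3), USE.NAMES = FALSE))
    id <- paste0("specimen_", block)
    if (i <= length(lines) && grepl("^ID=", lines[i], ignore.case = TRUE)) {
      id <- sub("^ID=", "", lines[i], ignore.case = TRUE)
      i <- i + 1L
    }
    miss <- apply(coords, 1L, function(r) anyNA(r) || all(r == -9999))
    coords[miss, ] <- NA_real_
    sets[[length(sets) + 1L]] <- landmark_set(coords, specimen_id = id,
                                              missing = miss)
  }
  sets
}

#' Write landmark sets to a TPS file
#' @param sets a \code{landmark_set} or list of them.
#' @param path output path.
#' @param digits significant digits written (default keeps full double
#'   precision so read/write round-trips are exact to 1e-12).
#' @export
write_tps <- function(sets, path, digits = 17L) {
  if (inherits(sets, "landmark_set")) sets <- list(sets)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in sets) {
    writeLines(paste0("LM3=", nrow(s$coords)), con)
    for (j in seq_len(nrow(s$coords))) {
      if (s$missing[j]) writeLines("NA NA NA", con)
      else writeLines(paste(formatC(s$coords[j, ], format = "g",
                                    digits = digits), collapse = " "), con)
    }
    writeLines(paste0("ID=", s$specimen_id), con)
  }
  invisible(path)
}

#' Read landmark sets from a wide CSV table
#'
#' Expected header: \code{specimen_id, group, diet, sex, x1, y1, z1, ...,
#' xk, yk, zk}. Empty coordinate cells mark missing landmarks. The
#' \code{anatomical_unit} column is optional.
#'
#' @param path path to a CSV file.
#' @param known_groups character vector of recognized group labels; rows
#'   with other labels are kept with a warning.
#' @return list of \code{landmark_set} objects.
#' @export
read_landmark_csv <- function(path,
                              known_groups = c("Mesolithic", "A-group",
                                               "C-group", "Pharaonic",
                                               "Meroitic")) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  meta_cols <- intersect(c("specimen_id", "anatomical_unit", "group",
                           "diet", "sex"), names(df))
  coord_cols <- setdiff(names(df), meta_cols)
  if (length(coord_cols) %% 3L != 0L)
    stop("coordinate columns are not a multiple of 3 in ", path)
  k <- length(coord_cols) %/% 3L
  unknown <- setdiff(unique(stats::na.omit(df$group)), known_groups)
  if (length(unknown))
    warning("unknown group label(s) kept as free labels: ",
            paste(unknown, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    xyz <- suppressWarnings(as.numeric(df[i, coord_cols]))
    coords <- matrix(xyz, ncol = 3L, byrow = TRUE)
    landmark_set(coords,
                 specimen_id = df$specimen_id[i],
                 anatomical_unit = if ("anatomical_unit" %in% meta_cols)
                   df$anatomical_unit[i] else NA_character_,
                 group = if ("group" %in% meta_cols) df$group[i]
                   else NA_character_,
                 diet = if ("diet" %in% meta_cols) df$diet[i]
                   else NA_character_,
                 sex = if ("sex" %in% meta_cols) df$sex[i] else "u")
  })
}

#' Write landmark sets to a wide CSV table
#' @param sets list of \code{landmark_set} objects with identical k.
#' @param path output path.
#' @export
write_landmark_csv <- function(sets, path) {
  if (inherits(sets, "landmark_set")) sets <- list(sets)
  ks <- vapply(sets, function(s) nrow(s$coords), integer(1))
  if (length(unique(ks)) != 1L)
    stop("all landmark sets must share the same landmark count")
  k <- ks[1]
  coord_names <- as.vector(t(outer(seq_len(k), c("x", "y", "z"),
                                   function(i, a) paste0(a, i))))
  rows <- lapply(sets, function(s) {
    xyz <- as.vector(t(s$coords))
    xyz[rep(s$missing, each = 3L)] <- NA_real_
    c(list(specimen_id = s$specimen_id, anatomical_unit = s$anatomical_unit,
           group = s$group, diet = s$diet, sex = s$sex),
      stats::setNames(as.list(xyz), coord_names))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r,
                check.names = FALSE, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Filter specimens by missing-landmark fraction
#'
#' Specimens are retained only when strictly less than \code{max_frac} of
#' their landmarks are missing (the conventional cut-off is 20\%).
#'
#' @param sets list of \code{landmark_set} objects.
#' @param max_frac maximum tolerated missing fraction, in (0, 1].
#' @return list with components \code{kept} and \code{excluded}; together
#'   they partition the input.
#' @export
filter_missingness <- function(sets, max_frac = 0.20) {
  if (!(max_frac > 0 && max_frac <= 1)) stop("max_frac must be in (0, 1]")
  frac <- vapply(sets, missing_fraction, numeric(1))
  keep <- frac < max_frac
  list(kept = sets[keep], excluded = sets[!keep])
}
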