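#' Construct a subject-by-feature table
#'
#' The universal exchange object of the package: a numeric matrix of
#' morphometric features (one row per subject), a class label per subject,
#' and the ordered set of diagnostic classes. The default class order
#' \code{c("NC", "MCI", "AD")} encodes disease progression from normal
#' control through mild cognitive impairment to Alzheimer's disease.
#'
#' @param values numeric matrix, \code{n_subjects x n_features}. Must be
#'   finite throughout; rows are subjects.
#' @param labels character or factor of length \code{nrow(values)}; every
#'   entry must belong to \code{classes}.
#' @param subject_ids unique character vector of length \code{nrow(values)}.
#' @param feature_names unique character vector of length
#'   \code{ncol(values)}.
#' @param classes ordered character vector of permitted class names.
#' @return an object of class \code{feature_table} with fields
#'   \code{subject_ids}, \code{labels} (factor with levels \code{classes}),
#'   \code{feature_names}, \code{values}, \code{classes}.
#' @export
feature_table <- function(values, labels, subject_ids = NULL,
                          feature_names = NULL,
                          classes = c("NC", "MCI", "AD")) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  d <- ncol(values)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n))
  if (is.null(feature_names)) {
    feature_names <- if (!is.null(colnames(values))) colnames(values)
                     else sprintf("f%02d", seq_len(d))
  }
  subject_ids <- as.character(subject_ids)
  feature_names <- as.character(feature_names)
  labels <- as.character(labels)
  if (length(subject_ids) != n)
    stop("subject_ids length (", length(subject_ids),
         ") does not match number of rows (", n, ")")
  if (length(feature_names) != d)
    stop("feature_names length (", length(feature_names),
         ") does not match number of columns (", d, ")")
  if (length(labels) != n)
    stop("labels length (", length(labels), ") does not match rows (", n, ")")
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (anyDuplicated(feature_names))
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]),
               collapse = ", "))
  bad <- setdiff(unique(labels), classes)
  if (length(bad))
    stop("labels outside the declared class set: ",
         paste(bad, collapse = ", "))
  if (d > 0 && !all(is.finite(values)))
    stop("feature values contain NaN/Inf/NA; the loader rejects missing ",
         "values by default")
  dimnames(values) <- list(subject_ids, feature_names)
  structure(
    list(subject_ids = subject_ids,
         labels = factor(labels, levels = classes),
         feature_names = feature_names,
         values = values,
         classes = classes),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table: ", nrow(x$values), " subjects x ",
      ncol(x$values), " features\n", sep = "")
  cat("classes:", paste(x$classes, collapse = " > "), "\n")
  print(table(x$labels))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

# Row subset preserving metadata; used by the CV machinery.
ft_subset <- function(table, rows) {
  feature_table(table$values[rows, , drop = FALSE],
                as.character(table$labels)[rows],
                subject_ids = table$subject_ids[rows],
                feature_names = table$feature_names,
                classes = table$classes)
}

#' Read a feature table from delimited text
#'
#' Expects one subject per row, a header line, an id column, a label column,
#' and numeric feature columns. The delimiter is auto-detected from comma
#' and tab.
#'
#' @param path path to a CSV/TSV file.
#' @param label_column,id_column column names holding the class label and
#'   the subject id.
#' @param classes ordered class set; defaults to the classes present, in
#'   NC/MCI/AD order when they match, otherwise sorted order of appearance.
#' @return a \code{\link{feature_table}}.
#' @export
read_feature_table <- function(path, label_column = "dx",
                               id_column = "subject_id", classes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  for (col in c(id_column, label_column))
    if (!col %in% names(df))
      stop("required column '", col, "' not found in ", path)
  feat_cols <- setdiff(names(df), c(id_column, label_column))
  vals <- matrix(NA_real_, nrow(df), length(feat_cols),
                 dimnames = list(NULL, feat_cols))
  for (j in seq_along(feat_cols)) {
    raw <- df[[feat_cols[j]]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad))
      stop("non-numeric or missing feature value '", raw[bad[1]],
           "' at row ", bad[1], ", column '", feat_cols[j], "'")
    vals[, j] <- num
  }
  labs <- df[[label_column]]
  if (is.null(classes)) {
    present <- unique(labs)
    std <- c("NC", "MCI", "AD")
    classes <- if (all(present %in% std)) std[std %in% present]
               else sort(present)
  }
  feature_table(vals, labs, subject_ids = df[[id_column]],
                feature_names = feat_cols, classes = classes)
}

#' Write a feature table to CSV
#'
#' Output is comma-delimited with full-precision floats (17 significant
#' digits), so \code{read_feature_table} round-trips it exactly.
#'
#' @param table a \code{\link{feature_table}}.
#' @param path output path; an id column and label column are written first.
#' @param label_column,id_column column names to use on output.
#' @export
write_feature_table <- function(table, path, label_column = "dx",
                                id_column = "subject_id") {
  stopifnot(inherits(table, "feature_table"))
  vals <- table$values
  cells <- matrix(sprintf("%.17g", vals), nrow(vals), ncol(vals))
  lines <- c(
    paste(c(id_column, label_column, table$feature_names), collapse = ","),
    vapply(seq_len(nrow(vals)), function(i) {
      paste(c(table$subject_ids[i], as.character(table$labels)[i],
              cells[i, ]), collapse = ",")
    }, character(1)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Assemble a volume feature table from FreeSurfer-style stats files
#'
#' Each input file is an aseg/aparc-style segmentation statistics table:
#' lines starting with \code{#} are comments, except an optional
#' \code{# ColHeaders} line naming the data columns. Data rows are
#' whitespace-delimited. One subject per file; the subject id is the
#' filename stem.
#'
#' Without a \code{ColHeaders} line the standard aseg.stats positional
#' layout is assumed: \code{Index SegId NVoxels Volume_mm3 StructName ...}.
#'
#' @param paths character vector of stats file paths.
#' @param structures structure names to extract, in the desired column
#'   order. Default: the intersection of structures across all files, in
#'   the order of the first file.
#' @param classes,labels optional class set and per-file labels; by default
#'   every subject is labelled with the single placeholder class
#'   \code{"unknown"} (volume assembly is label-agnostic).
#' @return a \code{\link{feature_table}} of volumes in mm^3.
#' @export
read_freesurfer_stats <- function(paths, structures = NULL,
                                  labels = NULL, classes = NULL) {
  if (!length(paths)) stop("no stats files given")
  per_file <- lapply(paths, parse_fs_stats_file)
  ids <- vapply(paths, function(p) sub("\\.[^.]*$", "", basename(p)),
                character(1))
  if (anyDuplicated(ids))
    stop("duplicate subject ids derived from filenames: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(structures)) {
    structures <- per_file[[1]]$structure
    for (f in per_file[-1]) structures <- structures[structures %in% f$structure]
    if (!length(structures))
      stop("no structures common to all input files")
  }
  vals <- matrix(NA_real_, length(paths), length(structures),
                 dimnames = list(ids, structures))
  for (i in seq_along(per_file)) {
    f <- per_file[[i]]
    miss <- setdiff(structures, f$structure)
    if (length(miss))
      stop("structure(s) ", paste(miss, collapse = ", "),
           " absent in file ", paths[i])
    vals[i, ] <- f$volume[match(structures, f$structure)]
  }
  if (is.null(labels)) {
    labels <- rep("unknown", length(ids))
    if (is.null(classes)) classes <- "unknown"
  }
  feature_table(vals, labels, subject_ids = ids,
                feature_names = structures, classes = classes)
}

parse_fs_stats_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  comment <- startsWith(trimws(lines), "#")
  col_names <- NULL
  ch <- grep("^#\\s*ColHeaders\\b", lines, value = TRUE)
  if (length(ch)) {
    col_names <- strsplit(trimws(sub("^#\\s*ColHeaders\\s*", "", ch[1])),
                          "\\s+")[[1]]
  }
  data_lines <- lines[!comment & nzchar(trimws(lines))]
  if (!length(data_lines))
    stop("no data rows (only comments/blank lines) in ", path)
  rows <- strsplit(trimws(data_lines), "\\s+")
  ncol_row <- lengths(rows)
  if (length(unique(ncol_row)) != 1L)
    stop("malformed data row in ", path, ": inconsistent column counts")
  m <- do.call(rbind, rows)
  if (!is.null(col_names)) {
    if (length(col_names) != ncol(m))
      stop("ColHeaders names ", length(col_names), " columns but data rows in ",
           path, " have ", ncol(m))
    colnames(m) <- col_names
    sn_col <- match("StructName", col_names)
    vol_col <- match("Volume_mm3", col_names)
    if (is.na(sn_col) || is.na(vol_col))
      stop("ColHeaders of ", path,
           " lack StructName and/or Volume_mm3 columns")
  } else {
    # standard aseg.stats positional layout
    if (ncol(m) < 5)
      stop("malformed data row in ", path,
           ": fewer than 5 whitespace-delimited fields")
    vol_col <- 4L
    sn_col <- 5L
  }
  volume <- suppressWarnings(as.numeric(m[, vol_col]))
  if (anyNA(volume))
    stop("malformed data row in ", path, ": non-numeric volume '",
         m[which(is.na(volume))[1], vol_col], "'")
  if (any(volume < 0))
    stop("negative volume in ", path)
  data.frame(structure = m[, sn_col], volume = volume,
             source_file = path, stringsAsFactors = FALSE)
}
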