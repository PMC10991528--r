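#' Tabular cohort container
#'
#' A `cohort` bundles the pieces of a prediction dataset that fairness
#' auditing must keep aligned: participant identifiers, one or more
#' categorical protected attributes (sex, ethnicity, income band, ...),
#' descriptive features, and a binary outcome where 1 marks the condition
#' present (the positive class).
#'
#' Missing values in a protected attribute are never dropped: they become an
#' explicit `"Missing"` category so that the corresponding subgroup is
#' audited like any other. Category levels are ordered lexicographically for
#' reproducibility.
#'
#' @param ids character or integer vector of participant identifiers.
#' @param protected data.frame of categorical protected attributes; each
#'   column is coerced to factor with lexicographic levels and `NA`/empty
#'   values mapped to `"Missing"`.
#' @param features data.frame of descriptive variables (numeric, ordinal or
#'   categorical).
#' @param labels binary outcome vector, values in `{0, 1}` (1 = condition
#'   present).
#' @return An object of class `cohort` with elements `ids`, `protected`,
#'   `features`, `labels`.
#' @examples
#' cohort(
#'   ids = 1:4,
#'   protected = data.frame(sex = c("f", "m", "f", NA)),
#'   features = data.frame(score = c(1.2, 0.4, 2.2, 0.9)),
#'   labels = c(1, 0, 1, 0)
#' )
#' @export
cohort <- function(ids, protected, features, labels) {
  protected <- as.data.frame(protected, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  n <- length(ids)
  if (nrow(protected) != n || nrow(features) != n || length(labels) != n) {
    stopf("ids, protected, features and labels must have identical row counts")
  }
  if (ncol(protected) < 1L) stopf("at least one protected attribute is required")
  labels <- validate_binary_labels(labels)
  protected[] <- lapply(protected, canonical_protected)
  structure(
    list(ids = ids, protected = protected, features = features,
         labels = labels),
    suppressed = character(0),
    class = "cohort"
  )
}

validate_binary_labels <- function(labels) {
  lv <- unique(labels[!is.na(labels)])
  if (anyNA(labels) || !all(lv %in% c(0, 1))) {
    stopf("labels must be 0/1 with no missing values")
  }
  as.integer(labels)
}

canonical_protected <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "Missing"
  factor(x, levels = sort(unique(x)))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> n = %d, prevalence = %.3f\n", length(x$ids),
              mean(x$labels)))
  cat(" protected:", paste(names(x$protected), collapse = ", "), "\n")
  cat(" features: ", ncol(x$features), "columns\n")
  sup <- attr(x, "suppressed")
  if (length(sup)) cat(" suppressed:", paste(sup, collapse = ", "), "\n")
  invisible(x)
}

#' Number of participants in a cohort
#' @param x a `cohort`.
#' @return integer count.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "cohort"))
  length(x$ids)
}

#' Subset a cohort by row index
#'
#' Keeps identifiers, protected attributes, features and labels aligned, and
#' preserves factor levels and any suppression marks.
#'
#' @param x a `cohort`.
#' @param i integer or logical row index.
#' @param ... unused.
#' @return a `cohort` with the selected rows.
#' @export
`[.cohort` <- function(x, i, ...) {
  out <- structure(
    list(
      ids = x$ids[i],
      protected = x$protected[i, , drop = FALSE],
      features = x$features[i, , drop = FALSE],
      labels = x$labels[i]
    ),
    suppressed = attr(x, "suppressed"),
    class = "cohort"
  )
  rownames(out$protected) <- NULL
  rownames(out$features) <- NULL
  out
}

#' Read a cohort from CSV
#'
#' The schema maps column roles to column names: `label` (one column),
#' `protected` (one or more columns), `features` (columns; omit to take every
#' remaining column), and optionally `id`. Columns present in the file but
#' not named by the schema are ignored with a warning. The schema may also be
#' the path to a YAML or JSON file holding the same mapping.
#'
#' @param path CSV file with a header row.
#' @param schema named list with entries `label`, `protected`, and optionally
#'   `features` and `id`; or a path to a YAML/JSON file encoding it.
#' @return a [cohort].
#' @export
load_cohort <- function(path, schema) {
  schema <- resolve_schema(schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  declared <- unique(c(schema$id, schema$label, schema$protected, schema$features))
  missing <- setdiff(declared, names(df))
  if (length(missing)) {
    stopf("schema names columns absent from %s: %s", path,
          paste(missing, collapse = ", "))
  }
  feat_cols <- schema$features %||%
    setdiff(names(df), c(schema$id, schema$label, schema$protected))
  extra <- setdiff(names(df), c(schema$id, schema$label, schema$protected, feat_cols))
  if (length(extra)) {
    warnf("ignoring undeclared columns: %s", paste(extra, collapse = ", "))
  }
  ids <- if (is.null(schema$id)) seq_len(nrow(df)) else df[[schema$id]]
  cohort(
    ids = ids,
    protected = df[, schema$protected, drop = FALSE],
    features = df[, feat_cols, drop = FALSE],
    labels = df[[schema$label]]
  )
}

resolve_schema <- function(schema) {
  if (is.character(schema) && length(schema) == 1L) {
    schema <- if (grepl("\\.json$", schema, ignore.case = TRUE)) {
      jsonlite::read_json(schema, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(schema)
    }
  }
  if (is.null(schema$label) || is.null(schema$protected)) {
    stopf("schema must declare 'label' and 'protected' columns")
  }
  schema
}

#' Write a cohort to CSV
#'
#' Emits one row per participant with columns `id`, the protected attributes,
#' the features, and `label`, round-trippable with [load_cohort()].
#'
#' @param x a `cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  df <- data.frame(id = x$ids, stringsAsFactors = FALSE)
  df <- cbind(df, x$protected, x$features, label = x$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Schema of a cohort, for round-tripping
#' @param x a `cohort`.
#' @return named list usable as the `schema` argument of [load_cohort()].
#' @export
cohort_schema <- function(x) {
  stopifnot(inherits(x, "cohort"))
  list(id = "id", label = "label", protected = names(x$protected),
       features = names(x$features))
}

#' Binarize PHQ-9 questionnaire totals
#'
#' The 9-item Patient Health Questionnaire yields a total score of 0-27; a
#' total of 10 or more is the standard screening cut-off for major depressive
#' disorder and defines the positive class here.
#'
#' @param scores integer totals in `[0, 27]`.
#' @return integer 0/1 labels, 1 when `scores >= 10`.
#' @examples
#' phq9_binarize(c(0, 9, 10, 27))
#' @export
phq9_binarize <- function(scores) {
  if (anyNA(scores) || any(scores < 0 | scores > 27)) {
    stopf("PHQ-9 scores must lie in [0, 27]")
  }
  as.integer(scores >= 10)
}

#' Partition cohort rows by a protected attribute
#'
#' A subgroup is the set of participants sharing one category of the
#' attribute. Categories are ordered lexicographically; the index sets are
#' disjoint and jointly cover all rows.
#'
#' @param x a `cohort`.
#' @param attribute name of a declared protected column.
#' @return an object of class `group_partition` with elements `attribute`,
#'   `categories` and `index` (named list of integer row indices).
#' @export
partition_by_group <- function(x, attribute) {
  stopifnot(inherits(x, "cohort"))
  if (!attribute %in% names(x$protected)) {
    stopf("unknown protected attribute: %s", attribute)
  }
  g <- x$protected[[attribute]]
  cats <- sort(unique(as.character(g)))
  idx <- lapply(cats, function(ct) which(as.character(g) == ct))
  names(idx) <- cats
  structure(list(attribute = attribute, categories = cats, index = idx),
            class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  sizes <- vapply(x$index, length, integer(1))
  cat(sprintf("<group_partition> %s: %s\n", x$attribute,
              paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}
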