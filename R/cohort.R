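#' Declare a cohort feature
#'
#' A feature specification names one baseline covariate, says whether it is
#' continuous or categorical, and (for categorical features) fixes the
#' admissible category labels in order. The ordered union of encoded columns
#' across all features defines the feature dimension `D` over which the
#' encoder's attention masks live.
#'
#' @param name Column name in the cohort file.
#' @param kind `"continuous"` or `"categorical"`.
#' @param categories Ordered character vector of admissible labels
#'   (categorical features only, at least two).
#' @param units Free-text units, for reporting only.
#' @return A `feature_spec` object.
#' @examples
#' feature_spec("albumin", "continuous", units = "g/L")
#' feature_spec("bclc", "categorical", categories = c("A_B", "C"))
#' @export
feature_spec <- function(name, kind = c("continuous", "categorical"),
                         categories = NULL, units = "") {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) < 2L) {
      stop("categorical feature '", name, "' needs >= 2 categories", call. = FALSE)
    }
    categories <- as.character(categories)
    if (anyDuplicated(categories)) {
      stop("duplicate category labels for feature '", name, "'", call. = FALSE)
    }
  } else {
    categories <- NULL
  }
  structure(list(name = name, kind = kind, categories = categories,
                 units = units),
            class = "feature_spec")
}

#' Build a cohort schema
#'
#' @param ... `feature_spec` objects (or a single list of them).
#' @return A `cohort_schema`: a named list of feature specs.
#' @export
cohort_schema <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1L]], "feature_spec")) {
    specs <- specs[[1L]]
  }
  ok <- vapply(specs, inherits, logical(1), "feature_spec")
  if (!all(ok)) stop("all schema entries must be feature_spec objects", call. = FALSE)
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("feature names must be unique", call. = FALSE)
  names(specs) <- nms
  structure(specs, class = "cohort_schema")
}

#' Read a cohort schema from a YAML config file
#'
#' The file holds a list of entries with fields `name`, `kind`, and optionally
#' `categories` and `units`.
#'
#' @param path Path to the YAML file.
#' @return A `cohort_schema`.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw, function(e) {
    feature_spec(e$name, e$kind, categories = e$categories,
                 units = e$units %||% "")
  })
  cohort_schema(specs)
}

encoded_columns <- function(spec) {
  if (spec$kind == "continuous") return(spec$name)
  if (length(spec$categories) == 2L) return(spec$name)
  paste(spec$name, spec$categories[-1L], sep = "=")
}

#' Encode one raw covariate column per its feature spec
#' @noRd
encode_feature <- function(x, spec) {
  if (spec$kind == "continuous") {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("feature '", spec$name, "': non-numeric or missing value in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    m <- matrix(v, ncol = 1L, dimnames = list(NULL, spec$name))
    return(m)
  }
  x <- as.character(x)
  unknown <- setdiff(unique(x), spec$categories)
  if (length(unknown)) {
    stop("feature '", spec$name, "': unknown category label(s) ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }
  if (length(spec$categories) == 2L) {
    # binary: 0/1 against the first (reference) level
    m <- matrix(as.numeric(x == spec$categories[2L]), ncol = 1L,
                dimnames = list(NULL, spec$name))
    return(m)
  }
  # multi-level: one-hot indicators, reference level dropped
  cols <- spec$categories[-1L]
  m <- vapply(cols, function(lv) as.numeric(x == lv), numeric(length(x)))
  m <- matrix(m, ncol = length(cols),
              dimnames = list(NULL, paste(spec$name, cols, sep = "=")))
  m
}

#' Assemble a survival cohort from a data frame
#'
#' A cohort bundles the encoded covariate matrix `X` (one column per
#' continuous feature, 0/1 for binary categoricals, one-hot indicators with
#' the first level as reference for multi-level categoricals), strictly
#' positive follow-up times in months, and a 0/1 event indicator
#' (1 = death, 0 = censored).
#'
#' @param data A data frame with one row per patient.
#' @param schema A [cohort_schema()] declaring the covariates.
#' @param time,event Column names of follow-up time and event indicator.
#' @return A `cohort` object with elements `X` (n x D numeric matrix),
#'   `features`, `encoded_names`, `time`, `event`.
#' @export
as_cohort <- function(data, schema, time = "time", event = "event") {
  stopifnot(is.data.frame(data))
  if (!inherits(schema, "cohort_schema")) schema <- cohort_schema(schema)
  need <- c(vapply(schema, `[[`, character(1), "name"), time, event)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tm <- suppressWarnings(as.numeric(data[[time]]))
  ev <- suppressWarnings(as.numeric(data[[event]]))
  bad_t <- which(is.na(tm) | tm <= 0)
  if (length(bad_t)) {
    stop("nonpositive or unparseable follow-up time in row(s) ",
         paste(utils::head(bad_t, 5L), collapse = ", "), call. = FALSE)
  }
  bad_e <- which(!(ev %in% c(0, 1)))
  if (length(bad_e)) {
    stop("event indicator not in {0,1} in row(s) ",
         paste(utils::head(bad_e, 5L), collapse = ", "), call. = FALSE)
  }
  blocks <- lapply(schema, function(sp) encode_feature(data[[sp$name]], sp))
  X <- do.call(cbind, blocks)
  if (anyNA(X)) stop("missing covariate entries are not permitted", call. = FALSE)
  structure(
    list(X = X, features = schema, encoded_names = colnames(X),
         time = tm, event = as.integer(ev)),
    class = "cohort"
  )
}

#' Load a cohort from a delimited text file
#'
#' Reads a comma-separated file with a header row, validates it against the
#' schema, and encodes covariates. Rows that fail validation are reported by
#' index.
#'
#' @inheritParams as_cohort
#' @param path Path to the CSV file.
#' @return A `cohort`.
#' @export
load_cohort <- function(path, schema, time = "time", event = "event") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_cohort(data, schema, time = time, event = event)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> n =", n_cohort(x), " D =", ncol(x$X),
      " events =", sum(x$event),
      sprintf(" (%.1f%% censored)\n", 100 * mean(x$event == 0)))
  invisible(x)
}

n_cohort <- function(cohort) length(cohort$time)

#' Convert a cohort back to a tibble
#'
#' Encoded covariates plus `time` and `event` columns, one row per patient.
#'
#' @param x A `cohort`.
#' @param ... Unused.
#' @return A tibble.
#' @export
as_tibble.cohort <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$X))
  out$time <- x$time
  out$event <- x$event
  out
}

subset_cohort <- function(cohort, idx) {
  structure(
    list(X = cohort$X[idx, , drop = FALSE], features = cohort$features,
         encoded_names = cohort$encoded_names,
         time = cohort$time[idx], event = cohort$event[idx]),
    class = "cohort"
  )
}

#' Fit leakage-safe preprocessing statistics
#'
#' Z-score statistics (mean and sample standard deviation, n-1 denominator)
#' are computed for every continuous encoded column from the supplied
#' training cohort only; indicator columns from categorical features are left
#' untouched. Apply the frozen stats to any cohort with
#' [apply_preprocess()] -- it never refits.
#'
#' @param train A training `cohort`.
#' @return A `preprocess_stats` object (per-column center/scale and a flag
#'   for which columns are standardized).
#' @export
fit_preprocess <- function(train) {
  stopifnot(inherits(train, "cohort"))
  cont <- unlist(lapply(train$features, function(sp) {
    if (sp$kind == "continuous") sp$name else character(0)
  }))
  std <- colnames(train$X) %in% cont
  center <- ifelse(std, colMeans(train$X), 0)
  scale <- rep(1, ncol(train$X))
  if (any(std)) {
    sds <- apply(train$X[, std, drop = FALSE], 2L, stats::sd)
    if (any(sds == 0)) {
      stop("constant continuous feature(s): ",
           paste(colnames(train$X)[std][sds == 0], collapse = ", "),
           call. = FALSE)
    }
    scale[std] <- sds
  }
  structure(list(center = stats::setNames(center, colnames(train$X)),
                 scale = stats::setNames(scale, colnames(train$X)),
                 standardized = stats::setNames(std, colnames(train$X))),
            class = "preprocess_stats")
}

#' Apply frozen preprocessing statistics to a cohort
#'
#' @param cohort A `cohort`.
#' @param stats A `preprocess_stats` from [fit_preprocess()].
#' @return The cohort with standardized continuous columns.
#' @export
apply_preprocess <- function(cohort, stats) {
  stopifnot(inherits(cohort, "cohort"), inherits(stats, "preprocess_stats"))
  if (!identical(colnames(cohort$X), names(stats$center))) {
    stop("cohort columns do not match preprocessing statistics", call. = FALSE)
  }
  X <- sweep(sweep(cohort$X, 2L, stats$center, "-"), 2L, stats$scale, "/")
  cohort$X <- X
  cohort
}

#' Serialize / restore preprocessing statistics
#'
#' Written as YAML so the exact training-time statistics can be reused at
#' inference.
#'
#' @param stats A `preprocess_stats`.
#' @param path File path.
#' @return `write_preprocess` returns `path` invisibly; `read_preprocess`
#'   returns the restored `preprocess_stats`.
#' @export
write_preprocess <- function(stats, path) {
  yaml::write_yaml(list(center = as.list(stats$center),
                        scale = as.list(stats$scale),
                        standardized = as.list(stats$standardized)), path,
                   precision = 17L)
  invisible(path)
}

#' @rdname write_preprocess
#' @export
read_preprocess <- function(path) {
  raw <- yaml::read_yaml(path)
  structure(list(center = unlist(raw$center), scale = unlist(raw$scale),
                 standardized = unlist(raw$standardized)),
            class = "preprocess_stats")
}

#' Albumin-bilirubin (ALBI) liver-function score
#'
#' `ALBI = 0.66 * log10(bilirubin [umol/L]) - 0.085 * albumin [g/L]`,
#' an objective laboratory index of hepatic functional reserve. More
#' negative values indicate better liver function.
#'
#' @param bilirubin Total bilirubin in umol/L (strictly positive).
#' @param albumin Serum albumin in g/L (strictly positive).
#' @return Numeric vector of ALBI scores.
#' @examples
#' albi_score(10, 40)   # -2.74
#' albi_score(100, 20)  # -0.38
#' @export
albi_score <- function(bilirubin, albumin) {
  if (any(!is.finite(bilirubin)) || any(bilirubin <= 0)) {
    stop("bilirubin must be strictly positive (log10 undefined otherwise)",
         call. = FALSE)
  }
  if (any(!is.finite(albumin)) || any(albumin <= 0)) {
    stop("albumin must be strictly positive", call. = FALSE)
  }
  0.66 * log10(bilirubin) - 0.085 * albumin
}

#' Seeded random cohort partition
#'
#' Splits a cohort into disjoint, exhaustive training and holdout parts.
#' The training size is `floor(ratio * n)` unless `sizes` supplies an
#' explicit `(train, holdout)` pair (so a published split such as 339/114
#' of 453 can be reproduced exactly). The same seed always reproduces the
#' same membership; the global RNG state is untouched.
#'
#' @param cohort A `cohort`.
#' @param ratio Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param sizes Optional explicit integer pair `c(n_train, n_holdout)`
#'   summing to `n`.
#' @return A list with `train` and `holdout` cohorts plus the index vectors.
#' @export
random_split <- function(cohort, ratio = 0.75, seed = 1L, sizes = NULL) {
  n <- n_cohort(cohort)
  if (n < 2L) stop("need at least 2 rows to split", call. = FALSE)
  if (is.null(sizes)) {
    if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio >= 1) {
      stop("ratio must lie strictly between 0 and 1", call. = FALSE)
    }
    n_train <- floor(ratio * n)
  } else {
    sizes <- as.integer(sizes)
    if (length(sizes) != 2L || sum(sizes) != n || any(sizes < 1L)) {
      stop("sizes must be two positive integers summing to n", call. = FALSE)
    }
    n_train <- sizes[1L]
  }
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  train_idx <- sort(perm[seq_len(n_train)])
  holdout_idx <- sort(perm[-seq_len(n_train)])
  list(train = subset_cohort(cohort, train_idx),
       holdout = subset_cohort(cohort, holdout_idx),
       train_idx = train_idx, holdout_idx = holdout_idx)
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [load_cohort()] for already-encoded cohorts: encoded covariate
#' columns plus `time` and `event`, comma-separated with a header row.
#'
#' @param cohort A `cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(as_tibble.cohort(cohort), path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
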