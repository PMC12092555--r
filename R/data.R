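#' Construct a validated two-group data set
#'
#' The elementary data object entering every model of the ensemble: two
#' vectors of real-valued observations, one per group. Both groups must
#' contain at least two finite values with nonzero sample variance, since all
#' likelihoods in the ensemble involve a per-group scale.
#'
#' @param group1,group2 Numeric vectors of observations (outcome units).
#'   Non-finite values are dropped with a warning.
#' @param labels Character vector of length two naming the groups. The first
#'   label defines "group 1", the group whose precision share the
#'   \eqn{\rho} parameter refers to.
#' @return An object of class `two_sample_data`: a list with elements
#'   `group1`, `group2` and `labels`.
#' @examples
#' d <- two_sample_data(c(1, 2, 3), c(4, 6))
#' summarize_groups(d)
#' @export
two_sample_data <- function(group1, group2, labels = c("group1", "group2")) {
  if (!is.numeric(group1) || !is.numeric(group2)) {
    stop_mbt("both groups must be numeric vectors.")
  }
  if (length(labels) != 2L || anyDuplicated(labels)) {
    stop_mbt("`labels` must be two distinct group names.")
  }
  drop1 <- sum(!is.finite(group1))
  drop2 <- sum(!is.finite(group2))
  if (drop1 + drop2 > 0) {
    warning(sprintf("dropped %d non-finite observation(s) (%d in '%s', %d in '%s').",
                    drop1 + drop2, drop1, labels[1], drop2, labels[2]),
            call. = FALSE)
  }
  group1 <- as.numeric(group1[is.finite(group1)])
  group2 <- as.numeric(group2[is.finite(group2)])
  for (g in 1:2) {
    y <- if (g == 1) group1 else group2
    if (length(y) < 2L) {
      stop_mbt(sprintf("group '%s' has fewer than 2 usable observations.", labels[g]))
    }
    if (stats::var(y) <= 0) {
      stop_mbt(sprintf("group '%s' has zero sample variance.", labels[g]))
    }
  }
  structure(list(group1 = group1, group2 = group2,
                 labels = as.character(labels)),
            class = "two_sample_data")
}

#' @export
print.two_sample_data <- function(x, ...) {
  cat(sprintf("<two_sample_data>  %s: n = %d | %s: n = %d\n",
              x$labels[1], length(x$group1), x$labels[2], length(x$group2)))
  invisible(x)
}

#' Coerce a two-group data set to a tidy tibble
#'
#' @param x A `two_sample_data` object.
#' @param ... Unused.
#' @return A tibble with columns `value` and `group`.
#' @export
as_tibble.two_sample_data <- function(x, ...) {
  tibble::tibble(
    value = c(x$group1, x$group2),
    group = factor(rep(x$labels, c(length(x$group1), length(x$group2))),
                   levels = x$labels)
  )
}

#' Per-group summary statistics
#'
#' Reduces a two-group data set to the sufficient statistics of the
#' normal-likelihood models: per-group sample size, mean and standard
#' deviation (divisor n - 1).
#'
#' @param data A `two_sample_data` object, or a data frame with a value and a
#'   group column (see `value`, `group` arguments).
#' @param value,group For data-frame input, column names (tidy-eval) holding
#'   the observations and the group labels.
#' @return A `two_sample_summary` object, also a tibble with one row per
#'   group and columns `group`, `n`, `mean`, `sd`.
#' @examples
#' summarize_groups(two_sample_data(c(1, 2, 3), c(4, 6)))
#' @export
summarize_groups <- function(data, value = NULL, group = NULL) {
  if (is.data.frame(data)) {
    data <- data_from_frame(data, {{ value }}, {{ group }})
  }
  stopifnot(inherits(data, "two_sample_data"))
  two_sample_summary(
    n1 = length(data$group1), mean1 = mean(data$group1), sd1 = stats::sd(data$group1),
    n2 = length(data$group2), mean2 = mean(data$group2), sd2 = stats::sd(data$group2),
    labels = data$labels
  )
}

# internal: data.frame -> two_sample_data with first-appearance group order
data_from_frame <- function(df, value, group, group_order = NULL) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  if (rlang::quo_is_null(value)) value <- rlang::sym("value")
  if (rlang::quo_is_null(group)) group <- rlang::sym("group")
  v <- rlang::eval_tidy(value, df)
  g <- rlang::eval_tidy(group, df)
  if (is.null(v) || is.null(g)) stop_mbt("value/group columns not found.")
  labs <- if (!is.null(group_order)) as.character(group_order) else
    as.character(unique(g[!is.na(g)]))
  if (length(setdiff(as.character(unique(g[!is.na(g)])), labs)) > 0 ||
      length(labs) != 2L) {
    stop_mbt(sprintf("expected exactly 2 group labels, found: %s.",
                     paste(unique(g), collapse = ", ")))
  }
  two_sample_data(v[g == labs[1]], v[g == labs[2]], labels = labs)
}

#' Construct summary statistics directly
#'
#' @param n1,n2 Group sample sizes (integers, at least 2).
#' @param mean1,mean2 Group sample means.
#' @param sd1,sd2 Group sample standard deviations (divisor n - 1, positive).
#' @param labels Two group names.
#' @return A `two_sample_summary`: a tibble with one row per group and an
#'   attribute-free column layout (`group`, `n`, `mean`, `sd`).
#' @export
two_sample_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                               labels = c("group1", "group2")) {
  assert_scalar_num(n1, "n1", 2); assert_scalar_num(n2, "n2", 2)
  if (n1 != round(n1) || n2 != round(n2)) stop_mbt("sample sizes must be integers.")
  assert_scalar_num(mean1, "mean1"); assert_scalar_num(mean2, "mean2")
  assert_scalar_num(sd1, "sd1", 0, strict = TRUE)
  assert_scalar_num(sd2, "sd2", 0, strict = TRUE)
  out <- tibble::tibble(
    group = factor(labels, levels = labels),
    n = as.integer(c(n1, n2)),
    mean = c(mean1, mean2),
    sd = c(sd1, sd2)
  )
  class(out) <- c("two_sample_summary", class(out))
  out
}

summary_fields <- function(stats) {
  stopifnot(inherits(stats, "two_sample_summary"))
  list(n1 = stats$n[1], mean1 = stats$mean[1], sd1 = stats$sd[1],
       n2 = stats$n[2], mean2 = stats$mean[2], sd2 = stats$sd[2],
       labels = as.character(stats$group))
}

#' Read a two-group data set from CSV
#'
#' Expects an RFC-4180 CSV with a header, a numeric value column and a group
#' column with exactly two distinct labels. Rows with missing values are
#' dropped with a warning reporting the count. Group 1 is the first label
#' encountered unless `group_order` overrides it.
#'
#' @param path Path to the CSV file.
#' @param value_column,group_column Column names (strings).
#' @param group_order Optional character vector of length two fixing which
#'   label is group 1.
#' @return A `two_sample_data` object.
#' @export
read_two_group_csv <- function(path, value_column = "value",
                               group_column = "group", group_order = NULL) {
  if (!file.exists(path)) stop_mbt(sprintf("file '%s' does not exist.", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_mbt(sprintf("file '%s' contains no data rows.", path))
  for (col in c(value_column, group_column)) {
    if (!col %in% names(df)) {
      stop_mbt(sprintf("column '%s' not found in '%s' (columns: %s).",
                       col, path, paste(names(df), collapse = ", ")))
    }
  }
  v <- df[[value_column]]
  if (!is.numeric(v)) {
    suppressWarnings(vn <- as.numeric(v))
    if (anyNA(vn) && !all(is.na(v[is.na(vn)]))) {
      bad <- utils::head(unique(v[is.na(vn) & !is.na(v)]), 3)
      stop_mbt(sprintf("value column '%s' is not numeric (e.g. %s).",
                       value_column, paste(bad, collapse = ", ")))
    }
    v <- vn
  }
  g <- df[[group_column]]
  miss <- is.na(v) | is.na(g)
  if (any(miss)) {
    warning(sprintf("dropped %d row(s) with missing values.", sum(miss)),
            call. = FALSE)
    v <- v[!miss]; g <- g[!miss]
  }
  labs <- unique(as.character(g))
  if (length(labs) != 2L) {
    stop_mbt(sprintf("expected exactly 2 group labels, found %d: %s.",
                     length(labs), paste(labs, collapse = ", ")))
  }
  if (!is.null(group_order)) {
    if (!setequal(group_order, labs)) {
      stop_mbt("`group_order` must be a permutation of the labels in the file.")
    }
    labs <- as.character(group_order)
  }
  two_sample_data(v[g == labs[1]], v[g == labs[2]], labels = labs)
}

#' Write a two-group data set to CSV
#'
#' Values are written with full double precision so that a read/write
#' round-trip is exact for finite doubles.
#'
#' @param data A `two_sample_data` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_two_group_csv <- function(data, path) {
  stopifnot(inherits(data, "two_sample_data"))
  df <- as_tibble.two_sample_data(data)
  df$value <- sprintf("%.17g", df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reconstruct raw data matching given summary statistics
#'
#' Generates per-group normal draws and affinely re-standardizes each group so
#' that the sample mean and SD reproduce the requested summaries to machine
#' precision. Useful for running raw-data methods on published summary
#' statistics; the within-group configuration beyond the first two moments is
#' arbitrary (seed-dependent), which is immaterial for normal-likelihood
#' models and an explicit approximation for t-likelihood models.
#'
#' @param stats A `two_sample_summary`.
#' @param seed Integer seed controlling the arbitrary configuration.
#' @return A `two_sample_data` whose [summarize_groups()] output equals
#'   `stats` up to floating-point roundoff.
#' @export
fixture_from_summary <- function(stats, seed = 1L) {
  f <- summary_fields(stats)
  gen <- function(n, m, s, which) {
    with_seed(sub_seed(seed, "fixture", which), {
      y <- stats::rnorm(n)
      m + s * (y - mean(y)) / stats::sd(y)
    })
  }
  two_sample_data(gen(f$n1, f$mean1, f$sd1, 1L),
                  gen(f$n2, f$mean2, f$sd2, 2L),
                  labels = f$labels)
}

#' Serialize / deserialize summary statistics as JSON
#'
#' Keys follow the flat convention `n1, mean1, sd1, n2, mean2, sd2`.
#'
#' @param stats A `two_sample_summary`.
#' @param path File path.
#' @return `read_summary_json` returns a `two_sample_summary`;
#'   `write_summary_json` returns `path` invisibly.
#' @export
write_summary_json <- function(stats, path) {
  f <- summary_fields(stats)
  jsonlite::write_json(
    list(n1 = f$n1, mean1 = f$mean1, sd1 = f$sd1,
         n2 = f$n2, mean2 = f$mean2, sd2 = f$sd2,
         labels = f$labels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_summary_json
#' @export
read_summary_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("n1", "mean1", "sd1", "n2", "mean2", "sd2")
  if (!all(need %in% names(x))) {
    stop_mbt(sprintf("summary JSON must contain keys: %s.",
                     paste(need, collapse = ", ")))
  }
  two_sample_summary(x$n1, x$mean1, x$sd1, x$n2, x$mean2, x$sd2,
                     labels = x$labels %||% c("group1", "group2"))
}
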