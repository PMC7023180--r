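#' Color distance between two delta-RGB response patterns
#'
#' The dissimilarity of two response patterns `a` and `b` over `n` bins is
#' the sum over bins of squared per-channel differences,
#' `sum_i (dR_i^a - dR_i^b)^2 + (dG_i^a - dG_i^b)^2 + (dB_i^a - dB_i^b)^2`.
#' The `"squared"` dialect returns this sum as printed in the metric's
#' definition (and is the conventional input to Ward linkage); the
#' `"euclidean"` dialect returns its square root, a true Euclidean metric
#' in the 3n-dimensional color-change space.
#'
#' @param a,b `"response_pattern"` objects, numeric matrices (bins x 3) or
#'   plain numeric vectors; `a` and `b` must have the same length and bin
#'   order.
#' @param dialect `"squared"` (default) or `"euclidean"`.
#' @return Non-negative scalar; 0 iff `a == b`.
#' @examples
#' color_distance(c(0, 0, 0), c(255, 0, 0))              # 65025
#' color_distance(c(0, 0, 0), c(255, 0, 0), "euclidean") # 255
#' @export
color_distance <- function(a, b, dialect = c("squared", "euclidean")) {
  dialect <- match.arg(dialect)
  va <- pattern_values(a)
  vb <- pattern_values(b)
  if (length(va) != length(vb))
    stop_csa("patterns have different bin counts (", length(va), " vs ",
             length(vb), ")", class = "incompatible_pattern")
  d2 <- sum((va - vb)^2)
  if (dialect == "squared") d2 else sqrt(d2)
}

pattern_values <- function(x) {
  if (inherits(x, "response_pattern")) return(as.vector(t(x$bins)))
  if (is.matrix(x)) return(as.vector(t(x)))
  as.numeric(x)
}

#' Pairwise color-distance matrix of a feature table
#'
#' @param features Feature table (data frame with `analyte_id` and numeric
#'   bin columns) or a numeric matrix with row names.
#' @param dialect `"squared"` or `"euclidean"` (see [color_distance()]).
#' @return An object of class `"color_dist"`: list with `labels`, the
#'   symmetric zero-diagonal `values` matrix, and the `dialect` used.
#' @export
distance_matrix <- function(features, dialect = c("squared", "euclidean")) {
  dialect <- match.arg(dialect)
  m <- if (is.data.frame(features)) feature_matrix(features)
       else as.matrix(features)
  if (nrow(m) < 2)
    stop_csa("need at least 2 patterns", class = "invalid_parameter")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  if (anyDuplicated(labels))
    stop_csa("duplicate analyte labels", class = "labeling_error")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <- color_distance(m[i, ], m[j, ], dialect)
  }
  structure(list(labels = labels, values = d, dialect = dialect),
            class = "color_dist")
}

as_distance_values <- function(d) {
  if (inherits(d, "color_dist")) return(d$values)
  if (inherits(d, "dist")) return(as.matrix(d))
  as.matrix(d)
}

#' @export
print.color_dist <- function(x, ...) {
  cat(sprintf("color_dist (%s dialect), %d patterns\n", x$dialect,
              length(x$labels)))
  print(round(x$values, 3))
  invisible(x)
}

#' Read / write a labeled square distance matrix as CSV
#'
#' @param d A `"color_dist"`.
#' @param path File path.
#' @return `read_distance_csv()` returns a `"color_dist"`;
#'   the writers return `path` invisibly.
#' @export
write_distance_csv <- function(d, path) {
  stopifnot(inherits(d, "color_dist"))
  df <- cbind(data.frame(label = d$labels), as.data.frame(d$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- df$label
  values <- as.matrix(df[, -1, drop = FALSE])
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values, dialect = "unknown"),
            class = "color_dist")
}

#' Write a distance matrix in PHYLIP lower-triangle format
#'
#' @rdname write_distance_csv
#' @export
write_distance_phylip <- function(d, path) {
  stopifnot(inherits(d, "color_dist"))
  n <- length(d$labels)
  lines <- sprintf("%5d", n)
  for (i in seq_len(n)) {
    name <- formatC(substr(d$labels[i], 1, 10), width = 10, flag = "-")
    row <- if (i > 1)
      paste(formatC(d$values[i, seq_len(i - 1)], format = "g", digits = 10),
            collapse = "  ")
    else ""
    lines <- c(lines, trimws(paste(name, row), which = "right"))
  }
  writeLines(lines, path)
  invisible(path)
}
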