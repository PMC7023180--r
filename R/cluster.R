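#' Agglomerative hierarchical clustering via the Lance-Williams recurrence
#'
#' Builds a dendrogram from a pairwise distance matrix by iteratively
#' merging the two clusters at minimum current inter-cluster distance and
#' updating distances to the merged cluster with the Lance-Williams
#' recurrence
#' `d(k, i+j) = a_i d(k,i) + a_j d(k,j) + b d(i,j) + g |d(k,i) - d(k,j)|`.
#'
#' The default `"ward_d"` linkage is Ward's minimum-variance criterion on
#' the distances as given (coefficients `a_i = (n_i + n_k) / (n_i + n_j +
#' n_k)`, `b = -n_k / (n_i + n_j + n_k)`, `g = 0`): when the input is a
#' squared-Euclidean distance matrix of points, each merge height is
#' proportional to the increment of the error sum of squares (ESS, the
#' total squared deviation of cluster members from their centroid) caused
#' by that merge, so the tree greedily minimises ESS growth. `"ward_d2"`
#' applies the same coefficients to squared distances and reports square-
#' rooted heights. `"single"`, `"complete"` and `"average"` are the usual
#' nearest-, furthest- and mean-neighbour rules. All five linkages are
#' reducible, so merge heights are monotone non-decreasing; this is
#' asserted on every run.
#'
#' Ties (two candidate pairs at exactly the minimal distance) are broken
#' deterministically in favour of the lexicographically smallest
#' `(left_id, right_id)` node-id pair; tie events are recorded in the
#' `ties` attribute of the result.
#'
#' Node ids follow the convention: leaves `0 .. n-1` in input order,
#' internal nodes `n .. 2n-2` in merge order.
#'
#' @param d A `"color_dist"`, `dist`, or symmetric non-negative matrix
#'   with zero diagonal.
#' @param linkage One of `"ward_d"`, `"ward_d2"`, `"single"`,
#'   `"complete"`, `"average"`.
#' @return An object of class `"color_dendrogram"`: list with `merges`
#'   (data frame `left`, `right`, `height`, `size`), `labels`, `n` and
#'   `linkage`.
#' @examples
#' d <- distance_matrix(matrix(c(0, 1, 10), 3, 1,
#'                             dimnames = list(c("a", "b", "c"), NULL)))
#' hierarchical_cluster(d)$merges
#' @export
hierarchical_cluster <- function(d, linkage = c("ward_d", "ward_d2",
                                                "single", "complete",
                                                "average")) {
  linkage <- match.arg(linkage)
  dm <- as_distance_values(d)
  n <- nrow(dm)
  if (n < 2) stop_csa("need at least 2 objects", class = "invalid_input")
  if (!isSymmetric(unname(dm), tol = 1e-8) || any(dm < 0) ||
      any(!is.finite(dm)) || any(abs(diag(dm)) > 1e-12))
    stop_csa("distance matrix must be symmetric, finite, non-negative ",
             "with zero diagonal", class = "invalid_input")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  work <- (dm + t(dm)) / 2
  if (linkage == "ward_d2") work <- work^2
  ids <- 0:(n - 1L)          # current cluster node ids, ascending
  sizes <- rep(1L, n)
  merges <- data.frame(left = integer(n - 1L), right = integer(n - 1L),
                       height = numeric(n - 1L), size = integer(n - 1L))
  ties <- list()

  for (m in seq_len(n - 1L)) {
    k <- length(ids)
    # scan i < j in ascending-id order; strict < keeps the lexicographically
    # smallest (left, right) pair among exact ties
    best <- c(NA_integer_, NA_integer_); best_d <- Inf; n_at_min <- 0L
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      if (work[i, j] < best_d) {
        best_d <- work[i, j]; best <- c(i, j); n_at_min <- 1L
      } else if (work[i, j] == best_d) n_at_min <- n_at_min + 1L
    }
    if (n_at_min > 1L)
      ties[[length(ties) + 1L]] <- list(step = m, distance = best_d,
                                        candidates = n_at_min)
    i <- best[1]; j <- best[2]
    ni <- sizes[i]; nj <- sizes[j]
    height <- if (linkage == "ward_d2") sqrt(best_d) else best_d
    merges$left[m] <- ids[i]; merges$right[m] <- ids[j]
    merges$height[m] <- height; merges$size[m] <- ni + nj

    others <- setdiff(seq_len(k), c(i, j))
    newd <- vapply(others, function(o) {
      dio <- work[i, o]; djo <- work[j, o]; no <- sizes[o]
      switch(linkage,
             single = min(dio, djo),
             complete = max(dio, djo),
             average = (ni * dio + nj * djo) / (ni + nj),
             # ward_d and ward_d2 share the Ward coefficients
             ((ni + no) * dio + (nj + no) * djo - no * best_d) /
               (ni + nj + no))
    }, 0)

    # merged cluster appended last: its id (n + m - 1) exceeds all others
    work <- rbind(cbind(work[others, others, drop = FALSE], newd),
                  c(newd, 0))
    sizes <- c(sizes[others], ni + nj)
    ids <- c(ids[others], n + m - 1L)
  }

  eps <- 1e-8 * max(1, abs(merges$height[n - 1L]))
  if (any(diff(merges$height) < -eps))
    stop_csa("internal error: non-monotone merge heights for reducible ",
             "linkage ", linkage, class = "invalid_input")

  structure(list(merges = merges, labels = labels, n = n,
                 linkage = linkage, ties = ties),
            class = "color_dendrogram")
}

#' @export
print.color_dendrogram <- function(x, ...) {
  cat(sprintf("color_dendrogram: %d leaves, %d merges, %s linkage\n",
              x$n, nrow(x$merges), x$linkage))
  print(x$merges)
  invisible(x)
}

# Leaf sets (0-based leaf ids) of every node, leaves then internal nodes.
node_members <- function(tree) {
  n <- tree$n
  members <- c(as.list(0:(n - 1L)), vector("list", n - 1L))
  for (m in seq_len(n - 1L)) {
    members[[n + m]] <- c(members[[tree$merges$left[m] + 1L]],
                          members[[tree$merges$right[m] + 1L]])
  }
  members
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` highest (last) merges and labels the connected
#' components. Labels are `0 .. k-1`, assigned in order of first
#' occurrence along the leaf order of the input.
#'
#' @param tree A `"color_dendrogram"`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster labels, named by leaf labels.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "color_dendrogram"))
  n <- tree$n
  if (k < 1 || k > n)
    stop_csa("k must be in [1, ", n, "]", class = "parameter_error")
  parent <- seq_len(2L * n - 1L)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (m in seq_len(n - k)) {
    node <- n + m
    parent[tree$merges$left[m] + 1L] <- node
    parent[tree$merges$right[m] + 1L] <- node
    # path-compress lazily via find()
  }
  roots <- vapply(seq_len(n), find, 0L)
  labels <- integer(n)
  seen <- integer(0)
  for (i in seq_len(n)) {
    pos <- match(roots[i], seen)
    if (is.na(pos)) { seen <- c(seen, roots[i]); pos <- length(seen) }
    labels[i] <- pos - 1L
  }
  names(labels) <- tree$labels
  labels
}

#' Cophenetic distance matrix of a dendrogram
#'
#' Entry `(i, j)` is the height of the lowest merge joining leaves `i` and
#' `j`. For any valid dendrogram with monotone heights the result is an
#' ultrametric: for every triple of leaves the maximum pairwise value is
#' attained at least twice.
#'
#' @param tree A `"color_dendrogram"`.
#' @return A `"color_dist"` whose values are cophenetic distances.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "color_dendrogram"))
  n <- tree$n
  members <- node_members(tree)
  values <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  for (m in seq_len(n - 1L)) {
    left <- members[[tree$merges$left[m] + 1L]] + 1L
    right <- members[[tree$merges$right[m] + 1L]] + 1L
    values[left, right] <- tree$merges$height[m]
    values[right, left] <- tree$merges$height[m]
  }
  structure(list(labels = tree$labels, values = values,
                 dialect = "cophenetic"),
            class = "color_dist")
}

#' Classify an unknown sample by nearest reference pattern
#'
#' Assigns a query response pattern the class of the reference pattern at
#' minimum color distance, the sensor-kit use of the array: once a
#' reference library of known chemicals has been measured, an unknown
#' exposure is read off by pattern matching. Ties are broken by reference
#' order. The distance is reported so callers can threshold it
#' ("no confident match").
#'
#' @param pattern Query: a `"response_pattern"`, numeric vector, or 1-row
#'   feature table compatible with the reference bins.
#' @param reference Feature table (data frame with `analyte_id` and bin
#'   columns) of known analytes.
#' @param classes Class label per reference row.
#' @param dialect Distance dialect, see [color_distance()].
#' @return List with `class`, `nearest` (reference analyte id) and
#'   `distance`.
#' @export
classify_unknown <- function(pattern, reference, classes,
                             dialect = c("squared", "euclidean")) {
  dialect <- match.arg(dialect)
  if (is.data.frame(pattern)) pattern <- feature_matrix(pattern)[1, ]
  refm <- feature_matrix(reference)
  if (nrow(refm) < 1)
    stop_csa("empty reference", class = "invalid_parameter")
  stopifnot(length(classes) == nrow(refm))
  dists <- vapply(seq_len(nrow(refm)), function(i)
    color_distance(pattern, refm[i, ], dialect), 0)
  best <- which.min(dists)   # first minimum = reference order tie-break
  list(class = classes[[best]], nearest = rownames(refm)[best],
       distance = dists[[best]])
}

#' Export a dendrogram as a Newick string
#'
#' Rooted Newick with branch lengths equal to the height drop from a
#' node's parent merge to the node (leaves sit at height 0), so root-to-
#' leaf path lengths equal the root merge height and the tree's cophenetic
#' structure is preserved. Labels containing Newick-reserved characters
#' are single-quoted.
#'
#' @param tree A `"color_dendrogram"`.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string terminated by `";"`.
#' @export
dendrogram_to_newick <- function(tree, digits = 12) {
  stopifnot(inherits(tree, "color_dendrogram"))
  n <- tree$n
  quote_label <- function(x) {
    if (grepl("[][ \t():;,']", x))
      paste0("'", gsub("'", "''", x), "'")
    else x
  }
  node_height <- function(id)
    if (id < n) 0 else tree$merges$height[id - n + 1L]
  render <- function(id, parent_height) {
    bl <- sprintf("%.*g", digits, parent_height - node_height(id))
    if (id < n)
      return(paste0(quote_label(tree$labels[id + 1L]), ":", bl))
    m <- id - n + 1L
    paste0("(", render(tree$merges$left[m], node_height(id)), ",",
           render(tree$merges$right[m], node_height(id)), "):", bl)
  }
  root <- 2L * n - 2L
  m <- root - n + 1L
  h <- tree$merges$height[m]
  paste0("(", render(tree$merges$left[m], h), ",",
         render(tree$merges$right[m], h), ");")
}

#' Convert to a base-R hclust object
#'
#' Allows plotting and interoperation with the `stats` dendrogram
#' toolchain.
#'
#' @param x A `"color_dendrogram"`.
#' @param ... Unused.
#' @return An object of class `"hclust"`.
#' @export
as.hclust.color_dendrogram <- function(x, ...) {
  n <- x$n
  to_hc <- function(id) if (id < n) -(id + 1L) else id - n + 1L
  merge <- cbind(vapply(x$merges$left, to_hc, 0L),
                 vapply(x$merges$right, to_hc, 0L))
  # leaf order for crossing-free plotting: in-order traversal
  order_of <- function(id) {
    if (id < n) return(id + 1L)
    m <- id - n + 1L
    c(order_of(x$merges$left[m]), order_of(x$merges$right[m]))
  }
  structure(list(merge = merge, height = x$merges$height,
                 order = order_of(2L * n - 2L), labels = x$labels,
                 method = x$linkage, call = match.call(),
                 dist.method = "color_distance"),
            class = "hclust")
}

#' Write the merge table of a dendrogram as CSV
#'
#' @param tree A `"color_dendrogram"`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_merges_csv <- function(tree, path) {
  stopifnot(inherits(tree, "color_dendrogram"))
  utils::write.csv(tree$merges, path, row.names = FALSE)
  invisible(path)
}
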