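# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (loops, enumeration) and
# never call the package's production code paths.

# Brute-force color distance: explicit loop over bins and channels.
oracle_color_distance <- function(bins_a, bins_b, dialect = "squared") {
  total <- 0
  for (i in seq_len(nrow(bins_a)))
    for (ch in 1:3)
      total <- total + (bins_a[i, ch] - bins_b[i, ch])^2
  if (dialect == "euclidean") sqrt(total) else total
}

# From-scratch Ward agglomeration on raw coordinates: at every step,
# evaluate the ESS increment of every candidate pair of current clusters
# (ESS = total squared deviation from the cluster centroid) and merge the
# minimum. Lance-Williams ward_d on squared-Euclidean input distances
# yields heights equal to 2x these increments (for singletons x, y the
# increment is |x - y|^2 / 2 while the input distance is |x - y|^2), so
# callers compare heights against 2 * increment.
oracle_ward_ess <- function(points) {
  ess <- function(rows) {
    if (length(rows) <= 1) return(0)
    m <- points[rows, , drop = FALSE]
    ctr <- colMeans(m)
    sum(sweep(m, 2, ctr)^2)
  }
  clusters <- as.list(seq_len(nrow(points)))
  merges <- data.frame(left = integer(0), right = integer(0),
                       increment = numeric(0))
  ids <- 0:(nrow(points) - 1L)
  next_id <- nrow(points)
  while (length(clusters) > 1) {
    best <- NULL; best_inc <- Inf
    for (i in seq_len(length(clusters) - 1L))
      for (j in seq.int(i + 1L, length(clusters))) {
        inc <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (inc < best_inc) { best_inc <- inc; best <- c(i, j) }
      }
    i <- best[1]; j <- best[2]
    merges <- rbind(merges, data.frame(left = ids[i], right = ids[j],
                                       increment = best_inc))
    merged <- c(clusters[[i]], clusters[[j]])
    keep <- setdiff(seq_along(clusters), best)
    clusters <- c(clusters[keep], list(merged))
    ids <- c(ids[keep], next_id)
    next_id <- next_id + 1L
  }
  merges
}

# Brute-force single linkage: inter-cluster distance = min pairwise leaf
# distance, recomputed from the original matrix at every step.
oracle_single_linkage <- function(dm) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  ids <- 0:(n - 1L)
  heights <- numeric(0)
  next_id <- n
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (i in seq_len(length(clusters) - 1L))
      for (j in seq.int(i + 1L, length(clusters))) {
        d <- min(dm[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    keep <- setdiff(seq_along(clusters), best)
    clusters <- c(clusters[keep], list(merged))
    ids <- c(ids[keep], next_id); next_id <- next_id + 1L
  }
  heights
}

# Lowest-common-ancestor search on the merge list for cophenetic checks.
oracle_cophenetic <- function(tree) {
  n <- tree$n
  members <- c(as.list(0:(n - 1L)), vector("list", n - 1L))
  for (m in seq_len(n - 1L))
    members[[n + m]] <- c(members[[tree$merges$left[m] + 1L]],
                          members[[tree$merges$right[m] + 1L]])
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    for (m in seq_len(n - 1L)) {
      mem <- members[[n + m]]
      if ((i - 1L) %in% mem && (j - 1L) %in% mem) {
        out[i, j] <- out[j, i] <- tree$merges$height[m]
        break
      }
    }
  }
  out
}

# Random response-pattern bins (n bins x 3 channels) in [-255, 255].
random_bins <- function(n_bins) {
  matrix(runif(n_bins * 3, -255, 255), n_bins, 3,
         dimnames = list(paste0("bin", seq_len(n_bins)),
                         c("R", "G", "B")))
}

# Small scenario (2 analytes x 2 temperatures) for fast pipeline tests.
tiny_scenario <- function(noise_sd = 0, seed = 42) {
  synthetic_scenario(
    analyte_ids = c("E2", "TET"),
    class_labels = c("estrogen", "antibiotic"),
    temperatures_c = c(30, 120),
    noise_sd = noise_sd, seed = seed)
}
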