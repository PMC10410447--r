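# Independent oracles used to freeze expected values: exhaustive DTW path
# enumeration, naive O(F^3) average linkage, a Gotoh global-alignment
# reimplementation, exact Mann-Whitney enumeration, brute-force histograms
# and distances.

# all monotone contiguous index paths from (1,1) to (la,lb); memoized by
# shape since the same shapes recur across random pairs
.path_cache <- new.env(parent = emptyenv())
enumerate_paths <- function(la, lb) {
  key <- paste(la, lb)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  grow <- function(path) {
    i <- path[nrow(path), 1]; j <- path[nrow(path), 2]
    if (i == la && j == lb) return(list(path))
    out <- list()
    if (i < la && j < lb) out <- c(out, grow(rbind(path, c(i + 1, j + 1))))
    if (i < la) out <- c(out, grow(rbind(path, c(i + 1, j))))
    if (j < lb) out <- c(out, grow(rbind(path, c(i, j + 1))))
    out
  }
  res <- grow(matrix(c(1, 1), 1))
  .path_cache[[key]] <- res
  res
}

# minimum total cost over every enumerated monotone path
oracle_dtw_total_cost <- function(cost) {
  paths <- enumerate_paths(nrow(cost), ncol(cost))
  min(vapply(paths, function(p) sum(cost[p]), numeric(1)))
}

# the residue-residue squared-deviation cost matrix for two anchored loops
# (a already superposed onto b), recomputed from first principles
oracle_cost_matrix <- function(a_bb, b_bb) {
  la <- nrow(a_bb) / 4; lb <- nrow(b_bb) / 4
  cost <- matrix(0, la, lb)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      ra <- a_bb[(4 * i - 3):(4 * i), , drop = FALSE]
      rb <- b_bb[(4 * j - 3):(4 * j), , drop = FALSE]
      cost[i, j] <- sum((ra - rb)^2)
    }
  }
  cost
}

# naive average-linkage agglomeration: merge heights in merge order
oracle_avg_linkage_heights <- function(dm) {
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (i in 1:(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- mean(dm[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Gotoh global alignment score with affine gaps (open charged on the first
# gap position in addition to extend), same scoring as the package:
# match +5, mismatch -4, open 10, extend 1
oracle_nw_score <- function(a, b, match = 5, mismatch = -4, open = 10,
                            ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1); E <- H; Fm <- H
  H[1, 1] <- 0
  for (i in 2:(n + 1)) { E[i, 1] <- NEG; Fm[i, 1] <- -open - ext * (i - 1); H[i, 1] <- Fm[i, 1] }
  for (j in 2:(m + 1)) { Fm[1, j] <- NEG; E[1, j] <- -open - ext * (j - 1); H[1, j] <- E[1, j] }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - ext, H[i, j - 1] - open - ext)
      Fm[i, j] <- max(Fm[i - 1, j] - ext, H[i - 1, j] - open - ext)
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      H[i, j] <- max(H[i - 1, j - 1] + s, E[i, j], Fm[i, j])
    }
  }
  H[n + 1, m + 1]
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x); pooled <- c(x, y); N <- length(pooled)
  r <- rank(pooled)
  u_of <- function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(N, n1), 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# brute-force cross-distance histogram with left-closed bins
oracle_rdf_counts <- function(a, b, edges) {
  nb <- length(edges) - 1
  counts <- numeric(nb)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      for (k in seq_len(nb)) {
        if (d >= edges[k] && d < edges[k + 1]) { counts[k] <- counts[k] + 1; break }
      }
    }
  }
  counts
}

oracle_min_distance <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    }
  }
  best
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
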