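# OPTICS density-based ordering (Ankerst et al. style) with xi cluster
# extraction. Used to pick out the dense group of genuinely apposed cluster
# pairs in (centroid distance, shell intensity) feature space. Implemented
# here because no installed package provides OPTICS; O(n^2) on a full
# distance matrix, which is ample for per-volume cluster counts.

#' OPTICS ordering
#'
#' Computes the density-based ordering of points together with core and
#' reachability distances (eps = Inf).
#'
#' @param x numeric matrix (points in rows).
#' @param min_samples neighborhood size defining core distance (the point
#'   itself counts, as is conventional).
#' @return list with `order` (visit order, indices into rows of `x`),
#'   `reachability` and `core` (per point, `Inf` where undefined).
#' @export
optics_order <- function(x, min_samples = 5L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= 1, min_samples >= 2)
  d <- as.matrix(stats::dist(x))
  core <- apply(d, 1, function(row) sort(row)[min_samples])  # incl. self (0)
  if (min_samples > n) core <- rep(Inf, n)
  reach <- rep(Inf, n)
  processed <- rep(FALSE, n)
  order_out <- integer(n)
  for (step in seq_len(n)) {
    cand <- which(!processed)
    p <- cand[which.min(reach[cand])]  # all-Inf -> first unprocessed (new start)
    processed[p] <- TRUE
    order_out[step] <- p
    if (is.finite(core[p])) {
      newreach <- pmax(core[p], d[p, ])
      upd <- !processed & newreach < reach
      reach[upd] <- newreach[upd]
    }
  }
  list(order = order_out, reachability = reach, core = core)
}

# maximal steep area starting at `i` (index into steep step indicator),
# tolerating up to min_samples-1 consecutive non-steep (but monotone) steps
extend_steep_area <- function(i, steep, mono, min_samples) {
  n <- length(steep)
  end <- i
  nonsteep <- 0L
  j <- i + 1L
  while (j <= n) {
    if (steep[j]) {
      end <- j
      nonsteep <- 0L
    } else if (mono[j]) {
      nonsteep <- nonsteep + 1L
      if (nonsteep >= min_samples) break
    } else break
    j <- j + 1L
  }
  end
}

#' Extract xi clusters from an OPTICS ordering
#'
#' Steep-area cluster extraction: a cluster is a valley in the reachability
#' plot bounded by a steep-down and a steep-up area, where "steep" means a
#' relative drop/rise of at least `xi`.
#'
#' @param reachability reachability values of [optics_order()] (per point).
#' @param order the visit order of [optics_order()].
#' @param xi steepness threshold in (0, 1).
#' @param min_samples used for steep-area gaps and minimum cluster size.
#' @param min_cluster_size minimum number of points in a reported cluster.
#' @return integer vector of cluster labels per point (0 = unclustered);
#'   nested clusters are resolved to the smallest containing cluster.
#' @export
optics_xi <- function(reachability, order, xi = 0.05, min_samples = 5L,
                      min_cluster_size = min_samples) {
  n <- length(order)
  r0 <- reachability[order]
  big <- if (any(is.finite(r0))) max(r0[is.finite(r0)]) * 2 + 1 else 1
  r0[!is.finite(r0)] <- big
  r <- c(r0, big)                      # sentinel terminates trailing valley
  m <- n                               # number of steps r[i] -> r[i+1]
  sdown <- r[1:m] * (1 - xi) >= r[2:(m + 1)]
  sup <- r[1:m] <= r[2:(m + 1)] * (1 - xi)
  down <- r[1:m] >= r[2:(m + 1)]
  up <- r[1:m] <= r[2:(m + 1)]

  clusters <- list()
  sdas <- list()                       # steep-down areas: list(start, end, mib)
  mib <- 0
  i <- 1L
  while (i <= m) {
    if (sdown[i]) {
      # filter and update existing areas
      sdas <- Filter(function(a) r[a$start] * (1 - xi) >= mib, sdas)
      sdas <- lapply(sdas, function(a) { a$mib <- max(a$mib, mib); a })
      end <- extend_steep_area(i, sdown, down, min_samples)
      sdas[[length(sdas) + 1]] <- list(start = i, end = end, mib = 0)
      i <- end + 1L
      mib <- r[i]
    } else if (sup[i]) {
      sdas <- Filter(function(a) r[a$start] * (1 - xi) >= mib, sdas)
      sdas <- lapply(sdas, function(a) { a$mib <- max(a$mib, mib); a })
      endU <- extend_steep_area(i, sup, up, min_samples)
      for (a in sdas) {
        # valley must be deeper than both shoulders by factor (1 - xi)
        if (a$mib > r[endU + 1] * (1 - xi)) next
        s <- a$start
        e <- endU
        if (r[s] * (1 - xi) >= r[endU + 1]) {
          cand <- which(r[a$start:a$end] > r[endU + 1])
          if (length(cand)) s <- a$start + max(cand) - 1L
        } else if (r[endU + 1] * (1 - xi) >= r[s]) {
          cand <- which(r[i:endU] < r[s])
          if (length(cand)) e <- i + min(cand) - 2L
        }
        if (e - s + 1 >= min_cluster_size && s < e)
          clusters[[length(clusters) + 1]] <- c(s, e)
      }
      i <- endU + 1L
      mib <- r[i]
    } else {
      mib <- max(mib, r[i + 1])
      i <- i + 1L
    }
  }

  labels <- integer(n)
  if (length(clusters)) {
    # assign smallest containing cluster: apply large-to-small
    sizes <- vapply(clusters, function(cl) cl[2] - cl[1], 0)
    for (ci in order(sizes, decreasing = TRUE)) {
      cl <- clusters[[ci]]
      labels[cl[1]:cl[2]] <- ci
    }
  }
  out <- integer(n)
  out[order] <- labels
  out
}
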