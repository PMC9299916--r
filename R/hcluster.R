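#' Agglomerative complete-linkage clustering of MoAs
#'
#' Joins MoAs hierarchically, most similar first. At every step the two
#' clusters with the smallest complete-linkage distance — the distance
#' between their most dissimilar members (furthest neighbours) — are merged
#' and the merge height recorded. Complete linkage favours compact clusters
#' of small diameter and is monotone: merge heights never decrease.
#'
#' Ties at equal linkage distance are broken deterministically by the
#' lexicographically smallest (left label, right label) pair, where a
#' cluster is labelled by its lexicographically smallest member.
#'
#' @param d symmetric distance matrix with zero diagonal and non-negative
#'   entries (e.g. [to_distance()] of a proximity matrix), or a
#'   [stats::dist] object. At least 2 items.
#' @return An object of class `moa_dendrogram`: a list with elements
#'   * `leaves` — item labels in input order;
#'   * `merge` — (M-1) x 2 integer matrix in [stats::hclust] convention
#'     (negative = leaf index, positive = earlier merge step);
#'   * `height` — merge heights, non-decreasing;
#'   * `members` — per step, the two member-label sets joined
#'     (`left`/`right`, left = cluster with the smaller representative
#'     label).
#' @examples
#' dend <- agglomerate(to_distance(table1_proximity()))
#' dend$members[[1]]  # first pair merged
#' @seealso [cut_dendrogram()], [agglomeration_schedule()], [select_k()]
#' @export
agglomerate <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("`d` must be a square distance matrix", call. = FALSE)
  }
  M <- nrow(d)
  if (M < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  if (any(diag(d) != 0)) stop("distance diagonal must be zero", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12, check.attributes = FALSE))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- sprintf("item%02d", seq_len(M))

  # live cluster state, positionally indexed; a merge collapses two
  # positions into the left one
  active <- rep(TRUE, M)
  reps <- labels                 # lexicographically smallest member
  code <- -seq_len(M)            # hclust merge coding
  members <- as.list(labels)
  D <- d
  diag(D) <- Inf

  merge <- matrix(0L, M - 1L, 2L)
  height <- numeric(M - 1L)
  step_members <- vector("list", M - 1L)

  for (s in seq_len(M - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    dmin <- min(sub)
    hit <- which(sub == dmin & upper.tri(sub), arr.ind = TRUE)
    # candidate pairs as (smaller rep, larger rep); pick lexicographic min
    cand_i <- idx[hit[, 1L]]
    cand_j <- idx[hit[, 2L]]
    li <- pmin(reps[cand_i], reps[cand_j])
    ri <- pmax(reps[cand_i], reps[cand_j])
    pick <- order(li, ri, method = "radix")[1L]
    a <- cand_i[pick]; b <- cand_j[pick]
    if (reps[b] < reps[a]) { tmp <- a; a <- b; b <- tmp }  # a = left

    merge[s, ] <- c(code[a], code[b])
    height[s] <- dmin
    step_members[[s]] <- list(left = members[[a]], right = members[[b]])

    # complete-linkage update: distance to the union is the max
    others <- setdiff(which(active), c(a, b))
    D[a, others] <- D[others, a] <- pmax(D[a, others], D[b, others])
    members[[a]] <- c(members[[a]], members[[b]])
    reps[a] <- min(reps[a], reps[b])
    code[a] <- s
    active[b] <- FALSE
  }

  structure(list(leaves = labels, merge = merge, height = height,
                 members = step_members),
            class = "moa_dendrogram")
}

#' @export
print.moa_dendrogram <- function(x, ...) {
  M <- length(x$leaves)
  cat(sprintf("moa_dendrogram: %d leaves, %d merges (complete linkage)\n",
              M, M - 1L))
  for (s in seq_len(min(3L, M - 1L))) {
    cat(sprintf("  step %d (h = %.3f): {%s} + {%s}\n", s, x$height[s],
                paste(x$members[[s]]$left, collapse = ","),
                paste(x$members[[s]]$right, collapse = ",")))
  }
  if (M - 1L > 3L) cat("  ...\n")
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' Returns the partition existing after exactly M - k merges. Cluster
#' indices are contiguous 1..k, numbered by the lexicographic order of each
#' cluster's smallest member label, so the output is deterministic.
#'
#' @param dend a `moa_dendrogram`.
#' @param k number of clusters, between 1 and the number of leaves.
#' @return named integer vector: cluster index per leaf, in leaf order.
#' @examples
#' dend <- agglomerate(to_distance(table1_proximity()))
#' split(names(cut_dendrogram(dend, 3)), cut_dendrogram(dend, 3))
#' @export
cut_dendrogram <- function(dend, k) {
  stopifnot(inherits(dend, "moa_dendrogram"))
  M <- length(dend$leaves)
  if (k < 1L || k > M) stop("`k` must be between 1 and ", M, call. = FALSE)
  grp <- seq_len(M)                 # union-find by direct relabel
  for (s in seq_len(M - k)) {
    pair <- dend$merge[s, ]
    ids <- vapply(pair, function(p) {
      if (p < 0L) grp[-p] else grp[match_step_leaf(dend, p)]
    }, integer(1))
    grp[grp == ids[2L]] <- ids[1L]
  }
  # contiguous ids ordered by smallest member label
  reps <- vapply(split(dend$leaves, grp), min, character(1))
  newid <- setNames(seq_along(reps), names(reps)[order(reps, method = "radix")])
  out <- newid[as.character(grp)]
  setNames(as.integer(out), dend$leaves)
}

# leaf index of one member of the cluster formed at merge step p
match_step_leaf <- function(dend, p) {
  repeat {
    q <- dend$merge[p, 1L]
    if (q < 0L) return(-q)
    p <- q
  }
}

#' Agglomeration schedule
#'
#' For each cluster count k from M-1 down to 1, the agglomeration
#' coefficient: the merge height (on the 1 - Jaccard scale) of the merge
#' that reduced the tree to k clusters. Plotting coefficient against k is
#' the elbow diagnostic used to pick the number of clusters.
#'
#' @param dend a `moa_dendrogram`.
#' @return data.frame with columns `k` and `coefficient`, rows in merge
#'   order (k descending).
#' @export
agglomeration_schedule <- function(dend) {
  stopifnot(inherits(dend, "moa_dendrogram"))
  M <- length(dend$leaves)
  data.frame(k = M - seq_len(M - 1L), coefficient = dend$height)
}

#' Cluster-number selection rule
#'
#' @param method `"balanced_no_singleton"` (default): among the candidate
#'   cuts whose clusters contain no singleton, pick the one with the most
#'   balanced cluster sizes (largest min/max size ratio) — a formalization
#'   of choosing "similarly sized clusters, none of a single item" by eye.
#'   `"max_gap"`: the textbook elbow — pick the k with the largest drop in
#'   the agglomeration coefficient between k-1 and k clusters.
#' @param k_range integer vector of candidate k (default 2:5).
#' @return object of class `selection_rule`.
#' @export
selection_rule <- function(method = c("balanced_no_singleton", "max_gap"),
                           k_range = 2:5) {
  method <- match.arg(method)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L)) stop("k_range must start at 2 or above",
                              call. = FALSE)
  structure(list(method = method, k_range = k_range),
            class = "selection_rule")
}

#' Select the number of clusters
#'
#' Applies a [selection_rule()] to a dendrogram. Ties are resolved in favour
#' of the smaller k (the more parsimonious clustering). If no candidate cut
#' is singleton-free, `balanced_no_singleton` falls back to `max_gap` with a
#' warning.
#'
#' @param dend a `moa_dendrogram` with at least 3 leaves.
#' @param rule a [selection_rule()].
#' @return list of class `k_selection` with elements `k` (chosen), `method`
#'   (rule actually applied), and `diagnostics`: per-candidate scores —
#'   `gap` table (k, coefficient drop) and `balance` table (k, min/max
#'   cluster size, balance ratio, singleton flag).
#' @export
select_k <- function(dend, rule = selection_rule()) {
  stopifnot(inherits(dend, "moa_dendrogram"), inherits(rule, "selection_rule"))
  M <- length(dend$leaves)
  if (M < 3L) stop("need at least 3 leaves to select k", call. = FALSE)
  k_range <- rule$k_range[rule$k_range <= M - 1L]
  if (length(k_range) == 0L) stop("k_range outside 2..M-1", call. = FALSE)

  sched <- agglomeration_schedule(dend)
  coef_of <- function(k) sched$coefficient[match(k, sched$k)]
  gap_tab <- data.frame(k = k_range,
                        gap = coef_of(k_range - 1L) - coef_of(k_range))

  parts <- lapply(k_range, function(k) cut_dendrogram(dend, k))
  sizes <- lapply(parts, function(p) as.integer(table(p)))
  bal_tab <- data.frame(
    k = k_range,
    min_size = vapply(sizes, min, integer(1)),
    max_size = vapply(sizes, max, integer(1)),
    balance = vapply(sizes, function(s) min(s) / max(s), numeric(1)),
    has_singleton = vapply(sizes, function(s) any(s == 1L), logical(1)))

  method <- rule$method
  if (method == "balanced_no_singleton") {
    ok <- !bal_tab$has_singleton
    if (!any(ok)) {
      warning("every candidate cut contains a singleton cluster; ",
              "falling back to max_gap", call. = FALSE)
      method <- "max_gap"
    } else {
      cand <- bal_tab[ok, , drop = FALSE]
      k <- cand$k[order(-cand$balance, cand$k)][1L]
    }
  }
  if (method == "max_gap") {
    k <- gap_tab$k[order(-gap_tab$gap, gap_tab$k)][1L]
  }
  structure(list(k = as.integer(k), method = method,
                 diagnostics = list(gap = gap_tab, balance = bal_tab)),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("selected k = %d (%s)\n", x$k, x$method))
  print(x$diagnostics$balance)
  invisible(x)
}

#' Convert to an hclust object
#'
#' @param x a `moa_dendrogram`.
#' @param ... unused.
#' @return a [stats::hclust] object (enables base dendrogram plotting).
#' @export
as.hclust.moa_dendrogram <- function(x, ...) {
  M <- length(x$leaves)
  ord <- integer(0)
  walk <- function(p) {
    if (p < 0L) return(-p)
    c(walk(x$merge[p, 1L]), walk(x$merge[p, 2L]))
  }
  ord <- walk(M - 1L)
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$leaves, method = "complete",
                 call = match.call(), dist.method = "jaccard"),
            class = "hclust")
}

#' @export
plot.moa_dendrogram <- function(x, ylab = "1 - Jaccard similarity",
                                main = "Complete-linkage clustering of MoAs",
                                ...) {
  plot(as.hclust.moa_dendrogram(x), ylab = ylab, main = main, ...)
  invisible(x)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are merge-height differences, so the root-to-leaf path
#' length of every leaf equals the final merge height (an ultrametric tree).
#'
#' @param dend a `moa_dendrogram`.
#' @param path optional file to write the tree to (one line, terminated
#'   by `;`).
#' @return the Newick string, invisibly if `path` is given.
#' @export
as_newick <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "moa_dendrogram"))
  M <- length(dend$leaves)
  node_h <- function(p) if (p < 0L) 0 else dend$height[p]
  build <- function(p, parent_h) {
    if (p < 0L) {
      lab <- gsub("[,;:() \t]", "_", dend$leaves[-p])
      return(sprintf("%s:%.10g", lab, parent_h))
    }
    h <- dend$height[p]
    kids <- vapply(dend$merge[p, ], build, character(1), parent_h = h)
    inner <- sprintf("(%s,%s)", kids[1L], kids[2L])
    if (is.na(parent_h)) inner else sprintf("%s:%.10g", inner, parent_h - h)
  }
  nwk <- paste0(build(M - 1L, NA_real_), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Plot the elbow diagnostic
#'
#' Agglomeration coefficient against number of clusters, with the selected
#' k marked.
#'
#' @param dend a `moa_dendrogram`.
#' @param selection optional `k_selection` to mark.
#' @param ... passed to [graphics::plot()].
#' @return the schedule data.frame, invisibly.
#' @export
plot_schedule <- function(dend, selection = NULL, ...) {
  sched <- agglomeration_schedule(dend)
  plot(sched$k, sched$coefficient, type = "b", pch = 19,
       xlab = "number of clusters", ylab = "agglomeration coefficient", ...)
  if (!is.null(selection)) abline(v = selection$k, lty = 3)
  invisible(sched)
}
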