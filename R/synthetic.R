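#' Configuration for the synthetic resistance-matrix generator
#'
#' The generator emulates a consolidated resistance database extract: ~10
#' MoAs, ~100 multi-resistant species, a right-skewed per-species MoA-count
#' distribution (median 3, a few extreme generalists resistant to 8+ MoAs),
#' planted MoA clusters, and a per-MoA prevalence gradient. Species are
#' assigned a home cluster and draw their MoAs mostly from it
#' (`p_within`) with occasional cross-cluster picks (`p_between`), each pick
#' weighted by the MoA's prevalence weight.
#'
#' @param n_clusters number of planted MoA clusters.
#' @param moas_per_cluster integer vector of cluster sizes; its sum is the
#'   total number of MoAs.
#' @param n_species number of species to simulate.
#' @param p_within probability that each MoA pick comes from the species'
#'   home cluster.
#' @param p_between probability of a cross-cluster pick; must equal
#'   `1 - p_within`.
#' @param moa_count_distribution probabilities over MoA counts 1, 2, ...;
#'   must sum to 1. The default has median 3 and ~2.5% mass at 8 or more.
#' @param prevalence_weights positive per-MoA sampling weights (recycled to
#'   the total MoA count); a gradient here yields a prevalence gradient in
#'   the output.
#' @param monocot_fraction probability a species is a monocot (else dicot).
#' @param seed integer seed; the single source of randomness for
#'   [generate_incidence()].
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_clusters = 3L,
                             moas_per_cluster = c(4L, 3L, 3L),
                             n_species = 110L,
                             p_within = 0.8,
                             p_between = 1 - p_within,
                             moa_count_distribution =
                               c(0.08, 0.30, 0.27, 0.15, 0.08,
                                 0.05, 0.045, 0.012, 0.008, 0.005),
                             prevalence_weights =
                               c(5, 3.5, 3, 2.5, 1.5, 1.2, 1, 1, 0.8, 0.8),
                             monocot_fraction = 0.45,
                             seed = 42L) {
  n_clusters <- as.integer(n_clusters)
  moas_per_cluster <- as.integer(moas_per_cluster)
  if (length(moas_per_cluster) != n_clusters || any(moas_per_cluster < 1L)) {
    stop("`moas_per_cluster` must give a positive size for each of the ",
         n_clusters, " cluster(s)", call. = FALSE)
  }
  n_moas <- sum(moas_per_cluster)
  if (any(c(p_within, p_between, monocot_fraction) < 0) ||
      any(c(p_within, p_between, monocot_fraction) > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(p_within + p_between - 1) > 1e-8) {
    stop("p_within + p_between must equal 1", call. = FALSE)
  }
  if (abs(sum(moa_count_distribution) - 1) > 1e-8 ||
      any(moa_count_distribution < 0)) {
    stop("moa_count_distribution must be a probability vector",
         call. = FALSE)
  }
  prevalence_weights <- rep_len(as.numeric(prevalence_weights), n_moas)
  if (any(prevalence_weights <= 0)) {
    stop("prevalence_weights must be positive", call. = FALSE)
  }
  if (n_species < 1L) stop("n_species must be >= 1", call. = FALSE)
  structure(list(n_clusters = n_clusters,
                 moas_per_cluster = moas_per_cluster,
                 n_species = as.integer(n_species),
                 p_within = p_within, p_between = p_between,
                 moa_count_distribution = moa_count_distribution,
                 prevalence_weights = prevalence_weights,
                 monocot_fraction = monocot_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# run expr under the config seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic incidence matrix with known structure
#'
#' For each species: draw its MoA count m from `moa_count_distribution`,
#' draw a home cluster (probability proportional to the cluster's share of
#' the prevalence weights), then pick m distinct MoAs — each pick from the
#' remaining home-cluster MoAs with probability `p_within`, otherwise from
#' the remaining MoAs of other clusters, always weighted by
#' `prevalence_weights`. When one pool is exhausted the other is used,
#' unless its selection probability is zero, in which case the species
#' stops accumulating MoAs (so with `p_between = 0` every species' MoA set
#' stays inside its home cluster, truncating its count at the cluster
#' size).
#' Growth form is monocot with probability `monocot_fraction`, else dicot.
#' The same config and seed always produce the identical matrix.
#'
#' @param config a [synthetic_config()].
#' @return list with elements
#'   * `matrix` — the [incidence_matrix] (MoA rows `g01`, `g02`, ...;
#'     species columns `Species 0001`, ...); MoA rows that no species
#'     picked (possible for tiny `n_species`) are dropped with a message;
#'   * `truth` — ground truth: `partition` (MoA -> planted cluster),
#'     `home_cluster` (species -> cluster), `prevalence` (realized per-MoA
#'     species counts), `dropped_moas`, and the `config`.
#' @examples
#' sim <- generate_incidence(synthetic_config(n_species = 50, seed = 1))
#' sim$matrix
#' @export
generate_incidence <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_moas <- sum(config$moas_per_cluster)
  moa_ids <- sprintf("g%02d", seq_len(n_moas))
  cluster_of_moa <- rep(seq_len(config$n_clusters),
                        times = config$moas_per_cluster)
  names(cluster_of_moa) <- moa_ids
  w <- config$prevalence_weights
  cluster_w <- tapply(w, cluster_of_moa, sum)

  dist_p <- config$moa_count_distribution
  counts_support <- seq_along(dist_p)
  truncated <- FALSE

  with_local_seed(config$seed, {
    n <- config$n_species
    m_raw <- sample(counts_support, n, replace = TRUE, prob = dist_p)
    if (any(m_raw > n_moas)) truncated <- TRUE
    m <- pmin(m_raw, n_moas)
    home <- sample(seq_len(config$n_clusters), n, replace = TRUE,
                   prob = cluster_w)
    gf <- ifelse(stats::runif(n) < config$monocot_fraction,
                 "monocot", "dicot")

    cells <- matrix(0L, n_moas, n)
    for (s in seq_len(n)) {
      taken <- logical(n_moas)
      for (pick in seq_len(m[s])) {
        in_home <- cluster_of_moa == home[s] & !taken
        out_home <- cluster_of_moa != home[s] & !taken
        use_home <- stats::runif(1) < config$p_within
        pool <- if (use_home) in_home else out_home
        if (!any(pool)) {
          # fall back to the other pool only when it has positive
          # selection probability; with p_between = 0 a species never
          # leaves its home cluster (its count truncates instead)
          other_p <- if (use_home) config$p_between else config$p_within
          if (other_p <= 0) break
          pool <- if (use_home) out_home else in_home
        }
        cand <- which(pool)
        picked <- if (length(cand) == 1L) cand else
          cand[sample.int(length(cand), 1L, prob = w[cand])]
        taken[picked] <- TRUE
      }
      cells[taken, s] <- 1L
    }
  })
  if (truncated) {
    warning("some drawn MoA counts exceeded the number of MoAs (",
            n_moas, "); truncated", call. = FALSE)
  }

  species <- sprintf("Species %04d", seq_len(config$n_species))
  dimnames(cells) <- list(moa_ids, species)
  empty <- rowSums(cells) == 0L
  dropped <- moa_ids[empty]
  if (any(empty)) {
    message("dropping ", sum(empty), " MoA row(s) no species picked: ",
            paste(dropped, collapse = ", "))
    cells <- cells[!empty, , drop = FALSE]
  }
  mat <- incidence_matrix(cells, growth_form = setNames(gf, species))
  truth <- list(partition = cluster_of_moa[rownames(cells)],
                home_cluster = setNames(home, species),
                prevalence = rowSums(cells),
                dropped_moas = dropped,
                config = config)
  list(matrix = mat, truth = truth)
}

#' Named scenario presets for the generator
#'
#' * `paperlike` — 10 MoAs in three planted clusters of sizes 4/3/3, 110
#'   species, within-cluster preference 0.8, a prevalence gradient, median
#'   MoA count 3: the scale of a consolidated real-world extract.
#' * `prevalence_driven` — a single undifferentiated cluster with strongly
#'   skewed prevalence weights: co-occurrence structure arises from
#'   prevalence alone.
#' * `similarity_driven` — three tight clusters (`p_within` 0.95) with
#'   uniform prevalence: structure arises from shared-target similarity
#'   alone.
#'
#' @return named list of [synthetic_config()] objects.
#' @export
scenario_presets <- function() {
  list(
    paperlike = synthetic_config(seed = 42L),
    prevalence_driven = synthetic_config(
      n_clusters = 1L, moas_per_cluster = 10L, n_species = 500L,
      p_within = 1, p_between = 0,
      prevalence_weights = c(12, 9, 7, 5, 4, 3, 2, 1.5, 1, 0.8),
      seed = 42L),
    similarity_driven = synthetic_config(
      n_clusters = 3L, moas_per_cluster = c(4L, 3L, 3L), n_species = 300L,
      p_within = 0.95, p_between = 0.05,
      prevalence_weights = rep(1, 10),
      seed = 42L))
}

#' Write generator ground truth as JSON
#'
#' @param truth the `truth` element returned by [generate_incidence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(partition = as.list(truth$partition),
         home_cluster = as.list(truth$home_cluster),
         prevalence = as.list(truth$prevalence),
         dropped_moas = truth$dropped_moas,
         config = unclass(truth$config)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read / write a generator configuration as YAML
#'
#' @param config a [synthetic_config()].
#' @param path YAML file path.
#' @return `path` invisibly (writer); a `synthetic_config` (reader).
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(synthetic_config, vals)
}
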