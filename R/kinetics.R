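# Telomere length kinetics: matrix assembly, hierarchical clustering,
# intra-cluster distance statistic, permutation significance and
# sub-cluster validation.

streak_cols <- function(df) {
  grep("^streak_[0-9]+$", names(df), value = TRUE)
}

kinetics_to_matrix <- function(kinetics) {
  cols <- streak_cols(kinetics)
  if (!length(cols)) {
    abort("no streak_* columns found in the kinetics table",
          class = "telka_error_input")
  }
  m <- as.matrix(kinetics[cols])
  rownames(m) <- kinetics$mutant
  storage.mode(m) <- "double"
  m
}

#' Assemble a relative-length kinetics matrix
#'
#' Per-streak telomere lengths of each mutant are divided by the wild-type
#' reference to give dimensionless relative lengths. Mutants must cover at
#' least `min_streaks` of the `n_streaks` streaks with no more than
#' `max_gap` consecutive missing streaks; qualifying gaps are filled by
#' linear interpolation between flanking streaks (edge gaps by the nearest
#' observed value), and mutants failing the rule are excluded with a
#' warning naming them.
#'
#' @param measurements Long tibble/data frame with columns `mutant`,
#'   `streak` (1-based integer) and `length_bp` (> 0).
#' @param wt_reference A positive scalar wild-type length, or a data frame
#'   with columns `streak` and `length_bp` giving a per-streak reference.
#' @param n_streaks Number of streaks spanned by a complete trajectory.
#' @param min_streaks Minimum observed streaks per mutant.
#' @param max_gap Maximum run of consecutive missing streaks to interpolate.
#' @return A kinetics tibble: `mutant`, `streak_1 .. streak_<n_streaks>`.
#' @export
build_kinetics_matrix <- function(measurements, wt_reference,
                                  n_streaks = 9, min_streaks = 7,
                                  max_gap = 2) {
  if (is.null(measurements) || !nrow(measurements)) {
    abort("no measurements supplied", class = "telka_error_input")
  }
  req <- c("mutant", "streak", "length_bp")
  if (!all(req %in% names(measurements))) {
    abort("measurements need columns mutant, streak, length_bp",
          class = "telka_error_input")
  }
  if (any(measurements$length_bp <= 0, na.rm = TRUE)) {
    abort("telomere lengths must be positive", class = "telka_error_input")
  }
  if (is.numeric(wt_reference) && length(wt_reference) == 1L) {
    wt <- rep(as.numeric(wt_reference), n_streaks)
  } else if (is.data.frame(wt_reference)) {
    wt <- rep(NA_real_, n_streaks)
    wt[wt_reference$streak] <- wt_reference$length_bp
    if (anyNA(wt)) {
      abort("per-streak wild-type reference must cover every streak",
            class = "telka_error_input")
    }
  } else {
    abort("wt_reference must be a scalar or a (streak, length_bp) table",
          class = "telka_error_input")
  }
  if (any(wt <= 0)) {
    abort("wild-type reference lengths must be positive",
          class = "telka_error_input")
  }
  mutants <- unique(measurements$mutant)
  rows <- list(); dropped <- character()
  for (m in mutants) {
    sub <- measurements[measurements$mutant == m, ]
    x <- rep(NA_real_, n_streaks)
    ok <- sub$streak >= 1 & sub$streak <= n_streaks & !is.na(sub$length_bp)
    x[sub$streak[ok]] <- sub$length_bp[ok]
    n_obs <- sum(!is.na(x))
    gap_max <- if (anyNA(x)) max(rle(is.na(x))$lengths[rle(is.na(x))$values]) else 0L
    if (n_obs < min_streaks || gap_max > max_gap) {
      dropped <- c(dropped, m)
      next
    }
    if (anyNA(x)) {
      x <- zoo::na.approx(x, x = seq_len(n_streaks), rule = 2)
    }
    rows[[m]] <- x / wt
  }
  if (length(dropped)) {
    warn(glue::glue("excluded mutant(s) with insufficient streak coverage: ",
                    "{paste(dropped, collapse = ', ')}"),
         class = "telka_warning_coverage")
  }
  if (!length(rows)) {
    abort("no mutant passed the streak-coverage rule",
          class = "telka_error_input")
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- paste0("streak_", seq_len(n_streaks))
  dplyr::bind_cols(tibble(mutant = names(rows)), as_tibble(mat))
}

# Flat cluster count from the merge-height profile: cut inside the largest
# relative (log-scale) jump between consecutive merge heights. Scale-free,
# so one distant cluster cannot swamp the separation between the others;
# ties break toward the smaller k.
choose_k_by_gap <- function(heights, n) {
  m <- length(heights)
  h_max <- max(heights)
  if (h_max <= .Machine$double.eps) return(1L)
  if (m == 1L) return(2L)
  eps <- h_max * 1e-9
  ratio <- (heights[-1] + eps) / (heights[-m] + eps)
  i <- max(which(ratio >= max(ratio) - 1e-12))  # ties -> larger i, smaller k
  as.integer(n - i)
}

#' Cluster telomere-length trajectories
#'
#' Agglomerative hierarchical clustering of the full trajectory vectors
#' (Euclidean distance, average linkage by default). The flat partition is
#' cut at the requested `k`, or, when `k` is `NULL`, inside the largest
#' relative gap between consecutive merge heights (see the methods
#' vignette for why the gap is taken on the log scale).
#'
#' @param kinetics A kinetics tibble (`mutant` + `streak_*` columns) from
#'   [build_kinetics_matrix()] or [simulate_kinetics()].
#' @param k Optional number of flat clusters.
#' @param method Linkage: `"average"` (default), `"complete"` or
#'   `"centroid"`.
#' @param scale Z-score each streak column before clustering (off by
#'   default: the values are already ratios on a common scale).
#' @return A `telka_clust` object; see [tidy()] / [glance()] methods.
#' @export
cluster_kinetics <- function(kinetics, k = NULL,
                             method = c("average", "complete", "centroid"),
                             scale = FALSE) {
  method <- match.arg(method)
  m <- kinetics_to_matrix(kinetics)
  if (nrow(m) < 2) {
    abort("need at least 2 trajectories to cluster",
          class = "telka_error_input")
  }
  if (!is.null(k) && (k < 1 || k > nrow(m))) {
    abort("k must be between 1 and the number of trajectories",
          class = "telka_error_input")
  }
  mm <- if (scale) base::scale(m) else m
  d <- dist(mm)
  hc <- hclust(d, method = method)
  k_use <- k %||% choose_k_by_gap(hc$height, nrow(m))
  labels <- cutree(hc, k = k_use)
  stat <- intra_cluster_statistic(kinetics, labels)
  structure(list(hclust = hc, dist = d,
                 labels = tibble(mutant = rownames(m),
                                 cluster = as.integer(labels)),
                 k = as.integer(k_use), statistic = stat,
                 kinetics = kinetics, method = method),
            class = "telka_clust")
}

#' @export
print.telka_clust <- function(x, ...) {
  cat(sprintf(
    "<telka_clust> %d trajectories, %s linkage, k = %d, intra-cluster statistic = %.4g\n",
    nrow(x$labels), x$method, x$k, x$statistic))
  invisible(x)
}

#' Intra-cluster distance statistic
#'
#' Sum over clusters of all within-cluster pairwise Euclidean distances
#' between trajectory vectors. Zero iff every cluster is a singleton or a
#' set of identical points.
#'
#' @param kinetics A kinetics tibble or numeric matrix.
#' @param labels Integer/character cluster label per row.
#' @return A nonnegative number.
#' @export
intra_cluster_statistic <- function(kinetics, labels) {
  m <- if (is.matrix(kinetics)) kinetics else kinetics_to_matrix(kinetics)
  if (length(labels) != nrow(m)) {
    abort("labels must have one entry per trajectory",
          class = "telka_error_input")
  }
  D <- as.matrix(dist(m))
  s <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1) s <- s + sum(D[idx, idx]) / 2
  }
  s
}

#' Permutation test of cluster separation
#'
#' Compares the observed intra-cluster distance statistic with its
#' distribution over random reassignments of trajectories to clusters of
#' the same sizes (label permutations), computed on the cached pairwise
#' distance matrix. The add-one p-value `(1 + n_as_extreme)/(1 + n_perm)`
#' is used, so with one million permutations and none as extreme the
#' smallest reportable p is just below 1e-6.
#'
#' @param kinetics A kinetics tibble or numeric matrix.
#' @param labels Cluster label per row (e.g. `tidy(clust)$cluster`).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @param method `"labels"` (default): permute cluster labels, preserving
#'   cluster sizes. `"entries"`: shuffle matrix entries independently
#'   within each streak column and recompute the statistic for the same
#'   labels — a sensitivity analysis destroying trajectory structure.
#' @return A `telka_perm` object with `p_value`, `n_as_extreme`, `n_perm`,
#'   `statistic`, `seed`.
#' @export
permutation_test <- function(kinetics, labels, n_perm = 1e6, seed = 1L,
                             method = c("labels", "entries")) {
  method <- match.arg(method)
  m <- if (is.matrix(kinetics)) kinetics else kinetics_to_matrix(kinetics)
  if (length(labels) != nrow(m)) {
    abort("labels must have one entry per trajectory",
          class = "telka_error_input")
  }
  if (n_perm < 1) {
    abort("n_perm must be at least 1", class = "telka_error_input")
  }
  n_perm <- as.integer(n_perm)
  lab <- as.integer(factor(labels))
  if (method == "labels") {
    D <- as.matrix(dist(m))
    res <- withr::with_seed(as.integer(seed),
                            .perm_count_cpp(D, lab, n_perm))
    s_obs <- res$statistic
    n_le <- res$n_as_extreme
  } else {
    s_obs <- intra_cluster_statistic(m, lab)
    n_le <- withr::with_seed(as.integer(seed), {
      sum(vapply(seq_len(n_perm), function(i) {
        ms <- apply(m, 2, sample)
        intra_cluster_statistic(ms, lab) <= s_obs + 1e-9 * (1 + abs(s_obs))
      }, logical(1)))
    })
  }
  structure(list(statistic = s_obs, n_perm = n_perm,
                 n_as_extreme = as.numeric(n_le),
                 p_value = (1 + n_le) / (1 + n_perm),
                 seed = as.integer(seed), method = method),
            class = "telka_perm")
}

#' @export
print.telka_perm <- function(x, ...) {
  cat(sprintf(
    "<telka_perm> statistic = %.4g, %d permutations (%s), p = %.3g\n",
    x$statistic, x$n_perm, x$method, x$p_value))
  invisible(x)
}

# Selection-adjusted null for a data-derived split: refit the same
# clustering (same k) on column-shuffled copies of the sub-matrix and use
# the refitted statistic as the reference. See the methods vignette.
refit_null_p <- function(m, k, s_obs, n_perm, method) {
  s_perm <- vapply(seq_len(n_perm), function(i) {
    ms <- apply(m, 2, sample)
    hc <- hclust(dist(ms), method = method)
    intra_cluster_statistic(ms, cutree(hc, k = k))
  }, numeric(1))
  (1 + sum(s_perm <= s_obs + 1e-9 * (1 + abs(s_obs)))) / (1 + n_perm)
}

#' Iterative sub-clustering with permutation validation
#'
#' Each flat cluster with at least `min_size` members is re-clustered with
#' the gap-based cut; the split is retained only when it is statistically
#' supported at level `alpha`. By default the reference distribution
#' accounts for the fact that the tested sub-labels were fitted to the
#' same data: the clustering is refitted on column-shuffled copies
#' (`null = "refit"`). `null = "labels"` uses the plain label-permutation
#' test instead, which is anti-conservative for fitted splits (vignette).
#' Recursion depth is one.
#'
#' @param clust A `telka_clust` from [cluster_kinetics()].
#' @param alpha Significance level for keeping a split.
#' @param n_perm Permutations per tested cluster.
#' @param seed Integer seed.
#' @param min_size Smallest cluster considered for splitting.
#' @param null `"refit"` (default) or `"labels"`.
#' @return A `telka_subclust` object: `partition` tibble (`mutant`,
#'   `cluster`, `subcluster`) and `tests` tibble (`cluster`, `n`, `k_sub`,
#'   `p_value`, `retained`).
#' @export
iterate_subclusters <- function(clust, alpha = 0.01, n_perm = 1e4,
                                seed = 1L, min_size = 4,
                                null = c("refit", "labels")) {
  stopifnot(inherits(clust, "telka_clust"))
  null <- match.arg(null)
  kin <- clust$kinetics
  part <- clust$labels
  part$subcluster <- as.character(part$cluster)
  tests <- list()
  for (g in sort(unique(part$cluster))) {
    idx <- which(part$cluster == g)
    if (length(idx) < min_size) next
    sub_kin <- kin[match(part$mutant[idx], kin$mutant), ]
    sub <- cluster_kinetics(sub_kin, method = clust$method)
    if (sub$k < 2) next
    m <- kinetics_to_matrix(sub_kin)
    p <- if (null == "refit") {
      withr::with_seed(as.integer(seed) + g,
                       refit_null_p(m, sub$k, sub$statistic, n_perm,
                                    clust$method))
    } else {
      permutation_test(m, sub$labels$cluster, n_perm = n_perm,
                       seed = as.integer(seed) + g)$p_value
    }
    retained <- p < alpha
    tests[[length(tests) + 1L]] <- tibble(cluster = g, n = length(idx),
                                          k_sub = sub$k, p_value = p,
                                          retained = retained)
    if (retained) {
      part$subcluster[idx] <- paste0(g, ".", sub$labels$cluster)
    }
  }
  structure(list(partition = part,
                 tests = if (length(tests)) dplyr::bind_rows(tests)
                         else tibble(cluster = integer(), n = integer(),
                                     k_sub = integer(), p_value = numeric(),
                                     retained = logical())),
            class = "telka_subclust")
}

#' @export
print.telka_subclust <- function(x, ...) {
  cat(sprintf("<telka_subclust> %d trajectories, %d subcluster(s)\n",
              nrow(x$partition), length(unique(x$partition$subcluster))))
  if (nrow(x$tests)) print(x$tests)
  invisible(x)
}

#' Per-group mean trajectories
#'
#' @param kinetics A kinetics tibble.
#' @param labels Cluster label per row.
#' @return A long tibble: `cluster`, `streak`, `mean_rel_length`.
#' @export
group_mean_profiles <- function(kinetics, labels) {
  m <- kinetics_to_matrix(kinetics)
  if (length(labels) != nrow(m)) {
    abort("labels must have one entry per trajectory",
          class = "telka_error_input")
  }
  purrr::map_dfr(sort(unique(labels)), function(g) {
    mu <- colMeans(m[labels == g, , drop = FALSE])
    tibble(cluster = g,
           streak = as.integer(sub("streak_", "", names(mu))),
           mean_rel_length = unname(mu))
  })
}

#' @rdname cluster_kinetics
#' @param x A `telka_clust` object.
#' @param ... Unused.
#' @export
tidy.telka_clust <- function(x, ...) x$labels

#' @rdname cluster_kinetics
#' @export
glance.telka_clust <- function(x, ...) {
  tibble(n = nrow(x$labels), k = x$k, statistic = x$statistic,
         method = x$method)
}

#' @rdname permutation_test
#' @param x A `telka_perm` object.
#' @param ... Unused.
#' @export
glance.telka_perm <- function(x, ...) {
  tibble(statistic = x$statistic, n_perm = x$n_perm,
         n_as_extreme = x$n_as_extreme, p_value = x$p_value,
         seed = x$seed, method = x$method)
}

#' @rdname iterate_subclusters
#' @param x A `telka_subclust` object.
#' @param ... Unused.
#' @export
tidy.telka_subclust <- function(x, ...) x$partition
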