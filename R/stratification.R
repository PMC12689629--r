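# Cohort stratification by drug-exposure profile: hierarchical clustering
# of log-transformed summed peak areas, and non-parametric testing of
# downstream metabolite differences between exposure groups.

#' Exposure matrix from an exposure table
#'
#' @param et An `exposure_table` (long).
#' @param transform Applied to summed areas; default `log1p`
#'   (log-transformation accommodating zeros).
#' @return Numeric matrix, samples x drugs.
#' @export
exposure_matrix <- function(et, transform = log1p) {
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(et)[, c("sample_id", "parent_drug", "summed_area")],
    names_from = "parent_drug", values_from = "summed_area",
    values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  transform(m)
}

#' Cluster samples by exposure profile
#'
#' Agglomerative hierarchical clustering (Ward's linkage on Euclidean
#' distances) of the samples-by-drugs matrix of `log(1 + summed area)`,
#' cut into `k` groups. Cluster labels are renumbered by decreasing
#' cluster size so reports are reproducible.
#'
#' @param x An `exposure_table` or a numeric samples x drugs matrix
#'   (already transformed).
#' @param k Number of clusters (1 <= k <= number of samples).
#' @param method Linkage method for [stats::hclust()]; `"ward.D2"`
#'   implements Ward's criterion on Euclidean distances.
#' @param metric Distance metric for [stats::dist()].
#' @return A `cluster_assignment`: tibble with `sample_id` and `cluster`,
#'   carrying the `hclust` tree, `k`, `method`, and `metric` as attributes.
#' @export
cluster_samples <- function(x, k, method = "ward.D2", metric = "euclidean") {
  m <- if (inherits(x, "exposure_table")) exposure_matrix(x) else as.matrix(x)
  if (!all(is.finite(m))) stop("exposure matrix must be finite", call. = FALSE)
  n <- nrow(m)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n) {
    stop("`k` must satisfy 1 <= k <= number of samples (", n, ")",
         call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(m, method = metric), method = method)
  raw <- stats::cutree(hc, k = k)
  # contiguous labels 1..k ordered by decreasing cluster size
  # (ties broken by first appearance for determinism)
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- tibble::tibble(
    sample_id = if (is.null(rownames(m))) as.character(seq_len(n))
                else rownames(m),
    cluster = as.integer(relabel[as.character(raw)])
  )
  structure(out, class = c("cluster_assignment", class(out)),
            hclust = hc, k = as.integer(k), method = method, metric = metric)
}

#' Glance at a cluster assignment
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @return One-row tibble with `k`, `n_samples`, `method`, `metric`.
#' @method glance cluster_assignment
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble::tibble(k = attr(x, "k"), n_samples = nrow(x),
                 method = attr(x, "method"), metric = attr(x, "metric"))
}

#' Test a metabolite for differences across exposure clusters
#'
#' Kruskal-Wallis omnibus test across the clusters, followed by all
#' pairwise two-sided Wilcoxon rank-sum tests with Benjamini-Hochberg
#' adjustment over the pairwise family. Clusters with fewer than two
#' members are excluded with a warning.
#'
#' @param values Per-sample metabolite intensity: a numeric vector named
#'   by sample id, or a tibble with `sample_id` and `value`.
#' @param clusters A `cluster_assignment` (or tibble with `sample_id`,
#'   `cluster`).
#' @param exact Use the exact Wilcoxon distribution for small groups;
#'   default uses the normal approximation with tie correction.
#' @return A `group_diff_test` with [tidy()] (pairwise table) and
#'   [glance()] (omnibus) methods.
#' @export
group_difference_test <- function(values, clusters, exact = FALSE) {
  if (is.numeric(values)) {
    values <- tibble::tibble(sample_id = names(values), value = values)
  }
  df <- dplyr::inner_join(tibble::as_tibble(values),
                          tibble::as_tibble(clusters), by = "sample_id")
  sizes <- table(df$cluster)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding cluster(s) with fewer than 2 members: ",
            paste(small, collapse = ", "))
    df <- df[!(df$cluster %in% as.integer(small)), ]
  }
  groups <- sort(unique(df$cluster))
  if (length(groups) < 2) {
    stop("need at least 2 groups with >= 2 members", call. = FALSE)
  }
  kw <- stats::kruskal.test(df$value, factor(df$cluster))
  if (length(unique(df$value)) == 1L) {
    # all observations tied: no evidence of any difference
    kw$statistic[] <- 0
    kw$p.value <- 1
  }
  pairs <- utils::combn(groups, 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    w <- suppressWarnings(stats::wilcox.test(
      df$value[df$cluster == g1], df$value[df$cluster == g2],
      exact = exact, correct = TRUE))
    tibble::tibble(group1 = g1, group2 = g2, statistic = unname(w$statistic),
                   p_value = w$p.value)
  })
  pw$p_adjusted <- stats::p.adjust(pw$p_value, method = "BH")
  structure(list(omnibus = kw, pairwise = pw,
                 n = nrow(df), k = length(groups)),
            class = "group_diff_test")
}

#' @export
print.group_diff_test <- function(x, ...) {
  cat("<group_diff_test> Kruskal-Wallis chi-squared = ",
      format(unname(x$omnibus$statistic), digits = 4),
      ", df = ", unname(x$omnibus$parameter),
      ", p = ", format(x$omnibus$p.value, digits = 3), "\n", sep = "")
  print(x$pairwise)
  invisible(x)
}

#' Tidy the pairwise comparisons of a group-difference test
#' @param x A `group_diff_test`.
#' @param ... Unused.
#' @return Tibble of pairwise Wilcoxon results with BH-adjusted p-values.
#' @method tidy group_diff_test
#' @export
tidy.group_diff_test <- function(x, ...) x$pairwise

#' Glance at the omnibus result of a group-difference test
#' @param x A `group_diff_test`.
#' @param ... Unused.
#' @return One-row tibble with the Kruskal-Wallis statistic, df, p-value,
#'   sample count and group count.
#' @method glance group_diff_test
#' @export
glance.group_diff_test <- function(x, ...) {
  tibble::tibble(statistic = unname(x$omnibus$statistic),
                 df = unname(x$omnibus$parameter),
                 p_value = x$omnibus$p.value, n = x$n, k = x$k)
}

#' Pearson chi-square test of independence
#'
#' @param table An r x c contingency table (matrix of non-negative
#'   counts); no row or column may sum to zero.
#' @return One-row tibble with `statistic`, `df` = (r-1)(c-1), `p_value`,
#'   `n`.
#' @export
chi_square_independence <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: zero row or column marginal", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = ct$p.value, n = sum(m))
}
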