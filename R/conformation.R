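#' Pair interaction energy (PIE) matrix
#'
#' A rectangular conformations-by-fragments table of pair interaction
#' energies (kJ/mol) between a ligand and the fragments of a receptor/cofactor
#' complex. More negative values mean stronger attraction.
#'
#' @param values Numeric matrix (conformations x fragments), no missing cells.
#' @param conformation_ids Unique row ids; default `conf_1 ...`.
#' @param fragment_labels Unique column labels (residue name+number, cofactor
#'   fragment, ...); default `frag_1 ...`.
#' @return An object of class `pie_matrix` (a numeric matrix with dimnames).
#' @export
pie_matrix <- function(values, conformation_ids = NULL, fragment_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("PIE matrix must be numeric with no missing or non-finite cells",
         call. = FALSE)
  }
  if (is.null(conformation_ids)) {
    conformation_ids <- rownames(values)
    if (is.null(conformation_ids)) conformation_ids <- paste0("conf_", seq_len(nrow(values)))
  }
  if (is.null(fragment_labels)) {
    fragment_labels <- colnames(values)
    if (is.null(fragment_labels)) fragment_labels <- paste0("frag_", seq_len(ncol(values)))
  }
  if (length(conformation_ids) != nrow(values) || anyDuplicated(conformation_ids)) {
    stop("conformation_ids must be unique, one per row", call. = FALSE)
  }
  if (length(fragment_labels) != ncol(values) || anyDuplicated(fragment_labels)) {
    stop("fragment_labels must be unique, one per column", call. = FALSE)
  }
  dimnames(values) <- list(as.character(conformation_ids),
                           as.character(fragment_labels))
  structure(values, class = c("pie_matrix", "matrix", "array"))
}

#' Total PIE per conformation
#'
#' Sums the pair interaction energies over all fragments for each
#' conformation: the interaction energy between the ligand and the whole
#' receptor/cofactor complex.
#'
#' @param m A [pie_matrix()].
#' @return Named numeric vector, kJ/mol, one entry per conformation.
#' @export
total_pie_per_conformation <- function(m) {
  stopifnot(inherits(m, "pie_matrix"))
  rowSums(unclass(m))
}

#' Per-fragment PIE profile
#'
#' Sums (over selected conformations) the interaction energy contributed by
#' each fragment; used to rank residues and cofactor fragments by their
#' contribution to ligand binding.
#'
#' @param m A [pie_matrix()].
#' @param labels Optional per-conformation cluster labels (required when
#'   `cluster` is given).
#' @param cluster Optional cluster id: restrict the sum to that cluster's
#'   conformations.
#' @param average If `TRUE`, return the mean per fragment instead of the sum.
#' @return Named numeric vector, kJ/mol, one entry per fragment.
#' @export
fragment_pie_profile <- function(m, labels = NULL, cluster = NULL,
                                 average = FALSE) {
  stopifnot(inherits(m, "pie_matrix"))
  rows <- seq_len(nrow(m))
  if (!is.null(cluster)) {
    if (is.null(labels)) {
      stop("cluster labels must be supplied to subset by cluster", call. = FALSE)
    }
    if (length(labels) != nrow(m)) {
      stop("labels must have one entry per conformation", call. = FALSE)
    }
    rows <- which(labels == cluster)
    if (length(rows) == 0) {
      stop(sprintf("unknown cluster id '%s'", as.character(cluster)), call. = FALSE)
    }
  }
  x <- unclass(m)[rows, , drop = FALSE]
  if (average) colMeans(x) else colSums(x)
}

#' Cluster conformations by their PIE profiles
#'
#' Hierarchical agglomerative clustering of conformations, with each row's
#' feature vector its PIEs against all fragments, on Euclidean distances.
#' Ward linkage is the default; complete and average linkage are exposed. The
#' partition is taken from the dendrogram: by requested cluster count, by cut
#' height, or (default) at the largest relative gap in merge heights.
#'
#' @param m A [pie_matrix()].
#' @param n_clusters Optional number of clusters (>= 1, <= conformations).
#' @param cut_height Optional dendrogram cut height (energy distance).
#'   Give at most one of `n_clusters` / `cut_height`.
#' @param linkage One of "ward", "complete", "average".
#' @param max_auto_k Upper bound on the automatically chosen cluster count.
#' @return An object of class `cluster_result`: list with `labels` (integer
#'   per conformation, clusters numbered by first appearance),
#'   `per_conformation_total`, `per_cluster_stats` (data frame: cluster, n,
#'   mean, sd of totals), `linkage_info`, and the `hclust` tree. `letters` and
#'   `stable_ids` are `NULL` until filled by [tukey_kramer()] /
#'   [select_stable_clusters()] (see [identify_stable_conformations()]).
#' @export
cluster_conformations <- function(m, n_clusters = NULL, cut_height = NULL,
                                  linkage = c("ward", "complete", "average"),
                                  max_auto_k = 12L) {
  stopifnot(inherits(m, "pie_matrix"))
  linkage <- match.arg(linkage)
  n <- nrow(m)
  if (!is.null(n_clusters) && !is.null(cut_height)) {
    stop("give at most one of n_clusters / cut_height", call. = FALSE)
  }
  if (!is.null(n_clusters) && (n_clusters < 1 || n_clusters > n)) {
    stop("n_clusters must be between 1 and the number of conformations",
         call. = FALSE)
  }
  hc_method <- c(ward = "ward.D2", complete = "complete", average = "average")[linkage]
  tree <- stats::hclust(stats::dist(unclass(m), method = "euclidean"),
                        method = hc_method)

  if (!is.null(n_clusters)) {
    raw <- stats::cutree(tree, k = n_clusters)
    cut_spec <- list(rule = "n_clusters", k = as.integer(n_clusters))
  } else if (!is.null(cut_height)) {
    raw <- stats::cutree(tree, h = cut_height)
    cut_spec <- list(rule = "cut_height", h = cut_height)
  } else {
    k <- auto_cluster_count(tree$height, n, max_auto_k)
    raw <- stats::cutree(tree, k = k)
    cut_spec <- list(rule = "auto_gap", k = k)
  }
  # Renumber clusters by order of first appearance so the labelling is
  # deterministic under the documented tie rule (input order).
  labels <- match(raw, unique(raw))

  totals <- total_pie_per_conformation(m)
  stats_df <- per_cluster_stats(totals, labels)

  structure(list(labels = labels,
                 per_conformation_total = totals,
                 per_cluster_stats = stats_df,
                 letters = NULL,
                 stable_ids = NULL,
                 linkage_info = c(list(method = linkage,
                                       distance = "euclidean"), cut_spec),
                 tree = tree),
            class = "cluster_result")
}

# Pick the cluster count at the largest relative gap between consecutive
# merge heights (the dendrogram's most prominent "shoulder").
auto_cluster_count <- function(heights, n, max_k) {
  if (n <= 2L) return(n)
  h <- heights  # nondecreasing, length n - 1
  k_max <- min(max_k, n - 1L)
  # Cutting between merge j and j+1 yields n - j clusters; restrict to cuts
  # giving 2..k_max clusters, i.e. j in (n - k_max)..(n - 2).
  js <- seq.int(max(1L, n - k_max), n - 2L)
  eps <- 1e-12 * max(h, 1)
  ratio <- (h[js + 1L] + eps) / (h[js] + eps)
  n - js[which.max(ratio)]
}

per_cluster_stats <- function(totals, labels) {
  ids <- sort(unique(labels))
  data.frame(
    cluster = ids,
    n = vapply(ids, function(k) sum(labels == k), integer(1)),
    mean = vapply(ids, function(k) mean(totals[labels == k]), numeric(1)),
    sd = vapply(ids, function(k) stats::sd(totals[labels == k]), numeric(1))
  )
}

#' Tukey-Kramer all-pairs comparison of cluster energies
#'
#' Studentized-range comparison of group means valid for unequal group sizes:
#' with pooled within-group variance \eqn{s^2} on \eqn{N - k} degrees of
#' freedom, each pair (a, b) is tested with
#' \eqn{q = |\bar{x}_a - \bar{x}_b| / \sqrt{(s^2/2)(1/n_a + 1/n_b)}}
#' against the studentized range distribution with `k` groups. Two groups are
#' declared different when the adjusted p-value falls below `alpha`. A compact
#' letter display is built by insert-and-absorb so that two groups share a
#' letter iff their comparison is not rejected; letters are assigned in
#' ascending order of group means (most negative, i.e. strongest-binding,
#' first).
#'
#' @param groups Named list of numeric vectors (per-cluster total PIEs),
#'   at least 2 groups, each of size >= 2.
#' @param alpha Family-wise significance level.
#' @return A list of class `tukey_kramer` with `table` (data frame: cluster_a,
#'   cluster_b, mean_diff, q_statistic, p_adjusted, reject), `letters` (named
#'   character vector per group), `alpha`, `df`, `pooled_variance`.
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("tukey_kramer needs at least 2 groups", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- as.character(seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop("every group must contain at least 2 observations", call. = FALSE)
  }
  stop_if_not_scalar_num(alpha, "alpha", lower = 0, upper = 1,
                         allow_equal_lower = FALSE)
  k <- length(groups)
  N <- sum(sizes)
  means <- vapply(groups, mean, numeric(1))
  df <- N - k
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / df

  pairs <- utils::combn(names(groups), 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    diff <- means[a] - means[b]
    if (s2 > 0) {
      se <- sqrt((s2 / 2) * (1 / sizes[a] + 1 / sizes[b]))
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    } else {
      # Degenerate zero pooled variance: comparisons defined by exact mean
      # equality (unequal means are unambiguously different).
      q <- if (diff == 0) 0 else Inf
      p <- if (diff == 0) 1 else 0
    }
    data.frame(cluster_a = a, cluster_b = b, mean_diff = unname(diff),
               q_statistic = unname(q), p_adjusted = unname(p),
               reject = unname(p < alpha), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  letters_vec <- compact_letter_display(names(groups), means, tab)
  structure(list(table = tab, letters = letters_vec, alpha = alpha,
                 df = df, pooled_variance = s2),
            class = "tukey_kramer")
}

# Insert-and-absorb compact letter display: start from one letter covering
# all groups; for each rejected pair split every column containing both;
# absorb columns that became subsets. Letter order follows ascending mean.
compact_letter_display <- function(ids, means, table) {
  ord <- ids[order(means[ids])]
  columns <- list(ord)
  rejected <- table[table$reject, , drop = FALSE]
  for (r in seq_len(nrow(rejected))) {
    a <- rejected$cluster_a[r]
    b <- rejected$cluster_b[r]
    new_cols <- list()
    for (col in columns) {
      if (a %in% col && b %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop any column that is a subset of another
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) {
      for (j in seq_along(new_cols)) {
        if (i != j && keep[i] &&
            all(new_cols[[i]] %in% new_cols[[j]]) &&
            (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j)) {
          keep[i] <- FALSE
        }
      }
    }
    columns <- new_cols[keep]
  }
  # Order columns by the strongest (lowest-mean) group they contain, then
  # assign letters a, b, c, ...
  first_rank <- vapply(columns, function(col) min(match(col, ord)), numeric(1))
  columns <- columns[order(first_rank)]
  out <- stats::setNames(rep("", length(ids)), ids)
  for (i in seq_along(columns)) {
    lt <- letters[(i - 1L) %% 26L + 1L]
    if (i > 26L) lt <- paste0(lt, (i - 1L) %/% 26L)
    for (g in columns[[i]]) out[g] <- paste0(out[g], lt)
  }
  out[ord] <- out[ord]  # keep original name order in the returned vector
  out[ids]
}

#' Select the stable (strongest-binding) clusters
#'
#' The stable set is every cluster whose compact-letter set equals that of the
#' cluster with the most negative mean total PIE: the group of clusters
#' statistically indistinguishable from the strongest-binding one.
#'
#' @param result A [cluster_conformations()] result (or any object with a
#'   `per_cluster_stats` data frame).
#' @param letters Named character vector of compact letters per cluster
#'   (names matching `per_cluster_stats$cluster` as character).
#' @return Vector of stable cluster ids.
#' @export
select_stable_clusters <- function(result, letters) {
  stats_df <- result$per_cluster_stats
  ids <- as.character(stats_df$cluster)
  if (!all(ids %in% names(letters))) {
    stop("letters must be named by cluster id", call. = FALSE)
  }
  strongest <- ids[which.min(stats_df$mean)]
  target <- sort(strsplit(letters[[strongest]], "")[[1]])
  keep <- vapply(ids, function(i) {
    identical(sort(strsplit(letters[[i]], "")[[1]]), target)
  }, logical(1))
  stats_df$cluster[keep]
}

#' Full stable-conformation identification workflow
#'
#' Clusters a PIE matrix, runs the Tukey-Kramer comparison on per-cluster
#' total PIEs, attaches the compact letter display, and selects the stable
#' cluster set.
#'
#' @inheritParams cluster_conformations
#' @param alpha Family-wise significance level for the Tukey-Kramer test.
#' @return The [cluster_conformations()] result with `letters`, `stable_ids`,
#'   and `tukey` filled in.
#' @export
identify_stable_conformations <- function(m, n_clusters = NULL,
                                          cut_height = NULL,
                                          linkage = "ward", alpha = 0.05) {
  res <- cluster_conformations(m, n_clusters = n_clusters,
                               cut_height = cut_height, linkage = linkage)
  groups <- split(res$per_conformation_total, res$labels)
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop("Tukey-Kramer comparison needs >= 2 clusters with >= 2 conformations each; adjust the cut",
         call. = FALSE)
  }
  tk <- tukey_kramer(groups, alpha = alpha)
  res$letters <- tk$letters
  res$tukey <- tk
  res$stable_ids <- select_stable_clusters(res, tk$letters)
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("PIE clustering: %d conformations in %d clusters (%s linkage, %s)\n",
              length(x$labels), nrow(x$per_cluster_stats),
              x$linkage_info$method, x$linkage_info$rule))
  df <- x$per_cluster_stats
  if (!is.null(x$letters)) df$letter <- x$letters[as.character(df$cluster)]
  print(df, row.names = FALSE)
  if (!is.null(x$stable_ids)) {
    cat("Stable clusters:", paste(x$stable_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ligand binding energy from component energies
#'
#' \eqn{\Delta G_{bind} = E_{complex} - (E_{receptor} + E_{ligand})}, the
#' bookkeeping identity relating the energy of the bound complex to its
#' isolated components. All energies kJ/mol.
#'
#' @param e_complex Energy of the receptor/cofactor/ligand complex.
#' @param e_receptor Energy of the receptor/cofactor complex alone.
#' @param e_ligand Energy of the isolated ligand.
#' @return Binding energy, kJ/mol (negative = favourable).
#' @examples
#' delta_g_bind(-1000, -900, -6) # -94
#' @export
delta_g_bind <- function(e_complex, e_receptor, e_ligand) {
  for (nm in c("e_complex", "e_receptor", "e_ligand")) {
    x <- get(nm)
    if (!is.numeric(x) || any(!is.finite(x))) {
      stop(sprintf("`%s` must be finite numeric", nm), call. = FALSE)
    }
  }
  e_complex - (e_receptor + e_ligand)
}
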