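# Pre-modeling tests of participant homogeneity.

#' Asymptotic chi-square test of participant heterogeneity
#'
#' Tests, separately for each multinomial tree and summed over trees,
#' whether the individual category frequencies are consistent with a common
#' category distribution shared by all participants (items assumed
#' homogeneous).  For tree `t` with pooled proportions
#' `p_k = sum_p n_pk / sum_p n_pt`, the statistic is
#' `sum_p sum_k (n_pk - n_pt p_k)^2 / (n_pt p_k)` with
#' `df = (P - 1) * sum_t (K_t - 1)`.
#'
#' Categories whose pooled count is zero carry no information; they are
#' dropped with a warning and the degrees of freedom reduced accordingly.
#'
#' @param data An `mpt_data` object, or a counts matrix together with
#'   `tree`: a vector assigning each column to a tree.
#' @param tree Optional tree assignment (character or integer per column)
#'   when `data` is a plain matrix.
#' @return List of class `hmpt_homogeneity` with `statistic`, `df`,
#'   `p_value`, `method = "chisq"`.
#' @export
chisq_participant_heterogeneity <- function(data, tree = NULL) {
  if (inherits(data, "mpt_data")) {
    counts <- data$counts
    tree <- data$tree[colnames(counts)]
  } else {
    counts <- as.matrix(data)
    if (is.null(tree)) stop("supply 'tree' assignments for a plain matrix")
    if (length(tree) != ncol(counts)) stop("'tree' must match the columns")
  }
  P <- nrow(counts)
  if (P < 2L) stop("need at least two participants")
  stat <- 0
  df <- 0L
  for (t in unique(tree)) {
    sub <- counts[, tree == t, drop = FALSE]
    n_pt <- rowSums(sub)
    if (any(n_pt <= 0)) stop("all participants need responses in every tree")
    pooled <- colSums(sub) / sum(sub)
    if (any(pooled == 0)) {
      warning(sprintf("dropping %d zero-count category(ies) in tree '%s'",
                      sum(pooled == 0), t))
      sub <- sub[, pooled > 0, drop = FALSE]
      pooled <- pooled[pooled > 0]
    }
    expd <- outer(n_pt, pooled)
    stat <- stat + sum((sub - expd)^2 / expd)
    df <- df + (P - 1L) * (length(pooled) - 1L)
  }
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = "chisq", n_permutations = NULL),
            class = "hmpt_homogeneity")
}

#' @export
print.hmpt_homogeneity <- function(x, ...) {
  if (x$method == "chisq") {
    cat(sprintf("Chi-square test of participant heterogeneity\n  X2(%d) = %.4g, p = %.3g\n",
                x$df, x$statistic, x$p_value))
  } else {
    cat(sprintf("Permutation test of participant heterogeneity (%d permutations)\n  statistic = %.4g, p = %.3g\n",
                x$n_permutations, x$statistic, x$p_value))
  }
  invisible(x)
}

#' Construct long-format response data
#'
#' @param records Data frame with three columns: participant id, item id,
#'   response category (header optional when read from CSV).
#' @param tree_map Named list mapping each tree label to the character
#'   vector of its category labels.
#' @return Object of class `mpt_long`.
#' @export
as_mpt_long <- function(records, tree_map) {
  records <- as.data.frame(records)
  if (ncol(records) < 3L) stop("long data needs participant, item, response")
  names(records)[1:3] <- c("participant", "item", "response")
  cats <- unlist(tree_map, use.names = FALSE)
  if (anyDuplicated(cats)) stop("a category appears in more than one tree")
  unknown <- setdiff(unique(records$response), cats)
  if (length(unknown) > 0L) {
    stop("response(s) not covered by tree_map: ", paste(unknown, collapse = ", "))
  }
  structure(list(records = records, tree_map = tree_map), class = "mpt_long")
}

#' Read long-format response data from CSV
#'
#' @param path CSV path (3 columns: participant, item, response; a header
#'   row is auto-detected).
#' @inheritParams as_mpt_long
#' @export
read_long_csv <- function(path, tree_map) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           stringsAsFactors = FALSE)
  cats <- unlist(tree_map, use.names = FALSE)
  has_header <- !(as.character(first[[3]]) %in% cats)
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  as_mpt_long(df, tree_map)
}

# participant x category contingency table from long data
long_to_counts <- function(long) {
  cats <- unlist(long$tree_map, use.names = FALSE)
  tab <- table(factor(long$records$participant),
               factor(long$records$response, levels = cats))
  counts <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  tree <- rep(names(long$tree_map), lengths(long$tree_map))
  names(tree) <- cats
  list(counts = counts, tree = tree[colnames(counts)])
}

#' Permutation test of participant heterogeneity
#'
#' Computes the chi-square heterogeneity statistic from the
#' participant-by-category table, then generates its null distribution by
#' independently permuting, for each item, the observed responses across the
#' participants who responded to that item.  This preserves item margins and
#' therefore remains valid when items are heterogeneous.  The p value uses
#' the add-one estimator `(1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @param data An `mpt_long` object.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return `hmpt_homogeneity` with `method = "permutation"`.
#' @export
permutation_participant_heterogeneity <- function(data, n_perm = 1000,
                                                 seed = 1) {
  if (!inherits(data, "mpt_long")) stop("'data' must be an mpt_long object")
  if (n_perm < 1) stop("n_perm must be >= 1")
  rec <- data$records
  if (anyDuplicated(rec[, c("participant", "item")])) {
    stop("each (participant, item) pair may appear at most once")
  }
  obs_tab <- long_to_counts(data)
  obs <- chisq_participant_heterogeneity(obs_tab$counts, tree = obs_tab$tree)
  item_split <- split(seq_len(nrow(rec)), rec$item)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      resp <- rec$response
      for (idx in item_split) {
        if (length(idx) > 1L) resp[idx] <- resp[sample(idx)]
      }
      prec <- rec
      prec$response <- resp
      tab <- long_to_counts(list(records = prec, tree_map = data$tree_map))
      chisq_participant_heterogeneity(tab$counts, tree = tab$tree)$statistic
    }, numeric(1))
  })
  p <- (1 + sum(perm_stats >= obs$statistic)) / (1 + n_perm)
  structure(list(statistic = obs$statistic, df = NULL, p_value = p,
                 method = "permutation", n_permutations = n_perm,
                 null_statistics = perm_stats),
            class = "hmpt_homogeneity")
}

#' Per-category frequency summaries (boxplot data)
#'
#' Returns, for every category, the quartiles, whiskers (1.5 IQR rule) and
#' mean of the individual frequencies -- the numbers behind a box plot of
#' individual against mean frequencies.
#'
#' @param data An `mpt_data` object.
#' @param relative If `TRUE`, frequencies are divided by the participant's
#'   per-tree total first.
#' @return Data frame with one row per category: `category`, `tree`, `mean`,
#'   `lower_whisker`, `q1`, `median`, `q3`, `upper_whisker`.
#' @export
frequency_summary <- function(data, relative = FALSE) {
  counts <- data$counts
  tree <- data$tree[colnames(counts)]
  if (relative) {
    for (t in unique(tree)) {
      sel <- tree == t
      counts[, sel] <- counts[, sel, drop = FALSE] /
        rowSums(counts[, sel, drop = FALSE])
    }
  }
  out <- lapply(seq_len(ncol(counts)), function(k) {
    x <- counts[, k]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lw <- min(x[x >= q[1] - 1.5 * iqr])
    uw <- max(x[x <= q[3] + 1.5 * iqr])
    data.frame(category = colnames(counts)[k], tree = tree[k], mean = mean(x),
               lower_whisker = lw, q1 = q[1], median = q[2], q3 = q[3],
               upper_whisker = uw, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
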