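# Branch/category probabilities and the product-multinomial likelihood.

# Compile an mpt_model into dense arrays for vectorized evaluation:
#   A, B: n_branches x S exponent matrices; logc: branch log-constants;
#   cat_of_branch: category index per branch; M: branch->category indicator;
#   cat_tree: tree label per category; tree_index: category -> tree number.
# Cached inside the model object's environment-free list on first use.
compile_mpt <- function(model) {
  if (!is.null(attr(model, "compiled"))) return(attr(model, "compiled"))
  S <- length(model$params)
  nb <- length(model$branches)
  K <- nrow(model$categories)
  A <- matrix(0L, nb, S, dimnames = list(NULL, model$params))
  B <- matrix(0L, nb, S, dimnames = list(NULL, model$params))
  logc <- numeric(nb)
  cat_of_branch <- integer(nb)
  for (i in seq_len(nb)) {
    br <- model$branches[[i]]
    if (length(br$a)) A[i, names(br$a)] <- br$a
    if (length(br$b)) B[i, names(br$b)] <- br$b
    logc[i] <- log(br$c)
    cat_of_branch[i] <- match(br$category, model$categories$category)
  }
  M <- matrix(0, nb, K)
  M[cbind(seq_len(nb), cat_of_branch)] <- 1
  cat_tree <- setNames(model$categories$tree, model$categories$category)
  list(A = A, B = B, logc = logc, cat_of_branch = cat_of_branch, M = M,
       cat_tree = cat_tree, K = K, S = S)
}

#' Probability of a single MPT branch
#'
#' Computes `c * prod_s theta_s^a_s * (1-theta_s)^b_s` for one branch.
#'
#' @param theta_row Named numeric vector of parameter values in (0,1).
#' @param branch One element of `model$branches`.
#' @return The branch probability.
#' @export
branch_probability <- function(theta_row, branch) {
  refs <- union(names(branch$a), names(branch$b))
  unknown <- setdiff(refs, names(theta_row))
  if (length(unknown) > 0L) {
    stop("branch references unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  }
  p <- branch$c
  for (s in names(branch$a)) p <- p * theta_row[[s]]^branch$a[[s]]
  for (s in names(branch$b)) p <- p * (1 - theta_row[[s]])^branch$b[[s]]
  unname(p)
}

#' Category probabilities for one or more parameter vectors
#'
#' Evaluates the per-category probabilities (the sum of branch probabilities
#' terminating in each category) for each row of a participant-by-parameter
#' matrix.  Within each tree the probabilities sum to 1.
#'
#' @param theta Numeric matrix (participants x parameters, columns named) or
#'   a single named vector.
#' @param model An `mpt_model`.
#' @return Matrix (participants x categories) with category labels as column
#'   names.
#' @export
category_probabilities <- function(theta, model) {
  cm <- compile_mpt(model)
  if (is.null(dim(theta))) {
    theta <- matrix(theta, nrow = 1,
                    dimnames = list(NULL, names(theta)))
  }
  if (is.null(colnames(theta))) {
    if (ncol(theta) != cm$S) stop("theta has wrong number of columns")
    colnames(theta) <- model$params
  }
  missing <- setdiff(model$params, colnames(theta))
  if (length(missing) > 0L) {
    stop("theta lacks parameter column(s): ", paste(missing, collapse = ", "))
  }
  th <- clip01(theta[, model$params, drop = FALSE])
  logp <- log(th) %*% t(cm$A) + log1p(-th) %*% t(cm$B)
  pb <- exp(sweep(logp, 2L, cm$logc, "+"))
  out <- pb %*% cm$M
  colnames(out) <- model$categories$category
  out
}

#' Construct an aligned participant-by-category frequency table
#'
#' Aligns a counts matrix/data frame to the category order of a model by
#' column name (never by position) and validates it.
#'
#' @param counts Matrix or data frame of non-negative integer counts with
#'   category labels as column names.  A leading non-numeric column is
#'   treated as participant identifiers.
#' @param model An `mpt_model`.
#' @return An object of class `mpt_data`: list with `counts` (P x K matrix,
#'   columns in model category order), `ids`, and `tree` (tree label per
#'   column).
#' @export
as_mpt_data <- function(counts, model) {
  ids <- NULL
  if (is.data.frame(counts)) {
    if (ncol(counts) > 0 && !is.numeric(counts[[1]]) &&
        !(names(counts)[1] %in% model$categories$category)) {
      ids <- as.character(counts[[1]])
      counts <- counts[, -1, drop = FALSE]
    }
    counts <- as.matrix(counts)
  }
  storage.mode(counts) <- "double"
  if (is.null(colnames(counts))) stop("counts must have category column names")
  unmatched <- setdiff(model$categories$category, colnames(counts))
  extra <- setdiff(colnames(counts), model$categories$category)
  if (length(unmatched) > 0L || length(extra) > 0L) {
    stop(sprintf("category labels do not match the model; missing: [%s], unexpected: [%s]",
                 paste(unmatched, collapse = ", "),
                 paste(extra, collapse = ", ")))
  }
  counts <- counts[, model$categories$category, drop = FALSE]
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(counts)))
  structure(list(counts = counts, ids = ids,
                 tree = setNames(model$categories$tree,
                                 model$categories$category)),
            class = "mpt_data")
}

#' Read a frequency CSV (header = category labels, one row per participant)
#'
#' A non-numeric first column is auto-detected as participant identifiers.
#'
#' @param path CSV file path.
#' @param model An `mpt_model` used for alignment.
#' @return An `mpt_data` object.
#' @export
read_freq_csv <- function(path, model) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_mpt_data(df, model)
}

#' Product-multinomial log-likelihood
#'
#' `sum_p sum_k n_pk log P(C_k | theta_p)`; the multinomial coefficient,
#' constant in theta, is omitted.  Theta values are clipped `1e-9` away from
#' the boundary before the log so the result is always finite.
#'
#' @param theta P x S matrix of individual parameters (columns named).
#' @param data An `mpt_data` object (or counts matrix aligned to the model).
#' @param model An `mpt_model`.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(theta, data, model) {
  if (!inherits(data, "mpt_data")) data <- as_mpt_data(data, model)
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1,
                                           dimnames = list(NULL, names(theta)))
  if (nrow(theta) != nrow(data$counts)) {
    stop("theta and counts disagree on the number of participants")
  }
  p <- category_probabilities(theta, model)
  sum(data$counts * log(pmax(p, 1e-300)))
}

# per-participant log-likelihood vector (internal, used by samplers)
log_likelihood_rows <- function(theta, counts, model) {
  p <- category_probabilities(theta, model)
  rowSums(counts * log(pmax(p, 1e-300)))
}

#' Expected category frequencies
#'
#' Multiplies the per-tree item counts by the expected category
#' probabilities.
#'
#' @param theta P x S matrix of individual parameters.
#' @param items_per_tree Named vector/list mapping each tree label to its
#'   number of items.
#' @param model An `mpt_model`.
#' @return P x K matrix of expected frequencies.
#' @export
expected_frequencies <- function(theta, items_per_tree, model) {
  items_per_tree <- unlist(items_per_tree)
  missing <- setdiff(model$trees, names(items_per_tree))
  if (length(missing) > 0L) {
    stop("items_per_tree lacks tree(s): ", paste(missing, collapse = ", "))
  }
  if (any(items_per_tree[model$trees] <= 0)) {
    stop("items_per_tree must be positive")
  }
  p <- category_probabilities(theta, model)
  n_per_cat <- items_per_tree[model$categories$tree]
  sweep(p, 2L, n_per_cat, "*")
}
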