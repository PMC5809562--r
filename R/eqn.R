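#' Parse an MPT model from EQN text
#'
#' Reads a multinomial processing tree (MPT) model in the EQN interchange
#' format shared with other MPT software.  The first line of the file is
#' always treated as a comment and skipped; additional lines starting with
#' `#` are skipped as well.  Every remaining non-blank line defines one
#' branch as three whitespace-separated fields: tree label, category label,
#' and the branch equation.  Equations are products of parameter symbols
#' `p`, complement factors `(1-p)`, and numeric constants; the `*`
#' separator is optional around parentheses.
#'
#' Each branch is stored as a constant `c` (the product of all numeric
#' factors) together with integer exponent maps `a` and `b` counting the
#' occurrences of each parameter and of its complement, so the branch
#' probability is `c * prod(theta^a * (1-theta)^b)`.
#'
#' @param text Character scalar (entire file content) or character vector of
#'   lines.
#' @return An object of class `mpt_model` with elements `trees` (tree labels
#'   in order of appearance), `categories` (data frame with columns
#'   `category`, `tree`), `branches` (list of branch records), and `params`
#'   (sorted free parameter names).
#' @seealso [read_eqn()], [apply_restrictions()], [validate_model()]
#' @export
parse_eqn <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- as.character(text)
  }
  if (length(lines) < 2L) {
    stop("EQN input needs a comment line plus at least one branch line")
  }
  lines <- lines[-1L]  # first line is always a comment
  branches <- list()
  cat_tree <- character(0)  # category -> tree
  cat_order <- character(0)
  tree_order <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("EQN line %d: expected 'tree category equation', got '%s'",
                   i + 1L, ln))
    }
    tree <- fields[1]
    categ <- fields[2]
    eq <- paste(fields[-(1:2)], collapse = "")
    br <- parse_branch_equation(eq, line = i + 1L)
    br$tree <- tree
    br$category <- categ
    if (categ %in% names(cat_tree)) {
      if (cat_tree[[categ]] != tree) {
        stop(sprintf("category '%s' appears in trees '%s' and '%s'",
                     categ, cat_tree[[categ]], tree))
      }
    } else {
      cat_tree[[categ]] <- tree
      cat_order <- c(cat_order, categ)
    }
    if (!(tree %in% tree_order)) tree_order <- c(tree_order, tree)
    branches[[length(branches) + 1L]] <- br
  }
  if (length(branches) == 0L) stop("EQN input contains no branch lines")
  params <- sort(unique(unlist(lapply(branches, function(b)
    union(names(b$a), names(b$b))))))
  if (length(params) < 1L) stop("model declares no free parameters")
  structure(
    list(trees = tree_order,
         categories = data.frame(category = cat_order,
                                 tree = unname(cat_tree[cat_order]),
                                 stringsAsFactors = FALSE),
         branches = branches,
         params = params),
    class = "mpt_model")
}

# Tokenize one branch equation into (constant, exponent maps).
# Accepts products of: symbol, (1-symbol), numeric constant; '*' optional.
parse_branch_equation <- function(eq, line = NA_integer_) {
  stripped <- gsub("[[:space:]]", "", eq)
  pat <- paste0(
    "\\(1-[A-Za-z_][A-Za-z0-9_.]*\\)",           # (1-p)
    "|[A-Za-z_][A-Za-z0-9_.]*",                  # p
    "|[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?")       # numeric constant
  bad <- function() stop(sprintf("malformed branch equation '%s'%s", eq,
                                 if (is.na(line)) ""
                                 else sprintf(" at line %d", line)))
  pieces <- strsplit(stripped, "*", fixed = TRUE)[[1]]
  if (length(pieces) == 0L || any(pieces == "")) bad()
  toks <- unlist(lapply(pieces, function(pc) {
    tk <- regmatches(pc, gregexpr(pat, pc))[[1]]
    if (length(tk) == 0L || paste(tk, collapse = "") != pc) bad()
    tk
  }))
  cc <- 1
  a <- integer(0)
  b <- integer(0)
  for (tk in toks) {
    if (grepl("^\\(1-", tk)) {
      p <- sub("^\\(1-", "", sub("\\)$", "", tk))
      b[p] <- if (p %in% names(b)) b[[p]] + 1L else 1L
    } else if (grepl("^[A-Za-z_]", tk)) {
      a[tk] <- if (tk %in% names(a)) a[[tk]] + 1L else 1L
    } else {
      val <- as.numeric(tk)
      if (!is.finite(val) || val <= 0 || val > 1) {
        stop(sprintf("numeric constant %s outside (0,1] in equation '%s'",
                     tk, eq))
      }
      cc <- cc * val
    }
  }
  list(c = cc, a = a, b = b)
}

#' Read an MPT model from an EQN file
#'
#' @param path Path to an EQN model file.
#' @return An `mpt_model`; see [parse_eqn()].
#' @export
read_eqn <- function(path) {
  parse_eqn(readLines(path, warn = FALSE))
}

#' @export
print.mpt_model <- function(x, ...) {
  cat(sprintf("MPT model: %d tree(s), %d categories, %d branches, %d parameter(s)\n",
              length(x$trees), nrow(x$categories), length(x$branches),
              length(x$params)))
  cat("Parameters:", paste(x$params, collapse = ", "), "\n")
  invisible(x)
}

#' Parse parameter restrictions
#'
#' Restrictions are chains `p1 = p2 = ... [= constant]`, one per element (or
#' per line of a file read with [readLines()]).  A numeric right-most element
#' fixes every parameter in the chain to that constant; otherwise the chain
#' forms an equality class collapsed to its first-listed name.
#'
#' @param source Character vector of restriction chains, or a list of such
#'   strings.
#' @param model Optional `mpt_model`; when given, all referenced parameter
#'   names are validated against `model$params`.
#' @return An object of class `mpt_restrictions`: list with
#'   `equality_classes` (list of character vectors, first element is the
#'   representative) and `constants` (named numeric vector).
#' @export
parse_restrictions <- function(source, model = NULL) {
  entries <- trimws(unlist(source, use.names = FALSE))
  entries <- entries[entries != "" & !startsWith(entries, "#")]
  classes <- list()
  constants <- numeric(0)
  for (e in entries) {
    parts <- trimws(strsplit(e, "=", fixed = TRUE)[[1]])
    if (length(parts) < 2L || any(parts == "")) {
      stop(sprintf("malformed restriction '%s'", e))
    }
    is_num <- suppressWarnings(!is.na(as.numeric(parts)))
    if (any(is_num[-length(parts)]) && sum(is_num) >= 1L &&
        !all(which(is_num) == length(parts))) {
      if (sum(is_num) > 1L) {
        stop(sprintf("restriction '%s' contains more than one constant", e))
      }
      stop(sprintf("constant must be the last element of restriction '%s'", e))
    }
    if (is_num[length(parts)]) {
      val <- as.numeric(parts[length(parts)])
      if (val <= 0 || val >= 1) {
        stop(sprintf("constant %g in '%s' must lie strictly in (0,1)", val, e))
      }
      for (p in parts[-length(parts)]) constants[p] <- val
    } else {
      classes[[length(classes) + 1L]] <- parts
    }
  }
  # merge classes sharing a member
  merged <- list()
  for (cl in classes) {
    hit <- which(vapply(merged, function(m) any(cl %in% m), logical(1)))
    if (length(hit) == 0L) {
      merged[[length(merged) + 1L]] <- cl
    } else {
      keep <- unique(c(unlist(merged[hit]), cl))
      merged <- merged[-hit]
      merged[[length(merged) + 1L]] <- keep
    }
  }
  both <- intersect(unlist(merged), names(constants))
  if (length(both) > 0L) {
    stop("parameter(s) both in an equality class and fixed to a constant: ",
         paste(both, collapse = ", "))
  }
  r <- structure(list(equality_classes = merged, constants = constants),
                 class = "mpt_restrictions")
  if (!is.null(model)) {
    refs <- c(unlist(merged), names(constants))
    unknown <- setdiff(refs, model$params)
    if (length(unknown) > 0L) {
      stop(sprintf("unknown parameter(s) %s; model parameters are: %s",
                   paste(unknown, collapse = ", "),
                   paste(model$params, collapse = ", ")))
    }
  }
  r
}

#' Read restrictions from a text file (one chain per line)
#'
#' @inheritParams parse_restrictions
#' @param path Path to the restriction file.
#' @export
read_restrictions <- function(path, model = NULL) {
  parse_restrictions(readLines(path, warn = FALSE), model = model)
}

#' Apply parameter restrictions to an MPT model
#'
#' Equality classes rename all members to the class representative (the
#' first-listed name), accumulating exponents.  Constants are folded into
#' each branch's numeric constant, i.e. a factor `theta^a (1-theta)^b`
#' becomes `v^a (1-v)^b` absorbed into `c`.
#'
#' @param model An `mpt_model`.
#' @param restrictions An `mpt_restrictions` object (or input accepted by
#'   [parse_restrictions()]).
#' @return A new `mpt_model` with the reduced free-parameter set.
#' @export
apply_restrictions <- function(model, restrictions) {
  if (!inherits(restrictions, "mpt_restrictions")) {
    restrictions <- parse_restrictions(restrictions, model = model)
  } else {
    refs <- c(unlist(restrictions$equality_classes),
              names(restrictions$constants))
    unknown <- setdiff(refs, model$params)
    if (length(unknown) > 0L) {
      stop("unknown parameter(s) in restrictions: ",
           paste(unknown, collapse = ", "))
    }
  }
  rename <- character(0)
  for (cl in restrictions$equality_classes) {
    for (p in cl[-1L]) rename[p] <- cl[1L]
  }
  consts <- restrictions$constants
  branches <- lapply(model$branches, function(br) {
    a <- br$a; b <- br$b; cc <- br$c
    # fold constants
    for (p in intersect(names(consts), names(a))) {
      cc <- cc * consts[[p]]^a[[p]]
      a <- a[names(a) != p]
    }
    for (p in intersect(names(consts), names(b))) {
      cc <- cc * (1 - consts[[p]])^b[[p]]
      b <- b[names(b) != p]
    }
    # rename equality-class members
    collapse_map <- function(v) {
      if (length(v) == 0L) return(v)
      nm <- names(v)
      nm[nm %in% names(rename)] <- rename[nm[nm %in% names(rename)]]
      out <- integer(0)
      for (j in seq_along(v)) {
        out[nm[j]] <- if (nm[j] %in% names(out)) out[[nm[j]]] + v[[j]] else v[[j]]
      }
      out
    }
    br$a <- collapse_map(a)
    br$b <- collapse_map(b)
    br$c <- cc
    br
  })
  params <- sort(unique(unlist(lapply(branches, function(b)
    union(names(b$a), names(b$b))))))
  if (length(params) == 0L) {
    stop("restrictions remove every free parameter; nothing left to estimate")
  }
  out <- model
  out$branches <- branches
  out$params <- params
  out
}

#' Replicate an MPT model for within-subjects conditions
#'
#' Clones the model once per condition label, suffixing trees, categories and
#' parameters with `_<label>`.  Parameters named in `constant_params` keep a
#' single shared name across conditions.
#'
#' @param model An `mpt_model`.
#' @param labels Character vector of distinct condition suffixes.
#' @param constant_params Character vector of parameters shared across
#'   conditions.
#' @return The replicated `mpt_model`.
#' @export
within_subject_eqn <- function(model, labels, constant_params = character(0)) {
  labels <- as.character(labels)
  if (length(labels) == 0L || anyDuplicated(labels)) {
    stop("'labels' must be a non-empty set of distinct condition suffixes")
  }
  unknown <- setdiff(constant_params, model$params)
  if (length(unknown) > 0L) {
    stop("constant_params not in model: ", paste(unknown, collapse = ", "))
  }
  varying <- setdiff(model$params, constant_params)
  new_names <- as.vector(outer(varying, labels, paste, sep = "_"))
  if (any(new_names %in% model$params)) {
    stop("suffixed parameter name(s) collide with existing names: ",
         paste(intersect(new_names, model$params), collapse = ", "))
  }
  branches <- list()
  cat_order <- character(0); cat_tree <- character(0); tree_order <- character(0)
  for (lb in labels) {
    for (br in model$branches) {
      nb <- br
      nb$tree <- paste(br$tree, lb, sep = "_")
      nb$category <- paste(br$category, lb, sep = "_")
      rn <- function(v) {
        if (length(v) == 0L) return(v)
        nm <- names(v)
        nm <- ifelse(nm %in% varying, paste(nm, lb, sep = "_"), nm)
        names(v) <- nm
        v
      }
      nb$a <- rn(br$a); nb$b <- rn(br$b)
      branches[[length(branches) + 1L]] <- nb
      if (!(nb$category %in% cat_order)) {
        cat_order <- c(cat_order, nb$category)
        cat_tree[[nb$category]] <- nb$tree
      }
      if (!(nb$tree %in% tree_order)) tree_order <- c(tree_order, nb$tree)
    }
  }
  params <- sort(unique(unlist(lapply(branches, function(b)
    union(names(b$a), names(b$b))))))
  structure(
    list(trees = tree_order,
         categories = data.frame(category = cat_order,
                                 tree = unname(cat_tree[cat_order]),
                                 stringsAsFactors = FALSE),
         branches = branches,
         params = params),
    class = "mpt_model")
}

#' Serialize an MPT model back to EQN text
#'
#' @param model An `mpt_model`.
#' @param comment Comment placed on the (always-skipped) first line.
#' @return Character vector of EQN lines.
#' @export
write_eqn <- function(model, comment = "model written by hmpt") {
  lines <- vapply(model$branches, function(br) {
    toks <- character(0)
    if (br$c != 1) toks <- c(toks, format(br$c, digits = 15))
    for (p in names(br$a)) toks <- c(toks, rep(p, br$a[[p]]))
    for (p in names(br$b)) toks <- c(toks, rep(sprintf("(1-%s)", p), br$b[[p]]))
    paste(br$tree, br$category, paste(toks, collapse = "*"))
  }, character(1))
  c(comment, lines)
}

#' Numerical validation report for an MPT model
#'
#' Evaluates the per-tree category-probability sums at random parameter
#' vectors (they must equal 1 for a well-formed model) and computes a
#' numerical local-identifiability diagnostic: the maximum rank across draws
#' of the Jacobian of category probabilities with respect to the free
#' parameters.  A rank below the number of free parameters indicates that
#' the model is not identifiable.
#'
#' @param model An `mpt_model`.
#' @param n_random_theta Number of uniform random parameter vectors.
#' @param seed Integer seed.
#' @return List with `max_sum_deviation` (named per tree), `jacobian_rank`,
#'   `n_params`, and `identifiable` (rank == number of parameters).
#' @export
validate_model <- function(model, n_random_theta = 10, seed = 1) {
  S <- length(model$params)
  cm <- compile_mpt(model)
  thetas <- with_seed(seed, matrix(0.05 + 0.9 * stats::runif(n_random_theta * S),
                                   n_random_theta, S))
  dev <- setNames(rep(0, length(model$trees)), model$trees)
  rank_max <- 0L
  h <- 1e-6
  for (i in seq_len(n_random_theta)) {
    th <- matrix(thetas[i, ], nrow = 1, dimnames = list(NULL, model$params))
    p <- category_probabilities(th, model)
    sums <- tapply(p[1, ], cm$cat_tree, sum)
    dev[names(sums)] <- pmax(dev[names(sums)], abs(sums - 1))
    J <- matrix(0, ncol(p), S)
    for (s in seq_len(S)) {
      up <- th; up[1, s] <- up[1, s] + h
      dn <- th; dn[1, s] <- dn[1, s] - h
      J[, s] <- (category_probabilities(up, model)[1, ] -
                 category_probabilities(dn, model)[1, ]) / (2 * h)
    }
    rank_max <- max(rank_max, qr(J, tol = 1e-7)$rank)
  }
  list(max_sum_deviation = dev, jacobian_rank = rank_max, n_params = S,
       identifiable = rank_max == S)
}
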