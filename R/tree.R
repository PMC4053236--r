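node_risk <- function(counts, criterion) {
  n <- sum(counts)
  if (n == 0) return(0)
  if (criterion == "deviance") {
    nz <- counts[counts > 0]
    -2 * sum(nz * log(nz / n))
  } else {
    n - max(counts)
  }
}

new_node <- function(counts, criterion) {
  counts <- as.numeric(counts)
  list(counts = counts,
       n = sum(counts),
       risk = node_risk(counts, criterion),
       pred = NA_integer_,
       is_leaf = TRUE,
       split_var = NULL, split_level = NULL,
       majority = NULL, left = NULL, right = NULL)
}

#' Grow a classification tree over categorical markers
#'
#' Recursive binary partitioning in the CART style: at each node every
#' marker is examined and, for multi-level markers, every
#' single-level-versus-rest partition; the split minimizing the summed
#' child risk (deviance by default, misclassification optionally) is
#' taken. Splitting stops when a node is pure, smaller than twice
#' `min_node_size`, would produce a child smaller than `min_node_size`, or
#' no split reduces the risk. Ties between equally good splits are broken
#' lexicographically by marker name, then by level order, which makes the
#' tree deterministic. Tumors with a missing value at a split follow the
#' majority branch of the training data at that node.
#'
#' @param features Data frame of categorical markers (factors or
#'   characters), one row per tumor.
#' @param labels Factor of class labels (e.g. `MA`/`BL`).
#' @param criterion `"deviance"` (default) or `"misclass"`.
#' @param min_node_size Minimum number of tumors in a leaf (default 5).
#' @return An object of class `ma_tree`.
#' @export
#' @examples
#' coh <- er_negative_subset(generate_fixture_replica())
#' fit <- grow_tree(fixture_tree_features(coh), factor(coh$group))
#' fit
grow_tree <- function(features, labels, criterion = c("deviance", "misclass"),
                      min_node_size = 5L) {
  criterion <- match.arg(criterion)
  stopifnot(is.data.frame(features), nrow(features) == length(labels),
            min_node_size >= 1)
  labels <- factor(labels)
  features <- as.data.frame(lapply(features, function(x) {
    factor(as.character(x))
  }), stringsAsFactors = TRUE)
  var_names <- sort(names(features))
  var_levels <- lapply(features, levels)

  y <- as.integer(labels)
  n_class <- nlevels(labels)
  count_of <- function(idx) tabulate(y[idx], nbins = n_class)

  build <- function(idx) {
    node <- new_node(count_of(idx), criterion)
    node$pred <- which.max(node$counts)
    pure <- sum(node$counts > 0) <= 1
    if (pure || node$n < 2 * min_node_size) return(node)

    best <- NULL
    for (v in var_names) {
      x <- features[[v]][idx]
      lvls <- var_levels[[v]]
      for (l in lvls) {
        go_left <- !is.na(x) & x == l
        go_right <- !is.na(x) & x != l
        if (sum(go_left) == 0 || sum(go_right) == 0) next
        # missing values follow the larger (majority) branch
        maj <- if (sum(go_left) >= sum(go_right)) "left" else "right"
        miss <- is.na(x)
        left_idx <- idx[go_left | (miss & maj == "left")]
        right_idx <- idx[go_right | (miss & maj == "right")]
        if (length(left_idx) < min_node_size ||
            length(right_idx) < min_node_size) next
        risk <- node_risk(count_of(left_idx), criterion) +
          node_risk(count_of(right_idx), criterion)
        if (is.null(best) || risk < best$risk - 1e-9) {
          best <- list(var = v, level = l, risk = risk, maj = maj,
                       left_idx = left_idx, right_idx = right_idx)
        }
      }
    }
    if (is.null(best) || best$risk > node$risk - 1e-9) return(node)
    node$is_leaf <- FALSE
    node$split_var <- best$var
    node$split_level <- best$level
    node$majority <- best$maj
    node$left <- build(best$left_idx)
    node$right <- build(best$right_idx)
    node
  }

  structure(
    list(root = build(seq_along(y)),
         var_levels = var_levels,
         label_levels = levels(labels),
         criterion = criterion,
         min_node_size = min_node_size),
    class = "ma_tree")
}

walk_count <- function(node, what) {
  if (node$is_leaf) {
    return(switch(what, leaves = 1, internal = 0, risk = node$risk))
  }
  l <- walk_count(node$left, what)
  r <- walk_count(node$right, what)
  if (what == "internal") 1 + l + r else l + r
}

#' Number of leaves of a classification tree
#' @param model An `ma_tree`.
#' @return Integer.
#' @export
n_leaves <- function(model) walk_count(model$root, "leaves")

#' Number of internal (split) nodes of a classification tree
#' @param model An `ma_tree`.
#' @return Integer.
#' @export
n_internal <- function(model) walk_count(model$root, "internal")

# collapse every internal node whose weakest-link value g(t) is <= alpha
# (bottom-up), yielding the cost-complexity-optimal subtree for alpha;
# ties resolve toward the smaller tree
prune_node_at <- function(node, alpha) {
  if (node$is_leaf) return(node)
  node$left <- prune_node_at(node$left, alpha)
  node$right <- prune_node_at(node$right, alpha)
  subtree_risk <- walk_count(node, "risk")
  leaves <- walk_count(node, "leaves")
  g <- (node$risk - subtree_risk) / (leaves - 1)
  if (g <= alpha + 1e-12) {
    node$is_leaf <- TRUE
    node$left <- node$right <- NULL
    node$split_var <- node$split_level <- node$majority <- NULL
  }
  node
}

min_g <- function(node) {
  if (node$is_leaf) return(Inf)
  g <- (node$risk - walk_count(node, "risk")) / (walk_count(node, "leaves") - 1)
  min(g, min_g(node$left), min_g(node$right))
}

# weakest-link alpha sequence of the cost-complexity pruning path
alpha_sequence <- function(model) {
  alphas <- numeric(0)
  node <- model$root
  while (!node$is_leaf) {
    a <- min_g(node)
    alphas <- c(alphas, a)
    node <- prune_node_at(node, a)
  }
  alphas
}

leaf_for_row <- function(model, node, row, unknown_action = "error") {
  while (!node$is_leaf) {
    v <- row[[node$split_var]]
    if (!is.na(v) && !v %in% model$var_levels[[node$split_var]]) {
      if (unknown_action == "error") {
        stop("unknown level '", v, "' for marker ", node$split_var,
             call. = FALSE)
      }
      v <- NA
    }
    if (is.na(v)) {
      node <- if (node$majority == "left") node$left else node$right
    } else {
      node <- if (v == node$split_level) node$left else node$right
    }
  }
  node
}

#' Predict tumor classes from a fitted tree
#'
#' Routes each tumor down the tree; missing marker values follow the
#' training majority branch of the node. An unknown categorical level
#' raises an error naming it.
#'
#' @param object An `ma_tree`.
#' @param newdata Data frame of markers (same columns as used to grow).
#' @param type `"class"` for predicted labels, `"counts"` for the training
#'   class counts of the assigned leaf.
#' @param ... Unused.
#' @return Factor of labels, or a matrix of leaf counts.
#' @export
predict.ma_tree <- function(object, newdata,
                            type = c("class", "counts"), ...) {
  type <- match.arg(type)
  unknown_action <- if (is.null(list(...)$unknown_action)) "error" else
    list(...)$unknown_action
  newdata <- as.data.frame(newdata)
  rows <- lapply(seq_len(max(1, nrow(newdata))), function(i) {
    row <- lapply(newdata[i, , drop = FALSE], as.character)
    leaf_for_row(object, object$root, row, unknown_action)
  })
  if (nrow(newdata) == 0) rows <- list()
  if (type == "class") {
    factor(object$label_levels[vapply(rows, function(l) l$pred, 1L)],
           levels = object$label_levels)
  } else {
    out <- t(vapply(rows, function(l) l$counts,
                    numeric(length(object$label_levels))))
    colnames(out) <- object$label_levels
    out
  }
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

validation_deviance <- function(model, features, labels) {
  counts <- predict(model, features, type = "counts",
                    unknown_action = "majority")
  n_class <- length(model$label_levels)
  y <- match(as.character(labels), model$label_levels)
  # Laplace-smoothed leaf probabilities keep held-out deviance finite
  p <- (counts[cbind(seq_along(y), y)] + 0.5) /
    (rowSums(counts) + 0.5 * n_class)
  -2 * sum(log(p))
}

#' Prune a classification tree by cross-validated cost complexity
#'
#' Computes the weakest-link cost-complexity pruning path of the maximal
#' tree, then chooses the complexity penalty by stratified k-fold
#' cross-validation (10 folds by default): within each fold a tree is
#' grown on the training portion, pruned along the candidate penalties
#' (geometric means of consecutive path values), and scored by held-out
#' deviance. The penalty with the smallest summed CV deviance wins; ties
#' go to the larger penalty, i.e. the smaller tree.
#'
#' @param model An `ma_tree` from [grow_tree()].
#' @param features,labels The training data the tree was grown on.
#' @param cv_folds Number of folds (>= 2, and at most the number of
#'   tumors).
#' @param seed Integer seed for the fold assignment.
#' @return The pruned `ma_tree`, with attributes `cv_alpha` (chosen
#'   penalty) and `cv_deviance` (per-candidate CV deviance table).
#' @export
prune_tree <- function(model, features, labels, cv_folds = 10L, seed = 1L) {
  stopifnot(inherits(model, "ma_tree"), cv_folds >= 2)
  labels <- factor(labels, levels = model$label_levels)
  if (cv_folds > length(labels)) {
    stop("cv_folds exceeds the number of tumors", call. = FALSE)
  }
  if (model$root$is_leaf) return(model)

  alphas <- alpha_sequence(model)
  k <- length(alphas)
  cand <- c(0, if (k > 1) sqrt(alphas[-k] * alphas[-1]), Inf)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fold <- stratified_folds(labels, cv_folds)

  cv_dev <- numeric(length(cand))
  for (f in seq_len(cv_folds)) {
    train <- fold != f
    if (length(unique(labels[train])) < 2) next
    ft <- grow_tree(features[train, , drop = FALSE], labels[train],
                    criterion = model$criterion,
                    min_node_size = model$min_node_size)
    for (j in seq_along(cand)) {
      pt <- ft
      pt$root <- prune_node_at(pt$root, cand[j])
      cv_dev[j] <- cv_dev[j] +
        validation_deviance(pt, features[!train, , drop = FALSE],
                            labels[!train])
    }
  }
  best <- max(which(cv_dev <= min(cv_dev) + 1e-9))  # ties -> smaller tree
  pruned <- model
  pruned$root <- prune_node_at(pruned$root, cand[best])
  attr(pruned, "cv_alpha") <- cand[best]
  attr(pruned, "cv_deviance") <- data.frame(alpha = cand, deviance = cv_dev)
  pruned
}

print_node <- function(node, model, prefix, branch) {
  cat(sprintf("%s%s %s (%s of %d)%s\n", prefix, branch,
              model$label_levels[node$pred],
              paste(node$counts, collapse = "/"), node$n,
              if (node$is_leaf) " *" else ""))
  if (!node$is_leaf) {
    print_node(node$left, model, paste0(prefix, "  "),
               sprintf("%s = %s:", node$split_var, node$split_level))
    print_node(node$right, model, paste0(prefix, "  "),
               sprintf("%s != %s:", node$split_var, node$split_level))
  }
}

#' @export
print.ma_tree <- function(x, ...) {
  cat("Classification tree (", x$criterion, " splitting); counts are ",
      paste(x$label_levels, collapse = "/"), " per node\n", sep = "")
  print_node(x$root, x, "", "root:")
  invisible(x)
}

#' Marker feature frame for tree building
#'
#' Assembles the categorical feature set offered to the classification
#' tree from a cohort's IHC panel: HER2 dichotomized as 3+ versus not-3+,
#' plus the GCDFP15, AR, FOXA1, EGFR, CK5/6 and CK17 calls.
#'
#' @param cohort An [ma_cohort].
#' @return Data frame of factors, one row per tumor.
#' @export
fixture_tree_features <- function(cohort) {
  data.frame(
    her2_3plus = factor(ifelse(is.na(cohort$her2_score), NA,
                               ifelse(cohort$her2_score == "3+",
                                      "3+", "not3+"))),
    gcdfp15 = call_ihc_marker(cohort, "gcdfp15"),
    ar = call_ihc_marker(cohort, "ar"),
    foxa1 = call_ihc_marker(cohort, "foxa1"),
    egfr = call_ihc_marker(cohort, "egfr"),
    ck56 = call_ihc_marker(cohort, "ck56"),
    ck17 = call_ihc_marker(cohort, "ck17"))
}
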