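## A compact random-forest classifier (CART + bagging + per-node feature
## subsampling) used for index weighting: mean-decrease-in-impurity
## importances and out-of-bag accuracy are the only outputs consumed.
## Written in vectorised base R; the feature space here is tiny (3 indices),
## which keeps exhaustive split search cheap.

# Best gini split at a node. Returns NULL when no split improves.
.best_split <- function(X, y, idx, feats, k) {
  n <- length(idx)
  cnt <- tabulate(y[idx], k)
  g_parent <- 1 - sum((cnt / n)^2)
  best <- NULL
  best_gain <- 1e-12
  for (f in feats) {
    x <- X[idx, f]
    o <- order(x, method = "radix")
    xs <- x[o]
    ys <- y[idx][o]
    hot <- matrix(0, n, k)
    hot[cbind(seq_len(n), ys)] <- 1
    cl <- apply(hot, 2L, cumsum)              # cumulative class counts
    cut <- which(xs[-n] < xs[-1L])            # splittable positions
    if (!length(cut)) next
    nl <- cut
    nr <- n - nl
    cl_cut <- cl[cut, , drop = FALSE]
    gl <- 1 - rowSums((cl_cut / nl)^2)
    cr <- rep(cnt, each = length(cut)) - cl_cut
    gr <- 1 - rowSums((cr / nr)^2)
    gain <- g_parent - (nl * gl + nr * gr) / n
    j <- which.max(gain)
    if (gain[j] > best_gain) {
      best_gain <- gain[j]
      best <- list(var = f, split = (xs[cut[j]] + xs[cut[j] + 1L]) / 2,
                   gain = gain[j])
    }
  }
  best
}

# Grow one tree on the rows `rows` (a bootstrap sample). Returns the node
# table plus the un-normalised impurity-decrease importance per feature.
.grow_tree <- function(X, y, rows, k, mtry, min_node, max_depth) {
  p <- ncol(X)
  var <- integer(0); split <- numeric(0)
  left <- integer(0); right <- integer(0); pred <- integer(0)
  imp <- numeric(p)
  n_root <- length(rows)

  new_node <- function() {
    var[length(var) + 1L] <<- 0L
    split[length(split) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- 0L
    right[length(right) + 1L] <<- 0L
    pred[length(pred) + 1L] <<- 0L
    length(var)
  }

  build <- function(idx, depth, node_id) {
    cnt <- tabulate(y[idx], k)
    majority <- which.max(cnt)
    if (length(idx) < min_node || depth >= max_depth ||
        sum(cnt > 0L) == 1L) {
      pred[node_id] <<- majority
      return(invisible())
    }
    feats <- sample.int(p, min(mtry, p))
    sp <- .best_split(X, y, idx, feats, k)
    if (is.null(sp)) {
      pred[node_id] <<- majority
      return(invisible())
    }
    imp[sp$var] <<- imp[sp$var] + (length(idx) / n_root) * sp$gain
    go_left <- X[idx, sp$var] < sp$split
    var[node_id] <<- sp$var
    split[node_id] <<- sp$split
    l <- new_node(); r <- new_node()
    left[node_id] <<- l; right[node_id] <<- r
    build(idx[go_left], depth + 1L, l)
    build(idx[!go_left], depth + 1L, r)
  }

  root <- new_node()
  build(rows, 0L, root)
  list(nodes = data.frame(var = var, split = split, left = left,
                          right = right, pred = pred),
       importance = imp)
}

# Vectorised routing of all rows of X through one tree.
.predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- integer(n)
  node <- rep(1L, n)
  active <- seq_len(n)
  nd_var <- tree$var; nd_split <- tree$split
  nd_left <- tree$left; nd_right <- tree$right; nd_pred <- tree$pred
  while (length(active)) {
    nd <- node[active]
    isleaf <- nd_var[nd] == 0L
    out[active[isleaf]] <- nd_pred[nd[isleaf]]
    active <- active[!isleaf]
    nd <- nd[!isleaf]
    if (!length(active)) break
    goleft <- X[cbind(active, nd_var[nd])] < nd_split[nd]
    node[active] <- ifelse(goleft, nd_left[nd], nd_right[nd])
  }
  out
}

#' Random-forest classifier for index weighting
#'
#' Bagged CART trees with gini splits and per-node feature subsampling.
#' Reports mean-decrease-in-impurity variable importances and out-of-bag
#' (OOB) classification accuracy; fully reproducible for a fixed seed.
#'
#' @param X Numeric matrix of predictors (columns = features).
#' @param y Class labels (factor or character).
#' @param n_trees Number of trees.
#' @param mtry Features tried per split.
#' @param min_node Minimum rows in a splittable node.
#' @param max_depth Maximum tree depth.
#' @param seed Integer seed.
#' @return List with `importance` (named, un-normalised impurity decrease),
#'   `oob_accuracy`, `n_trees`, and `classes`.
#' @export
random_forest <- function(X, y, n_trees = 500L, mtry = 2L,
                          min_node = 10L, max_depth = 12L, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- factor(y)
  if (nlevels(y) < 2L)
    stop("labels contain a single class; nothing to learn")
  yi <- as.integer(y)
  n <- nrow(X); p <- ncol(X); k <- nlevels(y)
  if (!(mtry >= 1L && mtry <= p)) stop("mtry must be in 1..", p)
  set.seed(seed)
  imp <- numeric(p)
  votes <- matrix(0L, n, k)
  for (t in seq_len(n_trees)) {
    rows <- sample.int(n, n, replace = TRUE)
    fit <- .grow_tree(X, yi, rows, k, mtry, min_node, max_depth)
    imp <- imp + fit$importance
    oob <- setdiff(seq_len(n), unique(rows))
    if (length(oob)) {
      pr <- .predict_tree(fit$nodes, X[oob, , drop = FALSE])
      votes[cbind(oob, pr)] <- votes[cbind(oob, pr)] + 1L
    }
  }
  seen <- rowSums(votes) > 0L
  oob_pred <- max.col(votes[seen, , drop = FALSE], ties.method = "first")
  acc <- mean(oob_pred == yi[seen])
  list(importance = stats::setNames(imp / n_trees, colnames(X)),
       oob_accuracy = acc, n_trees = n_trees, classes = levels(y))
}
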