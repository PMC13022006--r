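#' @keywords internal
.entropy <- function(counts) {
  tot <- sum(counts)
  if (tot <= 0) return(0)
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}

# Upper confidence limit of the binomial error count (pessimistic error),
# valid for fractional E and N.
.ucf <- function(E, N, cf) {
  if (N <= 0) return(0)
  E <- min(max(E, 0), N)
  if (N - E < 1e-9) return(N)
  N * stats::qbeta(1 - cf, E + 1, N - E)
}

.wcounts <- function(labels, w, classes) {
  vapply(classes, function(cl) sum(w[labels == cl]), numeric(1))
}

.grow_tree <- function(X, labels, w, classes, min_cases) {
  total <- sum(w)
  counts <- .wcounts(labels, w, classes)
  majority <- classes[which.max(counts)]
  errors <- total - max(counts)
  leaf <- list(type = "leaf", class = majority, weight = total,
               errors = errors, counts = counts)
  if (errors <= 1e-12 || total < 2 * min_cases) return(leaf)
  best <- NULL
  for (a in names(X)) {
    x <- X[[a]]
    known <- is.finite(x) & w > 0
    Wk <- sum(w[known])
    if (Wk < 2 * min_cases) next
    ord <- order(x[known])
    xs <- x[known][ord]
    ws <- w[known][ord]
    ls <- labels[known][ord]
    info_known <- .entropy(.wcounts(ls, ws, classes))
    if (length(ws) < 2) next
    # cumulative weighted class counts along the sorted attribute
    cum <- vapply(classes, function(cl) cumsum(ws * (ls == cl)),
                  numeric(length(ws)))
    totc <- cum[nrow(cum), ]
    cuts <- which(diff(xs) > 0)
    for (i in cuts) {
      cl_left <- cum[i, ]
      WL <- sum(cl_left)
      WR <- Wk - WL
      if (WL < min_cases || WR < min_cases) next
      info_split <- (WL / Wk) * .entropy(cl_left) +
        (WR / Wk) * .entropy(totc - cl_left)
      gain <- (Wk / total) * (info_known - info_split)
      if (gain <= 1e-12) next
      si <- .entropy(c(WL, WR))
      if (si <= 1e-12) next
      gr <- gain / si
      if (is.null(best) || gr > best$gr + 1e-12) {
        best <- list(gr = gr, attribute = a,
                     threshold = (xs[i] + xs[i + 1]) / 2,
                     pL = WL / Wk)
      }
    }
  }
  if (is.null(best)) return(leaf)
  x <- X[[best$attribute]]
  known <- is.finite(x)
  left_mask <- known & x <= best$threshold
  right_mask <- known & x > best$threshold
  wl <- w * left_mask + w * (!known) * best$pL
  wr <- w * right_mask + w * (!known) * (1 - best$pL)
  list(type = "split", attribute = best$attribute,
       threshold = best$threshold, weight = total, counts = counts,
       class = majority, errors = errors, p_left = best$pL,
       left = .grow_tree(X, labels, wl, classes, min_cases),
       right = .grow_tree(X, labels, wr, classes, min_cases))
}

.prune_tree <- function(node, cf) {
  if (node$type == "leaf") {
    node$est_errors <- .ucf(node$errors, node$weight, cf)
    return(node)
  }
  node$left <- .prune_tree(node$left, cf)
  node$right <- .prune_tree(node$right, cf)
  sub_est <- node$left$est_errors + node$right$est_errors
  leaf_est <- .ucf(node$errors, node$weight, cf)
  if (leaf_est <= sub_est + 1e-9) {
    return(list(type = "leaf", class = node$class, weight = node$weight,
                errors = node$errors, counts = node$counts,
                est_errors = leaf_est))
  }
  node$est_errors <- sub_est
  node
}

#' Induce a gain-ratio decision tree of the dominant trophic mode
#'
#' A C4.5-family classifier: recursive binary splits on numeric attributes
#' chosen by information gain ratio, thresholds placed at the midpoint of
#' the straddling values, missing attribute values sent fractionally down
#' both children in proportion to the known cases, and pessimistic-error
#' pruning controlled by the confidence factor `cf`. Induction is
#' deterministic for a given table (the `seed` argument exists for
#' interface symmetry with the stochastic stages).
#'
#' @param features Data frame of numeric predictors; NAs allowed.
#' @param labels Class label per row (2 or more classes for a non-trivial
#'   tree; a single-class table yields a single leaf with zero error).
#' @param min_cases Minimum case weight per child of a split.
#' @param cf Pruning confidence factor in (0, 1); smaller prunes harder.
#' @param prune Set FALSE to keep the unpruned tree.
#' @param seed Ignored (determinism); accepted for call symmetry.
#' @return Object of class `c45_tree` with the node structure, class
#'   levels and attribute names.
#' @export
induce_tree <- function(features, labels, min_cases = 2, cf = 0.25,
                        prune = TRUE, seed = NULL) {
  stopifnot(is.data.frame(features), nrow(features) == length(labels))
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels must be present for every training row")
  num <- vapply(features, is.numeric, logical(1))
  X <- features[num]
  classes <- sort(unique(labels))
  w <- rep(1, nrow(features))
  root <- .grow_tree(X, labels, w, classes, min_cases)
  if (prune) root <- .prune_tree(root, cf)
  structure(list(root = root, classes = classes, attributes = names(X),
                 n_train = nrow(features), cf = cf, min_cases = min_cases),
            class = "c45_tree")
}

.predict_row <- function(node, row) {
  while (node$type == "split") {
    v <- row[[node$attribute]]
    if (!is.finite(v)) {
      # majority path for missing values at prediction time
      node <- if (node$p_left >= 0.5) node$left else node$right
    } else {
      node <- if (v <= node$threshold) node$left else node$right
    }
  }
  node$class
}

#' Predict classes from a fitted tree
#'
#' @param object A `c45_tree`.
#' @param newdata Data frame with the training attributes; rows with a
#'   missing tested attribute follow the majority-weight child.
#' @param ... Unused.
#' @return Character vector of predicted classes.
#' @export
predict.c45_tree <- function(object, newdata, ...) {
  vapply(seq_len(nrow(newdata)), function(i)
    .predict_row(object$root, newdata[i, , drop = FALSE]),
    character(1))
}

#' Relative attribute usage of a tree
#'
#' For each attribute, the percentage of training case weight that passes
#' through any node testing it (each case counted at most once); the root
#' attribute is used by 100% of the cases.
#'
#' @param model A `c45_tree`.
#' @param features The training feature table.
#' @return Named numeric vector of percentages, sorted decreasing.
#' @export
attribute_usage <- function(model, features) {
  n <- nrow(features)
  w0 <- rep(1, n)
  enc <- new.env()
  for (a in model$attributes) assign(a, numeric(n), envir = enc)
  walk <- function(node, w) {
    if (node$type == "leaf" || sum(w) == 0) return(invisible())
    assign(node$attribute, get(node$attribute, envir = enc) + w, envir = enc)
    x <- features[[node$attribute]]
    known <- is.finite(x)
    wl <- w * (known & x <= node$threshold) + w * (!known) * node$p_left
    wr <- w * (known & x > node$threshold) + w * (!known) * (1 - node$p_left)
    walk(node$left, wl)
    walk(node$right, wr)
  }
  walk(model$root, w0)
  usage <- vapply(model$attributes, function(a)
    100 * sum(pmin(get(a, envir = enc), w0)) / n, numeric(1))
  sort(usage, decreasing = TRUE)
}

#' Resubstitution error of a fitted tree
#'
#' @param model A `c45_tree`.
#' @param features Training feature table.
#' @param labels Training labels.
#' @return Percent of training rows misclassified.
#' @export
training_error <- function(model, features, labels) {
  pred <- predict(model, features)
  100 * mean(pred != as.character(labels))
}

#' Render a tree as indented text
#' @param x A `c45_tree`.
#' @param ... Unused.
#' @export
print.c45_tree <- function(x, ...) {
  rec <- function(node, depth) {
    pad <- strrep("  ", depth)
    if (node$type == "leaf") {
      cat(sprintf("%s-> %s (w=%.1f, err=%.1f)\n", pad, node$class,
                  node$weight, node$errors))
    } else {
      cat(sprintf("%s%s <= %.4g:\n", pad, node$attribute, node$threshold))
      rec(node$left, depth + 1)
      cat(sprintf("%s%s >  %.4g:\n", pad, node$attribute, node$threshold))
      rec(node$right, depth + 1)
    }
  }
  cat(sprintf("Gain-ratio tree (%d training cases, cf=%.2f)\n",
              x$n_train, x$cf))
  rec(x$root, 0)
  invisible(x)
}
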