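#' Ward dendrogram of PLS-DA scores
#'
#' Agglomerative clustering of score vectors with Euclidean distance and
#' Ward's minimum-variance criterion (textbook Ward: `hclust` method
#' `"ward.D2"` on raw distances, equivalent to the Lance-Williams update on
#' squared distances). Merge ties are resolved by `hclust`'s deterministic
#' lowest-index rule, so the result depends only on the input order.
#'
#' @param scores n x k matrix of scores (n >= 2).
#' @param labels Class label per row.
#' @return Object of class `ward_dendrogram` wrapping the `hclust` object
#'   (`$hc`) and the row labels.
#' @export
ward_dendrogram <- function(scores, labels) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("size error: need at least two points",
                              call. = FALSE)
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  structure(list(hc = hc, labels = as.character(labels)),
            class = "ward_dendrogram")
}

#' Export a dendrogram as Newick text
#'
#' @param d A `ward_dendrogram`.
#' @param path Optional output file.
#' @return Newick string (invisibly when written to file). Requires the
#'   `ape` package.
#' @export
dendrogram_newick <- function(d, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export", call. = FALSE)
  }
  hc <- d$hc
  hc$labels <- make.unique(d$labels)
  ph <- ape::as.phylo(hc)
  if (is.null(path)) ape::write.tree(ph) else {
    ape::write.tree(ph, file = path)
    invisible(path)
  }
}

# canonical nested-list topology ordered by first class appearance in
# `order`; leaves are labels, internal nodes length-2 lists
.canon_topology <- function(topo, order) {
  if (!is.list(topo)) return(topo)
  kids <- lapply(topo, .canon_topology, order = order)
  first <- vapply(kids, function(k) min(match(unlist(k), order)),
                  numeric(1))
  kids[base::order(first)]
}

#' Format a class topology as text
#'
#' @param topo Nested list of fluid labels (internal nodes = length-2
#'   lists).
#' @return A string such as `"((blood,(saliva,semen)),(urine,sweat))"`.
#' @export
format_topology <- function(topo) {
  if (!is.list(topo)) return(topo)
  paste0("(", paste(vapply(topo, format_topology, character(1)),
                    collapse = ","), ")")
}

#' Class-level merge order of a dendrogram
#'
#' Reads the binary merge topology of the classes from the sample-level
#' dendrogram. This requires every class's samples to form a pure subtree
#' (each merge either grows a single class or joins groups of complete
#' classes); when the data are perfectly clustered by class this recovers
#' the order in which class clusters merge. If any class subtree is impure,
#' the function falls back to Ward clustering of the class centroids and
#' says so in a message.
#'
#' @param d A `ward_dendrogram` built from labeled scores.
#' @param class_order Class vocabulary used to canonicalize child order.
#' @return Nested list topology (see [format_topology()]), with attribute
#'   `method` equal to `"samples"` or `"centroid_fallback"`.
#' @export
class_merge_order <- function(d, class_order = fluid_labels()) {
  hc <- d$hc; labs <- d$labels
  class_order <- intersect(class_order, unique(labs))
  counts <- table(labs)
  n <- length(labs)
  # cluster state: label set, sample count, topology (NULL until complete)
  state <- vector("list", nrow(hc$merge))
  leaf_state <- function(i) {
    list(set = labs[i], size = 1L,
         topo = if (counts[[labs[i]]] == 1L) labs[i] else NULL)
  }
  pure <- TRUE
  for (m in seq_len(nrow(hc$merge))) {
    a <- hc$merge[m, 1]; b <- hc$merge[m, 2]
    ca <- if (a < 0) leaf_state(-a) else state[[a]]
    cb <- if (b < 0) leaf_state(-b) else state[[b]]
    set <- union(ca$set, cb$set)
    size <- ca$size + cb$size
    complete <- size == sum(counts[set])
    topo <- NULL
    if (identical(ca$set, cb$set) && length(ca$set) == 1L) {
      # within-class merge
      topo <- if (complete) ca$set else NULL
    } else if (!is.null(ca$topo) && !is.null(cb$topo) &&
               length(intersect(ca$set, cb$set)) == 0L) {
      topo <- list(ca$topo, cb$topo)
    } else {
      pure <- FALSE
      break
    }
    state[[m]] <- list(set = set, size = size, topo = topo)
  }
  if (pure) {
    topo <- state[[nrow(hc$merge)]]$topo
    if (!is.null(topo)) {
      topo <- .canon_topology(topo, class_order)
      attr(topo, "method") <- "samples"
      return(topo)
    }
    pure <- FALSE
  }
  message("class subtrees are impure; falling back to centroid clustering")
  scores <- NULL
  stop_if <- function() stop("topology error: centroid fallback needs the ",
                             "score matrix in d$scores", call. = FALSE)
  # centroid fallback: Ward on the class centroids of the original scores
  if (is.null(d$scores)) stop_if()
  cent <- matrix(0, length(class_order), ncol(d$scores))
  rownames(cent) <- class_order
  for (cl in class_order) {
    cent[cl, ] <- colMeans(d$scores[labs == cl, , drop = FALSE])
  }
  hc2 <- stats::hclust(stats::dist(cent), method = "ward.D2")
  st <- vector("list", nrow(hc2$merge))
  for (m in seq_len(nrow(hc2$merge))) {
    gets <- function(ix) if (ix < 0) class_order[-ix] else st[[ix]]
    st[[m]] <- list(gets(hc2$merge[m, 1]), gets(hc2$merge[m, 2]))
  }
  topo <- .canon_topology(st[[nrow(hc2$merge)]], class_order)
  attr(topo, "method") <- "centroid_fallback"
  topo
}

.topo_labels <- function(topo) as.character(unlist(topo))

#' Build a dichotomous classification tree
#'
#' Each internal node of the topology gets a two-class PLS-DA model
#' (left group vs right group as super-classes; components adopted by the
#' PRESS/RSS rule under donor-wise cross-validation) plus an LDA on its
#' training scores. Each leaf gets a one-class Q model fitted, at
#' significance `alpha`, to the residuals of that fluid's training spectra
#' under the leaf's parent-node PLS model -- so the Q-test is always tied
#' to the model that routed the sample.
#'
#' @param train Preprocessed [spectra_set()] of fresh training spectra
#'   covering every fluid in the topology.
#' @param topology Nested list of fluid labels, e.g. from
#'   [class_merge_order()].
#' @param alpha Leaf Q-test significance (0.00005 gives the 99.995 percent
#'   acceptance region used with this scheme).
#' @param K_max,k_folds,seed Component-selection settings per node.
#' @return Object of class `classification_tree`.
#' @export
build_tree <- function(train, topology, alpha = 5e-5, K_max = 10L,
                       k_folds = 5L, seed = 1L) {
  build_node <- function(topo) {
    if (!is.list(topo)) stop("topology error: leaf reached unexpectedly",
                             call. = FALSE)
    if (length(topo) != 2L) {
      stop("topology error: internal nodes must be binary", call. = FALSE)
    }
    left <- .topo_labels(topo[[1]]); right <- .topo_labels(topo[[2]])
    if (length(left) == 0L || length(right) == 0L) {
      stop("topology error: empty side at a node", call. = FALSE)
    }
    i <- train$meta$fluid %in% c(left, right)
    if (!all(c(left, right) %in% train$meta$fluid)) {
      stop("topology error: training data lacks some fluids of the node",
           call. = FALSE)
    }
    side <- ifelse(train$meta$fluid[i] %in% left, "L", "R")
    m <- fit_plsda_cv(train$X[i, , drop = FALSE], side,
                      train$meta$donor_id[i], K_max = K_max,
                      k_folds = k_folds, seed = seed,
                      class_order = c("L", "R"))
    pr <- pls_project(m, train$X[i, , drop = FALSE])
    lda <- fit_lda(pr$scores, side, class_order = c("L", "R"))
    make_child <- function(sub, side_labels) {
      if (is.list(sub)) return(build_node(sub))
      fl <- sub
      res <- pr$residual[train$meta$fluid[i] == fl, , drop = FALSE]
      list(type = "leaf", fluid = fl, q_model = fit_q_model(res, alpha))
    }
    list(type = "node", left_labels = left, right_labels = right,
         model = m, lda = lda,
         children = list(L = make_child(topo[[1]], left),
                         R = make_child(topo[[2]], right)))
  }
  structure(list(root = build_node(topology), topology = topology,
                 alpha = alpha, class_labels = .topo_labels(topology)),
            class = "classification_tree")
}

#' @export
print.classification_tree <- function(x, ...) {
  cat("classification_tree over", format_topology(x$topology), "\n")
  walk <- function(nd, depth) {
    ind <- strrep("  ", depth)
    if (nd$type == "leaf") {
      cat(sprintf("%sleaf %s (Q threshold %.3g, alpha %g)\n", ind, nd$fluid,
                  nd$q_model$q_threshold, nd$q_model$alpha))
    } else {
      cat(sprintf("%snode {%s} vs {%s}: %d LV\n", ind,
                  paste(nd$left_labels, collapse = ","),
                  paste(nd$right_labels, collapse = ","), nd$model$n_lv))
      walk(nd$children$L, depth + 1L)
      walk(nd$children$R, depth + 1L)
    }
  }
  walk(x$root, 1L)
  invisible(x)
}

#' Classify spectra with the dichotomous tree scheme
#'
#' Each spectrum descends from the root: at every node it is projected onto
#' the node's two-class PLS-DA model and the node LDA picks a side. At a
#' leaf, the Q-statistic of the parent-node residual is tested against the
#' leaf's threshold; spectra exceeding it are returned as `"OUTLIER"`.
#'
#' @param tree A `classification_tree`.
#' @param x Preprocessed spectrum vector or n x p matrix.
#' @return Data frame with `predicted`, `candidate` (the reached leaf),
#'   `q2`, `q_threshold` and `path` (node decisions joined by `>`).
#' @export
classify_tree <- function(tree, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  n <- nrow(x)
  out <- data.frame(predicted = character(n), candidate = character(n),
                    q2 = numeric(n), q_threshold = numeric(n),
                    path = character(n), stringsAsFactors = FALSE)
  descend <- function(nd, idx, path) {
    if (length(idx) == 0L) return()
    pr <- pls_project(nd$model, x[idx, , drop = FALSE])
    side <- predict_lda(nd$lda, pr$scores)$label
    for (s in c("L", "R")) {
      sel <- side == s
      if (!any(sel)) next
      child <- nd$children[[s]]
      grp <- paste(if (s == "L") nd$left_labels else nd$right_labels,
                   collapse = "+")
      pth <- paste0(path, ">", grp)
      if (child$type == "leaf") {
        q2 <- q_squared(pr$residual[sel, , drop = FALSE])
        i2 <- idx[sel]
        out$candidate[i2] <<- child$fluid
        out$q2[i2] <<- q2
        out$q_threshold[i2] <<- child$q_model$q_threshold
        out$predicted[i2] <<- ifelse(q_test(q2, child$q_model), "OUTLIER",
                                     child$fluid)
        out$path[i2] <<- pth
      } else {
        descend(child, idx[sel], pth)
      }
    }
  }
  descend(tree$root, seq_len(n), "root")
  out
}

#' Fit the tree scheme end to end
#'
#' Convenience wrapper reproducing the full modeling strategy: fit the flat
#' multi-class PLS-DA, cluster its training scores with Ward's criterion,
#' read the class merge topology, and build the dichotomous tree with leaf
#' Q-tests.
#'
#' @param train Preprocessed fresh-spectra [spectra_set()].
#' @param alpha Leaf Q-test significance.
#' @param K_max,k_folds,seed As in [build_tree()].
#' @return A `classification_tree`; the topology used is in
#'   `$topology` and the dendrogram in attribute `dendrogram`.
#' @export
fit_tree_scheme <- function(train, alpha = 5e-5, K_max = 10L, k_folds = 5L,
                            seed = 1L) {
  flat <- fit_plsda_cv(train$X, train$meta$fluid, train$meta$donor_id,
                       K_max = K_max, k_folds = k_folds, seed = seed,
                       class_order = intersect(fluid_labels(),
                                               unique(train$meta$fluid)))
  sc <- pls_project(flat, train$X)$scores
  d <- ward_dendrogram(sc, train$meta$fluid)
  d$scores <- sc
  topo <- class_merge_order(d)
  tree <- build_tree(train, topo, alpha = alpha, K_max = K_max,
                     k_folds = k_folds, seed = seed)
  attr(tree, "dendrogram") <- d
  tree
}
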