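#' @title Model bundle serialization
#' @description Versioned JSON serialization of fitted models (flat scheme
#'   and classification tree), with matrices stored as row-major nested
#'   arrays at full double precision.
#' @name serialize
NULL

.SCHEMA_VERSION <- "fluidspec-model-1"

.mat_to_list <- function(m) {
  list(dim = dim(m), data = as.vector(t(m)),
       dimnames = dimnames(m))
}

.list_to_mat <- function(l) {
  m <- matrix(unlist(l$data), nrow = l$dim[[1]], byrow = TRUE)
  if (!is.null(l$dimnames)) {
    dimnames(m) <- lapply(l$dimnames, function(d) {
      if (length(d)) unlist(d) else NULL
    })
  }
  m
}

.plsda_to_list <- function(m) {
  list(kind = "plsda_model", x_mean = m$x_mean, y_mean = m$y_mean,
       W = .mat_to_list(m$W), P = .mat_to_list(m$P),
       Qy = .mat_to_list(m$Qy), T_train = .mat_to_list(m$T_train),
       class_labels = m$class_labels, n_lv = m$n_lv)
}

.list_to_plsda <- function(l) {
  structure(list(x_mean = unlist(l$x_mean), y_mean = unlist(l$y_mean),
                 W = .list_to_mat(l$W), P = .list_to_mat(l$P),
                 Qy = .list_to_mat(l$Qy), T_train = .list_to_mat(l$T_train),
                 class_labels = unlist(l$class_labels),
                 n_lv = as.integer(l$n_lv)),
            class = "plsda_model")
}

.lda_to_list <- function(m) {
  list(kind = "lda_model", class_means = .mat_to_list(m$class_means),
       cov = .mat_to_list(m$cov), priors = as.vector(m$priors),
       class_labels = m$class_labels)
}

.list_to_lda <- function(l) {
  cov <- .list_to_mat(l$cov)
  pri <- unlist(l$priors)
  labs <- unlist(l$class_labels)
  names(pri) <- labs
  structure(list(class_means = .list_to_mat(l$class_means), cov = cov,
                 cov_inv = solve(cov), priors = pri, class_labels = labs),
            class = "lda_model")
}

.q_to_list <- function(m) {
  list(kind = "q_model", theta1 = m$theta1, theta2 = m$theta2,
       theta3 = m$theta3, h0 = m$h0, alpha = m$alpha, z_alpha = m$z_alpha,
       q_threshold = m$q_threshold, eigenvalues = m$eigenvalues)
}

.list_to_q <- function(l) {
  structure(list(theta1 = l$theta1, theta2 = l$theta2, theta3 = l$theta3,
                 h0 = l$h0, alpha = l$alpha, z_alpha = l$z_alpha,
                 q_threshold = l$q_threshold,
                 eigenvalues = unlist(l$eigenvalues)),
            class = "q_model")
}

.node_to_list <- function(nd) {
  if (nd$type == "leaf") {
    list(type = "leaf", fluid = nd$fluid, q_model = .q_to_list(nd$q_model))
  } else {
    list(type = "node", left_labels = nd$left_labels,
         right_labels = nd$right_labels, model = .plsda_to_list(nd$model),
         lda = .lda_to_list(nd$lda),
         children = list(L = .node_to_list(nd$children$L),
                         R = .node_to_list(nd$children$R)))
  }
}

.list_to_node <- function(l) {
  if (l$type == "leaf") {
    list(type = "leaf", fluid = l$fluid, q_model = .list_to_q(l$q_model))
  } else {
    list(type = "node", left_labels = unlist(l$left_labels),
         right_labels = unlist(l$right_labels),
         model = .list_to_plsda(l$model), lda = .list_to_lda(l$lda),
         children = list(L = .list_to_node(l$children$L),
                         R = .list_to_node(l$children$R)))
  }
}

.topo_to_list <- function(t) if (is.list(t)) lapply(t, .topo_to_list) else t

.list_to_topo <- function(l) {
  if (is.list(l)) lapply(l, .list_to_topo) else l
}

#' Write a fitted model to a JSON bundle
#'
#' @param model A `flat_scheme` or `classification_tree`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_model_bundle <- function(model, path) {
  body <- if (inherits(model, "flat_scheme")) {
    list(schema = .SCHEMA_VERSION, kind = "flat_scheme",
         alpha = model$alpha, plsda = .plsda_to_list(model$plsda),
         lda = if (!is.null(model$lda)) .lda_to_list(model$lda),
         qmodels = lapply(model$qmodels, .q_to_list))
  } else if (inherits(model, "classification_tree")) {
    list(schema = .SCHEMA_VERSION, kind = "classification_tree",
         alpha = model$alpha, topology = .topo_to_list(model$topology),
         class_labels = model$class_labels, root = .node_to_list(model$root))
  } else {
    stop("unsupported model class", call. = FALSE)
  }
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a fitted model from a JSON bundle
#'
#' @param path JSON file written by [write_model_bundle()].
#' @return The deserialized `flat_scheme` or `classification_tree`.
#' @export
read_model_bundle <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(l$schema, .SCHEMA_VERSION)) {
    stop("unsupported model schema: ", l$schema, call. = FALSE)
  }
  if (l$kind == "flat_scheme") {
    qm <- lapply(l$qmodels, .list_to_q)
    structure(list(plsda = .list_to_plsda(l$plsda),
                   lda = if (!is.null(l$lda)) .list_to_lda(l$lda),
                   qmodels = qm, alpha = l$alpha),
              class = "flat_scheme")
  } else if (l$kind == "classification_tree") {
    structure(list(root = .list_to_node(l$root),
                   topology = .list_to_topo(l$topology),
                   alpha = l$alpha, class_labels = unlist(l$class_labels)),
              class = "classification_tree")
  } else {
    stop("unsupported model kind: ", l$kind, call. = FALSE)
  }
}
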