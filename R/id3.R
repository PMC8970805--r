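# ID3 decision-tree classification over nominal attributes, with an
# equal-frequency discretizer bridging continuous feature vectors to
# multiway splits.

#' Shannon entropy of a label vector (bits)
#'
#' `I(S1..Sm) = -sum_i p_i log2 p_i` with `0 log2 0 = 0`.
#'
#' @param labels Nonempty vector of class labels (any atomic type).
#' @return Entropy in bits, in `[0, log2(m)]`.
#' @export
entropy <- function(labels) {
  if (length(labels) == 0) mi_stop("domain", "entropy of an empty label set")
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Expected (conditional) entropy of labels given an attribute
#'
#' `E(A) = sum_j |S_j|/|S| * I(S_1j..S_mj)` over the attribute's values;
#' empty subsets contribute zero.
#'
#' @param data Data frame of nominal attributes.
#' @param labels Class labels aligned to rows.
#' @param attribute Column name in `data`.
#' @return Conditional entropy in bits.
#' @export
expected_entropy <- function(data, labels, attribute) {
  if (!attribute %in% names(data))
    mi_stop("key", "unknown attribute '%s'", attribute)
  v <- data[[attribute]]
  total <- length(labels)
  sum(vapply(split(labels, v, drop = TRUE), function(s)
    length(s) / total * entropy(s), 0))
}

#' Information gain of an attribute
#'
#' `Gain(A) = I(S) - E(A)`; nonnegative.
#'
#' @inheritParams expected_entropy
#' @return Gain in bits.
#' @export
info_gain <- function(data, labels, attribute) {
  entropy(labels) - expected_entropy(data, labels, attribute)
}

#' Fit an equal-frequency discretizer on a feature matrix
#'
#' Per-feature bin edges at training quantiles; outer bins are open, so
#' out-of-range values at prediction time fall into the extreme bins. A
#' constant feature falls back to a single bin with a warning.
#'
#' @param F Numeric matrix (trials x d) or `feature_matrix`.
#' @param n_bins Number of bins (>= 2).
#' @return An object of class `discretizer_model` (list of per-feature edge
#'   vectors, strictly increasing interior edges).
#' @export
fit_discretizer <- function(F, n_bins = 10) {
  check_number(n_bins, "n_bins", lower = 2, integer = TRUE)
  F <- as.matrix(F)
  if (any(!is.finite(F))) mi_stop("config", "features must be finite")
  edges <- lapply(seq_len(ncol(F)), function(j) {
    q <- unique(stats::quantile(F[, j], probs = seq_len(n_bins - 1) / n_bins,
                                type = 7, names = FALSE))
    q[q > min(F[, j]) & q <= max(F[, j])]
  })
  n_const <- sum(vapply(edges, length, 0L) == 0)
  if (n_const > 0)
    mi_warn("degenerate",
            "%d constant feature(s); single-bin fallback applied", n_const)
  structure(list(edges = edges, n_bins = as.integer(n_bins), d = ncol(F)),
            class = "discretizer_model")
}

#' Apply a discretizer, producing a nominal dataset
#'
#' Values map to bin indices 1..k via `findInterval` on the trained edges.
#'
#' @param model A [fit_discretizer()] model.
#' @param F Feature matrix with the training dimensionality.
#' @param labels Optional labels carried into the result.
#' @return List of class `nominal_dataset`: `data` (data.frame of factor
#'   columns f1..fd), `labels`.
#' @export
apply_discretizer <- function(model, F, labels = attr(F, "labels")) {
  F <- as.matrix(F)
  if (ncol(F) != model$d)
    mi_stop("shape", "feature count %d != discretizer's %d", ncol(F), model$d)
  cols <- lapply(seq_len(ncol(F)), function(j) {
    k <- length(model$edges[[j]]) + 1L
    factor(findInterval(F[, j], model$edges[[j]]) + 1L, levels = seq_len(k))
  })
  names(cols) <- paste0("f", seq_len(ncol(F)))
  structure(list(data = as.data.frame(cols), labels = labels),
            class = "nominal_dataset")
}

majority_label <- function(labels) {
  tab <- table(labels)
  # ties break to the lowest class index
  names(tab)[which.max(tab)]
}

#' Build an ID3 decision tree
#'
#' Recursive top-down induction: at each node split on the attribute with
#' maximal information gain (ties to the lowest attribute index); stop on
#' label purity, attribute exhaustion, `max_depth` or `min_samples`; leaves
#' take the majority label (ties to the lowest class); each internal node
#' stores a majority fallback used for unseen attribute values at prediction.
#'
#' @param dataset A `nominal_dataset` (see [apply_discretizer()]), or a
#'   data.frame plus `labels`.
#' @param labels Class labels if `dataset` is a plain data.frame.
#' @param max_depth Depth limit (`Inf` = unlimited).
#' @param min_samples Minimum samples to attempt a split.
#' @return An object of class `id3_tree`.
#' @export
build_tree <- function(dataset, labels = NULL, max_depth = Inf,
                       min_samples = 1) {
  if (inherits(dataset, "nominal_dataset")) {
    labels <- labels %||% dataset$labels
    dataset <- dataset$data
  }
  if (is.null(dataset) || nrow(dataset) == 0)
    mi_stop("domain", "cannot build a tree from an empty dataset")
  if (is.null(labels) || length(labels) != nrow(dataset))
    mi_stop("domain", "labels must align with dataset rows")
  labels <- as.character(labels)

  grow <- function(rows, attrs, depth) {
    labs <- labels[rows]
    if (length(unique(labs)) == 1L)
      return(list(leaf = TRUE, label = labs[1]))
    # only attributes that actually partition this node are candidates
    attrs <- attrs[vapply(attrs, function(a)
      length(unique(dataset[[a]][rows])) > 1L, TRUE)]
    if (length(attrs) == 0L || depth >= max_depth ||
        length(rows) < min_samples)
      return(list(leaf = TRUE, label = majority_label(labs)))
    gains <- vapply(attrs, function(a)
      info_gain(dataset[rows, , drop = FALSE], labs, a), 0)
    best <- attrs[which.max(gains)]          # which.max ties -> lowest index
    v <- dataset[[best]][rows]
    children <- list()
    for (val in unique(as.character(v))) {
      sub <- rows[as.character(v) == val]
      children[[val]] <- grow(sub, setdiff(attrs, best), depth + 1L)
    }
    list(leaf = FALSE, attribute = best, children = children,
         fallback = majority_label(labs))
  }
  root <- grow(seq_len(nrow(dataset)), names(dataset), 0L)
  depth_of <- function(nd) if (nd$leaf) 0L else
    1L + max(vapply(nd$children, depth_of, 0L))
  structure(list(root = root, attributes = names(dataset),
                 classes = sort(unique(labels)), depth = depth_of(root),
                 n_train = nrow(dataset)),
            class = "id3_tree")
}

#' @export
print.id3_tree <- function(x, ...) {
  cat(sprintf("<id3_tree> depth %d, %d training samples, classes: %s\n",
              x$depth, x$n_train, paste(x$classes, collapse = ", ")))
  invisible(x)
}

predict_one <- function(node, sample) {
  while (!node$leaf) {
    val <- as.character(sample[[node$attribute]])
    child <- node$children[[val]]
    if (is.null(child)) return(node$fallback)   # unseen value -> majority
    node <- child
  }
  node$label
}

#' Predict labels with an ID3 tree
#'
#' Deterministic path-following; attribute values never seen at a node fall
#' back to that node's majority label.
#'
#' @param object An `id3_tree`.
#' @param newdata A `nominal_dataset` or data.frame of nominal attributes.
#' @param ... Ignored.
#' @return Character vector of predicted labels.
#' @export
predict.id3_tree <- function(object, newdata, ...) {
  if (inherits(newdata, "nominal_dataset")) newdata <- newdata$data
  vapply(seq_len(nrow(newdata)), function(i)
    predict_one(object$root, newdata[i, , drop = FALSE]), "")
}

#' Serialize / deserialize an ID3 tree as JSON
#'
#' @param tree An `id3_tree`.
#' @param path File path.
#' @return `path` (write) or an `id3_tree` (read).
#' @export
write_tree_json <- function(tree, path) {
  jsonlite::write_json(
    list(root = tree$root, attributes = tree$attributes,
         classes = tree$classes, depth = tree$depth, n_train = tree$n_train),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  fix <- function(nd) {
    nd$leaf <- isTRUE(nd$leaf)
    if (!nd$leaf) nd$children <- lapply(nd$children, fix)
    nd
  }
  structure(list(root = fix(x$root),
                 attributes = unlist(x$attributes),
                 classes = unlist(x$classes),
                 depth = x$depth, n_train = x$n_train),
            class = "id3_tree")
}
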