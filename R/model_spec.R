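#' Specify a linear ADMG causal model
#'
#' A model is an acyclic directed mixed graph (ADMG) over `variables`
#' together with parameter labels.  Directed edges carry path
#' coefficients (entries of the matrix `C`); bidirected edges carry
#' error (co)variances (entries of the symmetric matrix `Psi`), with a
#' self-pair `(v, v, label)` declaring the error variance of `v`.
#' Re-using a label on several edges imposes an equality constraint
#' (e.g. time-constant cross-lagged effects in a panel model); labels
#' listed in `fixed` are held at the given value and are not free
#' parameters.
#'
#' The free parameter vector `theta` of a model is ordered as
#' \eqn{\theta = (\theta_F, \theta_P)}: structural labels in order of
#' first appearance in `directed`, then covariance labels in order of
#' first appearance in `bidirected`.
#'
#' @param variables character vector of variable names (the causal
#'   order in which they are listed need not be topological).
#' @param directed directed edges: a data frame or matrix with columns
#'   `from`, `to`, `label`, or a list of 3-element character vectors.
#'   May be `NULL` for a model with no directed edges.
#' @param bidirected bidirected edges / error (co)variances in the same
#'   3-column format (`v1`, `v2`, `label`).  Every variable must appear
#'   as a self-pair so that the diagonal of `Psi` is fully specified.
#' @param fixed optional named numeric vector of labels held at fixed
#'   values.
#' @return an object of class `dosem_spec` with elements `variables`,
#'   `directed`, `bidirected`, `fixed`, `labels_F`, `labels_P`, `q`,
#'   `p`, `n` and the topological `order` of the directed part.
#' @seealso [read_model_spec()], [build_matrices()],
#'   [illustration_fixture()]
#' @export
#' @examples
#' spec <- model_spec(
#'   variables = c("V1", "V2"),
#'   directed = list(c("V1", "V2", "c")),
#'   bidirected = list(c("V1", "V1", "s1"), c("V2", "V2", "s2"))
#' )
#' spec$labels_F  # "c"
model_spec <- function(variables, directed = NULL, bidirected, fixed = NULL) {
  variables <- as.character(variables)
  if (anyDuplicated(variables))
    dosem_error("bad_spec", "duplicate variable names")
  n <- length(variables)

  directed <- normalize_edges(directed, c("from", "to", "label"))
  bidirected <- normalize_edges(bidirected, c("v1", "v2", "label"))
  if (nrow(bidirected) == 0L)
    dosem_error("bad_spec", "bidirected edges (error variances) are required")

  for (col in c(directed$from, directed$to, bidirected$v1, bidirected$v2)) {
    if (!all(col %in% variables))
      dosem_error("bad_spec", paste0(
        "unknown variable in edge list: ",
        paste(setdiff(col, variables), collapse = ", ")))
  }
  if (any(directed$from == directed$to))
    dosem_error("bad_spec", "a variable cannot cause itself (self-loop)")

  # Psi diagonal must be fully specified
  selfpairs <- bidirected$v1[bidirected$v1 == bidirected$v2]
  missing_var <- setdiff(variables, selfpairs)
  if (length(missing_var))
    dosem_error("bad_spec", paste0(
      "no error variance declared for: ", paste(missing_var, collapse = ", ")))

  # no label on both a directed and a bidirected edge
  shared <- intersect(directed$label, bidirected$label)
  if (length(shared))
    dosem_error("bad_spec", paste0(
      "label used on both directed and bidirected edges: ",
      paste(shared, collapse = ", ")))

  fixed <- validate_fixed(fixed, c(directed$label, bidirected$label))

  ord <- topological_order(variables, directed)
  if (is.null(ord))
    dosem_error("cycle", "directed part of the graph contains a cycle")

  labels_F <- setdiff(unique(directed$label), names(fixed))
  labels_P <- setdiff(unique(bidirected$label), names(fixed))

  structure(
    list(
      variables = variables,
      directed = directed,
      bidirected = bidirected,
      fixed = fixed,
      labels_F = labels_F,
      labels_P = labels_P,
      q = length(labels_F),
      p = length(labels_P),
      n = n,
      order = ord
    ),
    class = "dosem_spec"
  )
}

normalize_edges <- function(edges, cols) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0L)) {
    out <- data.frame(a = character(), b = character(), c = character(),
                      stringsAsFactors = FALSE)
    names(out) <- cols
    return(out)
  }
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) {
      if (length(e) != 3L)
        dosem_error("bad_spec", "each edge must be a (v, v, label) 3-tuple")
      as.character(e)
    }))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) != 3L)
    dosem_error("bad_spec", "edge table must have three columns")
  names(edges) <- cols
  for (j in seq_len(3L)) edges[[j]] <- as.character(edges[[j]])
  rownames(edges) <- NULL
  edges
}

validate_fixed <- function(fixed, all_labels) {
  if (is.null(fixed) || length(fixed) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  fixed <- unlist(fixed)
  if (is.null(names(fixed)) || any(names(fixed) == ""))
    dosem_error("bad_spec", "'fixed' must be a named numeric vector")
  unknown <- setdiff(names(fixed), all_labels)
  if (length(unknown))
    dosem_error("unknown_label", paste0(
      "fixed value for label not in the model: ",
      paste(unknown, collapse = ", ")))
  stats::setNames(as.numeric(fixed), names(fixed))
}

# Kahn's algorithm on the directed part; returns NULL on a cycle.
topological_order <- function(variables, directed) {
  n <- length(variables)
  idx <- stats::setNames(seq_len(n), variables)
  indeg <- integer(n)
  children <- vector("list", n)
  for (k in seq_len(nrow(directed))) {
    i <- idx[[directed$from[k]]]
    j <- idx[[directed$to[k]]]
    children[[i]] <- c(children[[i]], j)
    indeg[j] <- indeg[j] + 1L
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != n) return(NULL)
  out
}

#' Free parameter labels of a model in canonical order
#'
#' @param spec a [model_spec()] object.
#' @return character vector `c(labels_F, labels_P)`.
#' @export
theta_labels <- function(spec) {
  stopifnot(inherits(spec, "dosem_spec"))
  c(spec$labels_F, spec$labels_P)
}

# Validate a parameter vector and return it named, in canonical
# (labels_F, labels_P) order.  Unnamed vectors are taken to already be
# in canonical order.
theta_canonical <- function(spec, theta) {
  labels <- theta_labels(spec)
  theta <- unlist(theta)
  if (is.null(names(theta))) {
    if (length(theta) != length(labels))
      dosem_error("bad_theta", sprintf(
        "theta has length %d but the model has %d free parameters",
        length(theta), length(labels)))
    names(theta) <- labels
    return(theta)
  }
  unknown <- setdiff(names(theta), labels)
  if (length(unknown))
    dosem_error("unknown_label", paste0(
      "unknown parameter label: ", paste(unknown, collapse = ", ")))
  missing_lab <- setdiff(labels, names(theta))
  if (length(missing_lab))
    dosem_error("bad_theta", paste0(
      "no value for label: ", paste(missing_lab, collapse = ", ")))
  theta[labels]
}

#' @export
print.dosem_spec <- function(x, ...) {
  cat("Linear ADMG causal model (", x$n, " variables)\n", sep = "")
  cat("  variables:  ", paste(x$variables, collapse = ", "), "\n", sep = "")
  cat("  directed edges:   ", nrow(x$directed),
      " (", x$q, " free structural labels)\n", sep = "")
  cat("  bidirected edges: ", nrow(x$bidirected),
      " (", x$p, " free covariance labels)\n", sep = "")
  if (length(x$fixed))
    cat("  fixed: ", paste(names(x$fixed), "=", x$fixed, collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Read a model specification from a YAML or JSON file
#'
#' The file must contain the keys `variables`, `directed`, `bidirected`
#' and optionally `fixed`.  Edge entries are 3-element sequences
#' `(from, to, label)` for directed edges and `(v1, v2, label)` for
#' bidirected edges.  The order in which labels first appear defines
#' the parameter order of the model.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [model_spec()] object.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path))
    dosem_error("bad_spec", paste0("model file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (key in c("variables", "bidirected")) {
    if (is.null(raw[[key]]))
      dosem_error("bad_spec", paste0("model file lacks key '", key, "'"))
  }
  model_spec(
    variables = unlist(raw$variables),
    directed = raw$directed,
    bidirected = raw$bidirected,
    fixed = raw$fixed
  )
}
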