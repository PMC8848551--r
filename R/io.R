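# Serialization: JSON model files, CSV datasets, analysis reports.
#
# Models are stored as human-auditable JSON:
#   {nodes: [{id, arity, ancestors, table}], order: [...], meta: {...}}
# with each table a row-major (child-state x ancestor-event) matrix.  Reads
# are schema-validated: dangling ancestor references, ordering violations and
# non-stochastic columns are rejected with errors naming the offending node.

#' Write a model to a JSON file
#'
#' @param model a `bn_model`.
#' @param path output path.
#' @param meta named list of metadata to record (seed, alpha, density spec,
#'   ...); stored verbatim under `meta`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, meta = list()) {
  nodes <- lapply(model$dag$order, function(v) {
    list(id = v,
         arity = unname(model$arities[[v]]),
         ancestors = as.list(model$parents[[v]]),
         table = model$tables[[v]]$columns)
  })
  obj <- list(nodes = nodes, order = as.list(model$dag$order), meta = meta)
  # I(17) significant digits: doubles survive the round-trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read and validate a model from a JSON file
#'
#' @param path JSON file produced by [write_model()] (or conforming to its
#'   schema).
#' @return A validated `bn_model`.
#' @export
read_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyMatrix = TRUE),
                  error = function(e)
                    bn_stop("format_error", "cannot parse %s: %s",
                            path, conditionMessage(e)))
  if (is.null(obj$order) || is.null(obj$nodes))
    bn_stop("format_error", "model file lacks `order` or `nodes`")
  ord <- as.character(unlist(obj$order))
  nodes <- obj$nodes
  ids <- if (is.data.frame(nodes)) nodes$id else
    vapply(nodes, function(x) x$id, character(1))
  if (!setequal(ids, ord))
    bn_stop("format_error", "node ids do not match `order`")
  get_node <- function(i) {
    if (is.data.frame(nodes))
      list(id = nodes$id[i], arity = nodes$arity[i],
           ancestors = nodes$ancestors[[i]], table = nodes$table[[i]])
    else nodes[[i]]
  }
  pos <- stats::setNames(seq_along(ord), ord)
  arities <- integer(0)
  tables <- list()
  edges <- NULL
  for (i in seq_along(ids)) {
    nd <- get_node(i)
    anc <- as.character(unlist(nd$ancestors))
    dangling <- setdiff(anc, ord)
    if (length(dangling))
      bn_stop("format_error", "node %s references unknown ancestor %s",
              nd$id, dangling[1L])
    if (any(pos[anc] >= pos[nd$id]))
      bn_stop("format_error",
              "node %s has ancestor later in the topological order", nd$id)
    tab <- nd$table
    if (is.null(dim(tab))) tab <- matrix(tab, nrow = nd$arity)
    validate_stochastic(tab, nd$id)
    arities[nd$id] <- as.integer(nd$arity)
    anc <- anc[order(pos[anc])]
    tables[[nd$id]] <- new_cpt(tab, unname(arities[anc]) %||%
                                 integer(0))
    if (length(anc)) edges <- rbind(edges, cbind(from = anc, to = nd$id))
  }
  # ancestors of later nodes may be listed before their own arity is known;
  # re-derive ancestor arities in a second pass
  for (v in names(tables)) {
    anc <- if (is.null(edges)) character(0) else edges[edges[, "to"] == v, "from"]
    anc <- anc[order(pos[anc])]
    tables[[v]]$ancestor_arities <- as.integer(unname(arities[anc]))
  }
  if (is.null(edges))
    edges <- matrix(character(0), 0L, 2L,
                    dimnames = list(NULL, c("from", "to")))
  dag <- structure(list(n_nodes = length(ord), order = ord, edges = edges),
                   class = "bn_dag")
  model <- bn_model(dag, arities, tables)
  attr(model, "meta") <- obj$meta
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset to CSV
#'
#' Comma-separated, header row of node labels, 0-based integer states, no row
#' names.
#'
#' @param dataset data.frame as produced by [sample_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset from CSV, optionally validating against a model
#'
#' Columns are matched (and reordered) by header; when a model is supplied,
#' unknown headers, missing nodes and out-of-range states are rejected.
#'
#' @param path CSV file.
#' @param model optional `bn_model` to validate against.
#' @return data.frame of integer states.
#' @export
read_dataset <- function(path, model = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L)
    bn_stop("data_integrity", "dataset %s is empty", path)
  if (!is.null(model)) {
    nodes <- model$dag$order
    unknown <- setdiff(names(df), nodes)
    if (length(unknown))
      bn_stop("data_integrity", "unknown column(s): %s",
              paste(unknown, collapse = ", "))
    missing <- setdiff(nodes, names(df))
    if (length(missing))
      bn_stop("data_integrity", "missing column(s): %s",
              paste(missing, collapse = ", "))
    df <- df[, nodes, drop = FALSE]
    for (v in nodes) {
      bad <- which(df[[v]] < 0L | df[[v]] >= model$arities[[v]] |
                     df[[v]] != floor(df[[v]]))
      if (length(bad))
        bn_stop("data_integrity",
                "row %d: state %s out of range for node %s",
                bad[1L], df[bad[1L], v], v)
    }
  }
  df
}

#' Compare a dataset against a model's analytic joint
#'
#' @param model a `bn_model`.
#' @param dataset data.frame of 0-based states over the model's nodes.
#' @param base JSD logarithm base (default 2, bits).
#' @return List: `jsd`, `n_events` (size of the joint event space),
#'   `n_observed_events` (events with at least one sample), `n_rows`, and
#'   per-node `marginals` (analytic).
#' @export
analyze_dataset <- function(model, dataset, base = 2) {
  analytic <- enumerate_joint(model)
  emp <- empirical_joint(dataset, model)
  list(jsd = jsd(emp, analytic, base = base),
       n_events = length(analytic$probs),
       n_observed_events = sum(emp$probs > 0),
       n_rows = nrow(dataset),
       marginals = node_marginals(model))
}
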