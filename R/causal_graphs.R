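#' Count labeled directed acyclic graphs on M nodes
#'
#' Number of distinct binary causal configurations (DAGs) that `M` labeled
#' timeseries can exhibit, computed by the classical inclusion-exclusion
#' recursion over the number of sink-free... more precisely, over the number
#' of nodes with zero in-degree:
#' \deqn{a_M = \sum_{k=1}^{M} (-1)^{k-1} \binom{M}{k} 2^{k(M-k)} a_{M-k},
#'   \quad a_0 = 1.}
#'
#' @param M Non-negative integer number of labeled nodes.
#' @return The number of labeled DAGs on `M` nodes (`a_0 = 1`, `a_3 = 25`).
#' @examples
#' count_dags(3)  # 25
#' @export
count_dags <- function(M) {
  if (length(M) != 1L || !is.finite(M) || M != as.integer(M) || M < 0)
    stop("`M` must be a single non-negative integer", call. = FALSE)
  M <- as.integer(M)
  a <- numeric(M + 1L)
  a[1L] <- 1  # a_0
  if (M >= 1L) {
    for (m in seq_len(M)) {
      k <- seq_len(m)
      a[m + 1L] <- sum((-1)^(k - 1) * choose(m, k) * 2^(k * (m - k)) * a[m - k + 1L])
    }
  }
  a[M + 1L]
}

#' Test a binary adjacency matrix for acyclicity
#'
#' Kahn-style elimination: repeatedly remove nodes with zero in-degree; the
#' graph is acyclic iff every node can be removed.
#'
#' @param A Square binary matrix with zero diagonal; `A[i, j] = 1` means node
#'   `i` causes node `j`.
#' @return `TRUE` iff the directed graph of `A` has no directed cycle.
#' @export
is_acyclic <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("`A` must be a square matrix", call. = FALSE)
  if (!all(A %in% c(0, 1)))
    stop("`A` must be binary (0/1)", call. = FALSE)
  if (nrow(A) > 0 && any(diag(A) != 0))
    stop("`A` must have a zero diagonal", call. = FALSE)
  A <- matrix(as.numeric(A), nrow(A))
  alive <- rep(TRUE, nrow(A))
  repeat {
    if (!any(alive)) return(TRUE)
    indeg <- colSums(A[alive, , drop = FALSE])
    removable <- alive & indeg == 0
    if (!any(removable)) return(FALSE)
    alive[removable] <- FALSE
  }
}

#' Construct a causal configuration
#'
#' A causal configuration is an `M x M` binary acyclic adjacency matrix `A`
#' (`A[i, j] = 1` iff channel `i` causes channel `j`) plus its 0-based
#' position in the canonical catalog, when known.
#'
#' @param A Binary acyclic adjacency matrix with zero diagonal.
#' @param class_index Optional 0-based index in the canonical catalog.
#' @return An object of class `causal_config` with fields `M`, `A`,
#'   `class_index`.
#' @export
causal_config <- function(A, class_index = NA_integer_) {
  if (!is_acyclic(A)) stop("adjacency matrix contains a directed cycle", call. = FALSE)
  storage.mode(A) <- "integer"
  structure(list(M = nrow(A), A = A, class_index = as.integer(class_index)),
            class = "causal_config")
}

#' @export
print.causal_config <- function(x, ...) {
  cat("<causal_config> M =", x$M, " class_index =", x$class_index,
      " edges:", if (length(config_edges(x))) paste(vapply(config_edges(x), function(e)
        paste0(e[1], "->", e[2]), ""), collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Directed edges of a configuration
#'
#' @param config A `causal_config`.
#' @return List of integer pairs `c(i, j)` with `A[i, j] = 1`, in row-major
#'   order (for M = 3: X->Y, X->Z, Y->X, Y->Z, Z->X, Z->Y restricted to the
#'   edges present).
#' @export
config_edges <- function(config) {
  A <- config$A
  out <- list()
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    if (i != j && A[i, j] == 1) out[[length(out) + 1L]] <- c(i, j)
  out
}

#' Off-diagonal cell order used for edge scoring
#'
#' The fixed ordering of the `M * (M - 1)` directed node pairs used whenever
#' a flat vector of per-edge quantities is produced (row-major over the
#' off-diagonal cells; for M = 3: X->Y, X->Z, Y->X, Y->Z, Z->X, Z->Y).
#'
#' @param M Number of nodes.
#' @return Integer matrix with columns `from`, `to`, one row per ordered pair.
#' @export
edge_order <- function(M = 3L) {
  pairs <- expand.grid(to = seq_len(M), from = seq_len(M))[, c("from", "to")]
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[order(pairs$from, pairs$to), ]
  m <- as.matrix(pairs)
  dimnames(m) <- list(NULL, c("from", "to"))
  m
}

#' Enumerate the catalog of DAG causal configurations
#'
#' Brute-force enumeration of every zero-diagonal binary `M x M` matrix,
#' keeping the acyclic ones, in a canonical deterministic order: ascending by
#' edge count, ties broken lexicographically on the row-major flattened
#' adjacency. Class 0 is always the empty (fully independent) configuration.
#'
#' @param M Number of labeled nodes (feasible up to 4).
#' @return A `dag_catalog`: list with `M`, `configurations` (list of
#'   `causal_config`, `class_index` 0-based), and `ordering_rule`.
#' @export
enumerate_dags <- function(M) {
  if (length(M) != 1L || M < 1 || M != as.integer(M))
    stop("`M` must be a single positive integer", call. = FALSE)
  M <- as.integer(M)
  n_off <- M * (M - 1L)
  if (n_off > 16L)
    stop("enumeration over 2^", n_off, " digraphs is infeasible", call. = FALSE)
  off <- which(diag(M) == 0)  # column-major linear indices of off-diagonal cells
  mats <- list()
  for (code in 0:(2^n_off - 1L)) {
    bits <- as.integer(intToBits(code)[seq_len(n_off)])
    A <- matrix(0L, M, M)
    A[off] <- bits
    if (is_acyclic(A)) mats[[length(mats) + 1L]] <- A
  }
  # canonical order: edge count ascending, then lexicographic on row-major key
  keys <- vapply(mats, function(A) paste(t(A), collapse = ""), "")
  ord <- order(vapply(mats, sum, 0), keys)
  mats <- mats[ord]
  configs <- lapply(seq_along(mats), function(k) causal_config(mats[[k]], k - 1L))
  structure(list(M = M, configurations = configs,
                 ordering_rule = "edge count ascending, then lexicographic on row-major flattened adjacency"),
            class = "dag_catalog")
}

#' @export
print.dag_catalog <- function(x, ...) {
  cat("<dag_catalog> M =", x$M, ",", length(x$configurations), "configurations;",
      "ordering:", x$ordering_rule, "\n")
  invisible(x)
}

#' @export
length.dag_catalog <- function(x) length(x$configurations)

#' Advisory grouping of a configuration by interaction complexity
#'
#' Tags a configuration as `"independent"` (no edges), `"univariate"` (one
#' edge), `"bivariate"` (edges touching at most two distinct source-target
#' chains, i.e. exactly two edges), or `"trivariate"` (three or more edges).
#' The grouping is advisory: it is derived from edge count only.
#'
#' @param config A `causal_config`.
#' @return Character tag.
#' @export
config_group <- function(config) {
  ne <- sum(config$A)
  if (ne == 0) "independent" else if (ne == 1) "univariate"
  else if (ne == 2) "bivariate" else "trivariate"
}

#' Serialize a catalog to JSON
#'
#' @param catalog A `dag_catalog`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
catalog_to_json <- function(catalog, path = NULL) {
  obj <- list(M = catalog$M, ordering_rule = catalog$ordering_rule,
              configs = lapply(catalog$configurations, function(cf) as.integer(t(cf$A))))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Restore a catalog from JSON
#'
#' @param json JSON string or path to a JSON file produced by
#'   [catalog_to_json()].
#' @return A `dag_catalog`.
#' @export
catalog_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  M <- as.integer(obj$M)
  configs <- lapply(seq_along(obj$configs), function(k) {
    A <- matrix(as.integer(unlist(obj$configs[[k]])), M, M, byrow = TRUE)
    causal_config(A, k - 1L)
  })
  structure(list(M = M, configurations = configs, ordering_rule = obj$ordering_rule),
            class = "dag_catalog")
}

#' Look up a named 3-node configuration
#'
#' Convenience constructor for the scenarios used throughout the package:
#' `"empty"` (independent channels), `"xy"` (X->Y univariate), and
#' `"chain"` (X->Y->Z bivariate chain).
#'
#' @param name One of `"empty"`, `"xy"`, `"chain"`.
#' @param catalog Optional `dag_catalog` for M = 3 used to resolve the class
#'   index; enumerated on the fly when missing.
#' @return A `causal_config` with its catalog `class_index` filled in.
#' @export
named_config <- function(name = c("empty", "xy", "chain"), catalog = NULL) {
  name <- match.arg(name)
  A <- matrix(0L, 3, 3)
  if (name == "xy") A[1, 2] <- 1L
  if (name == "chain") { A[1, 2] <- 1L; A[2, 3] <- 1L }
  if (is.null(catalog)) catalog <- enumerate_dags(3L)
  idx <- config_class_index(catalog, A)
  causal_config(A, idx)
}

#' Catalog index of an adjacency matrix
#'
#' @param catalog A `dag_catalog`.
#' @param A Adjacency matrix to look up.
#' @return 0-based class index, or `NA` if absent.
#' @export
config_class_index <- function(catalog, A) {
  for (cf in catalog$configurations)
    if (all(cf$A == A)) return(cf$class_index)
  NA_integer_
}
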