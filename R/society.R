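#' Build the random social network of a model society
#'
#' Draws an Erdos-Renyi graph `G(N, rho)` — each of the `N(N-1)/2` node pairs
#' is linked independently with probability `rho` — and labels all nodes as
#' (uncoordinated) laborers: the initial society has no administrators.
#'
#' Uses the current R RNG state; [run_simulation()] seeds it from
#' `params$seed` so runs are reproducible.
#'
#' @param params A [model_params()] object.
#' @return An object of class `"society"`: a list with elements
#'   `n` (node count), `edges` (two-column integer matrix of undirected
#'   edges, node ids `1..N`), `nbrs` (adjacency list), `degree` (integer
#'   vector, precomputed once since the network is static) and `admin`
#'   (logical vector flagging administrators).
#' @examples
#' soc <- build_network(model_params(N = 50, seed = 7))
#' classify_roles(soc)
#' @export
build_network <- function(params) {
  stopifnot(inherits(params, "model_params"))
  n <- params$N
  g <- igraph::sample_gnp(n, params$rho)
  edges <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(edges) <- "integer"
  nbrs <- lapply(igraph::adjacent_vertices(g, seq_len(n)), as.integer)
  structure(
    list(
      n = n,
      edges = edges,
      nbrs = nbrs,
      degree = lengths(nbrs),
      admin = logical(n)
    ),
    class = "society"
  )
}

#' Construct a society from an explicit edge list
#'
#' Mostly useful for tests and for reading serialized societies; the
#' simulator itself builds random networks with [build_network()].
#'
#' @param n Node count; nodes are `1..n`.
#' @param edges Two-column matrix (or data frame) of undirected edges.
#'   Self-loops and duplicate edges are rejected.
#' @param admin Integer vector of administrator node ids (default none).
#' @return A `"society"` object.
#' @export
society <- function(n, edges = matrix(integer(), ncol = 2), admin = integer()) {
  edges <- as.matrix(edges)
  if (length(edges) == 0) edges <- matrix(integer(), ncol = 2)
  storage.mode(edges) <- "integer"
  stopifnot(n >= 1, ncol(edges) == 2)
  if (nrow(edges)) {
    if (any(edges < 1 | edges > n)) stop("edge endpoints must be in 1..n")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(key)) stop("multi-edges are not allowed")
  }
  nbrs <- rep(list(integer()), n)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]; v <- edges[i, 2]
    nbrs[[u]] <- c(nbrs[[u]], v)
    nbrs[[v]] <- c(nbrs[[v]], u)
  }
  adm <- logical(n)
  adm[as.integer(admin)] <- TRUE
  structure(
    list(n = as.integer(n), edges = edges, nbrs = nbrs,
         degree = lengths(nbrs), admin = adm),
    class = "society"
  )
}

#' Count laborers, coordinated laborers and administrators
#'
#' Role classification is derived, never cached: a non-administrator adjacent
#' to at least one administrator is a coordinated laborer (adjacency to more
#' than one administrator does not count extra); the remaining
#' non-administrators are uncoordinated laborers. The three classes always
#' partition the node set.
#'
#' @param state A `"society"` object.
#' @return One-row tibble with integer columns `N_L`, `N_C`, `N_A`.
#' @export
classify_roles <- function(state) {
  stopifnot(inherits(state, "society"))
  cnt <- admin_neighbor_counts(state)
  N_A <- sum(state$admin)
  N_C <- sum(!state$admin & cnt > 0L)
  tibble::tibble(N_L = state$n - N_A - N_C, N_C = N_C, N_A = N_A)
}

# number of administrator neighbors per node, recomputed from scratch
admin_neighbor_counts <- function(state) {
  cnt <- integer(state$n)
  for (v in which(state$admin)) {
    nb <- state$nbrs[[v]]
    if (length(nb)) cnt[nb] <- cnt[nb] + 1L
  }
  cnt
}

#' Per-node role table
#'
#' @param state A `"society"` object.
#' @return Tibble with one row per node: `node`, `degree`, `role`
#'   (`"L"`, `"C"` or `"A"`).
#' @export
node_roles <- function(state) {
  stopifnot(inherits(state, "society"))
  cnt <- admin_neighbor_counts(state)
  role <- ifelse(state$admin, "A", ifelse(cnt > 0L, "C", "L"))
  tibble::tibble(node = seq_len(state$n), degree = state$degree, role = role)
}

#' @export
print.society <- function(x, ...) {
  r <- classify_roles(x)
  cat(sprintf(
    "<society> %d nodes, %d edges | N_L = %d, N_C = %d, N_A = %d\n",
    x$n, nrow(x$edges), r$N_L, r$N_C, r$N_A
  ))
  invisible(x)
}

#' Serialize a society to a plain-text file
#'
#' Writes a whitespace-separated text format: a node section (`node role`,
#' one line per node) followed by an edge section (two integer columns, one
#' line per undirected edge). [read_society()] inverts it exactly.
#'
#' @param state A `"society"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_society <- function(state, path) {
  stopifnot(inherits(state, "society"))
  roles <- node_roles(state)
  lines <- c(
    sprintf("nodes %d", state$n),
    sprintf("%d %s", roles$node, roles$role),
    sprintf("edges %d", nrow(state$edges)),
    if (nrow(state$edges)) sprintf("%d %d", state$edges[, 1], state$edges[, 2])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a society written by [write_society()]
#'
#' @param path File path.
#' @return A `"society"` object; coordinated/laborer labels are re-derived
#'   from adjacency to the administrator set, as everywhere else.
#' @export
read_society <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (hd[1] != "nodes") stop("not a society file: ", path)
  n <- as.integer(hd[2])
  node_lines <- strsplit(lines[1 + seq_len(n)], " ", fixed = TRUE)
  admin <- vapply(node_lines, function(x) x[2] == "A", logical(1))
  eh <- strsplit(lines[n + 2], " ", fixed = TRUE)[[1]]
  if (eh[1] != "edges") stop("malformed society file: ", path)
  m <- as.integer(eh[2])
  edges <- matrix(integer(), ncol = 2)
  if (m > 0) {
    ed <- strsplit(lines[n + 2 + seq_len(m)], " ", fixed = TRUE)
    edges <- matrix(as.integer(unlist(ed)), ncol = 2, byrow = TRUE)
  }
  society(n, edges, admin = which(admin))
}
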