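#' Areal adjacency graph
#'
#' Constructs the adjacency structure used by every CAR computation in the
#' package: a set of areal units with a symmetric neighbour relation
#' (areas sharing a boundary), together with its connected components.
#' All per-area vectors in the package are index-aligned to the order of
#' `area_ids`.
#'
#' @param neighbours list of integer vectors; `neighbours[[i]]` holds the
#'   indices of the areas adjacent to area `i`. May be empty for islands.
#' @param area_ids optional character vector of unique area labels;
#'   defaults to `"1" ... "n"`.
#' @return An object of class `area_graph` with fields `n_areas`,
#'   `area_ids`, `neighbours`, `n_components`, `component_labels`.
#' @examples
#' g <- area_graph(list(2L, c(1L, 3L), 2L))
#' g$n_components
#' @export
area_graph <- function(neighbours, area_ids = NULL) {
  n <- length(neighbours)
  check(n >= 1, "graph must contain at least one area")
  if (is.null(area_ids)) area_ids <- as.character(seq_len(n))
  area_ids <- as.character(area_ids)
  check(length(area_ids) == n, "area_ids length (%d) != number of areas (%d)",
        length(area_ids), n)
  check(!anyDuplicated(area_ids), "duplicate area id: %s",
        paste(unique(area_ids[duplicated(area_ids)]), collapse = ", "))
  neighbours <- lapply(neighbours, function(v) sort(unique(as.integer(v))))
  for (i in seq_len(n)) {
    nb <- neighbours[[i]]
    check(all(nb >= 1 & nb <= n), "neighbour index out of range for area %s", area_ids[i])
    check(!(i %in% nb), "self-loop at area %s", area_ids[i])
    for (j in nb) {
      check(i %in% neighbours[[j]],
            "asymmetric adjacency: %s lists %s but not conversely",
            area_ids[i], area_ids[j])
    }
  }
  comp <- graph_components(neighbours)
  structure(
    list(n_areas = n, area_ids = area_ids, neighbours = neighbours,
         n_components = max(comp), component_labels = comp),
    class = "area_graph")
}

## breadth-first labelling of connected components
graph_components <- function(neighbours) {
  n <- length(neighbours)
  lab <- integer(n)
  comp <- 0L
  for (start in seq_len(n)) {
    if (lab[start] > 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (w in neighbours[[v]]) {
        if (lab[w] == 0L) {
          lab[w] <- comp
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

#' @export
print.area_graph <- function(x, ...) {
  deg <- lengths(x$neighbours)
  cat("area_graph:", x$n_areas, "areas,",
      sum(deg) / 2, "adjacencies,", x$n_components,
      if (x$n_components == 1L) "component\n" else "components\n")
  cat("  degree range:", min(deg), "-", max(deg),
      "; isolated areas:", sum(deg == 0L), "\n")
  invisible(x)
}

#' Read a GAL spatial-weights file
#'
#' Reads the GAL text dialect: a header line `0 <n> <name> <name>`, then for
#' each area a record line `<id> <k>` followed by a line of `k` neighbour
#' ids. Area order in the file fixes the index order of the graph.
#' Asymmetric entries are an error, never silently symmetrised.
#'
#' @param path path to a GAL file.
#' @return An `area_graph`.
#' @seealso [write_gal()]
#' @export
read_gal <- function(path) {
  check(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  check(length(lines) >= 1, "empty GAL file: %s", path)
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  check(length(header) >= 2, "malformed GAL header: %s", lines[[1]])
  n <- suppressWarnings(as.integer(header[[2]]))
  check(!is.na(n) && n >= 1, "bad area count in GAL header: %s", header[[2]])
  ids <- character(n)
  raw_nbs <- vector("list", n)
  cursor <- 2L
  for (i in seq_len(n)) {
    check(cursor <= length(lines), "truncated GAL file: expected %d areas", n)
    rec <- strsplit(trimws(lines[[cursor]]), "\\s+")[[1]]
    check(length(rec) == 2, "malformed GAL record line: %s", lines[[cursor]])
    ids[i] <- rec[[1]]
    k <- suppressWarnings(as.integer(rec[[2]]))
    check(!is.na(k) && k >= 0, "bad neighbour count for area %s", rec[[1]])
    if (k > 0) {
      check(cursor + 1L <= length(lines), "truncated GAL file at area %s", rec[[1]])
      nb <- strsplit(trimws(lines[[cursor + 1L]]), "\\s+")[[1]]
      check(length(nb) == k, "area %s declares %d neighbours but lists %d",
            rec[[1]], k, length(nb))
      raw_nbs[[i]] <- nb
      cursor <- cursor + 2L
    } else {
      raw_nbs[[i]] <- character(0)
      cursor <- cursor + 1L
    }
  }
  check(!anyDuplicated(ids), "duplicate area id in GAL file: %s",
        paste(unique(ids[duplicated(ids)]), collapse = ", "))
  idx <- seq_len(n)
  names(idx) <- ids
  neighbours <- lapply(raw_nbs, function(nb) {
    unknown <- setdiff(nb, ids)
    check(length(unknown) == 0, "neighbour id not defined in file: %s",
          paste(unknown, collapse = ", "))
    unname(idx[nb])
  })
  area_graph(neighbours, ids)
}

#' Write an `area_graph` as a GAL file
#'
#' @param graph an `area_graph`.
#' @param path output path.
#' @param name dataset name written into the header.
#' @return `path`, invisibly.
#' @export
write_gal <- function(graph, path, name = "areas") {
  stopifnot(inherits(graph, "area_graph"))
  out <- c(sprintf("0 %d %s %s", graph$n_areas, name, name))
  for (i in seq_len(graph$n_areas)) {
    nb <- graph$neighbours[[i]]
    out <- c(out, sprintf("%s %d", graph$area_ids[i], length(nb)))
    if (length(nb)) out <- c(out, paste(graph$area_ids[nb], collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}

#' Rectangular grid graph with rook adjacency
#'
#' The default synthetic map: a `nrow` by `ncol` lattice in which areas are
#' adjacent when they share an edge, optionally trimmed (in row-major order)
#' to the first `n_keep` cells. The package default map is a 22 x 22 grid
#' trimmed to 478 areas, standing in for a state-wide set of census areas.
#'
#' @param nrow,ncol grid dimensions.
#' @param n_keep optional number of areas to keep (row-major prefix).
#' @return An `area_graph` with ids `"r<row>c<col>"`; attribute `coords`
#'   holds the (row, col) of each kept cell.
#' @export
grid_graph <- function(nrow, ncol, n_keep = NULL) {
  check(nrow >= 1 && ncol >= 1, "grid dimensions must be positive")
  n_full <- nrow * ncol
  if (is.null(n_keep)) n_keep <- n_full
  check(n_keep >= 1 && n_keep <= n_full, "n_keep must be in 1..%d", n_full)
  cell <- function(r, c) (r - 1L) * ncol + c
  neighbours <- vector("list", n_keep)
  coords <- matrix(0L, n_keep, 2, dimnames = list(NULL, c("row", "col")))
  for (r in seq_len(nrow)) for (c in seq_len(ncol)) {
    i <- cell(r, c)
    if (i > n_keep) next
    coords[i, ] <- c(r, c)
    nb <- integer(0)
    if (r > 1L) nb <- c(nb, cell(r - 1L, c))
    if (r < nrow) nb <- c(nb, cell(r + 1L, c))
    if (c > 1L) nb <- c(nb, cell(r, c - 1L))
    if (c < ncol) nb <- c(nb, cell(r, c + 1L))
    neighbours[[i]] <- nb[nb <= n_keep]
  }
  ids <- sprintf("r%dc%d", coords[, "row"], coords[, "col"])
  g <- area_graph(neighbours, ids)
  attr(g, "coords") <- coords
  g
}

#' Default synthetic map (478 areas)
#'
#' A 22 x 22 rook-adjacency grid trimmed to 478 areas, matching the number
#' of areal units in the motivating cohort.
#' @return An `area_graph` with 478 areas.
#' @export
default_graph <- function() grid_graph(22, 22, 478)

#' Graph Laplacian of an areal graph
#'
#' Dense matrix `L = D - W` with `W` the 0/1 adjacency and `D` the degree
#' diagonal. The intrinsic CAR quadratic penalty is `x' L x`.
#' @param graph an `area_graph`.
#' @return An `n_areas` square matrix.
#' @export
graph_laplacian <- function(graph) {
  stopifnot(inherits(graph, "area_graph"))
  n <- graph$n_areas
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- graph$neighbours[[i]]
    L[i, i] <- length(nb)
    L[i, nb] <- -1
  }
  dimnames(L) <- list(graph$area_ids, graph$area_ids)
  L
}

#' Intrinsic CAR log-density (up to an additive constant)
#'
#' The intrinsic conditional autoregressive prior penalises squared
#' differences between neighbouring areas:
#' \deqn{\log p(x \mid \tau) = \frac{rank}{2}\log\tau -
#'   \frac{\tau}{2}\sum_{i \sim j}(x_i - x_j)^2 + const,}
#' where the sum runs over unordered neighbour pairs and
#' `rank = n_areas - n_components` (the rank of the graph Laplacian), so
#' that precision updates remain correct on maps with islands.
#'
#' @param x per-area numeric vector.
#' @param tau positive precision.
#' @param graph an `area_graph`.
#' @return log-density up to an additive constant.
#' @export
car_log_density <- function(x, tau, graph) {
  stopifnot(inherits(graph, "area_graph"))
  check(length(x) == graph$n_areas, "x has length %d, graph has %d areas",
        length(x), graph$n_areas)
  check(is.numeric(tau) && length(tau) == 1 && tau > 0, "tau must be a positive scalar")
  quad <- car_quad_form(x, graph)
  rank <- graph$n_areas - graph$n_components
  (rank / 2) * log(tau) - (tau / 2) * quad
}

## sum over unordered neighbour pairs of (x_i - x_j)^2 == x' L x
car_quad_form <- function(x, graph) {
  q <- 0
  for (i in seq_len(graph$n_areas)) {
    nb <- graph$neighbours[[i]]
    nb <- nb[nb > i]                      # each unordered pair once
    if (length(nb)) q <- q + sum((x[i] - x[nb])^2)
  }
  q
}

## eigendecomposition of the Laplacian, with the null space identified
laplacian_eigen <- function(graph, tol = 1e-8) {
  L <- graph_laplacian(graph)
  e <- eigen(L, symmetric = TRUE)
  pos <- e$values > tol * max(e$values, 1)
  list(values = e$values, vectors = e$vectors, pos = pos)
}

#' Sample a centred intrinsic CAR field
#'
#' Draws from the singular Gaussian with precision `tau * L` restricted to
#' the space orthogonal to the Laplacian null space, i.e. the intrinsic CAR
#' distribution under a per-component sum-to-zero constraint. Sampling is
#' along the positive Laplacian eigenvectors with variances
#' `1 / (tau * lambda)`, so the draw's covariance is the Moore-Penrose
#' pseudo-inverse of `tau * L`.
#'
#' @param graph an `area_graph`.
#' @param tau positive precision.
#' @param n number of draws.
#' @param seed optional integer; when given, the draw is made under a local
#'   RNG state so the ambient RNG stream is untouched.
#' @return a per-area numeric vector if `n == 1`, else an
#'   `n_areas x n` matrix of independent draws.
#' @export
sample_car_field <- function(graph, tau, n = 1, seed = NULL) {
  stopifnot(inherits(graph, "area_graph"))
  check(is.numeric(tau) && length(tau) == 1 && tau > 0, "tau must be a positive scalar")
  e <- laplacian_eigen(graph)
  k <- sum(e$pos)
  draw <- function() {
    if (k == 0) return(matrix(0, graph$n_areas, n))
    sd <- 1 / sqrt(tau * e$values[e$pos])
    z <- matrix(stats::rnorm(k * n, 0, sd), k, n)
    e$vectors[, e$pos, drop = FALSE] %*% z
  }
  x <- with_seed(seed, draw())
  if (n == 1) as.vector(x) else x
}

#' Centre a per-area vector to sum to zero within each component
#'
#' Subtracts the mean within each connected component, the identifiability
#' constraint imposed on all CAR fields. A global constraint would not pin
#' down the level of each island, so centring is per component.
#'
#' @param x per-area numeric vector.
#' @param graph an `area_graph`.
#' @return centred vector.
#' @export
center_sum_to_zero <- function(x, graph) {
  stopifnot(inherits(graph, "area_graph"))
  check(length(x) == graph$n_areas, "x has length %d, graph has %d areas",
        length(x), graph$n_areas)
  means <- tapply(x, graph$component_labels, mean)
  x - as.vector(means[as.character(graph$component_labels)])
}

#' CAR precision achieving a target marginal standard deviation
#'
#' Under the centred intrinsic CAR the marginal variance of area `i` is
#' `diag((tau L)^+)[i]`. This helper returns the precision for which the
#' average marginal standard deviation across areas equals `sd`, used by
#' the synthetic-cohort generator to state field strengths on an
#' interpretable scale.
#'
#' @param graph an `area_graph`.
#' @param sd target average marginal standard deviation (> 0).
#' @return positive precision `tau`.
#' @export
car_precision_for_sd <- function(graph, sd) {
  check(is.numeric(sd) && length(sd) == 1 && sd > 0, "sd must be a positive scalar")
  e <- laplacian_eigen(graph)
  check(any(e$pos), "graph has no adjacencies; CAR variance undefined")
  V <- e$vectors[, e$pos, drop = FALSE]
  mvar <- rowSums(sweep(V^2, 2, e$values[e$pos], "/"))  # diag of L^+
  mean(mvar) / sd^2
}
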