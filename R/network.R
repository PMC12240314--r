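#' Dichotomize an OD matrix
#'
#' Maps a weighted origin-destination matrix to a 0/1 adjacency matrix:
#' 1 wherever any positive flow exists.
#'
#' @param od An `od_matrix` (or plain numeric matrix).
#' @return A `binary_matrix` with the same indices and metadata.
#' @export
dichotomize <- function(od) {
  m <- unclass(od)
  b <- (m > 0) * 1
  structure(b,
            level = attr(od, "level"), category = attr(od, "category"),
            period = attr(od, "period"),
            class = c("binary_matrix", "od_matrix", class(b)))
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("<binary_matrix> level=%s category=%s period=%s [%d x %d], %d links\n",
              attr(x, "level"), attr(x, "category"), attr(x, "period"),
              nrow(x), ncol(x), sum(x > 0)))
  invisible(x)
}

#' Possible adjacencies between sources and destinations
#'
#' Ordered source-destination pairs, self-pairs included: with a full
#' national roster this gives 2,446 x 2,446 = 5,982,916 possible municipal
#' adjacencies and 32 x 32 = 1,024 possible state adjacencies.
#'
#' @param n_sources,n_destinations Node counts (>= 0).
#' @return Number of possible directed links.
#' @export
possible_adjacencies <- function(n_sources, n_destinations) {
  stopifnot(n_sources >= 0, n_destinations >= 0)
  as.numeric(n_sources) * as.numeric(n_destinations)
}

#' Link density as a percentage
#'
#' @param links Realized link count.
#' @param possible Possible link count (> 0).
#' @return Density in percent, in \[0, 100\].
#' @export
link_density <- function(links, possible) {
  if (possible <= 0)
    stop("density undefined for zero possible links", call. = FALSE)
  if (links < 0 || links > possible)
    stop("realized links must lie in [0, possible]", call. = FALSE)
  100 * links / possible
}

#' Network density of a dichotomized matrix
#'
#' Realized links as a percentage of possible links, where the possible
#' links are all ordered source-destination pairs including self-pairs
#' (the diagonal carries intra-unit trade).
#'
#' @param bm A `binary_matrix` (a weighted `od_matrix` is dichotomized
#'   first).
#' @return Tibble with columns `links`, `possible`, `density`.
#' @export
net_density <- function(bm) {
  if (!inherits(bm, "binary_matrix")) bm <- dichotomize(bm)
  if (nrow(bm) == 0 || ncol(bm) == 0)
    stop("density undefined for an empty node index", call. = FALSE)
  links <- sum(bm > 0)
  possible <- possible_adjacencies(nrow(bm), ncol(bm))
  tibble::tibble(links = links, possible = possible,
                 density = link_density(links, possible))
}

.degree_denominator <- function(bm, denominator) {
  n <- nrow(bm)
  diag_less <- function(m) { diag(m) <- 0; m }
  b <- diag_less(unclass(bm))
  switch(denominator,
         n_minus_1 = list(out = n - 1, `in` = n - 1),
         n_total = list(out = n, `in` = n),
         active_partners = list(
           # a destination's potential partners are the active sources
           # (nodes that ship to anyone), and symmetrically for sources
           out = sum(colSums(b) > 0),   # active destinations
           `in` = sum(rowSums(b) > 0)   # active sources
         ),
         stop("unknown denominator convention: ", denominator, call. = FALSE))
}

#' Supply and demand degree centrality
#'
#' Out-degree of a node is the number of distinct destinations it ships to
#' (self excluded); in-degree the number of distinct sources it receives
#' from. Relative centralities divide by a named denominator convention:
#' `"n_total"` (the full roster size, the reporting default),
#' `"n_minus_1"` (classical maximum degree, 31 on a 32-state network), or
#' `"active_partners"` (only nodes active on the opposite side count as
#' potential partners).
#'
#' @param bm A square `binary_matrix` (weighted input is dichotomized).
#' @param denominator Denominator convention for relative centrality.
#' @return Tibble with one row per node: `node`, `out_degree`, `in_degree`,
#'   `relative_out`, `relative_in` (percent).
#' @export
degree_centrality <- function(bm, denominator = c("n_total", "n_minus_1",
                                                  "active_partners")) {
  denominator <- match.arg(denominator)
  if (!inherits(bm, "binary_matrix")) bm <- dichotomize(bm)
  if (nrow(bm) != ncol(bm))
    stop("degree centrality needs a square matrix", call. = FALSE)
  b <- unclass(bm)
  diag(b) <- 0
  den <- .degree_denominator(bm, denominator)
  out_deg <- rowSums(b > 0)
  in_deg <- colSums(b > 0)
  tibble::tibble(
    node = rownames(bm),
    out_degree = as.integer(out_deg),
    in_degree = as.integer(in_deg),
    relative_out = if (den$out > 0) unname(100 * out_deg / den$out) else 0,
    relative_in = if (den$`in` > 0) unname(100 * in_deg / den$`in`) else 0
  )
}

#' Average network centrality
#'
#' Mean relative degree over all nodes, reported separately for the supply
#' (out) and demand (in) side.
#'
#' @inheritParams degree_centrality
#' @return Tibble with columns `side` ("supply"/"demand") and `centrality`
#'   (percent).
#' @export
average_centrality <- function(bm, denominator = c("n_total", "n_minus_1",
                                                   "active_partners")) {
  denominator <- match.arg(denominator)
  d <- degree_centrality(bm, denominator)
  tibble::tibble(
    side = c("supply", "demand"),
    centrality = c(mean(d$relative_out), mean(d$relative_in))
  )
}

#' Eigenvector prestige of network nodes
#'
#' Node prestige proportional to the prestige of trading partners, computed
#' as the principal eigenvector of `M %*% t(M)` for the supply side (hub
#' construction: a supplier is prestigious if it ships to the same markets
#' as other prestigious suppliers) or `t(M) %*% M` for the demand side
#' (authority construction). Solved by power iteration from the uniform
#' vector with Euclidean normalization, stopping when successive iterates
#' differ by less than `tol` in max-abs norm. Scores are nonnegative with
#' unit Euclidean norm.
#'
#' @param m Square `od_matrix` or `binary_matrix` (dichotomize first if the
#'   binary convention is wanted; the weighted matrix is used as given).
#' @param side `"supply"` or `"demand"`.
#' @param tol Convergence tolerance on successive iterates.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   last residual.
#' @return Tibble with columns `node` and `score`.
#' @export
eigen_prestige <- function(m, side = c("supply", "demand"),
                           tol = 1e-10, max_iter = 10000) {
  side <- match.arg(side)
  if (nrow(m) != ncol(m))
    stop("eigenvector prestige needs a square matrix", call. = FALSE)
  a <- unclass(m)
  storage.mode(a) <- "double"
  if (all(a == 0))
    stop("degenerate spectrum: the matrix has no links", call. = FALSE)
  s <- if (side == "supply") a %*% t(a) else t(a) %*% a
  v <- rep(1 / sqrt(nrow(s)), nrow(s))
  for (i in seq_len(max_iter)) {
    w <- as.vector(s %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0)
      stop("degenerate spectrum: power iteration collapsed to zero",
           call. = FALSE)
    w <- w / nw
    resid <- max(abs(w - v))
    v <- w
    if (resid < tol)
      return(tibble::tibble(node = rownames(m), score = v))
  }
  stop(sprintf("eigenvector prestige did not converge in %d iterations (last residual %.3e)",
               max_iter, resid), call. = FALSE)
}

#' Full per-node centrality table
#'
#' Combines supply/demand degrees, relative centralities, and eigenvector
#' prestige scores for both sides into one table.
#'
#' @param od A square `od_matrix`.
#' @param denominator Passed to [degree_centrality()].
#' @param eigen_on `"binary"` (the dichotomized matrix; default, matching
#'   the dichotomize-before-analysis convention) or `"weighted"`.
#' @inheritParams eigen_prestige
#' @return Tibble with columns `node`, `out_degree`, `in_degree`,
#'   `relative_out`, `relative_in`, `eigen_supply`, `eigen_demand`.
#' @export
centrality_table <- function(od, denominator = "n_total",
                             eigen_on = c("binary", "weighted"),
                             tol = 1e-10, max_iter = 10000) {
  eigen_on <- match.arg(eigen_on)
  bm <- dichotomize(od)
  em <- if (eigen_on == "binary") bm else od
  deg <- degree_centrality(bm, denominator)
  es <- eigen_prestige(em, "supply", tol, max_iter)
  ed <- eigen_prestige(em, "demand", tol, max_iter)
  deg |>
    dplyr::left_join(dplyr::rename(es, eigen_supply = "score"), by = "node") |>
    dplyr::left_join(dplyr::rename(ed, eigen_demand = "score"), by = "node") |>
    dplyr::arrange(.data$node)
}

#' Export a dichotomized network for external graph tools
#'
#' @param bm A `binary_matrix`.
#' @param path Output path.
#' @param format `"edges"` (CSV edge list) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(bm, path, format = c("edges", "graphml")) {
  format <- match.arg(format)
  edges <- tidy(bm)
  if (format == "edges") {
    readr::write_csv(edges, path)
  } else {
    nodes <- sort(unique(c(rownames(bm), colnames(bm))))
    esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <graph id="G" edgedefault="directed">',
      sprintf('    <node id="%s"/>', esc(nodes)),
      sprintf('    <edge source="%s" target="%s"/>',
              esc(edges$source), esc(edges$destination)),
      "  </graph>",
      "</graphml>"
    )
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}
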