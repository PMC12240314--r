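# brute-force degree oracle: row/column nonzero counts excluding diagonal
brute_degrees <- function(m) {
  n <- nrow(m)
  out <- integer(n); inn <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && m[i, j] > 0) { out[i] <- out[i] + 1L; inn[j] <- inn[j] + 1L }
  }
  list(out = out, `in` = inn)
}

test_that("dichotomization is the indicator of positive flow", {
  od <- random_od(7, seed = 3)
  bm <- dichotomize(od)
  expect_true(all(bm %in% c(0, 1)))
  expect_equal(sum(bm), sum(unclass(od) > 0))
  zero <- random_od(4, p = 0, seed = 1)
  expect_equal(sum(dichotomize(zero)), 0)
  expect_equal(unname(unclass(dichotomize(od))[unclass(od) > 0][1]), 1)
})

test_that("possible adjacencies count ordered pairs including self-pairs", {
  expect_equal(possible_adjacencies(2446, 2446), 5982916)
  expect_equal(possible_adjacencies(32, 32), 1024)
  expect_equal(possible_adjacencies(0, 17), 0)
})

test_that("density reproduces the published municipal worked example", {
  expect_equal(round(link_density(12355, 582426), 1), 2.1)
})

test_that("density spans its full range and fails on empty indices", {
  full <- random_od(5, p = 1, seed = 2)
  expect_equal(net_density(full)$density, 100)
  empty <- random_od(5, p = 0, seed = 2)
  expect_equal(net_density(empty)$density, 0)
  d <- net_density(random_od(9, seed = 4))
  expect_equal(d$density, 100 * d$links / d$possible)
  expect_equal(d$possible, 81)
  expect_error(link_density(1, 0), "possible")
})

test_that("degrees match the brute-force oracle and an igraph cross-check", {
  od <- random_od(8, seed = 10)
  bm <- dichotomize(od)
  deg <- degree_centrality(bm)
  oracle <- brute_degrees(unclass(bm))
  expect_equal(deg$out_degree, oracle$out)
  expect_equal(deg$in_degree, oracle$`in`)
  skip_if_not_installed("igraph")
  g <- igraph::graph_from_adjacency_matrix(unclass(bm), mode = "directed",
                                           diag = FALSE)
  expect_equal(deg$out_degree,
               unname(igraph::degree(g, mode = "out")))
  expect_equal(deg$in_degree,
               unname(igraph::degree(g, mode = "in")))
})

test_that("a full 32-state network has the maximum degree of 31", {
  od <- random_od(32, p = 1, seed = 1)
  deg <- degree_centrality(od, "n_minus_1")
  expect_true(all(deg$out_degree == 31))
  expect_true(all(deg$in_degree == 31))
  expect_true(all(deg$relative_out == 100))
})

test_that("relative centrality follows the chosen denominator convention", {
  m <- matrix(0, 32, 32, dimnames = list(sprintf("S%02d", 1:32),
                                         sprintf("S%02d", 1:32)))
  m[1, 2] <- 1
  od <- swinenet:::new_od_matrix(m, "state", "all", "all")
  expect_equal(degree_centrality(od, "n_total")$relative_out[1], 100 / 32)
  expect_equal(degree_centrality(od, "n_minus_1")$relative_out[1], 100 / 31)
  # one active destination and one active source under active_partners
  ap <- degree_centrality(od, "active_partners")
  expect_equal(ap$relative_out[1], 100)
  expect_equal(ap$relative_in[2], 100)
  expect_error(degree_centrality(od, "bogus"))
})

test_that("average centrality equals the mean of per-node relative degrees", {
  od <- random_od(10, seed = 20)
  for (den in c("n_total", "n_minus_1")) {
    avg <- average_centrality(od, den)
    deg <- degree_centrality(od, den)
    expect_equal(avg$centrality[avg$side == "supply"],
                 mean(deg$relative_out))
    expect_equal(avg$centrality[avg$side == "demand"],
                 mean(deg$relative_in))
  }
  full <- random_od(6, p = 1, seed = 1)
  m <- unclass(full); diag(m) <- 0
  off <- swinenet:::new_od_matrix(m, "state", "all", "all")
  expect_equal(average_centrality(off, "n_minus_1")$centrality, c(100, 100))
  empty <- random_od(6, p = 0, seed = 1)
  expect_equal(average_centrality(empty)$centrality, c(0, 0))
})

test_that("eigen prestige solves the textbook cases", {
  two <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  s <- eigen_prestige(two, "supply")
  expect_equal(s$score, c(1, 1) / sqrt(2), tolerance = 1e-10)

  star <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  star[1, 2:6] <- 1
  sup <- eigen_prestige(star, "supply")
  expect_equal(sup$score, c(1, rep(0, 5)), tolerance = 1e-10)
  dem <- eigen_prestige(star, "demand")
  expect_equal(dem$score[1], 0)
  expect_equal(sum(dem$score^2), 1)
})

test_that("eigen prestige matches a dense eigendecomposition on random matrices", {
  for (seed in 1:5) {
    m <- unclass(random_od(8, seed = seed))
    for (side in c("supply", "demand")) {
      v <- eigen_prestige(m, side, tol = 1e-12)$score
      s <- if (side == "supply") m %*% t(m) else t(m) %*% m
      ev <- eigen(s, symmetric = TRUE)$vectors[, 1]
      ev <- abs(ev) / sqrt(sum(ev^2))
      expect_equal(v, ev, tolerance = 1e-8)
      expect_true(all(v >= -1e-12))
      expect_equal(sum(v^2), 1, tolerance = 1e-10)
    }
  }
})

test_that("eigen prestige rejects degenerate inputs and reports non-convergence", {
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(eigen_prestige(z, "supply"), "degenerate")
  m <- unclass(random_od(8, seed = 2))
  expect_error(eigen_prestige(m, "supply", tol = 0, max_iter = 3),
               "did not converge")
})

test_that("supply and demand prestige coincide on symmetric matrices", {
  m <- unclass(random_od(7, seed = 9))
  m <- m + t(m)
  expect_equal(eigen_prestige(m, "supply")$score,
               eigen_prestige(m, "demand")$score, tolerance = 1e-8)
})

test_that("metrics are invariant under node relabeling (permutation)", {
  od <- random_od(9, seed = 14)
  m <- unclass(od)
  perm <- withr::with_seed(3, sample(9))
  relabeled <- m[perm, perm]
  od2 <- swinenet:::new_od_matrix(
    relabeled[order(rownames(relabeled)), order(colnames(relabeled))],
    "state", "all", "all")
  expect_equal(net_density(od2), net_density(od))
  expect_equal(degree_centrality(dichotomize(od2)),
               dplyr::arrange(degree_centrality(dichotomize(od)), node))
  e1 <- eigen_prestige(dichotomize(od), "supply")
  e2 <- eigen_prestige(dichotomize(od2), "supply")
  expect_equal(e2$score[match(e1$node, e2$node)], e1$score,
               tolerance = 1e-8)
})

test_that("adding a link never decreases density, degrees or centrality", {
  od <- random_od(8, p = 0.3, seed = 18)
  m <- unclass(od)
  zeros <- which(m == 0, arr.ind = TRUE)
  for (k in withr::with_seed(4, sample(nrow(zeros), 5))) {
    m2 <- m
    m2[zeros[k, 1], zeros[k, 2]] <- 42
    od2 <- swinenet:::new_od_matrix(m2, "state", "all", "all")
    expect_gte(net_density(od2)$density, net_density(od)$density)
    d1 <- degree_centrality(dichotomize(od))
    d2 <- degree_centrality(dichotomize(od2))
    expect_true(all(d2$out_degree >= d1$out_degree))
    expect_true(all(d2$in_degree >= d1$in_degree))
    a1 <- average_centrality(dichotomize(od))
    a2 <- average_centrality(dichotomize(od2))
    expect_true(all(a2$centrality >= a1$centrality))
  }
})

test_that("graphml and edge-list exports carry every link", {
  bm <- dichotomize(random_od(5, seed = 7))
  fe <- tempfile(fileext = ".csv")
  write_network(bm, fe, "edges")
  edges <- readr::read_csv(fe, show_col_types = FALSE)
  expect_equal(nrow(edges), sum(bm))
  fg <- tempfile(fileext = ".graphml")
  write_network(bm, fg, "graphml")
  doc <- readLines(fg)
  expect_equal(sum(grepl("<edge ", doc)), sum(bm))
  skip_if_not_installed("igraph")
  g <- igraph::read_graph(fg, format = "graphml")
  expect_equal(igraph::ecount(g), sum(bm))
})
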