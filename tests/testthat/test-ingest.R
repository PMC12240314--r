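test_that("valid rows parse and invalid rows are rejected with reasons", {
  f <- write_permit_csv(c(
    permit_header,
    "S01,M001,S02,M001,slaughter,2019-01-02,10",
    "S01,M001,S02,M002,Fattening ,2019-01-03,5",
    "S02,M003,S02,M003,breeding,2019-01-04,7"
  ))
  rec <- read_movements(f)
  expect_equal(nrow(rec), 3)
  expect_equal(parse_report(rec)$rejected, 0)
  # trimming + case-insensitivity accepted the second row
  expect_equal(as.character(rec$category[2]), "fattening")

  f2 <- write_permit_csv(c(
    permit_header,
    "S01,M001,S02,M001,exhibition_x,2019-01-02,10",
    "S01,M001,S02,M001,slaughter,2019-01-02,0",
    "S01,M001,S02,M001,slaughter,2019-01-02,abc",
    "S01,M001,S02,M001,slaughter,not-a-date,3",
    "S01,M001,S02,M001,fairs,2019-01-02,4"
  ))
  rec2 <- read_movements(f2)
  expect_equal(nrow(rec2), 1)
  rep2 <- parse_report(rec2)
  expect_equal(rep2$rejected, 4)
  expect_true("unknown category" %in% rep2$reasons$reason)
  expect_equal(rep2$reasons$rows[rep2$reasons$reason ==
                                 "non-positive or non-numeric heads"], 2)
})

test_that("a file with some zero-head rows keeps exactly the valid ones", {
  rows <- sprintf("S01,M001,S02,M001,slaughter,2019-01-%02d,%d", 1:10,
                  c(5, 0, 3, 8, 0, 2, 9, 1, 4, 6))
  rec <- read_movements(write_permit_csv(c(permit_header, rows)))
  expect_equal(nrow(rec), 8)
  expect_equal(parse_report(rec)$rejected, 2)
})

test_that("a missing required column is a hard error", {
  f <- write_permit_csv(c(
    "origin_state,origin_municipality,dest_state,dest_municipality,category,date",
    "S01,M001,S02,M001,slaughter,2019-01-02"
  ))
  expect_error(read_movements(f), "heads")
})

test_that("Spanish category synonyms map through the schema", {
  f <- write_permit_csv(c(
    permit_header,
    "S01,M001,S02,M001,Sacrificio,2019-01-02,10",
    "S01,M001,S02,M001,ENGORDA,2019-01-03,5"
  ))
  sch <- movement_schema(category_synonyms = c(sacrificio = "slaughter",
                                               engorda = "fattening"))
  rec <- read_movements(f, sch)
  expect_equal(as.character(rec$category), c("slaughter", "fattening"))
})

test_that("aggregation is additive and the diagonal holds intra-state flows", {
  rec <- make_records(
    origin_state = c("A", "A", "B"),
    dest_state = c("B", "B", "B"),
    heads = c(10, 5, 7)
  )
  od <- aggregate_od(rec, "state")
  expect_equal(od["A", "B"], 15)
  expect_equal(od["B", "B"], 7)  # intra-state movement on the diagonal
  expect_equal(sum(od), sum(rec$heads))
})

test_that("category and year filters conserve the filtered head total", {
  rec <- make_records(
    origin_state = c("A", "A", "B", "B", "C", "C"),
    dest_state = c("B", "C", "B", "A", "A", "C"),
    category = c("slaughter", "fattening", "slaughter", "breeding",
                 "slaughter", "fairs"),
    date = c("2019-03-01", "2019-04-01", "2020-05-01", "2019-06-01",
             "2020-07-01", "2019-08-01"),
    heads = c(10, 20, 30, 40, 50, 60)
  )
  for (cat in c("all", movement_categories())) {
    for (yr in list("all", 2019, 2020)) {
      od <- aggregate_od(rec, "state", category = cat, year = yr)
      keep <- rep(TRUE, nrow(rec))
      if (cat != "all") keep <- keep & rec$category == cat
      if (!identical(yr, "all"))
        keep <- keep & format(rec$date, "%Y") == as.character(yr)
      expect_equal(sum(od), sum(rec$heads[keep]),
                   info = paste(cat, yr))
    }
  }
})

test_that("aggregation is invariant to record order", {
  r <- simulate_movements(small_config(seed = 4))
  od1 <- aggregate_od(r, "municipality")
  perm <- withr::with_seed(2, sample(nrow(r)))
  od2 <- aggregate_od(r[perm, ], "municipality")
  expect_identical(od1, od2)
})

test_that("a fixed roster widens the matrix without changing totals", {
  rec <- make_records(origin_state = "A", dest_state = "B", heads = 9)
  od <- aggregate_od(rec, "state", roster = c("A", "B", "C", "D"))
  expect_equal(dim(unclass(od)), c(4L, 4L))
  expect_equal(sum(od), 9)
  expect_error(aggregate_od(rec, "state", roster = c("A", "X")), "roster")
})

test_that("municipal matrices roll up to the directly built state matrix", {
  r <- simulate_movements(small_config(seed = 12))
  od_m <- aggregate_od(r, "municipality")
  od_s <- aggregate_od(r, "state")
  rolled <- rollup_to_state(od_m)
  expect_equal(unclass(rolled)[rownames(od_s), colnames(od_s)],
               unclass(od_s), ignore_attr = TRUE)
})

test_that("intra/inter split handles the degenerate matrices", {
  all_diag <- aggregate_od(
    make_records(origin_state = c("A", "B"), dest_state = c("A", "B"),
                 heads = c(5, 5)), "state")
  expect_equal(intra_inter_split(all_diag),
               tibble::tibble(intra = 1, inter = 0))
  no_diag <- aggregate_od(
    make_records(origin_state = "A", dest_state = "B", heads = 5), "state")
  expect_equal(intra_inter_split(no_diag),
               tibble::tibble(intra = 0, inter = 1))
  empty <- aggregate_od(make_records(origin_state = "A", dest_state = "B",
                                     heads = 5),
                        "state", category = "fairs")
  expect_error(intra_inter_split(empty), "zero|all-zero")
})

test_that("daily frequency counts zero-permit days and matches a brute force", {
  rec <- make_records(origin_state = rep("A", 50), dest_state = "B",
                      date = rep(sprintf("2019-01-%02d", 1:5), each = 10))
  f <- daily_frequency(rec)
  expect_equal(f$mean, 10)
  expect_equal(f$sd, 0)

  # random fixture vs brute-force per-day tally over the full span
  r <- simulate_movements(small_config(seed = 33))
  f2 <- daily_frequency(r)
  span <- seq(min(r$date), max(r$date), by = "day")
  counts <- vapply(span, function(d) sum(r$date == d), numeric(1))
  expect_equal(f2$mean, mean(counts))
  expect_equal(f2$sd, sqrt(mean((counts - mean(counts))^2)))
  expect_equal(f2$days, length(span))

  expect_error(daily_frequency(rec[0, ]), "dated")
})

test_that("tidy edge lists and dense CSV exports round-trip the matrix", {
  od <- random_od(5, seed = 6)
  edges <- tidy(od)
  expect_equal(sum(edges$heads), sum(od))
  expect_true(all(edges$heads > 0))
  f <- tempfile(fileext = ".csv")
  write_od_matrix(od, f, "dense")
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(as.matrix(back[, -1]), unclass(od), ignore_attr = TRUE)
})
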