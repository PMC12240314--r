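# small in-code fixtures shared across tests

make_records <- function(origin_state, origin_municipality = "M001",
                         dest_state, dest_municipality = "M001",
                         category = "slaughter", date = "2019-06-01",
                         heads = 10) {
  tibble::tibble(
    origin_state = origin_state,
    origin_municipality = origin_municipality,
    dest_state = dest_state,
    dest_municipality = dest_municipality,
    category = factor(category, levels = movement_categories()),
    date = as.Date(date),
    heads = as.integer(heads)
  )
}

small_config <- function(seed = 1, n_permits_scale = 1, ...) {
  args <- list(
    n_states = 6, municipalities_per_state = 5,
    n_active_source_states = 5, years = 2019:2020,
    annual_head_total = 25000 * n_permits_scale,
    category_probs = c(0.7, 0.2, 0.09, 0.01),
    intra_state_prob = 0.4,
    source_concentration = 1.2, dest_concentration = 1,
    mean_heads_per_permit = 50, seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(movement_config, args)
}

# random OD matrix with sorted labels, ~density `p`, positive weights
random_od <- function(n, p = 0.4, seed = 1, level = "state") {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n * n, 1, p) * sample(1:500, n * n, replace = TRUE),
                n, n)
  })
  labels <- sprintf("S%02d", seq_len(n))
  dimnames(m) <- list(labels, labels)
  swinenet:::new_od_matrix(m, level = level, category = "all", period = "all")
}

write_permit_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

permit_header <- "origin_state,origin_municipality,dest_state,dest_municipality,category,date,heads"
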