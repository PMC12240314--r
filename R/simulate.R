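# Dirichlet draw with Zipf-decaying means: alpha_k proportional to k^-s,
# scaled to a fixed precision so realized shares track the Zipf calibration.
.dirichlet_zipf <- function(n, exponent, precision = 1000) {
  mean_shares <- seq_len(n)^(-exponent)
  mean_shares <- mean_shares / sum(mean_shares)
  g <- stats::rgamma(n, shape = mean_shares * precision, rate = 1)
  g / sum(g)
}

# sample() with prob is O(n log n) per draw set and fine at these sizes
.weighted_pick <- function(n, labels, weights) {
  labels[sample.int(length(labels), n, replace = TRUE, prob = weights)]
}

#' Simulate a national permit dataset
#'
#' Draws individual movement permits with the statistical structure set by
#' `config`: log-normal permit sizes around the configured mean, categories
#' drawn per permit from the category probabilities, origins drawn from a
#' Dirichlet volume allocation with Zipf-decaying concentration over active
#' source states (and over active supplier municipalities within each
#' state), destinations kept within the origin state with probability
#' `intra_state_prob` and otherwise allocated across other states by a
#' second concentration law, and dates uniform within each year.
#'
#' The draw is fully determined by `config` (including its `seed`): two
#' calls with the same config return identical tibbles. The caller's RNG
#' state is left untouched.
#'
#' @param config A [movement_config()].
#' @return A tibble of permits with columns `origin_state`,
#'   `origin_municipality`, `dest_state`, `dest_municipality`, `category`
#'   (factor over [movement_categories()]), `date` (Date), `heads`
#'   (positive integer).
#' @examples
#' cfg <- movement_config(
#'   n_states = 4, municipalities_per_state = 5, years = 2020,
#'   annual_head_total = 1e4, category_probs = c(0.7, 0.2, 0.09, 0.01),
#'   intra_state_prob = 0.5, mean_heads_per_permit = 50, seed = 42
#' )
#' simulate_movements(cfg)
#' @export
simulate_movements <- function(config) {
  if (!inherits(config, "movement_config"))
    stop("`config` must be a movement_config object", call. = FALSE)
  withr::with_seed(config$seed, .simulate_movements_impl(config))
}

.simulate_movements_impl <- function(config) {
  states <- state_roster(config)
  n_states <- config$n_states

  # active source states: the first n_active (roster order), volume shares
  # from the Zipf-mean Dirichlet
  active_src <- states[seq_len(config$n_active_source_states)]
  src_state_w <- .dirichlet_zipf(length(active_src),
                                 config$source_concentration)

  # demand: all states receive
  dst_state_w <- .dirichlet_zipf(n_states, config$dest_concentration)
  names(dst_state_w) <- states

  # municipality rosters; labels qualified by state elsewhere, plain here
  muni_labels <- lapply(seq_len(n_states), function(k) {
    sprintf("M%03d", seq_len(config$municipalities_per_state[k]))
  })
  names(muni_labels) <- states

  pick_active <- function(labels, frac, exponent) {
    n_active <- max(1L, round(frac * length(labels)))
    act <- sort(sample(labels, n_active))
    list(labels = act, w = .dirichlet_zipf(n_active, exponent))
  }
  supply_muni <- lapply(states, function(s) {
    pick_active(muni_labels[[s]], config$supply_municipality_frac,
                config$source_concentration)
  })
  demand_muni <- lapply(states, function(s) {
    pick_active(muni_labels[[s]], config$demand_municipality_frac,
                config$dest_concentration)
  })
  names(supply_muni) <- names(demand_muni) <- states

  permits_per_year <- max(1L, round(config$annual_head_total /
                                      config$mean_heads_per_permit))
  sdlog <- 1
  meanlog <- log(config$mean_heads_per_permit) - sdlog^2 / 2

  one_year <- function(year) {
    n <- permits_per_year
    heads <- pmax(1L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
    category <- .weighted_pick(n, movement_categories(),
                               config$category_probs)
    origin_state <- .weighted_pick(n, active_src, src_state_w)
    intra <- stats::runif(n) < config$intra_state_prob
    dest_state <- origin_state
    if (any(!intra)) {
      # inter-state: redraw from demand weights until off-origin; done by
      # per-origin renormalization, vectorized over origin states
      idx <- which(!intra)
      for (s in unique(origin_state[idx])) {
        sel <- idx[origin_state[idx] == s]
        w <- dst_state_w[states != s]
        dest_state[sel] <- .weighted_pick(length(sel), states[states != s], w)
      }
    }
    origin_muni <- character(n)
    for (s in unique(origin_state)) {
      sel <- origin_state == s
      sm <- supply_muni[[s]]
      origin_muni[sel] <- .weighted_pick(sum(sel), sm$labels, sm$w)
    }
    dest_muni <- character(n)
    for (s in unique(dest_state)) {
      sel <- dest_state == s
      dm <- demand_muni[[s]]
      dest_muni[sel] <- .weighted_pick(sum(sel), dm$labels, dm$w)
    }
    start <- as.Date(sprintf("%d-01-01", year))
    ndays <- as.integer(as.Date(sprintf("%d-12-31", year)) - start) + 1L
    date <- start + sample.int(ndays, n, replace = TRUE) - 1L
    tibble::tibble(
      origin_state = origin_state,
      origin_municipality = origin_muni,
      dest_state = dest_state,
      dest_municipality = dest_muni,
      category = factor(category, levels = movement_categories()),
      date = date,
      heads = heads
    )
  }

  dplyr::bind_rows(lapply(config$years, one_year))
}

#' Write permits to the canonical delimited format
#'
#' Emits the same comma-separated, UTF-8, ISO-8601-dated format that
#' [read_movements()] ingests, with header
#' `origin_state, origin_municipality, dest_state, dest_municipality,
#' category, date, heads`.
#'
#' @param records Permit tibble as returned by [simulate_movements()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_movements <- function(records, path) {
  out <- dplyr::mutate(records,
                       category = as.character(.data$category),
                       date = format(.data$date, "%Y-%m-%d"))
  readr::write_csv(out, path)
  invisible(path)
}
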