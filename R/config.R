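#' Movement categories recognized on a permit
#'
#' The four declared purposes a Mexican swine movement permit can carry.
#' @return Character vector of the four category labels, in canonical order.
#' @export
movement_categories <- function() {
  c("slaughter", "fattening", "breeding", "fairs")
}

#' Configuration for the synthetic permit generator
#'
#' Describes the statistical structure of a national swine movement permit
#' database: the state/municipality roster, how volume concentrates across
#' source and destination nodes, the split of heads across movement
#' categories, and the permit-size distribution.
#'
#' @param n_states Number of states in the roster.
#' @param municipalities_per_state Either a single count applied to every
#'   state or an integer vector of length `n_states`.
#' @param n_active_source_states How many states actually ship pigs
#'   (the remainder only receive). Must not exceed `n_states`.
#' @param years Strictly increasing integer vector of calendar years covered.
#' @param annual_head_total Heads transported per year.
#' @param category_probs Probability (by heads) of the four movement
#'   categories, in the order given by [movement_categories()]. Must sum
#'   to 1.
#' @param intra_state_prob Probability that a movement stays within its
#'   origin state.
#' @param source_concentration Zipf exponent shaping how volume
#'   concentrates across active source states (larger = more concentrated).
#' @param dest_concentration Zipf exponent for destination states.
#' @param mean_heads_per_permit Mean permit size in heads; permit sizes are
#'   log-normal around this mean.
#' @param supply_municipality_frac Fraction of each active state's
#'   municipalities that ever ship pigs.
#' @param demand_municipality_frac Fraction of each state's municipalities
#'   that ever receive pigs.
#' @param seed Integer seed; identical configs (including seed) generate
#'   byte-identical permit sets.
#'
#' @return A `movement_config` object (a validated list).
#' @seealso [senasica_preset()] for the calibrated national-scale preset,
#'   [simulate_movements()] to draw permits.
#' @export
movement_config <- function(n_states,
                            municipalities_per_state,
                            n_active_source_states = n_states,
                            years,
                            annual_head_total,
                            category_probs,
                            intra_state_prob,
                            source_concentration = 1,
                            dest_concentration = 1,
                            mean_heads_per_permit,
                            supply_municipality_frac = 1,
                            demand_municipality_frac = 1,
                            seed = 1L) {
  fail <- function(field, msg) {
    stop(sprintf("invalid generator configuration: `%s` %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(n_states) || length(n_states) != 1 || n_states < 1)
    fail("n_states", "must be a single positive count")
  n_states <- as.integer(n_states)
  if (length(municipalities_per_state) == 1)
    municipalities_per_state <- rep(municipalities_per_state, n_states)
  if (length(municipalities_per_state) != n_states ||
      any(municipalities_per_state < 1))
    fail("municipalities_per_state",
         "must be one count or one positive count per state")
  municipalities_per_state <- as.integer(municipalities_per_state)
  if (n_active_source_states < 1 || n_active_source_states > n_states)
    fail("n_active_source_states", "must lie in [1, n_states]")
  if (length(years) < 1 || any(diff(years) <= 0))
    fail("years", "must be non-empty and strictly increasing")
  if (!is.numeric(annual_head_total) || annual_head_total <= 0)
    fail("annual_head_total", "must be > 0")
  if (length(category_probs) != 4 || any(category_probs < 0) ||
      abs(sum(category_probs) - 1) > 1e-9)
    fail("category_probs",
         "must be 4 nonnegative probabilities summing to 1 (tol 1e-9)")
  if (intra_state_prob < 0 || intra_state_prob > 1)
    fail("intra_state_prob", "must lie in [0, 1]")
  if (source_concentration < 0) fail("source_concentration", "must be >= 0")
  if (dest_concentration < 0) fail("dest_concentration", "must be >= 0")
  if (!is.numeric(mean_heads_per_permit) || mean_heads_per_permit <= 0)
    fail("mean_heads_per_permit", "must be > 0")
  for (f in c("supply_municipality_frac", "demand_municipality_frac")) {
    v <- get(f)
    if (v <= 0 || v > 1) fail(f, "must lie in (0, 1]")
  }
  structure(
    list(
      n_states = n_states,
      municipalities_per_state = municipalities_per_state,
      n_active_source_states = as.integer(n_active_source_states),
      years = as.integer(years),
      annual_head_total = annual_head_total,
      category_probs = stats::setNames(as.numeric(category_probs),
                                       movement_categories()),
      intra_state_prob = intra_state_prob,
      source_concentration = source_concentration,
      dest_concentration = dest_concentration,
      mean_heads_per_permit = mean_heads_per_permit,
      supply_municipality_frac = supply_municipality_frac,
      demand_municipality_frac = demand_municipality_frac,
      seed = as.integer(seed)
    ),
    class = "movement_config"
  )
}

#' National-scale preset calibrated to Mexico's 2017-2021 swine market
#'
#' Returns a generator configuration reproducing the published structure of
#' the national permit database: 32 states of which 25 ship pigs, 2,446
#' municipalities, 33.3 million heads moved per year over 2017-2021 split
#' 87.29/12.20/0.50/0.01% across slaughter/fattening/breeding/fairs, a 38%
#' intra-state share, and a source concentration such that the four largest
#' supplying states carry about 73% of the volume. Mean permit size is set
#' so the expected permit count matches the roughly 1.16 million permits
#' the national database holds over five years.
#'
#' @param seed Integer seed passed through to the config.
#' @return A [movement_config()] object.
#' @export
senasica_preset <- function(seed = 1L) {
  # 2,446 municipalities over 32 states: 14 states get 77, the rest 76
  mps <- rep(76L, 32L)
  mps[seq_len(14)] <- 77L
  movement_config(
    n_states = 32,
    municipalities_per_state = mps,
    n_active_source_states = 25,
    years = 2017:2021,
    annual_head_total = 33.3e6,
    category_probs = c(0.8729, 0.1220, 0.0050, 0.0001),
    intra_state_prob = 0.38,
    # Zipf exponent solved so E[top-4 share of 25 sources] = 0.734
    source_concentration = 1.4441,
    dest_concentration = 1.2,
    # 33.3e6 heads/yr * 5 yr over ~1,162,851 permits
    mean_heads_per_permit = 33.3e6 * 5 / 1162851,
    supply_municipality_frac = 0.088,
    demand_municipality_frac = 0.153,
    seed = seed
  )
}

#' State roster implied by a generator configuration
#'
#' @param config A [movement_config()].
#' @return Character vector of state labels ("S01", "S02", ...), sorted.
#' @export
state_roster <- function(config) {
  stopifnot(inherits(config, "movement_config"))
  sprintf("S%02d", seq_len(config$n_states))
}

#' @export
print.movement_config <- function(x, ...) {
  cat("<movement_config>\n")
  cat(sprintf("  states: %d (%d active sources), municipalities: %d\n",
              x$n_states, x$n_active_source_states,
              sum(x$municipalities_per_state)))
  cat(sprintf("  years: %s, heads/year: %.3g\n",
              paste(range(x$years), collapse = "-"), x$annual_head_total))
  cat(sprintf("  category probs: %s\n",
              paste(sprintf("%s=%.4f", names(x$category_probs),
                            x$category_probs), collapse = " ")))
  cat(sprintf("  intra-state prob: %.2f, mean heads/permit: %.1f, seed: %d\n",
              x$intra_state_prob, x$mean_heads_per_permit, x$seed))
  invisible(x)
}
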