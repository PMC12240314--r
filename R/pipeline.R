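#' Configure a pipeline run
#'
#' Exactly one of `input` (a permit CSV path) or `preset` (a
#' [movement_config()], e.g. [senasica_preset()]) must be supplied.
#'
#' @param input Path to a delimited permit file, or `NULL`.
#' @param preset A [movement_config()] to simulate from, or `NULL`.
#' @param levels Geographic levels to analyze (`"state"`,
#'   `"municipality"`). Municipal metrics are computed only for the
#'   unfiltered network to keep large runs tractable.
#' @param categories Category filters; `"all"` plus any of
#'   [movement_categories()].
#' @param years Year filters; `"all"` plus calendar years.
#' @param denominator Relative-centrality convention, see
#'   [degree_centrality()].
#' @param eigen_on `"binary"` or `"weighted"`, see [centrality_table()].
#' @param roster Optional state roster fixing the node universe; defaults
#'   to the preset's full roster when simulating, observed nodes otherwise.
#' @param out_dir Output directory for artifacts (created if needed), or
#'   `NULL` to skip writing.
#' @param seed Seed recorded in the summary; when simulating it overrides
#'   the preset's seed.
#' @param schema [movement_schema()] used when reading `input`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, preset = NULL,
                            levels = "state",
                            categories = c("all", movement_categories()),
                            years = "all",
                            denominator = "n_total",
                            eigen_on = "binary",
                            roster = NULL,
                            out_dir = NULL,
                            seed = 1L,
                            schema = movement_schema()) {
  if (is.null(input) == is.null(preset))
    stop("exactly one of `input` or `preset` must be set", call. = FALSE)
  if (!is.null(preset) && !inherits(preset, "movement_config"))
    stop("`preset` must be a movement_config", call. = FALSE)
  stopifnot(all(levels %in% c("state", "municipality")),
            all(categories %in% c("all", movement_categories())))
  structure(
    list(input = input, preset = preset, levels = levels,
         categories = categories, years = years,
         denominator = denominator, eigen_on = eigen_on,
         roster = roster, out_dir = out_dir, seed = as.integer(seed),
         schema = schema),
    class = "pipeline_config"
  )
}

#' Run the full movement-network pipeline
#'
#' Ingests or simulates permits, builds origin-destination matrices for
#' every requested (level, category, year) combination, and computes the
#' network and market statistics: density, average supply/demand
#' centrality, per-node centrality tables, eigenvector prestige, source
#' and destination market shares with top-4 concentration, intra/inter
#' split, daily permit frequency, per-category annual volumes with growth
#' rates and trend correlations, and the category-by-year location
#' quotients and specialization coefficients.
#'
#' The returned summary is a plain list (JSON-serializable); given the same
#' config and seed it is identical across runs. If `out_dir` is set, the
#' summary, per-node centrality CSVs and dichotomized edge lists are
#' written there.
#'
#' @param config A [pipeline_config()].
#' @return The summary list, invisibly classed `pipeline_summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$preset)) {
    gen <- config$preset
    gen$seed <- config$seed
    records <- simulate_movements(gen)
    report <- list(accepted = nrow(records), rejected = 0L, reasons = list())
    roster <- if (is.null(config$roster)) state_roster(gen) else config$roster
  } else {
    records <- read_movements(config$input, config$schema)
    pr <- parse_report(records)
    report <- list(accepted = pr$accepted, rejected = pr$rejected,
                   reasons = as.list(stats::setNames(pr$reasons$rows,
                                                     pr$reasons$reason)))
    roster <- config$roster
  }

  networks <- list()
  for (level in config$levels) {
    cats <- if (level == "municipality") "all" else config$categories
    yrs <- if (level == "municipality") "all" else config$years
    for (cat in cats) for (yr in yrs) {
      key <- paste(level, cat, yr, sep = "/")
      od <- aggregate_od(records, level = level, category = cat, year = yr,
                         roster = if (level == "state") roster else NULL)
      if (sum(od) == 0) {
        networks[[key]] <- list(status = "no data")
        next
      }
      bm <- dichotomize(od)
      dens <- net_density(bm)
      avg <- average_centrality(bm, config$denominator)
      ct <- centrality_table(od, config$denominator, config$eigen_on)
      networks[[key]] <- list(
        status = "ok",
        nodes = nrow(od),
        total_heads = sum(od),
        links = dens$links,
        possible_links = dens$possible,
        density = dens$density,
        avg_centrality_supply = avg$centrality[avg$side == "supply"],
        avg_centrality_demand = avg$centrality[avg$side == "demand"],
        top_supply = as.list(ct[order(-ct$eigen_supply, ct$node), ][1, ]),
        top_demand = as.list(ct[order(-ct$eigen_demand, ct$node), ][1, ])
      )
      if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
        slug <- gsub("/", "_", key)
        readr::write_csv(ct, file.path(config$out_dir,
                                       paste0("centrality_", slug, ".csv")))
        write_network(bm, file.path(config$out_dir,
                                    paste0("edges_", slug, ".csv")))
      }
    }
  }

  # market statistics on the unfiltered state network
  od_all <- aggregate_od(records, level = "state", roster = roster)
  supply_vol <- rowSums(od_all)
  demand_vol <- colSums(od_all)
  split <- intra_inter_split(od_all)
  freq <- daily_frequency(records)

  years_obs <- sort(unique(as.integer(format(records$date, "%Y"))))
  vol_by_cat_year <- matrix(0, 4, length(years_obs),
                            dimnames = list(movement_categories(),
                                            as.character(years_obs)))
  tab <- dplyr::count(records,
                      category = as.character(.data$category),
                      year = as.integer(format(.data$date, "%Y")),
                      wt = .data$heads, name = "heads")
  vol_by_cat_year[cbind(tab$category, as.character(tab$year))] <- tab$heads

  per_category <- lapply(movement_categories(), function(cat) {
    v <- vol_by_cat_year[cat, ]
    out <- list(total_heads = sum(v), share = sum(v) / sum(vol_by_cat_year))
    if (length(v) >= 2 && v[1] > 0) {
      out$growth_cagr <- annual_growth(v)
      out$growth_mean <- annual_growth(v, "mean")
    }
    if (length(v) >= 3 && stats::sd(v) > 0) {
      tc <- trend_correlation(v)
      out$trend_r <- tc$r
      out$trend_p <- tc$p_value
    }
    out
  })
  names(per_category) <- movement_categories()

  lq <- location_quotients(vol_by_cat_year)
  cs <- specialization_coefficient(vol_by_cat_year)

  summary <- list(
    conventions = list(denominator = config$denominator,
                       eigen_on = config$eigen_on,
                       rest_at_end = FALSE),
    seed = config$seed,
    records = report,
    total_heads = sum(records$heads),
    intra_fraction = split$intra,
    inter_fraction = split$inter,
    daily_frequency = list(mean = freq$mean, sd = freq$sd),
    supply_shares = .share_list(supply_vol),
    demand_shares = .share_list(demand_vol),
    top4_supply_share = top_k_share(supply_vol[supply_vol > 0], 4),
    top4_demand_share = top_k_share(demand_vol[demand_vol > 0], 4),
    per_category = per_category,
    location_quotients = .lq_list(lq),
    specialization = as.list(stats::setNames(cs$CS, cs$region)),
    networks = networks
  )
  class(summary) <- c("pipeline_summary", "list")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(summary),
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(summary)
}

.share_list <- function(vol) {
  vol <- vol[vol > 0]
  if (length(vol) == 0) return(list())
  s <- market_shares(vol)
  as.list(stats::setNames(s$share, s$node))
}

.lq_list <- function(lq) {
  lapply(split(lq, lq$category), function(d) {
    as.list(stats::setNames(d$Q, d$region))
  })
}

#' One-line summary of a pipeline run
#'
#' @param x A `pipeline_summary`.
#' @param ... Unused.
#' @return Tibble with headline figures.
#' @export
glance.pipeline_summary <- function(x, ...) {
  net <- x$networks[["state/all/all"]]
  tibble::tibble(
    total_heads = x$total_heads,
    intra_fraction = x$intra_fraction,
    top4_supply_share = x$top4_supply_share,
    state_density = if (!is.null(net$density)) net$density else NA_real_,
    state_links = if (!is.null(net$links)) net$links else NA_integer_,
    possible_links = if (!is.null(net$possible_links)) net$possible_links
                     else NA_real_
  )
}

#' Generic one-row summarizer
#' @param x Object to summarize.
#' @param ... Passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Render a pipeline summary as a markdown report
#'
#' Deterministic human-readable rendering of an existing summary: headline
#' totals, convention footnotes, and ranked supply/demand tables (share
#' descending, ties broken by label). Every number is taken from the
#' summary; nothing is recomputed.
#'
#' @param summary A `pipeline_summary` (or the equivalent list read back
#'   from `summary.json`).
#' @return Character vector of markdown lines.
#' @export
render_report <- function(summary) {
  if (is.null(summary$conventions) || is.null(summary$networks))
    stop("malformed summary: missing conventions or networks", call. = FALSE)
  fmt_pct <- function(x) sprintf("%.1f%%", 100 * x)
  ranked <- function(shares) {
    if (length(shares) == 0) return("(no data)")
    d <- tibble::tibble(node = names(shares), share = unlist(shares)) |>
      dplyr::arrange(dplyr::desc(.data$share), .data$node)
    c("| rank | node | share |", "|---|---|---|",
      sprintf("| %d | %s | %s |", seq_len(nrow(d)), d$node,
              fmt_pct(d$share)))
  }
  net_lines <- unlist(lapply(names(summary$networks), function(k) {
    n <- summary$networks[[k]]
    if (identical(n$status, "no data"))
      return(sprintf("- `%s`: no data", k))
    sprintf("- `%s`: %d nodes, %s links of %s possible (density %.1f%%), avg centrality supply %.1f%% / demand %.1f%%",
            k, n$nodes, format(n$links, big.mark = ","),
            format(n$possible_links, big.mark = ","), n$density,
            n$avg_centrality_supply, n$avg_centrality_demand)
  }))
  c(
    "# Swine movement network report",
    "",
    sprintf("Total heads: %s; intra-state fraction %s; daily permit frequency %.1f (sd %.1f).",
            format(summary$total_heads, big.mark = ","),
            fmt_pct(summary$intra_fraction),
            summary$daily_frequency$mean, summary$daily_frequency$sd),
    sprintf("Top-4 supply concentration: %s; top-4 demand concentration: %s.",
            fmt_pct(summary$top4_supply_share),
            fmt_pct(summary$top4_demand_share)),
    "",
    "## Supply ranking", ranked(summary$supply_shares),
    "",
    "## Demand ranking", ranked(summary$demand_shares),
    "",
    "## Networks", net_lines,
    "",
    "## Conventions",
    sprintf("- relative centrality denominator: %s",
            summary$conventions$denominator),
    sprintf("- eigenvector prestige computed on: %s matrix",
            summary$conventions$eigen_on),
    sprintf("- rest stop at exact journey end counted: %s",
            tolower(as.character(summary$conventions$rest_at_end))),
    sprintf("- seed: %d", summary$seed)
  )
}
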