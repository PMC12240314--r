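#' Market shares and top-k concentration
#'
#' @param volumes Per-node head counts: a named numeric vector, or a data
#'   frame whose first column is the node label and second the volume.
#' @return Tibble with columns `node`, `volume`, `share`, ordered by share
#'   descending then node label (deterministic tie-break).
#' @export
market_shares <- function(volumes) {
  if (is.data.frame(volumes)) {
    node <- as.character(volumes[[1]])
    vol <- as.numeric(volumes[[2]])
  } else {
    node <- names(volumes)
    if (is.null(node)) node <- as.character(seq_along(volumes))
    vol <- as.numeric(volumes)
  }
  total <- sum(vol)
  if (total <= 0) stop("market shares undefined for zero total volume",
                       call. = FALSE)
  tibble::tibble(node = node, volume = vol, share = vol / total) |>
    dplyr::arrange(dplyr::desc(.data$share), .data$node)
}

#' Combined share of the k largest nodes
#'
#' @param volumes As in [market_shares()].
#' @param k Number of top nodes.
#' @return Numeric share in \[0, 1\].
#' @export
top_k_share <- function(volumes, k) {
  s <- market_shares(volumes)
  sum(utils::head(s$share, k))
}

#' Average annual growth rate of a volume series
#'
#' Default is the compound annual growth rate
#' `100 * ((last/first)^(1/(n-1)) - 1)`; `method = "mean"` instead averages
#' the year-over-year percentage changes.
#'
#' @param series Annual volumes: a numeric vector in year order, or a data
#'   frame with year and volume columns.
#' @param method `"cagr"` or `"mean"`.
#' @return Growth rate in percent per year.
#' @export
annual_growth <- function(series, method = c("cagr", "mean")) {
  method <- match.arg(method)
  x <- if (is.data.frame(series)) as.numeric(series[[2]]) else as.numeric(series)
  if (length(x) < 2) stop("growth rate needs at least two years", call. = FALSE)
  if (x[1] <= 0) stop("growth rate undefined for non-positive first value",
                      call. = FALSE)
  if (method == "cagr") {
    100 * ((x[length(x)] / x[1])^(1 / (length(x) - 1)) - 1)
  } else {
    100 * mean(diff(x) / utils::head(x, -1))
  }
}

#' Linear trend correlation of an annual series
#'
#' Pearson correlation between year index and volume, with the two-sided
#' p-value from the t transform on n - 2 degrees of freedom.
#'
#' @param series As in [annual_growth()]; needs >= 3 years and nonzero
#'   variance.
#' @return Tibble with columns `r` and `p_value`.
#' @export
trend_correlation <- function(series) {
  x <- if (is.data.frame(series)) as.numeric(series[[2]]) else as.numeric(series)
  if (length(x) < 3) stop("trend correlation needs at least three years",
                          call. = FALSE)
  if (stats::sd(x) == 0) stop("trend correlation undefined for a constant series",
                              call. = FALSE)
  ct <- stats::cor.test(seq_along(x), x)
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value)
}

.as_volume_matrix <- function(table) {
  if (is.data.frame(table)) {
    m <- as.matrix(table[, -1, drop = FALSE])
    rownames(m) <- as.character(table[[1]])
  } else {
    m <- as.matrix(table)
  }
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("volumes must be nonnegative", call. = FALSE)
  if (sum(m) <= 0) stop("grand total must be positive", call. = FALSE)
  m
}

#' Location quotients of a category-by-region volume table
#'
#' `Q(i, r)` compares category i's share within region r to its national
#' share: `Q = (V_ir / V_.r) / (V_i. / V_..)`. Values above 1 indicate the
#' region is relatively specialized in the category. Regions are typically
#' years in a temporal analysis, or states in a spatial one.
#'
#' @param table Category-by-region head counts: a matrix with category row
#'   names and region column names, or a data frame whose first column is
#'   the category.
#' @return Tibble with columns `category`, `region`, `Q`. Regions with a
#'   zero total get `NA` quotients (flagged undefined).
#' @export
location_quotients <- function(table) {
  m <- .as_volume_matrix(table)
  region_tot <- colSums(m)
  national_share <- rowSums(m) / sum(m)
  q <- sweep(m, 2, region_tot, "/") / national_share
  q[, region_tot == 0] <- NA_real_
  q[national_share == 0, ] <- NA_real_
  tibble::tibble(
    category = rep(rownames(m), times = ncol(m)),
    region = rep(colnames(m), each = nrow(m)),
    Q = as.vector(q)
  )
}

#' Specialization coefficient per region
#'
#' Half the L1 distance between a region's category shares and the national
#' category shares: 0 means the region mirrors the national structure, 1
#' means complete specialization away from it.
#'
#' @inheritParams location_quotients
#' @return Tibble with columns `region`, `CS` (in \[0, 1\]; `NA` for a
#'   region with zero total).
#' @export
specialization_coefficient <- function(table) {
  m <- .as_volume_matrix(table)
  region_tot <- colSums(m)
  s_national <- rowSums(m) / sum(m)
  s_region <- sweep(m, 2, region_tot, "/")
  cs <- colSums(abs(sweep(s_region, 1, s_national, "-"))) / 2
  cs[region_tot == 0] <- NA_real_
  tibble::tibble(region = colnames(m), CS = unname(cs))
}

#' Published category-by-year distribution of transported heads
#'
#' Reconstructs the category-by-year volume table of Mexico's 2017-2021
#' swine movements from two published summaries: the aggregate share of
#' heads per category (87.29/12.20/0.50/0.01% for
#' slaughter/fattening/breeding/fairs) and each category's percentage
#' distribution across the five years. Cell (i, y) is the aggregate share
#' of category i times the percentage of category i's volume that fell in
#' year y, so the table is in relative volume units (each category row sums
#' to 100 x its aggregate share); location quotients and specialization
#' coefficients are scale-invariant, so the units drop out.
#'
#' @return 4 x 5 numeric matrix (categories x years 2017-2021).
#' @export
senasica_category_year_table <- function() {
  year_pct <- matrix(
    c(17.2, 18.5, 20.7, 22.3, 21.3,   # slaughter
      10.9, 18.3, 27.8, 23.4, 19.6,   # fattening
      11.9, 17.6, 22.9, 22.2, 25.5,   # breeding
      28.8, 27.1, 15.1, 10.1, 18.9),  # fairs and exhibitions
    nrow = 4, byrow = TRUE,
    dimnames = list(movement_categories(), as.character(2017:2021))
  )
  aggregate_share <- c(0.8729, 0.1220, 0.0050, 0.0001)
  aggregate_share * year_pct
}

#' Transport-duration compliance under the 20-hour rule
#'
#' Mexican regulation caps continuous livestock transport at 20 driving
#' hours and requires at least one hour of rest after every eight hours of
#' uninterrupted travel. Rest stops add one hour each to the elapsed time;
#' a rest that would fall exactly at journey end is not counted by default.
#'
#' @param driving_hours Nonnegative driving time in hours (vectorized).
#' @param rest_at_end Count a rest stop falling exactly at the end of the
#'   journey? Default `FALSE`.
#' @param max_hours Driving-hour ceiling (inclusive). Default 20.
#' @param rest_interval Hours of driving after which a rest is due.
#'   Default 8.
#' @return Tibble with columns `driving_hours`, `rest_stops`,
#'   `total_elapsed_hours`, `compliant`.
#' @export
transport_compliance <- function(driving_hours, rest_at_end = FALSE,
                                 max_hours = 20, rest_interval = 8) {
  if (any(driving_hours < 0))
    stop("driving hours must be nonnegative", call. = FALSE)
  stops <- floor(driving_hours / rest_interval)
  if (!rest_at_end) {
    at_end <- driving_hours > 0 & driving_hours %% rest_interval == 0
    stops[at_end] <- stops[at_end] - 1
  }
  tibble::tibble(
    driving_hours = driving_hours,
    rest_stops = as.integer(stops),
    total_elapsed_hours = driving_hours + stops,
    compliant = driving_hours <= max_hours
  )
}
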