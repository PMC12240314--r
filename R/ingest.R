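#' Field-name and category-synonym mapping for permit files
#'
#' Maps the canonical record fields onto the column names of a delimited
#' permit file, and optionally maps source-database category labels (e.g.
#' Spanish synonyms) onto the four canonical categories. Category matching
#' is case-insensitive after trimming.
#'
#' @param origin_state,origin_municipality,dest_state,dest_municipality,category,date,heads
#'   Column names in the input file holding each field.
#' @param category_synonyms Named character vector mapping source labels
#'   (lower-case) to canonical categories, e.g.
#'   `c(sacrificio = "slaughter", engorda = "fattening")`.
#' @return A `movement_schema` list.
#' @export
movement_schema <- function(origin_state = "origin_state",
                            origin_municipality = "origin_municipality",
                            dest_state = "dest_state",
                            dest_municipality = "dest_municipality",
                            category = "category",
                            date = "date",
                            heads = "heads",
                            category_synonyms = NULL) {
  structure(
    list(columns = c(origin_state = origin_state,
                     origin_municipality = origin_municipality,
                     dest_state = dest_state,
                     dest_municipality = dest_municipality,
                     category = category,
                     date = date,
                     heads = heads),
         category_synonyms = category_synonyms),
    class = "movement_schema"
  )
}

#' Read and validate permit records from a delimited file
#'
#' Parses a CSV of movement permits, validates each row, and returns the
#' accepted records as a tibble. Rows with an unrecognized movement
#' category, a non-positive or non-numeric head count, or an unparseable
#' date are rejected individually; a missing required column is a hard
#' error. The per-reason reject tally is attached and retrievable with
#' [parse_report()].
#'
#' @param path Path to a delimited permit file with a header row.
#' @param schema A [movement_schema()] mapping the required fields.
#' @return Tibble of validated records (same columns as
#'   [simulate_movements()]), with a `parse_report` attribute.
#' @export
read_movements <- function(path, schema = movement_schema()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  validate_movements(raw, schema)
}

#' Validate an in-memory permit table
#'
#' Same validation as [read_movements()] applied to a data frame already in
#' memory (all columns may be character).
#'
#' @param data Data frame of raw permit rows.
#' @param schema A [movement_schema()].
#' @return Tibble of validated records with a `parse_report` attribute.
#' @export
validate_movements <- function(data, schema = movement_schema()) {
  cols <- schema$columns
  missing_cols <- setdiff(unname(cols), names(data))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- tibble::tibble(
    origin_state = as.character(data[[cols[["origin_state"]]]]),
    origin_municipality = as.character(data[[cols[["origin_municipality"]]]]),
    dest_state = as.character(data[[cols[["dest_state"]]]]),
    dest_municipality = as.character(data[[cols[["dest_municipality"]]]]),
    category_raw = tolower(trimws(as.character(data[[cols[["category"]]]]))),
    date_raw = as.character(data[[cols[["date"]]]]),
    heads_raw = as.character(data[[cols[["heads"]]]])
  )

  cat_map <- stats::setNames(movement_categories(), movement_categories())
  if (!is.null(schema$category_synonyms))
    cat_map <- c(cat_map, stats::setNames(
      as.character(schema$category_synonyms),
      tolower(names(schema$category_synonyms))))
  category <- unname(cat_map[d$category_raw])
  heads <- suppressWarnings(as.numeric(d$heads_raw))
  date <- suppressWarnings(as.Date(d$date_raw, format = "%Y-%m-%d"))

  reason <- rep(NA_character_, nrow(d))
  reason[is.na(date)] <- "unparseable date"
  reason[is.na(heads) | heads < 1 | heads != round(heads)] <-
    "non-positive or non-numeric heads"
  reason[is.na(category)] <- "unknown category"

  keep <- is.na(reason)
  records <- tibble::tibble(
    origin_state = d$origin_state[keep],
    origin_municipality = d$origin_municipality[keep],
    dest_state = d$dest_state[keep],
    dest_municipality = d$dest_municipality[keep],
    category = factor(category[keep], levels = movement_categories()),
    date = date[keep],
    heads = as.integer(heads[keep])
  )
  report <- tibble::tibble(reason = reason[!keep]) |>
    dplyr::count(.data$reason, name = "rows")
  attr(records, "parse_report") <- list(
    accepted = sum(keep),
    rejected = sum(!keep),
    reasons = report
  )
  records
}

#' Retrieve the parse report attached by the record reader
#'
#' @param records Tibble returned by [read_movements()] or
#'   [validate_movements()].
#' @return List with `accepted`, `rejected`, and a per-reason tibble.
#' @export
parse_report <- function(records) {
  rep <- attr(records, "parse_report")
  if (is.null(rep)) stop("no parse report attached to these records",
                         call. = FALSE)
  rep
}

# qualified municipality key: names repeat across states
.muni_key <- function(state, municipality) paste(state, municipality, sep = ":")

#' Aggregate permits into an origin-destination matrix
#'
#' Sums heads moved from each origin to each destination at the requested
#' geographic level, optionally restricted to one movement category and/or
#' one calendar year. The diagonal holds intra-unit flows (e.g. movements
#' within a state) and is meaningful. At municipality level, nodes are
#' qualified `state:municipality` keys since municipality names repeat
#' across states.
#'
#' @param records Validated permit tibble.
#' @param level `"state"` or `"municipality"`.
#' @param category One of [movement_categories()] or `"all"`.
#' @param year A calendar year or `"all"`.
#' @param roster Node universe. `NULL` (default) uses the nodes observed
#'   under the filters; a character vector fixes the full roster for both
#'   rows and columns (possible-link counts then use the roster size).
#' @return An `od_matrix`: a numeric matrix with sorted row/column labels
#'   and attributes `level`, `category`, `period`.
#' @export
aggregate_od <- function(records, level = c("state", "municipality"),
                         category = "all", year = "all", roster = NULL) {
  level <- match.arg(level)
  if (!identical(category, "all") &&
      !category %in% movement_categories())
    stop("unknown category filter: ", category, call. = FALSE)
  r <- records
  if (!identical(category, "all"))
    r <- dplyr::filter(r, .data$category == !!category)
  if (!identical(year, "all"))
    r <- dplyr::filter(r, as.integer(format(.data$date, "%Y")) ==
                         as.integer(!!year))
  if (level == "state") {
    src <- r$origin_state
    dst <- r$dest_state
  } else {
    src <- .muni_key(r$origin_state, r$origin_municipality)
    dst <- .muni_key(r$dest_state, r$dest_municipality)
  }
  labels <- if (is.null(roster)) sort(unique(c(src, dst))) else sort(unique(roster))
  if (!is.null(roster)) {
    bad <- setdiff(unique(c(src, dst)), labels)
    if (length(bad) > 0)
      stop("records contain nodes outside the supplied roster: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  if (nrow(r) > 0) {
    agg <- stats::aggregate(r$heads,
                            by = list(src = src, dst = dst), FUN = sum)
    m[cbind(match(agg$src, labels), match(agg$dst, labels))] <- agg$x
  }
  new_od_matrix(m, level = level, category = category, period = year)
}

new_od_matrix <- function(m, level, category, period) {
  structure(m, level = level, category = category, period = period,
            class = c("od_matrix", class(m)))
}

#' @export
print.od_matrix <- function(x, ...) {
  cat(sprintf("<od_matrix> level=%s category=%s period=%s [%d x %d], total heads %s\n",
              attr(x, "level"), attr(x, "category"), attr(x, "period"),
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Tidy an OD or binary matrix into an edge-list tibble
#'
#' @param x An `od_matrix` or `binary_matrix`.
#' @param keep_zeros Keep zero cells? Default drops them.
#' @param ... Unused.
#' @return Tibble with columns `source`, `destination`, `heads` (or
#'   `linked` for a binary matrix).
#' @export
tidy.od_matrix <- function(x, keep_zeros = FALSE, ...) {
  value_col <- if (inherits(x, "binary_matrix")) "linked" else "heads"
  out <- tibble::tibble(
    source = rep(rownames(x), times = ncol(x)),
    destination = rep(colnames(x), each = nrow(x)),
    value = as.vector(x)
  )
  if (!keep_zeros) out <- dplyr::filter(out, .data$value > 0)
  names(out)[3] <- value_col
  dplyr::arrange(out, .data$source, .data$destination)
}

#' @rdname tidy.od_matrix
#' @export
tidy.binary_matrix <- tidy.od_matrix

#' Generic tidier
#'
#' @param x Object to tidy.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Split heads into intra- and inter-state fractions
#'
#' @param od A state-level `od_matrix`.
#' @return Tibble with columns `intra` and `inter` (fractions of heads;
#'   intra = diagonal share).
#' @export
intra_inter_split <- function(od) {
  stopifnot(inherits(od, "od_matrix"))
  if (!identical(attr(od, "level"), "state"))
    stop("intra/inter split is defined at state level", call. = FALSE)
  total <- sum(od)
  if (total <= 0)
    stop("cannot compute intra/inter fractions of an all-zero matrix",
         call. = FALSE)
  intra <- sum(diag(od)) / total
  tibble::tibble(intra = intra, inter = 1 - intra)
}

#' Daily permit frequency
#'
#' Mean and population standard deviation of the number of permits per
#' calendar day across the whole observed span (first to last permit
#' date), counting days with zero permits.
#'
#' @param records Validated permit tibble with dates.
#' @return Tibble with columns `mean`, `sd`, `days`.
#' @export
daily_frequency <- function(records) {
  if (nrow(records) == 0 || all(is.na(records$date)))
    stop("no dated records", call. = FALSE)
  span <- seq(min(records$date), max(records$date), by = "day")
  counts <- table(factor(as.character(records$date),
                         levels = as.character(span)))
  x <- as.numeric(counts)
  tibble::tibble(
    mean = mean(x),
    sd = sqrt(mean((x - mean(x))^2)),
    days = length(x)
  )
}

#' Roll a municipal OD matrix up to state level
#'
#' Sums municipal flows by the originating and receiving state encoded in
#' the qualified `state:municipality` node keys.
#'
#' @param od A municipality-level `od_matrix`.
#' @param roster Optional state roster fixing the node universe.
#' @return A state-level `od_matrix`.
#' @export
rollup_to_state <- function(od, roster = NULL) {
  stopifnot(inherits(od, "od_matrix"))
  if (!identical(attr(od, "level"), "municipality"))
    stop("rollup expects a municipality-level matrix", call. = FALSE)
  state_of <- function(keys) sub(":.*$", "", keys)
  rs <- state_of(rownames(od))
  cs <- state_of(colnames(od))
  labels <- if (is.null(roster)) sort(unique(c(rs, cs))) else sort(unique(roster))
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  ri <- match(rs, labels)
  ci <- match(cs, labels)
  for (i in seq_along(rs)) {
    nz <- which(od[i, ] > 0)
    if (length(nz) > 0)
      for (j in nz) m[ri[i], ci[j]] <- m[ri[i], ci[j]] + od[i, j]
  }
  new_od_matrix(m, level = "state", category = attr(od, "category"),
                period = attr(od, "period"))
}

#' Write an OD matrix to CSV
#'
#' @param od An `od_matrix`.
#' @param path Output path.
#' @param format `"dense"` (row label + one column per destination) or
#'   `"edges"` (three-column source, destination, heads list).
#' @return `path`, invisibly.
#' @export
write_od_matrix <- function(od, path, format = c("dense", "edges")) {
  format <- match.arg(format)
  if (format == "dense") {
    df <- tibble::as_tibble(as.data.frame(unclass(od)), .name_repair = "minimal")
    df <- dplyr::bind_cols(tibble::tibble(source = rownames(od)), df)
    readr::write_csv(df, path)
  } else {
    readr::write_csv(tidy(od), path)
  }
  invisible(path)
}
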