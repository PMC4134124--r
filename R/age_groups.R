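#' Age groupings
#'
#' An age grouping is an ordered set of contiguous, non-overlapping bins that
#' partition `[0, Inf)`. Two groupings are bundled: the 10-year reporting bins
#' used for case tables and age-standardized rates (`<10`, `10-19`, ...,
#' `70-79`, `80+`), and the coarser bins used for stratified trend models
#' (`<20`, `20-29`, `30-39`, `40-49`, `50+`).
#'
#' @param breaks increasing numeric vector of lower bounds starting at 0, with
#'   a final `Inf` upper bound implied; e.g. `c(0, 10, 20)` gives bins
#'   `[0,10)`, `[10,20)`, `[20,Inf)`.
#' @param labels optional character labels, one per bin; generated from the
#'   breaks when omitted.
#' @return an object of class `age_grouping`: a list with `breaks` (lower
#'   bounds), `upper` (exclusive upper bounds, last = `Inf`) and `labels`.
#' @examples
#' g <- age_grouping(c(0, 20, 30, 40, 50))
#' assign_age_group(c(5, 20, 49, 80), g)
#' @export
age_grouping <- function(breaks, labels = NULL) {
  if (breaks[1] != 0 || is.unsorted(breaks, strictly = TRUE)) {
    stop("`breaks` must be strictly increasing lower bounds starting at 0")
  }
  upper <- c(breaks[-1], Inf)
  if (is.null(labels)) {
    labels <- ifelse(
      breaks == 0, paste0("<", upper),
      ifelse(is.infinite(upper), paste0(breaks, "+"),
             paste0(breaks, "-", upper - 1))
    )
  }
  if (length(labels) != length(breaks)) {
    stop("`labels` must have one entry per bin")
  }
  structure(list(breaks = breaks, upper = upper, labels = labels),
            class = "age_grouping")
}

#' @rdname age_grouping
#' @export
default_age_grouping <- function() {
  age_grouping(seq(0, 80, by = 10))
}

#' @rdname age_grouping
#' @export
trend_age_grouping <- function() {
  age_grouping(c(0, 20, 30, 40, 50))
}

#' @rdname age_grouping
#' @param age integer vector of ages in completed years.
#' @param grouping an [age_grouping()].
#' @return `assign_age_group()`: a factor with the grouping's labels.
#' @export
assign_age_group <- function(age, grouping = default_age_grouping()) {
  if (any(age < 0, na.rm = TRUE)) stop("negative ages cannot be binned")
  idx <- findInterval(age, grouping$breaks)
  factor(grouping$labels[idx], levels = grouping$labels)
}

#' @export
print.age_grouping <- function(x, ...) {
  cat("<age_grouping> ", paste(x$labels, collapse = " | "), "\n")
  invisible(x)
}

# Map each bin of `from` onto the bin of `to` that contains it; errors unless
# `from` nests inside `to` (e.g. 10-year bins nest in <20/20-29/.../50+).
regroup_map <- function(from, to) {
  lo <- assign_age_group(from$breaks, to)
  hi_probe <- ifelse(is.infinite(from$upper), from$breaks, from$upper - 1)
  hi <- assign_age_group(hi_probe, to)
  if (any(as.integer(lo) != as.integer(hi))) {
    stop("age groupings do not nest: a source bin straddles a target boundary")
  }
  stats::setNames(as.character(lo), from$labels)
}

#' Re-aggregate a population table to a coarser age grouping
#'
#' @param population tibble with columns `year`, `age_group`, `sex`, `count`,
#'   whose `age_group` labels come from `from`.
#' @param from,to [age_grouping()] objects; `from` bins must nest inside `to`
#'   bins.
#' @return population tibble with `age_group` relabelled per `to` and counts
#'   summed.
#' @export
regroup_population <- function(population, from, to) {
  check_columns(population, c("year", "age_group", "sex", "count"),
                "population table")
  map <- regroup_map(from, to)
  unknown <- setdiff(unique(as.character(population$age_group)), names(map))
  if (length(unknown) > 0) {
    stop("population age_group label(s) not in source grouping: ",
         paste(unknown, collapse = ", "))
  }
  population |>
    dplyr::mutate(age_group = factor(map[as.character(.data$age_group)],
                                     levels = to$labels)) |>
    dplyr::group_by(.data$year, .data$age_group, .data$sex) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}
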