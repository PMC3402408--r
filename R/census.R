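#' Phenotype category frequency
#'
#' Percentage of a surveyed population falling in one phenotype category,
#' rounded half-up to two decimals (so 8/2610 = 0.3065\% prints as 0.31\%,
#' matching the convention of published phenotype-census tables).
#'
#' @param count number of mutants observed in the category.
#' @param population number of individuals surveyed.
#' @return Percentage as a plain number (two decimals).
#' @examples
#' category_frequency(35, 2610) # 1.34
#' @export
category_frequency <- function(count, population) {
  if (!is_count(population) || population < 1) stop_tk("'population' must be a positive integer")
  if (!all(vapply(count, is_count, logical(1)))) stop_tk("'count' must be non-negative integers")
  if (any(count > population)) stop_tk("'count' cannot exceed 'population'")
  round_half_up(100 * count / population, 2L)
}

#' Overall visible-phenotype rate
#'
#' Aggregate frequency of individuals showing any scored phenotype, over
#' disjoint categories (an individual with several altered traits is counted
#' once, under its major trait). All tallies must refer to the same surveyed
#' population.
#'
#' @param tallies data frame with columns `count` and `population`
#'   (constant), e.g. the phenotype table from [load_jinmai47_tables()];
#'   may be empty.
#' @param digits decimal places for the half-up rounding (default 2).
#' @return Percentage of the population with a visible phenotype.
#' @examples
#' overall_visible_rate(data.frame(count = c(35, 16), population = 2610))
#' @export
overall_visible_rate <- function(tallies, digits = 2L) {
  stopifnot(is.data.frame(tallies))
  if (nrow(tallies) == 0L) return(0)
  if (!all(c("count", "population") %in% names(tallies))) {
    stop_tk("'tallies' needs columns 'count' and 'population'")
  }
  pop <- unique(tallies$population)
  if (length(pop) != 1L) {
    stop_tk("inconsistent population sizes across categories: ",
            paste(pop, collapse = ", "))
  }
  category_frequency(sum(tallies$count), pop) |>
    round_half_up(digits)
}
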