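#' Published summary tables for a 67-country resource-needs analysis
#'
#' Small reference tables of published group-level summary estimates for
#' scaling up health services in 67 low- and middle-income countries:
#' end-term (2026-30) mean annual incremental cost and mean population by
#' country group and scenario, and deaths averted (2016-30) by cause under
#' the progress and ambitious scenarios.  They serve as printed-table inputs
#' for arithmetic consistency checks — e.g. applying [per_person()] to the
#' cost and population cells recovers the published per-person investment
#' needs, and summing the ambitious deaths-averted entries (stillbirths
#' included) recovers the published lives-saved headline.
#'
#' @return A tibble.
#' @export
published_group_costs <- function() {
  readr::read_csv(system.file("extdata", "published_group_costs.csv",
                              package = "uhcproj", mustWork = TRUE),
                  show_col_types = FALSE)
}

#' @rdname published_group_costs
#' @export
published_deaths_averted <- function() {
  readr::read_csv(system.file("extdata", "published_deaths_averted.csv",
                              package = "uhcproj", mustWork = TRUE),
                  show_col_types = FALSE)
}
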