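#' Abridged age-band structure
#'
#' The demographic engine works on the conventional abridged age grouping:
#' ages 0, 1-4, then 5-year bands up to the open-ended 85+ band (19 bands).
#' Band widths drive both within-band ageing (a fraction `1/width` of each
#' band's survivors advances to the next band every year) and the life-table
#' person-year computation.
#'
#' @return A tibble with columns `band` (label), `start` (lower age bound in
#'   years) and `width` (band width in years; `Inf` for the open band).
#' @export
#' @examples
#' age_bands()
age_bands <- function() {
  start <- c(0L, 1L, seq(5L, 85L, by = 5L))
  width <- c(1, 4, rep(5, 16), Inf)
  lab <- c("0", "1-4",
           paste(seq(5, 80, by = 5), seq(9, 84, by = 5), sep = "-"),
           "85+")
  tibble::tibble(band = lab, start = start, width = width)
}

#' @rdname age_bands
#' @export
sexes <- function() c("female", "male")

#' Reproductive-age bands used for fertility rates
#' @return Character vector of the seven maternal age-band labels (15-49).
#' @export
fertility_bands <- function() {
  paste(seq(15, 45, by = 5), seq(19, 49, by = 5), sep = "-")
}

# bands whose start age lies in [lo, hi] (inclusive); used by effect filters
bands_in_range <- function(lo, hi) {
  ab <- age_bands()
  ab$band[ab$start >= lo & ab$start <= hi]
}
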