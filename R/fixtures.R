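#' Packaged T/C reading tables
#'
#' The package ships the published readout tables for three LFA strip sets
#' assayed at five albumin quantities (10 fg, 100 fg, 1 pg, 10 pg, 100 pg),
#' five readings per strip: 75 T/C ratios in total, stored verbatim at the
#' 3-decimal precision at which they were reported. Sets 1 and 2 are the
#' conventional training split; set 3 is the held-out test split.
#'
#' @param sets optional character vector restricting to some of `"set1"`,
#'   `"set2"`, `"set3"`.
#' @return Data frame with columns `set_id`, `quantity_fg`, `reading_index`,
#'   `tc_ratio`.
#' @export
load_fixture_readings <- function(sets = NULL) {
  path <- system.file("extdata", "tc_readings.csv", package = "lfaquant",
                      mustWork = TRUE)
  d <- read_readings(path)
  if (!is.null(sets)) {
    bad <- setdiff(sets, unique(d$set_id))
    if (length(bad)) {
      stop(sprintf("unknown set id(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    d <- d[d$set_id %in% sets, , drop = FALSE]
    rownames(d) <- NULL
  }
  d
}
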