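# Moving spatio-temporal window sampling: the 16-day day-of-year window
# pooled across years, per-stratum sample assembly, the 5000-sample cap,
# the 1000-sample training floor and the 70:30 split.

#' The 16-day day-of-year window
#'
#' Returns the ordered window for a target day of year: the 7 days before,
#' the target itself and the 8 days after (16 days in total), wrapping
#' around the 365-day year boundary.
#'
#' @param doy Integer in 1..365.
#' @return Integer vector of 16 DOYs, in window order.
#' @export
doy_window <- function(doy) {
  if (length(doy) != 1 || is.na(doy) || doy < 1 || doy > 365 ||
      doy != round(doy))
    stop("doy must be a single integer in 1..365")
  ((doy - 7):(doy + 8) - 1) %% 365 + 1
}

# circular distance between two DOYs on the 365-day year
circular_doy_distance <- function(a, b) {
  d <- abs(a - b) %% 365
  pmin(d, 365 - d)
}

#' Collect the samples of one model key
#'
#' Filters a labelled training table to the rows of one (day-of-year,
#' stratum) model: stratum equal to `stratum` (or every vegetated row when
#' `stratum = "universal"`) and day of year inside [doy_window()] of the
#' target, pooled over all years present.
#'
#' @param table Training table with `doy`, `stratum`, `year` columns.
#' @param doy Target day of year.
#' @param stratum Model ID 1..19 or `"universal"`.
#' @return The matching rows.
#' @export
collect_window_samples <- function(table, doy, stratum) {
  win <- doy_window(doy)
  sel <- table$doy %in% win
  if (!identical(stratum, "universal"))
    sel <- sel & table$stratum == stratum
  table[sel & !is.na(table$stratum), , drop = FALSE]
}

#' Apply the sample-size rules
#'
#' With `n` available samples: above the cap, a seeded uniform random subset
#' of exactly `cap` rows is kept; between the floor and the cap, all rows are
#' kept; at or below the floor (`min_n`), the model is skipped.
#'
#' @param table Candidate samples for one model key.
#' @param cap Maximum training-pool size (default 5000).
#' @param min_n Minimum sample size below which no model is trained
#'   (default 1000).
#' @param seed Integer seed for the subset draw.
#' @return A list with `table` (the retained rows, or `NULL` when skipped),
#'   `skipped` (logical), `n_found` and `n_used`.
#' @export
apply_sampling_rules <- function(table, cap = 5000L, min_n = 1000L,
                                 seed = 1L) {
  stopifnot(cap > min_n, min_n > 0)
  n <- nrow(table)
  if (n <= min_n)
    return(list(table = NULL, skipped = TRUE, n_found = n, n_used = 0L))
  if (n > cap) {
    set.seed(seed)
    table <- table[sort(sample.int(n, cap)), , drop = FALSE]
  }
  list(table = table, skipped = FALSE, n_found = n, n_used = nrow(table))
}

#' Split into training and validation sets
#'
#' Seeded exact 70:30 (by default) partition: `round(ratio * n)` rows go to
#' training, the rest to validation; the two parts are disjoint and
#' exhaustive.
#'
#' @param table Table to split (`n >= 2`).
#' @param ratio Training fraction (default 0.7).
#' @param seed Integer seed for the shuffle.
#' @return A list with elements `train` and `val`.
#' @export
split_train_val <- function(table, ratio = 0.7, seed = 1L) {
  n <- nrow(table)
  if (n < 2) stop("cannot split a table with fewer than 2 rows")
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- round(ratio * n)
  list(train = table[sort(idx[seq_len(n_train)]), , drop = FALSE],
       val = table[sort(idx[-seq_len(n_train)]), , drop = FALSE])
}
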