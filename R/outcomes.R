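#' EQ-5D-5L value sets
#'
#' A value set (tariff) maps a five-digit EQ-5D-5L health-state profile to a
#' utility anchored at 1 for full health (state 11111). This package uses
#' additive value sets: the utility of a state is 1 minus the sum of the
#' decrement for the attained level in each of the five dimensions (mobility,
#' self-care, usual activities, pain/discomfort, anxiety/depression).
#' Decrements must be non-negative and non-decreasing with level within a
#' dimension. Country tariffs (e.g. the Dutch EQ-5D-5L tariff) are supplied
#' by the user as a decrement table; a clearly synthetic illustrative set
#' ships with the package for examples and tests.
#'
#' @param decrements A 5 x 4 numeric matrix (or data frame): rows are the
#'   dimensions MO, SC, UA, PD, AD; columns are levels 2-5; entries are the
#'   total utility decrement at that level.
#' @param name Label for the value set.
#' @return An object of class `value_set` with fields `decrements`, `name`
#'   and `minimum` (the utility of state 55555).
#' @export
value_set <- function(decrements, name = "custom") {
  decrements <- as.matrix(decrements)
  if (!all(dim(decrements) == c(5L, 4L)))
    stopf("`decrements` must be 5 dimensions x levels 2-5")
  if (any(decrements < 0))
    stopf("decrements must be non-negative")
  if (any(apply(decrements, 1L, function(r) any(diff(r) < 0))))
    stopf("decrements must be non-decreasing with level within each dimension")
  rownames(decrements) <- c("MO", "SC", "UA", "PD", "AD")
  colnames(decrements) <- paste0("L", 2:5)
  structure(list(name = name, decrements = decrements,
                 minimum = 1 - sum(decrements[, "L5"])),
            class = "value_set")
}

#' @rdname value_set
#' @details `example_value_set()` returns the illustrative synthetic value
#'   set shipped in `inst/extdata/valueset_synthetic.csv`. Its decrements are
#'   invented for testing and do not reproduce any national tariff.
#' @export
example_value_set <- function() {
  read_value_set(system.file("extdata", "valueset_synthetic.csv",
                             package = "tbcea", mustWork = TRUE),
                 name = "synthetic-illustrative")
}

#' @rdname value_set
#' @param path CSV with columns `dimension` (MO/SC/UA/PD/AD), `level` (2-5)
#'   and `decrement`.
#' @export
read_value_set <- function(path, name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dimension", "level", "decrement")
  if (!all(need %in% names(df)))
    stopf("value-set CSV needs columns: %s", paste(need, collapse = ", "))
  m <- matrix(NA_real_, 5L, 4L,
              dimnames = list(c("MO", "SC", "UA", "PD", "AD"),
                              paste0("L", 2:5)))
  m[cbind(match(df$dimension, rownames(m)), df$level - 1L)] <- df$decrement
  if (anyNA(m)) stopf("value-set CSV does not cover all 5 x 4 decrements")
  value_set(m, name = name)
}

#' Utility of an EQ-5D-5L health state
#'
#' Converts five-digit profiles (e.g. `"21321"`) to utilities: 1 minus the
#' sum of the value set's decrements for the attained levels. Vectorised over
#' states.
#'
#' @param state Character vector of five-digit profiles, digits 1-5.
#' @param vset A [value_set()].
#' @return Numeric utilities; state `"11111"` maps to exactly 1.
#' @export
#' @examples
#' utility_from_state("11111", example_value_set())  # 1
utility_from_state <- function(state, vset) {
  stopifnot(inherits(vset, "value_set"))
  state <- as.character(state)
  if (any(is.na(state)) || any(!grepl("^[1-5]{5}$", state)))
    stopf("each state must be five digits, each in 1-5")
  lv <- matrix(as.integer(unlist(strsplit(state, ""), use.names = FALSE)),
               ncol = 5L, byrow = TRUE)
  dec <- cbind(0, vset$decrements)  # level 1 has no decrement
  total <- numeric(nrow(lv))
  for (d in 1:5) total <- total + unname(dec[d, lv[, d]])
  1 - total
}

#' Quality-adjusted life-years by the area-under-the-curve method
#'
#' For consecutive measurements the mean of the two utilities is multiplied
#' by the time in years between them, and the per-segment products are
#' summed (the trapezoid rule). No flooring is applied, so value sets that
#' permit utilities below 0 can yield negative QALYs.
#'
#' @param times Assessment times in years, strictly increasing, length >= 2.
#' @param utilities Utilities at those times (<= 1), same length.
#' @return Total QALYs over the trajectory span.
#' @export
#' @examples
#' qaly_auc(c(0, 0.25, 0.5, 0.75, 1), c(0.4, 0.6, 0.8, 0.8, 1.0))  # 0.725
qaly_auc <- function(times, utilities) {
  if (length(times) < 2L) stopf("need at least two measurements")
  if (length(times) != length(utilities)) stopf("length mismatch")
  if (anyNA(times) || anyNA(utilities))
    stopf("QALY calculation requires complete (post-imputation) trajectories")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (any(utilities > 1 + 1e-9)) stopf("utilities cannot exceed 1")
  dt <- diff(times)
  mid <- (utilities[-1] + utilities[-length(utilities)]) / 2
  sum(mid * dt)
}

#' Linear 0-100 transformation of a raw subscale sum
#'
#' Maps a RAND-36-style raw item sum onto a 0-100 scale, higher scores
#' meaning better functioning: `100 * (raw - min) / (max - min)`.
#'
#' @param raw_item_sum Raw sum of the subscale's items.
#' @param raw_min,raw_max Lowest and highest possible raw sums.
#' @return Score on 0-100.
#' @export
subscale_score <- function(raw_item_sum, raw_min, raw_max) {
  if (raw_min >= raw_max) stopf("`raw_min` must be below `raw_max`")
  if (any(raw_item_sum < raw_min | raw_item_sum > raw_max, na.rm = TRUE))
    stopf("raw sum outside [%s, %s]", raw_min, raw_max)
  100 * (raw_item_sum - raw_min) / (raw_max - raw_min)
}
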