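#' Experimental conditions
#'
#' A condition is the combination of a sharing treatment and the number of
#' estimates `tau` shown to each subject.  The full experiment crosses the
#' three treatments with `tau = 1, 3, 5, 7, 9, 11`, giving 18 conditions.
#'
#' @param treatments Character vector of treatment names, a subset of
#'   `"random"`, `"median"`, `"shifted_median"`.
#' @param taus Integer vector of numbers of shared estimates.
#' @return A data frame with columns `condition` (integer id), `treatment`
#'   and `tau`, one row per condition.
#' @examples
#' conditions_grid()                      # the full 18-condition design
#' conditions_grid("random", c(1, 3))    # a reduced design
#' @export
conditions_grid <- function(treatments = c("random", "median", "shifted_median"),
                            taus = c(1L, 3L, 5L, 7L, 9L, 11L)) {
  treatments <- match.arg(treatments, c("random", "median", "shifted_median"),
                          several.ok = TRUE)
  taus <- as.integer(taus)
  if (any(taus < 1L)) stop_domain("tau must be a positive integer")
  grid <- expand.grid(tau = taus, treatment = treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(condition = seq_len(nrow(grid)),
             treatment = grid$treatment,
             tau = grid$tau,
             stringsAsFactors = FALSE)
}
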