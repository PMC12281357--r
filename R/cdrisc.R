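#' Score a CD-RISC 25-item response
#'
#' Computes the Connor-Davidson Resilience Scale total (0-100) from the 25
#' item responses (each on a 0-4 Likert scale). Following the scale authors'
#' recommendation, up to 6 missing items are mean-imputed from the observed
#' items before summing; a respondent with more than 6 missing items cannot
#' be scored and is flagged for exclusion.
#'
#' @param items numeric vector of length 25; values in 0..4 or `NA` for
#'   missing items.
#' @return A list with `score` (possibly fractional total in \[0, 100\], or
#'   `NA` if excluded), `excluded` (logical), and `n_missing`.
#' @examples
#' score_cdrisc(rep(4, 25))$score            # 100
#' score_cdrisc(c(rep(2, 24), NA))$score     # 50: imputed item = 2
#' score_cdrisc(c(rep(3, 18), rep(NA, 7)))   # excluded: 7 items missing
#' @export
score_cdrisc <- function(items) {
  if (length(items) != 25L) {
    stopf("a CD-RISC response has 25 items, got %d", length(items))
  }
  obs <- items[!is.na(items)]
  if (length(obs) && (any(obs < 0 | obs > 4) || any(obs != round(obs)))) {
    stopf("CD-RISC item scores must be integers in [0, 4]")
  }
  n_missing <- sum(is.na(items))
  if (n_missing > 6L) {
    return(list(score = NA_real_, excluded = TRUE, n_missing = n_missing))
  }
  score <- sum(obs) + n_missing * mean(obs)
  list(score = score, excluded = FALSE, n_missing = n_missing)
}
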