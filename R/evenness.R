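# evenness indices: Camargo (space use) and Pielou (diet selection)

#' Camargo's index of evenness
#'
#' \eqn{E = 1 - \sum_{i<j} |p_i - p_j| / S} where \eqn{p_i} are the category
#' proportions and \eqn{S} the number of categories. Here the categories are
#' 5 x 5 m grid cells and the proportions are shares of GPS fixes, with
#' zero-count cells inside the paddock included (evenness is judged against
#' the whole available area, not just the visited part).
#'
#' The pairwise sum is evaluated by a sorted prefix-sum identity
#' (\eqn{O(S \log S)}): for ascending \eqn{p_{(1)} \le \dots \le p_{(S)}},
#' \eqn{\sum_{i<j} |p_i - p_j| = \sum_k (2k - 1 - S)\, p_{(k)}}.
#'
#' @param counts Non-negative counts per category (cell), zeros allowed,
#'   sum > 0.
#' @return Evenness in (0, 1]; 1 for perfectly uniform counts.
#' @examples
#' camargo_evenness(c(10, 10, 10, 10)) # 1
#' camargo_evenness(c(4, 0, 0, 0))     # 0.25
#' @export
camargo_evenness <- function(counts) {
  check_number(counts, "counts")
  if (any(counts < 0)) abort_bad_arg("`counts` must be non-negative.")
  total <- sum(counts)
  if (total <= 0) abort_bad_arg("all counts are zero; evenness undefined.",
                                class = "grazemetry_degenerate_error")
  s <- length(counts)
  p <- sort(counts / total)
  k <- seq_len(s)
  pair_sum <- sum((2 * k - 1 - s) * p)
  1 - pair_sum / s
}

#' Pielou's evenness of a proportion vector
#'
#' \eqn{J = H / \ln S} with Shannon entropy \eqn{H = -\sum p \ln p} over the
#' \eqn{S} categories actually present (p > 0). Used here for the evenness
#' of diet selection across consumed taxa: J near 1 means the animal ate
#' what it met, J near 0 means strict selection.
#'
#' @param proportions Non-negative proportions; zeros are dropped; need not
#'   be normalized (they are renormalized over the positive entries).
#' @return Evenness in (0, 1], or `NA` carrying attribute
#'   `undefined = TRUE` when only a single category is present
#'   (\eqn{\ln 1 = 0}).
#' @examples
#' pielou_evenness(c(0.75, 0.25)) # 0.8113
#' @export
pielou_evenness <- function(proportions) {
  check_number(proportions, "proportions")
  if (any(proportions < 0)) abort_bad_arg("`proportions` must be non-negative.")
  p <- proportions[proportions > 0]
  if (length(p) == 0) abort_bad_arg("no positive proportions.",
                                    class = "grazemetry_degenerate_error")
  if (length(p) == 1) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  p <- p / sum(p)
  h <- -sum(p * log(p))
  h / log(length(p))
}
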