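#' @importFrom Rcpp evalCpp
#' @useDynLib treeDenovo, .registration = TRUE
NULL

#' Area under the ROC curve for a two-class score split
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, ties counted half.
#'
#' @param posScores scores of the positive class.
#' @param negScores scores of the negative class.
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(posScores, negScores) {
  np <- length(posScores)
  nn <- length(negScores)
  stopifnot(np > 0, nn > 0)
  r <- rank(c(posScores, negScores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}
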