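#' Fraction of a read covered by high-quality windows
#'
#' Slides a fixed-length window (step 1) along the PHRED score vector; a
#' base passes when it lies inside at least one window whose mean score
#' reaches the threshold. Reads shorter than the window are evaluated as a
#' single whole-read window. The returned value is the fraction of bases
#' that pass — the "portion of the sequence" with average PHRED quality at
#' or above the threshold.
#'
#' @param phred Integer vector of per-base PHRED scores.
#' @param window Window length in bases.
#' @param threshold Minimum window mean score.
#' @return Proportion in `[0, 1]`.
#' @export
#' @examples
#' window_pass_fraction(c(rep(30, 20), rep(2, 80)))  # 0.23
window_pass_fraction <- function(phred, window = 10L, threshold = 20) {
  if (length(phred) == 0) stop("empty PHRED score vector")
  stopifnot(window >= 1, all(phred >= 0))
  L <- length(phred)
  if (L < window) return(as.numeric(mean(phred) >= threshold))
  cs <- cumsum(c(0, phred))
  sums <- cs[(window + 1):(L + 1)] - cs[1:(L - window + 1)]
  starts <- which(sums >= threshold * window)
  if (length(starts) == 0) return(0)
  covered <- logical(L)
  for (s in starts) covered[s:(s + window - 1L)] <- TRUE
  mean(covered)
}

#' Quality-filter sequencing reads
#'
#' Applies the sliding-window criterion of [window_pass_fraction()] to each
#' read and discards reads for which less than `min_fraction` of their
#' length meets it (a read at exactly the threshold fraction is kept).
#'
#' @param reads Data.frame with `read_id` and `qual` (PHRED+33 string)
#'   columns, or a single integer PHRED vector.
#' @param window,threshold Passed to [window_pass_fraction()].
#' @param min_fraction Minimum kept fraction of the read length.
#' @return Data.frame: `read_id`, `pass_fraction`, `kept`.
#' @export
qc_filter <- function(reads, window = 10L, threshold = 20,
                      min_fraction = 0.15) {
  if (is.numeric(reads)) {
    reads <- data.frame(read_id = "read", qual = phred_to_chars(reads),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("read_id", "qual") %in% names(reads)))
  frac <- vapply(reads$qual, function(q) {
    window_pass_fraction(chars_to_phred(q), window, threshold)
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(
    read_id = reads$read_id,
    pass_fraction = frac,
    kept = frac >= min_fraction,
    stringsAsFactors = FALSE
  )
}
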