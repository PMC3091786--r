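#' Round half away from zero
#'
#' Display rounding used in all human-readable statistics (percentages to
#' the nearest integer, mean degrees to a configurable number of decimals),
#' with ties rounded away from zero rather than to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage of a count over a denominator
#'
#' Helper used by the report module for confirmation-rate and coverage
#' arithmetic, e.g. `percent_of(27, 31)` is 87.
#'
#' @param num Numerator count.
#' @param den Denominator count (> 0).
#' @param digits Decimal places of the displayed percentage.
#' @return Numeric percentage, rounded half away from zero.
#' @export
percent_of <- function(num, den, digits = 0) {
  stopifnot(is.numeric(num), is.numeric(den), all(den > 0))
  round_half_away(100 * num / den, digits)
}

#' Reverse complement of a nucleotide string
#' @param nt Single nucleotide string (A/C/G/T/N).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Translate a nucleotide string in frame 1
#'
#' Translates from the first base, ignoring any trailing partial codon.
#' When `truncate_at_stop` is TRUE (the behaviour the prey-calling module
#' relies on) the returned peptide ends just before the first stop codon,
#' mirroring what the ribosome would produce from a fusion transcript.
#'
#' @param nt Nucleotide string.
#' @param truncate_at_stop Truncate the peptide at the first stop codon.
#' @return Amino-acid string (possibly empty).
#' @export
translate_nt <- function(nt, truncate_at_stop = TRUE) {
  n <- nchar(nt) - nchar(nt) %% 3
  if (n < 3) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
  if (truncate_at_stop) {
    stop_at <- regexpr("*", aa, fixed = TRUE)
    if (stop_at > 0) aa <- substr(aa, 1, stop_at - 1)
  }
  aa
}

# PHRED+33 encoding helpers -------------------------------------------------

phred_to_chars <- function(q) {
  stopifnot(all(q >= 0), all(q <= 93))
  rawToChar(as.raw(q + 33L))
}

chars_to_phred <- function(s) {
  as.integer(charToRaw(s)) - 33L
}

# Back-translation: one uniformly drawn synonymous codon per residue,
# vectorised over all residues of all sequences at once (the generator
# back-translates megabase-scale toy proteomes).
codon_choices <- local({
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  by_aa
})

back_translate <- function(aa_seqs, stop_codons) {
  stopifnot(length(stop_codons) == length(aa_seqs))
  res <- strsplit(aa_seqs, "", fixed = TRUE)
  lens <- lengths(res)
  flat <- unlist(res, use.names = FALSE)
  bad <- setdiff(unique(flat), names(codon_choices))
  if (length(bad) > 0)
    stop("cannot back-translate residue(s): ", paste(bad, collapse = ", "))
  n_syn <- lengths(codon_choices)[flat]
  pick <- floor(stats::runif(length(flat)) * n_syn) + 1L
  # index into a padded codon matrix: rows = residues, cols = synonym slot
  max_syn <- max(lengths(codon_choices))
  codon_mat <- t(vapply(codon_choices,
                        function(x) c(x, rep(NA_character_, max_syn - length(x))),
                        character(max_syn)))
  codons <- codon_mat[cbind(match(flat, rownames(codon_mat)), pick)]
  grp <- rep.int(seq_along(lens), lens)
  cds <- vapply(split(codons, grp), paste, character(1), collapse = "")
  paste0(cds, stop_codons)
}

# Internal TSV helpers: all tabular artifacts are plain TSV with a header.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = colClasses,
                    comment.char = "", quote = "")
}
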