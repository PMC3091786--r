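#' Classify a protein C-terminus into a PDZ-binding consensus class
#'
#' Canonical PDZ ligands are defined by the last three residues of the
#' partner protein (positions -2, -1, 0, where 0 is the C-terminus):
#' class 1 `[ST]X[Phi]`, class 2 `[Phi]X[Phi]`, class 3 `[DE]X[Phi]` with
#' Phi = \{Y,F,W,C,M,V,I,L,A\} and X any residue. The position -2 sets are
#' disjoint, so every terminus matches at most one class; termini matching
#' none are "non-consensus".
#'
#' @param aa_seq Character vector of amino-acid sequences (each of length
#'   >= 3). Only the final three residues are inspected.
#' @param motifs Motif definitions, see [consensus_motifs()].
#' @return Character vector over `"1"`, `"2"`, `"3"`, `"none"`.
#' @export
#' @examples
#' classify_cterm(c("MKTSV", "MKVAV", "MKEAV", "IAAELR"))
classify_cterm <- function(aa_seq, motifs = consensus_motifs()) {
  stopifnot(is.character(aa_seq), length(aa_seq) >= 1)
  n <- nchar(aa_seq)
  if (any(n < 3)) stop("sequences must be at least 3 residues long")
  last3 <- substr(aa_seq, n - 2, n)
  m2 <- substr(last3, 1, 1)
  p0 <- substr(last3, 3, 3)
  nonstd <- !(m2 %in% AA_STANDARD) | !(substr(last3, 2, 2) %in% AA_STANDARD) |
    !(p0 %in% AA_STANDARD)
  if (any(nonstd))
    warning("non-standard residue(s) in terminal tripeptide; classified as 'none'")
  cls <- rep("none", length(aa_seq))
  for (k in names(motifs)) {
    hit <- m2 %in% motifs[[k]]$m2 & p0 %in% motifs[[k]]$p0 & cls == "none"
    cls[hit] <- k
  }
  cls[nonstd] <- "none"
  cls
}

#' Classify a gene from its splice-form set
#'
#' When the C-terminus of the sequenced clone is experimentally confirmed,
#' only that form's terminus counts. When it is not (sequencing from the
#' N-terminus did not span the fragment), the conservative rule applies: if
#' any predicted splice form of the gene carries a consensus terminus, a
#' class is attributed. When different forms match different classes the
#' lowest-numbered class is reported.
#'
#' @param forms Named character vector of splice-form sequences
#'   (names = splice-form ids) or a data.frame with `protein_id` and
#'   `sequence` columns; must contain at least one form.
#' @param cterm_confirmed Is the C-terminus of the first form (the observed
#'   clone) experimentally confirmed?
#' @param motifs Motif definitions.
#' @return A one-row data.frame: `cls`, `basis` (`"confirmed_cterm"` or
#'   `"any_splice_form"`), `matched_form`, `last3`.
#' @export
classify_protein <- function(forms, cterm_confirmed = FALSE,
                             motifs = consensus_motifs()) {
  if (is.data.frame(forms)) {
    seqs <- stats::setNames(forms$sequence, forms$protein_id)
  } else {
    seqs <- forms
  }
  if (length(seqs) == 0 || !any(nzchar(seqs)))
    stop("empty splice-form set")
  if (is.null(names(seqs))) names(seqs) <- paste0("form", seq_along(seqs))
  last3 <- substr(seqs, nchar(seqs) - 2, nchar(seqs))
  if (isTRUE(cterm_confirmed)) {
    cls <- classify_cterm(seqs[1], motifs)
    return(data.frame(cls = cls, basis = "confirmed_cterm",
                      matched_form = if (cls == "none") "" else names(seqs)[1],
                      last3 = unname(last3[1]), stringsAsFactors = FALSE))
  }
  cls_all <- classify_cterm(seqs, motifs)
  hits <- which(cls_all != "none")
  if (length(hits) == 0) {
    return(data.frame(cls = "none", basis = "any_splice_form",
                      matched_form = "", last3 = unname(last3[1]),
                      stringsAsFactors = FALSE))
  }
  best <- hits[order(cls_all[hits])][1]
  data.frame(cls = cls_all[best], basis = "any_splice_form",
             matched_form = names(seqs)[best], last3 = unname(last3[best]),
             stringsAsFactors = FALSE)
}

#' Classify every gene of a proteome
#'
#' Applies [classify_protein()] gene by gene: confirmed termini are
#' classified directly; unconfirmed ones fall back to the conservative
#' any-splice-form rule over all forms sharing the gene id.
#'
#' @param proteome A `pdz_proteome` object or proteome table.
#' @param motifs Motif definitions.
#' @return Data.frame with one row per protein entry: `protein_id`,
#'   `gene_id`, `last3`, `cls` (own terminus), `cls_gene` (after the
#'   splice-form rule), `basis`, `matched_form`.
#' @export
classify_proteome <- function(proteome, motifs = consensus_motifs()) {
  tab <- as_proteome_table(proteome)
  if (nrow(tab) == 0) stop("empty proteome")
  own <- classify_cterm(tab$sequence, motifs)
  if (is.null(tab$gene_id)) tab$gene_id <- tab$protein_id
  if (is.null(tab$cterm_confirmed)) tab$cterm_confirmed <- TRUE
  out <- data.frame(
    protein_id = tab$protein_id,
    gene_id = tab$gene_id,
    last3 = substr(tab$sequence, nchar(tab$sequence) - 2, nchar(tab$sequence)),
    cls = own,
    cls_gene = own,
    basis = ifelse(tab$cterm_confirmed, "confirmed_cterm", "any_splice_form"),
    matched_form = ifelse(own == "none", "", tab$protein_id),
    stringsAsFactors = FALSE
  )
  todo <- which(!tab$cterm_confirmed)
  for (i in todo) {
    sibs <- which(tab$gene_id == tab$gene_id[i])
    # the observed entry first, then its sibling forms
    ord <- c(i, setdiff(sibs, i))
    call <- classify_protein(
      stats::setNames(tab$sequence[ord], tab$protein_id[ord]),
      cterm_confirmed = FALSE, motifs = motifs
    )
    out$cls_gene[i] <- call$cls
    out$matched_form[i] <- call$matched_form
    out$last3[i] <- call$last3
  }
  out
}

#' Append the B2 read-through tail to a protein
#'
#' Models an ORFeome-derived construct: the native stop codon is replaced
#' by the Gateway B2 sequence, so the expressed protein carries the fixed
#' 21-residue extension [B2_TAIL_PEPTIDE]. The resulting terminus (`PIL`)
#' never matches a consensus class.
#'
#' @param aa_seq Character vector of protein sequences (non-empty).
#' @return The tagged sequences.
#' @export
b2_tag <- function(aa_seq) {
  stopifnot(is.character(aa_seq))
  if (any(nchar(aa_seq) == 0)) stop("empty protein sequence")
  paste0(aa_seq, B2_TAIL_PEPTIDE)
}

#' Design a C-terminally truncated construct
#'
#' Builds the Delta-Cter construct used to probe internal (non-canonical)
#' binding: the last three residues of the minimal interacting region (or
#' full protein) are removed and replaced by a stop codon in the cloning
#' primers. Truncation can itself create a new consensus terminus; the
#' flag reports whether it did.
#'
#' @param aa_seq Protein sequence.
#' @param mir_span Optional length-2 integer vector (aa start, aa end) of
#'   the minimal interacting region; defaults to the full protein.
#' @param motifs Motif definitions.
#' @return A one-row data.frame: `construct` (the truncated sequence),
#'   `original_cls` (class of the untruncated span terminus),
#'   `new_cls`, `new_site_created`.
#' @export
design_truncated <- function(aa_seq, mir_span = NULL,
                             motifs = consensus_motifs()) {
  stopifnot(is.character(aa_seq), length(aa_seq) == 1)
  span <- if (is.null(mir_span)) c(1L, nchar(aa_seq)) else as.integer(mir_span)
  stopifnot(length(span) == 2, span[1] >= 1, span[2] <= nchar(aa_seq))
  frag <- substr(aa_seq, span[1], span[2])
  if (nchar(frag) < 6)
    stop("span too short to truncate: need >= 6 aa, got ", nchar(frag))
  construct <- substr(frag, 1, nchar(frag) - 3)
  new_cls <- classify_cterm(construct, motifs)
  data.frame(
    construct = construct,
    original_cls = classify_cterm(frag, motifs),
    new_cls = new_cls,
    new_site_created = new_cls != "none",
    stringsAsFactors = FALSE
  )
}

#' Consensus-class composition of a proteome
#'
#' Counts and proportions of C-terminal consensus classes over all protein
#' entries, the background row of a Table-1-style report.
#'
#' @param proteome A `pdz_proteome`, proteome table, or the output of
#'   [classify_proteome()].
#' @param motifs Motif definitions.
#' @return A list with `counts` (named integer vector over
#'   1/2/3/none), `proportions`, `total_consensus` (count and proportion of
#'   classes 1-3 combined) and `n`.
#' @export
proteome_class_table <- function(proteome, motifs = consensus_motifs()) {
  if (is.data.frame(proteome) && "cls" %in% names(proteome)) {
    cls <- proteome$cls
  } else {
    tab <- as_proteome_table(proteome)
    if (nrow(tab) == 0) stop("empty proteome")
    cls <- classify_cterm(tab$sequence, motifs)
  }
  if (length(cls) == 0) stop("empty proteome")
  lev <- c("1", "2", "3", "none")
  counts <- table(factor(cls, levels = lev))
  counts <- stats::setNames(as.integer(counts), lev)
  n <- sum(counts)
  props <- counts / n
  list(
    counts = counts,
    proportions = props,
    total_consensus = c(count = sum(counts[c("1", "2", "3")]),
                        proportion = unname(sum(props[c("1", "2", "3")]))),
    n = n
  )
}
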