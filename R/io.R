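#' Write proteome and CDS FASTA files
#'
#' @param proteome A proteome object from [generate_proteome()] or a
#'   data.frame with `protein_id`, `sequence`, `cds` columns.
#' @param aa_path Output path for the amino-acid FASTA.
#' @param cds_path Output path for the coding-sequence FASTA.
#' @return Invisibly, the two paths.
#' @export
write_proteome_fasta <- function(proteome, aa_path, cds_path) {
  tab <- as_proteome_table(proteome)
  aa <- Biostrings::AAStringSet(tab$sequence)
  names(aa) <- tab$protein_id
  Biostrings::writeXStringSet(aa, aa_path, width = 70)
  nt <- Biostrings::DNAStringSet(tab$cds)
  names(nt) <- tab$protein_id
  Biostrings::writeXStringSet(nt, cds_path, width = 70)
  invisible(c(aa_path, cds_path))
}

#' Read a proteome from FASTA files
#'
#' Reconstructs the tabular proteome representation from an amino-acid
#' FASTA and its matched CDS FASTA, optionally joining a splice-form table
#' (columns `protein_id`, `gene_id`, `is_splice_form`, `cterm_confirmed`).
#' Records are validated: CDS translations must equal the protein sequences
#' (terminal stop excluded).
#'
#' @param aa_path Amino-acid FASTA path.
#' @param cds_path CDS FASTA path.
#' @param splice_path Optional splice-form table TSV path.
#' @return A `pdz_proteome` object.
#' @export
read_proteome_fasta <- function(aa_path, cds_path, splice_path = NULL) {
  aa <- Biostrings::readAAStringSet(aa_path)
  nt <- Biostrings::readDNAStringSet(cds_path)
  ids <- names(aa)
  if (!setequal(ids, names(nt)))
    stop("protein and CDS FASTA files carry different identifiers")
  nt <- nt[ids]
  tab <- data.frame(
    protein_id = ids,
    gene_id = ids,
    is_splice_form = FALSE,
    cterm_confirmed = TRUE,
    sequence = as.character(aa),
    cds = as.character(nt),
    stringsAsFactors = FALSE
  )
  if (!is.null(splice_path)) {
    sp <- read_tsv(splice_path)
    idx <- match(tab$protein_id, sp$protein_id)
    if (anyNA(idx)) stop("splice-form table does not cover all proteins")
    tab$gene_id <- sp$gene_id[idx]
    tab$is_splice_form <- as.logical(sp$is_splice_form[idx])
    tab$cterm_confirmed <- as.logical(sp$cterm_confirmed[idx])
  }
  rownames(tab) <- NULL
  validate_proteome(tab)
  structure(list(proteins = tab), class = "pdz_proteome")
}

as_proteome_table <- function(proteome) {
  if (inherits(proteome, "pdz_proteome")) return(proteome$proteins)
  stopifnot(is.data.frame(proteome),
            all(c("protein_id", "sequence", "cds") %in% names(proteome)))
  proteome
}

validate_proteome <- function(tab) {
  stopifnot(nrow(tab) >= 1, !anyDuplicated(tab$protein_id))
  ok_alpha <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", tab$sequence)
  if (!all(ok_alpha))
    stop("non-standard residues in protein(s): ",
         paste(utils::head(tab$protein_id[!ok_alpha], 3), collapse = ", "))
  tr <- vapply(tab$cds, translate_nt, character(1), USE.NAMES = FALSE)
  bad <- tr != tab$sequence
  if (any(bad))
    stop("CDS translation disagrees with protein sequence for: ",
         paste(utils::head(tab$protein_id[bad], 3), collapse = ", "))
  invisible(tab)
}

#' Write sequencing reads to FASTQ (PHRED+33)
#'
#' @param reads Data.frame with `read_id`, `bases` and `qual` (PHRED+33
#'   symbol string) columns, as produced by [generate_screen()].
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$read_id
  q <- Biostrings::PhredQuality(reads$qual)
  qx <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(qx, path)
  invisible(path)
}

#' Read sequencing reads from FASTQ (PHRED+33)
#'
#' @param path FASTQ path.
#' @return Data.frame with `read_id`, `bases`, `qual`.
#' @export
read_reads_fastq <- function(path) {
  # readQualityScaledDNAStringSet warns when dropping the FASTQ metadata
  # columns it attaches itself; the drop is intentional here
  qx <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(
    read_id = names(qx),
    bases = as.character(qx),
    qual = as.character(Biostrings::quality(qx)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Read and write domain-annotation tables
#'
#' The TSV dialect shared by the generator and the catalog module has
#' columns `protein_id`, `start`, `end`, `source` (one row per source
#' record before merging; merged catalogs carry comma-separated source
#' labels and a `domain_id` column).
#'
#' @param path TSV path.
#' @return Data.frame of annotation records.
#' @export
read_annotation_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("protein_id", "start", "end", "source")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' @rdname read_annotation_tsv
#' @param annotations Data.frame of annotation records.
#' @export
write_annotation_tsv <- function(annotations, path) {
  write_tsv(annotations, path)
}
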