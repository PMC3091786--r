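#' Merge domain annotations from two sources
#'
#' Cross-references two annotation sources (e.g. a curated database and a
#' profile-based domain scan): annotations on the same protein whose
#' intervals overlap are merged into their coordinate union and carry both
#' source labels; source-unique annotations are retained unchanged. Merging
#' is transitive (a chain of pairwise-overlapping records collapses into one
#' interval).
#'
#' @param srcA,srcB Data.frames with `protein_id`, `start`, `end` and
#'   optionally `source` (defaults to `"srcA"`/`"srcB"`).
#' @param proteome Optional proteome used to validate coordinates.
#' @return Data.frame `protein_id`, `start`, `end`, `sources`
#'   (comma-separated labels), sorted by (protein_id, start).
#' @export
merge_domain_annotations <- function(srcA, srcB, proteome = NULL) {
  label <- function(df, default) {
    if (is.null(df) || nrow(df) == 0)
      return(data.frame(protein_id = character(), start = integer(),
                        end = integer(), source = character(),
                        stringsAsFactors = FALSE))
    if (is.null(df$source)) df$source <- default
    df[c("protein_id", "start", "end", "source")]
  }
  all <- rbind(label(srcA, "srcA"), label(srcB, "srcB"))
  if (nrow(all) == 0)
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), sources = character(),
                      stringsAsFactors = FALSE))
  if (any(all$start < 1) || any(all$end < all$start))
    stop("invalid annotation coordinates (start < 1 or end < start)")
  if (!is.null(proteome)) {
    tab <- as_proteome_table(proteome)
    len <- stats::setNames(nchar(tab$sequence), tab$protein_id)
    unknown <- !(all$protein_id %in% names(len))
    if (any(unknown))
      stop("annotation references unknown protein(s): ",
           paste(unique(all$protein_id[unknown]), collapse = ", "))
    over <- all$end > len[all$protein_id]
    if (any(over))
      stop("annotation exceeds protein length for: ",
           paste(unique(all$protein_id[over]), collapse = ", "))
  }
  out <- do.call(rbind, lapply(split(all, all$protein_id), function(df) {
    df <- df[order(df$start, df$end), , drop = FALSE]
    runs <- list()
    cur <- df[1, ]
    cur_src <- cur$source
    for (i in seq_len(nrow(df))[-1]) {
      if (df$start[i] <= cur$end) {  # strictly overlapping intervals merge
        cur$end <- max(cur$end, df$end[i])
        cur_src <- union(cur_src, df$source[i])
      } else {
        runs[[length(runs) + 1]] <- data.frame(
          protein_id = cur$protein_id, start = cur$start, end = cur$end,
          sources = paste(sort(cur_src), collapse = ","),
          stringsAsFactors = FALSE)
        cur <- df[i, ]
        cur_src <- cur$source
      }
    }
    runs[[length(runs) + 1]] <- data.frame(
      protein_id = cur$protein_id, start = cur$start, end = cur$end,
      sources = paste(sort(cur_src), collapse = ","),
      stringsAsFactors = FALSE)
    do.call(rbind, runs)
  }))
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign domain identifiers
#'
#' A protein carrying a single domain keeps its protein id as the domain
#' id; proteins with several domains get a `.n` extension numbered from the
#' start codon (i.e. ordered by start coordinate).
#'
#' @param annotations Merged, per-protein non-overlapping annotations.
#' @return The annotations with a `domain_id` column, sorted by
#'   (protein_id, start).
#' @export
assign_domain_ids <- function(annotations) {
  stopifnot(all(c("protein_id", "start", "end") %in% names(annotations)))
  key <- paste(annotations$protein_id, annotations$start, annotations$end)
  if (anyDuplicated(key)) stop("duplicate annotation coordinates")
  ann <- annotations[order(annotations$protein_id, annotations$start), ,
                     drop = FALSE]
  n_per <- stats::ave(seq_len(nrow(ann)), ann$protein_id, FUN = length)
  idx <- stats::ave(seq_len(nrow(ann)), ann$protein_id, FUN = seq_along)
  ann$domain_id <- ifelse(n_per == 1, ann$protein_id,
                          paste0(ann$protein_id, ".", idx))
  rownames(ann) <- NULL
  ann
}

#' Extend domain boundaries for cloning
#'
#' Each domain interval is extended on each side by a fixed amino-acid tail
#' (default 10) to preserve the structural integrity of the domain, clamped
#' to the protein ends, and mapped to CDS nucleotide coordinates
#' (`nt_start = 3*(ext_start-1)+1`, `nt_end = 3*ext_end`, 1-based
#' inclusive).
#'
#' @param annotations Catalog rows with `protein_id`, `start`, `end`,
#'   `domain_id`.
#' @param proteome Proteome providing sequences and CDS.
#' @param tail_aa Tail size in residues.
#' @return Data.frame of clone regions: `domain_id`, `protein_id`,
#'   `ext_start`, `ext_end`, `nt_start`, `nt_end`, `insert_nt`.
#' @export
extend_boundaries <- function(annotations, proteome, tail_aa = 10L) {
  tab <- as_proteome_table(proteome)
  idx <- match(annotations$protein_id, tab$protein_id)
  if (anyNA(idx)) stop("annotation references protein absent from proteome")
  L <- nchar(tab$sequence[idx])
  stopifnot(all(annotations$start >= 1), all(annotations$end <= L))
  ext_start <- pmax(1L, annotations$start - as.integer(tail_aa))
  ext_end <- pmin(L, annotations$end + as.integer(tail_aa))
  nt_start <- 3L * (ext_start - 1L) + 1L
  nt_end <- 3L * ext_end
  data.frame(
    domain_id = annotations$domain_id,
    protein_id = annotations$protein_id,
    ext_start = ext_start,
    ext_end = ext_end,
    nt_start = nt_start,
    nt_end = nt_end,
    insert_nt = substr(tab$cds[idx], nt_start, nt_end),
    stringsAsFactors = FALSE
  )
}

#' Design Gateway-tailed cloning primers for a clone region
#'
#' Forward primer = B1 recombination tail + the first `gs_len` nt of the
#' insert; reverse primer = B2 tail + the reverse complement of the insert
#' end with a stop codon appended (so the amplified fragment encodes the
#' extended domain followed by a stop before the B2 tail). Gene-specific
#' parts use a fixed length rather than melting-temperature optimisation.
#'
#' @param regions Clone regions from [extend_boundaries()].
#' @param b1_tail,b2_tail Recombination tail sequences.
#' @param stop_codon Stop codon inserted before the B2 tail.
#' @param gs_len Gene-specific primer length (nt).
#' @return Data.frame `domain_id`, `forward`, `reverse`,
#'   `gene_specific_len`.
#' @export
design_primers <- function(regions, b1_tail = ATTB1_TAIL,
                           b2_tail = ATTB2_TAIL, stop_codon = "TAA",
                           gs_len = 21L) {
  short <- nchar(regions$insert_nt) < gs_len
  if (any(short))
    stop("insert shorter than gene-specific primer length for: ",
         paste(regions$domain_id[short], collapse = ", "))
  fwd_gs <- substr(regions$insert_nt, 1, gs_len)
  templ <- paste0(regions$insert_nt, stop_codon)
  rev_gs <- vapply(templ, function(tp) {
    substr(revcomp(tp), 1, gs_len)
  }, character(1), USE.NAMES = FALSE)
  data.frame(
    domain_id = regions$domain_id,
    forward = paste0(b1_tail, fwd_gs),
    reverse = paste0(b2_tail, rev_gs),
    gene_specific_len = as.integer(gs_len),
    stringsAsFactors = FALSE
  )
}

#' Reconstruct the amplicon defined by a primer pair on a template
#'
#' Locates the forward gene-specific sequence and the (reverse-complemented)
#' reverse gene-specific sequence on `template + stop_codon` and returns the
#' delimited amplicon — for a correct pair this equals the insert followed
#' by the stop codon.
#'
#' @param primer One row of [design_primers()] output.
#' @param template The insert template (without stop codon).
#' @param b1_tail,b2_tail,stop_codon As used in primer design.
#' @return The amplified sequence, or `NA_character_` when either primer
#'   does not anneal.
#' @export
pcr_amplicon <- function(primer, template, b1_tail = ATTB1_TAIL,
                         b2_tail = ATTB2_TAIL, stop_codon = "TAA") {
  fwd_gs <- sub(paste0("^", b1_tail), "", primer$forward)
  rev_gs <- sub(paste0("^", b2_tail), "", primer$reverse)
  full <- paste0(template, stop_codon)
  f_at <- regexpr(fwd_gs, full, fixed = TRUE)
  r_at <- regexpr(revcomp(rev_gs), full, fixed = TRUE)
  if (f_at < 0 || r_at < 0) return(NA_character_)
  substr(full, f_at, r_at + nchar(rev_gs) - 1L)
}

#' Build the complete domain catalog
#'
#' Convenience wrapper chaining [merge_domain_annotations()],
#' [assign_domain_ids()], [extend_boundaries()] and [design_primers()].
#'
#' @param annotations Raw annotation table (columns `protein_id`, `start`,
#'   `end`, `source`) holding records from both sources.
#' @param proteome Proteome object or table.
#' @param tail_aa,b1_tail,b2_tail,stop_codon,gs_len See the individual
#'   steps.
#' @return List with `catalog` (annotations + domain ids), `regions`,
#'   `primers`.
#' @export
build_domain_catalog <- function(annotations, proteome, tail_aa = 10L,
                                 b1_tail = ATTB1_TAIL, b2_tail = ATTB2_TAIL,
                                 stop_codon = "TAA", gs_len = 21L) {
  srcs <- split(annotations, annotations$source)
  if (length(srcs) == 1) srcs[[2]] <- NULL
  merged <- merge_domain_annotations(srcs[[1]],
                                     if (length(srcs) > 1) srcs[[2]] else NULL,
                                     proteome = proteome)
  if (length(srcs) > 2) {
    for (k in 3:length(srcs)) {
      merged$source <- merged$sources
      merged <- merge_domain_annotations(merged, srcs[[k]], proteome = proteome)
    }
  }
  catalog <- assign_domain_ids(merged)
  regions <- extend_boundaries(catalog, proteome, tail_aa = tail_aa)
  primers <- design_primers(regions, b1_tail = b1_tail, b2_tail = b2_tail,
                            stop_codon = stop_codon, gs_len = gs_len)
  list(catalog = catalog, regions = regions, primers = primers)
}
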