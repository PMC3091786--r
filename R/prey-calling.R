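#' Colony phenotype filter
#'
#' A colony proceeds to sequencing only when it activated at least two of
#' the three Y2H reporter genes and its insert PCR gave a single band on
#' the gel.
#'
#' @param colonies Data.frame with logical columns `reporter1`,
#'   `reporter2`, `reporter3`, `single_band`.
#' @return Logical keep vector.
#' @export
colony_filter <- function(colonies) {
  need <- c("reporter1", "reporter2", "reporter3", "single_band")
  stopifnot(all(need %in% names(colonies)))
  n_rep <- colonies$reporter1 + colonies$reporter2 + colonies$reporter3
  n_rep >= 2 & colonies$single_band
}

# Smith-Waterman scoring used for all internal searches: match +1,
# mismatch -1, linear gap -2 per gapped position.
sw_params <- function(alphabet) {
  mat <- matrix(-1, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- 1
  mat
}
.sw_dna <- NULL
.sw_aa <- NULL
sw_matrix <- function(kind = c("dna", "aa")) {
  kind <- match.arg(kind)
  if (kind == "dna") {
    if (is.null(.sw_dna))
      utils::assignInMyNamespace(".sw_dna", sw_params(c("A", "C", "G", "T", "N")))
    .sw_dna
  } else {
    if (is.null(.sw_aa))
      utils::assignInMyNamespace(".sw_aa", sw_params(c(AA_STANDARD, "X", "*")))
    .sw_aa
  }
}

sw_align <- function(pattern, subject, kind, score_only = FALSE) {
  Biostrings::pairwiseAlignment(
    pattern, subject, type = "local",
    substitutionMatrix = sw_matrix(kind),
    gapOpening = 0, gapExtension = 2,
    scoreOnly = score_only)
}

#' Locate the activation-domain fusion junction on a read
#'
#' Local alignment of the vector's 3' AD suffix against the 5' region of
#' the read. The junction is the first read position downstream of the
#' (extrapolated) suffix end; because the suffix is stored in frame and
#' ends on a codon boundary of the AD open reading frame, the fusion
#' reading frame of the insert starts exactly at the junction. Reads in
#' which the suffix cannot be found above the score floor are
#' `Unassigned`.
#'
#' @param bases Read sequence (single string).
#' @param ad_suffix AD vector 3' suffix (in frame, length multiple of 3).
#' @param min_score Minimum local-alignment score (default: 60% of the
#'   suffix length, i.e. a mostly intact junction).
#' @return List: `junction` (read position, NA when unassigned), `score`.
#' @export
locate_ad_junction <- function(bases, ad_suffix = GAL4_AD_SUFFIX,
                               min_score = ceiling(0.6 * nchar(ad_suffix))) {
  stopifnot(length(bases) == 1, nchar(ad_suffix) %% 3 == 0)
  head_len <- min(nchar(bases), 2L * nchar(ad_suffix))
  if (head_len < 1) return(list(junction = NA_integer_, score = -Inf))
  aln <- sw_align(ad_suffix, substr(bases, 1, head_len), "dna")
  sc <- Biostrings::score(aln)
  if (sc < min_score) return(list(junction = NA_integer_, score = sc))
  pat_end <- Biostrings::end(Biostrings::pattern(aln))
  sub_end <- Biostrings::end(Biostrings::subject(aln))
  junction <- sub_end + (nchar(ad_suffix) - pat_end) + 1L
  list(junction = as.integer(junction), score = sc)
}

# Generic unique-best-hit local search of `query` against a named database.
# Exact-substring fast path (score = query length under +1 match scoring),
# Smith-Waterman fallback otherwise; forward strand only.
search_db <- function(query, db, kind, min_score) {
  stopifnot(length(db) >= 1, !is.null(names(db)))
  if (nchar(query) == 0)
    return(list(status = "none", hit = NA_character_, hits = character(),
                score = 0, sub_start = NA_integer_, sub_end = NA_integer_))
  set <- if (kind == "dna") Biostrings::DNAStringSet(db) else
    Biostrings::AAStringSet(db)
  qpat <- if (kind == "dna") Biostrings::DNAString(query) else
    Biostrings::AAString(query)
  exact <- Biostrings::vmatchPattern(qpat, set)
  n_hit <- S4Vectors::elementNROWS(exact)
  if (sum(n_hit > 0) >= 1 && nchar(query) >= min_score) {
    hits <- which(n_hit > 0)
    if (length(hits) > 1)
      return(list(status = "ambiguous", hit = NA_character_,
                  hits = names(db)[hits], score = nchar(query),
                  sub_start = NA_integer_, sub_end = NA_integer_))
    m <- exact[[hits]][1]
    return(list(status = "unique", hit = names(db)[hits],
                hits = names(db)[hits], score = nchar(query),
                sub_start = Biostrings::start(m),
                sub_end = Biostrings::end(m)))
  }
  # seed-and-extend: exact seed words select candidate subjects, then
  # Smith-Waterman scores only the candidates. A subject sharing no seed
  # word cannot reach the score floor on these desk-scale databases, so a
  # seed miss is reported as "none".
  seed_w <- if (kind == "dna") 30L else 10L
  cand <- seq_along(db)
  if (nchar(query) >= seed_w) {
    starts <- unique(pmin(seq(1L, nchar(query), by = max(seed_w, 50L)),
                          nchar(query) - seed_w + 1L))
    hit_any <- rep(FALSE, length(db))
    for (s in starts) {
      seed <- substr(query, s, s + seed_w - 1L)
      spat <- if (kind == "dna") Biostrings::DNAString(seed) else
        Biostrings::AAString(seed)
      hit_any <- hit_any | Biostrings::vcountPattern(spat, set) > 0
    }
    cand <- which(hit_any)
    if (length(cand) == 0)
      return(list(status = "none", hit = NA_character_, hits = character(),
                  score = 0, sub_start = NA_integer_, sub_end = NA_integer_))
  }
  scores <- vapply(cand, function(i) {
    sw_align(query, db[[i]], kind, score_only = TRUE)
  }, numeric(1))
  best <- max(scores)
  if (best < min_score)
    return(list(status = "none", hit = NA_character_, hits = character(),
                score = best, sub_start = NA_integer_, sub_end = NA_integer_))
  top <- cand[which(scores == best)]
  if (length(top) > 1)
    return(list(status = "ambiguous", hit = NA_character_,
                hits = names(db)[top], score = best,
                sub_start = NA_integer_, sub_end = NA_integer_))
  aln <- sw_align(query, db[[top]], kind)
  list(status = "unique", hit = names(db)[top], hits = names(db)[top],
       score = best,
       sub_start = Biostrings::start(Biostrings::subject(aln)),
       sub_end = Biostrings::end(Biostrings::subject(aln)))
}

#' Identify a prey insert against the CDS database
#'
#' Forward-strand local-alignment search of the insert nucleotide sequence
#' against all coding sequences; a call requires a unique best hit at or
#' above the score floor. Tied best hits are reported `ambiguous` and
#' discarded downstream; scores below the floor give `none`.
#'
#' @param insert_nt Insert nucleotide sequence (read minus vector).
#' @param cds_db Named character vector of coding sequences.
#' @param min_score Score floor (match +1 / mismatch -1 / gap -2 scoring).
#' @return List: `status` (`unique`/`ambiguous`/`none`), `hit` (protein
#'   id), `score`, `sub_start`, `sub_end` (CDS nucleotide coordinates of
#'   the aligned region).
#' @export
identify_nt <- function(insert_nt, cds_db, min_score = 60L) {
  if (length(cds_db) == 0) stop("empty CDS database")
  search_db(insert_nt, cds_db, "dna", min_score)
}

#' Identify a translated insert against the proteome
#'
#' @param peptide Amino-acid query (the fusion-frame translation).
#' @param protein_db Named character vector of protein sequences.
#' @param min_score Score floor.
#' @return As [identify_nt()], with coordinates in protein residues.
#' @export
identify_aa <- function(peptide, protein_db, min_score = 20L) {
  if (length(protein_db) == 0) stop("empty protein database")
  search_db(peptide, protein_db, "aa", min_score)
}

#' Call the prey identity and reading frame of a read
#'
#' Implements the frame-agreement rule: the insert (read downstream of the
#' AD junction) is identified at the nucleotide level against the CDS
#' database; its fusion-frame translation (truncated at the first stop
#' codon) is searched against the proteome; the read is `InFrame` only
#' when both searches give unique best hits on the same gene, otherwise
#' `OutOfFrame`. Reads without a locatable junction are `Unassigned`.
#' Agreement is evaluated at gene level, so splice forms sharing a gene do
#' not spuriously fail the check.
#'
#' @param bases Read sequence.
#' @param junction AD junction position from [locate_ad_junction()] (NA
#'   for unassigned reads).
#' @param cds_db Named character vector of CDS.
#' @param protein_db Named character vector of protein sequences.
#' @param gene_of Named character vector mapping protein id to gene id
#'   (defaults to identity).
#' @param nt_min_score,aa_min_score Score floors of the two searches.
#' @return One-row data.frame: `protein_id`, `frame_status`
#'   (`InFrame`/`OutOfFrame`/`Unassigned`), `insert_aa_start`,
#'   `insert_aa_end` (prey protein coordinates, NA unless InFrame),
#'   `nt_score`, `aa_score`.
#' @export
call_frame <- function(bases, junction, cds_db, protein_db,
                       gene_of = NULL, nt_min_score = 60L,
                       aa_min_score = 20L) {
  if (is.null(gene_of))
    gene_of <- stats::setNames(names(protein_db), names(protein_db))
  no_call <- function(status, prot = "none", nt_s = NA_real_, aa_s = NA_real_)
    data.frame(protein_id = prot, frame_status = status,
               insert_aa_start = NA_integer_, insert_aa_end = NA_integer_,
               nt_score = nt_s, aa_score = aa_s, stringsAsFactors = FALSE)
  if (is.na(junction) || junction > nchar(bases))
    return(no_call("Unassigned"))
  insert <- substr(bases, junction, nchar(bases))
  nt <- identify_nt(insert, cds_db, nt_min_score)
  if (nt$status == "ambiguous") return(no_call("OutOfFrame", "ambiguous",
                                               nt_s = nt$score))
  if (nt$status == "none") return(no_call("OutOfFrame", "none",
                                          nt_s = nt$score))
  peptide <- translate_nt(insert)
  aa <- identify_aa(peptide, protein_db, aa_min_score)
  # tied protein-level hits are tolerated when they are splice forms of one
  # gene: agreement is evaluated at gene level
  aa_genes <- unique(unname(gene_of[aa$hits]))
  agree <- aa$status != "none" && length(aa_genes) == 1 &&
    identical(aa_genes, unname(gene_of[nt$hit]))
  if (!agree)
    return(no_call("OutOfFrame", nt$hit, nt_s = nt$score,
                   aa_s = aa$score))
  prot_len <- nchar(protein_db[nt$hit])
  aa_start <- (nt$sub_start - 1L) %/% 3L + 1L
  aa_end <- min(prot_len, (nt$sub_end + 2L) %/% 3L)
  data.frame(protein_id = nt$hit, frame_status = "InFrame",
             insert_aa_start = as.integer(aa_start),
             insert_aa_end = as.integer(aa_end),
             nt_score = nt$score, aa_score = aa$score,
             stringsAsFactors = FALSE)
}

#' Run colony filtering, QC, junction location and frame calling on a
#' batch of reads
#'
#' @param reads Data.frame `read_id`, `bases`, `qual`.
#' @param colonies Data.frame keyed by `read_id` with reporter flags,
#'   `single_band`, `bait_domain_id`, `library`.
#' @param proteome A `pdz_proteome` or proteome table.
#' @param ad_suffix,window,threshold,min_fraction,junction_min_score,nt_min_score,aa_min_score
#'   Stage parameters; see the individual operations.
#' @return Data.frame of prey calls, one row per colony-filtered read:
#'   QC columns plus junction and [call_frame()] columns, `bait_domain_id`
#'   and `library` carried through.
#' @export
call_preys <- function(reads, colonies, proteome,
                       ad_suffix = GAL4_AD_SUFFIX, window = 10L,
                       threshold = 20, min_fraction = 0.15,
                       junction_min_score = ceiling(0.6 * nchar(ad_suffix)),
                       nt_min_score = 60L, aa_min_score = 20L) {
  tab <- as_proteome_table(proteome)
  cds_db <- stats::setNames(tab$cds, tab$protein_id)
  protein_db <- stats::setNames(tab$sequence, tab$protein_id)
  gene_of <- stats::setNames(tab$gene_id %||% tab$protein_id,
                             tab$protein_id)
  keep_colony <- colony_filter(colonies)
  kept <- merge(reads, colonies[keep_colony,
                                c("read_id", "bait_domain_id", "library")],
                by = "read_id")
  if (nrow(kept) == 0) return(empty_prey_calls())
  qc <- qc_filter(kept, window, threshold, min_fraction)
  kept <- kept[qc$kept, , drop = FALSE]
  qc <- qc[qc$kept, , drop = FALSE]
  if (nrow(kept) == 0) return(empty_prey_calls())
  calls <- do.call(rbind, lapply(seq_len(nrow(kept)), function(i) {
    j <- locate_ad_junction(kept$bases[i], ad_suffix, junction_min_score)
    cf <- call_frame(kept$bases[i], j$junction, cds_db, protein_db,
                     gene_of, nt_min_score, aa_min_score)
    cbind(data.frame(read_id = kept$read_id[i],
                     bait_domain_id = kept$bait_domain_id[i],
                     library = kept$library[i],
                     pass_fraction = qc$pass_fraction[i],
                     junction = j$junction, junction_score = j$score,
                     stringsAsFactors = FALSE),
          cf)
  }))
  rownames(calls) <- NULL
  calls
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_prey_calls <- function() {
  data.frame(read_id = character(), bait_domain_id = character(),
             library = character(), pass_fraction = numeric(),
             junction = integer(), junction_score = numeric(),
             protein_id = character(), frame_status = character(),
             insert_aa_start = integer(), insert_aa_end = integer(),
             nt_score = numeric(), aa_score = numeric(),
             stringsAsFactors = FALSE)
}

#' Aggregate in-frame prey calls into interactions
#'
#' Groups `InFrame` calls by (bait domain, prey protein, library); the
#' clone count `n_hits` is the number of independent colonies supporting
#' the pair. Interactions that failed retesting are discarded.
#'
#' @param prey_calls Output of [call_preys()] (only `InFrame` rows are
#'   used).
#' @param retest Optional data.frame `bait_domain_id`, `prey_protein_id`,
#'   `retest_confirmed`; pairs absent from the table are treated as
#'   confirmed (`default_retest`).
#' @param default_retest Default retest outcome for pairs without a
#'   recorded retest.
#' @return Data.frame `bait_domain_id`, `prey_protein_id`, `library`,
#'   `n_hits`, `retest_confirmed`, with failed pairs removed, plus MIR
#'   columns `mir_start`, `mir_end` from [compute_mir()].
#' @export
aggregate_interactions <- function(prey_calls, retest = NULL,
                                   default_retest = TRUE) {
  inframe <- prey_calls[prey_calls$frame_status == "InFrame", , drop = FALSE]
  if (nrow(inframe) == 0)
    return(data.frame(bait_domain_id = character(),
                      prey_protein_id = character(), library = character(),
                      n_hits = integer(), retest_confirmed = logical(),
                      mir_start = integer(), mir_end = integer(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(
    list(n_hits = inframe$read_id),
    by = list(bait_domain_id = inframe$bait_domain_id,
              prey_protein_id = inframe$protein_id,
              library = inframe$library),
    FUN = length)
  agg$retest_confirmed <- default_retest
  if (!is.null(retest)) {
    idx <- match(paste(agg$bait_domain_id, agg$prey_protein_id),
                 paste(retest$bait_domain_id, retest$prey_protein_id))
    agg$retest_confirmed[!is.na(idx)] <-
      retest$retest_confirmed[idx[!is.na(idx)]]
  }
  agg <- agg[agg$retest_confirmed, , drop = FALSE]
  spans <- data.frame(prey_protein_id = inframe$protein_id,
                      aa_start = inframe$insert_aa_start,
                      aa_end = inframe$insert_aa_end,
                      stringsAsFactors = FALSE)
  mir <- compute_mir(spans)
  idx <- match(agg$prey_protein_id, mir$prey_protein_id)
  agg$mir_start <- mir$mir_start[idx]
  agg$mir_end <- mir$mir_end[idx]
  agg <- agg[order(agg$bait_domain_id, agg$prey_protein_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Minimal interacting region per prey
#'
#' The MIR is the smallest clone fragment (in residues) recovered among
#' all clones of all interactions involving a prey; when a prey appears in
#' several bait pairs the global minimum over all pairs is used for all of
#' them. Ties are broken towards the smallest start coordinate.
#'
#' @param spans Data.frame `prey_protein_id`, `aa_start`, `aa_end`, one
#'   row per in-frame clone.
#' @return Data.frame `prey_protein_id`, `mir_start`, `mir_end`.
#' @export
compute_mir <- function(spans) {
  stopifnot(nrow(spans) >= 1)
  spans <- spans[!is.na(spans$aa_start), , drop = FALSE]
  out <- do.call(rbind, lapply(split(spans, spans$prey_protein_id),
                               function(df) {
    len <- df$aa_end - df$aa_start + 1L
    best <- which(len == min(len))
    best <- best[order(df$aa_start[best])][1]
    data.frame(prey_protein_id = df$prey_protein_id[1],
               mir_start = df$aa_start[best], mir_end = df$aa_end[best],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
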