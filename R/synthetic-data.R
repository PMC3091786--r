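#' Generate a synthetic proteome with controlled C-terminal composition
#'
#' Builds a toy proteome whose C-terminal consensus-class composition
#' follows `class_probs` exactly in expectation: each entry draws its class
#' (1/2/3/none) and its terminal tripeptide is sampled from the matching
#' motif set. Coding sequences are obtained by back-translation with
#' uniformly sampled synonymous codons and a terminal stop codon, so
#' `translate(cds) == sequence` for every entry. A fraction of genes carry
#' a second splice form sharing the gene id but differing in its C-terminal
#' residues (classes drawn independently), which gives the conservative
#' splice-form classification rule real work.
#'
#' @param n_proteins Number of primary protein entries (>= 10).
#' @param class_probs Probabilities of classes 1, 2, 3 and none; must sum
#'   to 1.
#' @param splice_form_rate Probability that a gene has a second splice
#'   form.
#' @param mean_protein_len Mean protein length (residues); lengths are
#'   gamma-distributed with a 120-residue floor so that planted domains
#'   always fit.
#' @param cterm_confirmed_rate Probability that an entry's C-terminus is
#'   flagged experimentally confirmed.
#' @param seed Integer seed; identical seed and parameters give
#'   byte-identical output.
#' @return A `pdz_proteome` object: `$proteins` is a data.frame with
#'   `protein_id`, `gene_id`, `is_splice_form`, `cterm_confirmed`,
#'   `class_true`, `sequence`, `cds`.
#' @export
generate_proteome <- function(n_proteins = 200,
                              class_probs = c(0.08, 0.18, 0.05, 0.69),
                              splice_form_rate = 0.1,
                              mean_protein_len = 400,
                              cterm_confirmed_rate = 0.7,
                              seed = 1L) {
  stopifnot(n_proteins >= 10, mean_protein_len >= 150)
  if (length(class_probs) != 4 || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-9)
    stop("class_probs must be 4 non-negative probabilities summing to 1")
  set.seed(as.integer(seed))
  n_forms <- 1L + stats::rbinom(n_proteins, 1L, splice_form_rate)
  gene_id <- sprintf("g%05d", seq_len(n_proteins))
  lens <- pmax(120L, as.integer(round(stats::rgamma(
    n_proteins, shape = 4, scale = mean_protein_len / 4))))
  cls1 <- sample(c("1", "2", "3", "none"), n_proteins, replace = TRUE,
                 prob = class_probs)
  body <- vapply(lens, function(L) {
    paste(sample(AA_STANDARD, L - 3L, replace = TRUE), collapse = "")
  }, character(1))
  last3 <- vapply(cls1, sample_terminal_tripeptide, character(1),
                  USE.NAMES = FALSE)
  primary <- paste0(body, last3)
  # secondary splice forms share the gene body but differ over the final
  # ~30 residues (independently drawn class), so conservative splice-form
  # classification has real work while nucleotide identity stays resolvable
  has2 <- n_forms == 2L
  cls2 <- sample(c("1", "2", "3", "none"), sum(has2), replace = TRUE,
                 prob = class_probs)
  alt_tail <- vapply(seq_len(sum(has2)), function(i) {
    paste0(paste(sample(AA_STANDARD, 27, replace = TRUE), collapse = ""),
           sample_terminal_tripeptide(cls2[i]))
  }, character(1))
  secondary <- paste0(substr(primary[has2], 1, nchar(primary[has2]) - 30L),
                      alt_tail)
  gene_of <- c(gene_id, gene_id[has2])
  protein_id <- c(ifelse(has2, paste0(gene_id, "a"), gene_id),
                  paste0(gene_id[has2], "b"))
  seqs <- c(primary, secondary)
  cls <- c(cls1, cls2)
  is_alt <- c(rep(FALSE, n_proteins), rep(TRUE, sum(has2)))
  ord <- order(gene_of, is_alt)
  gene_of <- gene_of[ord]; protein_id <- protein_id[ord]
  seqs <- seqs[ord]; cls <- cls[ord]; is_alt <- is_alt[ord]
  n <- length(seqs)
  stops <- sample(c("TAA", "TAG", "TGA"), n, replace = TRUE)
  cds <- back_translate(seqs, stops)
  tab <- data.frame(
    protein_id = protein_id,
    gene_id = gene_of,
    is_splice_form = is_alt,
    cterm_confirmed = stats::runif(n) < cterm_confirmed_rate,
    class_true = cls,
    sequence = seqs,
    cds = cds,
    stringsAsFactors = FALSE
  )
  structure(list(proteins = tab,
                 params = list(n_proteins = n_proteins,
                               class_probs = class_probs,
                               splice_form_rate = splice_form_rate,
                               mean_protein_len = mean_protein_len,
                               seed = as.integer(seed))),
            class = "pdz_proteome")
}

# Draw a terminal tripeptide whose consensus class is exactly `cls`.
# Position -1 is unconstrained; "none" uses rejection sampling over random
# tripeptides (acceptance probability ~0.7).
sample_terminal_tripeptide <- function(cls) {
  motifs <- consensus_motifs()
  if (cls %in% names(motifs)) {
    m <- motifs[[cls]]
    return(paste0(sample(m$m2, 1), sample(AA_STANDARD, 1), sample(m$p0, 1)))
  }
  repeat {
    tri <- paste(sample(AA_STANDARD, 3, replace = TRUE), collapse = "")
    if (classify_cterm(tri) == "none") return(tri)
  }
}

#' Plant bait domains into a synthetic proteome
#'
#' Selects proteins to carry one or more non-overlapping ~`domain_len`
#' domains and emits annotation records from two pseudo-sources (`srcA`,
#' `srcB`) whose boundaries disagree by up to `jitter` residues while still
#' overlapping, exercising the cross-source merge.
#'
#' @param proteome A `pdz_proteome`.
#' @param n_domain_proteins Number of distinct domain-carrying proteins.
#' @param total_domains Total number of domains; multiplicities are
#'   Poisson-spread over the carriers (capped by what fits in each protein)
#'   and adjusted to force this exact total.
#' @param domain_len Domain length in residues.
#' @param jitter Maximum per-boundary disagreement between the two sources.
#' @param seed Integer seed.
#' @return List with `annotations` (the two-source record table:
#'   `protein_id`, `start`, `end`, `source`) and `truth` (one row per
#'   planted domain: `protein_id`, `start`, `end`).
#' @export
plant_bait_domains <- function(proteome, n_domain_proteins = 62,
                               total_domains = 93, domain_len = 80L,
                               jitter = 3L, seed = 1L) {
  tab <- as_proteome_table(proteome)
  primary <- tab[!tab$is_splice_form, , drop = FALSE]
  if (n_domain_proteins > nrow(primary))
    stop("n_domain_proteins exceeds the number of (primary) proteins")
  stopifnot(total_domains >= n_domain_proteins)
  set.seed(as.integer(seed))
  # a domain plus an inter-domain spacer wide enough that source-boundary
  # jitter can never make neighbouring domains overlap
  slot <- domain_len + 2L * jitter + 10L
  capacity <- nchar(primary$sequence) %/% slot
  eligible <- primary[capacity >= 1, , drop = FALSE]
  capacity <- capacity[capacity >= 1]
  if (nrow(eligible) < n_domain_proteins)
    stop("not enough proteins long enough to host a domain")
  pick <- sample(nrow(eligible), n_domain_proteins)
  # swap in higher-capacity proteins when the drawn carriers cannot host the
  # requested total
  while (sum(capacity[pick]) < total_domains) {
    rest <- setdiff(seq_len(nrow(eligible)), pick)
    worst <- pick[which.min(capacity[pick])]
    best <- if (length(rest)) rest[which.max(capacity[rest])] else worst
    if (capacity[best] <= capacity[worst])
      stop("proteins too short for requested domain count")
    pick[pick == worst] <- best
  }
  carriers <- eligible[pick, , drop = FALSE]
  cap <- capacity[pick]
  mult <- pmin(cap, 1L + stats::rpois(n_domain_proteins,
                                      total_domains / n_domain_proteins - 1))
  # force the exact total by raising/lowering multiplicities where possible
  delta <- total_domains - sum(mult)
  while (delta != 0) {
    if (delta > 0) {
      room <- which(mult < cap)
      if (length(room) == 0) stop("proteins too short for requested domain count")
      i <- room[sample.int(length(room), 1)]
      mult[i] <- mult[i] + 1L
      delta <- delta - 1L
    } else {
      room <- which(mult > 1L)
      i <- room[sample.int(length(room), 1)]
      mult[i] <- mult[i] - 1L
      delta <- delta + 1L
    }
  }
  truth <- do.call(rbind, lapply(seq_len(nrow(carriers)), function(i) {
    L <- nchar(carriers$sequence[i])
    k <- mult[i]
    # place k domains in k equal-width bays, random offset inside each bay
    bay <- L %/% k
    start <- vapply(seq_len(k), function(j) {
      lo <- (j - 1L) * bay + 1L + jitter + 1L
      hi <- j * bay - domain_len + 1L - (jitter + 1L)
      as.integer(lo + floor(stats::runif(1) * max(1L, hi - lo + 1L)))
    }, integer(1))
    data.frame(protein_id = carriers$protein_id[i], start = start,
               end = start + domain_len - 1L, stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  jit <- function(x, lo, hi) pmin(hi, pmax(lo, x + sample(-jitter:jitter,
                                                          length(x), TRUE)))
  lenv <- nchar(tab$sequence)[match(truth$protein_id, tab$protein_id)]
  srcA <- data.frame(protein_id = truth$protein_id,
                     start = truth$start, end = truth$end,
                     source = "srcA", stringsAsFactors = FALSE)
  srcB <- data.frame(protein_id = truth$protein_id,
                     start = jit(truth$start, 1L, pmax(1L, truth$start)),
                     end = jit(truth$end, truth$end, lenv),
                     source = "srcB", stringsAsFactors = FALSE)
  # srcB jitter only widens intervals, so merged unions stay non-overlapping
  list(annotations = rbind(srcA, srcB), truth = truth)
}

#' Define the ground truth of a simulated Y2H screen
#'
#' Samples the true bait-prey edge set, per-edge clone counts, decoy
#' colonies and per-read noise assignments. In cDNA mode prey sampling
#' weights combine a log-normal abundance skew (a non-normalized library)
#' with a `consensus_bias` multiplier for consensus-class preys; ORFeome
#' mode (a normalized library) samples preys uniformly.
#'
#' @param proteome A `pdz_proteome`.
#' @param catalog Domain catalog (rows with `domain_id`, `protein_id`).
#' @param library_kind `"cDNA"` or `"ORFeome"`.
#' @param n_edges Number of true bait-prey edges.
#' @param mean_clones Mean number of independent colonies per edge
#'   (1 + Poisson(mean_clones - 1)).
#' @param consensus_bias Sampling-weight multiplier (>= 1) for
#'   consensus-class preys, cDNA mode only.
#' @param decoy_rate Decoy (spurious) colonies per true edge; decoy pairs
#'   fail retesting.
#' @param read_error_params List of probabilities: `frame_shift_rate`,
#'   `low_quality_rate`, `chimera_rate`, `reporter_fail_rate`,
#'   `single_band_fail_rate`.
#' @param seed Integer seed.
#' @return A `pdz_screen_truth` object with `$edges`
#'   (bait_domain_id, prey_protein_id, n_clones, is_decoy), `$params`,
#'   `$library_kind`, `$seed`.
#' @export
make_screen_truth <- function(proteome, catalog,
                              library_kind = c("cDNA", "ORFeome"),
                              n_edges = 60, mean_clones = 2,
                              consensus_bias = 2.2, decoy_rate = 0.1,
                              read_error_params = list(), seed = 1L) {
  library_kind <- match.arg(library_kind)
  stopifnot(consensus_bias >= 1)
  errs <- utils::modifyList(
    list(frame_shift_rate = 0.05, low_quality_rate = 0.05,
         chimera_rate = 0.03, reporter_fail_rate = 0.05,
         single_band_fail_rate = 0.05),
    read_error_params)
  stopifnot(all(unlist(errs) >= 0), all(unlist(errs) <= 1))
  tab <- as_proteome_table(proteome)
  set.seed(as.integer(seed))
  # preys: any protein long enough to yield an informative insert
  prey_pool <- tab[nchar(tab$sequence) >= 60, , drop = FALSE]
  w <- rep(1, nrow(prey_pool))
  if (library_kind == "cDNA") {
    w <- stats::rlnorm(nrow(prey_pool), sdlog = 1)
    cons <- classify_cterm(prey_pool$sequence) != "none"
    w[cons] <- w[cons] * consensus_bias
  }
  n_pairs <- n_edges + ceiling(decoy_rate * n_edges)
  baits <- sample(catalog$domain_id, n_pairs, replace = TRUE)
  preys <- sample(prey_pool$protein_id, n_pairs, replace = TRUE, prob = w)
  keep <- !duplicated(paste(baits, preys))
  baits <- baits[keep]; preys <- preys[keep]
  n_true <- min(n_edges, length(baits))
  edges <- data.frame(
    bait_domain_id = baits,
    prey_protein_id = preys,
    n_clones = 1L + stats::rpois(length(baits), max(0, mean_clones - 1)),
    is_decoy = seq_along(baits) > n_true,
    stringsAsFactors = FALSE
  )
  edges$n_clones[edges$is_decoy] <- 1L
  structure(list(edges = edges, params = c(list(
    n_edges = n_edges, mean_clones = mean_clones,
    consensus_bias = consensus_bias, decoy_rate = decoy_rate),
    errs), library_kind = library_kind, seed = as.integer(seed)),
    class = "pdz_screen_truth")
}

#' Simulate Y2H screen colonies and sequencing reads
#'
#' For each clone of each (true or decoy) edge, emits one single-pass read
#' of the prey insert downstream of the activation-domain vector: read =
#' AD 3' suffix + insert, truncated at a fixed read length. cDNA-mode
#' inserts are 5'-truncated at a random codon-aligned position and keep the
#' native 3' end (stop codon included); ORFeome-mode inserts are the full
#' ORF with the stop removed and the fixed B2-tail codons appended. Noise
#' processes, applied per read at the rates recorded in the truth object:
#' frame-shifted truncation (+1/+2), uniformly low base qualities (fails
#' QC), and chimeric reads (a short in-frame fragment of another protein
#' spliced in front of a frame-broken insert, so nucleotide identity and
#' fusion-frame translation disagree). Reporter-gene triples and gel
#' single-band flags are emitted per colony with configurable false rates.
#'
#' @param proteome A `pdz_proteome`.
#' @param truth A `pdz_screen_truth` from [make_screen_truth()].
#' @param ad_suffix In-frame 3' suffix of the AD vector ORF (length must be
#'   a multiple of 3).
#' @param read_len Fixed single-pass read length (nt); reads are truncated
#'   at the insert end if shorter.
#' @param base_quality,low_quality PHRED scores of normal and failed
#'   traces.
#' @param seed Integer seed (defaults to the truth object's seed + 1).
#' @return List: `reads` (read_id, bases, qual), `colonies` (read_id,
#'   bait_domain_id, library, reporter1..3, single_band), `read_truth`
#'   (read_id, prey_protein_id, is_decoy, frame_shift, low_quality,
#'   chimera, insert_aa_start, insert_aa_end), and `retest`
#'   (bait_domain_id, prey_protein_id, retest_confirmed).
#' @export
generate_screen <- function(proteome, truth, ad_suffix = GAL4_AD_SUFFIX,
                            read_len = 700L, base_quality = 40L,
                            low_quality = 8L, seed = NULL) {
  stopifnot(inherits(truth, "pdz_screen_truth"))
  if (nchar(ad_suffix) %% 3 != 0)
    stop("ad_suffix must be stored in frame (length a multiple of 3)")
  tab <- as_proteome_table(proteome)
  if (is.null(seed)) seed <- truth$seed + 1L
  set.seed(as.integer(seed))
  p <- truth$params
  edges <- truth$edges
  if (nrow(edges) == 0) {
    empty <- data.frame(read_id = character(), stringsAsFactors = FALSE)
    return(list(reads = cbind(empty, bases = character(), qual = character()),
                colonies = empty, read_truth = empty,
                retest = data.frame(bait_domain_id = character(),
                                    prey_protein_id = character(),
                                    retest_confirmed = logical())))
  }
  clone_edge <- rep(seq_len(nrow(edges)), edges$n_clones)
  n_reads <- length(clone_edge)
  read_id <- sprintf("r%05d", seq_len(n_reads))
  frame_shift <- stats::runif(n_reads) < p$frame_shift_rate
  low_q <- stats::runif(n_reads) < p$low_quality_rate
  chimera <- stats::runif(n_reads) < p$chimera_rate
  prey_idx <- match(edges$prey_protein_id[clone_edge], tab$protein_id)
  bases <- character(n_reads)
  aa_start <- integer(n_reads); aa_end <- integer(n_reads)
  for (i in seq_len(n_reads)) {
    cds <- tab$cds[prey_idx[i]]
    L_aa <- (nchar(cds) - 3L) %/% 3L
    if (truth$library_kind == "ORFeome") {
      insert <- paste0(substr(cds, 1, nchar(cds) - 3L), B2_TAIL_NT)
      aa_start[i] <- 1L; aa_end[i] <- L_aa
    } else {
      # 5'-truncate at a codon boundary, keep >= 20 aa of native sequence
      t_aa <- sample.int(max(1L, L_aa - 20L), 1L) - 1L
      insert <- substr(cds, 3L * t_aa + 1L, nchar(cds))
      aa_start[i] <- t_aa + 1L; aa_end[i] <- L_aa
    }
    if (frame_shift[i]) {
      insert <- substr(insert, 1L + sample(1:2, 1), nchar(insert))
    }
    if (chimera[i]) {
      # short in-frame 5' fragment of another protein, then the (frame-
      # broken) insert: nucleotide identity and translation must disagree
      other <- sample(setdiff(seq_len(nrow(tab)), prey_idx[i]), 1)
      frag <- substr(tab$cds[other], 1, 90)
      insert <- paste0(frag, substr(insert, 2, nchar(insert)))
    }
    bases[i] <- substr(paste0(ad_suffix, insert), 1, read_len)
  }
  qual <- vapply(seq_len(n_reads), function(i) {
    q <- if (low_q[i]) low_quality else base_quality
    phred_to_chars(rep(q, nchar(bases[i])))
  }, character(1))
  rep_fail <- matrix(stats::runif(3 * n_reads) < p$reporter_fail_rate, ncol = 3)
  colonies <- data.frame(
    read_id = read_id,
    bait_domain_id = edges$bait_domain_id[clone_edge],
    library = truth$library_kind,
    reporter1 = !rep_fail[, 1],
    reporter2 = !rep_fail[, 2],
    reporter3 = !rep_fail[, 3],
    single_band = !(stats::runif(n_reads) < p$single_band_fail_rate),
    stringsAsFactors = FALSE
  )
  read_truth <- data.frame(
    read_id = read_id,
    prey_protein_id = edges$prey_protein_id[clone_edge],
    is_decoy = edges$is_decoy[clone_edge],
    frame_shift = frame_shift,
    low_quality = low_q,
    chimera = chimera,
    insert_aa_start = aa_start,
    insert_aa_end = aa_end,
    stringsAsFactors = FALSE
  )
  retest <- data.frame(
    bait_domain_id = edges$bait_domain_id,
    prey_protein_id = edges$prey_protein_id,
    retest_confirmed = !edges$is_decoy,
    stringsAsFactors = FALSE
  )
  list(reads = data.frame(read_id = read_id, bases = bases, qual = qual,
                          stringsAsFactors = FALSE),
       colonies = colonies, read_truth = read_truth, retest = retest)
}

#' Serialize screen-truth parameters to JSON
#'
#' @param truth A `pdz_screen_truth`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_screen_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(seed = truth$seed, library_kind = truth$library_kind,
         params = truth$params, edges = truth$edges),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
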