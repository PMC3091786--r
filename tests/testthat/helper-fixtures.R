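# Shared fixtures and independent oracles, built in code at test time.

# fixed codon per residue, for hand-built CDS in exact tests
.codon_of <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTC", G = "GGT",
  H = "CAC", I = "ATT", K = "AAA", L = "CTT", M = "ATG", N = "AAC",
  P = "CCA", Q = "CAA", R = "CGT", S = "TCT", T = "ACA", V = "GTT",
  W = "TGG", Y = "TAC")

aa_to_cds <- function(aa, stop_codon = "TAA") {
  paste0(paste(.codon_of[strsplit(aa, "")[[1]]], collapse = ""), stop_codon)
}

# tiny hand-built proteome: deterministic sequences with known termini
manual_proteome <- function() {
  set.seed(424242)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mk <- function(n, tail) paste0(
    paste(sample(aa20, n - nchar(tail), replace = TRUE), collapse = ""), tail)
  seqs <- c(
    p1 = mk(200, "ETSV"),   # class 1 terminus
    p2 = mk(150, "IAAELR"), # non-consensus
    p3 = mk(180, "KEAV"),   # class 3
    p4 = mk(120, "GVAV")    # class 2
  )
  tab <- data.frame(
    protein_id = names(seqs),
    gene_id = names(seqs),
    is_splice_form = FALSE,
    cterm_confirmed = TRUE,
    sequence = unname(seqs),
    cds = vapply(unname(seqs), aa_to_cds, character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(proteins = tab), class = "pdz_proteome")
}

# brute-force O(L*W) sliding-window oracle, independent of the package path
window_pass_fraction_oracle <- function(phred, window = 10L, threshold = 20) {
  L <- length(phred)
  if (L < window) return(as.numeric(mean(phred) >= threshold))
  pass <- logical(L)
  for (s in 1:(L - window + 1)) {
    if (mean(phred[s:(s + window - 1)]) >= threshold)
      pass[s:(s + window - 1)] <- TRUE
  }
  mean(pass)
}

# regex-based consensus classifier, independent of classify_cterm()
classify_oracle <- function(aa_seq) {
  last3 <- substr(aa_seq, nchar(aa_seq) - 2, nchar(aa_seq))
  phi <- "YFWCMVILA"
  ifelse(grepl(sprintf("^[ST].[%s]$", phi), last3), "1",
  ifelse(grepl(sprintf("^[%s].[%s]$", phi, phi), last3), "2",
  ifelse(grepl(sprintf("^[DE].[%s]$", phi), last3), "3", "none")))
}

# a small noise-free simulated screen shared by prey-calling tests
noise_free_screen <- function(seed = 11, n_proteins = 80, n_edges = 15,
                              library_kind = "cDNA", decoy_rate = 0,
                              frame_shift_rate = 0, ...) {
  prot <- generate_proteome(n_proteins = n_proteins, mean_protein_len = 300,
                            seed = seed)
  planted <- plant_bait_domains(prot, n_domain_proteins = 8,
                                total_domains = 12, seed = seed)
  cat_obj <- build_domain_catalog(planted$annotations, prot)
  truth <- make_screen_truth(
    prot, cat_obj$catalog, library_kind = library_kind, n_edges = n_edges,
    mean_clones = 2, decoy_rate = decoy_rate,
    read_error_params = list(frame_shift_rate = frame_shift_rate,
                             low_quality_rate = 0, chimera_rate = 0,
                             reporter_fail_rate = 0,
                             single_band_fail_rate = 0, ...),
    seed = seed)
  scr <- generate_screen(prot, truth)
  list(proteome = prot, catalog = cat_obj$catalog, truth = truth,
       screen = scr)
}
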