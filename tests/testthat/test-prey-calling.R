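test_that("colony filter requires two of three reporters and a single band", {
  col <- data.frame(
    reporter1 = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    reporter2 = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    reporter3 = c(TRUE, FALSE, FALSE, TRUE, TRUE),
    single_band = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(colony_filter(col), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(colony_filter(data.frame(reporter1 = TRUE)))
})

test_that("AD junction is located exactly, tolerates mismatches, and rejects absence", {
  suf <- GAL4_AD_SUFFIX
  insert <- "ATGGCTGCAGAAACTTCTGTT"
  r <- locate_ad_junction(paste0(suf, insert))
  expect_equal(r$junction, nchar(suf) + 1L)
  expect_equal(r$score, nchar(suf))

  # two scattered mismatches still localise the junction at the same position
  mut <- suf
  substr(mut, 10, 10) <- if (substr(mut, 10, 10) == "A") "C" else "A"
  substr(mut, 40, 40) <- if (substr(mut, 40, 40) == "G") "T" else "G"
  r2 <- locate_ad_junction(paste0(mut, insert))
  expect_equal(r2$junction, nchar(suf) + 1L)
  expect_lt(r2$score, nchar(suf))

  # an unrelated read has no junction
  set.seed(2)
  junk <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  expect_true(is.na(locate_ad_junction(junk)$junction))
})

test_that("nucleotide identification separates unique, ambiguous and absent hits", {
  prot <- manual_proteome()
  cds_db <- stats::setNames(prot$proteins$cds, prot$proteins$protein_id)
  frag <- substr(cds_db[["p1"]], 91, 270)
  hit <- identify_nt(frag, cds_db)
  expect_equal(hit$status, "unique")
  expect_equal(hit$hit, "p1")
  expect_equal(hit$sub_start, 91L)
  expect_equal(hit$sub_end, 270L)

  # duplicated CDS (paralogs) make the same fragment ambiguous
  dup <- c(cds_db, p1b = unname(cds_db[["p1"]]))
  amb <- identify_nt(frag, dup)
  expect_equal(amb$status, "ambiguous")
  expect_setequal(amb$hits, c("p1", "p1b"))

  set.seed(8)
  junk <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  expect_equal(identify_nt(junk, cds_db)$status, "none")
  expect_error(identify_nt(frag, character(0)), "empty")
})

test_that("frame calling recovers identity and protein-residue span of in-frame reads", {
  prot <- manual_proteome()
  cds_db <- stats::setNames(prot$proteins$cds, prot$proteins$protein_id)
  protein_db <- stats::setNames(prot$proteins$sequence,
                                prot$proteins$protein_id)
  insert <- substr(cds_db[["p1"]], 91, 270)   # codons 31..90
  bases <- paste0(GAL4_AD_SUFFIX, insert)
  j <- locate_ad_junction(bases)
  cf <- call_frame(bases, j$junction, cds_db, protein_db)
  expect_equal(cf$frame_status, "InFrame")
  expect_equal(cf$protein_id, "p1")
  expect_equal(cf$insert_aa_start, 31L)
  expect_equal(cf$insert_aa_end, 90L)
})

test_that("frame-shifted and chimeric reads are called OutOfFrame", {
  prot <- manual_proteome()
  cds_db <- stats::setNames(prot$proteins$cds, prot$proteins$protein_id)
  protein_db <- stats::setNames(prot$proteins$sequence,
                                prot$proteins$protein_id)
  insert <- substr(cds_db[["p1"]], 91, 270)

  # +1 shift: the nucleotide hit survives, the fusion-frame peptide does not
  shifted <- paste0(GAL4_AD_SUFFIX, "G", insert)
  cf <- call_frame(shifted, nchar(GAL4_AD_SUFFIX) + 1L, cds_db, protein_db)
  expect_equal(cf$frame_status, "OutOfFrame")
  expect_true(is.na(cf$insert_aa_start))

  # chimera: in-frame 5' fragment of p1 fused to a frame-broken p3 segment;
  # nucleotide and peptide searches then disagree on the gene
  chim <- paste0(GAL4_AD_SUFFIX, substr(cds_db[["p1"]], 1, 90), "G",
                 substr(cds_db[["p3"]], 1, 210))
  cf2 <- call_frame(chim, nchar(GAL4_AD_SUFFIX) + 1L, cds_db, protein_db)
  expect_equal(cf2$frame_status, "OutOfFrame")

  # no junction means no call at all
  cf3 <- call_frame(chim, NA_integer_, cds_db, protein_db)
  expect_equal(cf3$frame_status, "Unassigned")
})

test_that("splice forms of one gene do not break frame agreement", {
  # two forms share the body; a peptide from the shared region hits both
  body <- "MSTAGKLVEEWQRNPHDFIMSTAGKLVEEWQRNPHDFI"
  forms <- c(g1a = paste0(body, "AAETSV"), g1b = paste0(body, "GGKEAV"))
  set.seed(61)
  cds_db <- stats::setNames(back_translate(forms, c("TAA", "TAA")),
                            names(forms))
  cds_db <- substr(cds_db, 1, nchar(cds_db) - 3L)  # drop the stop codons
  bases <- paste0(GAL4_AD_SUFFIX, substr(cds_db[["g1a"]], 1, 114))
  gene_of <- c(g1a = "g1", g1b = "g1")
  cf <- call_frame(bases, nchar(GAL4_AD_SUFFIX) + 1L, cds_db, forms, gene_of)
  expect_equal(cf$frame_status, "InFrame")
  expect_equal(cf$protein_id, "g1a")
})

test_that("batch prey calling on a noise-free screen matches the read truth", {
  fix <- noise_free_screen(seed = 23)
  calls <- call_preys(fix$screen$reads, fix$screen$colonies, fix$proteome)
  expect_equal(nrow(calls), nrow(fix$screen$reads))
  expect_true(all(calls$frame_status == "InFrame"))
  tr <- fix$screen$read_truth[match(calls$read_id,
                                    fix$screen$read_truth$read_id), ]
  gene_of <- stats::setNames(fix$proteome$proteins$gene_id,
                             fix$proteome$proteins$protein_id)
  expect_equal(unname(gene_of[calls$protein_id]),
               unname(gene_of[tr$prey_protein_id]))
})

test_that("interactions aggregate clone counts and honour retest outcomes", {
  calls <- data.frame(
    read_id = paste0("r", 1:5),
    bait_domain_id = c("d1", "d1", "d1", "d2", "d2"),
    library = "cDNA",
    protein_id = c("pA", "pA", "pA", "pB", "pB"),
    frame_status = c("InFrame", "InFrame", "InFrame", "InFrame",
                     "OutOfFrame"),
    insert_aa_start = c(10L, 50L, 30L, 5L, 1L),
    insert_aa_end = c(200L, 200L, 200L, 80L, 90L),
    stringsAsFactors = FALSE)
  agg <- aggregate_interactions(calls)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$n_hits[agg$prey_protein_id == "pA"], 3L)
  expect_equal(agg$n_hits[agg$prey_protein_id == "pB"], 1L)
  # the MIR of pA is its shortest clone (50..200)
  expect_equal(agg$mir_start[agg$prey_protein_id == "pA"], 50L)
  expect_equal(agg$mir_end[agg$prey_protein_id == "pA"], 200L)

  retest <- data.frame(bait_domain_id = "d1", prey_protein_id = "pA",
                       retest_confirmed = FALSE)
  agg2 <- aggregate_interactions(calls, retest)
  expect_equal(agg2$prey_protein_id, "pB")
})

test_that("the MIR is a global per-prey minimum with start-coordinate tie-break", {
  spans <- data.frame(
    prey_protein_id = c("p", "p", "p", "q", "q"),
    aa_start = c(10L, 50L, 30L, 40L, 20L),
    aa_end = c(200L, 200L, 200L, 140L, 120L))
  mir <- compute_mir(spans)
  expect_equal(mir$mir_start[mir$prey_protein_id == "p"], 50L)
  # q: both spans are 101 residues; the tie goes to the smaller start
  expect_equal(mir$mir_start[mir$prey_protein_id == "q"], 20L)
  expect_equal(mir$mir_end[mir$prey_protein_id == "q"], 120L)
})

test_that("the MIR never exceeds any observed clone span", {
  set.seed(44)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    st <- sample(1:100, n, replace = TRUE)
    spans <- data.frame(prey_protein_id = "p", aa_start = st,
                        aa_end = st + sample(20:120, n, replace = TRUE))
    mir <- compute_mir(spans)
    width <- mir$mir_end - mir$mir_start + 1L
    expect_equal(width, min(spans$aa_end - spans$aa_start + 1L))
    expect_true(any(spans$aa_start == mir$mir_start &
                    spans$aa_end == mir$mir_end))
  }
})
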