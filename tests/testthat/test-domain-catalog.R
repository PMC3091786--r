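test_that("overlapping cross-source annotations merge to their union", {
  a <- data.frame(protein_id = "p1", start = 50L, end = 130L, source = "A")
  b <- data.frame(protein_id = "p1", start = 55L, end = 135L, source = "B")
  m <- merge_domain_annotations(a, b)
  expect_equal(m$start, 50L)
  expect_equal(m$end, 135L)
  expect_equal(m$sources, "A,B")

  # source-unique annotations pass through with a single label
  m2 <- merge_domain_annotations(
    data.frame(protein_id = "p1", start = 10L, end = 90L, source = "A"),
    NULL)
  expect_equal(m2[c("start", "end", "sources")],
               data.frame(start = 10L, end = 90L, sources = "A"))
  expect_error(merge_domain_annotations(
    data.frame(protein_id = "p1", start = 5L, end = 2L, source = "A"), NULL),
    "invalid")
})

test_that("merged count equals connected components of the overlap graph", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    st <- sample(1:150, n, replace = TRUE)
    en <- st + sample(10:60, n, replace = TRUE)
    src <- sample(c("A", "B"), n, replace = TRUE)
    df <- data.frame(protein_id = "p", start = st, end = en, source = src)
    m <- merge_domain_annotations(df[df$source == "A", ],
                                  df[df$source == "B", ])
    # oracle: connected components of the pairwise interval-overlap graph
    adj <- outer(seq_len(n), seq_len(n), function(i, j)
      st[i] <= en[j] & st[j] <= en[i])
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(nrow(m), igraph::components(g)$no)
  }
})

test_that("domain ids follow the single/multi-domain naming rule", {
  ann <- data.frame(
    protein_id = c("p1", "p1", "p2"),
    start = c(300L, 50L, 40L), end = c(380L, 130L, 120L),
    sources = "A", stringsAsFactors = FALSE)
  ids <- assign_domain_ids(ann)
  expect_equal(ids$domain_id, c("p1.1", "p1.2", "p2"))
  expect_equal(ids$start, c(50L, 300L, 40L))  # numbered from the start codon

  # invariant under input shuffling
  ids2 <- assign_domain_ids(ann[c(3, 1, 2), ])
  expect_equal(ids2$domain_id[order(ids2$protein_id, ids2$start)],
               ids$domain_id)
  # bijection between annotations and ids
  expect_false(anyDuplicated(ids$domain_id) > 0)
  expect_error(assign_domain_ids(ann[c(1, 1, 2), ]), "duplicate")
})

test_that("boundary extension clamps to the protein and maps to CDS coordinates", {
  prot <- manual_proteome()
  L <- nchar(prot$proteins$sequence[1])  # 200
  ann <- data.frame(protein_id = "p1",
                    start = c(50L, 5L, L - 20L),
                    end = c(130L, 90L, L),
                    domain_id = c("p1.1", "p1.2", "p1.3"))
  reg <- extend_boundaries(ann, prot, tail_aa = 10)
  expect_equal(reg$ext_start, c(40L, 1L, L - 30L))
  expect_equal(reg$ext_end, c(140L, 100L, L))
  expect_equal(reg$nt_start, 3L * (reg$ext_start - 1L) + 1L)
  expect_equal(reg$nt_end, 3L * reg$ext_end)
  expect_equal(nchar(reg$insert_nt), 3L * (reg$ext_end - reg$ext_start + 1L))
  # insert translates back to the extended protein span
  expect_equal(translate_nt(reg$insert_nt[1]),
               substr(prot$proteins$sequence[1], 40, 140))
})

test_that("extension never exceeds protein bounds on random catalogs", {
  set.seed(21)
  prot <- generate_proteome(n_proteins = 40, seed = 3)
  for (i in 1:20) {
    planted <- plant_bait_domains(prot, n_domain_proteins = 10,
                                  total_domains = 14, seed = i)
    cat_obj <- build_domain_catalog(planted$annotations, prot)
    lens <- nchar(prot$proteins$sequence)[
      match(cat_obj$regions$protein_id, prot$proteins$protein_id)]
    expect_true(all(cat_obj$regions$ext_start >= 1))
    expect_true(all(cat_obj$regions$ext_end <= lens))
    # every merged annotation traces to >= 1 source record
    expect_true(all(nchar(cat_obj$catalog$sources) > 0))
    expect_false(anyDuplicated(cat_obj$catalog$domain_id) > 0)
  }
})

test_that("primer pairs carry the Gateway tails and reconstruct the amplicon", {
  prot <- manual_proteome()
  ann <- assign_domain_ids(data.frame(
    protein_id = c("p1", "p3"), start = c(50L, 30L), end = c(130L, 110L),
    sources = "A"))
  reg <- extend_boundaries(ann, prot)
  pr <- design_primers(reg)
  expect_true(all(startsWith(pr$forward, ATTB1_TAIL)))
  expect_true(all(startsWith(pr$reverse, ATTB2_TAIL)))
  for (i in seq_len(nrow(pr))) {
    expect_equal(pcr_amplicon(pr[i, ], reg$insert_nt[i]),
                 paste0(reg$insert_nt[i], "TAA"))
  }
  # reverse gene-specific part begins with the reverse complement of the
  # appended stop codon: TAA -> TTA
  gs <- substr(pr$reverse, nchar(ATTB2_TAIL) + 1, nchar(ATTB2_TAIL) + 3)
  expect_true(all(gs == "TTA"))
  expect_error(design_primers(data.frame(domain_id = "d", insert_nt = "ATG")),
               "shorter")
})

test_that("a 93-domain synthetic catalog yields valid primer pairs throughout", {
  prot <- generate_proteome(n_proteins = 150, mean_protein_len = 400,
                            seed = 12)
  planted <- plant_bait_domains(prot, n_domain_proteins = 62,
                                total_domains = 93, seed = 12)
  expect_equal(nrow(planted$truth), 93)
  expect_equal(length(unique(planted$truth$protein_id)), 62)
  obj <- build_domain_catalog(planted$annotations, prot)
  expect_equal(nrow(obj$catalog), 93)
  expect_equal(nrow(obj$primers), 93)
  expect_true(all(startsWith(obj$primers$forward, ATTB1_TAIL)))
  expect_true(all(startsWith(obj$primers$reverse, ATTB2_TAIL)))
  ok <- vapply(seq_len(93), function(i) {
    identical(pcr_amplicon(obj$primers[i, ], obj$regions$insert_nt[i]),
              paste0(obj$regions$insert_nt[i], "TAA"))
  }, logical(1))
  expect_true(all(ok))
})
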