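make_catalog <- function(ids) {
  data.frame(domain_id = ids, protein_id = sub("\\.\\d+$", "", ids),
             stringsAsFactors = FALSE)
}

make_network <- function(dom, prey, catalog_ids = unique(dom),
                         library = "cDNA", auto = character()) {
  assemble_network(
    data.frame(bait_domain_id = dom, prey_protein_id = prey,
               stringsAsFactors = FALSE),
    make_catalog(catalog_ids), auto_activators = auto, library = library)
}

test_that("network assembly validates edges against catalog and auto-activators", {
  nw <- make_network(c("d1", "d1", "d2"), c("pA", "pB", "pA"),
                     catalog_ids = c("d1", "d2", "d3"))
  expect_s3_class(nw, "pdz_network")
  expect_output(print(nw), "3 edges, 2/3 productive domains, 2 preys")

  expect_error(make_network("d1", "pA", auto = "d1"), "auto-activator")
  expect_error(make_network(c("d1", "d1"), c("pA", "pA")), "duplicate")
  expect_error(make_network("dX", "pA", catalog_ids = "d1"),
               "absent from the catalog")
})

test_that("degree statistics on a hand-built network are exact", {
  # 7 edges over 3 productive domains of a 5-domain catalog
  nw <- make_network(
    c("d1", "d1", "d1", "d1", "d2", "d2", "d3"),
    c("pA", "pB", "pC", "pD", "pA", "pB", "pA"),
    catalog_ids = paste0("d", 1:5))
  st <- degree_stats(nw, mean_digits = 1)
  expect_equal(st$n_edges, 7)
  expect_equal(st$n_domains_productive, 3)
  expect_equal(st$mean_degree, 7 / 3)
  expect_equal(st$mean_degree_display, 2.3)
  expect_equal(st$median_degree, 2)
  expect_equal(st$coverage, 3 / 5)
  expect_equal(st$coverage_pct, 60)
  expect_equal(st$prey_mean_degree, 7 / 4)
  # degree sums on both sides equal the edge count
  expect_equal(sum(st$domain_degrees$degree), st$n_edges)
  expect_equal(sum(st$prey_degrees$degree), st$n_edges)

  single <- degree_stats(make_network("d1", "pA"))
  expect_equal(single$mean_degree, 1)
  expect_equal(single$coverage_pct, 100)
})

test_that("degree sums are conserved on simulated networks", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    dom <- paste0("d", sample(1:12, n, replace = TRUE))
    prey <- paste0("p", sample(1:30, n, replace = TRUE))
    keep <- !duplicated(paste(dom, prey))
    nw <- make_network(dom[keep], prey[keep], catalog_ids = paste0("d", 1:12))
    st <- degree_stats(nw)
    expect_equal(sum(st$domain_degrees$degree), st$n_edges)
    expect_equal(sum(st$prey_degrees$degree), st$n_edges)
    expect_equal(st$mean_degree * st$n_domains_productive, st$n_edges)
  }
})

test_that("class proportion table distinguishes redundant and nonredundant rows", {
  # pA (class 1) binds two domains, pB (none) one
  nw <- make_network(c("d1", "d2", "d1"), c("pA", "pA", "pB"),
                     catalog_ids = c("d1", "d2"))
  calls <- data.frame(protein_id = c("pA", "pB"), cls_gene = c("1", "none"),
                      stringsAsFactors = FALSE)
  tab <- class_proportion_table(nw, calls)
  expect_equal(rownames(tab), c("redundant", "nonredundant"))
  expect_equal(tab["redundant", "class1"], 67)     # 2 of 3
  expect_equal(tab["nonredundant", "class1"], 50)  # 1 of 2
  expect_equal(tab["redundant", "total_nonconsensus"], 33)
  expect_equal(tab$n, c(3, 2))

  # all-class-1 preys give a 100/0/0 row
  nw1 <- make_network(c("d1", "d2"), c("pA", "pA"),
                      catalog_ids = c("d1", "d2"))
  tab1 <- class_proportion_table(nw1, calls)
  expect_equal(unlist(tab1["redundant",
                           c("class1", "class2", "class3",
                             "total_consensus", "total_nonconsensus")],
                      use.names = FALSE), c(100, 0, 0, 100, 0))
  expect_error(class_proportion_table(nw, calls[1, , drop = FALSE]),
               "unclassified")
})

test_that("class proportion table accepts a proteome background row", {
  nw <- make_network("d1", "pA")
  calls <- data.frame(protein_id = "pA", cls_gene = "1")
  prot <- generate_proteome(n_proteins = 100, seed = 10)
  tab <- class_proportion_table(nw, calls, proteome_class_table(prot))
  expect_equal(rownames(tab)[3], "proteome")
  expect_equal(tab["proteome", "n"], nrow(prot$proteins))
  expect_equal(tab["proteome", "total_consensus"] +
                 tab["proteome", "total_nonconsensus"], 100)
})

test_that("overlap is counted in shared pairs relative to the smaller screen", {
  a <- make_network(c("d1", "d1", "d2", "d3"), c("pA", "pB", "pA", "pC"),
                    catalog_ids = paste0("d", 1:3))
  b <- make_network(c("d1", "d2"), c("pB", "pA"),
                    catalog_ids = paste0("d", 1:3), library = "ORFeome")
  ov <- network_overlap(a, b)
  expect_equal(ov$shared, 2)
  expect_equal(ov$percent, 100)   # 2 of min(4, 2)
  expect_equal(nrow(ov$shared_edges), 2)

  disjoint <- make_network("d3", "pZ", catalog_ids = paste0("d", 1:3))
  expect_equal(network_overlap(a, disjoint)$shared, 0)
  expect_equal(network_overlap(a, disjoint)$percent, 0)
  expect_equal(network_overlap(a, a)$percent, 100)
})

test_that("pooling sums interactions and unions distinct preys and domains", {
  a <- make_network(c("d1", "d2"), c("pA", "pB"),
                    catalog_ids = paste0("d", 1:3))
  b <- make_network(c("d1", "d3"), c("pA", "pC"),
                    catalog_ids = paste0("d", 1:3), library = "ORFeome")
  pool <- pool_networks(list(a, b))
  expect_equal(pool$n_interactions, 4)   # plain sum, shared pair kept twice
  expect_equal(pool$n_preys, 3)
  expect_equal(pool$n_domains, 3)
  expect_equal(pool$network$library, "pooled")

  solo <- pool_networks(list(a))
  expect_equal(solo$n_interactions, nrow(a$edges))
  # additivity of edge counts under pooling
  expect_equal(pool$n_interactions, nrow(a$edges) + nrow(b$edges))
})

test_that("graph export round-trips through GraphML and SIF", {
  nw <- make_network(c("d1", "d1", "d2"), c("pA", "pB", "pA"),
                     catalog_ids = c("d1", "d2"))
  calls <- data.frame(protein_id = c("pA", "pB"), cls_gene = c("1", "none"),
                      stringsAsFactors = FALSE)
  d <- withr::local_tempdir()
  gml <- file.path(d, "net.graphml")
  sif <- file.path(d, "net.sif")
  g <- export_graph(nw, calls, graphml_path = gml, sif_path = sif)
  expect_equal(igraph::vcount(g), 4)   # 2 domain + 2 prey nodes
  expect_equal(igraph::ecount(g), 3)

  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 4)
  expect_equal(igraph::ecount(back), 3)
  expect_setequal(igraph::V(back)$name, c("PDZ:d1", "PDZ:d2", "pA", "pB"))
  expect_equal(sort(igraph::V(back)$consensus_class), c("", "", "1", "none"))

  lines <- readLines(sif)
  expect_length(lines, 3)
  expect_true(all(grepl("^PDZ:d[12] pd p[AB]$", lines)))

  # a prey sharing its id with a bait protein still yields distinct nodes
  clash <- make_network(c("p1", "p2"), c("p2", "p3"),
                        catalog_ids = c("p1", "p2"))
  g2 <- export_graph(clash)
  expect_equal(igraph::vcount(g2), 4)
})
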