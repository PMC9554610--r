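make_hits <- function(cluster, mge, s_start = NULL) {
  n <- max(length(cluster), length(mge))
  cluster <- rep_len(cluster, n); mge <- rep_len(mge, n)
  if (is.null(s_start)) s_start <- seq(10, by = 100, length.out = n)
  data.frame(cluster_id = cluster, mge_id = mge, identity = 1,
             aln_len = 32L, mismatches = 0L, gap_openings = 0L,
             q_start = 1L, q_end = 32L, s_start = s_start,
             s_end = s_start + 31L, evalue = 1e-9, bitscore = 45,
             qcov = 1, strand = "+", score_raw = 32,
             stringsAsFactors = FALSE)
}

test_that("greedy cover follows the re-sorting rule with lexicographic tie-breaks", {
  # worked instance: A covers 3, then B adds 1 new but C adds 2
  sel <- greedy_cover(paste0("p", 1:5),
                      list(A = c("p1", "p2", "p3"), B = c("p3", "p4"),
                           C = c("p4", "p5")))
  expect_identical(sel, c("A", "C"))
  # one candidate covering everything
  expect_identical(greedy_cover(c("x", "y"),
                                list(M = c("x", "y"), N = "x")), "M")
  # perfect tie: lexicographically smallest id wins
  expect_identical(greedy_cover(c("p1", "p2"),
                                list(B = c("p1", "p2"),
                                     A = c("p1", "p2"))), "A")
  # uncoverable universe names the uncovered elements
  expect_error(greedy_cover(c("p1", "p2"), list(A = "p1")), "p2")
})

test_that("every greedy pick adds new coverage and the selection is near-optimal (random instances)", {
  set.seed(301)
  for (rep in 1:40) {
    inst <- random_cover_instance()
    sel <- greedy_cover(inst$universe, inst$candidates)
    # selection covers the universe
    expect_setequal(unique(unlist(inst$candidates[sel])), inst$universe)
    # each pick contributed at least one new element
    covered <- character(0)
    for (s in sel) {
      gain <- setdiff(inst$candidates[[s]], covered)
      expect_gt(length(gain), 0)
      covered <- union(covered, inst$candidates[[s]])
    }
    # within the (1 + ln d) bound of the exhaustive optimum
    opt <- oracle_min_cover_size(inst$universe, inst$candidates)
    d <- max(lengths(inst$candidates))
    expect_lte(length(sel), (1 + log(d)) * opt)
  }
})

test_that("MGE selection covers all matched clusters; duplicate MGEs collapse to one", {
  h <- make_hits(c("s1", "s2", "s3", "s3", "s4", "s4", "s5"),
                 c("A", "A", "A", "B", "B", "C", "C"))
  expect_identical(select_mges(h), c("A", "C"))
  # one MGE containing protospacers for every cluster
  expect_identical(select_mges(make_hits(c("s1", "s2"), "Z")), "Z")
  # disjoint repertoires: all MGEs needed
  expect_setequal(select_mges(make_hits(c("s1", "s2"), c("A", "B"))),
                  c("A", "B"))
  # two identical MGEs: exactly one selected (lexicographic)
  expect_identical(select_mges(make_hits(c("s1", "s1"), c("Y", "X"))), "X")
})

test_that("host selection mirrors the greedy over host spacer repertoires", {
  h <- make_hits(c("a", "b", "c", "d", "e"), "M")
  catalog <- data.frame(
    host_id = c("h1", "h1", "h1", "h2", "h2", "h3", "h3"),
    cluster_id = c("a", "b", "c", "c", "d", "d", "e"),
    stringsAsFactors = FALSE)
  expect_identical(select_hosts(h, catalog), c("h1", "h3"))
  # single host
  expect_identical(
    select_hosts(make_hits("a", "M"),
                 data.frame(host_id = "h9", cluster_id = "a")), "h9")
  # identical repertoires: one host, lexicographic
  cat2 <- data.frame(host_id = c("hB", "hA"), cluster_id = c("a", "a"))
  expect_identical(select_hosts(make_hits("a", "M"), cat2), "hA")
})

test_that("the spacer-MGE network has selection-restricted nodes, deduplicated edges and locus counts", {
  cl <- make_clusters(c("ACGT", "TTTT", "GGGG"),
                      ids = c("s1", "s2", "s3"))
  cl$crispr_types <- I(list("II-C", character(0), "I-C"))
  meta <- data.frame(mge_id = c("A", "B"), mge_class = c("phage", "plasmid"),
                     source_db = "t", known_host = "", stringsAsFactors = FALSE)
  # s1 hits A twice (two loci) and B once; s2 hits B only; B not selected
  h <- rbind(make_hits("s1", "A", 10), make_hits("s1", "A", 200),
             make_hits("s1", "B", 10), make_hits("s2", "B", 300))
  g <- build_spacer_mge_network(h, selected_mges = "A", cl, meta)
  expect_setequal(igraph::V(g)$name, c("s1", "A"))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$nmatches, 2)  # two loci, one edge
  expect_equal(igraph::V(g)$crisprtype[igraph::V(g)$name == "s1"], "II-C")
  expect_equal(igraph::V(g)$mgeclass[igraph::V(g)$name == "A"], "phage")
})

test_that("the host-MGE network joins selected hosts to selected MGEs through shared clusters", {
  catalog <- data.frame(host_id = c("h1", "h2", "h3"),
                        cluster_id = c("a", "a", "z"),
                        stringsAsFactors = FALSE)
  h <- make_hits("a", "M")
  g <- build_host_mge_network(h, selected_hosts = c("h1", "h2"),
                              selected_mges = "M", catalog)
  expect_setequal(igraph::V(g)$name, c("h1", "h2", "M"))
  expect_equal(igraph::ecount(g), 2)  # both hosts share the cluster
  # h3's spacers match nothing: absent from the network
  expect_false("h3" %in% igraph::V(g)$name)
  expect_true(igraph::bipartite_mapping(g)$res)
})

test_that("emitted networks are bipartite with minimum degree one and no duplicate edges", {
  set.seed(302)
  for (rep in 1:5) {
    n_cl <- sample(5:15, 1); n_mge <- sample(3:8, 1)
    cls <- sprintf("s%02d", 1:n_cl); mgs <- sprintf("M%02d", 1:n_mge)
    h <- make_hits(sample(cls, 25, replace = TRUE),
                   sample(mgs, 25, replace = TRUE),
                   s_start = seq(10, by = 100, length.out = 25))
    cl <- make_clusters(random_dna(n_cl, 32), ids = cls)
    sel <- select_mges(h)
    g <- build_spacer_mge_network(h, sel, cl)
    expect_true(igraph::bipartite_mapping(g)$res ||
                  igraph::ecount(g) == 0)
    expect_false(igraph::any_multiple(g))
    expect_false(any(igraph::which_loop(g)))
    if (igraph::vcount(g) > 0) expect_gte(min(igraph::degree(g)), 1)
    # every selected MGE appears with degree >= 1
    expect_true(all(sel %in% igraph::V(g)$name))
  }
})

test_that("connected components match a BFS oracle and are numbered by size", {
  # two disjoint edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "c"), to = c("b", "d"), nmatches = 1),
    directed = FALSE)
  cmp <- network_components(g)
  expect_length(cmp$components, 2)
  expect_equal(cmp$components[[1]]$nodes, c("a", "b"))  # tie: lexicographic
  # path of 4 nodes
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "d")),
    directed = FALSE)
  expect_length(network_components(g2)$components, 1)
  # random bipartite graphs against the oracle
  set.seed(303)
  for (rep in 1:5) {
    nl <- sample(10:25, 1); nr <- sample(10:25, 1)
    from <- sprintf("L%02d", sample.int(nl, 40, replace = TRUE))
    to <- sprintf("R%02d", sample.int(nr, 40, replace = TRUE))
    ed <- unique(data.frame(from = from, to = to,
                            stringsAsFactors = FALSE))
    g3 <- igraph::graph_from_data_frame(ed, directed = FALSE)
    cmp3 <- network_components(g3)
    want <- oracle_bfs_components(igraph::V(g3)$name, ed$from, ed$to)
    expect_identical(lapply(cmp3$components, `[[`, "nodes"), want)
  }
})

test_that("module composition reports count spacers per CRISPR type and MGEs per class", {
  # synthetic module: 59 II-C spacers, 2 I-C spacers, 4 phages
  cls <- sprintf("s%02d", 1:61)
  cl <- make_clusters(random_dna(61, 32), ids = cls)
  cl$crispr_types <- I(c(rep(list("II-C"), 59), rep(list("I-C"), 2)))
  mgs <- c("P1", "P2", "P3", "P4")
  meta <- data.frame(mge_id = mgs, mge_class = "phage", source_db = "t",
                     known_host = "", stringsAsFactors = FALSE)
  h <- make_hits(cls, rep(mgs, length.out = 61))
  g <- build_spacer_mge_network(h, mgs, cl, meta)
  rep_ <- module_type_report(igraph::V(g)$name, g)
  expect_equal(rep_$n_phages, 4)
  expect_equal(rep_$n_spacers, 61)
  expect_equal(rep_$spacer_types[["II-C"]], 59)
  expect_equal(rep_$spacer_types[["I-C"]], 2)
  # untyped spacers are counted under "untyped"
  cl2 <- make_clusters(c("AAAA", "CCCC"), ids = c("u1", "u2"))
  g2 <- build_spacer_mge_network(make_hits(c("u1", "u2"), "P1"), "P1",
                                 cl2, meta)
  rep2 <- module_type_report(igraph::V(g2)$name, g2)
  expect_equal(rep2$spacer_types[["untyped"]], 2)
})

test_that("GML export round-trips networks losslessly, including ids with spaces", {
  cl <- make_clusters(c("ACGT", "CCGG"), ids = c("sp 1", "sp 2"))
  cl$crispr_types <- I(list("I-C", character(0)))
  meta <- data.frame(mge_id = "mge A", mge_class = "phage",
                     source_db = "db x", known_host = "Bacteroides",
                     stringsAsFactors = FALSE)
  h <- make_hits(c("sp 1", "sp 2"), "mge A")
  g <- build_spacer_mge_network(h, "mge A", cl, meta)
  f <- tempfile(fileext = ".gml")
  write_network(g, f)
  expect_true(crisprnet:::networks_equal(read_network(f), g))
  # empty network: valid file with zero nodes
  g0 <- build_spacer_mge_network(h[0, ], character(0), cl)
  f0 <- tempfile(fileext = ".gml")
  write_network(g0, f0)
  expect_equal(igraph::vcount(read_network(f0)), 0)
  # TSV export for Cytoscape
  write_network(g, tempfile(), format = "tsv")
  expect_error(write_network(g, "/nonexistent_dir_xyz/g.gml"), "directory")
})

test_that("component summary table carries per-type spacer counts", {
  cl <- make_clusters(c("ACGT", "CCGG"), ids = c("s1", "s2"))
  cl$crispr_types <- I(list("I-C", "I-C"))
  meta <- data.frame(mge_id = "M", mge_class = "phage", source_db = "t",
                     known_host = "", stringsAsFactors = FALSE)
  g <- build_spacer_mge_network(make_hits(c("s1", "s2"), "M"), "M", cl,
                                meta)
  f <- tempfile(fileext = ".tsv")
  write_components_tsv(network_components(g), f)
  df <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(nrow(df), 1)
  expect_equal(df$n_spacers, 2)
  expect_equal(df$spacer_types, "I-C=2")
})
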