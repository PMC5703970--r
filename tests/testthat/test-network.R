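toyNet <- function() {
  desc <- matrix(0, 2, 2, dimnames = list(NULL, c("a", "b")))
  cs <- CompoundSet(c("c1", "c2"), desc)
  inter <- data.frame(compound_id = c("c1", "c1", "c2", "c2"),
                      target_id = c("T1", "T2", "T1", "T1"),
                      stringsAsFactors = FALSE)
  buildCTNetwork(cs, inter)
}

test_that("the C-T network builder keeps set semantics and referential
           integrity", {
  net <- toyNet()  # includes a duplicate (c2, T1) row
  expect_equal(nrow(networkEdges(net)), 3L)
  expect_equal(lengths(layers(net)), c(compound = 2L, target = 2L))
  desc <- matrix(0, 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(
    buildCTNetwork(CompoundSet("c1", desc),
                   data.frame(compound_id = "cX", target_id = "T1")),
    "unknown compound")
})

test_that("isolated compounds are retained, targets only when connected", {
  desc <- matrix(0, 3, 2, dimnames = list(NULL, c("a", "b")))
  cs <- CompoundSet(c("c1", "c2", "c3"), desc)
  net <- buildCTNetwork(cs, data.frame(compound_id = "c1", target_id = "T1"))
  expect_equal(layers(net)$compound, c("c1", "c2", "c3"))
  expect_equal(layers(net)$target, "T1")
})

test_that("layered-network validity rejects malformed graphs", {
  expect_error(LayeredNetwork(list(a = "x", b = "x"),
                              data.frame(from = "x", to = "x")),
               "unique|self-loops")
  expect_error(
    LayeredNetwork(list(a = c("x", "y"), b = "z"),
                   data.frame(from = "x", to = "y")),
    "adjacent")
})

test_that("degree statistics: handshake lemma and exact partition means", {
  net <- toyNet()
  rep1 <- degreeStatistics(net)
  expect_equal(sum(rep1@perNode), 2L * nrow(networkEdges(net)))
  # 1 compound, 1 target, 1 edge
  desc <- matrix(0, 1, 2, dimnames = list(NULL, c("a", "b")))
  tiny <- buildCTNetwork(CompoundSet("c1", desc),
                         data.frame(compound_id = "c1", target_id = "T1"))
  tm <- degreeStatistics(tiny)@partitionMeans
  expect_equal(unname(tm), c(1, 1))
  # 3 compounds, 2 targets, 4 edges -> 4/3 and 2
  desc3 <- matrix(0, 3, 2, dimnames = list(NULL, c("a", "b")))
  net3 <- buildCTNetwork(
    CompoundSet(c("c1", "c2", "c3"), desc3),
    data.frame(compound_id = c("c1", "c1", "c2", "c3"),
               target_id = c("T1", "T2", "T1", "T2")))
  m3 <- degreeStatistics(net3)@partitionMeans
  expect_equal(unname(m3), c(4 / 3, 2), tolerance = 1e-12)
  # random graphs: handshake holds
  for (s in 1:5) {
    r <- degreeStatistics(ctCountsFixture(s))
    expect_equal(sum(r@perNode), 964L)
  }
  expect_error(degreeStatistics(
    LayeredNetwork(list(a = character(0), b = "t"),
                   data.frame(from = character(0), to = character(0)))),
    "empty partition")
})

test_that("hub detection uses a strict cutoff and matches a direct recount", {
  deg <- c(x = 1L, y = 2L, z = 9L)
  rep1 <- new("DegreeReport", perNode = deg,
              nodeLayer = c(x = "compound", y = "compound", z = "compound"),
              partitionMeans = c(compound = 4), nEdges = 6L)
  expect_equal(hubNodes(rep1, "compound"), "z")
  allEq <- new("DegreeReport", perNode = c(a = 2L, b = 2L),
               nodeLayer = c(a = "compound", b = "compound"),
               partitionMeans = c(compound = 2), nEdges = 2L)
  expect_length(hubNodes(allEq, "compound"), 0L)
  expect_error(hubNodes(rep1, "pathway"), "unknown layer")
  # oracle equivalence on a random 63 x 43 graph with 482 edges
  net <- ctCountsFixture(7)
  r <- degreeStatistics(net)
  hubs <- hubNodes(r, "compound")
  mean_deg <- r@partitionMeans[["compound"]]
  brute <- names(which(r@perNode[layers(net)$compound] > mean_deg))
  expect_setequal(hubs, brute)
  expect_true(all(diff(r@perNode[hubs]) <= 0))
})

test_that("the C-T-P builder links pathways at their member targets", {
  pw <- GeneSets(list(P1 = c("T1", "TX"), P2 = "TY"),
                 universe = c("T1", "TX", "TY"))
  inter <- data.frame(compound_id = c("c1", "c1"),
                      target_id = c("T1", "T2"), stringsAsFactors = FALSE)
  net <- buildCTPNetwork("c1", inter, pw)
  # c1 -> {T1, T2}; only T1 sits in a pathway; P2 has no member target
  expect_equal(lengths(layers(net)),
               c(compound = 1L, target = 2L, pathway = 1L))
  expect_equal(nrow(networkEdges(net)), 3L)
  # single chain: 1 compound, 1 target, 1 pathway -> 3 nodes, 2 edges
  chain <- buildCTPNetwork("c1",
                           data.frame(compound_id = "c1", target_id = "T1"),
                           GeneSets(list(P1 = "T1"), universe = "T1"))
  expect_equal(sum(lengths(layers(chain))), 3L)
  expect_equal(nrow(networkEdges(chain)), 2L)
})

test_that("C-T-P node/edge counts match a brute-force recount on random
           inputs", {
  set.seed(31)
  for (rep in 1:5) {
    comps <- sprintf("c%d", 1:6)
    targs <- sprintf("T%d", 1:12)
    inter <- unique(data.frame(
      compound_id = sample(comps, 40, TRUE),
      target_id = sample(targs, 40, TRUE), stringsAsFactors = FALSE))
    pw <- GeneSets(setNames(lapply(1:5, function(i) sample(targs, 4)),
                            sprintf("P%d", 1:5)),
                   universe = targs)
    use <- sample(comps, 3)
    net <- buildCTPNetwork(use, inter, pw)
    sub <- inter[inter$compound_id %in% use, ]
    tset <- unique(sub$target_id)
    tp <- sum(vapply(pw@sets, function(g) length(intersect(g, tset)),
                     integer(1)))
    pwUsed <- sum(vapply(pw@sets, function(g) any(tset %in% g), logical(1)))
    expect_equal(nrow(networkEdges(net)), nrow(sub) + tp)
    expect_equal(sum(lengths(layers(net))),
                 length(use) + length(tset) + pwUsed)
  }
})

test_that("SIF export writes one relation-tagged line per edge", {
  chain <- buildCTPNetwork("c1",
                           data.frame(compound_id = "c1", target_id = "T1"),
                           GeneSets(list(P1 = "T1"), universe = "T1"))
  path <- withr::local_tempfile(fileext = ".sif")
  exportNetwork(chain, path, "sif")
  lines <- readLines(path)
  expect_length(lines, 2L)
  expect_true(any(grepl("c1\tcompound-target\tT1", lines, fixed = TRUE)))
  expect_true(any(grepl("T1\ttarget-pathway\tP1", lines, fixed = TRUE)))
  expect_error(exportNetwork(chain, path, "dot"), "arg")
})

test_that("TSV export/import round-trips the network", {
  net <- ctCountsFixture(2)
  stem <- withr::local_tempfile()
  exportNetwork(net, stem, "tsv")
  back <- importNetworkTSV(stem)
  expect_equal(lengths(layers(back)), lengths(layers(net)))
  expect_setequal(paste(networkEdges(back)$from, networkEdges(back)$to),
                  paste(networkEdges(net)$from, networkEdges(net)$to))
  expect_equal(back@nodeLabels, net@nodeLabels)
})

test_that("GraphML export is well-formed, carries the layer attribute and
           reads back with igraph", {
  net <- toyNet()
  path <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(net, path, "graphml")
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "graphml")
  expect_true(grepl("graphml", xml2::xml_ns(doc)[[1]]))
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::gorder(g), 4L)
  expect_equal(igraph::gsize(g), 3L)
  expect_setequal(unique(igraph::V(g)$layer), c("compound", "target"))
})
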