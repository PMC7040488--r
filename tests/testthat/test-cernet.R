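mk_pairs <- function(mirna, target, r = -0.85, retained = TRUE) {
  data.frame(mirna_id = mirna, target_id = target, r = r,
             p = 0.01, n = 9, retained = retained,
             stringsAsFactors = FALSE)
}
mk_targets <- function(mirna, transcript) {
  sites <- data.frame(mirna_id = mirna, transcript_id = transcript,
                      start = 0L, end = 8L, site_type = "8mer",
                      stringsAsFactors = FALSE)
  cernetr:::target_prediction(sites)
}

test_that("a shared miRNA with both partners yields one triplet", {
  net <- build_cernet(mk_pairs("m1", "g1"), mk_pairs("m1", "l1"),
                      mk_targets(c("m1", "m1"), c("g1", "l1")),
                      dev_genes = "g1")
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$triplets[c("mirna_id", "mrna_id", "lncrna_id")],
               data.frame(mirna_id = "m1", mrna_id = "g1",
                          lncrna_id = "l1"))
  expect_setequal(net$nodes$node_type, c("miRNA", "mRNA", "lncRNA"))
})

test_that("edges without a completing partner stay in the graph without triplets", {
  net <- build_cernet(mk_pairs("m2", "g2"), mk_pairs("m9", "l9"),
                      mk_targets(c("m2", "m9"), c("g2", "l9")),
                      dev_genes = "g2")
  expect_equal(nrow(net$triplets), 0)
  expect_setequal(net$nodes$id, c("m2", "g2", "m9", "l9"))
  expect_equal(nrow(net$edges), 2)
})

test_that("the development gate excludes mRNA edges and targets gate both sides", {
  # mRNA outside the development set: edge dropped entirely
  net <- build_cernet(mk_pairs("m1", "g1"), mk_pairs("m1", "l1"),
                      mk_targets(c("m1", "m1"), c("g1", "l1")),
                      dev_genes = character(0))
  expect_false("g1" %in% net$nodes$id)
  expect_equal(nrow(net$triplets), 0)
  # pair without target evidence: dropped with a warning
  expect_warning(
    net2 <- build_cernet(mk_pairs("m1", "g1"), mk_pairs("m1", "l1"),
                         mk_targets("m1", "g1"), dev_genes = "g1"),
    "lacked target evidence")
  expect_equal(nrow(net2$triplets), 0)
  expect_true("g1" %in% net2$nodes$id)
  # non-retained pairs never enter the network
  net3 <- build_cernet(mk_pairs("m1", "g1", retained = FALSE),
                       mk_pairs("m1", "l1"),
                       mk_targets(c("m1", "m1"), c("g1", "l1")),
                       dev_genes = "g1")
  expect_equal(nrow(net3$triplets), 0)
  expect_false("g1" %in% net3$nodes$id)
})

test_that("exports are line-per-edge and round-trip through the tables", {
  net <- build_cernet(mk_pairs("m1", "g1"), mk_pairs("m1", "l1"),
                      mk_targets(c("m1", "m1"), c("g1", "l1")),
                      dev_genes = "g1")
  dir <- withr::local_tempdir()
  paths <- export_network(net, dir)
  expect_equal(length(readLines(paths["sif"])), 2)
  expect_match(readLines(paths["sif"])[1], "^m1\tinteracts\t")
  back <- import_network(paths["edge_table"], paths["node_table"])
  expect_setequal(paste(back$edges$source, back$edges$target),
                  paste(net$edges$source, net$edges$target))
  expect_equal(back$nodes[order(back$nodes$id), ],
               net$nodes[order(net$nodes$id), ], ignore_attr = TRUE)
  expect_equal(back$triplets[c("mirna_id", "mrna_id", "lncrna_id")],
               net$triplets[c("mirna_id", "mrna_id", "lncrna_id")],
               ignore_attr = TRUE)
  # GraphML is well-formed XML
  xml <- xml2::read_xml(paths["graphml"])
  expect_equal(xml2::xml_name(xml), "graphml")
  expect_error(export_network(net, dir, formats = "dot"), "unknown")
  # empty graph: files exist with headers only
  empty <- build_cernet(mk_pairs("m", "g", retained = FALSE), NULL,
                        mk_targets("m", "g"), dev_genes = "g")
  p2 <- export_network(empty, file.path(dir, "empty"))
  expect_equal(nrow(read.delim(p2["edge_table"])), 0)
})

test_that("recovery scoring follows the stated conventions", {
  truth <- data.frame(mirna_id = c("m1", "m2"), mrna_id = c("g1", "g2"),
                      lncrna_id = c("l1", "l2"))
  perfect <- evaluate_recovery(truth, truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  half <- evaluate_recovery(truth[1, ], truth)
  expect_equal(half$precision, 1)
  expect_equal(half$recall, 0.5)
  expect_equal(half$f1, 2 / 3)
  none <- evaluate_recovery(truth[0, ], truth)
  expect_equal(none$precision, 0)
  expect_equal(none$recall, 0)
  expect_equal(none$f1, 0)
  spurious <- rbind(truth, data.frame(mirna_id = "mX", mrna_id = "gX",
                                      lncrna_id = "lX"))
  expect_equal(evaluate_recovery(spurious, truth)$precision, 2 / 3)
})
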