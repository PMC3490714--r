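pathGraph <- function() {
  ed <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                   pcor = c(0.3, -0.2), p_value = 0.01, q_value = 0.02)
  ann <- data.frame(gene_id = c("A", "B", "C"),
                    role = c("regulator", "regulator", "target"),
                    family = "")
  buildAnnotatedGraph(ed, annotation = ann)
}

test_that("degree table, histogram and hub follow the path-graph enumeration", {
  g <- pathGraph()
  dt <- degreeTable(g)
  expect_equal(setNames(dt$table$degree, dt$table$node),
               c(B = 2L, A = 1L, C = 1L))
  expect_equal(dt$hub, "B")
  expect_equal(sum(dt$table$degree), 2L * igraph::ecount(g))
  emptyG <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(nrow(degreeTable(emptyG)$table), 0L)
})

test_that("a planted star center is reported as the hub with its degree", {
  leaves <- sprintf("L%02d", 1:15)
  ed <- data.frame(gene_a = "HUB", gene_b = leaves, pcor = 0.3,
                   p_value = 0.01, q_value = 0.01)
  extra <- data.frame(gene_a = c("X1", "X2"), gene_b = c("X2", "X3"),
                      pcor = 0.2, p_value = 0.02, q_value = 0.02)
  g <- buildAnnotatedGraph(rbind(ed, extra))
  dt <- degreeTable(g)
  expect_equal(dt$hub, "HUB")
  expect_equal(dt$table$degree[dt$table$node == "HUB"], 15L)
  # hub ties broken lexicographically, all tied hubs reported
  tie <- buildAnnotatedGraph(data.frame(
    gene_a = c("B", "A"), gene_b = c("C", "C"), pcor = 0.1,
    p_value = 0.1, q_value = 0.1))
  expect_equal(degreeTable(tie)$hub, "C")
  pair <- buildAnnotatedGraph(data.frame(gene_a = "A", gene_b = "B",
                                         pcor = 0.1, p_value = 0.1,
                                         q_value = 0.1))
  expect_setequal(degreeTable(pair)$tiedHubs, c("A", "B"))
})

test_that("first-neighbour subnetwork matches hand enumeration and is idempotent", {
  # 8-node toy: star around S1 plus a detached triangle and an isolate S3
  ed <- data.frame(
    gene_a = c("S1", "S1", "T1", "T3", "T3", "T4"),
    gene_b = c("T1", "T2", "T3", "T4", "T5", "T5"),
    pcor = 0.3, p_value = 0.01, q_value = 0.01)
  ann <- data.frame(gene_id = c("S1", "S3", paste0("T", 1:5)),
                    role = c("target", "target", rep("regulator", 5)),
                    family = "")
  g <- buildAnnotatedGraph(ed, annotation = ann, includeIsolated = TRUE)
  sg <- firstNeighborSubnetwork(g, c("S1", "S3"))
  expect_setequal(igraph::V(sg)$name, c("S1", "S3", "T1", "T2"))
  # induced: includes the T1-T2 edges only if present among kept nodes
  expect_equal(igraph::ecount(sg), 2L)
  expect_true(igraph::degree(sg)["S3"] == 0)        # isolated seed retained
  sg2 <- firstNeighborSubnetwork(sg, c("S1", "S3"))
  expect_setequal(igraph::V(sg2)$name, igraph::V(sg)$name)
  expect_equal(igraph::ecount(sg2), igraph::ecount(sg))
  expect_warning(firstNeighborSubnetwork(g, c("S1", "NOPE")), "skipped")
  # star center as seed returns the whole star
  star <- buildAnnotatedGraph(data.frame(gene_a = "H", gene_b = paste0("L", 1:4),
                                         pcor = 0.2, p_value = 0.01,
                                         q_value = 0.01))
  expect_equal(igraph::vcount(firstNeighborSubnetwork(star, "H")), 5L)
})

test_that("edge typing pools clock with regulators and conserves counts", {
  ed <- data.frame(gene_a = c("TF1", "TF1", "S1"),
                   gene_b = c("TF2", "S1", "S2"),
                   pcor = 0.3, p_value = 0.01, q_value = 0.01)
  ann <- data.frame(gene_id = c("TF1", "TF2", "S1", "S2", "CLK"),
                    role = c("regulator", "regulator", "target", "target",
                             "clock"),
                    family = "")
  cls <- classifyEdges(ed, ann)
  expect_equal(unname(cls$counts), c(1L, 1L, 1L))
  expect_equal(sum(cls$counts), 3L)
  # clock-clock and clock-TF are regulator-regulator
  ed2 <- data.frame(gene_a = c("CLK", "CLK"), gene_b = c("TF1", "S1"),
                    pcor = 0.1, p_value = 0.01, q_value = 0.01)
  cls2 <- classifyEdges(ed2, ann)
  expect_equal(cls2$counts[["regulator-regulator"]], 1L)
  expect_equal(cls2$counts[["regulator-target"]], 1L)
  # all-target graph
  ed3 <- data.frame(gene_a = "S1", gene_b = "S2", pcor = 0.1,
                    p_value = 0.01, q_value = 0.01)
  expect_equal(classifyEdges(ed3, ann)$counts[["target-target"]], 1L)
  # counts invariant under role-preserving relabeling
  relab <- c(TF1 = "TFX", TF2 = "TFY", S1 = "SX", S2 = "SY", CLK = "CLKX")
  ed4 <- data.frame(gene_a = relab[ed$gene_a], gene_b = relab[ed$gene_b],
                    pcor = 0.3, p_value = 0.01, q_value = 0.01)
  ann4 <- data.frame(gene_id = unname(relab[ann$gene_id]), role = ann$role,
                     family = "")
  expect_equal(classifyEdges(ed4, ann4)$counts, cls$counts)
})

test_that("edge overlap reproduces shared fractions per type", {
  mk <- function(ed, ann) buildAnnotatedGraph(ed, annotation = ann)
  ann <- data.frame(gene_id = c(paste0("T", 1:8), "S1", "S2"),
                    role = c(rep("regulator", 8), "target", "target"),
                    family = "")
  ed1 <- data.frame(gene_a = c(paste0("T", 1:7), "S1", "T1", "T2"),
                    gene_b = c(paste0("T", 2:8), "S2", "S1", "S2"),
                    pcor = 0.2, p_value = 0.01, q_value = 0.01)
  g1 <- mk(ed1, ann)
  ov <- edgeOverlap(g1, g1)
  expect_true(all(ov$fraction == 1))
  g2 <- mk(ed1[1:7, ], ann)                        # drop 3 edges
  ovp <- edgeOverlap(g1, g2)
  expect_equal(ovp$fraction[ovp$type == "all"], 0.7)
  disj <- mk(data.frame(gene_a = "T1", gene_b = "T8", pcor = 0.1,
                        p_value = 0.1, q_value = 0.1), ann)
  expect_equal(edgeOverlap(disj, g2)$fraction[1], 0)
})
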