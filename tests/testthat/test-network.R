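test_that("network assembly aggregates miRNAs per pair and enforces invariants", {
  tr <- make_triplets(rep("A", 3), rep("B", 3), c("z1", "z2", "z3"),
                      s = c(0.7, 0.8, 0.9))
  net <- build_network(tr)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$mirnas, "z1,z2,z3")
  expect_identical(net$edges$n_mirna, 3L)
  expect_identical(sort(net$nodes$id), c("A", "B"))
  expect_equal(net$edges$max_sensitivity, 0.9)

  # degree sum = 2 x edge count
  tr2 <- make_triplets(c("A", "A", "C"), c("B", "C", "D"),
                       c("z1", "z1", "z2"), s = c(0.9, 0.8, 0.7))
  net2 <- build_network(tr2)
  expect_identical(sum(net2$nodes$degree), 2L * nrow(net2$edges))

  # unordered pairs collapse
  tr3 <- make_triplets(c("A", "B"), c("B", "A"), c("z1", "z2"),
                       s = c(0.9, 0.8))
  expect_identical(nrow(build_network(tr3)$edges), 1L)

  # seed filter and error diagnostics
  trs <- make_triplets(c("A", "C"), c("B", "D"), c("z1", "z2"),
                       s = c(0.9, 0.8), seed_match = c(TRUE, FALSE))
  netf <- build_network(trs, seed_filter = TRUE)
  expect_identical(netf$edges$node1, "A")
  trs$seed_match <- FALSE
  expect_error(build_network(trs, seed_filter = TRUE), "0 with shared")
  self <- make_triplets("A", "A", "z1", s = 0.9)
  expect_error(build_network(self), "self-loop")

  # idempotence: same triplets give identical network tables
  expect_identical(build_network(tr2)$edges, net2$edges)
})

test_that("connected components agree with a union-find oracle on random graphs", {
  two_triangles <- make_triplets(c("A", "B", "A", "P", "Q", "P"),
                                 c("B", "C", "C", "Q", "R", "R"),
                                 paste0("z", 1:6), s = seq(0.5, 1, 0.1))
  comps <- connected_components(build_network(two_triangles))
  expect_length(comps, 2L)
  expect_identical(vapply(comps, function(cc) length(cc$nodes), 1L),
                   c(3L, 3L))
  expect_identical(vapply(comps, function(cc) cc$n_edges, 1L), c(3L, 3L))

  single <- build_network(make_triplets("A", "B", "z1", s = 0.9))
  expect_length(connected_components(single), 1L)
  expect_identical(connected_components(single)[[1]]$nodes, c("A", "B"))

  set.seed(12)
  for (i in 1:100) {
    n_nodes <- sample(5:200, 1)
    n_edges <- sample(1:(2 * n_nodes), 1)
    from <- sprintf("n%03d", sample(n_nodes, n_edges, replace = TRUE))
    to <- sprintf("n%03d", sample(n_nodes, n_edges, replace = TRUE))
    keep <- from != to
    if (!any(keep)) next
    tr <- make_triplets(from[keep], to[keep],
                        sprintf("z%04d", seq_len(sum(keep))), s = 0.9)
    net <- build_network(tr)
    got <- connected_components(net)
    want <- union_find_components(net$nodes$id, net$edges$node1,
                                  net$edges$node2)
    got_sets <- lapply(got, function(cc) cc$nodes)
    want_sets <- lapply(want, sort)
    expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                    vapply(want_sets, paste, "", collapse = ","))
    # per-component edge counts sum to the total
    expect_identical(sum(vapply(got, function(cc) cc$n_edges, 1L)),
                     nrow(net$edges))
  }
})

test_that("hub detection uses strict degree > 5 with deterministic ordering", {
  star <- function(n) {
    make_triplets(rep("HUB", n), paste0("leaf", seq_len(n)),
                  paste0("z", seq_len(n)), s = 0.9)
  }
  expect_identical(find_hubs(build_network(star(6)))$id, "HUB")
  expect_identical(nrow(find_hubs(build_network(star(5)))), 0L)

  two <- rbind(star(6),
               make_triplets(rep("AHUB", 6), paste0("x", 1:6),
                             paste0("w", 1:6), s = 0.9))
  hubs <- find_hubs(build_network(two))
  expect_identical(hubs$id, c("AHUB", "HUB"))   # equal degree: lexicographic
})

test_that("network export writes SIF/TSV/GraphML and TSV import round-trips", {
  tr <- make_triplets(c("A", "A", "C"), c("B", "B", "D"),
                      c("z1", "z2", "z3"), s = c(0.9, 0.85, 0.7))
  net <- build_network(tr)
  d <- withr::local_tempdir()
  paths <- export_network(net, d)
  expect_true(all(file.exists(paths)))

  sif <- readLines(paths[["sif"]])
  expect_length(sif, 3L)                     # one line per triplet
  expect_identical(sif[1], "A z1 B")
  expect_identical(nrow(utils::read.delim(paths[["edges"]])), 2L)

  back <- import_network(paths[["edges"]], paths[["nodes"]])
  expect_equal(back$edges, net$edges)
  expect_equal(back$nodes, net$nodes)

  # SIF switches to tabs when an id contains a space
  tr_sp <- make_triplets("gene A", "gene B", "z 1", s = 0.9)
  p2 <- export_network(build_network(tr_sp), file.path(d, "sp"), "sif")
  expect_identical(readLines(p2[["sif"]]), "gene A\tz 1\tgene B")

  expect_error(export_network(net, d, "dot"), "unknown export")
})
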