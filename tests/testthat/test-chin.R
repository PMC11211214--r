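# chromatin interaction networks: edge filtering, promoter-centric graph
# construction, distance-class labeling vs an exhaustive path oracle

test_that("significant edges: external q filter and builtin quantile rule", {
  entries <- data.table::data.table(
    chrom = "chr1", bin_i = c(1L, 2L, 3L, 4L, 5L), bin_j = c(10L, 11L, 12L, 13L, 14L),
    contact = c(5, 4, 3, 2, 1))
  cm <- contact_map(entries, 5000L)
  loops <- data.table::data.table(chrom = "chr1", bin_i = c(1L, 2L),
                                  bin_j = c(10L, 11L), q = c(0.01, 0.2))
  kept <- call_significant_edges(cm, loops, q_threshold = 0.05)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$contact, 5)
  expect_equal(attr(kept, "mode"), "external")
  expect_error(call_significant_edges(cm, loops, q_threshold = 0), "q_threshold")

  # builtin: one distance bin (all pairs at distance 9 bins), keep 0.4 -> top 2
  blt <- call_significant_edges(cm, NULL, keep_fraction = 0.4,
                                n_distance_bins = 1L)
  expect_equal(sort(blt$contact), c(4, 5))
  expect_equal(attr(blt, "mode"), "builtin")

  empty <- call_significant_edges(contact_map(NULL, 5000L), NULL)
  expect_equal(nrow(empty), 0L)
})

test_that("ChIN construction filters to promoter plus tested enhancers", {
  el <- make_elements("chr1", c(1e6, 2e6, 3e6, 4e6, 5e6),
                      c("tss", "enhancer", "enhancer", "enhancer", "tss"),
                      ids = c("P", "E1", "E2", "X", "P2"))
  edges <- data.table::data.table(id1 = c("P", "E1", "E2"),
                                  id2 = c("E1", "E2", "X"),
                                  weight = c(0.5, 0.4, 0.3))
  ch <- build_chin(edges, el, "P", c("E1", "E2"))
  expect_setequal(ch$nodes$element_id, c("P", "E1", "E2"))
  expect_equal(nrow(ch$edges), 2L)          # E2-X dropped
  expect_setequal(ch$edges$weight, c(0.5, 0.4))  # weights preserved
  expect_error(build_chin(edges, el, "nope", "E1"), "unknown promoter")

  # no tested enhancers -> promoter alone
  solo <- build_chin(edges, el, "P", character(0))
  expect_equal(solo$nodes$element_id, "P")
  expect_equal(nrow(solo$edges), 0L)
})

test_that("distance classes follow enhancer-mediated shortest paths", {
  el <- make_elements("chr1", (1:6) * 1e6,
                      c("tss", "enhancer", "enhancer", "enhancer",
                        "enhancer", "tss"),
                      ids = c("P", "E1", "E2", "E3", "E4", "P2"))
  # chain P-E1-E2-E3, isolated E4
  edges <- data.table::data.table(id1 = c("P", "E1", "E2"),
                                  id2 = c("E1", "E2", "E3"), weight = 1)
  ch <- build_chin(edges, el, "P", c("E1", "E2", "E3", "E4"))
  labs <- label_ep_distance(ch, c("E1", "E2", "E3", "E4"),
                            enhancer_bin = 1:4, promoter_bin = 99L)
  expect_equal(labs, c("e1", "e2", "e3", "einf"))

  # bin equality wins even with no edge
  expect_equal(label_ep_distance(ch, "E4", enhancer_bin = 7L,
                                 promoter_bin = 7L), "e0")

  # a promoter never mediates: P-P2-E5 leaves E5 unreachable
  el2 <- rbind(el, make_elements("chr1", 6.5e6, "enhancer", ids = "E5"))
  edges2 <- data.table::data.table(id1 = c("P", "P2"), id2 = c("P2", "E5"),
                                   weight = 1)
  ch2 <- build_chin(edges2, el2, "P", "E5")
  expect_equal(label_ep_distance(ch2, "E5", 1L, 2L), "einf")

  expect_error(label_ep_distance(ch, "EZ", 1L, 2L), "absent")
})

test_that("labels match exhaustive path enumeration on random graphs", {
  set.seed(42)
  for (trial in 1:60) {
    n <- sample(4:12, 1)
    kinds <- c("tss", sample(c("enhancer", "tss"), n - 1, replace = TRUE,
                             prob = c(0.8, 0.2)))
    ids <- sprintf("n%02d", seq_len(n))
    names(kinds) <- ids
    el <- make_elements("chr1", seq_len(n) * 1e5, kinds, ids = ids)
    m <- sample(0:(n * 2), 1)
    edges <- unique(data.table::data.table(
      id1 = sample(ids, m, replace = TRUE),
      id2 = sample(ids, m, replace = TRUE)))
    edges <- edges[id1 != id2]
    edges[, weight := runif(.N) + 0.1]
    promoter <- ids[1]
    tested <- ids[kinds == "enhancer"]
    if (length(tested) == 0L) next
    ch <- build_chin(edges, el, promoter, tested)
    got <- label_ep_distance(ch, tested, enhancer_bin = seq_along(tested),
                             promoter_bin = 0L)
    want <- vapply(tested, function(tg)
      oracle_chin_label(as.data.frame(edges), as.list(kinds), promoter, tg),
      character(1))
    expect_equal(got, unname(want), info = paste("trial", trial))
  }
})

test_that("adding an edge never worsens any distance class", {
  set.seed(7)
  lev <- c(e0 = 0, e1 = 1, e2 = 2, e3 = 3, einf = 4)
  n <- 8
  ids <- sprintf("n%d", 1:n)
  kinds <- setNames(c("tss", rep("enhancer", n - 1)), ids)
  el <- make_elements("chr1", seq_len(n) * 1e5, kinds, ids = ids)
  edges <- data.table::data.table(id1 = c("n1", "n2"), id2 = c("n2", "n3"),
                                  weight = 1)
  tested <- ids[-1]
  base <- label_ep_distance(build_chin(edges, el, "n1", tested),
                            tested, seq_along(tested), 0L)
  for (k in 1:10) {
    extra <- data.table::data.table(id1 = sample(ids, 1), id2 = sample(ids, 1),
                                    weight = 1)
    if (extra$id1 == extra$id2) next
    more <- rbind(edges, extra)
    after <- label_ep_distance(build_chin(more, el, "n1", tested),
                               tested, seq_along(tested), 0L)
    expect_true(all(lev[after] <= lev[base]))
    edges <- more
    base <- after
  }
})

test_that("simulated pairs classify end to end through the loop-call path", {
  cfg <- sim_config(n_chrom = 2L, chrom_length_bp = 10e6,
                    n_enhancers = 60L, n_tss = 20L, seed = 77L)
  sim <- simulate_ep_dataset(cfg)
  cm <- sim$contacts
  # synthesize an external loop table: the strongest decile gets small q
  e <- cm$entries
  q <- ifelse(e$contact >= quantile(e$contact, 0.9), 0.01, 0.5)
  f <- withr::local_tempfile(fileext = ".bedpe")
  bs <- cm$bin_size
  data.table::fwrite(data.table::data.table(
    e$chrom, e$bin_i * bs, (e$bin_i + 1L) * bs,
    e$chrom, e$bin_j * bs, (e$bin_j + 1L) * bs, q),
    f, sep = "\t", col.names = FALSE)
  loops <- read_loops(f, bs)
  sig <- call_significant_edges(cm, loops, q_threshold = 0.05)
  expect_equal(attr(sig, "mode"), "external")
  expect_equal(nrow(sig), sum(q < 0.05))
  el_edges <- edges_to_element_pairs(sig, sim$elements, bs)
  labs <- classify_ep_pairs(sim$ep, sim$elements, el_edges)
  expect_true(all(labs %in% c("e0", "e1", "e2", "e3", "einf")))
  # e0 exactly when the pair shares a contact bin
  expect_equal(labs == "e0", sim$ep$enh_bin == sim$ep$tss_bin)
  # every e1 pair is backed by a significant edge between its elements
  e1 <- which(labs == "e1")
  key <- paste(pmin(el_edges$id1, el_edges$id2),
               pmax(el_edges$id1, el_edges$id2))
  expect_true(all(paste(pmin(sim$ep$enhancer_id[e1], sim$ep$tss_id[e1]),
                        pmax(sim$ep$enhancer_id[e1], sim$ep$tss_id[e1]))
                  %in% key))
  part <- partition_by_class(labs)
  expect_equal(length(part), nrow(sim$ep))
  expect_equal(sum(table(part)), nrow(sim$ep))
})

test_that("class partition is disjoint and exhaustive", {
  labs <- c("e0", "e1", "e2", "einf")
  p <- partition_by_class(labs)
  expect_equal(as.vector(table(p)), c(2L, 2L))
  expect_equal(sum(table(p)), length(labs))
  expect_true(all(partition_by_class(rep("einf", 3)) == "e2plus"))
  expect_error(partition_by_class("e9"))
})
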