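# candidate enumeration and every feature family, checked against hand
# values and a naive all-pairs oracle

test_that("candidate pairing applies the half-window rule on each side", {
  el <- make_elements("chr1", c(9e6, 14e6, 10e6), c("enhancer", "enhancer", "tss"))
  ep <- ep_candidates(el, window_bp = 5e6)
  # 1 Mb away is in; 4 Mb away exceeds the 2.5 Mb half-window
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$enhancer_id, "e01")
  expect_equal(ep$distance, 1e6)

  # other chromosome excluded
  el2 <- rbind(el, make_elements("chr2", 10e6, "enhancer", ids = "eX"))
  expect_false("eX" %in% ep_candidates(el2, 5e6)$enhancer_id)

  # exactly at the half-window: included (closed boundary)
  el3 <- make_elements("chr1", c(10e6 + 2.5e6, 10e6), c("enhancer", "tss"))
  expect_equal(nrow(ep_candidates(el3, 5e6)), 1L)

  # no enhancers -> empty table, no error
  expect_equal(nrow(ep_candidates(make_elements("chr1", 1e6, "tss"), 5e6)), 0L)
})

test_that("ABC scores normalize to one per TSS and handle degenerate cases", {
  el <- make_elements("chr1", c(100e3, 200e3, 150e3),
                      c("enhancer", "enhancer", "tss"),
                      normalized_H3K27ac_e = c(2, 1, NA))
  cm <- make_contacts(el, data.frame(id1 = c("e01", "e02"), id2 = "p01",
                                     contact = c(0.3, 0.1)))
  ep <- ep_attach_contact(ep_candidates(el, 5e6), cm)
  s <- abc_score(ep, el)
  expect_equal(sort(s, decreasing = TRUE), c(0.6 / 0.7, 0.1 / 0.7))
  expect_equal(sum(s), 1)

  # single candidate with positive product -> 1
  one <- ep[ep$enhancer_id == "e01", ]
  expect_equal(abc_score(one, el), 1)

  # all contacts zero -> all scores zero
  ep0 <- data.table::copy(ep)[, contact := 0]
  expect_equal(abc_score(ep0, el), c(0, 0))

  el_neg <- data.table::copy(el)[, normalized_H3K27ac_e := c(-1, 1, NA)]
  expect_error(abc_score(ep, el_neg), "negative")
})

test_that("relative-contact features match hand values", {
  el <- make_elements("chr1", c(100e3, 200e3, 300e3, 150e3),
                      c("enhancer", "enhancer", "enhancer", "tss"))
  cm <- make_contacts(el, data.frame(id1 = c("e01", "e02", "e03"),
                                     id2 = "p01",
                                     contact = c(0.5, 0.3, 0.1)))
  ep <- ep_attach_contact(ep_candidates(el, 5e6), cm)
  rel <- contact_relative_features(ep)
  i <- which(ep$enhancer_id == "e02")   # focal 0.3 among (0.5, 0.3, 0.1)
  expect_equal(rel$diff.from.max.contact.to.TSS[i], 0.2)
  expect_equal(rel$rank.contact.to.TSS[i], 2)
  # the maximum has zero difference
  j <- which(ep$enhancer_id == "e01")
  expect_equal(rel$diff.from.max.contact.to.TSS[j], 0)
  expect_equal(rel$rank.contact.to.TSS[j], 1)
  # enhancer-side neighborhoods are singletons here
  expect_equal(rel$diff.from.max.contact.from.enhancer, rep(0, 3))
  expect_equal(rel$rank.contact.from.enhancer, rep(1, 3))
})

test_that("remaining-contact sums exclude the focal partner", {
  el <- make_elements("chr1", c(1000e3, 900e3, 1100e3, 1200e3),
                      c("enhancer", "tss", "tss", "tss"))
  cm <- make_contacts(el, data.frame(id1 = "e01",
                                     id2 = c("p01", "p02", "p03"),
                                     contact = c(0.3, 0.2, 0.05)))
  ep <- ep_attach_contact(ep_candidates(el, 5e6), cm)
  rem <- remaining_contact_sums(ep)
  i <- which(ep$tss_id == "p01")
  expect_equal(rem$remaining.TSS.contact.from.enhancer[i], 0.25)
  # permutation invariance
  perm <- sample(nrow(ep))
  rem2 <- remaining_contact_sums(ep[perm])
  expect_equal(rem2$remaining.TSS.contact.from.enhancer,
               rem$remaining.TSS.contact.from.enhancer[perm])
})

test_that("density counts are region totals including the focal element", {
  el <- make_elements("chr1", c(8e6, 12e6, 16e6, 10e6),
                      c("enhancer", "enhancer", "enhancer", "tss"))
  ep <- ep_candidates(el, 5e6)
  d <- density_counts(ep, el, 5e6)
  expect_equal(unique(d$Enhancer.count.near.TSS), 2L)  # 8 and 12 Mb in range
  expect_true(all(d$Enhancer.count.near.TSS >= 1L))
  # counts non-decreasing as the window grows
  d2 <- density_counts(ep, el, 20e6)
  expect_true(all(d2$Enhancer.count.near.TSS >= d$Enhancer.count.near.TSS))
})

test_that("TF presence uses half-open overlap and the promoter flank", {
  el <- data.table::data.table(
    chrom = "chr1", start = c(150L, 1000L), end = c(250L, 1001L),
    element_id = c("e01", "p01"), kind = c("enhancer", "tss"))
  ep <- ep_candidates(el, 5e6)
  peaks <- list(
    A = data.table::data.table(chrom = "chr1", start = 100L, end = 200L),
    B = data.table::data.table(chrom = "chr1", start = 100L, end = 150L),
    C = data.table::data.table(chrom = "chr1", start = 1400L, end = 1450L))
  tf <- tf_presence(ep, el, peaks, tss_flank_bp = 500L)
  expect_equal(tf$A_e, 1L)   # [100,200) overlaps [150,250)
  expect_equal(tf$B_e, 0L)   # half-open abutment at 150
  expect_equal(tf$C_TSS, 1L) # peak at TSS+400 within the 500 bp flank
  expect_equal(tf$C_e, 0L)
  expect_error(tf_presence(ep, el, setNames(peaks[c(1, 1)], c("A", "A"))),
               "duplicate")
})

test_that("labeling follows the adjusted-p rule with direction", {
  ep <- data.table::data.table(
    enhancer_id = c("e1", "e2", "e3", "e4"), tss_id = "p1",
    adj_p = c(0.05, 0.05, NA, 0.2),
    effect_direction = c("down", "up", "down", "down"))
  lab <- label_positives(ep, 0.1)
  expect_equal(nrow(lab), 3L)            # NA row excluded
  expect_equal(lab$label, c(1L, 0L, 0L)) # up-regulation is not positive
  expect_error(label_positives(ep, 1.5), "alpha")
})

test_that("assembly keys rows, records provenance, rejects name clashes", {
  el <- make_elements("chr1", c(100e3, 200e3, 150e3),
                      c("enhancer", "enhancer", "tss"))
  cm <- make_contacts(el, data.frame(id1 = c("e01", "e02"), id2 = "p01",
                                     contact = c(0.3, 0.1)))
  ep <- ep_attach_contact(ep_candidates(el, 5e6), cm)
  fx <- assemble_features(ep, relative = contact_relative_features(ep))
  expect_equal(names(fx)[1:4],
               c("enhancer_id", "tss_id", "distance", "contact"))
  prov <- attr(fx, "provenance")
  expect_equal(unname(prov["rank.contact.to.TSS"]), "relative")
  expect_error(
    assemble_features(ep, a = data.table::data.table(contact = 1:2)),
    "conflicting")
  # enabling only distance+contact -> exactly those feature columns
  expect_equal(ncol(assemble_features(ep)) - 2L, 2L)
})

test_that("production features equal the naive all-pairs oracle", {
  for (seed in 1:3) {
    cfg <- sim_config(n_chrom = 2L, chrom_length_bp = 8e6,
                      n_enhancers = 30L, n_tss = 12L, seed = seed)
    el <- simulate_elements(cfg)$elements
    cm <- simulate_contacts(el, cfg)
    ep <- ep_attach_contact(ep_candidates(el, 5e6), cm)
    prod <- cbind(ep[, .(enhancer_id, tss_id, distance, contact)],
                  contact_relative_features(ep),
                  remaining_contact_sums(ep),
                  density_counts(ep, el, 5e6))
    data.table::setorderv(prod, c("tss_id", "enhancer_id"))
    orc <- oracle_features(el, cm, 5e6)
    expect_equal(nrow(prod), nrow(orc))
    for (cc in setdiff(names(orc), c("enhancer_id", "tss_id")))
      expect_equal(prod[[cc]], orc[[cc]], tolerance = 1e-12,
                   info = paste(seed, cc))
    # ABC against its own brute-force sum
    act <- as.list(setNames(el$normalized_H3K27ac_e, el$element_id))
    expect_equal(abc_score(ep, el), oracle_abc(ep, act))
  }
})
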