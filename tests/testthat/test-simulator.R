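test_that("metaphase simulation respects event bounds and determinism", {
  m0 <- simulate_metaphase(male_kar, bias_model(), 0, seed = 1)
  expect_equal(nrow(m0$events), 0)
  expect_equal(length(m0$structures), 8) # 8 singleton chains
  expect_true(all(vapply(m0$structures, function(s) s$type, "") == "chain"))

  m8 <- simulate_metaphase(male_kar, bias_model(), 8, seed = 2)
  expect_equal(nrow(m8$events), 8) # saturation: all 16 telomeres consumed
  expect_equal(sum(vapply(m8$structures, function(s) s$n_events, 0L)), 8)

  expect_error(simulate_metaphase(male_kar, bias_model(), 9), "n_events")
  expect_identical(
    simulate_metaphase(male_kar, bias_model(het_weight = 3), 4, seed = 9)$events,
    simulate_metaphase(male_kar, bias_model(het_weight = 3), 4, seed = 9)$events
  )
})

test_that("derive_structures reconstructs the worked configurations", {
  # ring autosome: both ends of one chromosome-2 copy fused
  s <- derive_structures(data.frame(end1 = "2L.1", end2 = "2R.1"), female_kar)
  rings <- Filter(function(x) x$type == "ring", s)
  expect_length(rings, 1)
  expect_equal(rings[[1]]$chromosomes, "2")
  expect_equal(rings[[1]]$n_events, 1L)
  expect_length(s, 8) # ring + 7 singleton chains

  # YL-YS fusion: ring Y of size one
  sy <- derive_structures(data.frame(end1 = "YL.1", end2 = "YS.1"), male_kar)
  ry <- Filter(function(x) x$type == "ring", sy)
  expect_equal(ry[[1]]$chromosomes, "Y")

  # tricentric 4-Y-X chain from 4R-YS and YL-XR fusions
  st <- derive_structures(
    data.frame(end1 = c("4R.1", "YL.1"), end2 = c("YS.1", "XR.1")), male_kar
  )
  tri <- Filter(function(x) x$n_chromosomes == 3, st)
  expect_length(tri, 1)
  expect_equal(tri[[1]]$type, "chain")
  expect_equal(tri[[1]]$chromosomes, c("4", "Y", "X"))
  expect_length(st, 1 + 5) # plus five singleton chains

  # XR-4 fusion plus an A-A-A-A multicentric chain (3 junctions)
  ev <- data.frame(
    end1 = c("XR.1", "2R.1", "2R.2", "3R.1"),
    end2 = c("4L.1", "2L.2", "3L.1", "3L.2")
  )
  sa <- derive_structures(ev, female_kar)
  lens <- vapply(sa, function(x) x$n_chromosomes, 0L)
  chain4 <- sa[[which(lens == 4)]]
  expect_equal(chain4$chromosomes, c("2", "2", "3", "3"))
  expect_equal(chain4$n_events, 3L)

  expect_error(
    derive_structures(
      data.frame(end1 = c("XR.1", "XR.1"), end2 = c("4L.1", "2L.1")),
      female_kar
    ),
    "more than one fusion event"
  )
  expect_error(
    derive_structures(data.frame(end1 = "XX.9", end2 = "4L.1"), female_kar),
    "unknown telomere"
  )
})

test_that("structure accounting holds over random metaphases", {
  set.seed(33)
  for (i in 1:25) {
    n_ev <- sample(0:8, 1)
    m <- simulate_metaphase(male_kar, bias_model(het_weight = runif(1, 0.2, 5)),
      n_ev)
    per_struct <- vapply(m$structures, function(s) {
      if (s$type == "chain") s$n_chromosomes - 1L else s$n_chromosomes
    }, 0L)
    expect_equal(sum(per_struct), n_ev)
    # every chromosome copy in exactly one structure
    copies <- unlist(lapply(m$structures, function(s) s$copies))
    expect_setequal(copies, unique(male_kar$telomeres$copy))
    expect_false(anyDuplicated(copies) > 0)
  }
})

test_that("count_fused_telomeres applies the 2-FTs-per-fusion convention", {
  m <- list(
    karyotype = male_kar,
    events = data.frame(end1 = "XR.1", end2 = "4L.1", association = "DTA"),
    structures = NULL
  )
  class(m) <- "metaphase"
  ct <- count_fused_telomeres(m)
  expect_equal(ct$counts, c(A = 0, XL = 0, XR = 1, Fourth = 1, Y = 0))
  expect_equal(ct$n_TFs, 1)
  expect_equal(sum(ct$counts), 2 * ct$n_TFs)

  # XR-4 fusion + A-A-A-A chain: {XR 1, Fourth 1, A 6}, 4 fusions
  m2 <- m
  m2$karyotype <- female_kar
  m2$events <- data.frame(
    end1 = c("XR.1", "2R.1", "2R.2", "3R.1"),
    end2 = c("4L.1", "2L.2", "3L.1", "3L.2"),
    association = "DTA"
  )
  ct2 <- count_fused_telomeres(m2)
  expect_equal(ct2$counts, c(A = 6, XL = 0, XR = 1, Fourth = 1))
  expect_equal(ct2$n_TFs, 4)

  # empty event lists give an all-zero table with n_cells set
  m3 <- simulate_metaphase(male_kar, bias_model(), 0, seed = 5)
  ct3 <- count_fused_telomeres(list(m3, m3))
  expect_equal(sum(ct3$counts), 0)
  expect_equal(ct3$n_cells, 2)

  # ring Y tallied per fused Y telomere
  m4 <- m
  m4$events <- data.frame(end1 = "YL.1", end2 = "YS.1", association = "DTA")
  ct4 <- count_fused_telomeres(m4)
  expect_equal(ct4$y_fusions, 2)
  expect_equal(ct4$y_rings, 2)
})

test_that("simulate_experiment is seed-deterministic and conserves counts", {
  b <- bias_model(het_weight = 2, events_per_cell_mean = 1.5)
  a <- simulate_experiment(male_kar, b, 400, seed = 77)
  b2 <- simulate_experiment(male_kar, b, 400, seed = 77)
  expect_identical(a$counts, b2$counts)
  expect_identical(a$y_rings, b2$y_rings)
  expect_equal(sum(a$counts), 2 * a$n_TFs)
  expect_equal(a$sta + a$dta, a$n_TFs)
  expect_lte(a$y_rings, a$y_fusions)
})

test_that("null simulation converges to the analytic frequencies", {
  ct <- simulate_experiment(male_kar, bias_model(), 4000, seed = 101)
  freq <- expected_involvement_frequencies(male_kar)
  emp <- ct$counts / sum(ct$counts)
  se <- sqrt(freq * (1 - freq) / sum(ct$counts))
  expect_true(all(abs(emp - freq) <= 3 * se))
})

test_that("strong bias drives the heterochromatic FT fraction towards 1", {
  ct <- simulate_experiment(male_kar, bias_model(het_weight = 1e6), 300,
    seed = 6)
  eh <- aggregate_eu_het(ct)
  expect_gt(eh[["Het"]] / sum(eh), 0.9)
})

test_that("sister fusions and Ha-DTA censoring behave as documented", {
  b <- bias_model(allow_sister = TRUE, events_per_cell_mean = 2)
  ct <- simulate_experiment(male_kar, b, 500, seed = 13)
  expect_equal(sum(ct$counts), 2 * ct$n_TFs) # sister events still count 2 FTs

  m <- simulate_metaphase(male_kar,
    bias_model(het_weight = 50, p_G1 = 0, ha_dta_censoring = TRUE), 4,
    seed = 3)
  tel <- male_kar$telomeres
  hetgrp <- tel$label[tel$category %in% c("XR", "Fourth", "Y")]
  both_het <- m$events$end1 %in% hetgrp & m$events$end2 %in% hetgrp
  expect_true(all(m$events$association[both_het] == "DTA"))
  expect_true(all(m$events$association[!both_het] == "STA")) # p_G1 = 0
})
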