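test_that("pooling partitions every individual once, last pool short", {
  ids <- sprintf("i%04d", 1:2610)
  pools <- make_pools(ids, 4, seed = 1)
  expect_equal(length(unique(pools$pool)), 653L)  # 652 of 4 + one of 2
  sizes <- table(pools$pool)
  expect_equal(sum(sizes == 4), 652L)
  expect_equal(sum(sizes == 2), 1L)
  expect_setequal(pools$indiv, ids)
  expect_identical(pools, make_pools(ids, 4, seed = 1))
  expect_false(identical(pools, make_pools(ids, 4, seed = 2)))
  expect_equal(length(unique(make_pools(ids[1:8], 8, seed = 1)$pool)), 1L)
  expect_error(make_pools(ids, 9), "\\[1, 8\\]")
  expect_error(make_pools(character(0), 4), "empty")
})

test_that("heteroduplexes form only when the pool mixes ref and alt alleles", {
  z4 <- function(...) stats::setNames(c(...), paste0("i", seq_along(c(...))))
  expect_false(heteroduplex_present(z4("hom_ref", "hom_ref", "hom_ref", "hom_ref")))
  expect_false(heteroduplex_present(z4("hom_alt", "hom_alt", "hom_alt", "hom_alt")))
  expect_true(heteroduplex_present(z4("het", "hom_ref", "hom_ref", "hom_ref")))
  expect_true(heteroduplex_present(z4("hom_alt", "hom_ref", "hom_ref", "hom_ref")))
  expect_true(heteroduplex_present(z4("het")))
  expect_error(heteroduplex_present(stats::setNames(NA_character_, "i1")),
               "missing genotype")
  expect_error(heteroduplex_present(z4("aa")), "invalid zygosity")
  expect_error(heteroduplex_present(character(0)), "empty")
})

test_that("amplicons require room for the end trim", {
  a <- amplicon_spec("amp", 1000, 2496)
  expect_equal(a$full_length, 1496L)
  expect_equal(c(a$eff_start, a$eff_end), c(1100L, 2396L))
  expect_error(amplicon_spec("tiny", 0, 200), "effective region")
})

test_that("default method sensitivities reflect the three gel systems", {
  expect_equal(detection_method("page_silver")$sensitivity, 1.0)
  expect_equal(detection_method("agarose_etbr")$sensitivity, 14 / 15)
  expect_equal(detection_method("page_etbr")$sensitivity, 11 / 15)
  expect_equal(detection_method("page_etbr", 0.5)$sensitivity, 0.5)
  expect_error(detection_method("page_silver", 1.5), "probability")
})

test_that("calls respect the dead zones, fragment arithmetic, and deconvolution", {
  # one het carrier at offset 300 and one inside the 100 bp dead zone
  gt <- data.frame(
    line = c("p001", "p002"),
    indiv = c("p001-1", "p002-1"),
    pos = c(300L, 50L), ref = "G", alt = "A",
    zygosity = "het")
  filler <- data.frame(line = sprintf("p%03d", 3:8),
                       indiv = sprintf("p%03d-1", 3:8),
                       pos = 300L, ref = "G", alt = "A",
                       zygosity = "hom_ref")
  pop <- manual_population(rbind(gt, filler))
  pools <- make_pools(pop$individuals$indiv, 4, seed = 3)
  amp <- amplicon_spec("amp", 0, 1496)
  calls <- screen_amplicon(pop, amp, pools, detection_method("page_silver"),
                           seed = 5)
  expect_equal(nrow(calls), 1L)           # dead-zone mutation never called
  expect_equal(calls$site, 300L)
  expect_equal(calls$fragment_a, 300L)
  expect_equal(calls$fragment_b, 1196L)
  expect_equal(calls$fragment_a + calls$fragment_b, amp$full_length)
  expect_equal(calls$indiv, "p001-1")
  # zero sensitivity silences everything
  none <- screen_amplicon(pop, amp, pools, detection_method("page_silver", 0),
                          seed = 5)
  expect_equal(nrow(none), 0L)
})

test_that("a homozygous-mutant carrier is recovered via wild-type spiking, but an all-mutant pool is silent", {
  gt <- data.frame(line = c("p001", sprintf("p%03d", 2:4)),
                   indiv = c("p001-1", sprintf("p%03d-1", 2:4)),
                   pos = 500L, ref = "C", alt = "T",
                   zygosity = c("hom_alt", rep("hom_ref", 3)))
  pop <- manual_population(gt)
  pools <- data.frame(pool = "pool0001", indiv = pop$individuals$indiv)
  amp <- amplicon_spec("amp", 0, 1496)
  calls <- screen_amplicon(pop, amp, pools, detection_method("page_silver"),
                           seed = 1)
  expect_equal(calls$indiv, "p001-1")
  expect_equal(calls$zygosity, "hom_alt")
  # all four members homozygous mutant: no wild-type strand in the pool
  gt$zygosity <- "hom_alt"
  silent <- screen_amplicon(manual_population(gt), amp, pools,
                            detection_method("page_silver"), seed = 1)
  expect_equal(nrow(silent), 0L)
})

test_that("call count is monotone in sensitivity and calls are sound", {
  rep1 <- screen_replicate(41, n_lines = 120L, siblings = 2L,
                           n_amplicons = 8L)
  calls <- do.call(rbind, rep1$calls)
  # soundness: every call is a truth mutation inside an effective region
  truth_key <- paste(rep1$pop$truth$line, rep1$pop$truth$pos)
  expect_true(all(paste(calls$line, calls$site) %in% truth_key))
  for (a in rep1$amplicons) {
    in_amp <- calls[calls$amplicon == a$name, ]
    expect_true(all(in_amp$site >= a$eff_start & in_amp$site < a$eff_end))
    expect_true(all(in_amp$fragment_a + in_amp$fragment_b == a$full_length))
  }
  # monotone in sensitivity at fixed seed and truth
  n_calls <- vapply(c(0, 0.3, 0.7, 1), function(s) {
    sum(vapply(rep1$amplicons, function(a) {
      nrow(screen_amplicon(rep1$pop, a, rep1$pools,
                           detection_method("page_silver", s),
                           seed = 41 + 3000L + a$start))
    }, integer(1)))
  }, numeric(1))
  expect_true(all(diff(n_calls) >= 0))
  expect_equal(n_calls[1], 0)
})

test_that("a perfect screen of all-het carriers recovers exactly the effective-region truth", {
  rep1 <- screen_replicate(43, n_lines = 80L, siblings = 2L, n_amplicons = 8L)
  pop <- all_het_population(rep1$pop)
  found <- unique(do.call(rbind, lapply(rep1$amplicons, function(a) {
    screen_amplicon(pop, a, rep1$pools, detection_method("page_silver"),
                    seed = 7)[, c("line", "site")]
  })))
  in_eff <- Reduce(`|`, lapply(rep1$amplicons, function(a) {
    pop$truth$pos >= a$eff_start & pop$truth$pos < a$eff_end
  }))
  want <- unique(data.frame(line = pop$truth$line[in_eff],
                            site = pop$truth$pos[in_eff]))
  expect_setequal(paste(found$line, found$site), paste(want$line, want$site))
})

test_that("screen mutation tallies dedupe per line or per individual", {
  calls <- data.frame(amplicon = "a", site = c(10L, 10L, 10L, 20L),
                      line = c("p1", "p1", "p2", "p1"),
                      indiv = c("p1-1", "p1-2", "p2-1", "p1-1"))
  expect_equal(count_screen_mutations(calls), 3L)
  expect_equal(count_screen_mutations(calls, "individual"), 4L)
  expect_equal(count_screen_mutations(calls[0, ]), 0L)
})
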