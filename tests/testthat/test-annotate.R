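# Synthetic three-exon gene used throughout: 5 bp pad, 12 bp exon,
# 8 bp intron (GT..AG), 12 bp exon, 10 bp intron, 12 bp exon, 5 bp pad.
# CDS codons: ATG GGA TGG GGT | CCT AAA CAG GAT | CTG TGG TCA GCC
toy_ref <- function() {
  reference_sequence("toy", paste0(
    "TTTTT", "ATGGGATGGGGT", "GTAAAAAG", "CCTAAACAGGAT",
    "GTCCCCCCAG", "CTGTGGTCAGCC", "TTTTT"))
}
toy_exons <- data.frame(start = c(5L, 25L, 47L), end = c(17L, 37L, 59L))
toy_model <- function(strand = "+") gene_model("toy", toy_exons, strand)

test_that("transition typing flags everything but C>T and G>A as non-canonical", {
  expect_equal(classify_transition("C", "T"), "C>T")
  expect_equal(classify_transition("G", "A"), "G>A")
  expect_equal(classify_transition("A", "G"), "non_canonical")
  expect_equal(classify_transition("T", "A"), "non_canonical")
  expect_error(classify_transition("C", "C"), "differ")
  expect_error(classify_transition("C", "N"), "single bases")
})

test_that("coding substitutions classify as silent, missense or nonsense with protein notation", {
  m <- toy_model(); r <- toy_ref()
  # codon 10 TGG -> TGA: stop gained
  non <- classify_effect(52L, "G", "A", m, r)
  expect_equal(non$class, "nonsense")
  expect_equal(non$protein, "W10*")
  # codon 2 GGA -> GAA
  mis <- classify_effect(9L, "G", "A", m, r)
  expect_equal(mis$class, "missense")
  expect_equal(mis$protein, "G2E")
  # codon 4 third position GGT -> GGC
  sil <- classify_effect(16L, "T", "C", m, r)
  expect_equal(sil$class, "silent")
  expect_equal(sil$protein, "G4G")
})

test_that("intronic positions split into splice-junction (2 bp) and plain intron", {
  m <- toy_model(); r <- toy_ref()
  # donor side of intron 1 (positions 17, 18 = GT)
  expect_equal(classify_effect(17L, "G", "A", m, r)$class, "splice_junction")
  expect_equal(classify_effect(18L, "T", "C", m, r)$class, "splice_junction")
  expect_equal(classify_effect(19L, "A", "G", m, r)$class, "intron")
  # acceptor side of intron 1 (positions 23, 24 = AG)
  expect_equal(classify_effect(24L, "G", "A", m, r)$class, "splice_junction")
  expect_equal(classify_effect(23L, "A", "G", m, r)$class, "splice_junction")
  expect_equal(classify_effect(22L, "A", "G", m, r)$class, "intron")
  expect_true(is.na(classify_effect(19L, "A", "G", m, r)$protein))
})

test_that("every in-region position gets exactly one of the five classes", {
  m <- toy_model(); r <- toy_ref()
  b <- strsplit(r$residues, "")[[1]]
  classes <- c("intron", "silent", "missense", "nonsense", "splice_junction")
  for (pos in 5:58) {
    ref <- b[pos + 1]
    alt <- setdiff(c("A", "G"), ref)[1]
    cls <- classify_effect(pos, ref, alt, m, r)$class
    expect_true(cls %in% classes)
  }
})

test_that("effect calls are invariant under reverse-complement representation", {
  r_plus <- toy_ref(); m_plus <- toy_model()
  n <- r_plus$length
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  r_minus <- reference_sequence("toy_rc", paste(
    rev(unname(comp[strsplit(r_plus$residues, "")[[1]]])), collapse = ""))
  ex_rc <- data.frame(start = n - toy_exons$end, end = n - toy_exons$start)
  m_minus <- gene_model("toy_rc", ex_rc, strand = "-")
  cases <- data.frame(pos = c(52L, 9L, 16L, 8L),
                      ref = c("G", "G", "T", "G"),
                      alt = c("A", "A", "C", "T"))
  for (i in seq_len(nrow(cases))) {
    plus <- classify_effect(cases$pos[i], cases$ref[i], cases$alt[i],
                            m_plus, r_plus)
    minus <- classify_effect(n - 1L - cases$pos[i],
                             unname(comp[cases$ref[i]]),
                             unname(comp[cases$alt[i]]),
                             m_minus, r_minus)
    expect_equal(minus, plus)
  }
})

test_that("misdeclared reference bases and out-of-region sites are rejected", {
  m <- toy_model(); r <- toy_ref()
  expect_error(classify_effect(9L, "C", "T", m, r), "reference mismatch")
  expect_error(classify_effect(2L, "T", "C", m, r), "outside the modeled region")
  expect_error(classify_effect(60L, "T", "C", m, r), "outside the modeled region")
})

test_that("sibling repeats collapse within lines only", {
  tab <- load_jinmai47_tables()$mutations
  dd <- dedupe_sibling_repeats(tab)
  expect_equal(nrow(dd$unique), 15L)
  expect_equal(nrow(dd$groups), 3L)
  expect_setequal(dd$groups$line, c("p20", "p127", "p190"))
  expect_true(all(dd$groups$n_records == 2L))
  # all-distinct input passes through
  distinct <- tab[!duplicated(paste(tab$line, tab$pos)), ]
  dd2 <- dedupe_sibling_repeats(distinct)
  expect_equal(nrow(dd2$unique), nrow(distinct))
  expect_equal(nrow(dd2$groups), 0L)
  # the same substitution in two different lines stays distinct
  two <- data.frame(line = c("pA", "pB"), indiv = c("pA-1", "pB-1"),
                    pos = 100L, ref = "C", alt = "T")
  expect_equal(nrow(dedupe_sibling_repeats(two)$unique), 2L)
})

test_that("the deduplicated mutation records reproduce the published spectrum and effect tallies", {
  tab <- load_jinmai47_tables()$mutations
  uniq <- dedupe_sibling_repeats(tab)$unique
  trans <- classify_transition(uniq$ref, uniq$alt)
  expect_equal(sum(trans == "C>T"), 9L)
  expect_equal(sum(trans == "G>A"), 6L)
  expect_false(any(trans == "non_canonical"))
  uniq$effect <- effect_from_notation(uniq$amino_acid_change)
  s <- summarize_effects(uniq)
  expect_equal(unname(s$effects[c("silent", "missense", "intron")]),
               c(4L, 6L, 5L))
  expect_equal(unname(s$effects["nonsense"] + s$effects["splice_junction"]), 0L)
  expect_equal(sum(s$zygosity), 15L)
})

test_that("effect summaries handle empty input and match simulator truth labels", {
  empty <- summarize_effects(data.frame())
  expect_true(all(empty$effects == 0L))
  # simulated mutations annotated against the toy gene tally consistently
  r <- toy_ref(); m <- toy_model()
  mu <- induce_ems_mutations(r, 1 / 30, seed = 12)
  mu <- mu[mu$pos >= 5L & mu$pos < 59L, ]
  ann <- annotate_mutations(mu, m, r)
  s <- summarize_effects(ann)
  expect_equal(sum(s$effects), nrow(ann))
  expect_equal(unname(s$effects["intron"]), sum(ann$effect == "intron"))
})

test_that("nucleotide-change notation parses and round-trips coordinates", {
  p <- parse_nucleotide_change(c("C1687T", "G2779A"))
  expect_equal(p$pos, c(1686L, 2778L))  # 0-based internally
  expect_equal(p$ref, c("C", "G"))
  expect_equal(p$alt, c("T", "A"))
  expect_error(parse_nucleotide_change("C16X"), "malformed")
  expect_equal(effect_from_notation(c("Intron", "S242S", "T438M", "W10*")),
               c("intron", "silent", "missense", "nonsense"))
})
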