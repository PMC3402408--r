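# Shared builders for the test suite. Everything is generated in code;
# no binary fixtures.

# Population object with fully specified genotypes (bypasses breeding),
# for deterministic screen tests. `genotypes` needs columns
# line, indiv, pos, ref, alt, zygosity.
manual_population <- function(genotypes, reference = NULL) {
  truth <- unique(genotypes[, c("line", "pos", "ref", "alt")])
  truth$sector <- 1L
  structure(
    list(reference = reference,
         individuals = unique(data.frame(line = genotypes$line,
                                         indiv = genotypes$indiv,
                                         sector = 1L)),
         genotypes = genotypes,
         truth = truth[, c("line", "sector", "pos", "ref", "alt")]),
    class = "population"
  )
}

# Population in which every sampled individual is heterozygous for every
# mutation of its line (the all-carrier limit where a perfect screen must
# recover truth exactly).
all_het_population <- function(pop) {
  gt <- pop$genotypes
  gt$zygosity <- "het"
  pop$genotypes <- gt
  pop
}

# One recovery replicate: simulate, pool, screen every amplicon at a given
# sensitivity, return per-amplicon screen results.
screen_replicate <- function(seed, density = 1 / 47000, n_lines = 512L,
                             siblings = 1L, ref_len = 30000L,
                             n_amplicons = 16L, amp_len = 1700L,
                             method = detection_method("page_silver")) {
  ref <- generate_reference(ref_len, 0.45, seed = seed + 1000L)
  cfg <- sim_config(seed = seed, target_density = density, n_m1 = n_lines,
                    siblings_per_line = siblings)
  pop <- simulate_population(ref, cfg)
  pools <- make_pools(pop$individuals$indiv, 4, seed = seed + 2000L)
  amps <- lapply(seq_len(n_amplicons), function(i) {
    amplicon_spec(sprintf("a%02d", i), (i - 1L) * amp_len, i * amp_len)
  })
  calls <- lapply(amps, function(a) {
    screen_amplicon(pop, a, pools, method, seed = seed + 3000L + a$start)
  })
  list(pop = pop, amplicons = amps, pools = pools, calls = calls,
       results = mapply(function(a, cl) {
         amplicon_screen_result(a$name, a$full_length,
                                nrow(pop$individuals),
                                count_screen_mutations(cl))
       }, amps, calls, SIMPLIFY = FALSE))
}
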