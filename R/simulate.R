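#' Simulation configuration
#'
#' Collects the parameters of the forward mutagenesis/breeding simulator.
#'
#' @param seed master seed; every random stream in a run is derived from it.
#' @param target_density expected mutations per bp (e.g. `1/47000` for one
#'   mutation per 47 kb). Interpreted on the generation named by
#'   `density_basis`.
#' @param n_m1 number of M1 plants (mutagenized seed plants).
#' @param sectors_per_m1 independent meristem sectors per M1 plant.
#'   Mutagenesis of a multicellular embryo makes the M1 plant chimeric:
#'   spikes arising from different meristem cells carry different mutation
#'   sets. Default 1 (chimerism is rare in practice but documented).
#' @param siblings_per_line M2 individuals sampled per M1 line (default 2).
#' @param pool_size individuals per screening pool, 1--8 (default 4;
#'   non-denaturing PAGE with silver staining can resolve eightfold pools).
#' @param context_bias_weight multiplicative preference for eligible G:C
#'   sites in 5'-PuG-3' context (default 1 = no bias). EMS alkylation is
#'   reported to favour such sites; no quantitative weight is established,
#'   so the bias is off unless requested. Weights are renormalized so the
#'   genome-wide expected density is preserved.
#' @param density_basis `"m2"` (default) or `"m1"`. With `"m1"`,
#'   `target_density` is the density of induced (heterozygous) mutations in
#'   each M1 sector genome. With `"m2"` it is the expected density of
#'   detectable (non-wild-type) sites per *screened M2 individual*: since an
#'   M1-heterozygous site is transmitted to an M2 sibling in the carrier
#'   (Aa or aa) state with probability 3/4, the per-sector induction rate is
#'   scaled by 4/3. Screens measure M2 plants, so `"m2"` is the basis on
#'   which screen-derived density estimates are comparable to the target.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       target_density = 1 / 45000,
                       n_m1 = 100L,
                       sectors_per_m1 = 1L,
                       siblings_per_line = 2L,
                       pool_size = 4L,
                       context_bias_weight = 1,
                       density_basis = c("m2", "m1")) {
  density_basis <- match.arg(density_basis)
  if (!is.numeric(target_density) || target_density < 0) {
    stop_tk("'target_density' must be >= 0")
  }
  if (!is_count(n_m1) || n_m1 < 1) stop_tk("'n_m1' must be a positive integer")
  if (!is_count(sectors_per_m1) || sectors_per_m1 < 1) {
    stop_tk("'sectors_per_m1' must be >= 1")
  }
  if (!is_count(siblings_per_line) || siblings_per_line < 1) {
    stop_tk("'siblings_per_line' must be >= 1")
  }
  if (!is_count(pool_size) || pool_size < 1 || pool_size > 8) {
    stop_tk("'pool_size' must be in [1, 8]")
  }
  if (!is.numeric(context_bias_weight) || context_bias_weight <= 0) {
    stop_tk("'context_bias_weight' must be positive")
  }
  structure(
    list(seed = as.integer(seed),
         target_density = target_density,
         n_m1 = as.integer(n_m1),
         sectors_per_m1 = as.integer(sectors_per_m1),
         siblings_per_line = as.integer(siblings_per_line),
         pool_size = as.integer(pool_size),
         context_bias_weight = context_bias_weight,
         density_basis = density_basis),
    class = "sim_config"
  )
}

#' Generate a random reference sequence
#'
#' Draws an i.i.d. DNA sequence with the requested GC content, standing in
#' for a wild-type screening target.
#'
#' @param length sequence length in bp (>= 1).
#' @param gc_fraction expected fraction of G+C, in \[0, 1\].
#' @param seed integer seed; identical seeds give identical sequences.
#' @param id sequence identifier.
#' @return An object of class `reference_sequence` with fields `id`,
#'   `residues` (a single string over A/C/G/T) and `length`.
#' @export
generate_reference <- function(length, gc_fraction = 0.45, seed = 1L,
                               id = "ref") {
  if (!is_count(length) || length < 1) stop_tk("'length' must be a positive integer")
  if (!is.numeric(gc_fraction) || gc_fraction < 0 || gc_fraction > 1) {
    stop_tk("'gc_fraction' must be in [0, 1]")
  }
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  bases <- with_seed(seed, sample(DNA_BASES, length, replace = TRUE, prob = p))
  reference_sequence(id, paste(bases, collapse = ""))
}

#' Construct a reference sequence from a string
#'
#' @param id sequence identifier.
#' @param residues string over the alphabet A/C/G/T (lower case accepted).
#' @return An object of class `reference_sequence`.
#' @export
reference_sequence <- function(id, residues) {
  stopifnot(length(residues) == 1L, is.character(residues))
  residues <- toupper(residues)
  if (nchar(residues) < 1L) stop_tk("reference sequence must be non-empty")
  bad <- regexpr("[^ACGT]", residues)
  if (bad > 0) {
    stop_tk("non-ACGT character '", substr(residues, bad, bad),
            "' at position ", bad, " in sequence '", id, "'")
  }
  structure(
    list(id = as.character(id), residues = residues,
         length = nchar(residues)),
    class = "reference_sequence"
  )
}

#' @export
print.reference_sequence <- function(x, ...) {
  cat(sprintf("<reference_sequence> %s: %d bp, GC %.3f\n", x$id, x$length,
              gc_content(x)))
  invisible(x)
}

#' GC fraction of a reference sequence
#' @param reference a `reference_sequence`.
#' @return Fraction of G+C bases.
#' @export
gc_content <- function(reference) {
  stopifnot(inherits(reference, "reference_sequence"))
  b <- strsplit(reference$residues, "")[[1]]
  mean(b %in% c("G", "C"))
}

# Eligible EMS target sites (0-based positions of G and C) plus their
# 5'-PuG-3' context flag. For a G on the reference strand the context is a
# purine immediately 5' of it; for a C (a G on the opposite strand) the
# context is read on that strand, i.e. a pyrimidine immediately 3' of the C
# on the reference.
ems_eligible_sites <- function(reference) {
  b <- strsplit(reference$residues, "")[[1]]
  n <- length(b)
  is_g <- b == "G"
  is_c <- b == "C"
  prev <- c(NA, b[-n])
  nxt <- c(b[-1], NA)
  pug <- (is_g & prev %in% c("A", "G")) |
    (is_c & nxt %in% c("C", "T"))
  pos <- which(is_g | is_c) - 1L
  data.frame(pos = pos,
             ref = b[pos + 1L],
             pug_context = pug[pos + 1L] %in% TRUE)
}

#' Induce EMS mutations on a reference
#'
#' Draws independent point mutations over the eligible G:C sites of the
#' reference, reproducing the EMS spectrum: alkylation of guanine yields
#' exclusively G:C -> A:T transitions, recorded on the reference strand as
#' G>A or C>T. The per-site mutation probability at eligible sites is
#' rescaled so the expected *genome-wide* density (mutations per bp over the
#' whole sequence, including A:T sites that can never mutate) equals
#' `density`. With `context_bias_weight > 1`, sites in 5'-PuG-3' context are
#' proportionally more likely to mutate, with weights renormalized so the
#' genome-wide expectation is unchanged.
#'
#' @param reference a `reference_sequence`.
#' @param density expected mutations per bp of reference.
#' @param seed integer seed.
#' @param context_bias_weight weight >= 0 applied to 5'-PuG-3' sites
#'   (default 1 = unbiased).
#' @param sites precomputed eligible-site table (internal use; lets a
#'   caller simulating many genomes on one reference scan it only once).
#' @return A data frame of mutation records with columns `pos` (0-based),
#'   `ref` (`G` or `C`) and `alt` (`A` or `T` respectively), sorted by
#'   position. Zero rows when `density = 0`.
#' @export
induce_ems_mutations <- function(reference, density, seed = 1L,
                                 context_bias_weight = 1, sites = NULL) {
  stopifnot(inherits(reference, "reference_sequence"))
  if (!is.numeric(density) || density < 0) stop_tk("'density' must be >= 0")
  empty <- data.frame(pos = integer(), ref = character(), alt = character())
  if (density == 0) return(empty)
  if (is.null(sites)) sites <- ems_eligible_sites(reference)
  if (nrow(sites) == 0L) {
    stop_tk("reference contains no G or C sites: the EMS transition ",
            "spectrum cannot realize a positive mutation density")
  }
  w <- ifelse(sites$pug_context, context_bias_weight, 1)
  # expected total count = density * length; distribute over sites by weight
  p <- density * reference$length * w / sum(w)
  if (any(p > 1)) {
    stop_tk("requested density too high: per-site mutation probability ",
            "exceeds 1 at ", sum(p > 1), " site(s)")
  }
  hit <- with_seed(seed, stats::runif(nrow(sites)) < p)
  out <- sites[hit, c("pos", "ref"), drop = FALSE]
  out$alt <- ifelse(out$ref == "G", "A", "T")
  rownames(out) <- NULL
  out
}

#' Zygosity of an allele pair
#'
#' @param alleles character vector of length 2 over \{"ref", "alt"\}.
#' @return `"hom_ref"`, `"het"` or `"hom_alt"`.
#' @export
zygosity_of <- function(alleles) {
  stopifnot(length(alleles) == 2L, all(alleles %in% c("ref", "alt")))
  n_alt <- sum(alleles == "alt")
  c("hom_ref", "het", "hom_alt")[n_alt + 1L]
}

#' Breed M1 mutation sets to an M2 population
#'
#' Given the per-sector mutation sets of each M1 plant, samples M2 sibling
#' individuals. Each sibling descends from exactly one meristem sector of
#' its M1 parent (drawn uniformly), so siblings from different sectors of a
#' chimeric M1 carry disjoint mutation sets. Every induced mutation is
#' heterozygous in the M1 germ line, so at each of its sites a sibling's
#' genotype is drawn hom_alt : het : hom_ref = 1 : 2 : 1 (selfing).
#'
#' @param m1_mutations list over M1 plants; each element is a list over
#'   sectors of mutation data frames as returned by
#'   [induce_ems_mutations()] (a bare data frame is treated as one sector).
#' @param config a [sim_config()] (`siblings_per_line`, `sectors_per_m1`).
#' @param seed integer seed.
#' @param reference optional `reference_sequence` carried into the result.
#' @return An object of class `population` with fields:
#'   \describe{
#'     \item{reference}{the reference, or NULL.}
#'     \item{individuals}{data frame `line`, `indiv`, `sector`.}
#'     \item{genotypes}{data frame `line`, `indiv`, `pos`, `ref`, `alt`,
#'       `zygosity` — one row per sibling per segregating site of its own
#'       sector (hom_ref draws included; sites of other sectors and all
#'       unmutated sites are implicitly hom_ref).}
#'     \item{truth}{data frame `line`, `sector`, `pos`, `ref`, `alt` of all
#'       induced mutations.}
#'   }
#' @export
breed_to_m2 <- function(m1_mutations, config, seed = config$seed,
                        reference = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.list(m1_mutations) || length(m1_mutations) == 0L) {
    stop_tk("'m1_mutations' must be a non-empty list (one element per M1 plant)")
  }
  m1_mutations <- lapply(m1_mutations, function(x) {
    if (is.data.frame(x)) list(x) else x
  })
  if (any(vapply(m1_mutations, length, integer(1)) == 0L)) {
    stop_tk("each M1 plant needs at least one sector (possibly mutation-free)")
  }
  with_seed(seed, {
    ind <- list(); gt <- list(); tr <- list()
    for (li in seq_along(m1_mutations)) {
      line_id <- sprintf("p%03d", li)
      sectors <- m1_mutations[[li]]
      for (si in seq_along(sectors)) {
        mu <- sectors[[si]]
        if (nrow(mu) > 0L) {
          tr[[length(tr) + 1L]] <- data.frame(
            line = line_id, sector = si, pos = mu$pos,
            ref = mu$ref, alt = mu$alt)
        }
      }
      for (sb in seq_len(config$siblings_per_line)) {
        indiv_id <- sprintf("%s-%d", line_id, sb)
        sector <- sample.int(length(sectors), 1L)
        ind[[length(ind) + 1L]] <- data.frame(
          line = line_id, indiv = indiv_id, sector = sector)
        mu <- sectors[[sector]]
        if (nrow(mu) > 0L) {
          z <- sample(c("hom_alt", "het", "hom_ref"), nrow(mu),
                      replace = TRUE, prob = c(1, 2, 1) / 4)
          gt[[length(gt) + 1L]] <- data.frame(
            line = line_id, indiv = indiv_id, pos = mu$pos,
            ref = mu$ref, alt = mu$alt, zygosity = z)
        }
      }
    }
    structure(
      list(reference = reference,
           individuals = do.call(rbind, ind),
           genotypes = if (length(gt)) do.call(rbind, gt) else
             data.frame(line = character(), indiv = character(),
                        pos = integer(), ref = character(),
                        alt = character(), zygosity = character()),
           truth = if (length(tr)) do.call(rbind, tr) else
             data.frame(line = character(), sector = integer(),
                        pos = integer(), ref = character(),
                        alt = character())),
      class = "population"
    )
  })
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d individuals in %d M2 lines; %d induced mutations\n",
              nrow(x$individuals), length(unique(x$individuals$line)),
              nrow(x$truth)))
  invisible(x)
}

#' Simulate a full mutagenized M2 population
#'
#' Runs the mutagenesis and breeding stages end to end: induces an
#' independent EMS mutation set in each meristem sector of each M1 plant,
#' then samples M2 siblings with Mendelian segregation via [breed_to_m2()].
#' When `config$density_basis == "m2"` the per-sector induction density is
#' `target_density * 4/3`, so that the expected density of detectable
#' (carrier) sites per screened M2 individual equals `target_density`; with
#' `"m1"` the induction density is used as given.
#'
#' @param reference a `reference_sequence`.
#' @param config a [sim_config()].
#' @return A `population` (see [breed_to_m2()]).
#' @export
simulate_population <- function(reference, config) {
  stopifnot(inherits(reference, "reference_sequence"),
            inherits(config, "sim_config"))
  d <- config$target_density
  if (config$density_basis == "m2") d <- d * 4 / 3
  sites <- ems_eligible_sites(reference)
  m1 <- vector("list", config$n_m1)
  for (li in seq_len(config$n_m1)) {
    m1[[li]] <- lapply(seq_len(config$sectors_per_m1), function(si) {
      induce_ems_mutations(
        reference, d,
        seed = derive_seed(config$seed, sprintf("m1-%d-%d", li, si)),
        context_bias_weight = config$context_bias_weight,
        sites = sites)
    })
  }
  breed_to_m2(m1, config, seed = derive_seed(config$seed, "breed"),
              reference = reference)
}
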