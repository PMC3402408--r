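#' Amplicon specification
#'
#' A PCR target screened by mismatch cleavage. Coordinates are 0-based
#' half-open on the reference. Band sizes within `end_trim` bp of either
#' amplicon end cannot be read reliably on a gel ("base ambiguity"), so the
#' scannable *effective region* is `[start + end_trim, end - end_trim)`.
#'
#' @param name amplicon label.
#' @param start,end half-open interval on the reference (bp).
#' @param end_trim bp discarded at each end (default 100).
#' @return An object of class `amplicon_spec` with derived fields
#'   `full_length`, `eff_start`, `eff_end`.
#' @export
amplicon_spec <- function(name, start, end, end_trim = 100L) {
  if (!is_count(start) || !is_count(end) || end <= start) {
    stop_tk("'start'/'end' must be non-negative integers with end > start")
  }
  full_length <- end - start
  if (full_length <= 2 * end_trim) {
    stop_tk("amplicon '", name, "' (", full_length,
            " bp) has no effective region with end_trim = ", end_trim)
  }
  structure(
    list(name = as.character(name), start = as.integer(start),
         end = as.integer(end), full_length = as.integer(full_length),
         end_trim = as.integer(end_trim),
         eff_start = as.integer(start + end_trim),
         eff_end = as.integer(end - end_trim)),
    class = "amplicon_spec"
  )
}

#' Detection method with its sensitivity
#'
#' The three gel systems differ in how reliably they reveal a genuine
#' cleavage-product pair. Default sensitivities are the relative per-method
#' detection rates observed on a common amplicon screened three ways
#' (silver-stained PAGE recovered the most mutations and is taken as 1.0;
#' ethidium-bromide agarose 14/15; ethidium-bromide PAGE 11/15). They are
#' configurable, not physical constants.
#'
#' @param name one of `"page_silver"`, `"page_etbr"`, `"agarose_etbr"`.
#' @param sensitivity probability in \[0, 1\] that a true in-region
#'   heteroduplex signal is called; defaults per method as above.
#' @return An object of class `detection_method`.
#' @export
detection_method <- function(name = c("page_silver", "page_etbr", "agarose_etbr"),
                             sensitivity = NULL) {
  name <- match.arg(name)
  if (is.null(sensitivity)) {
    sensitivity <- switch(name,
      page_silver = 1.0,
      agarose_etbr = 14 / 15,
      page_etbr = 11 / 15)
  }
  if (!is.numeric(sensitivity) || length(sensitivity) != 1L ||
      sensitivity < 0 || sensitivity > 1) {
    stop_tk("'sensitivity' must be a probability in [0, 1]")
  }
  structure(list(name = name, sensitivity = sensitivity),
            class = "detection_method")
}

#' Partition individuals into screening pools
#'
#' Shuffles the individuals (deterministically under `seed`) and fills
#' pools of `pool_size` in order; the last pool may be smaller. Every
#' individual lands in exactly one pool.
#'
#' @param individual_ids character vector of distinct individual ids.
#' @param pool_size pool size, 1--8 (fourfold pooling is the routine
#'   choice; eightfold is the documented maximum a silver-stained gel can
#'   resolve).
#' @param seed integer seed.
#' @return A data frame with columns `pool` and `indiv`.
#' @examples
#' pools <- make_pools(sprintf("i%04d", 1:2610), 4, seed = 1)
#' length(unique(pools$pool)) # 653
#' @export
make_pools <- function(individual_ids, pool_size = 4L, seed = 1L) {
  if (length(individual_ids) == 0L) stop_tk("'individual_ids' is empty")
  if (anyDuplicated(individual_ids)) stop_tk("'individual_ids' must be distinct")
  if (!is_count(pool_size) || pool_size < 1 || pool_size > 8) {
    stop_tk("'pool_size' must be in [1, 8]")
  }
  shuffled <- with_seed(seed, sample(individual_ids))
  n_pools <- ceiling(length(shuffled) / pool_size)
  data.frame(
    pool = sprintf("pool%04d", rep(seq_len(n_pools), each = pool_size,
                                   length.out = length(shuffled))),
    indiv = shuffled
  )
}

#' Does a pool form a heteroduplex at a site?
#'
#' After PCR and re-annealing, mismatch-bearing heteroduplexes form only if
#' the pooled template mixture carries *both* alleles: a pool of wild-type
#' homozygotes has nothing to mismatch against, and so does a pool in which
#' every member is homozygous mutant.
#'
#' @param zygosities named character vector over
#'   \{"hom_ref", "het", "hom_alt"\}, one entry per pool member.
#' @return TRUE iff the pooled allele mixture contains ref and alt.
#' @export
heteroduplex_present <- function(zygosities) {
  if (length(zygosities) == 0L) stop_tk("empty pool")
  if (anyNA(zygosities)) stop_tk("missing genotype for pool member(s): ",
                                 paste(names(zygosities)[is.na(zygosities)],
                                       collapse = ", "))
  bad <- setdiff(zygosities, c("hom_ref", "het", "hom_alt"))
  if (length(bad)) stop_tk("invalid zygosity value(s): ", paste(bad, collapse = ", "))
  has_ref <- any(zygosities %in% c("hom_ref", "het"))
  has_alt <- any(zygosities %in% c("het", "hom_alt"))
  has_ref && has_alt
}

#' Screen one amplicon over a pooled population
#'
#' Models the mismatch-cleavage screen of a single amplicon. For each true
#' mutation whose site lies inside the effective region, each pool
#' containing at least one carrier is tested: a call is emitted iff the
#' pooled mixture forms a heteroduplex and an independent Bernoulli draw at
#' the method's sensitivity succeeds. Cleavage yields two fragments whose
#' sizes are the distances from the site to the amplicon ends
#' (`site - start`, `end - site`), summing to the full amplicon length —
#' the signature used to recognize genuine cleavage bands on the gel.
#' Called pools are then deconvolved by re-testing each member singly,
#' mixed with wild-type reference DNA before digestion so homozygous mutant
#' individuals still form heteroduplexes; every carrier member yields one
#' resolved call row. No false-positive mechanism is modeled (calls are
#' assumed sequencing-confirmed).
#'
#' @param population a `population` from [simulate_population()] or
#'   [breed_to_m2()].
#' @param amplicon an [amplicon_spec()].
#' @param pools data frame `pool`, `indiv` from [make_pools()] covering the
#'   population's individuals.
#' @param method a [detection_method()].
#' @param seed integer seed for the sensitivity draws.
#' @return A data frame of cleavage calls with columns `pool`, `amplicon`,
#'   `site` (0-based reference position), `fragment_a`, `fragment_b`
#'   (bp, relative to the amplicon; `fragment_a + fragment_b ==
#'   full_length`), `indiv` (resolved carrier), `line`, `zygosity`.
#' @export
screen_amplicon <- function(population, amplicon, pools, method, seed = 1L) {
  stopifnot(inherits(population, "population"),
            inherits(amplicon, "amplicon_spec"),
            inherits(method, "detection_method"),
            is.data.frame(pools))
  if (!is.null(population$reference) &&
      amplicon$end > population$reference$length) {
    stop_tk("amplicon '", amplicon$name, "' extends beyond the reference (",
            population$reference$length, " bp)")
  }
  empty <- data.frame(pool = character(), amplicon = character(),
                      site = integer(), fragment_a = integer(),
                      fragment_b = integer(), indiv = character(),
                      line = character(), zygosity = character())
  gt <- population$genotypes
  carriers <- gt[gt$zygosity != "hom_ref" &
                   gt$pos >= amplicon$eff_start &
                   gt$pos < amplicon$eff_end, , drop = FALSE]
  if (nrow(carriers) == 0L) return(empty)
  pool_of <- stats::setNames(pools$pool, pools$indiv)
  carriers$pool <- pool_of[carriers$indiv]
  carriers <- carriers[!is.na(carriers$pool), , drop = FALSE]
  if (nrow(carriers) == 0L) return(empty)
  tests <- unique(carriers[, c("pool", "pos")])
  tests <- tests[order(tests$pos, tests$pool), , drop = FALSE]
  detected <- with_seed(seed,
                        stats::runif(nrow(tests)) < method$sensitivity)
  out <- list()
  for (k in which(detected)) {
    pool_id <- tests$pool[k]; site <- tests$pos[k]
    members <- pools$indiv[pools$pool == pool_id]
    z <- gt[gt$pos == site & gt$indiv %in% members, , drop = FALSE]
    zyg <- stats::setNames(rep("hom_ref", length(members)), members)
    zyg[z$indiv] <- z$zygosity
    if (!heteroduplex_present(zyg)) next
    hits <- z[z$zygosity != "hom_ref", , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      pool = pool_id, amplicon = amplicon$name, site = site,
      fragment_a = site - amplicon$start,
      fragment_b = amplicon$end - site,
      indiv = hits$indiv, line = hits$line, zygosity = hits$zygosity)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tally unique mutations discovered by a screen
#'
#' Collapses per-individual cleavage calls to unique mutation discoveries,
#' the unit in which screen results are reported. `dedupe = "line"`
#' (default) counts a site once per M2 line, so the same segregating
#' mutation observed in two siblings of one line is a single discovery,
#' while the same site hit independently in two different lines counts
#' twice. `dedupe = "individual"` counts per carrier individual.
#'
#' @param calls call data frame from [screen_amplicon()] (possibly several
#'   amplicons row-bound).
#' @param dedupe `"line"` or `"individual"`.
#' @return Integer count of unique mutations.
#' @export
count_screen_mutations <- function(calls, dedupe = c("line", "individual")) {
  dedupe <- match.arg(dedupe)
  stopifnot(is.data.frame(calls))
  if (nrow(calls) == 0L) return(0L)
  key <- switch(dedupe,
    line = unique(calls[, c("amplicon", "site", "line")]),
    individual = unique(calls[, c("amplicon", "site", "indiv")]))
  nrow(key)
}
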