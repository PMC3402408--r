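#' Mutation-density estimate
#'
#' Container for a mutation-density estimate expressed as base pairs of
#' screened sequence per mutation, together with its conventional report
#' form "one mutation per X kb". The reported kb value is the *floor* of
#' `bp_per_mutation / 1000` (truncation, not rounding): an estimate of
#' 44,236.8 bp per mutation is reported as 1/44 kb. Truncation is the
#' convention that reproduces published per-primer and per-amplicon report
#' values; rounding half-up would not.
#'
#' @param bp_per_mutation positive number, base pairs per mutation.
#' @return An object of class `density_estimate` with fields
#'   `bp_per_mutation` and `kb_report` (integer kb).
#' @examples
#' density_estimate(44236.8) # 1/44 kb
#' @export
density_estimate <- function(bp_per_mutation) {
  if (!is.numeric(bp_per_mutation) || length(bp_per_mutation) != 1L ||
      !is.finite(bp_per_mutation) || bp_per_mutation <= 0) {
    stop_tk("'bp_per_mutation' must be a single positive finite number")
  }
  structure(
    list(
      bp_per_mutation = as.numeric(bp_per_mutation),
      kb_report = as.integer(floor(bp_per_mutation / 1000))
    ),
    class = "density_estimate"
  )
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("Mutation density: 1/%d kb (%.1f bp per mutation)\n",
              x$kb_report, x$bp_per_mutation))
  invisible(x)
}

#' @export
format.density_estimate <- function(x, ...) sprintf("1/%d kb", x$kb_report)

#' Band-based (RAPD/ISJ) mutation-density estimator
#'
#' Estimates genome-wide mutation density from a dominant-marker band
#' survey. Each band routinely amplified in the wild type is taken to scan
#' two primer-binding sites of `primer_length` bp in every line screened, so
#' the total scanned sequence is `2 * L * B * N` bp; gained or lost bands
#' relative to wild type each count as one mutation event:
#'
#' \deqn{bp/mutation = (2L)(B \times N) / m}
#'
#' where L is the primer length, B the wild-type band count, N the number of
#' M2 lines screened and m the number of mutant bands observed. A line may
#' contribute more than one mutant band; m is a plain event count.
#'
#' @param survey a `primer_survey` (see [primer_survey()]), or a data frame
#'   of surveys with columns `primer_length`, `bands_wt`, `n_lines`,
#'   `mutant_bands` (one estimate per row is returned as a list).
#' @return A [density_estimate()], or a list of them for a data-frame input.
#' @examples
#' rapd_density(primer_survey("A-09", primer_length = 10, bands_wt = 6,
#'                            n_lines = 300, mutant_bands = 1)) # 1/36 kb
#' @seealso [mean_primer_density()] to aggregate across primers.
#' @export
rapd_density <- function(survey) {
  if (is.data.frame(survey)) {
    return(lapply(seq_len(nrow(survey)), function(i) {
      rapd_density(primer_survey(
        primer_name = if ("primer_name" %in% names(survey)) survey$primer_name[i] else as.character(i),
        primer_length = survey$primer_length[i],
        bands_wt = survey$bands_wt[i],
        n_lines = survey$n_lines[i],
        mutant_bands = survey$mutant_bands[i]
      ))
    }))
  }
  stopifnot(inherits(survey, "primer_survey"))
  if (survey$mutant_bands < 1) {
    stop_tk("no mutant bands observed: mutation density is undefined (m = 0)")
  }
  bp <- (2 * survey$primer_length) * (survey$bands_wt * survey$n_lines) /
    survey$mutant_bands
  density_estimate(bp)
}

#' One primer's band survey
#'
#' @param primer_name primer identifier.
#' @param primer_length primer length L in bp.
#' @param bands_wt number of bands routinely obtained in the wild type (B).
#' @param n_lines number of M2 lines screened (N).
#' @param mutant_bands number of gained/lost bands across all lines (m).
#' @return An object of class `primer_survey`.
#' @export
primer_survey <- function(primer_name, primer_length, bands_wt, n_lines,
                          mutant_bands) {
  if (!is_count(primer_length) || primer_length < 1) stop_tk("'primer_length' must be a positive integer")
  if (!is_count(bands_wt) || bands_wt < 1) stop_tk("'bands_wt' must be a positive integer")
  if (!is_count(n_lines) || n_lines < 1) stop_tk("'n_lines' must be a positive integer")
  if (!is_count(mutant_bands)) stop_tk("'mutant_bands' must be a non-negative integer")
  structure(
    list(primer_name = as.character(primer_name),
         primer_length = as.integer(primer_length),
         bands_wt = as.integer(bands_wt),
         n_lines = as.integer(n_lines),
         mutant_bands = as.integer(mutant_bands)),
    class = "primer_survey"
  )
}

#' Average several per-primer density estimates
#'
#' Aggregates band-survey estimates by taking the arithmetic mean of the
#' per-primer *reported* kb intervals (the "1/X kb" values), not by pooling
#' bands across primers. Averaging the reported intervals treats each primer
#' as one independent genome-wide probe; pooling bands would instead weight
#' primers by their band counts and gives a different (smaller) answer. Both
#' behaviours are available via `method`.
#'
#' @param estimates list of [density_estimate()] objects (for
#'   `method = "mean_kb"`), or a data frame / list of [primer_survey()]s
#'   (for `method = "pooled"`).
#' @param method `"mean_kb"` (default) averages the per-primer kb reports;
#'   `"pooled"` sums scanned bp and mutant bands across surveys.
#' @return A [density_estimate()].
#' @examples
#' est <- lapply(c(36, 16, 10, 86, 31, 27) * 1000, density_estimate)
#' mean_primer_density(est) # 1/34 kb
#' @export
mean_primer_density <- function(estimates, method = c("mean_kb", "pooled")) {
  method <- match.arg(method)
  if (method == "mean_kb") {
    if (!is.list(estimates) || length(estimates) == 0L) {
      stop_tk("'estimates' must be a non-empty list of density_estimate objects")
    }
    stopifnot(all(vapply(estimates, inherits, logical(1), "density_estimate")))
    kb <- vapply(estimates, function(e) e$kb_report, numeric(1))
    return(density_estimate(mean(kb) * 1000))
  }
  surveys <- estimates
  if (is.data.frame(surveys)) surveys <- rapd_density(surveys) # validate shape
  if (is.list(estimates) && all(vapply(estimates, inherits, logical(1), "primer_survey"))) {
    bp <- sum(vapply(estimates, function(s) 2 * s$primer_length * s$bands_wt * s$n_lines, numeric(1)))
    m <- sum(vapply(estimates, function(s) s$mutant_bands, numeric(1)))
    if (m < 1) stop_tk("no mutant bands in any survey")
    return(density_estimate(bp / m))
  }
  stop_tk("'pooled' aggregation needs the original primer_survey objects")
}

#' One amplicon's pooled mismatch-cleavage screen result
#'
#' @param gene target gene / amplicon label.
#' @param full_length amplicon length in bp.
#' @param n_plants number of M2 plants screened.
#' @param n_mutations number of confirmed mutations found.
#' @param end_trim bp discarded from each amplicon end when computing the
#'   scanned length (default 100: band sizes within ~100 bp of either end
#'   cannot be read reliably on the gel).
#' @return An object of class `amplicon_screen_result`.
#' @export
amplicon_screen_result <- function(gene, full_length, n_plants, n_mutations,
                                   end_trim = 100L) {
  if (!is_count(full_length) || full_length < 1) stop_tk("'full_length' must be a positive integer")
  if (!is_count(end_trim)) stop_tk("'end_trim' must be a non-negative integer")
  if (full_length <= 2 * end_trim) {
    stop_tk("amplicon of ", full_length, " bp has no effective region after trimming ",
            end_trim, " bp from each end")
  }
  if (!is_count(n_plants) || n_plants < 1) stop_tk("'n_plants' must be a positive integer")
  if (!is_count(n_mutations)) stop_tk("'n_mutations' must be a non-negative integer")
  structure(
    list(gene = as.character(gene),
         full_length = as.integer(full_length),
         end_trim = as.integer(end_trim),
         effective_bp = as.integer(full_length - 2L * end_trim),
         n_plants = as.integer(n_plants),
         n_mutations = as.integer(n_mutations)),
    class = "amplicon_screen_result"
  )
}

#' Amplicon (TILLING) mutation-density estimator
#'
#' Density from a pooled mismatch-cleavage screen of one amplicon: the
#' scanned sequence is the effective amplicon length (full length minus
#' `end_trim` bp at each end) times the number of plants screened, divided
#' by the number of mutations found:
#'
#' \deqn{bp/mutation = (full\_length - 2\,end\_trim) \times n_{plants} / n_{mutations}}
#'
#' @param result an [amplicon_screen_result()].
#' @return A [density_estimate()].
#' @examples
#' tilling_density(amplicon_screen_result("Ppd-D1", 1496, 512, 15)) # 1/44 kb
#' @export
tilling_density <- function(result) {
  stopifnot(inherits(result, "amplicon_screen_result"))
  if (result$n_mutations < 1) {
    stop_tk("no mutations found: density is undefined (n_mutations = 0)")
  }
  density_estimate(result$effective_bp * result$n_plants / result$n_mutations)
}

#' Pooled density across several amplicons
#'
#' Sums scanned base pairs (effective length times plants) and mutation
#' counts over amplicons before dividing, so long amplicons and large
#' screens carry proportionally more weight. For a single amplicon this
#' reduces to [tilling_density()]; duplicating an amplicon leaves the
#' estimate unchanged.
#'
#' @param results list of [amplicon_screen_result()] objects.
#' @return A [density_estimate()].
#' @export
pooled_tilling_density <- function(results) {
  if (!is.list(results) || length(results) == 0L) {
    stop_tk("'results' must be a non-empty list of amplicon_screen_result objects")
  }
  stopifnot(all(vapply(results, inherits, logical(1), "amplicon_screen_result")))
  scanned <- sum(vapply(results, function(r) as.numeric(r$effective_bp) * r$n_plants, numeric(1)))
  m <- sum(vapply(results, function(r) r$n_mutations, numeric(1)))
  if (m < 1) stop_tk("zero mutations across all amplicons: density undefined")
  density_estimate(scanned / m)
}

#' Genome-wide mutation-load extrapolation
#'
#' Expected number of induced mutations carried by one individual, given a
#' genome size and a per-genome mutation density. The raw quotient is
#' reported rounded to two significant figures, the precision at which such
#' extrapolations are quoted.
#'
#' @param genome_size genome size in bp (hexaploid bread wheat is about
#'   1.6e10 bp, i.e. 16,000 Mb).
#' @param bp_per_mutation density in bp per mutation.
#' @return A list with `raw` (exact quotient) and `report` (2 significant
#'   figures).
#' @examples
#' genome_mutation_load(1.6e10, 47000)$report # 340000
#' @export
genome_mutation_load <- function(genome_size, bp_per_mutation) {
  if (!is.numeric(genome_size) || length(genome_size) != 1L || genome_size <= 0) {
    stop_tk("'genome_size' must be a single positive number")
  }
  if (!is.numeric(bp_per_mutation) || length(bp_per_mutation) != 1L ||
      bp_per_mutation <= 0) {
    stop_tk("'bp_per_mutation' must be a single positive number")
  }
  raw <- genome_size / bp_per_mutation
  list(raw = raw, report = signif(raw, 2))
}
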