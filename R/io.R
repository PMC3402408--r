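#' Read reference sequences from FASTA
#'
#' Sequences are uppercased and validated against the strict A/C/G/T
#' alphabet; the position of the first offending character is reported.
#'
#' @param path FASTA file.
#' @return A list of `reference_sequence` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_tk("file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop_tk("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    reference_sequence(ids[i], as.character(set[[i]]))
  })
}

#' Write reference sequences to FASTA
#'
#' @param references a `reference_sequence` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(references, path) {
  if (inherits(references, "reference_sequence")) references <- list(references)
  seqs <- Biostrings::DNAStringSet(
    vapply(references, function(r) r$residues, character(1)))
  names(seqs) <- vapply(references, function(r) r$id, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write / read a truth mutation table
#'
#' Tab-separated, VCF-like layout (CHROM, POS, REF, ALT, LINE, SECTOR).
#' Positions are 1-based in the file and converted to the package's
#' internal 0-based convention at this boundary.
#'
#' @param truth data frame with columns `pos` (0-based), `ref`, `alt`,
#'   `line`, `sector`.
#' @param path output TSV.
#' @param chrom reference id written in the CHROM column.
#' @return `path` invisibly, or the truth data frame for the reader.
#' @export
write_mutation_table <- function(truth, path, chrom = "ref") {
  stopifnot(is.data.frame(truth))
  out <- data.frame(CHROM = chrom, POS = truth$pos + 1L, REF = truth$ref,
                    ALT = truth$alt, LINE = truth$line,
                    SECTOR = truth$sector)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutation_table
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) stop_tk("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(line = tab$LINE, sector = tab$SECTOR, pos = tab$POS - 1L,
             ref = tab$REF, alt = tab$ALT)
}

#' Load the bundled 'Jinmai47' wheat TILLING tables
#'
#' The package ships, as plain TSV, the published summary tables of an
#' EMS-mutagenized TILLING population of the hexaploid bread-wheat cultivar
#' 'Jinmai47' (2610 M2 individuals): the six-primer RAPD/ISJ band survey,
#' the three-gene pooled mismatch-cleavage screen, the *Ppd-D1* mutation
#' records, and the phenotype census. These drive the real-data pathway of
#' every estimator without any network access.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{primer_survey}{6 rows: `primer`, `sequence`, `primer_length`,
#'       `bands_wt`, `mutant_bands`, `n_lines`, `reported_kb`.}
#'     \item{amplicon_screen}{5 rows: per gene x detection method,
#'       `full_length`, `n_plants`, `n_mutations`, per-class counts,
#'       `reported_kb`.}
#'     \item{mutations}{18 records: `indiv`, `line`, `nucleotide_change`
#'       (plus parsed `ref`, `pos` 0-based, `alt`), `amino_acid_change`,
#'       opaque imported `pssm`/`sift` severity scores, `zygosity`,
#'       `type` ("repeat" where a sibling re-discovery was flagged).}
#'     \item{phenotypes}{20 disjoint categories: `category`, `count`,
#'       `population`, `reported_pct`.}
#'   }
#' @export
load_jinmai47_tables <- function() {
  f <- function(name) {
    path <- system.file("extdata", name, package = "tillkit")
    if (path == "") stop_tk("bundled fixture missing: ", name)
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  primer <- f("jinmai47_primer_survey.tsv")
  screen <- f("jinmai47_amplicon_screen.tsv")
  mut <- f("jinmai47_ppd_d1_mutations.tsv")
  phen <- f("jinmai47_phenotypes.tsv")
  stopifnot(nrow(primer) == 6L, nrow(screen) == 5L, nrow(mut) == 18L,
            nrow(phen) == 20L)
  mut$type[is.na(mut$type)] <- ""
  mut$line <- tolower(sub("-[0-9]+$", "", mut$indiv))
  parsed <- parse_nucleotide_change(mut$nucleotide_change)
  mut$ref <- parsed$ref
  mut$pos <- parsed$pos
  mut$alt <- parsed$alt
  list(primer_survey = primer, amplicon_screen = screen,
       mutations = mut, phenotypes = phen)
}

#' Pipeline configuration
#'
#' Parameters for [run_pipeline()]'s end-to-end demonstration run:
#' simulate, screen, estimate, annotate, census.
#'
#' @param seed master seed.
#' @param reference_length simulated reference length, bp.
#' @param gc_fraction reference GC content.
#' @param target_density mutations per bp per screened M2 individual.
#' @param n_lines M1/M2 lines simulated.
#' @param siblings_per_line M2 individuals per line.
#' @param pool_size screening pool size.
#' @param n_amplicons,amplicon_length,end_trim amplicon tiling over the
#'   reference (non-overlapping from position 0).
#' @param method detection method name (see [detection_method()]).
#' @param sensitivity optional sensitivity override.
#' @param genome_size genome used for the mutation-load extrapolation
#'   (default 1.6e10 bp, hexaploid bread wheat).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            reference_length = 50000L,
                            gc_fraction = 0.45,
                            target_density = 1 / 45000,
                            n_lines = 64L,
                            siblings_per_line = 2L,
                            pool_size = 4L,
                            n_amplicons = 10L,
                            amplicon_length = 1500L,
                            end_trim = 100L,
                            method = "page_silver",
                            sensitivity = NULL,
                            genome_size = 1.6e10) {
  if (n_amplicons * amplicon_length > reference_length) {
    stop_tk("amplicon tiling exceeds the reference length")
  }
  structure(
    list(seed = as.integer(seed), reference_length = as.integer(reference_length),
         gc_fraction = gc_fraction, target_density = target_density,
         n_lines = as.integer(n_lines),
         siblings_per_line = as.integer(siblings_per_line),
         pool_size = as.integer(pool_size),
         n_amplicons = as.integer(n_amplicons),
         amplicon_length = as.integer(amplicon_length),
         end_trim = as.integer(end_trim),
         method = method, sensitivity = sensitivity,
         genome_size = genome_size),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> screen -> estimate -> annotate -> census on a
#' simulated population plus the bundled survey tables, and returns a
#' machine-readable report. Identical configurations produce bit-identical
#' reports. Any stage failure aborts with the stage name in the message.
#'
#' @param config a [pipeline_config()].
#' @param out optional path; when given, the report is written there as
#'   JSON.
#' @return The report, a named list.
#' @export
run_pipeline <- function(config, out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_tk("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  sim <- stage("simulate", {
    ref <- generate_reference(config$reference_length, config$gc_fraction,
                              seed = derive_seed(config$seed, "reference"))
    sc <- sim_config(seed = config$seed,
                     target_density = config$target_density,
                     n_m1 = config$n_lines,
                     siblings_per_line = config$siblings_per_line,
                     pool_size = config$pool_size)
    list(ref = ref, pop = simulate_population(ref, sc))
  })
  scr <- stage("screen", {
    amps <- lapply(seq_len(config$n_amplicons), function(i) {
      s <- (i - 1L) * config$amplicon_length
      amplicon_spec(sprintf("amp%02d", i), s, s + config$amplicon_length,
                    end_trim = config$end_trim)
    })
    pools <- make_pools(sim$pop$individuals$indiv, config$pool_size,
                        seed = derive_seed(config$seed, "pools"))
    method <- detection_method(config$method, config$sensitivity)
    calls <- do.call(rbind, lapply(amps, function(a) {
      screen_amplicon(sim$pop, a, pools, method,
                      seed = derive_seed(config$seed, paste0("screen-", a$name)))
    }))
    list(amplicons = amps, pools = pools, method = method, calls = calls)
  })
  est <- stage("estimate", {
    n_plants <- nrow(sim$pop$individuals)
    per_amp <- lapply(scr$amplicons, function(a) {
      m <- count_screen_mutations(scr$calls[scr$calls$amplicon == a$name, ,
                                            drop = FALSE])
      amplicon_screen_result(a$name, a$full_length, n_plants, m,
                             end_trim = a$end_trim)
    })
    with_mut <- Filter(function(r) r$n_mutations > 0, per_amp)
    pooled <- if (length(with_mut)) pooled_tilling_density(with_mut) else NULL
    tables <- load_jinmai47_tables()
    surveys <- lapply(seq_len(nrow(tables$primer_survey)), function(i) {
      s <- tables$primer_survey[i, ]
      primer_survey(s$primer, s$primer_length, s$bands_wt, s$n_lines,
                    s$mutant_bands)
    })
    rapd <- lapply(surveys, rapd_density)
    list(per_amplicon = per_amp, pooled = pooled,
         rapd_mean = mean_primer_density(rapd),
         load = if (!is.null(pooled))
           genome_mutation_load(config$genome_size, pooled$bp_per_mutation)
         else NULL,
         tables = tables)
  })
  ann <- stage("annotate", {
    a1 <- scr$amplicons[[1]]
    ex <- data.frame(start = a1$start + c(120L, 520L, 980L),
                     end = a1$start + c(420L, 880L, 1340L))
    model <- gene_model("simgene1", ex)
    region <- sim$pop$truth[sim$pop$truth$pos >= ex$start[1] &
                              sim$pop$truth$pos < ex$end[3], , drop = FALSE]
    annotated <- annotate_mutations(region, model, sim$ref)
    dd <- dedupe_sibling_repeats(annotated)
    list(model = model, annotated = annotated,
         summary = summarize_effects(dd$unique))
  })
  cen <- stage("census", {
    phen <- est$tables$phenotypes
    list(per_category = category_frequency(phen$count, phen$population[1]),
         overall = overall_visible_rate(phen))
  })
  fixture_files <- vapply(c("jinmai47_primer_survey.tsv",
                            "jinmai47_amplicon_screen.tsv",
                            "jinmai47_ppd_d1_mutations.tsv",
                            "jinmai47_phenotypes.tsv"),
                          function(f) unname(tools::md5sum(
                            system.file("extdata", f, package = "tillkit"))),
                          character(1))
  report <- list(
    package_version = as.character(utils::packageVersion("tillkit")),
    seed = config$seed,
    fixture_md5 = as.list(fixture_files),
    n_individuals = nrow(sim$pop$individuals),
    n_truth_mutations = nrow(sim$pop$truth),
    n_calls = if (is.null(scr$calls)) 0L else nrow(scr$calls),
    per_amplicon_kb = stats::setNames(
      lapply(est$per_amplicon, function(r)
        if (r$n_mutations > 0) tilling_density(r)$kb_report else NA),
      vapply(est$per_amplicon, function(r) r$gene, character(1))),
    pooled_bp_per_mutation = if (!is.null(est$pooled))
      est$pooled$bp_per_mutation else NA,
    pooled_kb = if (!is.null(est$pooled)) est$pooled$kb_report else NA,
    rapd_mean_kb = est$rapd_mean$kb_report,
    genome_load = if (!is.null(est$load)) est$load$report else NA,
    effect_summary = as.list(ann$summary$effects),
    zygosity_summary = as.list(ann$summary$zygosity),
    census_overall_pct = cen$overall
  )
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}
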