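#' Classify a substitution against the EMS spectrum
#'
#' EMS alkylates guanine, producing almost exclusively G:C -> A:T
#' transitions, seen on the reference strand as `G>A` or `C>T`. Any other
#' substitution is flagged `non_canonical` — unexpected under EMS and worth
#' scrutiny (sequencing error, pre-existing polymorphism).
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @return Character vector over \{"C>T", "G>A", "non_canonical"\}.
#' @examples
#' classify_transition("C", "T") # "C>T"
#' classify_transition("A", "G") # "non_canonical"
#' @export
classify_transition <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (!all(ref %in% DNA_BASES) || !all(alt %in% DNA_BASES)) {
    stop_tk("'ref' and 'alt' must be single bases in {A,C,G,T}")
  }
  if (any(ref == alt)) stop_tk("'ref' and 'alt' must differ")
  ifelse(ref == "C" & alt == "T", "C>T",
         ifelse(ref == "G" & alt == "A", "G>A", "non_canonical"))
}

#' Minimal gene model for effect calling
#'
#' An exon chain on the reference with a reading frame, sufficient to
#' classify point mutations as intron / splice-junction / silent /
#' missense / nonsense. Coordinates are 0-based half-open; exons must be
#' sorted and disjoint. The coding sequence is the concatenation of exon
#' sequences (reverse-complemented, in reverse order, for `strand = "-"`),
#' read in frame from `frame_offset` bp into that concatenation; residue 1
#' of the protein notation is the codon starting there unless
#' `anchor_residue` shifts the numbering (useful when the modeled region is
#' an internal slice of a longer CDS).
#'
#' @param gene_id gene identifier.
#' @param exons data frame with columns `start`, `end` (0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @param frame_offset bp skipped at the start of the concatenated exon
#'   sequence before the first complete codon (0--2, or more for a partial
#'   model).
#' @param anchor_residue residue number assigned to that first codon.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, exons, strand = c("+", "-"),
                       frame_offset = 0L, anchor_residue = 1L) {
  strand <- match.arg(strand)
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            nrow(exons) >= 1L)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (any(exons$end <= exons$start)) stop_tk("exons must have end > start")
  if (nrow(exons) > 1L && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop_tk("exons must be disjoint")
  }
  if (!is_count(frame_offset)) stop_tk("'frame_offset' must be a non-negative integer")
  if (!is_count(anchor_residue) || anchor_residue < 1) {
    stop_tk("'anchor_residue' must be a positive integer")
  }
  cds_len <- sum(exons$end - exons$start) - frame_offset
  structure(
    list(gene_id = as.character(gene_id), exons = exons, strand = strand,
         frame_offset = as.integer(frame_offset),
         anchor_residue = as.integer(anchor_residue),
         partial = (cds_len %% 3L) != 0L),
    class = "gene_model"
  )
}

# Map a reference position inside an exon to its 0-based offset in the
# concatenated plus-strand exon sequence; NA if intronic/outside.
exonic_offset <- function(model, pos) {
  ex <- model$exons
  off <- NA_integer_
  cum <- 0L
  for (i in seq_len(nrow(ex))) {
    if (pos >= ex$start[i] && pos < ex$end[i]) {
      off <- cum + (pos - ex$start[i])
      break
    }
    cum <- cum + (ex$end[i] - ex$start[i])
  }
  off
}

#' Classify the effect of a point mutation
#'
#' Assigns exactly one of five mutually exclusive classes:
#' \describe{
#'   \item{splice_junction}{intronic position within `splice_window` bp of
#'     an internal exon boundary (the canonical GT/AG dinucleotides at the
#'     default window of 2).}
#'   \item{intron}{any other position outside all exons.}
#'   \item{silent / missense / nonsense}{exonic positions, by translating
#'     the affected codon before and after the substitution with the
#'     standard genetic code: same residue, changed residue, or stop
#'     gained. Coding calls carry protein notation such as `"T438M"`
#'     (`"W10*"` for a stop), numbered from the model's frame anchor.}
#' }
#'
#' @param pos 0-based reference position of the mutation.
#' @param ref,alt reference and alternate base as observed on the
#'   reference (plus) strand.
#' @param model a [gene_model()].
#' @param reference the `reference_sequence` the model lives on.
#' @param splice_window intronic bp at each internal exon boundary called
#'   splice-junction (default 2).
#' @return A list with `class` and `protein` (NA for non-coding calls).
#' @examples
#' \dontrun{classify_effect(27, "G", "A", model, ref)}
#' @export
classify_effect <- function(pos, ref, alt, model, reference,
                            splice_window = 2L) {
  stopifnot(inherits(model, "gene_model"),
            inherits(reference, "reference_sequence"))
  region_start <- model$exons$start[1]
  region_end <- model$exons$end[nrow(model$exons)]
  if (!is_count(pos) || pos < region_start || pos >= region_end) {
    stop_tk("position ", pos, " lies outside the modeled region [",
            region_start, ", ", region_end, ")")
  }
  seq_ref <- substr(reference$residues, pos + 1L, pos + 1L)
  if (seq_ref != ref) {
    stop_tk("reference mismatch at position ", pos, ": sequence has '",
            seq_ref, "', record claims '", ref, "'")
  }
  if (!alt %in% DNA_BASES || alt == ref) stop_tk("invalid alternate base")
  off <- exonic_offset(model, pos)
  if (is.na(off)) {
    # intronic: splice-junction iff within splice_window of an internal
    # exon boundary, on the intron side
    ex <- model$exons
    donor_like <- any(pos >= ex$end[-nrow(ex)] &
                        pos < ex$end[-nrow(ex)] + splice_window)
    acceptor_like <- any(pos < ex$start[-1] &
                           pos >= ex$start[-1] - splice_window)
    cls <- if (isTRUE(donor_like) || isTRUE(acceptor_like))
      "splice_junction" else "intron"
    return(list(class = cls, protein = NA_character_))
  }
  # exonic: translate the affected codon before/after on the coding strand
  exon_seq <- paste(vapply(seq_len(nrow(model$exons)), function(i) {
    substr(reference$residues, model$exons$start[i] + 1L, model$exons$end[i])
  }, character(1)), collapse = "")
  if (model$strand == "-") {
    exon_seq <- revcomp(exon_seq)
    off <- nchar(exon_seq) - 1L - off
    ref_c <- unname(complement_base(ref))
    alt_c <- unname(complement_base(alt))
  } else {
    ref_c <- ref; alt_c <- alt
  }
  cds_pos <- off - model$frame_offset
  if (cds_pos < 0L) {
    stop_tk("position ", pos, " precedes the reading-frame anchor")
  }
  codon_idx <- cds_pos %/% 3L
  within <- cds_pos %% 3L
  codon_start <- model$frame_offset + codon_idx * 3L
  if (codon_start + 3L > nchar(exon_seq)) {
    stop_tk("position ", pos, " falls in an incomplete trailing codon ",
            "of a partial gene model")
  }
  codon <- substr(exon_seq, codon_start + 1L, codon_start + 3L)
  stopifnot(substr(codon, within + 1L, within + 1L) == ref_c)
  codon_alt <- codon
  substr(codon_alt, within + 1L, within + 1L) <- alt_c
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon])
  aa_alt <- unname(code[codon_alt])
  residue <- codon_idx + model$anchor_residue
  notation <- paste0(aa_ref, residue, aa_alt)
  cls <- if (aa_alt == aa_ref) "silent"
  else if (aa_alt == "*") "nonsense"
  else "missense"
  list(class = cls, protein = notation)
}

#' Annotate a mutation table against a gene model
#'
#' Convenience wrapper applying [classify_transition()] and
#' [classify_effect()] to every row of a mutation data frame.
#'
#' @param mutations data frame with columns `pos`, `ref`, `alt` (0-based),
#'   plus any carrier columns, which are preserved.
#' @param model a [gene_model()].
#' @param reference the `reference_sequence`.
#' @param ... passed to [classify_effect()].
#' @return The input with added columns `transition`, `effect`, `protein`.
#' @export
annotate_mutations <- function(mutations, model, reference, ...) {
  stopifnot(is.data.frame(mutations))
  if (nrow(mutations) == 0L) {
    mutations$transition <- character(0)
    mutations$effect <- character(0)
    mutations$protein <- character(0)
    return(mutations)
  }
  eff <- lapply(seq_len(nrow(mutations)), function(i) {
    classify_effect(mutations$pos[i], mutations$ref[i], mutations$alt[i],
                    model, reference, ...)
  })
  mutations$transition <- classify_transition(mutations$ref, mutations$alt)
  mutations$effect <- vapply(eff, `[[`, character(1), "class")
  mutations$protein <- vapply(eff, `[[`, character(1), "protein")
  mutations
}

#' Collapse sibling repeats within M2 lines
#'
#' The same segregating mutation is often re-discovered in two or three
#' siblings of one M2 line; such records are one mutation, not several.
#' Records identical in (site, ref, alt) *within one line* collapse to a
#' single unique mutation (first record kept as representative, flagged
#' `repeat_group` when collapsed); identical substitutions found in
#' different lines are independent mutation events and remain distinct.
#'
#' @param records data frame with columns `line`, `pos`, `ref`, `alt`
#'   (plus anything else, preserved on the representative row).
#' @return A list with `unique` (deduplicated data frame, column `n_records`
#'   added) and `groups` (data frame of collapsed groups: `line`, `pos`,
#'   `ref`, `alt`, `n_records`).
#' @export
dedupe_sibling_repeats <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("line", "pos", "ref", "alt") %in% names(records)))
  if (nrow(records) == 0L) {
    return(list(unique = cbind(records, n_records = integer(0)),
                groups = records[0, c("line", "pos", "ref", "alt")]))
  }
  key <- paste(records$line, records$pos, records$ref, records$alt,
               sep = "\r")
  first <- !duplicated(key)
  uniq <- records[first, , drop = FALSE]
  uniq$n_records <- as.integer(table(key)[key[first]])
  rownames(uniq) <- NULL
  grp <- uniq[uniq$n_records > 1L, c("line", "pos", "ref", "alt", "n_records"),
              drop = FALSE]
  rownames(grp) <- NULL
  list(unique = uniq, groups = grp)
}

#' Tally effect classes and zygosity over unique mutations
#'
#' @param mutations data frame of (deduplicated) mutations with an
#'   `effect` column and optionally a `zygosity` column.
#' @return A list with `effects` (named integer vector over intron, silent,
#'   missense, nonsense, splice_junction) and `zygosity` (named integer
#'   vector over het, hom; zeros if no zygosity column).
#' @export
summarize_effects <- function(mutations) {
  stopifnot(is.data.frame(mutations))
  classes <- c("intron", "silent", "missense", "nonsense", "splice_junction")
  eff <- stats::setNames(integer(length(classes)), classes)
  zyg <- c(het = 0L, hom = 0L)
  if (nrow(mutations) > 0L) {
    stopifnot("effect" %in% names(mutations))
    bad <- setdiff(mutations$effect, classes)
    if (length(bad)) stop_tk("unknown effect class(es): ", paste(bad, collapse = ", "))
    tab <- table(factor(mutations$effect, levels = classes))
    eff[] <- as.integer(tab)
    if ("zygosity" %in% names(mutations)) {
      z <- tolower(mutations$zygosity)
      zyg["het"] <- sum(z == "het")
      zyg["hom"] <- sum(z %in% c("hom", "hom_alt"))
    }
  }
  list(effects = eff, zygosity = zyg)
}

#' Parse nucleotide-change notation
#'
#' Splits strings like `"C1687T"` into reference base, 1-based position and
#' alternate base. The returned `pos` is converted to the package's
#' internal 0-based convention.
#'
#' @param x character vector of `<ref><1-based position><alt>` strings.
#' @return Data frame with columns `ref`, `pos` (0-based), `alt`.
#' @export
parse_nucleotide_change <- function(x) {
  m <- regmatches(x, regexec("^([ACGT])([0-9]+)([ACGT])$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop_tk("malformed nucleotide change: ", paste(x[bad], collapse = ", "))
  }
  data.frame(ref = vapply(m, `[`, character(1), 2L),
             pos = as.integer(vapply(m, `[`, character(1), 3L)) - 1L,
             alt = vapply(m, `[`, character(1), 4L))
}

#' Effect class from protein/region notation
#'
#' Interprets the amino-acid-change column of a mutation table:
#' `"Intron"` -> intron, `"S242S"` (same residue) -> silent,
#' `"T438M"` -> missense, `"W10*"` -> nonsense, `"Splice"` ->
#' splice_junction.
#'
#' @param x character vector of annotations.
#' @return Character vector of effect classes.
#' @export
effect_from_notation <- function(x) {
  vapply(x, function(s) {
    if (grepl("^intron$", s, ignore.case = TRUE)) return("intron")
    if (grepl("^splice", s, ignore.case = TRUE)) return("splice_junction")
    m <- regmatches(s, regexec("^([A-Z])([0-9]+)([A-Z*])$", s))[[1]]
    if (length(m) != 4L) stop_tk("unrecognized effect notation: '", s, "'")
    if (m[4] == "*") "nonsense" else if (m[2] == m[4]) "silent" else "missense"
  }, character(1), USE.NAMES = FALSE)
}
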