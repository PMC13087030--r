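# Interval bookkeeping uses 0-based half-open BED coordinates throughout.
# GenomicRanges (1-based closed) does the overlap work internally; the
# conversion happens only at this boundary.

bed_to_granges <- function(bed) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  if (any(bed$start >= bed$end)) stop_bad_arg("BED intervals require start < end.")
  GenomicRanges::GRanges(bed$chrom,
                         IRanges::IRanges(bed$start + 1L, bed$end))
}

overlaps_any <- function(bed, other) {
  if (is.null(other) || !nrow(other)) return(rep(FALSE, nrow(bed)))
  IRanges::overlapsAny(bed_to_granges(bed), bed_to_granges(other))
}

#' Annotate promoters, enhancers and TSS-flanking nucleosome windows
#'
#' Builds the reference interval sets used by the peak classifiers, from a
#' strand-aware TSS list and histone-mark peak sets:
#'
#' * promoter: 1 kb upstream to 500 bp downstream of the TSS, strand-aware;
#'   `active` when overlapping an H3K4me3 peak and no repressive mark,
#'   `bivalent` when overlapping both H3K4me3 and H3K27me3, `inactive` when
#'   overlapping only H3K27me3.
#' * enhancer: intervals outside all promoters; `active` = H3K27ac and
#'   H3K4me1, `poised` = H3K4me1 and H3K27me3, `inactive` = no H3K4me1.
#' * TSS nucleosome: TSS +/- 20 bp; the -1/+1 nucleosome windows are the
#'   400 bp immediately upstream/downstream of that window, strand-aware.
#'
#' All coordinates are 0-based half-open; overlap means >= 1 shared bp.
#'
#' @param tss Tibble with `chrom`, `pos` (0-based TSS coordinate) and
#'   `strand` (`"+"`/`"-"`); an optional `name` column is carried through.
#' @param marks Named list of BED tibbles (`chrom`, `start`, `end`) for
#'   `H3K4me3`, `H3K27me3`, `H3K27ac`, `H3K4me1` (missing marks are treated
#'   as empty).
#' @param candidate_enhancers Optional BED tibble of intervals to classify as
#'   enhancers; defaults to the H3K4me1 and H3K27ac peaks outside promoters.
#' @return A `regulatory_annotation` object: list of tibbles `promoters`
#'   (with `class`), `enhancers` (with `class`), `tss_nucleosome`,
#'   `minus1_nucleosome`, `plus1_nucleosome`.
#' @examples
#' tss <- tibble::tibble(chrom = "chr1", pos = 10000, strand = "+")
#' ann <- annotate_regulatory(tss, marks = list())
#' ann$promoters$start  # 9000
#' @export
annotate_regulatory <- function(tss, marks = list(),
                                candidate_enhancers = NULL) {
  stopifnot(is.data.frame(tss))
  if (!all(c("chrom", "pos", "strand") %in% names(tss))) {
    stop_bad_arg("`tss` needs columns chrom, pos, strand.")
  }
  if (any(is.na(tss$strand)) || !all(tss$strand %in% c("+", "-"))) {
    stop_bad_arg("every TSS must carry strand '+' or '-'.")
  }
  plus <- tss$strand == "+"

  promoters <- tibble(
    chrom = tss$chrom,
    start = ifelse(plus, tss$pos - 1000L, tss$pos - 500L),
    end   = ifelse(plus, tss$pos + 500L,  tss$pos + 1000L),
    strand = tss$strand,
    name = if ("name" %in% names(tss)) tss$name else
      sprintf("tss%04d", seq_len(nrow(tss))))

  k4me3  <- overlaps_any(promoters, marks$H3K4me3)
  k27me3 <- overlaps_any(promoters, marks$H3K27me3)
  promoters$class <- dplyr::case_when(
    k4me3 & k27me3 ~ "bivalent",
    k4me3 & !k27me3 ~ "active",
    !k4me3 & k27me3 ~ "inactive",
    TRUE ~ "unmarked")

  # enhancer candidates: mark peaks outside any promoter
  cand <- candidate_enhancers %||% {
    pool <- dplyr::bind_rows(marks$H3K4me1, marks$H3K27ac)
    if (is.null(pool) || !nrow(pool)) {
      tibble(chrom = character(0), start = integer(0), end = integer(0))
    } else dplyr::distinct(pool, .data$chrom, .data$start, .data$end)
  }
  if (nrow(cand)) {
    in_prom <- overlaps_any(cand, promoters)
    enh <- cand[!in_prom, , drop = FALSE]
  } else {
    enh <- cand
  }
  if (nrow(enh)) {
    k4me1  <- overlaps_any(enh, marks$H3K4me1)
    k27ac  <- overlaps_any(enh, marks$H3K27ac)
    k27me3e <- overlaps_any(enh, marks$H3K27me3)
    enh$class <- dplyr::case_when(
      k27ac & k4me1 ~ "active",
      k4me1 & k27me3e ~ "poised",
      !k4me1 ~ "inactive",
      TRUE ~ "other")
  } else {
    enh$class <- character(0)
  }

  tss_nuc <- tibble(chrom = tss$chrom,
                    start = tss$pos - 20L, end = tss$pos + 20L,
                    strand = tss$strand, name = promoters$name)
  minus1 <- tibble(chrom = tss$chrom,
                   start = ifelse(plus, tss_nuc$start - 400L, tss_nuc$end),
                   end   = ifelse(plus, tss_nuc$start, tss_nuc$end + 400L),
                   strand = tss$strand, name = promoters$name)
  plus1 <- tibble(chrom = tss$chrom,
                  start = ifelse(plus, tss_nuc$end, tss_nuc$start - 400L),
                  end   = ifelse(plus, tss_nuc$end + 400L, tss_nuc$start),
                  strand = tss$strand, name = promoters$name)

  structure(list(promoters = promoters, enhancers = enh,
                 tss_nucleosome = tss_nuc,
                 minus1_nucleosome = minus1, plus1_nucleosome = plus1),
            class = "regulatory_annotation")
}

#' @export
print.regulatory_annotation <- function(x, ...) {
  cat(sprintf("<regulatory_annotation> %d promoters (%s), %d enhancers\n",
              nrow(x$promoters),
              paste(sprintf("%s: %d", names(table(x$promoters$class)),
                            table(x$promoters$class)), collapse = ", "),
              nrow(x$enhancers)))
  invisible(x)
}

#' Assign promoter/enhancer context to motif occurrences
#'
#' Overlap (>= 1 bp) against the annotation's promoter and enhancer sets.
#' Occurrences overlapping both are assigned `promoter` (promoters take
#' precedence, mirroring the order in which the reference sets are built);
#' when that happens a message reports how many.
#'
#' @param occurrences BED-like tibble (`chrom`, `start`, `end`, further
#'   columns carried through).
#' @param annotation A `regulatory_annotation` object.
#' @return The input with a `context` column (`promoter`/`enhancer`/`other`).
#' @export
assign_context <- function(occurrences, annotation) {
  stopifnot(inherits(annotation, "regulatory_annotation"))
  in_prom <- overlaps_any(occurrences, annotation$promoters)
  in_enh <- overlaps_any(occurrences, annotation$enhancers)
  both <- in_prom & in_enh
  if (any(both)) {
    rlang::inform(sprintf("%d occurrence(s) overlap both a promoter and an enhancer; assigned promoter.",
                          sum(both)))
  }
  occurrences$context <- ifelse(in_prom, "promoter",
                         ifelse(in_enh, "enhancer", "other"))
  occurrences
}
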