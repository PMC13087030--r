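#' Create a position frequency matrix object
#'
#' @param counts 4 x N numeric matrix with rownames A, C, G, T (raw counts as
#'   distributed in JASPAR PFM files; no pseudocounts are added).
#' @param name Motif name.
#' @return A `pwm` object.
#' @export
pwm <- function(counts, name = "motif") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  if (!setequal(rownames(counts), c("A", "C", "G", "T"))) {
    stop_bad_arg(sprintf("PFM '%s' must have rows A, C, G, T.", name))
  }
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(counts) < 1) stop_bad_arg(sprintf("PFM '%s' has no positions.", name))
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_bad_arg(sprintf("PFM '%s' must contain finite non-negative counts.", name))
  }
  if (any(colSums(counts) <= 0)) {
    stop_bad_arg(sprintf("PFM '%s' has a position with all-zero counts.", name))
  }
  structure(list(name = name, counts = counts, N = ncol(counts)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm '%s'> %d positions\n", x$name, x$N))
  print(x$counts)
  invisible(x)
}

#' Read motifs from a JASPAR PFM text file
#'
#' Parses the JASPAR text format: a `>identifier name` header line followed
#' by four base rows, either bracketed (`A [ 4 19 0 ]`) or plain whitespace
#' separated counts.
#'
#' @param source Path to a JASPAR-format PFM file, or a character vector of
#'   its lines.
#' @return A named list of [pwm()] objects.
#' @export
read_jaspar_pfm <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source)
  } else as.character(source)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop_bad_arg("no JASPAR header lines ('>') found.")
  blocks <- Map(function(from, to) lines[from:to],
                heads, c(heads[-1] - 1L, length(lines)))
  out <- lapply(blocks, parse_jaspar_block)
  names(out) <- vapply(out, function(p) p$name, character(1))
  out
}

parse_jaspar_block <- function(block) {
  header <- sub("^>\\s*", "", block[[1]])
  name <- strsplit(header, "\\s+")[[1]]
  name <- paste(name[nzchar(name)], collapse = " ")
  body <- block[-1]
  if (length(body) != 4L) {
    stop_bad_arg(sprintf("motif '%s': expected 4 base rows, found %d.",
                         name, length(body)))
  }
  rows <- lapply(body, function(l) {
    base <- sub("^([ACGTacgt]).*$", "\\1", l)
    if (!toupper(base) %in% c("A", "C", "G", "T")) {
      stop_bad_arg(sprintf("motif '%s': row does not start with a base letter: '%s'",
                           name, l))
    }
    nums <- gsub("^[ACGTacgt]\\s*|\\[|\\]", " ", l)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
    if (any(is.na(vals))) {
      stop_bad_arg(sprintf("motif '%s': non-numeric counts in row '%s'.", name, l))
    }
    list(base = toupper(base), vals = vals)
  })
  lens <- vapply(rows, function(r) length(r$vals), integer(1))
  if (length(unique(lens)) != 1L) {
    stop_bad_arg(sprintf("motif '%s': base rows have unequal lengths (%s).",
                         name, paste(lens, collapse = ", ")))
  }
  bases <- vapply(rows, `[[`, character(1), "base")
  if (!setequal(bases, c("A", "C", "G", "T"))) {
    stop_bad_arg(sprintf("motif '%s': missing base rows (%s found).",
                         name, paste(bases, collapse = ", ")))
  }
  m <- do.call(rbind, lapply(rows, `[[`, "vals"))
  rownames(m) <- bases
  pwm(m, name = name)
}

#' Write motifs to a JASPAR PFM text file
#'
#' @param pwms A list of [pwm()] objects (or a single one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$name),
      vapply(c("A", "C", "G", "T"), function(b) {
        sprintf("%s [ %s ]", b,
                paste(format(p$counts[b, ], trim = TRUE), collapse = " "))
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' CpG score of a motif
#'
#' Quantifies how strongly a motif demands a CpG dinucleotide, weighted by
#' how informative the matrix is at the contributing positions. With
#' \eqn{P(C)_i} the C fraction of the counts at position i,
#' \eqn{Weight_i} the column sum divided by the mean of all 4N matrix
#' entries, the score is
#' \deqn{\sum_{i=1}^{N-1} P(C)_i \, P(G)_{i+1} \, (Weight_i + Weight_{i+1}).}
#' The score is invariant to rescaling the whole count matrix by a positive
#' constant and is zero for a single-position motif (empty sum).
#'
#' @param x A [pwm()] object.
#' @return Dimensionless score (scalar).
#' @examples
#' cpg_score(pwm(matrix(1, 4, 2)))                      # 0.5
#' cpg_score(pwm(rbind(A = c(0, 0), C = c(1, 0),
#'                     G = c(0, 1), T = c(0, 0))))      # 8
#' @export
cpg_score <- function(x) {
  stopifnot(inherits(x, "pwm"))
  m <- x$counts
  if (x$N < 2) return(0)
  colsum <- colSums(m)
  pC <- m["C", ] / colsum
  pG <- m["G", ] / colsum
  weight <- colsum / mean(m)
  i <- seq_len(x$N - 1)
  sum(pC[i] * pG[i + 1] * (weight[i] + weight[i + 1]))
}

#' Does a motif contain a CpG?
#'
#' Strictly-greater comparison of [cpg_score()] against the threshold
#' (default 6); a score of exactly 6 does not qualify.
#'
#' @param x A [pwm()] object.
#' @param threshold CpG-score threshold (default 6).
#' @return Logical scalar.
#' @export
has_cpg <- function(x, threshold = 6) {
  cpg_score(x) > threshold
}

#' Promoter-versus-enhancer score of a motif
#'
#' The likelihood that an occurrence of the motif falls in a promoter rather
#' than an enhancer: each occurrence in a promoter contributes 1, in an
#' enhancer 0, and the contributions are averaged. Occurrences in neither
#' context are excluded from the denominator.
#'
#' @param occurrences A tibble with a `context` column taking values
#'   `"promoter"`, `"enhancer"` or `"other"` (extra columns are ignored), or
#'   a character vector of contexts.
#' @return Fraction in `[0, 1]`.
#' @examples
#' pe_score(c("promoter", "promoter", "promoter", "enhancer"))  # 0.75
#' @export
pe_score <- function(occurrences) {
  ctx <- if (is.data.frame(occurrences)) occurrences$context else occurrences
  ctx <- as.character(ctx)
  bad <- setdiff(unique(ctx), c("promoter", "enhancer", "other"))
  if (length(bad)) {
    stop_bad_arg(sprintf("unknown context value(s): %s", paste(bad, collapse = ", ")))
  }
  used <- ctx[ctx %in% c("promoter", "enhancer")]
  if (!length(used)) {
    stop_bad_arg("no promoter or enhancer occurrences: the score is undefined.")
  }
  mean(used == "promoter")
}

#' Pioneer-factor tally among up- and down-regulated motifs
#'
#' Counts how many of the motifs gaining (`up`) and losing (`down`)
#' footprinting belong to a list of pioneer transcription factors, and tests
#' the 2 x 2 association with a two-sided exact (hypergeometric) test.
#'
#' @param up_motifs,down_motifs Disjoint character sets of motif names.
#' @param ptf_list Character set of pioneer-factor motif names.
#' @return A list with `prop_up`, `prop_down`, `table` (2 x 2 contingency
#'   matrix) and `p_value`.
#' @examples
#' ptf_tally(c("A", "B", "C", "D"), c("E", "F", "G", "H"),
#'           ptf_list = c("A", "B"))
#' @export
ptf_tally <- function(up_motifs, down_motifs, ptf_list) {
  up <- unique(as.character(up_motifs))
  down <- unique(as.character(down_motifs))
  if (!length(up) || !length(down)) {
    stop_bad_arg("both the up and the down motif set must be non-empty.")
  }
  if (length(intersect(up, down))) {
    stop_bad_arg("up and down motif sets must be disjoint.")
  }
  ptf <- unique(as.character(ptf_list))
  up_ptf <- length(intersect(up, ptf))
  down_ptf <- length(intersect(down, ptf))
  tab <- matrix(c(up_ptf, length(up) - up_ptf,
                  down_ptf, length(down) - down_ptf),
                nrow = 2, byrow = TRUE,
                dimnames = list(direction = c("up", "down"),
                                pTF = c("pTF", "non_pTF")))
  p <- if (!length(ptf)) 1 else fisher.test(tab)$p.value
  list(prop_up = up_ptf / length(up), prop_down = down_ptf / length(down),
       table = tab, p_value = p)
}
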