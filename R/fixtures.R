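#' Generate a genomic fixture with planted classification labels
#'
#' Emits everything the peak-level pipeline consumes, with known ground
#' truth: a peak table whose per-sample scores realize planted differential,
#' rescue, turnover and methylation classes exactly; an H2A.Z score column
#' whose rank-based level classes are recorded; strand-aware TSS and
#' histone-mark BED tables realizing planted promoter and enhancer types;
#' Drosophila spike-in counts; and a small set of toy position frequency
#' matrices (uniform, perfect-CG and an asymmetric one). Fully deterministic
#' for a fixed seed.
#'
#' @param n_peaks Number of peaks (>= 1).
#' @param planted Class specification, a list with elements
#'   `frac_up`, `frac_down` (differential fractions, default 0.2 each),
#'   `effect_up`, `effect_down` (relative score change, default 0.5),
#'   `mark_class` (`"histone"` or `"tf"`, default `"histone"`),
#'   `frac_rescued` (default 0.3),
#'   `turnover` (named fractions over `2h`,`4h`,`6h`,`8h`,`stable`;
#'   default `c(2h = .72, 4h = .1, 6h = .05, 8h = .05, stable = .08)`),
#'   `frac_hyper`, `frac_hypo` (default 0.15 each).
#'   Differential fractions must sum to <= 1.
#' @param n_tss Number of TSS records for the annotation fixture.
#' @param spike_counts Named spike-in read counts per sample.
#' @param seed Integer seed.
#' @return A list with `peaks` (score tibble with planted `class_*` label
#'   columns), `tss`, `marks` (list of BED tibbles), `planted_promoters`,
#'   `planted_enhancers`, `spike_counts`, `pwms`.
#' @export
make_genomic_fixture <- function(n_peaks = 200, planted = list(),
                                 n_tss = 30,
                                 spike_counts = c(ctrl = 100000, iaa = 200000),
                                 seed) {
  seed <- check_seed(seed)
  if (n_peaks < 1) stop_bad_arg("`n_peaks` must be >= 1.")
  def <- list(frac_up = 0.2, frac_down = 0.2, effect_up = 0.5,
              effect_down = 0.5, mark_class = "histone", frac_rescued = 0.3,
              turnover = c("2h" = 0.72, "4h" = 0.10, "6h" = 0.05,
                           "8h" = 0.05, stable = 0.08),
              frac_hyper = 0.15, frac_hypo = 0.15)
  unknown <- setdiff(names(planted), names(def))
  if (length(unknown)) {
    stop_bad_arg(sprintf("unknown planted-class field(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  p <- utils::modifyList(def, planted)
  if (p$frac_up + p$frac_down > 1 + 1e-12) {
    stop_bad_arg("differential class fractions must sum to <= 1.")
  }
  if (abs(sum(p$turnover) - 1) > 1e-9) {
    stop_bad_arg("turnover fractions must sum to 1.")
  }
  threshold <- switch(p$mark_class, histone = 0.20, tf = 0.30,
                      stop_bad_arg("mark_class must be 'histone' or 'tf'."))
  if (p$effect_up <= threshold || p$effect_down <= threshold) {
    stop_bad_arg("planted effects must exceed the class threshold to be recoverable.")
  }

  withr::with_seed(seed, {
    peaks <- tibble(
      chrom = "chr1",
      start = as.integer(seq(10000, by = 2000, length.out = n_peaks)),
      end = as.integer(seq(10000, by = 2000, length.out = n_peaks)) + 500L,
      peak_id = sprintf("peak%05d", seq_len(n_peaks)))

    # --- differential classes ------------------------------------------------
    n_up <- round(p$frac_up * n_peaks)
    n_down <- round(p$frac_down * n_peaks)
    cls <- sample(rep(c("up", "down", "stable"),
                      c(n_up, n_down, n_peaks - n_up - n_down)))
    ctrl <- runif(n_peaks, 50, 150)
    treat <- ctrl * dplyr::case_when(
      cls == "up" ~ 1 + p$effect_up,
      cls == "down" ~ 1 - p$effect_down,
      TRUE ~ 1 + runif(n_peaks, -0.05, 0.05))
    peaks$score_ctrl <- ctrl
    peaks$score_treat <- treat
    peaks$class_differential <- factor(cls, levels = c("down", "stable", "up"))

    # --- H2A.Z level classes (rank-derived) ----------------------------------
    h2az <- sample(seq(1, 400, length.out = n_peaks)) # distinct scores
    peaks$score_h2az <- h2az
    rk <- rank(h2az, ties.method = "first")
    n_no <- max(1L, floor(0.03 * n_peaks))
    n_q1 <- floor(0.25 * n_peaks)
    peaks$class_h2az <- factor(
      ifelse(rk <= n_no, "No",
      ifelse(rk <= n_q1, "Low",
      ifelse(rk > n_peaks - floor(0.25 * n_peaks), "High", "Intermediate"))),
      levels = c("No", "Low", "Intermediate", "High"))

    # --- rescue --------------------------------------------------------------
    n_res <- round(p$frac_rescued * n_peaks)
    rescued <- sample(c(rep(TRUE, n_res), rep(FALSE, n_peaks - n_res)))
    wt_loss <- runif(n_peaks, 5, 20)
    cd_loss <- ifelse(rescued, wt_loss * runif(n_peaks, 1.5, 2.5),
                      wt_loss * runif(n_peaks, 0.5, 1.0))
    peaks$wt_ctrl <- ctrl
    peaks$wt_iaa <- ctrl - wt_loss
    peaks$cd_ctrl <- ctrl
    peaks$cd_iaa <- ctrl - cd_loss
    peaks$rescued <- rescued

    # --- turnover time series ------------------------------------------------
    groups <- names(p$turnover)
    n_per <- diff(round(cumsum(c(0, p$turnover)) * n_peaks))
    grp <- sample(rep(groups, n_per))
    s0 <- runif(n_peaks, 80, 120)
    frac_left <- function(g) {
      # remaining fraction at 2,4,6,8 h; first drop below 0.5 at the group time
      t(vapply(g, function(gg) {
        switch(gg,
          "2h" = c(0.35, 0.30, 0.25, 0.20),
          "4h" = c(0.60, 0.40, 0.35, 0.30),
          "6h" = c(0.70, 0.60, 0.45, 0.40),
          "8h" = c(0.80, 0.70, 0.60, 0.45),
          stable = c(0.90, 0.85, 0.80, 0.75))
      }, numeric(4)))
    }
    fl <- frac_left(grp)
    peaks$score_t0 <- s0
    peaks$score_t2 <- s0 * fl[, 1]
    peaks$score_t4 <- s0 * fl[, 2]
    peaks$score_t6 <- s0 * fl[, 3]
    peaks$score_t8 <- s0 * fl[, 4]
    peaks$turnover_group <- factor(grp, levels = groups)

    # --- methylation ---------------------------------------------------------
    n_hyper <- round(p$frac_hyper * n_peaks)
    n_hypo <- round(p$frac_hypo * n_peaks)
    mcls <- sample(rep(c("hyper", "hypo", "stable"),
                       c(n_hyper, n_hypo, n_peaks - n_hyper - n_hypo)))
    m0 <- runif(n_peaks, 20, 70)
    m1 <- m0 + dplyr::case_when(
      mcls == "hyper" ~ runif(n_peaks, 6, 12),
      mcls == "hypo" ~ -runif(n_peaks, 6, 12),
      TRUE ~ runif(n_peaks, -2, 2))
    peaks$meth_ctrl <- m0
    peaks$meth_treat <- pmin(pmax(m1, 0), 100)
    peaks$class_methylation <- factor(mcls, levels = c("hypo", "stable", "hyper"))

    # --- annotation fixture --------------------------------------------------
    ann <- fixture_annotation(n_tss)
  })

  list(peaks = peaks, tss = ann$tss, marks = ann$marks,
       planted_promoters = ann$planted_promoters,
       planted_enhancers = ann$planted_enhancers,
       spike_counts = spike_counts, pwms = fixture_pwms())
}

# TSS + mark peaks realizing known promoter/enhancer classes (deterministic
# given the RNG state of the caller).
fixture_annotation <- function(n_tss) {
  pos <- as.integer(seq(50000, by = 10000, length.out = n_tss))
  strand <- rep(c("+", "-"), length.out = n_tss)
  prom_class <- rep(c("active", "bivalent", "inactive"), length.out = n_tss)
  tss <- tibble(chrom = "chr2", pos = pos, strand = strand,
                name = sprintf("gene%03d", seq_len(n_tss)))
  # a mark peak inside each promoter window regardless of strand
  mark_win <- tibble(chrom = "chr2", start = pos - 200L, end = pos + 200L)
  k4me3 <- mark_win[prom_class %in% c("active", "bivalent"), ]
  k27me3_prom <- mark_win[prom_class %in% c("bivalent", "inactive"), ]

  # enhancers far from all promoters
  n_enh <- max(3L, n_tss %/% 2L)
  e_start <- as.integer(seq(1000000, by = 5000, length.out = n_enh))
  enh_class <- rep(c("active", "poised", "inactive"), length.out = n_enh)
  enh <- tibble(chrom = "chr2", start = e_start, end = e_start + 400L,
                class = enh_class)
  k4me1 <- enh[enh$class %in% c("active", "poised"), c("chrom", "start", "end")]
  k27ac <- enh[enh$class == "active", c("chrom", "start", "end")]
  k27me3 <- dplyr::bind_rows(k27me3_prom,
                             enh[enh$class == "poised", c("chrom", "start", "end")])
  list(tss = tss,
       marks = list(H3K4me3 = k4me3, H3K27me3 = k27me3,
                    H3K27ac = k27ac, H3K4me1 = k4me1),
       planted_promoters = tibble(name = tss$name, class = prom_class),
       planted_enhancers = enh)
}

fixture_pwms <- function() {
  uniform <- pwm(matrix(1, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL)),
                 name = "toy_uniform")
  cg <- pwm(rbind(A = c(0, 0), C = c(1, 0), G = c(0, 1), T = c(0, 0)),
            name = "toy_perfect_cg")
  asym <- pwm(rbind(A = c(8, 1, 0, 2), C = c(1, 6, 1, 0),
                    G = c(0, 1, 7, 1), T = c(1, 2, 2, 7)),
              name = "toy_asymmetric")
  list(toy_uniform = uniform, toy_perfect_cg = cg, toy_asymmetric = asym)
}
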