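#' Moderated between-class statistic per gene
#'
#' Signed evidence that a gene's mean log expression differs between two
#' sample classes (e.g. growth phase a versus phase b):
#' `(mean_a - mean_b) / (s + s0)` with `s` the pooled standard error of the
#' difference and `s0` the median of `s` across genes (a shrinkage constant
#' stabilising genes with tiny variance). The sign carries direction.
#'
#' @param study An [expression_study()].
#' @param class_a_samples,class_b_samples Character vectors of sample ids
#'   (each >= 2).
#' @return Tibble: `gene`, `position_bp`, `strand`, `mean_a`, `mean_b`,
#'   `mean_diff`, `s`, `raw_stat`.
#' @export
between_class_statistic <- function(study, class_a_samples, class_b_samples) {
  a <- match(class_a_samples, colnames(study$matrix))
  b <- match(class_b_samples, colnames(study$matrix))
  if (length(a) < 2L || anyNA(a)) stop("class a needs >= 2 known samples", call. = FALSE)
  if (length(b) < 2L || anyNA(b)) stop("class b needs >= 2 known samples", call. = FALSE)
  Xa <- study$matrix[, a, drop = FALSE]
  Xb <- study$matrix[, b, drop = FALSE]
  na <- ncol(Xa); nb <- ncol(Xb)
  ma <- rowMeans(Xa); mb <- rowMeans(Xb)
  va <- rowSums((Xa - ma)^2); vb <- rowSums((Xb - mb)^2)
  sp2 <- (va + vb) / (na + nb - 2)
  s <- sqrt(sp2 * (1 / na + 1 / nb))
  s0 <- stats::median(s)
  den <- s + s0
  # degenerate all-constant input: every denominator zero
  den[den == 0] <- 1
  tibble::tibble(gene = study$genes$gene,
                 position_bp = study$genes$position_bp,
                 strand = study$genes$strand,
                 mean_a = ma, mean_b = mb, mean_diff = ma - mb,
                 s = s, raw_stat = (ma - mb) / den)
}

#' Tricube weight matrix for adaptive-bandwidth smoothing
#'
#' Row i holds the normalised tricube weights of all genes around gene i,
#' with bandwidth `h_i` = distance to the i-th gene's `knn`-th nearest
#' neighbour. On circular chromosomes the shorter arc distance is used.
#' @noRd
lap_weight_matrix <- function(positions, knn, circular_length = NULL) {
  n <- length(positions)
  if (knn %% 2L == 0L || knn < 3L) {
    stop("knn must be odd and >= 3", call. = FALSE)
  }
  if (n < knn) stop(sprintf("need >= %d genes on the strand, have %d", knn, n),
                    call. = FALSE)
  D <- abs(outer(positions, positions, "-"))
  if (!is.null(circular_length)) {
    D <- pmin(D, circular_length - D)
  }
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- sort(D[i, -i])[knn]
    u <- D[i, ] / h
    w <- ifelse(u < 1, (1 - u^3)^3, 0)
    W[i, ] <- w / sum(w)
  }
  W
}

#' Adaptive-bandwidth kernel smoothing of a positional statistic
#'
#' Non-parametric regression of the raw statistic on chromosomal position
#' with a local variable bandwidth: at each gene the bandwidth is the
#' distance to its `knn`-th nearest gene, and a tricube kernel
#' `K(u) = (1 - |u|^3)^3` for `|u| < 1` weights the neighbours. Gene-dense
#' stretches therefore smooth over short ranges and sparse stretches over
#' long ones.
#'
#' @param positions Gene positions (bp) on one strand, any order.
#' @param raw Raw per-gene statistic, same length.
#' @param knn Odd neighbour count defining the bandwidth (default 11).
#' @param circular_length Chromosome length for circular distance; `NULL`
#'   for linear.
#' @return Numeric vector of smoothed values (same order as input).
#' @export
smooth_statistic <- function(positions, raw, knn = 11L,
                             circular_length = NULL) {
  stopifnot(length(positions) == length(raw))
  W <- lap_weight_matrix(positions, knn, circular_length)
  as.numeric(W %*% raw)
}

#' Position-specific permutation p-values for the smoothed statistic
#'
#' Raw statistics are permuted across chromosomal positions `B` times and
#' re-smoothed; since every gene has a unique neighbourhood, the null is kept
#' position-specific (no pooling): the two-sided p-value at gene i is
#' `(1 + #\{b : |smoothed_i^(b)| >= |smoothed_i|\}) / (1 + B)`.
#'
#' @inheritParams smooth_statistic
#' @param B Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List: `p` (per-gene), `smoothed` (observed smoothed values).
#' @export
permutation_pvalues <- function(positions, raw, knn = 11L, B = 1000L,
                                seed = 1L, circular_length = NULL) {
  if (B < 100L) stop("B must be >= 100", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(raw)
  W <- lap_weight_matrix(positions, knn, circular_length)
  obs <- as.numeric(W %*% raw)
  perm <- matrix(0, n, B)
  for (b in seq_len(B)) perm[, b] <- raw[sample.int(n)]
  S <- W %*% perm
  # count ties at the observed value with a small tolerance (matrix-matrix
  # and matrix-vector products round differently in the last ulp);
  # over-counting ties is the conservative direction for a permutation test
  thr <- abs(obs) - 1e-8 * (abs(obs) + 1)
  p <- (1 + rowSums(abs(S) >= thr)) / (1 + B)
  list(p = p, smoothed = obs)
}

#' Call contiguous differentially expressed chromosomal regions
#'
#' Genes pass when their region q-value is at or below `q_threshold` and
#' their absolute class-mean log difference reaches `fc_threshold`; maximal
#' runs of consecutive passing genes on one strand with a consistent sign of
#' the smoothed statistic become one region each. Strands are processed
#' independently.
#'
#' @param lap_tbl Per-gene tibble with columns `gene`, `position_bp`,
#'   `strand`, `mean_diff`, `smoothed_stat`, `q` (as built by [lap_scan()]).
#' @param q_threshold Region q-value cutoff (default 0.01).
#' @param fc_threshold Minimum |class-mean log difference| (default 0.5).
#' @return Tibble of regions: `strand`, `start_position`, `end_position`,
#'   `direction`, `n_genes`, `genes` (list-column), `min_q`.
#' @export
call_regions <- function(lap_tbl, q_threshold = 0.01, fc_threshold = 0.5) {
  out <- list()
  for (st in unique(lap_tbl$strand)) {
    tb <- lap_tbl |>
      dplyr::filter(.data$strand == st) |>
      dplyr::arrange(.data$position_bp)
    pass <- tb$q <= q_threshold & abs(tb$mean_diff) >= fc_threshold &
      tb$smoothed_stat != 0
    sgn <- sign(tb$smoothed_stat)
    grp <- cumsum(c(TRUE, diff(pass) != 0 | diff(sgn) != 0))
    for (g in unique(grp[pass])) {
      idx <- which(grp == g & pass)
      if (length(idx) == 0L) next
      out[[length(out) + 1L]] <- tibble::tibble(
        strand = st,
        start_position = tb$position_bp[idx[1]],
        end_position = tb$position_bp[idx[length(idx)]],
        direction = if (sgn[idx[1]] > 0) "up" else "down",
        n_genes = length(idx),
        genes = list(tb$gene[idx]),
        min_q = min(tb$q[idx]))
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(strand = character(), start_position = integer(),
                          end_position = integer(), direction = character(),
                          n_genes = integer(), genes = list(),
                          min_q = numeric()))
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$strand, .data$start_position)
}

#' Locally adaptive chromosomal-region scan (LAP)
#'
#' The full procedure per strand: moderated between-class statistic,
#' adaptive-bandwidth tricube smoothing along the chromosome, permutation
#' null with position-specific two-sided p-values, Storey q-values, and
#' contiguous region calls filtered on q and fold change.
#'
#' @inheritParams between_class_statistic
#' @param knn Bandwidth neighbour count (odd, default 11).
#' @param B Permutations per strand (default 1000).
#' @param seed Integer seed (offset per strand for independence).
#' @param q_threshold,fc_threshold Region filters (defaults 0.01 / 0.5).
#' @param circular_length Chromosome length for circular distances (`NULL`
#'   = linear).
#' @param lambda Storey lambda.
#' @return A `lap_result` object; see [tidy.lap_result()].
#' @export
lap_scan <- function(study, class_a_samples, class_b_samples, knn = 11L,
                     B = 1000L, seed = 1L, q_threshold = 0.01,
                     fc_threshold = 0.5, circular_length = NULL,
                     lambda = 0.5) {
  base <- between_class_statistic(study, class_a_samples, class_b_samples)
  strands <- unique(base$strand)
  per_strand <- purrr::imap(stats::setNames(strands, strands), function(st, nm) {
    tb <- base |>
      dplyr::filter(.data$strand == st) |>
      dplyr::arrange(.data$position_bp)
    pp <- permutation_pvalues(tb$position_bp, tb$raw_stat, knn = knn, B = B,
                              seed = seed + match(st, strands),
                              circular_length = circular_length)
    tb$smoothed_stat <- pp$smoothed
    tb$p <- pp$p
    tb$q <- as.numeric(storey_qvalues(pp$p, lambda = lambda))
    tb
  })
  gene_tbl <- dplyr::bind_rows(per_strand)
  regions <- call_regions(gene_tbl, q_threshold = q_threshold,
                          fc_threshold = fc_threshold)
  structure(list(genes = gene_tbl, regions = regions, knn = knn, B = B,
                 seed = seed, q_threshold = q_threshold,
                 fc_threshold = fc_threshold,
                 circular_length = circular_length),
            class = "lap_result")
}

#' @export
print.lap_result <- function(x, ...) {
  cat(sprintf("<lap_result> %d genes on %d strand(s); %d region(s) at q <= %g, |fc| >= %g\n",
              nrow(x$genes), length(unique(x$genes$strand)), nrow(x$regions),
              x$q_threshold, x$fc_threshold))
  invisible(x)
}

#' Export region calls as BED
#'
#' Six-column BED: chrom, 0-based start, end, name = direction,
#' score = `-log10(min_q)` (capped at 1000), strand.
#'
#' @param regions Region tibble from [call_regions()].
#' @param chrom Chromosome name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, chrom, path) {
  if (nrow(regions) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- pmin(1000, round(-10 * log10(pmax(regions$min_q, 1e-100))))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", chrom,
                     regions$start_position - 1L, regions$end_position,
                     regions$direction, score, regions$strand), path)
  invisible(path)
}

#' Export the per-gene smoothed-statistic track (bedGraph-style TSV)
#'
#' @param lap An object from [lap_scan()].
#' @param chrom Chromosome name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smoothed_track <- function(lap, chrom, path) {
  tb <- lap$genes
  utils::write.table(
    data.frame(chrom = chrom, start = tb$position_bp - 1L,
               end = tb$position_bp, strand = tb$strand,
               smoothed = tb$smoothed_stat, q = tb$q),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
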