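#' Spline goodness-of-fit statistic for time-course differential expression
#'
#' Per gene, a null model (intercept only: no temporal modulation) and an
#' alternative model (natural cubic spline in time with `spline_df` degrees
#' of freedom) are fitted by least squares, and the evidence for modulation
#' is the scale-free ratio `(RSS0 - RSS1) / RSS1`. An `"odp"` variant is also
#' available: each gene is scored by the ratio of summed Gaussian likelihoods
#' of its profile under *all* genes' fitted alternative models versus all
#' genes' null models (reported on the log scale), so information is shared
#' across genes the way the optimal discovery procedure does.
#'
#' @param study An [expression_study()].
#' @param spline_df Spline degrees of freedom (default 3); the design needs
#'   at least `spline_df + 2` distinct time points.
#' @param method `"f"` (default) or `"odp"`.
#' @return Named numeric vector of per-gene statistics (>= 0 for `"f"`).
#' @export
timecourse_statistic <- function(study, spline_df = 3L, method = c("f", "odp")) {
  method <- match.arg(method)
  time <- study$samples$time_h
  n_t <- length(unique(time))
  if (n_t < spline_df + 2L) {
    stop(sprintf("need >= %d distinct time points for a %d-df spline, have %d",
                 spline_df + 2L, spline_df, n_t), call. = FALSE)
  }
  X <- study$matrix
  fits <- spline_fits(X, time, spline_df)
  if (method == "f") {
    stat <- ifelse(fits$rss0 <= 0, 0,
                   pmax(0, (fits$rss0 - fits$rss1) / pmax(fits$rss1, 1e-300)))
    names(stat) <- rownames(X)
    return(stat)
  }
  odp_statistic(X, fits)
}

#' Least-squares fits under null (intercept) and spline alternative
#' @noRd
spline_fits <- function(X, time, spline_df) {
  n <- ncol(X)
  basis <- splines::ns(time, df = spline_df)
  D1 <- cbind(1, basis)
  H1 <- D1 %*% solve(crossprod(D1), t(D1))
  fit1 <- X %*% t(H1)
  mu0 <- rowMeans(X)
  rss0 <- rowSums((X - mu0)^2)
  rss1 <- rowSums((X - fit1)^2)
  list(fit1 = fit1, mu0 = mu0, rss0 = rss0, rss1 = rss1, n = n)
}

#' ODP-style shared-model likelihood-ratio statistic (log scale)
#' @noRd
odp_statistic <- function(X, fits) {
  n <- fits$n
  sd1 <- sqrt(pmax(fits$rss1 / n, 1e-8))
  sd0 <- sqrt(pmax(fits$rss0 / n, 1e-8))
  # log-likelihood of gene i's profile under gene j's fitted model:
  # -n log sd_j - (||x_i||^2 - 2 x_i . mu_j + ||mu_j||^2) / (2 sd_j^2)
  sq_x <- rowSums(X^2)
  dev1 <- sweep(sweep(-2 * (X %*% t(fits$fit1)), 1, sq_x, "+"),
                2, rowSums(fits$fit1^2), "+")   # ||x_i - mu1_j||^2
  ll1 <- sweep(-sweep(dev1, 2, 2 * sd1^2, "/"), 2, n * log(sd1), "-")
  mu0 <- fits$mu0
  dev0 <- sweep(sweep(-2 * outer(rowSums(X), mu0), 1, sq_x, "+"),
                2, n * mu0^2, "+")              # ||x_i - mu0_j||^2
  ll0 <- sweep(-sweep(dev0, 2, 2 * sd0^2, "/"), 2, n * log(sd0), "-")
  stat <- apply(ll1, 1, logsumexp) - apply(ll0, 1, logsumexp)
  names(stat) <- rownames(X)
  stat
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Permutation null and pooled p-values for the time-course statistic
#'
#' The per-sample time assignment is permuted uniformly `B` times — the
#' design (replicate count per time point) is preserved — and the statistic
#' recomputed for every gene. Null statistics are pooled across genes (the
#' statistic is exchangeable across genes under the null), giving
#' `p_i = (1 + #\{null >= observed_i\}) / (1 + B * G)`.
#'
#' @param study An [expression_study()].
#' @param B Number of permutations (>= 50).
#' @param seed Integer seed.
#' @param spline_df Spline degrees of freedom.
#' @return Named numeric vector of per-gene p-values.
#' @export
permutation_null <- function(study, B = 200L, seed = 1L, spline_df = 3L) {
  if (B < 50L) stop("B must be >= 50", call. = FALSE)
  set.seed(as.integer(seed))
  obs <- timecourse_statistic(study, spline_df = spline_df)
  time <- study$samples$time_h
  X <- study$matrix
  G <- nrow(X)
  null_stats <- matrix(0, G, B)
  for (b in seq_len(B)) {
    perm_time <- sample(time)
    f <- spline_fits(X, perm_time, spline_df)
    null_stats[, b] <- ifelse(f$rss0 <= 0, 0,
                              pmax(0, (f$rss0 - f$rss1) / pmax(f$rss1, 1e-300)))
  }
  pooled <- sort(as.numeric(null_stats))
  n_ge <- length(pooled) - findInterval(obs, pooled, left.open = TRUE)
  p <- (1 + n_ge) / (1 + length(pooled))
  names(p) <- rownames(X)
  p
}

#' Storey q-values
#'
#' Estimates the null proportion as
#' `pi0 = #\{p > lambda\} / (m (1 - lambda))`, capped at 1, then computes
#' `q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j)` — the
#' step-up construction that makes q monotone in p. With `pi0 = 1` this is
#' exactly the Benjamini-Hochberg adjustment.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param lambda Tuning parameter for the `pi0` estimate (single-lambda
#'   estimator, default 0.5).
#' @param pi0 Optional fixed `pi0`, overriding the estimate.
#' @return Numeric vector of q-values (same order as `p`), with attribute
#'   `"pi0"`.
#' @export
storey_qvalues <- function(p, lambda = 0.5, pi0 = NULL) {
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  }
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  running_min <- Inf
  rank_desc <- m:1  # rank of the ordered (descending) p-values
  for (k in seq_len(m)) {
    i <- ord[k]
    # same operation order as stats::p.adjust("BH") so pi0 = 1 is bitwise BH
    running_min <- min(running_min, pi0 * (m / rank_desc[k] * p[i]))
    q[i] <- min(running_min, 1)
  }
  names(q) <- names(p)
  attr(q, "pi0") <- pi0
  q
}

#' Threshold q-values into a DEG call set
#'
#' @param q Numeric q-values (named by gene when available).
#' @param threshold q-value cutoff (default 0.001).
#' @return List: `genes` (names or indices called), `n`, `percent` (of all
#'   genes tested).
#' @export
select_degs <- function(q, threshold = 0.001) {
  hit <- which(q <= threshold)
  genes <- if (!is.null(names(q))) names(q)[hit] else hit
  list(genes = genes, n = length(hit),
       percent = 100 * length(hit) / length(q))
}

#' Cluster DEGs and assign growth phases
#'
#' Profiles are standardized per gene to mean 0 / sd 1, clustered by
#' hierarchical agglomeration with distance `1 - Pearson` and centroid
#' linkage (the dChip convention), the tree is cut into as many clusters as
#' there are phases, and each cluster is labelled with the phase containing
#' the maximum of its mean standardized profile.
#'
#' @param deg_matrix Genes x samples matrix of the DEGs (>= 2 rows).
#' @param time Per-sample time (h).
#' @param phase_breaks Phase partition as in [expression_sim_spec()].
#' @return List: `assignments` (tibble `gene`, `cluster`, `phase`), `tree`
#'   (an `hclust`), `standardized` (the scaled matrix).
#' @export
assign_phases <- function(deg_matrix, time, phase_breaks = c(36, 60)) {
  stopifnot(is.matrix(deg_matrix), nrow(deg_matrix) >= 2)
  sds <- apply(deg_matrix, 1, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("gene '%s' is constant (sd 0): cannot standardize",
                 rownames(deg_matrix)[sds == 0][1]), call. = FALSE)
  }
  Z <- t(scale(t(deg_matrix)))
  d <- stats::as.dist(1 - stats::cor(t(Z)))
  tree <- stats::hclust(d, method = "centroid")
  phases <- sort(unique(phase_of(time, phase_breaks)))
  K <- length(phases)
  cl <- stats::cutree(tree, k = K)
  sample_phase <- phase_of(time, phase_breaks)
  cluster_phase <- vapply(seq_len(K), function(k) {
    prof <- colMeans(Z[cl == k, , drop = FALSE])
    sample_phase[which.max(prof)]
  }, character(1))
  tibble::tibble(gene = rownames(deg_matrix), cluster = unname(cl),
                 phase = cluster_phase[cl]) -> assignments
  list(assignments = assignments, tree = tree, standardized = Z)
}

#' COG category representation of a DEG set
#'
#' For each category, the percentage of all genes on the chip and the
#' percentage of DEGs are compared: a category is over-represented when its
#' DEG percentage is at least twice its chip percentage, under-represented
#' when at most half (categories with a zero percentage on either side are
#' flagged `neither`).
#'
#' @param deg_genes Character vector of DEG ids.
#' @param annotations Tibble with columns `gene`, `cog_category` (one
#'   category per gene; `NA` = unclassified).
#' @return Tibble: `cog_category`, `chip_percent`, `deg_percent`, `flag`.
#' @export
cog_representation <- function(deg_genes, annotations) {
  stopifnot(all(c("gene", "cog_category") %in% names(annotations)))
  ann <- annotations |>
    dplyr::mutate(cog_category = dplyr::coalesce(.data$cog_category,
                                                 "unclassified"))
  n_chip <- nrow(ann)
  n_deg <- length(deg_genes)
  ann |>
    dplyr::group_by(.data$cog_category) |>
    dplyr::summarise(
      chip_percent = 100 * dplyr::n() / n_chip,
      deg_percent = if (n_deg == 0) 0 else
        100 * sum(.data$gene %in% deg_genes) / n_deg,
      .groups = "drop") |>
    dplyr::mutate(flag = cog_flag(.data$chip_percent, .data$deg_percent))
}

#' The over/under-representation rule on printed percentages
#'
#' @param chip_percent,deg_percent Percentages of a category among all chip
#'   probesets and among DEGs.
#' @return `"over"` if `deg_percent >= 2 * chip_percent` (and nonzero),
#'   `"under"` if `deg_percent <= chip_percent / 2` (both nonzero), else
#'   `"neither"`.
#' @export
cog_flag <- function(chip_percent, deg_percent) {
  dplyr::case_when(
    deg_percent > 0 & deg_percent >= 2 * chip_percent ~ "over",
    deg_percent > 0 & chip_percent > 0 &
      deg_percent <= 0.5 * chip_percent ~ "under",
    TRUE ~ "neither")
}

#' Run the full time-course DE analysis for one strain
#'
#' Statistic, resampling null, Storey q-values, DEG selection and phase
#' assignment in one call.
#'
#' @inheritParams timecourse_statistic
#' @inheritParams permutation_null
#' @param q_threshold DEG q-value cutoff.
#' @param phase_breaks Phase partition of the time axis.
#' @param lambda Storey lambda.
#' @return A `timecourse_de` object: tibble-backed results plus metadata;
#'   see [tidy.timecourse_de()].
#' @export
timecourse_de <- function(study, spline_df = 3L, B = 200L, seed = 1L,
                          q_threshold = 0.001, phase_breaks = c(36, 60),
                          lambda = 0.5) {
  stat <- timecourse_statistic(study, spline_df = spline_df)
  p <- permutation_null(study, B = B, seed = seed, spline_df = spline_df)
  q <- storey_qvalues(p, lambda = lambda)
  degs <- select_degs(q, threshold = q_threshold)
  phase <- rep("none", nrow(study$matrix))
  names(phase) <- rownames(study$matrix)
  tree <- NULL
  if (degs$n >= 2) {
    ph <- assign_phases(study$matrix[degs$genes, , drop = FALSE],
                        study$samples$time_h, phase_breaks)
    phase[ph$assignments$gene] <- ph$assignments$phase
    tree <- ph$tree
  }
  res <- tibble::tibble(gene = rownames(study$matrix),
                        statistic = unname(stat), p = unname(p),
                        q = as.numeric(q), phase = unname(phase))
  structure(list(results = res, degs = degs, tree = tree,
                 pi0 = attr(q, "pi0"), q_threshold = q_threshold,
                 spline_df = spline_df, B = B, seed = seed,
                 n_genes = nrow(study$matrix),
                 strain = unique(study$samples$strain)),
            class = "timecourse_de")
}

#' @export
print.timecourse_de <- function(x, ...) {
  cat(sprintf("<timecourse_de> %s: %d genes, %d DEGs at q <= %g (%.2f%%), pi0 = %.3f\n",
              paste(x$strain, collapse = "/"), x$n_genes, x$degs$n,
              x$q_threshold, x$degs$percent, x$pi0))
  invisible(x)
}
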