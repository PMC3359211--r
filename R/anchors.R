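#' Find unique-seed maximal exact matches between two genomes
#'
#' Enumerates maximal exact matches (MUM-style anchors) of length `>= k`
#' whose seed k-mer occurs exactly once in both sequences. Seeds on the same
#' diagonal are merged and extended to maximality, so each anchor is reported
#' once. Only the forward strand is compared: the two genomes are assumed
#' collinear (no inversions), which is the regime this diff targets.
#'
#' @param ref,qry [genome()] objects.
#' @param k Seed length (>= 12; shorter seeds collide too often on GC-rich
#'   genomes).
#' @return Tibble of anchors: `ref_start`, `qry_start`, `length`, sorted by
#'   `ref_start`.
#' @export
find_anchors <- function(ref, qry, k = 20L) {
  stopifnot(inherits(ref, "genome"), inherits(qry, "genome"))
  if (k < 12L) stop("k must be >= 12 (k-mer collision risk on GC-rich genomes)",
                    call. = FALSE)
  rseq <- ref$sequence; qseq <- qry$sequence
  nr <- nchar(rseq); nq <- nchar(qseq)
  if (nr < k || nq < k) return(empty_anchor_tbl())

  rk <- substring(rseq, 1:(nr - k + 1L), k:nr)
  qk <- substring(qseq, 1:(nq - k + 1L), k:nq)
  r_unique <- !(duplicated(rk) | duplicated(rk, fromLast = TRUE))
  q_unique <- !(duplicated(qk) | duplicated(qk, fromLast = TRUE))

  ri <- which(r_unique)
  hit <- match(rk[ri], qk)
  ok <- !is.na(hit)
  ri <- ri[ok]; qi <- hit[ok]
  ok <- q_unique[qi]
  ri <- ri[ok]; qi <- qi[ok]
  if (length(ri) == 0L) return(empty_anchor_tbl())

  # merge seeds on a common diagonal into runs, then extend to maximality
  diag <- qi - ri
  ord <- order(diag, ri)
  ri <- ri[ord]; qi <- qi[ord]; diag <- diag[ord]
  new_run <- c(TRUE, diff(ri) != 1L | diff(diag) != 0L)
  run_id <- cumsum(new_run)
  run_start <- tapply(ri, run_id, min)
  run_end <- tapply(ri, run_id, max) + k - 1L
  run_diag <- diag[new_run]

  rchars <- strsplit(rseq, "", fixed = TRUE)[[1]]
  qchars <- strsplit(qseq, "", fixed = TRUE)[[1]]

  n_runs <- length(run_start)
  a_ref <- integer(n_runs); a_len <- integer(n_runs)
  for (i in seq_len(n_runs)) {
    s <- run_start[[i]]; e <- run_end[[i]]; d <- run_diag[[i]]
    while (s > 1L && s + d > 1L && rchars[s - 1L] == qchars[s + d - 1L]) s <- s - 1L
    while (e < nr && e + d < nq && rchars[e + 1L] == qchars[e + d + 1L]) e <- e + 1L
    a_ref[i] <- s; a_len[i] <- e - s + 1L
  }

  out <- tibble::tibble(ref_start = a_ref, qry_start = a_ref + run_diag,
                        length = a_len) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$ref_start, .data$qry_start)
  out
}

empty_anchor_tbl <- function() {
  tibble::tibble(ref_start = integer(), qry_start = integer(),
                 length = integer())
}

#' Chain anchors into the heaviest collinear set
#'
#' Selects the strictly increasing, non-overlapping subset of anchors with
#' maximum total anchored bases (weighted longest-increasing-subsequence).
#' Among equal-weight chains the lexicographically smallest sequence of
#' `ref_start` values is preferred, making the output deterministic.
#' Anchors not on the chain (e.g. copies seeding off-diagonal matches) are
#' returned separately for transposition detection.
#'
#' @param anchors Anchor tibble from [find_anchors()].
#' @return List with `chain` and `off_chain` anchor tibbles.
#' @export
chain_anchors <- function(anchors) {
  n <- nrow(anchors)
  if (n == 0L) return(list(chain = anchors, off_chain = anchors))
  a <- anchors |> dplyr::arrange(.data$ref_start, .data$qry_start)
  rs <- a$ref_start; qs <- a$qry_start; len <- a$length
  re <- rs + len - 1L; qe <- qs + len - 1L
  best <- as.numeric(len)   # best chain weight ending at i
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    # predecessors strictly before i in all four coordinates; partial
    # overlaps (maximal matches extending through repeat copies) are allowed
    # here and clipped below
    js <- which(rs < rs[i] & qs < qs[i] & re < re[i] & qe < qe[i])
    if (length(js)) {
      w <- best[js] + len[i]
      m <- max(w)
      cand <- js[w == m]
      j <- cand[which.min(rs[cand])]   # lexicographic tie-break
      if (m > best[i] || (m == best[i] && is.na(prev[i]))) {
        best[i] <- m; prev[i] <- j
      }
    }
  }
  end <- which(best == max(best))
  end <- end[which.min(rs[end])]
  path <- integer()
  i <- end
  while (!is.na(i)) { path <- c(i, path); i <- prev[i] }
  chain <- clip_chain_overlaps(a[path, ])
  list(chain = chain, off_chain = a[setdiff(seq_len(n), path), ])
}

#' Trim chained anchors so consecutive anchors never overlap
#'
#' When a maximal match extends through a repeat copy it can overlap its
#' chain neighbour; the downstream anchor is trimmed from its start by the
#' larger of the reference/query overlaps (a diagonal exact match stays
#' exact under start-trimming). Anchors consumed entirely are dropped.
#' @noRd
clip_chain_overlaps <- function(chain) {
  if (nrow(chain) < 2L) return(chain)
  keep <- rep(TRUE, nrow(chain))
  last <- 1L
  for (i in 2L:nrow(chain)) {
    re_last <- chain$ref_start[last] + chain$length[last] - 1L
    qe_last <- chain$qry_start[last] + chain$length[last] - 1L
    o <- max(re_last - chain$ref_start[i] + 1L,
             qe_last - chain$qry_start[i] + 1L, 0L)
    if (o >= chain$length[i]) { keep[i] <- FALSE; next }
    if (o > 0L) {
      chain$ref_start[i] <- chain$ref_start[i] + o
      chain$qry_start[i] <- chain$qry_start[i] + o
      chain$length[i] <- chain$length[i] - o
    }
    last <- i
  }
  chain[keep, ]
}

#' Dot-plot data for two genomes
#'
#' Plain reformatting of the anchor set for plotting/export: one row per
#' anchor with its reference and query start and its length (the diagonal
#' segments of a Nucmer-style dot plot).
#'
#' @param anchors Anchor tibble from [find_anchors()].
#' @return Tibble `(ref_start, qry_start, length)`.
#' @export
dotplot_data <- function(anchors) {
  tibble::as_tibble(anchors[, c("ref_start", "qry_start", "length")])
}

#' Verify probe sequences against a genome
#'
#' Checks each 25-mer probe for a perfect full-length match on either strand
#' of the genome — the array-design sanity check that every probe still has a
#' 100%-identity, 25-bp hit in the strain being profiled.
#'
#' @param probes Character vector of probe sequences (all length 25).
#' @param genome A [genome()].
#' @return List with `report` (tibble: `probe`, `matched`) and
#'   `fraction_matched`.
#' @export
verify_probes <- function(probes, genome) {
  stopifnot(inherits(genome, "genome"))
  if (length(probes) == 0L) {
    return(list(report = tibble::tibble(probe = character(),
                                        matched = logical()),
                fraction_matched = NA_real_, n_probes = 0L))
  }
  if (any(nchar(probes) != 25L)) {
    stop(sprintf("probe length must be 25 bp, got %d",
                 nchar(probes)[nchar(probes) != 25L][1]), call. = FALSE)
  }
  probes <- toupper(probes)
  fwd <- genome$sequence
  rev <- revcomp(fwd)
  matched <- vapply(probes, function(p) {
    grepl(p, fwd, fixed = TRUE) || grepl(p, rev, fixed = TRUE)
  }, logical(1), USE.NAMES = FALSE)
  list(report = tibble::tibble(probe = probes, matched = matched),
       fraction_matched = mean(matched), n_probes = length(probes))
}
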