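# Shared fixtures and independent oracles used across test files.

toy_genome <- function(seq, id = "toy", circular = TRUE) {
  genome(id, seq, circular = circular)
}

# Independent apply-edits oracle: reconstructs the mutated sequence from a
# truth table by char-vector surgery, back to front (the package builds
# front to back from substr pieces).
oracle_apply_edits <- function(refseq, truth) {
  chars <- strsplit(refseq, "")[[1]]
  truth <- truth[order(truth$ref_position, decreasing = TRUE), ]
  for (i in seq_len(nrow(truth))) {
    t <- truth[i, ]
    if (t$type == "snv") {
      chars[t$ref_position] <- t$alt_allele
    } else if (t$type == "deletion") {
      chars <- chars[-(t$ref_position:(t$ref_position + nchar(t$ref_allele) - 1L))]
    } else {
      chars <- append(chars, strsplit(t$alt_allele, "")[[1]],
                      after = t$ref_position)
    }
  }
  paste(chars, collapse = "")
}

# Brute-force Needleman-Wunsch score with unit match/mismatch/gap scores.
oracle_nw_score <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- -(0:n); D[1, ] <- -(0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- max(D[i, j] + ifelse(ac[i] == bc[j], 1, -1),
                             D[i, j + 1] - 1, D[i + 1, j] - 1)
    }
  }
  D[n + 1, m + 1]
}

# Brute-force enumeration of maximal exact matches whose seed k-mer is
# unique in both sequences (quadratic; tiny inputs only).
oracle_mums <- function(a, b, k) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  na <- length(ac); nb <- length(bc)
  kmers <- function(x, n) if (n < k) character(0) else
    vapply(1:(n - k + 1), function(i) paste(x[i:(i + k - 1)], collapse = ""),
           character(1))
  ka <- kmers(ac, na); kb <- kmers(bc, nb)
  ua <- table(ka); ub <- table(kb)
  out <- list()
  for (i in seq_along(ka)) {
    if (ua[[ka[i]]] != 1L) next
    j <- which(kb == ka[i])
    if (length(j) != 1L || ub[[ka[i]]] != 1L) next
    s1 <- i; s2 <- j
    while (s1 > 1 && s2 > 1 && ac[s1 - 1] == bc[s2 - 1]) { s1 <- s1 - 1; s2 <- s2 - 1 }
    e1 <- i + k - 1; e2 <- j + k - 1
    while (e1 < na && e2 < nb && ac[e1 + 1] == bc[e2 + 1]) { e1 <- e1 + 1; e2 <- e2 + 1 }
    out[[length(out) + 1L]] <- c(s1, s2, e1 - s1 + 1)
  }
  if (length(out) == 0L) {
    return(tibble::tibble(ref_start = integer(), qry_start = integer(),
                          length = integer()))
  }
  m <- unique(do.call(rbind, out))
  tibble::tibble(ref_start = m[, 1], qry_start = m[, 2], length = m[, 3]) |>
    dplyr::arrange(ref_start, qry_start)
}

# Exhaustive heaviest strictly-increasing chain over <= 10 anchors.
oracle_best_chain <- function(anchors) {
  n <- nrow(anchors)
  best_w <- -1; best_set <- integer(0)
  rs <- anchors$ref_start; qs <- anchors$qry_start; len <- anchors$length
  re <- rs + len - 1; qe <- qs + len - 1
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) > 1) {
      o <- idx[order(rs[idx])]
      ok <- all(diff(rs[o]) > 0) && all(diff(qs[o]) > 0) &&
        all(re[o][-length(o)] < rs[o][-1]) && all(qe[o][-length(o)] < qs[o][-1])
      if (!ok) next
    }
    w <- sum(len[idx])
    if (w > best_w) { best_w <- w; best_set <- sort(idx) }
  }
  list(weight = best_w, idx = best_set)
}

# Tricube weighted-mean smoother, straightforward double loop.
oracle_smooth <- function(positions, raw, knn, circular_length = NULL) {
  n <- length(positions)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(positions - positions[i])
    if (!is.null(circular_length)) d <- pmin(d, circular_length - d)
    h <- sort(d[-i])[knn]
    u <- d / h
    w <- ifelse(u < 1, (1 - u^3)^3, 0)
    out[i] <- sum(w * raw) / sum(w)
  }
  out
}

# Build a small in-memory expression study with explicit values.
tiny_study <- function(values, time, reps = 2) {
  G <- nrow(values)
  samples <- tibble::tibble(sample = colnames(values), strain = "s",
                            time_h = time,
                            replicate = stats::ave(time, time, FUN = seq_along))
  genes <- tibble::tibble(gene = rownames(values),
                          position_bp = seq_len(G) * 1000, strand = "+")
  expression_study(values, samples, genes)
}

random_cds_genome <- function(n_cds = 5, seed = 1) {
  random_genome(20000, 0.6, seed = seed)
}
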