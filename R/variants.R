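#' Call variants between two collinear genomes from an anchor chain
#'
#' Every inter-anchor gap pair (including the unanchored genome ends) is
#' globally aligned with unit match/mismatch/gap scores; runs of mismatches
#' become SNVs and gap runs become left-aligned indels (VCF normalisation).
#' An insertion of at least `sv_min_len` bp whose sequence matches the
#' reference elsewhere at `>= sv_identity` identity is reclassified: as a
#' duplication when the copy sits adjacent to (tandem with) its source
#' interval, otherwise as a transposition.
#'
#' @param chained Result of [chain_anchors()], or an anchor tibble (then
#'   chained internally).
#' @param ref,qry [genome()] objects, linearised at position 1.
#' @param sv_min_len Minimum insertion length for copy classification (bp).
#' @param sv_identity Minimum identity of the copy to its source.
#' @param max_gap Maximum inter-anchor gap the aligner will accept (bp).
#' @return Tibble of variants sorted by `ref_pos`: `type` (`snv`, `insertion`,
#'   `deletion`, `transposition`, `duplication`), `ref_pos` (for insertions,
#'   the base after which material is inserted), `ref_allele`, `alt_allele`,
#'   `length`, `source_start`, `source_end`.
#' @export
call_variants <- function(chained, ref, qry, sv_min_len = 100L,
                          sv_identity = 0.95, max_gap = 50000L) {
  stopifnot(inherits(ref, "genome"), inherits(qry, "genome"))
  if (is.data.frame(chained)) chained <- chain_anchors(chained)
  chain <- chained$chain
  if (nrow(chain) == 0L) {
    stop("empty anchor chain: genomes not collinear enough", call. = FALSE)
  }
  cov_ref <- sum(chain$length) / ref$length
  cov_qry <- sum(chain$length) / qry$length
  if (cov_ref < 0.5 || cov_qry < 0.5) {
    stop(sprintf("anchor chain covers only %.0f%%/%.0f%% of ref/qry: genomes not collinear enough",
                 100 * cov_ref, 100 * cov_qry), call. = FALSE)
  }

  re <- chain$ref_start + chain$length - 1L
  qe <- chain$qry_start + chain$length - 1L
  # virtual zero-length anchors at both genome ends
  gap_ref_start <- c(1L, re + 1L)
  gap_ref_end   <- c(chain$ref_start - 1L, ref$length)
  gap_qry_start <- c(1L, qe + 1L)
  gap_qry_end   <- c(chain$qry_start - 1L, qry$length)

  out <- list()
  for (i in seq_along(gap_ref_start)) {
    rs <- gap_ref_start[i]; rer <- gap_ref_end[i]
    qs <- gap_qry_start[i]; qer <- gap_qry_end[i]
    rlen <- rer - rs + 1L; qlen <- qer - qs + 1L
    if (rlen <= 0L && qlen <= 0L) next
    if (rlen > max_gap || qlen > max_gap) {
      stop(sprintf("inter-anchor gap of %d bp exceeds the %d bp alignment band",
                   max(rlen, qlen), max_gap), call. = FALSE)
    }
    rseq <- if (rlen > 0L) genome_subseq(ref, rs, rer) else ""
    qseq <- if (qlen > 0L) genome_subseq(qry, qs, qer) else ""
    if (rlen <= 0L) {
      out[[length(out) + 1L]] <- variant_row("insertion", rs - 1L, "", qseq)
    } else if (qlen <= 0L) {
      out[[length(out) + 1L]] <- variant_row("deletion", rs, rseq, "")
    } else {
      out[[length(out) + 1L]] <- parse_gap_alignment(rseq, qseq, rs)
    }
  }
  vars <- dplyr::bind_rows(out)
  if (nrow(vars) == 0L) return(empty_variant_tbl())

  # left-align indels against the full reference
  for (i in which(vars$type %in% c("insertion", "deletion"))) {
    if (vars$type[i] == "deletion") {
      la <- left_align_indel(ref$sequence, vars$ref_pos[i], vars$ref_allele[i],
                             "deletion")
      vars$ref_pos[i] <- la$pos; vars$ref_allele[i] <- la$allele
    } else {
      la <- left_align_indel(ref$sequence, vars$ref_pos[i], vars$alt_allele[i],
                             "insertion")
      vars$ref_pos[i] <- la$pos; vars$alt_allele[i] <- la$allele
    }
  }

  vars <- classify_copies(vars, ref, sv_min_len, sv_identity)
  vars |> dplyr::arrange(.data$ref_pos, .data$type)
}

variant_row <- function(type, ref_pos, ref_allele, alt_allele,
                        source_start = NA_integer_, source_end = NA_integer_) {
  tibble::tibble(type = type, ref_pos = as.integer(ref_pos),
                 ref_allele = ref_allele, alt_allele = alt_allele,
                 length = nchar(if (type == "deletion") ref_allele else alt_allele),
                 source_start = source_start, source_end = source_end)
}

empty_variant_tbl <- function() {
  tibble::tibble(type = character(), ref_pos = integer(),
                 ref_allele = character(), alt_allele = character(),
                 length = integer(), source_start = integer(),
                 source_end = integer())
}

#' Globally align one gap pair and emit raw variants
#'
#' The two gap sequences are first trimmed of their common prefix and suffix
#' (a large indel then reduces to a one-sided remainder and is emitted
#' directly, without letting the aligner fragment it); only genuinely
#' substituted remainders reach the unit-score global aligner.
#' @noRd
parse_gap_alignment <- function(rseq, qseq, ref_offset) {
  nr <- nchar(rseq); nq <- nchar(qseq)
  pre <- common_prefix_len(rseq, qseq)
  suf <- common_suffix_len(rseq, qseq, max_len = min(nr, nq) - pre)
  r_mid <- substr(rseq, pre + 1L, nr - suf)
  q_mid <- substr(qseq, pre + 1L, nq - suf)
  if (nchar(r_mid) == 0L && nchar(q_mid) == 0L) return(empty_variant_tbl())
  if (nchar(r_mid) == 0L) {
    return(variant_row("insertion", ref_offset + pre - 1L, "", q_mid))
  }
  if (nchar(q_mid) == 0L) {
    return(variant_row("deletion", ref_offset + pre, r_mid, ""))
  }
  align_gap_pair(r_mid, q_mid, ref_offset + pre)
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ac <- substring(a, 1:n, 1:n); bc <- substring(b, 1:n, 1:n)
  neq <- which(ac != bc)
  if (length(neq) == 0L) n else neq[1] - 1L
}

common_suffix_len <- function(a, b, max_len) {
  na <- nchar(a); nb <- nchar(b)
  n <- max(0L, min(na, nb, max_len))
  if (n == 0L) return(0L)
  ac <- substring(a, na - n + 1:n, na - n + 1:n)
  bc <- substring(b, nb - n + 1:n, nb - n + 1:n)
  neq <- which(ac != bc)
  if (length(neq) == 0L) n else n - neq[length(neq)]
}

align_gap_pair <- function(rseq, qseq, ref_offset) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(rseq),
    subject = Biostrings::DNAString(qseq),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 0, gapExtension = 1
  )
  pr <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  out <- list()
  rpos <- ref_offset - 1L   # last consumed ref position
  i <- 1L; n <- length(pr)
  while (i <= n) {
    if (pr[i] == "-") {                       # insertion run
      j <- i
      while (j < n && pr[j + 1L] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- variant_row(
        "insertion", rpos, "", paste(sb[i:j], collapse = ""))
      i <- j + 1L
    } else if (sb[i] == "-") {                # deletion run
      j <- i
      while (j < n && sb[j + 1L] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- variant_row(
        "deletion", rpos + 1L, paste(pr[i:j], collapse = ""), "")
      rpos <- rpos + (j - i + 1L)
      i <- j + 1L
    } else {
      rpos <- rpos + 1L
      if (pr[i] != sb[i]) {
        out[[length(out) + 1L]] <- variant_row("snv", rpos, pr[i], sb[i])
      }
      i <- i + 1L
    }
  }
  dplyr::bind_rows(out)
}

#' Reclassify large insertions that copy existing reference sequence
#'
#' An exact full-length search runs first (Boyer-Moore, fast); when the copy
#' has diverged slightly, exact 30-mer seeds from the start/middle/end of
#' the insertion locate candidate source windows, which are verified by
#' percent identity under a global alignment.
#' @noRd
classify_copies <- function(vars, ref, sv_min_len, sv_identity) {
  idx <- which(vars$type == "insertion" & vars$length >= sv_min_len)
  if (length(idx) == 0L) return(vars)
  ref_dna <- Biostrings::DNAString(ref$sequence)
  for (i in idx) {
    src <- find_copy_source(vars$alt_allele[i], ref_dna, sv_identity)
    if (is.null(src)) next
    # prefer the hit nearest the insertion point
    d <- pmax(0L, src$start - vars$ref_pos[i], vars$ref_pos[i] - src$end)
    j <- which.min(d)
    src_s <- src$start[j]; src_e <- src$end[j]
    adjacent <- vars$ref_pos[i] >= src_s - 10L && vars$ref_pos[i] <= src_e + 10L
    vars$type[i] <- if (adjacent) "duplication" else "transposition"
    vars$source_start[i] <- src_s
    vars$source_end[i] <- src_e
  }
  vars
}

find_copy_source <- function(ins, ref_dna, sv_identity, seed_len = 30L) {
  hits <- Biostrings::matchPattern(ins, ref_dna)
  if (length(hits) > 0L) {
    return(list(start = BiocGenerics::start(hits),
                end = BiocGenerics::end(hits)))
  }
  len <- nchar(ins)
  if (len <= seed_len) return(NULL)
  offs <- unique(pmax(1L, pmin(len - seed_len + 1L,
                               c(1L, (len - seed_len) %/% 2L + 1L,
                                 len - seed_len + 1L))))
  cand_s <- integer(); cand_e <- integer()
  L <- length(ref_dna)
  for (o in offs) {
    seed <- substr(ins, o, o + seed_len - 1L)
    sh <- Biostrings::matchPattern(seed, ref_dna)
    for (s in BiocGenerics::start(sh)) {
      ws <- s - (o - 1L)           # implied source start
      we <- ws + len - 1L
      if (ws < 1L || we > L) next
      if (any(cand_s == ws)) next
      window <- as.character(Biostrings::subseq(ref_dna, ws, we))
      pid <- Biostrings::pid(Biostrings::pairwiseAlignment(
        Biostrings::DNAString(ins), Biostrings::DNAString(window),
        type = "global")) / 100
      if (pid >= sv_identity) {
        cand_s <- c(cand_s, ws); cand_e <- c(cand_e, we)
      }
    }
  }
  if (length(cand_s) == 0L) NULL else list(start = cand_s, end = cand_e)
}

#' Reconstruct the query sequence from reference plus variant calls
#'
#' @param ref Reference [genome()].
#' @param variants Variant tibble from [call_variants()] (or a truth table
#'   with column `ref_position`).
#' @return Reconstructed query sequence (character).
#' @export
apply_variants <- function(ref, variants) {
  stopifnot(inherits(ref, "genome"))
  v <- variants
  if ("ref_pos" %in% names(v)) {
    v <- dplyr::rename(v, ref_position = "ref_pos")
  }
  apply_truth(ref$sequence, v)
}

#' One-call collinear comparison of two genomes
#'
#' Runs [find_anchors()], [chain_anchors()] and [call_variants()] and bundles
#' the results.
#'
#' @inheritParams find_anchors
#' @inheritParams call_variants
#' @return List with `anchors`, `chain`, `off_chain`, `variants`, `dotplot`.
#' @export
compare_genomes <- function(ref, qry, k = 20L, sv_min_len = 100L,
                            sv_identity = 0.95, max_gap = 50000L) {
  anchors <- find_anchors(ref, qry, k = k)
  chained <- chain_anchors(anchors)
  variants <- call_variants(chained, ref, qry, sv_min_len = sv_min_len,
                            sv_identity = sv_identity, max_gap = max_gap)
  list(anchors = anchors, chain = chained$chain,
       off_chain = chained$off_chain, variants = variants,
       dotplot = dotplot_data(chained$chain))
}
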