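#' Generate a random annotated bacterial genome
#'
#' Bases are drawn i.i.d. at the requested G+C fraction (the high-GC
#' actinomycete default is 0.71). Non-overlapping CDSs (`ATG ... stop`,
#' lengths 300-1500 nt, both strands) are planted to tile roughly 85% of the
#' sequence: start and stop codons are written in, and in-frame internal stop
#' codons are repaired with a single GC-neutral-ish middle-base edit, so the
#' empirical GC stays within 1% of target for genomes of 100 kb and up.
#'
#' @param length Genome length in bp (>= 10,000).
#' @param gc Target G+C fraction, strictly inside (0, 1).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param id Genome id.
#' @param cog_categories Optional character vector of COG category codes to
#'   assign to CDSs at random (e.g. `c("III.5", "II.11")`); `NA` to skip.
#' @return A list with elements `genome` (a [genome()]) and `features`
#'   (a CDS tibble as from [read_gff()]).
#' @export
random_genome <- function(length, gc, seed, id = "synthetic_chr",
                          cog_categories = NULL) {
  stopifnot(length >= 10000)
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) {
    stop(sprintf("gc must lie strictly in (0, 1), got %s", gc), call. = FALSE)
  }
  set.seed(as.integer(seed))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(names(p), length, replace = TRUE, prob = p)

  # CDS tiling: alternate geometric gaps (mean ~160 bp) with CDSs of
  # 300-1500 nt, giving ~85% coding density.
  pos <- 1L
  starts <- integer(); ends <- integer(); strands <- character()
  while (TRUE) {
    gap <- stats::rgeom(1, 1 / 160) + 1L
    L <- 3L * sample(100:500, 1L)
    s <- pos + gap
    e <- s + L - 1L
    if (e > length - 3L) break
    starts <- c(starts, s); ends <- c(ends, e)
    strands <- c(strands, sample(c("+", "-"), 1L))
    pos <- e + 1L
  }

  stops_fwd <- c("TAA", "TAG", "TGA")
  fix_mid_fwd <- c(TAA = "C", TAG = "C", TGA = "C")   # coding middle base -> C
  stops_rev <- c("TTA", "CTA", "TCA")                 # revcomp of the stops
  fix_mid_rev <- c(TTA = "G", CTA = "G", TCA = "G")

  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    if (strands[i] == "+") {
      chars[s:(s + 2L)] <- c("A", "T", "G")
      chars[(e - 2L):e] <- c("T", "G", "A")
      cod_starts <- seq(s + 3L, e - 5L, by = 3L)
      cod <- paste0(chars[cod_starts], chars[cod_starts + 1L], chars[cod_starts + 2L])
      bad <- which(cod %in% stops_fwd)
      if (length(bad)) chars[cod_starts[bad] + 1L] <- fix_mid_fwd[cod[bad]]
    } else {
      chars[(e - 2L):e] <- c("C", "A", "T")           # revcomp(ATG)
      chars[s:(s + 2L)] <- c("T", "C", "A")           # revcomp(TGA)
      cod_starts <- seq(s + 3L, e - 5L, by = 3L)
      cod <- paste0(chars[cod_starts], chars[cod_starts + 1L], chars[cod_starts + 2L])
      bad <- which(cod %in% stops_rev)
      if (length(bad)) chars[cod_starts[bad] + 1L] <- fix_mid_rev[cod[bad]]
    }
  }

  g <- genome(id, paste(chars, collapse = ""), circular = TRUE)
  n <- length(starts)
  feats <- tibble::tibble(
    locus_tag    = sprintf("SYN_%04d", seq_len(n)),
    start        = starts,
    end          = ends,
    strand       = strands,
    product      = "hypothetical protein",
    cog_category = if (is.null(cog_categories)) NA_character_ else
      sample(cog_categories, n, replace = TRUE),
    core         = starts < 0.6 * length,
    translatable = TRUE
  )
  list(genome = g, features = feats)
}

#' Specify a mutation plan for a synthetic strain pair
#'
#' @param n_snv,n_small_indel,n_large_indel,n_mobile_insertion,n_duplication
#'   Event counts (all >= 0).
#' @param small_indel_max Maximum small-indel length (bp).
#' @param large_indel_range Length range for large indels (bp).
#' @param min_spacing Minimum distance between planted events (bp); must be
#'   at least twice the anchor seed size so events never merge.
#' @param seed Integer seed.
#' @return A `mutation_plan` list.
#' @export
mutation_plan <- function(n_snv = 0L, n_small_indel = 0L, n_large_indel = 0L,
                          n_mobile_insertion = 0L, n_duplication = 0L,
                          small_indel_max = 4L,
                          large_indel_range = c(100L, 1200L),
                          min_spacing = 2000L, seed = 1L) {
  counts <- c(n_snv, n_small_indel, n_large_indel, n_mobile_insertion,
              n_duplication)
  stopifnot(all(counts >= 0), small_indel_max >= 1,
            length(large_indel_range) == 2, min_spacing >= 40)
  structure(list(n_snv = n_snv, n_small_indel = n_small_indel,
                 n_large_indel = n_large_indel,
                 n_mobile_insertion = n_mobile_insertion,
                 n_duplication = n_duplication,
                 small_indel_max = small_indel_max,
                 large_indel_range = large_indel_range,
                 min_spacing = min_spacing, seed = seed),
            class = "mutation_plan")
}

#' Plant mutations in a genome, emitting the mutated genome and a truth table
#'
#' Events are placed at least `min_spacing` bp apart so each is independently
#' identifiable by the diff engine. Mobile insertions copy an existing
#' `>= 300` bp reference segment (a transposase-like event) into a new site;
#' duplications tandem-copy a whole CDS immediately after itself. Indel truth
#' records are left-aligned (VCF normalisation), matching the caller's output
#' convention.
#'
#' @param genome Reference [genome()].
#' @param plan A [mutation_plan()].
#' @param features CDS tibble (required when `n_duplication > 0` or
#'   `n_mobile_insertion > 0`).
#' @return List with `genome` (mutated, id suffixed `"_mut"`) and `truth`
#'   (tibble: `type`, `ref_position`, `ref_allele`, `alt_allele`, `length`,
#'   `source_start`, `source_end`, `affected_locus_tag`), sorted by position.
#' @export
mutate_genome <- function(genome, plan, features = NULL) {
  stopifnot(inherits(genome, "genome"), inherits(plan, "mutation_plan"))
  set.seed(as.integer(plan$seed))
  L <- genome$length
  n_events <- plan$n_snv + plan$n_small_indel + plan$n_large_indel +
    plan$n_mobile_insertion + plan$n_duplication
  if (n_events == 0L) {
    return(list(genome = genome, truth = empty_truth_tbl()))
  }
  max_span <- max(plan$large_indel_range[2], plan$small_indel_max, 1500L)
  span_total <- plan$n_large_indel * plan$large_indel_range[2] +
    (plan$n_mobile_insertion + plan$n_duplication) * 1500L
  if (n_events * plan$min_spacing + span_total > 0.85 * L) {
    stop("cannot satisfy min_spacing for this many events; lower the counts",
         call. = FALSE)
  }

  need_cds <- plan$n_duplication > 0L || plan$n_mobile_insertion > 0L
  if (need_cds && (is.null(features) || nrow(features) == 0L)) {
    stop("duplications/mobile insertions need a CDS feature table", call. = FALSE)
  }

  truth <- list()
  add <- function(type, ref_position, ref_allele, alt_allele,
                  source_start = NA_integer_, source_end = NA_integer_,
                  locus = NA_character_) {
    truth[[length(truth) + 1L]] <<- tibble::tibble(
      type = type, ref_position = as.integer(ref_position),
      ref_allele = ref_allele, alt_allele = alt_allele,
      length = nchar(if (type == "deletion") ref_allele else alt_allele),
      source_start = source_start, source_end = source_end,
      affected_locus_tag = locus)
  }

  # --- copy events: pick disjoint source CDSs, reserve their intervals ----
  n_copy <- plan$n_duplication + plan$n_mobile_insertion
  copy_src <- NULL
  if (need_cds) {
    cand <- features |>
      dplyr::filter(.data$end - .data$start + 1L <= 1500L,
                    .data$end - .data$start + 1L >= 300L,
                    .data$start > plan$min_spacing + 1500L,
                    .data$end < L - plan$min_spacing - 1500L)
    if (nrow(cand) < n_copy) {
      stop("not enough 300-1500 bp CDSs for the requested copy events",
           call. = FALSE)
    }
    copy_src <- cand[sample.int(nrow(cand), n_copy), ] |>
      dplyr::arrange(.data$start)
    for (j in seq_len(plan$n_duplication)) {
      f <- copy_src[j, ]
      seg <- genome_subseq(genome, f$start, f$end)
      add("duplication", f$end, "", seg, f$start, f$end, f$locus_tag)
    }
  }

  # --- remaining point/indel events: structured left-to-right layout -----
  # Rejection sampling jams far below the densities the event counts demand,
  # so positions are laid out sequentially with Dirichlet-distributed slack:
  # uniform-ish placement that always succeeds when the arithmetic allows.
  ev <- tibble::tibble(kind = character(), len = integer())
  row <- function(kind, len) tibble::tibble(kind = kind, len = as.integer(len))
  if (plan$n_snv > 0L) ev <- dplyr::bind_rows(ev, row(rep("snv", plan$n_snv), 1L))
  for (i in seq_len(plan$n_small_indel)) {
    kind <- if (stats::runif(1) < 0.5) "del" else "ins"
    ev <- dplyr::bind_rows(ev, row(kind, sample.int(plan$small_indel_max, 1L)))
  }
  for (i in seq_len(plan$n_large_indel)) {
    kind <- if (stats::runif(1) < 0.5) "del" else "ins"
    ev <- dplyr::bind_rows(ev, row(kind,
      sample(plan$large_indel_range[1]:plan$large_indel_range[2], 1L)))
  }
  if (plan$n_mobile_insertion > 0L) {
    ev <- dplyr::bind_rows(ev, row(rep("mobile", plan$n_mobile_insertion), 1L))
  }

  if (nrow(ev) > 0L) {
    ev <- ev[sample.int(nrow(ev)), ]
    # free segments between reserved source intervals (with spacing margins)
    margin <- plan$min_spacing
    blocked_s <- integer(); blocked_e <- integer()
    if (!is.null(copy_src) && nrow(copy_src) > 0L) {
      blocked_s <- copy_src$start - margin
      blocked_e <- copy_src$end + margin
    }
    seg_s <- c(margin + 1L, blocked_e + 1L)
    seg_e <- c(blocked_s - 1L, L - margin)
    keep <- seg_e - seg_s >= 0L
    seg_s <- seg_s[keep]; seg_e <- seg_e[keep]
    seg_len <- seg_e - seg_s + 1L

    need <- ev$len + margin   # footprint of each event incl. spacing
    # assign events to segments proportionally to capacity, greedy fill
    seg_order <- order(seg_len, decreasing = TRUE)
    assignment <- integer(nrow(ev))
    cap <- as.numeric(seg_len)
    for (i in seq_len(nrow(ev))) {
      ok <- which(cap >= need[i] + margin)
      if (length(ok) == 0L) {
        stop("cannot satisfy min_spacing for this many events; lower the counts",
             call. = FALSE)
      }
      pick <- if (length(ok) == 1L) ok else
        sample(ok, 1L, prob = cap[ok] / sum(cap[ok]))
      assignment[i] <- pick
      cap[pick] <- cap[pick] - need[i]
    }

    positions <- integer(nrow(ev))
    for (sgi in unique(assignment)) {
      idx <- which(assignment == sgi)
      footprint <- sum(need[idx])
      slack <- seg_len[sgi] - footprint
      cuts <- sort(stats::runif(length(idx), 0, slack))
      gaps <- diff(c(0, cuts))
      cur <- seg_s[sgi]
      for (j in seq_along(idx)) {
        cur <- cur + gaps[j]
        positions[idx[j]] <- as.integer(round(cur))
        cur <- cur + need[idx[j]]
      }
    }

    for (i in seq_len(nrow(ev))) {
      pos <- positions[i]
      kind <- ev$kind[i]; len <- ev$len[i]
      if (kind == "snv") {
        ref <- genome_subseq(genome, pos, pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        add("snv", pos, ref, alt)
      } else if (kind == "del") {
        ref <- genome_subseq(genome, pos, pos + len - 1L)
        la <- left_align_indel(genome$sequence, pos, ref, "deletion")
        add("deletion", la$pos, la$allele, "")
      } else if (kind == "ins") {
        alt <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        la <- left_align_indel(genome$sequence, pos, alt, "insertion")
        add("insertion", la$pos, "", la$allele)
      } else {  # mobile: copy a reserved source CDS into this site
        f <- copy_src[plan$n_duplication +
                        match(i, which(ev$kind == "mobile")), ]
        seg <- genome_subseq(genome, f$start, f$end)
        add("transposition", pos, "", seg, f$start, f$end, f$locus_tag)
      }
    }
  }

  truth <- dplyr::bind_rows(truth) |> dplyr::arrange(.data$ref_position)
  mutated <- apply_truth(genome$sequence, truth)
  list(genome = genome(paste0(genome$id, "_mut"), mutated,
                       circular = genome$circular),
       truth = truth)
}

empty_truth_tbl <- function() {
  tibble::tibble(type = character(), ref_position = integer(),
                 ref_allele = character(), alt_allele = character(),
                 length = integer(), source_start = integer(),
                 source_end = integer(), affected_locus_tag = character())
}

#' Left-align an indel against the reference sequence
#'
#' Shifts an indel to the lowest reference position at which the same edited
#' sequence results (VCF normalisation). For a deletion `allele` is the
#' deleted reference string starting at `pos`; for an insertion it is the
#' inserted string placed after `pos`.
#' @noRd
left_align_indel <- function(refseq, pos, allele, type) {
  len <- nchar(allele)
  if (type == "deletion") {
    # shift left while the base before the run equals the last deleted base
    while (pos > 1L &&
           substr(refseq, pos - 1L, pos - 1L) == substr(allele, len, len)) {
      allele <- paste0(substr(refseq, pos - 1L, pos - 1L),
                       substr(allele, 1L, len - 1L))
      pos <- pos - 1L
    }
  } else {
    while (pos > 0L &&
           substr(refseq, pos, pos) == substr(allele, len, len)) {
      allele <- paste0(substr(refseq, pos, pos), substr(allele, 1L, len - 1L))
      pos <- pos - 1L
    }
  }
  list(pos = pos, allele = allele)
}

#' Apply a truth table of edits to a reference sequence
#' @noRd
apply_truth <- function(refseq, truth) {
  if (nrow(truth) == 0L) return(refseq)
  truth <- truth[order(truth$ref_position), ]
  pieces <- character(); cur <- 1L
  for (i in seq_len(nrow(truth))) {
    t <- truth[i, ]
    if (t$type == "snv") {
      pieces <- c(pieces, substr(refseq, cur, t$ref_position - 1L), t$alt_allele)
      cur <- t$ref_position + 1L
    } else if (t$type == "deletion") {
      pieces <- c(pieces, substr(refseq, cur, t$ref_position - 1L))
      cur <- t$ref_position + nchar(t$ref_allele)
    } else {  # insertion / transposition / duplication: insert after ref_position
      pieces <- c(pieces, substr(refseq, cur, t$ref_position), t$alt_allele)
      cur <- t$ref_position + 1L
    }
  }
  paste0(paste(pieces, collapse = ""), substr(refseq, cur, nchar(refseq)))
}

#' Write a truth table (or variant calls) as VCF 4.2
#'
#' SNVs and indels are written with VCF anchor-base conventions; large copy
#' events carry `SVTYPE=DUP` or `SVTYPE=INS` plus the source interval in
#' `INFO`.
#'
#' @param truth Truth tibble from [mutate_genome()] or calls from
#'   [call_variants()] (column `type` plus positions/alleles).
#' @param genome Reference [genome()] (for the anchor bases and header).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, genome, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", genome$id, genome$length),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Structural variant type\">",
    "##INFO=<ID=SOURCE,Number=1,Type=String,Description=\"Source interval of copied segment\">",
    "##INFO=<ID=VT,Number=1,Type=String,Description=\"Variant class\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- purrr::pmap_chr(truth, function(type, ref_position, ref_allele,
                                          alt_allele, ...) {
    extra <- list(...)
    if (type == "snv") {
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tVT=snv", genome$id, ref_position,
              ref_allele, alt_allele)
    } else if (type == "deletion") {
      anchor_pos <- max(1L, ref_position - 1L)
      anchor <- genome_subseq(genome, anchor_pos, anchor_pos)
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tVT=deletion", genome$id, anchor_pos,
              paste0(anchor, ref_allele), anchor)
    } else {
      anchor <- genome_subseq(genome, ref_position, ref_position)
      info <- sprintf("VT=%s", type)
      if (type %in% c("transposition", "duplication")) {
        sv <- if (type == "duplication") "DUP" else "INS"
        src <- if (!is.null(extra$source_start) && !is.na(extra$source_start)) {
          sprintf(";SOURCE=%d-%d", extra$source_start, extra$source_end)
        } else ""
        info <- sprintf("VT=%s;SVTYPE=%s%s", type, sv, src)
      }
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", genome$id, ref_position,
              anchor, paste0(anchor, alt_allele), info)
    }
  })
  writeLines(c(header, rows), path)
  invisible(path)
}
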