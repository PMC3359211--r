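#' Annotate variants with their consequences on CDSs
#'
#' Maps each variant onto the (sorted, non-overlapping) CDS list and
#' classifies the effect per overlapped CDS: `missense`, `nonsense`,
#' `silent`, `frameshift`, `in_frame_insertion`, `in_frame_deletion`,
#' `duplication`, `transposon_insertion` or `intergenic` (intergenic records
#' name the flanking locus tags). Positions are reported on the coding
#' strand, in nucleotides from the CDS start. All SNVs falling in one codon
#' are applied jointly before translating, so double substitutions in a codon
#' are evaluated as one amino-acid change.
#'
#' @param variants Variant tibble from [call_variants()] (columns `type`,
#'   `ref_pos`, `ref_allele`, `alt_allele`, `length`).
#' @param cds CDS tibble from [read_gff()], sorted and non-overlapping.
#' @param ref_genome Reference [genome()].
#' @return Tibble of effect records: `locus_tag`, `effect_class`,
#'   `cds_position`, `protein_changes` (list of tibbles `ref_aa`, `position`,
#'   `alt_aa`), `notation`, `variant_type`, `ref_pos`.
#' @export
annotate_variants <- function(variants, cds, ref_genome) {
  stopifnot(inherits(ref_genome, "genome"))
  if (nrow(variants) == 0L) return(empty_effect_tbl())
  if (any(variants$ref_pos < 0L | variants$ref_pos > ref_genome$length)) {
    stop("variant beyond genome length", call. = FALSE)
  }
  cds <- dplyr::arrange(cds, .data$start)

  # reference interval touched by each variant
  v <- variants |>
    dplyr::mutate(iv_start = dplyr::if_else(.data$type == "deletion",
                                            .data$ref_pos,
                                            .data$ref_pos),
                  iv_end = dplyr::if_else(
                    .data$type == "deletion",
                    .data$ref_pos + nchar(.data$ref_allele) - 1L,
                    .data$ref_pos))

  recs <- list()
  for (i in seq_len(nrow(v))) {
    vi <- v[i, ]
    # a duplication is credited to the CDS it copies (its source interval),
    # not to the locus at the insertion point
    if (vi$type == "duplication" && !is.na(vi$source_start)) {
      hit <- which(cds$end >= vi$source_start & cds$start <= vi$source_end)
      if (length(hit) > 0L) {
        for (h in hit) {
          f <- cds[h, ]
          recs[[length(recs) + 1L]] <- tibble::tibble(
            locus_tag = f$locus_tag, effect_class = "duplication",
            cds_position = 1L, protein_changes = list(empty_change_tbl()),
            notation = sprintf("Duplication (%d bp)", vi$length),
            variant_type = "duplication", ref_pos = vi$ref_pos)
        }
        next
      }
    }
    # insertions sit between ref_pos and ref_pos+1: they hit a CDS only if
    # strictly inside it
    if (vi$type == "deletion") {
      hit <- which(cds$end >= vi$iv_start & cds$start <= vi$iv_end)
    } else if (vi$type == "snv") {
      hit <- which(cds$start <= vi$ref_pos & cds$end >= vi$ref_pos)
    } else {
      hit <- which(cds$start <= vi$ref_pos & cds$end >= vi$ref_pos + 1L)
    }
    if (length(hit) == 0L) {
      recs[[length(recs) + 1L]] <- intergenic_record(vi, cds)
      next
    }
    for (h in hit) {
      recs[[length(recs) + 1L]] <- cds_effect(vi, cds[h, ], ref_genome,
                                              variants)
    }
  }
  dplyr::bind_rows(recs)
}

#' @rdname annotate_variants
#' @param variant One-row variant tibble.
#' @export
annotate_variant <- function(variant, cds, ref_genome) {
  annotate_variants(variant, cds, ref_genome)
}

empty_effect_tbl <- function() {
  tibble::tibble(locus_tag = character(), effect_class = character(),
                 cds_position = integer(), protein_changes = list(),
                 notation = character(), variant_type = character(),
                 ref_pos = integer())
}

intergenic_record <- function(vi, cds) {
  left <- cds$locus_tag[cds$end < vi$iv_start]
  right <- cds$locus_tag[cds$start > vi$iv_end]
  flank <- sprintf("between %s and %s",
                   if (length(left)) left[length(left)] else "origin",
                   if (length(right)) right[1] else "terminus")
  tibble::tibble(locus_tag = NA_character_, effect_class = "intergenic",
                 cds_position = NA_integer_,
                 protein_changes = list(empty_change_tbl()),
                 notation = sprintf("Intergenic (%s)", flank),
                 variant_type = vi$type, ref_pos = vi$ref_pos)
}

empty_change_tbl <- function() {
  tibble::tibble(ref_aa = character(), position = integer(),
                 alt_aa = character())
}

#' Coding-strand CDS position of a genome coordinate
#' @noRd
cds_coord <- function(pos, feat) {
  if (feat$strand == "+") pos - feat$start + 1L else feat$end - pos + 1L
}

#' Classify one variant against one CDS
#' @noRd
cds_effect <- function(vi, feat, ref_genome, all_variants) {
  rec <- function(class, cds_position, changes, notation) {
    tibble::tibble(locus_tag = feat$locus_tag, effect_class = class,
                   cds_position = as.integer(cds_position),
                   protein_changes = list(changes), notation = notation,
                   variant_type = vi$type, ref_pos = vi$ref_pos)
  }

  if (vi$type %in% c("transposition", "duplication")) {
    class <- if (vi$type == "duplication") "duplication" else
      "transposon_insertion"
    cp <- cds_coord(vi$ref_pos, feat)
    label <- if (vi$type == "duplication") "Duplication" else
      "Transposon insertion"
    return(rec(class, cp, empty_change_tbl(),
               sprintf("%s (%d bp at %d)", label, vi$length, cp)))
  }

  if (vi$type == "snv") {
    return(snv_effect(vi, feat, ref_genome, all_variants, rec))
  }

  # indels
  net <- if (vi$type == "insertion") vi$length else -vi$length
  if (abs(net) %% 3L != 0L) {
    return(frameshift_effect(vi, feat, rec))
  }
  in_frame_effect(vi, feat, ref_genome, rec)
}

snv_effect <- function(vi, feat, ref_genome, all_variants, rec) {
  cp <- cds_coord(vi$ref_pos, feat)
  codon_idx <- (cp - 1L) %/% 3L + 1L
  # genome coordinates of the codon
  if (feat$strand == "+") {
    g0 <- feat$start + 3L * (codon_idx - 1L)
    gpos <- g0:(g0 + 2L)
  } else {
    g0 <- feat$end - 3L * (codon_idx - 1L)
    gpos <- g0:(g0 - 2L)
  }
  ref_codon <- chartr_strand(genome_bases(ref_genome, gpos), feat$strand)
  # apply every SNV hitting this codon jointly
  mut_codon <- ref_codon
  snvs_here <- all_variants[all_variants$type == "snv" &
                              all_variants$ref_pos %in% range_span(gpos), ]
  for (k in seq_len(nrow(snvs_here))) {
    off <- match(snvs_here$ref_pos[k], gpos)
    base <- snvs_here$alt_allele[k]
    if (feat$strand == "-") base <- REVCOMP_MAP[[base]]
    substr(mut_codon, off, off) <- base
  }
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(mut_codon)
  n_codons <- (feat$end - feat$start + 1L) %/% 3L
  changes <- tibble::tibble(ref_aa = ref_aa, position = codon_idx,
                            alt_aa = alt_aa)
  if (alt_aa == ref_aa) {
    rec("silent", cp, changes, sprintf("Silent (%s%d)", ref_aa, codon_idx))
  } else if (alt_aa == "*" && codon_idx < n_codons) {
    rec("nonsense", cp, changes, format_changes("Nonsense", changes))
  } else {
    rec("missense", cp, changes, format_changes("Missense", changes))
  }
}

range_span <- function(gpos) min(gpos):max(gpos)

genome_bases <- function(g, gpos) {
  paste(vapply(sort(gpos), function(p) genome_subseq(g, p, p), character(1)),
        collapse = "")
}

#' Read a genome segment on a given strand (coding orientation)
#' @noRd
chartr_strand <- function(seq, strand) {
  if (strand == "-") revcomp(seq) else seq
}

frameshift_effect <- function(vi, feat, rec) {
  if (vi$type == "deletion") {
    if (feat$strand == "+") {
      cp <- cds_coord(vi$ref_pos, feat)
      bases <- vi$ref_allele
    } else {
      cp <- cds_coord(vi$ref_pos + vi$length - 1L, feat)
      bases <- revcomp(vi$ref_allele)
    }
    notation <- sprintf("Frameshift (-%s %d)", bases, cp)
  } else {
    # insertion after ref_pos on the forward strand; on the coding strand it
    # follows position p with p = cds_coord of the flanking base
    if (feat$strand == "+") {
      cp <- cds_coord(vi$ref_pos, feat)
      bases <- vi$alt_allele
    } else {
      cp <- cds_coord(vi$ref_pos + 1L, feat)
      bases <- revcomp(vi$alt_allele)
    }
    notation <- sprintf("Frameshift (+%s %d/%d)", bases, cp, cp + 1L)
  }
  rec("frameshift", cp, empty_change_tbl(), notation)
}

in_frame_effect <- function(vi, feat, ref_genome, rec) {
  # Rebuild the CDS locally: splice the allele into the reference CDS and
  # retranslate from the first affected codon onward.
  cds_seq <- chartr_strand(genome_subseq(ref_genome, feat$start, feat$end),
                           feat$strand)
  if (vi$type == "deletion") {
    if (feat$strand == "+") {
      cp <- cds_coord(vi$ref_pos, feat)
    } else {
      cp <- cds_coord(vi$ref_pos + vi$length - 1L, feat)
    }
    mut_seq <- paste0(substr(cds_seq, 1L, cp - 1L),
                      substr(cds_seq, cp + vi$length, nchar(cds_seq)))
  } else {
    if (feat$strand == "+") {
      cp <- cds_coord(vi$ref_pos, feat)
      ins <- vi$alt_allele
    } else {
      cp <- cds_coord(vi$ref_pos + 1L, feat)
      ins <- revcomp(vi$alt_allele)
    }
    mut_seq <- paste0(substr(cds_seq, 1L, cp),
                      ins, substr(cds_seq, cp + 1L, nchar(cds_seq)))
  }
  ref_aa <- safe_translate(cds_seq)
  alt_aa <- safe_translate(mut_seq)
  changes <- diff_proteins(ref_aa, alt_aa)
  if (vi$type == "deletion") {
    rec("in_frame_deletion", cp, changes,
        format_changes("In frame deletion", changes))
  } else {
    rec("in_frame_insertion", cp, changes,
        format_changes("In frame insertion", changes))
  }
}

safe_translate <- function(nt) {
  nt <- substr(nt, 1L, 3L * (nchar(nt) %/% 3L))
  if (nchar(nt) < 3L) return("")
  translate_orf(nt)
}

#' Diff two protein strings into per-residue changes
#'
#' Aligns the two proteins by anchoring on their common prefix and suffix
#' (sufficient for single in-frame events) and reports removed residues as
#' `alt_aa = "-"`, inserted residues as `ref_aa = "-"`, substitutions
#' directly.
#' @noRd
diff_proteins <- function(ref_aa, alt_aa) {
  r <- strsplit(ref_aa, "")[[1]]; a <- strsplit(alt_aa, "")[[1]]
  nr <- length(r); na <- length(a)
  pre <- 0L
  while (pre < min(nr, na) && r[pre + 1L] == a[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < min(nr, na) - pre && r[nr - suf] == a[na - suf]) suf <- suf + 1L
  mid_r <- if (pre + suf < nr) r[(pre + 1L):(nr - suf)] else character()
  mid_a <- if (pre + suf < na) a[(pre + 1L):(na - suf)] else character()
  out <- list()
  n_sub <- min(length(mid_r), length(mid_a))
  for (k in seq_len(n_sub)) {
    out[[length(out) + 1L]] <- tibble::tibble(ref_aa = mid_r[k],
                                              position = pre + k,
                                              alt_aa = mid_a[k])
  }
  if (length(mid_r) > n_sub) {
    for (k in (n_sub + 1L):length(mid_r)) {
      out[[length(out) + 1L]] <- tibble::tibble(ref_aa = mid_r[k],
                                                position = pre + k,
                                                alt_aa = "-")
    }
  } else if (length(mid_a) > n_sub) {
    for (k in (n_sub + 1L):length(mid_a)) {
      out[[length(out) + 1L]] <- tibble::tibble(ref_aa = "-",
                                                position = pre + k,
                                                alt_aa = mid_a[k])
    }
  }
  if (length(out) == 0L) empty_change_tbl() else dplyr::bind_rows(out)
}

#' Format an effect record as mutation-table notation
#'
#' Produces the conventional strings: `"Missense (G38S)"`,
#' `"Nonsense (Y30*)"`, `"Frameshift (-C 717)"` for a deletion frameshift,
#' `"Frameshift (+T 2003/2004)"` for an insertion frameshift (the inserted
#' base follows coding-strand position 2003), `"In frame deletion (V196-,
#' H197-)"`, `"In frame insertion (-196V)"`. This is a pure function of the
#' record's fields.
#'
#' @param e One effect record (row of [annotate_variants()] output).
#' @return Notation string.
#' @export
format_effect <- function(e) {
  changes <- e$protein_changes[[1]]
  switch(e$effect_class,
    missense  = format_changes("Missense", changes),
    nonsense  = format_changes("Nonsense", changes),
    silent    = sprintf("Silent (%s%d)", changes$ref_aa[1], changes$position[1]),
    frameshift = e$notation,
    in_frame_deletion  = format_changes("In frame deletion", changes),
    in_frame_insertion = format_changes("In frame insertion", changes),
    e$notation
  )
}

format_changes <- function(label, changes) {
  if (nrow(changes) == 0L) return(sprintf("%s ()", label))
  parts <- purrr::pmap_chr(changes, function(ref_aa, position, alt_aa) {
    if (alt_aa == "-") sprintf("%s%d-", ref_aa, position)        # residue lost
    else if (ref_aa == "-") sprintf("-%d%s", position, alt_aa)   # residue gained
    else sprintf("%s%d%s", ref_aa, position, alt_aa)
  })
  sprintf("%s (%s)", label, paste(parts, collapse = ", "))
}

#' Core / non-core membership of a genome position
#'
#' Intervals are half-open `[start, end)` in 1-based coordinates, so a
#' position equal to an interval's `end` is non-core.
#'
#' @param position Genome coordinate(s).
#' @param core_intervals Tibble `(start, end)`, sorted, non-overlapping (as
#'   from [read_core_bed()]).
#' @param genome_length Upper bound for validation.
#' @return Character vector in `{"core", "noncore"}`.
#' @export
classify_region <- function(position, core_intervals, genome_length = Inf) {
  if (any(position < 1 | position > genome_length)) {
    stop("position out of genome range", call. = FALSE)
  }
  vapply(position, function(p) {
    inside <- any(core_intervals$start <= p & p < core_intervals$end)
    if (inside) "core" else "noncore"
  }, character(1))
}

#' Summarize variant and effect counts
#'
#' Tallies the inventory a strain-pair comparison reports: deletion sites,
#' insertion sites, transposition sites, duplicated CDSs, CDSs hit by SNVs,
#' missense/nonsense/silent changes, frameshift-bearing CDSs, and the number
#' of distinct affected proteins (distinct locus tags over non-silent,
#' non-intergenic effect records — silent changes are recorded but do not
#' count a protein as affected).
#'
#' @param effects Effect tibble from [annotate_variants()].
#' @param variants Variant tibble from [call_variants()].
#' @return One-row tibble of counts.
#' @export
summarize_counts <- function(effects, variants) {
  n_distinct_tags <- function(tbl) length(unique(stats::na.omit(tbl$locus_tag)))
  affected <- effects |>
    dplyr::filter(!.data$effect_class %in% c("silent", "intergenic"))
  tibble::tibble(
    deletion_sites = sum(variants$type == "deletion"),
    insertion_sites = sum(variants$type == "insertion"),
    transposition_sites = sum(variants$type == "transposition"),
    duplication_sites = sum(variants$type == "duplication"),
    snv_sites = sum(variants$type == "snv"),
    snv_cds = n_distinct_tags(effects[effects$variant_type == "snv" &
                                        effects$effect_class != "intergenic", ]),
    missense = sum(effects$effect_class == "missense"),
    nonsense = sum(effects$effect_class == "nonsense"),
    silent = sum(effects$effect_class == "silent"),
    frameshift_cds = n_distinct_tags(effects[effects$effect_class == "frameshift", ]),
    duplicated_cds = n_distinct_tags(effects[effects$effect_class == "duplication", ]),
    transposon_insertion_cds = n_distinct_tags(
      effects[effects$effect_class == "transposon_insertion", ]),
    affected_proteins = n_distinct_tags(affected)
  )
}

#' Write effects as a mutation-table style TSV
#'
#' Columns mirror the published table layout: locus, protein length (aa),
#' variation notation, product.
#'
#' @param effects Effect tibble.
#' @param cds CDS tibble (for lengths/products).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effect_tsv <- function(effects, cds, path) {
  tab <- effects |>
    dplyr::left_join(cds |>
                       dplyr::transmute(locus_tag = .data$locus_tag,
                                        length_aa = (.data$end - .data$start + 1L) %/% 3L - 1L,
                                        product = .data$product),
                     by = "locus_tag") |>
    dplyr::select("locus_tag", "length_aa", "notation", "product", "ref_pos")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
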