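# Builds a toy genome holding one CDS with a known coding sequence, padded
# by non-coding flanks, on either strand.
one_cds_genome <- function(cds_nt, strand = "+", flank = 60L) {
  set.seed(nchar(cds_nt))
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  placed <- if (strand == "+") cds_nt else revcomp(cds_nt)
  seq <- paste0(pad(flank), placed, pad(flank))
  g <- genome("toy", seq)
  cds <- tibble::tibble(locus_tag = "cds1", start = flank + 1L,
                        end = flank + nchar(cds_nt), strand = strand,
                        product = "test protein", cog_category = NA_character_,
                        core = TRUE, translatable = TRUE)
  list(genome = g, cds = cds)
}

# Independent oracle: apply the variant to the whole genome, extract the CDS
# from the mutated genome (coordinates shifted by any upstream indel),
# retranslate with the package translator, and diff the two proteins.
oracle_effect <- function(variant, cds, g) {
  truth <- dplyr::rename(variant, ref_position = "ref_pos")
  mut_seq <- oracle_apply_edits(g$sequence, truth)
  net <- if (variant$type == "insertion") variant$length else
    if (variant$type == "deletion") -variant$length else 0L
  mut_end <- cds$end + net
  mg <- genome("mut", mut_seq)
  ref_aa <- translate_cds(cds, g)
  len <- mut_end - cds$start + 1L
  mut_nt <- substr(mut_seq, cds$start, cds$start + 3L * (len %/% 3L) - 1L)
  if (cds$strand == "-") {
    mut_nt <- substr(mut_seq, cds$end + net - 3L * (len %/% 3L) + 1L,
                     cds$end + net)
    mut_nt <- revcomp(mut_nt)
  }
  alt_aa <- straindiff:::translate_orf(mut_nt)
  if (net %% 3L != 0L && net != 0L) return(list(class = "frameshift"))
  if (net != 0L) {
    return(list(class = if (net < 0) "in_frame_deletion" else "in_frame_insertion",
                changes = straindiff:::diff_proteins(ref_aa, alt_aa)))
  }
  d <- straindiff:::diff_proteins(ref_aa, alt_aa)
  if (nrow(d) == 0L) return(list(class = "silent"))
  n_codons <- (cds$end - cds$start + 1L) / 3L
  if (any(d$alt_aa == "*") && all(d$position < n_codons)) {
    return(list(class = "nonsense", changes = d))
  }
  list(class = "missense", changes = d)
}
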