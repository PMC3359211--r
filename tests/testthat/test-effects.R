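test_that("the published notation strings are reproduced from constructed variants", {
  # Missense (G38S): codon 38 GGT -> AGT in a '+' CDS
  set.seed(1)
  body <- replicate(60, {
    repeat {
      cod <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
      if (!cod %in% c("TAA", "TAG", "TGA")) return(cod)
    }
  })
  body[38] <- "GGT"
  body[30] <- "TAC"   # for the nonsense case below
  cds_nt <- paste0("ATG", paste(body[-1], collapse = ""), "TGA")
  fix <- one_cds_genome(cds_nt)
  pos_g38 <- fix$cds$start + (38 - 1) * 3   # first base of codon 38 is G
  v <- tibble::tibble(type = "snv", ref_pos = pos_g38, ref_allele = "G",
                      alt_allele = "A", length = 1L,
                      source_start = NA_integer_, source_end = NA_integer_)
  e <- annotate_variants(v, fix$cds, fix$genome)
  expect_equal(e$effect_class, "missense")
  expect_equal(e$notation, "Missense (G38S)")
  expect_equal(format_effect(e[1, ]), "Missense (G38S)")

  # Nonsense (Y30*): codon 30 TAC -> TAA
  pos_y30 <- fix$cds$start + (30 - 1) * 3 + 2   # third base of codon 30
  v2 <- tibble::tibble(type = "snv", ref_pos = pos_y30, ref_allele = "C",
                       alt_allele = "A", length = 1L,
                       source_start = NA_integer_, source_end = NA_integer_)
  e2 <- annotate_variants(v2, fix$cds, fix$genome)
  expect_equal(e2$effect_class, "nonsense")
  expect_equal(e2$notation, "Nonsense (Y30*)")

  # Frameshift (-C 717): single-base deletion at CDS position 717
  set.seed(2)
  body2 <- replicate(335, {
    repeat {
      cod <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
      if (!cod %in% c("TAA", "TAG", "TGA")) return(cod)
    }
  })
  cds2 <- paste0("ATG", paste(body2[-1], collapse = ""), "TGA")
  expect_equal(nchar(cds2), 335 * 3 + 3)   # 335 aa plus the trailing stop
  fix2 <- one_cds_genome(cds2)
  g2seq <- fix2$genome$sequence
  pos717 <- fix2$cds$start + 717 - 1
  # ensure the deleted base really is C and is not left-shiftable
  substr(g2seq, pos717 - 1, pos717 + 1) <- "ACG"
  fix2$genome <- genome("toy", g2seq)
  v3 <- tibble::tibble(type = "deletion", ref_pos = pos717, ref_allele = "C",
                       alt_allele = "", length = 1L,
                       source_start = NA_integer_, source_end = NA_integer_)
  e3 <- annotate_variants(v3, fix2$cds, fix2$genome)
  expect_equal(e3$effect_class, "frameshift")
  expect_equal(e3$notation, "Frameshift (-C 717)")

  # Frameshift (+T 2003/2004): insertion of T after CDS position 2003
  set.seed(3)
  body3 <- replicate(752 + 1, {
    repeat {
      cod <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
      if (!cod %in% c("TAA", "TAG", "TGA")) return(cod)
    }
  })
  cds3 <- paste0("ATG", paste(body3[-1], collapse = ""), "TGA")
  fix3 <- one_cds_genome(cds3)
  g3seq <- fix3$genome$sequence
  pos2003 <- fix3$cds$start + 2003 - 1
  substr(g3seq, pos2003, pos2003 + 1) <- "AC"   # inserted T cannot left-shift
  fix3$genome <- genome("toy", g3seq)
  v4 <- tibble::tibble(type = "insertion", ref_pos = pos2003, ref_allele = "",
                       alt_allele = "T", length = 1L,
                       source_start = NA_integer_, source_end = NA_integer_)
  e4 <- annotate_variants(v4, fix3$cds, fix3$genome)
  expect_equal(e4$effect_class, "frameshift")
  expect_equal(e4$notation, "Frameshift (+T 2003/2004)")
})

test_that("silent and in-frame variants classify and format correctly", {
  cds_nt <- paste0("ATG", "CTG", "GTT", "CAT", "TGA")  # M L V H stop
  fix <- one_cds_genome(cds_nt)
  # CTG -> CTC is synonymous (L)
  v <- tibble::tibble(type = "snv", ref_pos = fix$cds$start + 5L,
                      ref_allele = "G", alt_allele = "C", length = 1L,
                      source_start = NA_integer_, source_end = NA_integer_)
  e <- annotate_variants(v, fix$cds, fix$genome)
  expect_equal(e$effect_class, "silent")

  # in-frame deletion of codons 3-4 (GTT CAT): V3-, H4-
  v2 <- tibble::tibble(type = "deletion", ref_pos = fix$cds$start + 6L,
                       ref_allele = "GTTCAT", alt_allele = "", length = 6L,
                       source_start = NA_integer_, source_end = NA_integer_)
  e2 <- annotate_variants(v2, fix$cds, fix$genome)
  expect_equal(e2$effect_class, "in_frame_deletion")
  expect_equal(e2$notation, "In frame deletion (V3-, H4-)")

  # in-frame insertion of GCT (A) after codon 2
  v3 <- tibble::tibble(type = "insertion", ref_pos = fix$cds$start + 5L,
                       ref_allele = "", alt_allele = "GCT", length = 3L,
                       source_start = NA_integer_, source_end = NA_integer_)
  e3 <- annotate_variants(v3, fix$cds, fix$genome)
  expect_equal(e3$effect_class, "in_frame_insertion")
  expect_equal(e3$notation, "In frame insertion (-3A)")
})

test_that("intergenic variants name their flanking loci", {
  sim <- random_genome(20000, 0.6, seed = 71)
  f <- sim$features
  gap_pos <- f$end[1] + which.max(seq(f$end[1] + 1, f$start[2] - 1)) %/% 2L
  v <- tibble::tibble(type = "snv", ref_pos = f$end[1] + 2L,
                      ref_allele = substr(sim$genome$sequence, f$end[1] + 2L,
                                          f$end[1] + 2L),
                      alt_allele = "A", length = 1L,
                      source_start = NA_integer_, source_end = NA_integer_)
  if (v$ref_allele == "A") v$alt_allele <- "C"
  e <- annotate_variants(v, f, sim$genome)
  expect_equal(e$effect_class, "intergenic")
  expect_match(e$notation, f$locus_tag[1], fixed = TRUE)
  expect_match(e$notation, f$locus_tag[2], fixed = TRUE)
})

test_that("joint evaluation of two SNVs in one codon gives one amino-acid change", {
  cds_nt <- paste0("ATG", "CGT", "CCT", "TGA")  # M R P stop
  fix <- one_cds_genome(cds_nt)
  # codon 2 CGT -> GGT via SNV at base 1; plus codon 3 CCT -> CGT
  v <- tibble::tibble(
    type = c("snv", "snv"),
    ref_pos = fix$cds$start + c(3L, 7L),
    ref_allele = c("C", "C"), alt_allele = c("G", "G"), length = 1L,
    source_start = NA_integer_, source_end = NA_integer_)
  e <- annotate_variants(v, fix$cds, fix$genome)
  expect_equal(e$notation, c("Missense (R2G)", "Missense (P3R)"))
})

test_that("strand is handled symmetrically: a '-' CDS matches its '+' mirror", {
  cds_nt <- paste0("ATG", "GGT", "CAT", "CTG", "TGA")
  for (codon_target in 2:4) {
    fwd <- one_cds_genome(cds_nt, strand = "+")
    rev <- one_cds_genome(cds_nt, strand = "-")
    # same coding change: first base of codon codon_target -> A
    cp <- (codon_target - 1L) * 3L + 1L
    ref_base <- substr(cds_nt, cp, cp)
    vf <- tibble::tibble(type = "snv", ref_pos = fwd$cds$start + cp - 1L,
                         ref_allele = ref_base, alt_allele = "A", length = 1L,
                         source_start = NA_integer_, source_end = NA_integer_)
    # on the '-' genome the same coding base sits at end - cp + 1, complemented
    vr <- tibble::tibble(type = "snv", ref_pos = rev$cds$end - cp + 1L,
                         ref_allele = straindiff:::REVCOMP_MAP[[ref_base]],
                         alt_allele = "T", length = 1L,
                         source_start = NA_integer_, source_end = NA_integer_)
    ef <- annotate_variants(vf, fwd$cds, fwd$genome)
    er <- annotate_variants(vr, rev$cds, rev$genome)
    expect_equal(er$notation, ef$notation, label = paste("codon", codon_target))
    expect_equal(er$effect_class, ef$effect_class)
  }
})

test_that("effect classes and protein changes match the rebuild-and-retranslate oracle", {
  set.seed(202)
  bases <- c("A", "C", "G", "T")
  n_cases <- 300
  mism <- 0
  for (rep in seq_len(n_cases)) {
    n_codons <- sample(30:80, 1)
    body <- replicate(n_codons - 1, {
      repeat {
        cod <- paste(sample(bases, 3, replace = TRUE), collapse = "")
        if (!cod %in% c("TAA", "TAG", "TGA")) return(cod)
      }
    })
    cds_nt <- paste0("ATG", paste(body, collapse = ""), "TGA")
    strand <- sample(c("+", "-"), 1)
    fix <- one_cds_genome(cds_nt, strand = strand)
    L_cds <- nchar(cds_nt)
    kind <- sample(c("snv", "del1", "ins1", "del3", "ins3"), 1)
    # keep variants inside the CDS body (sparing start and stop codons)
    cp <- sample(4:(L_cds - 9), 1)
    gpos <- if (strand == "+") fix$cds$start + cp - 1L else
      fix$cds$end - cp + 1L
    v <- switch(kind,
      snv = {
        rb <- substr(fix$genome$sequence, gpos, gpos)
        tibble::tibble(type = "snv", ref_pos = gpos, ref_allele = rb,
                       alt_allele = sample(setdiff(bases, rb), 1), length = 1L)
      },
      del1 = ,
      del3 = {
        len <- if (kind == "del3") 3L else 1L
        gs <- min(gpos, if (strand == "+") gpos else gpos - len + 1L)
        tibble::tibble(type = "deletion", ref_pos = gs,
                       ref_allele = substr(fix$genome$sequence, gs, gs + len - 1L),
                       alt_allele = "", length = len)
      },
      ins1 = ,
      ins3 = {
        len <- if (kind == "ins3") 3L else 1L
        tibble::tibble(type = "insertion", ref_pos = gpos, ref_allele = "",
                       alt_allele = paste(sample(bases, len, replace = TRUE),
                                          collapse = ""), length = len)
      })
    v$source_start <- NA_integer_; v$source_end <- NA_integer_
    got <- annotate_variants(v, fix$cds, fix$genome)
    want <- oracle_effect(v, fix$cds, fix$genome)
    ok <- identical(got$effect_class, want$class)
    if (ok && got$effect_class %in% c("missense", "nonsense")) {
      ok <- identical(as.data.frame(got$protein_changes[[1]]),
                      as.data.frame(want$changes))
    }
    if (!ok) mism <- mism + 1
  }
  expect_equal(mism, 0L)
})

test_that("core/non-core classification uses half-open intervals", {
  iv <- tibble::tibble(start = c(100L, 500L), end = c(200L, 600L))
  expect_equal(classify_region(150, iv), "core")
  expect_equal(classify_region(300, iv), "noncore")
  expect_equal(classify_region(200, iv), "noncore")   # end is exclusive
  expect_equal(classify_region(100, iv), "core")      # start is inclusive
  expect_error(classify_region(1000, iv, genome_length = 700), "range")
})

test_that("summary counts tally sites, classes and distinct affected proteins", {
  empty <- summarize_counts(straindiff:::empty_effect_tbl(),
                            straindiff:::empty_variant_tbl())
  expect_true(all(unlist(empty) == 0))

  eff <- tibble::tibble(
    locus_tag = c("a", "a", "b", "c"),
    effect_class = c("missense", "missense", "nonsense", "frameshift"),
    cds_position = 1L, protein_changes = list(tibble::tibble()),
    notation = "x", variant_type = c("snv", "snv", "snv", "deletion"),
    ref_pos = 1:4)
  vars <- tibble::tibble(type = c("snv", "snv", "snv", "deletion"),
                         ref_pos = 1:4, ref_allele = "A", alt_allele = "C",
                         length = 1L, source_start = NA_integer_,
                         source_end = NA_integer_)
  s <- summarize_counts(eff, vars)
  expect_equal(s$missense, 2L)
  expect_equal(s$nonsense, 1L)
  expect_equal(s$affected_proteins, 3L)
  expect_equal(s$snv_cds, 2L)
  expect_equal(s$frameshift_cds, 1L)
})

test_that("disjoint per-class counts add up the way the headline accounting does", {
  # 144 SNV CDSs + 71 frameshift + 4 duplication + 7 transposon insertion +
  # 1 excision, all disjoint, give 227 distinct affected proteins
  tags <- sprintf("L%03d", 1:227)
  eff <- tibble::tibble(
    locus_tag = tags,
    effect_class = c(rep("missense", 144), rep("frameshift", 71),
                     rep("duplication", 4), rep("transposon_insertion", 7),
                     rep("in_frame_deletion", 1)),
    cds_position = 1L, protein_changes = list(tibble::tibble()),
    notation = "x",
    variant_type = c(rep("snv", 144), rep("deletion", 71),
                     rep("duplication", 4), rep("transposition", 7),
                     rep("deletion", 1)),
    ref_pos = seq_len(227))
  s <- summarize_counts(eff, straindiff:::empty_variant_tbl())
  expect_equal(s$affected_proteins, 144L + 71L + 4L + 7L + 1L)
  expect_equal(s$affected_proteins, 227L)
})
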