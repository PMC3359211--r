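#' Build a run configuration
#'
#' One configuration drives the whole synthetic pipeline: genome simulation,
#' collinear comparison, effect annotation, time-course DE and the
#' chromosomal-region scan. All randomness flows from the single root
#' `seed`. A configuration round-trips through YAML unchanged
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param seed Root integer seed.
#' @param out_dir Output directory.
#' @param genome_length,gc Synthetic reference genome size and G+C fraction.
#' @param n_snv,n_small_indel,n_large_indel,n_mobile_insertion,n_duplication
#'   Mutation counts (see [mutation_plan()]).
#' @param min_spacing Minimum event spacing (bp).
#' @param n_genes,frac_deg,effect_sd,n_region_blocks,block_size,noise_sd
#'   Expression simulation settings (see [expression_sim_spec()]).
#' @param k Anchor seed length.
#' @param q_de DEG q-value threshold.
#' @param q_region,fc Region q-value and fold-change thresholds.
#' @param knn LAP bandwidth neighbour count.
#' @param B_de,B_region Permutation counts.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("straindiff_run_"),
                       genome_length = 200000L, gc = 0.71,
                       n_snv = 100L, n_small_indel = 20L, n_large_indel = 5L,
                       n_mobile_insertion = 3L, n_duplication = 2L,
                       min_spacing = 2000L,
                       n_genes = 1000L, frac_deg = 0.1, effect_sd = 2,
                       n_region_blocks = 2L, block_size = 30L,
                       noise_sd = 0.25,
                       k = 20L, q_de = 0.001, q_region = 0.01, fc = 0.5,
                       knn = 11L, B_de = 200L, B_region = 500L) {
  stopifnot(k >= 12, knn %% 2 == 1, knn >= 3, q_de > 0, q_de < 1,
            q_region > 0, q_region < 1, fc >= 0, B_de >= 50, B_region >= 100)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path YAML path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full synthetic strain-comparison pipeline
#'
#' Stages, in dependency order: simulate a reference genome and a mutated
#' query plus a two-strain-style time-course expression matrix; compare the
#' genomes (anchors, chain, variant calls); annotate CDS effects; run the
#' time-course DE analysis; run the chromosomal-region scan; write every
#' artefact (FASTA, GFF3, truth and call VCFs, effect/dot-plot/COG TSVs,
#' region BED, smoothed track, Newick tree when available) and a JSON
#' manifest of seeds, input hashes and summary counts.
#'
#' @param cfg A [run_config()].
#' @return The manifest, invisibly, with attribute `"dir"`; all outputs are
#'   under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(cfg$out_dir, ...)

  # --- simulate ---------------------------------------------------------
  sim <- random_genome(cfg$genome_length, cfg$gc, seed = cfg$seed,
                       cog_categories = paste0("C", 1:8))
  plan <- mutation_plan(n_snv = cfg$n_snv, n_small_indel = cfg$n_small_indel,
                        n_large_indel = cfg$n_large_indel,
                        n_mobile_insertion = cfg$n_mobile_insertion,
                        n_duplication = cfg$n_duplication,
                        min_spacing = cfg$min_spacing, seed = cfg$seed + 1L)
  mut <- mutate_genome(sim$genome, plan, sim$features)
  write_fasta(sim$genome, path("ref.fasta"))
  write_fasta(mut$genome, path("qry.fasta"))
  write_gff(sim$features, sim$genome, path("ref.gff3"))
  write_truth_vcf(mut$truth, sim$genome, path("truth.vcf"))

  espec <- expression_sim_spec(n_genes = cfg$n_genes, frac_deg = cfg$frac_deg,
                               effect_sd = cfg$effect_sd,
                               n_region_blocks = cfg$n_region_blocks,
                               block_size = cfg$block_size,
                               noise_sd = cfg$noise_sd, seed = cfg$seed + 2L)
  esim <- simulate_timecourse(espec)
  write_expression_tsv(esim$study, path("expression"))

  # --- compare ----------------------------------------------------------
  cmp <- compare_genomes(sim$genome, mut$genome, k = cfg$k)
  write_truth_vcf(dplyr::rename(cmp$variants, ref_position = "ref_pos"),
                  sim$genome, path("variants.vcf"))
  utils::write.table(cmp$dotplot, path("dotplot.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- annotate ---------------------------------------------------------
  effects <- annotate_variants(cmp$variants, sim$features, sim$genome)
  write_effect_tsv(effects, sim$features, path("effects.tsv"))
  counts <- summarize_counts(effects, cmp$variants)

  # --- de ---------------------------------------------------------------
  de <- timecourse_de(esim$study, B = cfg$B_de, seed = cfg$seed + 3L,
                      q_threshold = cfg$q_de)
  utils::write.table(de$results, path("deg_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cog <- cog_representation(de$degs$genes,
                            esim$study$genes |>
                              dplyr::mutate(cog_category = rep_len(
                                paste0("C", 1:8), dplyr::n())))
  utils::write.table(cog, path("cog_table.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(de$tree) && requireNamespace("ape", quietly = TRUE)) {
    ape::write.tree(ape::as.phylo(de$tree), path("clusters.nwk"))
  }

  # --- regions ----------------------------------------------------------
  ph <- phase_of(esim$study$samples$time_h, espec$phase_breaks)
  lap <- lap_scan(esim$study,
                  class_a_samples = esim$study$samples$sample[ph == "a"],
                  class_b_samples = esim$study$samples$sample[ph == "b"],
                  knn = cfg$knn, B = cfg$B_region, seed = cfg$seed + 4L,
                  q_threshold = cfg$q_region, fc_threshold = cfg$fc,
                  circular_length = 8e6)
  write_regions_bed(lap$regions, "synthetic_chr", path("regions.bed"))
  utils::write.table(dplyr::select(lap$regions, -"genes"),
                     path("regions.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_smoothed_track(lap, "synthetic_chr", path("smoothed.tsv"))

  # --- report -----------------------------------------------------------
  deg_phase <- table(factor(de$results$phase[de$results$q <= cfg$q_de],
                            levels = c("a", "b", "c")))
  inputs <- c("ref.fasta", "qry.fasta", "ref.gff3", "expression_matrix.tsv")
  manifest <- list(
    seed = cfg$seed,
    thresholds = list(q_de = cfg$q_de, q_region = cfg$q_region, fc = cfg$fc,
                      k = cfg$k, knn = cfg$knn),
    input_md5 = as.list(stats::setNames(unname(tools::md5sum(path(inputs))),
                                        inputs)),
    counts = c(as.list(counts),
               list(deg_total = de$degs$n,
                    deg_percent = de$degs$percent,
                    deg_phase_a = unname(deg_phase["a"]),
                    deg_phase_b = unname(deg_phase["b"]),
                    deg_phase_c = unname(deg_phase["c"]),
                    regions = nrow(lap$regions))))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest <- jsonlite::read_json(path("manifest.json"))
  attr(manifest, "dir") <- cfg$out_dir
  invisible(manifest)
}

#' Circular-map export of effect and region layers
#'
#' Converts linear coordinates to angular ones (`2 * pi * position /
#' genome_length`) for circular chromosome plotting, with the conventional
#' colour classes (green = frameshift, purple = nonsense, yellow =
#' missense).
#'
#' @param effects Effect tibble from [annotate_variants()] (may be empty).
#' @param regions Region tibble from [call_regions()] (may be empty).
#' @param genome_length Chromosome length (bp).
#' @return Tibble: `layer`, `position`, `angle`, `class`, `color`.
#' @export
export_circular_map <- function(effects, regions, genome_length) {
  color_of <- c(frameshift = "green", nonsense = "purple",
                missense = "yellow")
  eff <- effects |>
    dplyr::filter(.data$effect_class %in% names(color_of)) |>
    dplyr::transmute(layer = "variant", position = as.numeric(.data$ref_pos),
                     class = .data$effect_class,
                     color = unname(color_of[.data$effect_class]))
  reg <- regions |>
    dplyr::transmute(layer = "region",
                     position = (.data$start_position + .data$end_position) / 2,
                     class = .data$direction,
                     color = dplyr::if_else(.data$direction == "up", "red",
                                            "green"))
  out <- dplyr::bind_rows(eff, reg)
  if (nrow(out) > 0 && any(out$position > genome_length | out$position < 0)) {
    stop("position beyond genome length", call. = FALSE)
  }
  out$angle <- 2 * pi * out$position / genome_length
  out[, c("layer", "position", "angle", "class", "color")]
}
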