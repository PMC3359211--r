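#' Specify a synthetic time-course expression study
#'
#' Defaults mirror an erythromycin-fermentation style design: six time points
#' (12-72 h) in duplicate, a time axis partitioned into three growth phases
#' (a: rapid increase, b: slowdown, c: late increase), a modest fraction of
#' genes with a phase-shaped temporal signal, and i.i.d. Gaussian noise on the
#' log scale (the simulation starts from normalized log expression; probe
#' level processing is out of scope).
#'
#' @param n_genes Number of genes.
#' @param time_points Ordered time points in hours.
#' @param replicates Replicates per time point (>= 2; each replicate is an
#'   independent sample).
#' @param phase_breaks Two increasing cut points on the time axis splitting it
#'   into phases a (`t <= breaks[1]`), b (`breaks[1] < t <= breaks[2]`) and c.
#' @param frac_deg Fraction of genes given a temporal bump (in `[0, 1]`).
#' @param effect_sd Bump amplitude in units of `noise_sd`.
#' @param n_region_blocks,block_size Number and size (genes) of chromosomally
#'   contiguous blocks sharing a common up/down offset between phases a and b
#'   (the signal the region-level scan looks for).
#' @param noise_sd Noise standard deviation in log units.
#' @param strain Strain label stamped on the samples.
#' @param seed Integer seed.
#' @return An `expression_sim_spec` list.
#' @export
expression_sim_spec <- function(n_genes = 2000L,
                                time_points = c(12, 24, 36, 48, 60, 72),
                                replicates = 2L,
                                phase_breaks = c(36, 60),
                                frac_deg = 0,
                                effect_sd = 2,
                                n_region_blocks = 0L,
                                block_size = 30L,
                                noise_sd = 0.25,
                                strain = "synthetic",
                                seed = 1L) {
  stopifnot(n_genes >= 2, length(time_points) >= 3,
            !is.unsorted(time_points, strictly = TRUE),
            frac_deg >= 0, frac_deg <= 1, effect_sd >= 0, noise_sd > 0,
            length(phase_breaks) == 2, phase_breaks[1] < phase_breaks[2],
            n_region_blocks >= 0, block_size >= 2)
  if (replicates < 2) {
    stop("replicates must be >= 2: each time point replicate is an independent entry",
         call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), time_points = time_points,
                 replicates = as.integer(replicates),
                 phase_breaks = phase_breaks, frac_deg = frac_deg,
                 effect_sd = effect_sd,
                 n_region_blocks = as.integer(n_region_blocks),
                 block_size = as.integer(block_size), noise_sd = noise_sd,
                 strain = strain, seed = seed),
            class = "expression_sim_spec")
}

#' Map time points to phases a/b/c
#' @param time Numeric times.
#' @param phase_breaks Two cut points as in [expression_sim_spec()].
#' @return Character vector in `{"a","b","c"}`.
#' @export
phase_of <- function(time, phase_breaks) {
  dplyr::case_when(time <= phase_breaks[1] ~ "a",
                   time <= phase_breaks[2] ~ "b",
                   TRUE ~ "c")
}

#' Assemble an expression study container
#'
#' @param matrix Genes x samples numeric matrix of log expression (no missing
#'   values), rownames = gene ids, colnames = sample ids.
#' @param samples Tibble with columns `sample`, `strain`, `time_h`,
#'   `replicate` (one row per column of `matrix`).
#' @param genes Tibble with columns `gene`, `position_bp`, `strand` and
#'   optionally `cog_category`, `core` (one row per row of `matrix`).
#' @return An `expression_study` object.
#' @export
expression_study <- function(matrix, samples, genes) {
  stopifnot(is.matrix(matrix), !anyNA(matrix),
            nrow(samples) == ncol(matrix), nrow(genes) == nrow(matrix),
            all(c("sample", "strain", "time_h", "replicate") %in% names(samples)),
            all(c("gene", "position_bp", "strand") %in% names(genes)))
  reps <- table(samples$time_h)
  if (any(reps < 2)) {
    stop("every time point needs >= 2 replicates", call. = FALSE)
  }
  ord <- order(genes$strand, genes$position_bp)
  structure(list(matrix = matrix[ord, , drop = FALSE],
                 samples = tibble::as_tibble(samples),
                 genes = tibble::as_tibble(genes)[ord, ]),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %d genes x %d samples; %d time points x %s replicates; strain(s): %s\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(x$samples$time_h)),
              paste(unique(table(x$samples$time_h)), collapse = "/"),
              paste(unique(x$samples$strain), collapse = ", ")))
  invisible(x)
}

#' Simulate a two-phase-structured time-course expression study
#'
#' Log expression is `baseline + phase bump (DEGs only) + block modulation
#' (region-block members only) + N(0, noise_sd)`. A DEG is up-regulated in
#' exactly one phase by `effect_sd * noise_sd`; region-block members share a
#' common signed modulation *between* the two designated phases: offset by
#' `+effect_sd * noise_sd` in phase a and by the same amount with opposite
#' sign in phase b (or the reverse for down blocks), so the
#' phase-a-versus-b contrast the region scan tests equals twice the offset. Gene positions are laid out uniformly along a
#' circular chromosome, alternating strands in contiguous stretches so each
#' strand has positional runs.
#'
#' @param spec An [expression_sim_spec()].
#' @param gene_positions Optional tibble (`gene`, `position_bp`, `strand`)
#'   overriding the generated layout; must have `n_genes` rows.
#' @param genome_length Chromosome length used for the generated layout.
#' @return List with `study` (an [expression_study()]) and `truth` (tibble:
#'   `gene`, `status` in `{null, deg}`, `phase`, `block`, `block_sign`).
#' @export
simulate_timecourse <- function(spec, gene_positions = NULL,
                                genome_length = 8e6) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  set.seed(as.integer(spec$seed))
  G <- spec$n_genes
  times <- rep(spec$time_points, each = spec$replicates)
  n <- length(times)
  samples <- tibble::tibble(
    sample = sprintf("s%02d", seq_len(n)),
    strain = spec$strain,
    time_h = times,
    replicate = rep(seq_len(spec$replicates), times = length(spec$time_points))
  )

  if (is.null(gene_positions)) {
    pos <- sort(sample.int(genome_length, G))
    # strands in contiguous stretches of ~50 genes
    n_stretch <- ceiling(G / 50)
    strand <- rep(rep(c("+", "-"), length.out = n_stretch), each = 50)[seq_len(G)]
    gene_positions <- tibble::tibble(gene = sprintf("gene_%05d", seq_len(G)),
                                     position_bp = pos, strand = strand)
  }
  stopifnot(nrow(gene_positions) == G)

  phase <- phase_of(times, spec$phase_breaks)
  baseline <- stats::rnorm(G, mean = 8, sd = 1)
  X <- matrix(baseline, G, n) +
    matrix(stats::rnorm(G * n, 0, spec$noise_sd), G, n)

  truth <- tibble::tibble(gene = gene_positions$gene, status = "null",
                          phase = NA_character_, block = NA_integer_,
                          block_sign = NA_real_)

  n_deg <- round(spec$frac_deg * G)
  if (n_deg > 0) {
    deg_idx <- sample.int(G, n_deg)
    deg_phase <- sample(c("a", "b", "c"), n_deg, replace = TRUE)
    amp <- spec$effect_sd * spec$noise_sd
    for (k in seq_len(n_deg)) {
      X[deg_idx[k], phase == deg_phase[k]] <-
        X[deg_idx[k], phase == deg_phase[k]] + amp
    }
    truth$status[deg_idx] <- "deg"
    truth$phase[deg_idx] <- deg_phase
  }

  if (spec$n_region_blocks > 0) {
    # pick non-overlapping runs of consecutive genes within one strand
    ord <- order(gene_positions$strand, gene_positions$position_bp)
    used <- logical(G)
    amp <- spec$effect_sd * spec$noise_sd
    b <- 0L; tries <- 0L
    while (b < spec$n_region_blocks && tries < 10000L) {
      tries <- tries + 1L
      s <- sample.int(G - spec$block_size + 1L, 1L)
      run <- ord[s:(s + spec$block_size - 1L)]
      if (any(used[run])) next
      if (length(unique(gene_positions$strand[run])) > 1L) next
      b <- b + 1L
      used[run] <- TRUE
      sgn <- sample(c(-1, 1), 1L)
      X[run, phase == "a"] <- X[run, phase == "a"] + sgn * amp
      X[run, phase == "b"] <- X[run, phase == "b"] - sgn * amp
      truth$block[run] <- b
      truth$block_sign[run] <- sgn
    }
    if (b < spec$n_region_blocks) {
      stop("could not place the requested non-overlapping region blocks",
           call. = FALSE)
    }
  }

  rownames(X) <- gene_positions$gene
  colnames(X) <- samples$sample
  study <- expression_study(X, samples, gene_positions)
  truth <- truth[match(study$genes$gene, truth$gene), ]
  list(study = study, truth = truth)
}

#' Write / read an expression study as TSV files
#'
#' Three files: `<stem>_matrix.tsv` (genes x samples), `<stem>_samples.tsv`
#' and `<stem>_genes.tsv`.
#'
#' @param study An [expression_study()].
#' @param stem Path stem.
#' @return The three paths, invisibly.
#' @export
write_expression_tsv <- function(study, stem) {
  mp <- paste0(stem, "_matrix.tsv")
  sp <- paste0(stem, "_samples.tsv")
  gp <- paste0(stem, "_genes.tsv")
  utils::write.table(data.frame(gene = rownames(study$matrix), study$matrix,
                                check.names = FALSE),
                     mp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$samples, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$genes, gp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = mp, samples = sp, genes = gp))
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(stem) {
  m <- utils::read.delim(paste0(stem, "_matrix.tsv"), check.names = FALSE)
  mat <- as.matrix(m[, -1, drop = FALSE])
  rownames(mat) <- m$gene
  expression_study(mat,
                   tibble::as_tibble(utils::read.delim(paste0(stem, "_samples.tsv"))),
                   tibble::as_tibble(utils::read.delim(paste0(stem, "_genes.tsv"))))
}
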