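#' Construct a genome object
#'
#' A genome is a single named nucleotide sequence over `{A, C, G, T}` with a
#' circular/linear topology flag. All coordinates throughout the package are
#' 1-based and inclusive (GFF3 convention).
#'
#' @param id Non-empty character label.
#' @param sequence Nucleotide string; lower case is accepted and upper-cased.
#'   Ambiguity codes are rejected (the diff engine requires an exact alphabet).
#' @param circular Logical; bacterial chromosomes default to `TRUE`. Features
#'   spanning the origin are not supported: circularity is recorded for
#'   distance computations, but the sequence is handled as linearised at
#'   position 1.
#' @return An object of class `genome` with fields `id`, `sequence`,
#'   `circular` and `length`.
#' @export
genome <- function(id, sequence, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  bad <- stringr::str_locate(sequence, "[^ACGT]")[1, "start"]
  if (!is.na(bad)) {
    stop(sprintf("non-ACGT symbol '%s' at position %d in genome '%s'",
                 substr(sequence, bad, bad), bad, id), call. = FALSE)
  }
  structure(
    list(id = id, sequence = sequence, circular = isTRUE(circular),
         length = nchar(sequence)),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp (%s), GC %.2f%%\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              100 * gc_content(x)))
  invisible(x)
}

#' @export
length.genome <- function(x) x$length

#' G+C content of a genome
#'
#' @param g A [genome()].
#' @return Fraction of G or C bases.
#' @export
gc_content <- function(g) {
  stopifnot(inherits(g, "genome"))
  stringr::str_count(g$sequence, "[GC]") / g$length
}

#' Extract a subsequence (1-based, inclusive)
#' @noRd
genome_subseq <- function(g, start, end) {
  substr(g$sequence, start, end)
}

#' Read a single-record FASTA file as a genome
#'
#' @param path Path to a FASTA file holding exactly one record.
#' @param circular Topology flag for the resulting genome (default circular).
#' @return A [genome()].
#' @export
read_fasta <- function(path, circular = TRUE) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1L) {
    stop(sprintf("expected 1 record, found %d in '%s'", length(set), path),
         call. = FALSE)
  }
  genome(id = sub("\\s.*$", "", names(set)[1]),
         sequence = as.character(set[[1]]),
         circular = circular)
}

#' Write a genome to FASTA
#'
#' @param g A [genome()].
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 70L) {
  stopifnot(inherits(g, "genome"))
  set <- Biostrings::DNAStringSet(g$sequence)
  names(set) <- g$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read CDS features from a GFF3 file
#'
#' Only rows of type `CDS` are consumed. Each CDS must carry a `locus_tag`
#' attribute; `product`, `cog` and `core` attributes are picked up when
#' present. Coordinates are validated against the genome and the result is
#' sorted by start. CDS lengths that are not a multiple of 3 are flagged in
#' the `translatable` column rather than rejected.
#'
#' @param path GFF3 file path.
#' @param genome A [genome()] the coordinates refer to.
#' @return A tibble with columns `locus_tag`, `start`, `end`, `strand`,
#'   `product`, `cog_category`, `core`, `translatable`.
#' @export
read_gff <- function(path, genome) {
  stopifnot(file.exists(path), inherits(genome, "genome"))
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(lines) & !startsWith(lines, "#"))) {
    return(empty_cds_tbl())
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) return(empty_cds_tbl())
  md <- S4Vectors::mcols(gr)
  get_attr <- function(name, default = NA_character_) {
    if (name %in% colnames(md)) as.character(md[[name]]) else
      rep(default, length(gr))
  }
  tags <- get_attr("locus_tag")
  if (anyNA(tags)) stop("CDS row without a locus_tag attribute", call. = FALSE)
  if (anyDuplicated(tags)) {
    stop(sprintf("duplicate locus_tag: %s", tags[duplicated(tags)][1]),
         call. = FALSE)
  }
  feats <- tibble::tibble(
    locus_tag    = tags,
    start        = BiocGenerics::start(gr),
    end          = BiocGenerics::end(gr),
    strand       = as.character(BiocGenerics::strand(gr)),
    product      = get_attr("product"),
    cog_category = get_attr("cog"),
    core         = tolower(get_attr("core")) %in% "true"
  )
  validate_cds(feats, genome)
}

empty_cds_tbl <- function() {
  tibble::tibble(locus_tag = character(), start = integer(), end = integer(),
                 strand = character(), product = character(),
                 cog_category = character(), core = logical(),
                 translatable = logical())
}

#' Validate a CDS feature table against a genome
#' @noRd
validate_cds <- function(feats, genome) {
  if (any(feats$start < 1L | feats$end > genome$length)) {
    bad <- feats$locus_tag[feats$start < 1L | feats$end > genome$length][1]
    stop(sprintf("CDS '%s' lies outside the %d-bp genome", bad, genome$length),
         call. = FALSE)
  }
  if (any(feats$start > feats$end)) {
    stop("CDS with start > end (origin-spanning features are not supported)",
         call. = FALSE)
  }
  if (!all(feats$strand %in% c("+", "-"))) {
    stop("CDS strand must be '+' or '-'", call. = FALSE)
  }
  feats |>
    dplyr::mutate(translatable = (.data$end - .data$start + 1L) %% 3L == 0L) |>
    dplyr::arrange(.data$start)
}

#' Write CDS features as GFF3
#'
#' @param feats CDS tibble as returned by [read_gff()].
#' @param genome The [genome()] the features annotate.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(feats, genome, path) {
  attrs <- sprintf("locus_tag=%s;product=%s", feats$locus_tag,
                   ifelse(is.na(feats$product), "hypothetical protein",
                          feats$product))
  has_cog <- !is.na(feats$cog_category)
  attrs[has_cog] <- paste0(attrs[has_cog], ";cog=",
                           feats$cog_category[has_cog])
  attrs <- paste0(attrs, ";core=", ifelse(feats$core %in% TRUE, "true", "false"))
  rows <- sprintf("%s\tstraindiff\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                  genome$id, feats$start, feats$end, feats$strand, attrs)
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", genome$id, genome$length),
               rows), path)
  invisible(path)
}

#' Read core-genome intervals from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to the package's
#' 1-based half-open convention (`[start, end)`), so the covered bases are
#' unchanged.
#'
#' @param path BED file path.
#' @return Tibble with columns `start`, `end` (1-based, half-open), sorted.
#' @export
read_core_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) return(tibble::tibble(start = integer(), end = integer()))
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(start = BiocGenerics::start(gr),
                 end = BiocGenerics::end(gr) + 1L) |>
    dplyr::arrange(.data$start)
}

REVCOMP_MAP <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse-complement a nucleotide string
#' @param x Character string over ACGT.
#' @return Reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a CDS under the bacterial genetic code
#'
#' Translation uses genetic code table 11. The initial codon is rendered `M`
#' when it is one of the bacterial starts `ATG`/`GTG`/`TTG`; internal stop
#' codons render as `*` and translation continues (so nonsense positions stay
#' visible); a trailing stop codon is dropped, so the reported protein length
#' is `CDS length / 3 - 1` for a stop-terminated CDS — the "Length (amino
#' acids)" convention of mutation tables.
#'
#' @param feature One row of a CDS tibble (or a list with `locus_tag`,
#'   `start`, `end`, `strand`).
#' @param genome The [genome()].
#' @return Amino-acid string.
#' @export
translate_cds <- function(feature, genome) {
  len <- feature$end - feature$start + 1L
  if (len %% 3L != 0L || len < 6L) {
    stop(sprintf("CDS '%s' has length %d, not a multiple of 3 (>= 6) — cannot translate",
                 feature$locus_tag, len), call. = FALSE)
  }
  nt <- genome_subseq(genome, feature$start, feature$end)
  if (identical(feature$strand, "-")) nt <- revcomp(nt)
  translate_orf(nt)
}

#' Translate an in-frame nucleotide string (coding strand)
#' @noRd
translate_orf <- function(nt) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE
  ))
  if (substr(nt, 1, 3) %in% c("ATG", "GTG", "TTG")) {
    substr(aa, 1, 1) <- "M"
  }
  sub("\\*$", "", aa)
}

#' Translate a single codon (no start-codon special-casing)
#' @noRd
translate_codon <- function(codon) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(codon),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE
  ))
}
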