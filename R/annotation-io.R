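## Annotation and track I/O.
##
## Coordinate contract used everywhere in the package: 0-based, half-open
## [start, end) on the forward genomic axis. GFF3 (1-based inclusive) is
## converted at the I/O boundary only; BED and bedGraph already match.

# genome_annotation ------------------------------------------------------

#' Create a genome annotation
#'
#' Bundles a tibble of gene models with the chromosome lengths they live on.
#' All coordinates are 0-based half-open; `strand` must be `"+"` or `"-"`.
#' The TSS of a gene is `start` on the plus strand and `end - 1` on the minus
#' strand; the TES is the opposite end.
#'
#' @param genes A data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and optionally `biotype` (defaulted to `"protein_coding"`).
#' @param chrom_lengths Named integer vector of chromosome lengths. If `NULL`,
#'   lengths are inferred as the maximum gene `end` per chromosome.
#' @return An object of class `genome_annotation`: a list with elements
#'   `genes` (tibble) and `chrom_lengths` (named integer vector).
#' @examples
#' ann <- genome_annotation(
#'   data.frame(gene_id = "g1", chrom = "chrI", start = 100L, end = 600L,
#'              strand = "+"),
#'   chrom_lengths = c(chrI = 1000L)
#' )
#' ann$genes
#' @export
genome_annotation <- function(genes, chrom_lengths = NULL) {
  genes <- tibble::as_tibble(genes)
  required <- c("gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("genes is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"biotype" %in% names(genes)) genes$biotype <- "protein_coding"
  genes <- genes[, c(required, "biotype")]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)

  if (any(genes$start < 0) || any(genes$start >= genes$end)) {
    abort("gene coordinates must satisfy 0 <= start < end")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-' for every gene")
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene_id: ", paste(unique(dup), collapse = ", ")))
  }

  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(genes$end, genes$chrom), max, integer(1))
  }
  chrom_lengths <- setNames(as.integer(chrom_lengths), names(chrom_lengths))
  bad_chrom <- setdiff(unique(genes$chrom), names(chrom_lengths))
  if (length(bad_chrom) > 0) {
    abort(paste0("no chromosome length for: ",
                 paste(bad_chrom, collapse = ", ")))
  }
  over <- genes$end > chrom_lengths[genes$chrom]
  if (any(over)) {
    abort(paste0("gene(s) extend beyond their chromosome: ",
                 paste(genes$gene_id[over], collapse = ", ")))
  }

  structure(list(genes = genes, chrom_lengths = chrom_lengths),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d genes on %d chromosome(s) (%s bp)\n",
              nrow(x$genes), length(x$chrom_lengths),
              format(sum(as.numeric(x$chrom_lengths)), big.mark = ",")))
  print(x$genes, n = 5)
  invisible(x)
}

#' Look up genes by id
#'
#' @param annotation A [genome_annotation()].
#' @param gene_ids Character vector of gene ids; all must exist.
#' @return Tibble of the matching gene rows, in the requested order.
#' @export
gene_lookup <- function(annotation, gene_ids) {
  stopifnot(inherits(annotation, "genome_annotation"))
  idx <- match(gene_ids, annotation$genes$gene_id)
  if (anyNA(idx)) {
    abort(paste0("unknown gene_id: ",
                 paste(gene_ids[is.na(idx)], collapse = ", ")))
  }
  annotation$genes[idx, ]
}

# loaders ----------------------------------------------------------------

validate_line_fields <- function(path, n_fields, skip_prefixes = "#") {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, skip_prefixes[1]) & nzchar(trimws(lines))
  for (p in skip_prefixes[-1]) body <- body & !startsWith(lines, p)
  counts <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[counts < n_fields]
  if (length(bad) > 0) {
    abort(sprintf("parse error at line %d of %s: expected %d tab-separated fields",
                  bad[1], path, n_fields))
  }
  invisible(lines)
}

#' Load a gene annotation from GFF3 or BED
#'
#' GFF3 coordinates (1-based inclusive) are shifted to the internal 0-based
#' half-open convention; BED6 is passed through unchanged. Chromosome lengths
#' are read from GFF3 `##sequence-region` directives when present, otherwise
#' taken from `chrom_lengths` or inferred from the genes themselves.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @param chrom_lengths Optional named integer vector of chromosome lengths.
#' @param feature_type GFF3 feature type to keep (default `"gene"`); ignored
#'   for BED.
#' @return A [genome_annotation()].
#' @export
load_annotation <- function(path, format = c("gff3", "bed"),
                            chrom_lengths = NULL, feature_type = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))

  if (format == "gff3") {
    validate_line_fields(path, 9, skip_prefixes = "#")
    gr <- rtracklayer::import(path, format = "gff3")
    meta <- as.data.frame(gr)
    if ("type" %in% names(meta) && feature_type %in% meta$type) {
      meta <- meta[meta$type == feature_type, , drop = FALSE]
    }
    gene_id <- meta$ID %||% meta$gene_id %||% meta$Name
    if (is.null(gene_id)) abort("GFF3 records carry no ID/gene_id attribute")
    biotype <- meta$biotype %||% rep("protein_coding", nrow(meta))
    biotype[is.na(biotype)] <- "protein_coding"
    genes <- tibble::tibble(
      gene_id = as.character(gene_id),
      chrom = as.character(meta$seqnames),
      start = meta$start - 1L,
      end = meta$end,
      strand = as.character(meta$strand),
      biotype = as.character(biotype)
    )
    if (is.null(chrom_lengths)) {
      chrom_lengths <- parse_sequence_regions(path)
      if (length(chrom_lengths) == 0) chrom_lengths <- NULL
    }
    return(genome_annotation(genes, chrom_lengths))
  }

  # BED6
  lines <- validate_line_fields(path, 6,
                                skip_prefixes = c("#", "track", "browser"))
  body <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                  !startsWith(lines, "browser") & nzchar(trimws(lines))]
  fields <- strsplit(body, "\t", fixed = TRUE)
  genes <- tibble::tibble(
    chrom = vapply(fields, `[`, "", 1),
    start = suppressWarnings(as.integer(vapply(fields, `[`, "", 2))),
    end = suppressWarnings(as.integer(vapply(fields, `[`, "", 3))),
    gene_id = vapply(fields, `[`, "", 4),
    strand = vapply(fields, `[`, "", 6)
  )
  if (anyNA(genes$start) || anyNA(genes$end)) {
    bad <- which(is.na(genes$start) | is.na(genes$end))[1]
    abort(sprintf("parse error at line %d of %s: non-integer coordinates",
                  bad, path))
  }
  genome_annotation(genes, chrom_lengths)
}

parse_sequence_regions <- function(path) {
  lines <- grep("^##sequence-region", readLines(path, warn = FALSE),
                value = TRUE)
  if (length(lines) == 0) return(integer(0))
  parts <- strsplit(trimws(lines), "\\s+")
  setNames(vapply(parts, function(p) as.integer(p[4]), integer(1)),
           vapply(parts, `[`, "", 2))
}

#' Write a genome annotation as GFF3
#'
#' Emits `##sequence-region` directives for the chromosome lengths and one
#' `gene` feature per row, converting the internal 0-based half-open
#' coordinates back to GFF3's 1-based inclusive ones. `write_annotation()`
#' followed by [load_annotation()] reproduces the annotation exactly.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s 1 %d",
                      names(annotation$chrom_lengths),
                      annotation$chrom_lengths))
  rows <- sprintf("%s\ttidychip\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                  g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$biotype)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Load a tiling-array probe table
#'
#' Reads the tab-separated probe table used throughout the array analysis:
#' header `probe_id, chrom, position, strand, pm, mm, gene_id`, one row per
#' PM/MM probe pair. `position` is the genomic coordinate (0-based) of the
#' lowest-coordinate base of the probe footprint. Probes whose `gene_id` is
#' absent from `annotation` are kept under the sentinel id `"unassigned"`.
#'
#' @param path Path to the TSV file.
#' @param annotation Optional [genome_annotation()] used to validate gene ids.
#' @return Tibble with one row per probe pair.
#' @export
load_probe_table <- function(path, annotation = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    chrom = readr::col_character(),
    position = readr::col_integer(),
    strand = readr::col_character(),
    pm = readr::col_character(),
    mm = readr::col_character(),
    gene_id = readr::col_character()
  ), progress = FALSE)
  required <- c("probe_id", "chrom", "position", "strand", "pm", "mm",
                "gene_id")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("probe table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  pm <- suppressWarnings(as.numeric(tab$pm))
  mm <- suppressWarnings(as.numeric(tab$mm))
  if (anyNA(pm) || anyNA(mm)) abort("non-numeric pm/mm intensity in probe table")
  if (any(pm <= 0) || any(mm <= 0)) {
    abort("probe intensities must be positive (pm > 0, mm > 0)")
  }
  tab$pm <- pm
  tab$mm <- mm
  if (!is.null(annotation)) {
    known <- tab$gene_id %in% annotation$genes$gene_id
    tab$gene_id[!known] <- "unassigned"
  }
  tab
}

#' Write a probe table
#'
#' @param probes Probe tibble as produced by [load_probe_table()] or
#'   [simulate_probe_array()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  readr::write_tsv(probes, path, progress = FALSE)
  invisible(path)
}

# coverage tracks --------------------------------------------------------

#' Create a per-base coverage track
#'
#' A coverage track stores one numeric value per base per chromosome. Raw
#' (unnormalized) tracks must be non-negative; normalized tracks may carry
#' `NA` at masked bases (e.g. where the input control is zero).
#'
#' @param values Named list of numeric vectors, one per chromosome; each
#'   vector has one element per base.
#' @param label Free-text label carried through downstream operations.
#' @param normalized Logical flag; `FALSE` for raw read counts.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, label = "", normalized = FALSE) {
  if (!is.list(values) || is.null(names(values)) || any(!nzchar(names(values)))) {
    abort("values must be a named list of numeric vectors")
  }
  values <- lapply(values, as.numeric)
  if (!normalized) {
    neg <- vapply(values, function(v) any(v < 0, na.rm = TRUE), logical(1))
    if (any(neg)) abort("raw coverage tracks must be non-negative")
  }
  structure(list(values = values, label = label, normalized = normalized),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> '%s' (%s), %d chromosome(s), %s bases\n",
              x$label, if (x$normalized) "normalized" else "raw",
              length(x$values),
              format(sum(lengths(x$values)), big.mark = ",")))
  invisible(x)
}

#' Convert a coverage track to a long tibble
#'
#' @param x A [coverage_track()].
#' @param ... Unused.
#' @return Tibble with columns `chrom`, `pos` (0-based) and `value`.
#' @method as_tibble coverage_track
#' @export
as_tibble.coverage_track <- function(x, ...) {
  purrr::map2_dfr(names(x$values), x$values, function(chrom, v) {
    tibble::tibble(chrom = chrom, pos = seq_along(v) - 1L, value = v)
  })
}

#' Read a bedGraph file into a coverage track
#'
#' The bedGraph dialect is 0-based half-open with the value in the fourth
#' column; bases not covered by any interval are 0. Masked bases written by
#' [write_bedgraph()] as `nan` are read back as `NA`, so write-then-read is
#' the identity at every base. Overlapping intervals are an error unless they
#' agree on the value.
#'
#' @param path Path to the bedGraph file.
#' @param chrom_lengths Named integer vector giving the length of every
#'   chromosome the track should cover.
#' @param label,normalized Metadata stored on the returned track.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, chrom_lengths, label = basename(path),
                          normalized = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & !startsWith(lines, "track") &
                  !startsWith(lines, "browser") & nzchar(trimws(lines)))
  values <- lapply(chrom_lengths, function(n) numeric(n))
  seen <- lapply(chrom_lengths, function(n) logical(n))
  for (i in body) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(f) < 4) {
      abort(sprintf("parse error at line %d of %s: expected 4 fields", i, path))
    }
    chrom <- f[1]
    if (!chrom %in% names(chrom_lengths)) {
      abort(sprintf("line %d of %s: unknown chromosome '%s'", i, path, chrom))
    }
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    v <- suppressWarnings(as.numeric(f[4]))
    if (is.na(s) || is.na(e) || s < 0 || s >= e) {
      abort(sprintf("parse error at line %d of %s: bad interval", i, path))
    }
    if (e > chrom_lengths[[chrom]]) {
      abort(sprintf("line %d of %s: interval end %d beyond chromosome length %d",
                    i, path, e, chrom_lengths[[chrom]]))
    }
    idx <- (s + 1L):e
    clash <- seen[[chrom]][idx] &
      !same_coverage_value(values[[chrom]][idx], v)
    if (any(clash)) {
      abort(sprintf("line %d of %s: overlapping intervals with conflicting values",
                    i, path))
    }
    values[[chrom]][idx] <- v
    seen[[chrom]][idx] <- TRUE
  }
  values <- lapply(values, function(v) {
    v[is.nan(v)] <- NA_real_
    v
  })
  coverage_track(values, label = label, normalized = normalized)
}

same_coverage_value <- function(existing, v) {
  if (is.nan(v)) return(is.nan(existing))
  !is.nan(existing) & existing == v
}

#' Write a coverage track as bedGraph
#'
#' Zero runs are omitted (bedGraph treats unspecified bases as 0); `NA` bases
#' are written as `nan` runs so that masked tracks round-trip exactly.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (any(is.infinite(v) & v < 0, na.rm = TRUE)) {
      abort("coverage values of -Inf cannot be serialized")
    }
    enc <- v
    enc[is.na(enc)] <- -Inf  # sentinel: rle-safe stand-in for NA
    r <- rle(enc)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- !(r$values == 0 & is.finite(r$values))
    if (any(keep)) {
      val_str <- ifelse(is.infinite(r$values[keep]), "nan",
                        sprintf("%.17g", r$values[keep]))
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                         val_str), con)
    }
  }
  invisible(path)
}

#' Read aligned-read intervals from BED
#'
#' @param path Path to a BED file with at least 3 columns (6 are used when
#'   present: name, score, strand).
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & !startsWith(lines, "track") &
                  !startsWith(lines, "browser") & nzchar(trimws(lines)))
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3)) {
    abort(sprintf("parse error at line %d of %s: expected >= 3 fields",
                  body[which(n < 3)[1]], path))
  }
  get <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default, "")
  }
  out <- tibble::tibble(
    chrom = get(1, ""),
    start = suppressWarnings(as.integer(get(2, NA))),
    end = suppressWarnings(as.integer(get(3, NA))),
    name = get(4, "."),
    score = suppressWarnings(as.numeric(get(5, "0"))),
    strand = get(6, "+")
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    bad <- body[which(is.na(out$start) | is.na(out$end))[1]]
    abort(sprintf("parse error at line %d of %s: non-integer coordinates",
                  bad, path))
  }
  out
}

#' Write read intervals as BED6
#'
#' @param reads Tibble with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(reads, path) {
  name <- reads$name %||% rep(".", nrow(reads))
  score <- reads$score %||% rep(0, nrow(reads))
  strand <- reads$strand %||% rep("+", nrow(reads))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s", reads$chrom,
                     as.integer(reads$start), as.integer(reads$end),
                     name, score, strand), path)
  invisible(path)
}
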