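#' Read an annotated variant table
#'
#' Two dialects are supported:
#' * `"tsv"` — the package's simplified tab-separated dialect with columns
#'   `chrom, pos, ref, alt, consequence, sift, transcript_id, gene_id,
#'   lines_present` (semicolon-joined line ids; `sift`/`transcript_id`/
#'   `gene_id` use `.` for absent). Multi-allelic `alt` values may be
#'   comma-separated and are split into one record per alt.
#' * `"vcf_vep"` — VCF 4.x with a VEP `CSQ` INFO field carrying at least the
#'   `Allele`, `Consequence` and `Feature` subfields (optionally `SIFT` and
#'   `Gene`). Per-line presence is derived from the genotype columns: a line
#'   is present for an alt allele iff its genotype carries that allele at
#'   least once.
#'
#' Either dialect may be gzip-compressed. Consequence terms are normalized
#' with [normalize_consequence()] and indel alleles reduced to minimal
#' left-aligned form.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"vcf_vep"`.
#' @return a `vp_variants` tibble, one row per (site, alt allele).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf_vep")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  switch(dialect,
    tsv = read_variants_tsv(path),
    vcf_vep = read_variants_vcf(path)
  )
}

read_variants_tsv <- function(path) {
  raw <- readr::read_tsv(
    path, na = ".", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character(),
      consequence = readr::col_character(), sift = readr::col_double(),
      transcript_id = readr::col_character(),
      gene_id = readr::col_character(),
      lines_present = readr::col_character()
    )
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(paste0("malformed variant TSV row at line ", prob$row[1] + 1L,
                 " of ", path, ": ", prob$expected[1], " expected."))
  }
  bad <- which(is.na(raw$pos) | is.na(raw$chrom) | is.na(raw$ref) |
                 is.na(raw$alt) | is.na(raw$lines_present))
  if (length(bad) > 0) {
    abort(paste0("malformed variant TSV row at line ", bad[1] + 1L,
                 " of ", path, " (missing required field)."))
  }
  # split multi-allelic alts into one record per alt
  raw <- tidyr::separate_rows(raw, "alt", sep = ",")
  raw$consequence <- normalize_consequence(raw$consequence)
  norm <- normalize_alleles(raw$pos, raw$ref, raw$alt)
  raw$pos <- norm$pos; raw$ref <- norm$ref; raw$alt <- norm$alt
  raw$lines <- strsplit(raw$lines_present, ";", fixed = TRUE)
  raw$lines_present <- NULL
  variant_table(raw)
}

#' Write a variant table in the simplified TSV dialect
#'
#' @param x a `vp_variants` tibble.
#' @param path output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  out <- as_tibble(x)
  out$lines_present <- vapply(out$lines, paste, character(1), collapse = ";")
  out$lines <- NULL
  out <- out[, c("chrom", "pos", "ref", "alt", "consequence", "sift",
                 "transcript_id", "gene_id", "lines_present")]
  readr::write_tsv(out, path, na = ".", progress = FALSE)
  invisible(path)
}

read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(variant_table(tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), consequence = character(), sift = numeric(),
      transcript_id = character(), gene_id = character(), lines = list()
    )))
  }
  csq_fields <- vcf_csq_fields(v)
  info <- vcfR::extract.info(v, element = "CSQ")
  gt <- vcfR::extract.gt(v, element = "GT")
  sample_ids <- colnames(gt)

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ann <- parse_csq(info[i], csq_fields)
    gts <- gt[i, ]
    for (k in seq_along(alts)) {
      # a line is present iff its GT carries allele index k at least once
      present <- sample_ids[vapply(gts, function(g) {
        if (is.na(g)) return(FALSE)
        any(strsplit(g, "[/|]")[[1]] == as.character(k))
      }, logical(1))]
      if (length(present) == 0) next
      a <- ann[ann$allele == alts[k], , drop = FALSE]
      if (nrow(a) == 0) a <- tibble(allele = alts[k], consequence = NA_character_,
                                    sift = NA_real_, transcript_id = NA_character_,
                                    gene_id = NA_character_)
      csq <- if (is.na(a$consequence[1])) "intergenic" else
        normalize_consequence(a$consequence[1])
      rows[[length(rows) + 1]] <- tibble(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], consequence = csq,
        sift = a$sift[1], transcript_id = a$transcript_id[1],
        gene_id = a$gene_id[1], lines = list(present)
      )
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(variant_table(tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), consequence = character(), sift = numeric(),
      transcript_id = character(), gene_id = character(), lines = list()
    )))
  }
  out <- dplyr::bind_rows(rows)
  norm <- normalize_alleles(out$pos, out$ref, out$alt)
  out$pos <- norm$pos; out$ref <- norm$ref; out$alt <- norm$alt
  variant_table(out)
}

vcf_csq_fields <- function(v) {
  meta <- v@meta
  line <- grep("^##INFO=<ID=CSQ", meta, value = TRUE)
  if (length(line) == 0) abort("VCF has no CSQ INFO definition (VEP annotation required).")
  fmt <- sub('.*Format: *([^">]+).*', "\\1", line[1])
  strsplit(fmt, "|", fixed = TRUE)[[1]]
}

parse_csq <- function(csq_string, fields) {
  empty <- tibble(allele = character(), consequence = character(),
                  sift = numeric(), transcript_id = character(),
                  gene_id = character())
  if (is.na(csq_string) || csq_string == "") return(empty)
  entries <- strsplit(csq_string, ",", fixed = TRUE)[[1]]
  parts <- strsplit(entries, "|", fixed = TRUE)
  grab <- function(p, name) {
    idx <- match(name, fields)
    if (is.na(idx) || idx > length(p) || p[idx] == "") NA_character_ else p[idx]
  }
  tibble(
    allele = vapply(parts, grab, character(1), "Allele"),
    consequence = vapply(parts, grab, character(1), "Consequence"),
    sift = vapply(parts, function(p) parse_sift(grab(p, "SIFT")), numeric(1)),
    transcript_id = vapply(parts, grab, character(1), "Feature"),
    gene_id = vapply(parts, grab, character(1), "Gene")
  )
}

# VEP writes SIFT either bare ("0.03") or as "deleterious(0.03)"
parse_sift <- function(s) {
  if (is.na(s)) return(NA_real_)
  m <- regmatches(s, regexpr("[0-9]*\\.?[0-9]+", s))
  if (length(m) == 0) NA_real_ else as.numeric(m)
}

#' Read a transcript catalog
#'
#' Accepts either a GTF/GFF file (CDS feature lengths are summed per
#' transcript; gene spans taken from the range of each gene's features) or a
#' TSV with columns `transcript_id, gene_id, cds_length` and optionally
#' `chrom, gene_start, gene_end`. Transcripts with zero CDS length are
#' excluded with a warning. An optional GMT file attaches GO/KEGG categories
#' at the gene level.
#'
#' @param path catalog path (`.gtf`/`.gff`/`.gff3` or TSV).
#' @param gmt optional path to a GMT gene-set file.
#' @return a `vp_catalog` tibble: `transcript_id, gene_id, cds_length`
#'   (+ span columns when available), with a `gene_sets` attribute (tibble
#'   `category_id, gene_id`) when `gmt` is given.
#' @export
read_transcript_catalog <- function(path, gmt = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  is_gtf <- grepl("\\.(gtf|gff3?)(\\.gz)?$", path, ignore.case = TRUE)
  cat_tbl <- if (is_gtf) read_catalog_gtf(path) else read_catalog_tsv(path)
  zero <- cat_tbl$cds_length <= 0 | is.na(cat_tbl$cds_length)
  if (any(zero)) {
    warn(paste0("excluding ", sum(zero), " transcript(s) with zero CDS length: ",
                paste(head(cat_tbl$transcript_id[zero], 5), collapse = ", ")))
    cat_tbl <- cat_tbl[!zero, , drop = FALSE]
  }
  if (anyDuplicated(cat_tbl$transcript_id)) {
    abort("transcript ids must be unique within a catalog.")
  }
  if (!is.null(gmt)) attr(cat_tbl, "gene_sets") <- read_gmt(gmt)
  class(cat_tbl) <- c("vp_catalog", class(cat_tbl))
  cat_tbl
}

read_catalog_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, na = ".")
  needed <- c("transcript_id", "gene_id", "cds_length")
  if (!all(needed %in% names(x))) {
    abort(paste0("catalog TSV needs columns: ", paste(needed, collapse = ", ")))
  }
  x$cds_length <- as.integer(x$cds_length)
  as_tibble(x)
}

read_catalog_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) abort("GTF contains no CDS features.")
  lens <- cds |>
    dplyr::group_by(.data$transcript_id, .data$gene_id) |>
    dplyr::summarise(cds_length = as.integer(sum(.data$width)), .groups = "drop")
  spans <- df |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(chrom = as.character(.data$seqnames[1]),
                     gene_start = min(.data$start),
                     gene_end = max(.data$end), .groups = "drop")
  as_tibble(dplyr::left_join(lens, spans, by = "gene_id"))
}

#' Read / write GMT gene-set files
#'
#' GMT is tab-separated: category id, description, then member gene ids.
#'
#' @param path GMT file path.
#' @return tidy tibble with columns `category_id`, `description`, `gene_id`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort(paste0("malformed GMT line: ", substr(l, 1, 60)))
    tibble(category_id = f[1], description = f[2], gene_id = f[-(1:2)])
  })
  dplyr::bind_rows(rows)
}

#' @rdname read_gmt
#' @param sets tidy tibble as returned by [read_gmt()].
#' @export
write_gmt <- function(sets, path) {
  lines <- sets |>
    dplyr::group_by(.data$category_id, .data$description) |>
    dplyr::summarise(members = paste(.data$gene_id, collapse = "\t"),
                     .groups = "drop") |>
    dplyr::arrange(.data$category_id)
  readr::write_lines(
    paste(lines$category_id, lines$description, lines$members, sep = "\t"),
    path
  )
  invisible(path)
}

#' Read a CNV call table
#'
#' Dialects:
#' * `"cnvnator_txt"` — CNVnator's text output: columns `type`
#'   (duplication/deletion), `coordinates` (`chrom:start-end`, 1-based
#'   inclusive), `size`, then quality columns of which `q0` (fraction of
#'   reads mapping to multiple locations) is read as `multimap_fraction`.
#' * `"bed_tsv"` — BED-like TSV with columns `chrom, start, end, cnv_type,
#'   multimap_fraction[, line_id]`; coordinates are 0-based half-open and
#'   converted to 1-based inclusive at the boundary.
#'
#' @param path file path.
#' @param dialect `"cnvnator_txt"` or `"bed_tsv"`.
#' @param line_id line id to assign when the file does not carry one.
#' @return `vp_cnvs` tibble: `chrom, start, end, cnv_type, size,
#'   multimap_fraction, line_id` (1-based inclusive; `size = end - start + 1`).
#' @export
read_cnv_table <- function(path, dialect = c("bed_tsv", "cnvnator_txt"),
                           line_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- switch(dialect,
    cnvnator_txt = {
      raw <- readr::read_tsv(path, col_names = c("type", "coordinates", "size",
                                                 "normalized_rd", "e_val1",
                                                 "e_val2", "e_val3", "e_val4", "q0"),
                             show_col_types = FALSE, progress = FALSE)
      m <- stringr::str_match(raw$coordinates, "^([^:]+):([0-9]+)-([0-9]+)$")
      if (anyNA(m[, 1])) {
        abort(paste0("malformed CNVnator coordinates at row ",
                     which(is.na(m[, 1]))[1]))
      }
      tibble(
        chrom = m[, 2], start = as.integer(m[, 3]), end = as.integer(m[, 4]),
        cnv_type = dplyr::case_match(raw$type, "duplication" ~ "gain",
                                     "deletion" ~ "loss", .default = raw$type),
        multimap_fraction = as.numeric(raw$q0)
      )
    },
    bed_tsv = {
      raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
      tb <- tibble(
        chrom = as.character(raw$chrom),
        start = as.integer(raw$start) + 1L,  # BED 0-based half-open -> 1-based
        end = as.integer(raw$end),
        cnv_type = dplyr::case_match(raw$cnv_type, "duplication" ~ "gain",
                                     "deletion" ~ "loss", .default = raw$cnv_type),
        multimap_fraction = as.numeric(raw$multimap_fraction)
      )
      if ("line_id" %in% names(raw)) tb$line_id <- as.character(raw$line_id)
      tb
    }
  )
  if (!"line_id" %in% names(x)) {
    x$line_id <- line_id %||% NA_character_
  }
  cnv_table(x)
}

#' Construct / validate a CNV table
#'
#' @param x data frame with `chrom, start, end, cnv_type, multimap_fraction,
#'   line_id` (1-based inclusive coordinates). `size` is recomputed.
#' @return `vp_cnvs` tibble.
#' @export
cnv_table <- function(x) {
  x <- as_tibble(x)
  if (any(x$end < x$start)) abort("CNV records with end < start.")
  if (!all(x$cnv_type %in% c("gain", "loss"))) {
    abort("cnv_type must be 'gain' or 'loss' (duplication/deletion are mapped on read).")
  }
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  x$size <- x$end - x$start + 1L
  x <- x[, c("chrom", "start", "end", "cnv_type", "size",
             "multimap_fraction", "line_id")]
  class(x) <- c("vp_cnvs", class(x))
  x
}

#' Write a CNV table as BED-like TSV
#'
#' Coordinates are written 0-based half-open (BED convention), so
#' write-then-read is an identity on the records.
#'
#' @param x `vp_cnvs` tibble.
#' @param path output path.
#' @export
write_cnv_table <- function(x, path) {
  out <- tibble(
    chrom = x$chrom, start = x$start - 1L, end = x$end,
    cnv_type = x$cnv_type, multimap_fraction = x$multimap_fraction,
    line_id = x$line_id
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
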