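#' Regions qualifying for phylogenetic SNP selection
#'
#' Intersects, across every line of the panel, the genomic intervals whose
#' uniquely-mapped read depth exceeds the platform threshold: strictly more
#' than `illumina_min` reads for Illumina-sequenced lines and strictly more
#' than `solid_min` for SOLiD-sequenced lines (a depth of exactly 10 in an
#' Illumina line disqualifies the position).
#'
#' @param masks tibble of depth step functions: `line_id, chrom, start, end,
#'   depth` (1-based inclusive intervals; positions not covered by any
#'   interval have depth 0).
#' @param panel `vp_panel`; every line must have a mask.
#' @param illumina_min,solid_min strict depth thresholds (defaults 10 and 5).
#' @return tibble `chrom, start, end` of qualifying intervals.
#' @export
qualifying_regions <- function(masks, panel, illumina_min = 10, solid_min = 5) {
  missing_lines <- setdiff(panel$line_id, unique(masks$line_id))
  if (length(missing_lines) > 0) {
    abort(paste0("no coverage mask for line(s): ",
                 paste(missing_lines, collapse = ", ")))
  }
  thresholds <- setNames(
    ifelse(panel$platform == "illumina", illumina_min, solid_min),
    panel$line_id
  )
  out <- list()
  for (ch in sort(unique(masks$chrom))) {
    per_line <- lapply(panel$line_id, function(l) {
      m <- masks[masks$line_id == l & masks$chrom == ch &
                   masks$depth > thresholds[[l]], , drop = FALSE]
      IRanges::reduce(IRanges::IRanges(m$start, m$end))
    })
    inter <- Reduce(IRanges::intersect, per_line)
    if (length(inter) > 0) {
      out[[ch]] <- tibble(chrom = ch,
                          start = IRanges::start(inter),
                          end = IRanges::end(inter))
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  dplyr::bind_rows(out)
}

#' Platform-presence filter for phylogenetic SNPs
#'
#' Restricts a SNP panel to qualifying regions (when supplied) and keeps
#' SNPs carried by at least `min_illumina` Illumina-sequenced lines and at
#' least `min_solid` SOLiD-sequenced lines.
#'
#' @param snps `vp_variants` tibble.
#' @param panel `vp_panel`.
#' @param regions optional tibble from [qualifying_regions()]; SNPs outside
#'   it are dropped first.
#' @param min_illumina,min_solid presence thresholds (defaults 1 and 2).
#' @return filtered `vp_variants` tibble.
#' @export
presence_filter <- function(snps, panel, regions = NULL,
                            min_illumina = 1, min_solid = 2) {
  x <- snps
  if (!is.null(regions)) {
    inside <- rep(FALSE, nrow(x))
    for (ch in unique(regions$chrom)) {
      rr <- regions[regions$chrom == ch, ]
      idx <- which(x$chrom == ch)
      if (length(idx) == 0) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(x$pos[idx], x$pos[idx]),
        IRanges::IRanges(rr$start, rr$end))
      inside[idx[unique(S4Vectors::queryHits(hits))]] <- TRUE
    }
    x <- x[inside, , drop = FALSE]
  }
  ill <- panel$line_id[panel$platform == "illumina"]
  sol <- panel$line_id[panel$platform == "solid"]
  n_ill <- vapply(x$lines, function(l) sum(ill %in% l), integer(1))
  n_sol <- vapply(x$lines, function(l) sum(sol %in% l), integer(1))
  x[n_ill >= min_illumina & n_sol >= min_solid, , drop = FALSE]
}

#' Concatenated SNP alignment
#'
#' Builds the character matrix whose columns are the retained SNP sites
#' (sorted by chromosome, then position) and whose rows are the panel lines
#' plus an outgroup. A line's allele at a site is the alternate base when
#' the line carries the variant and the reference base otherwise;
#' the outgroup row is all-reference unless its calls are part of the
#' panel. Heterozygous calls are represented by the alternate allele
#' (presence semantics). Only single-base substitutions are used; indel
#' records are dropped with a warning.
#'
#' @param snps filtered `vp_variants` tibble (see [presence_filter()]).
#' @param panel `vp_panel`.
#' @param outgroup name for the all-reference outgroup row (default
#'   `"outgroup"`; set NULL to omit).
#' @return object of class `vp_alignment`: list with `matrix` (lines x
#'   sites character matrix) and `sites` (tibble `column, chrom, pos, ref,
#'   alt`).
#' @export
build_snp_alignment <- function(snps, panel, outgroup = "outgroup") {
  is_snp <- nchar(snps$ref) == 1 & nchar(snps$alt) == 1
  if (any(!is_snp)) {
    warn(paste0("dropping ", sum(!is_snp), " non-SNP record(s) from the alignment."))
    snps <- snps[is_snp, , drop = FALSE]
  }
  if (nrow(snps) == 0) {
    abort(paste0("no SNPs retained for the alignment; ",
                 "consider relaxing the depth or presence thresholds."))
  }
  snps <- snps[order(snps$chrom, snps$pos, snps$alt), , drop = FALSE]
  rows <- panel$line_id
  mat <- matrix(rep(snps$ref, each = length(rows)),
                nrow = length(rows), dimnames = list(rows, NULL))
  for (j in seq_len(nrow(snps))) {
    carriers <- intersect(snps$lines[[j]], rows)
    mat[carriers, j] <- snps$alt[j]
  }
  if (!is.null(outgroup)) {
    mat <- rbind(mat, matrix(snps$ref, nrow = 1, dimnames = list(outgroup, NULL)))
  }
  out <- list(
    matrix = mat,
    sites = tibble(column = seq_len(nrow(snps)), chrom = snps$chrom,
                   pos = snps$pos, ref = snps$ref, alt = snps$alt)
  )
  class(out) <- "vp_alignment"
  out
}

#' @exportS3Method base::print
print.vp_alignment <- function(x, ...) {
  cat("Concatenated SNP alignment:", nrow(x$matrix), "sequences x",
      ncol(x$matrix), "sites\n")
  invisible(x)
}

#' Serialize an alignment
#'
#' `write_alignment_fasta()` writes standard FASTA (via Biostrings);
#' `write_alignment_phylip()` writes relaxed PHYLIP (full names, single
#' space separator). `read_alignment_fasta()` / `read_alignment_phylip()`
#' decode either format back to the character matrix, so round-trips are
#' exact.
#'
#' @param alignment a `vp_alignment`.
#' @param path output path.
#' @return `path` invisibly (writers); character matrix (readers).
#' @export
write_alignment_fasta <- function(alignment, path) {
  seqs <- apply(alignment$matrix, 1, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @export
write_alignment_phylip <- function(alignment, path) {
  m <- alignment$matrix
  lines <- c(paste(nrow(m), ncol(m)),
             paste(rownames(m), apply(m, 1, paste, collapse = "")))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  w <- unique(Biostrings::width(ss))
  if (length(w) != 1) abort("FASTA sequences have unequal lengths.")
  mat <- t(vapply(as.character(ss), function(s) strsplit(s, "")[[1]],
                  character(w)))
  rownames(mat) <- names(ss)
  mat
}

#' @rdname write_alignment_fasta
#' @export
read_alignment_phylip <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  header <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1][nzchar(lines[-1])]
  parts <- strsplit(trimws(body), "\\s+")
  mat <- t(vapply(parts, function(p) strsplit(p[2], "")[[1]],
                  character(header[2])))
  rownames(mat) <- vapply(parts, `[[`, character(1), 1)
  stopifnot(nrow(mat) == header[1])
  mat
}

#' Site map TSV for an alignment
#'
#' Writes the column -> chrom:pos mapping alongside the alignment.
#'
#' @param alignment a `vp_alignment`.
#' @param path output path.
#' @export
write_site_map <- function(alignment, path) {
  readr::write_tsv(alignment$sites, path, progress = FALSE)
  invisible(path)
}
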