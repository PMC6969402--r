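#' Consequence vocabulary
#'
#' The fixed, normalized consequence vocabulary used throughout the package.
#' External annotation terms (VEP, ANNOVAR) are mapped onto it at read time;
#' see [normalize_consequence()].
#'
#' @return character vector of accepted consequence classes.
#' @export
consequence_levels <- function() {
  c(
    "synonymous", "nonsynonymous", "intergenic", "intronic",
    "utr5", "utr3", "frameshift_indel", "nonframeshift_indel",
    "stop_gain", "stop_loss", "start_loss"
  )
}

# high-impact classes used by Strategy 3
high_impact_levels <- function() c("frameshift_indel", "start_loss", "stop_gain")

# severity order used when an annotation lists several terms for one allele
.csq_priority <- c(
  "stop_gain", "start_loss", "stop_loss", "frameshift_indel",
  "nonframeshift_indel", "nonsynonymous", "synonymous",
  "utr5", "utr3", "intronic", "intergenic"
)

# external-term dictionary (VEP release-87 style and ANNOVAR refGene style)
.csq_map <- c(
  missense_variant        = "nonsynonymous",
  synonymous_variant      = "synonymous",
  intron_variant          = "intronic",
  intergenic_variant      = "intergenic",
  `5_prime_UTR_variant`   = "utr5",
  `3_prime_UTR_variant`   = "utr3",
  frameshift_variant      = "frameshift_indel",
  inframe_insertion       = "nonframeshift_indel",
  inframe_deletion        = "nonframeshift_indel",
  stop_gained             = "stop_gain",
  stop_lost               = "stop_loss",
  start_lost              = "start_loss",
  `nonsynonymous SNV`     = "nonsynonymous",
  `synonymous SNV`        = "synonymous",
  UTR5                    = "utr5",
  UTR3                    = "utr3",
  `frameshift insertion`  = "frameshift_indel",
  `frameshift deletion`   = "frameshift_indel",
  `nonframeshift insertion` = "nonframeshift_indel",
  `nonframeshift deletion`  = "nonframeshift_indel",
  stopgain                = "stop_gain",
  stoploss                = "stop_loss",
  startloss               = "start_loss"
)

#' Normalize annotation consequence terms
#'
#' Maps VEP/ANNOVAR consequence strings (possibly several joined by `&` or
#' `,`) onto the package vocabulary, keeping the most severe mappable term.
#' Terms already in the vocabulary pass through unchanged.
#'
#' @param x character vector of consequence strings.
#' @return character vector drawn from [consequence_levels()].
#' @export
normalize_consequence <- function(x) {
  out <- vapply(x, function(s) {
    terms <- unlist(strsplit(s, "[&,]"))
    terms <- trimws(terms)
    mapped <- ifelse(terms %in% consequence_levels(), terms,
                     unname(.csq_map[terms]))
    mapped <- mapped[!is.na(mapped)]
    if (length(mapped) == 0) {
      abort(paste0(
        "Unknown consequence string '", s, "'. Accepted vocabulary: ",
        paste(consequence_levels(), collapse = ", "),
        " (or a mappable VEP/ANNOVAR term)."
      ))
    }
    mapped[which.min(match(mapped, .csq_priority))]
  }, character(1))
  unname(out)
}

#' Construct / validate a variant table
#'
#' The internal variant representation is a tibble with one row per
#' (site, alt allele): columns `chrom`, `pos` (1-based), `ref`, `alt`,
#' `consequence`, `sift` (NA when unscored), `transcript_id` (NA for
#' intergenic), `gene_id` (NA allowed) and `lines` (list-column of line ids
#' in which the variant was called). Multi-allelic sites must already be
#' split. Indel alleles are stored in minimal left-aligned form (see
#' [normalize_alleles()]).
#'
#' @param x a data frame with the columns above (`lines` may be a
#'   semicolon-separated character column, which is converted).
#' @return a validated tibble of class `vp_variants`.
#' @export
variant_table <- function(x) {
  x <- as_tibble(x)
  needed <- c("chrom", "pos", "ref", "alt", "consequence", "sift",
              "transcript_id", "gene_id", "lines")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(paste0("variant table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (!is.list(x$lines)) {
    x$lines <- strsplit(as.character(x$lines), ";", fixed = TRUE)
  }
  x$pos <- as.integer(x$pos)
  x$sift <- as.numeric(x$sift)
  if (any(x$pos < 1L)) abort("variant positions must be >= 1.")
  if (any(lengths(x$lines) == 0)) {
    abort("every variant must be present in at least one line.")
  }
  bad_sift <- !is.na(x$sift) & (x$sift < 0 | x$sift > 1)
  if (any(bad_sift)) abort("SIFT scores must lie in [0, 1].")
  unknown <- setdiff(unique(x$consequence), consequence_levels())
  if (length(unknown) > 0) {
    abort(paste0("Unknown consequence class(es): ",
                 paste(unknown, collapse = ", "),
                 ". Accepted vocabulary: ",
                 paste(consequence_levels(), collapse = ", ")))
  }
  class(x) <- c("vp_variants", class(x))
  x
}

#' Minimal left-aligned allele representation
#'
#' Trims shared trailing bases, then shared leading bases (advancing `pos`),
#' so that e.g. `pos 100 ref ACG alt ACT` becomes `pos 102 ref G alt T` and
#' indel records from different callers compare equal. At least one base of
#' ref and alt is always retained.
#'
#' @param pos,ref,alt parallel vectors describing one allele per element.
#' @return tibble with normalized `pos`, `ref`, `alt`.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  for (i in seq_along(pos)) {
    r <- strsplit(ref[i], "")[[1]]
    a <- strsplit(alt[i], "")[[1]]
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    }
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]; a <- a[-1]; pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = ""); alt[i] <- paste(a, collapse = "")
  }
  tibble(pos = pos, ref = ref, alt = alt)
}

#' Variant identity keys
#'
#' A variant's identity is the exact tuple (chrom, pos, ref, alt) —
#' annotations and zygosity are ignored, mirroring position/allele
#' intersection semantics of `vcf-isec`.
#'
#' @param x a variant table.
#' @return character vector of `chrom:pos:ref:alt` keys.
#' @export
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Line panel constructor
#'
#' Describes the sequenced lines: id, sequencing platform and role in the
#' longitudinal design. Exactly one line must carry each focal role.
#'
#' @param line_id character ids.
#' @param platform `"illumina"` or `"solid"` per line.
#' @param role one of `"focal_1957"`, `"focal_1978"`, `"focal_ross308"`,
#'   `"background"` per line.
#' @return tibble of class `vp_panel`.
#' @export
line_panel <- function(line_id, platform, role) {
  platform <- match.arg(platform, c("illumina", "solid"), several.ok = TRUE)
  ok_roles <- c("focal_1957", "focal_1978", "focal_ross308", "background")
  if (!all(role %in% ok_roles)) {
    abort(paste0("roles must be among: ", paste(ok_roles, collapse = ", ")))
  }
  x <- tibble(line_id = line_id, platform = platform, role = role)
  for (r in c("focal_1957", "focal_1978", "focal_ross308")) {
    if (sum(x$role == r) != 1) {
      abort(paste0("exactly one line must carry role '", r, "'."))
    }
  }
  if (anyDuplicated(x$line_id)) abort("line ids must be unique.")
  class(x) <- c("vp_panel", class(x))
  x
}

# focal line ids in temporal order 1957 -> 1978 -> ross308
focal_lines <- function(panel) {
  c(panel$line_id[panel$role == "focal_1957"],
    panel$line_id[panel$role == "focal_1978"],
    panel$line_id[panel$role == "focal_ross308"])
}

background_lines <- function(panel) panel$line_id[panel$role == "background"]
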