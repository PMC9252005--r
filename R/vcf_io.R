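#' Construct a genotype matrix
#'
#' The central container of the package: a samples x variants matrix of
#' alternate-allele counts (0, 1, 2 or `NA` for missing), together with a
#' variant table and, for phased data, the underlying haplotype matrix.
#'
#' @param gt integer matrix, samples in rows, variants in columns; entries
#'   must be 0, 1, 2 or `NA`.
#' @param variants data frame with columns `chrom`, `pos` (1-based bp),
#'   and optionally `id`, `ref`, `alt` (comma-separated for multiallelic
#'   records), `multiallelic`, `impact` (`"HIGH"`, `"OTHER"` or `NA`) and
#'   `dr2`.
#' @param sample_ids character vector of sample labels; defaults to the
#'   row names of `gt`.
#' @param phased logical; if `TRUE`, `haplotypes` must be supplied.
#' @param haplotypes 0/1 matrix with two rows per sample (rows `2i - 1`
#'   and `2i` are the two chromosome copies of sample `i`). Per sample,
#'   the two haplotype rows must sum to `gt`.
#' @param chrom_order character vector giving the chromosome sort order;
#'   defaults to order of first appearance in `variants$chrom`.
#'
#' @details Variants are stored sorted by `(chrom, pos)`, with chromosome
#'   order taken from `chrom_order`. Missingness is always encoded as `NA`,
#'   never as 0, so that masked genotypes remain distinguishable from
#'   homozygous reference calls.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(gt, variants, sample_ids = rownames(gt),
                            phased = FALSE, haplotypes = NULL,
                            chrom_order = NULL) {
  gt <- as.matrix(gt)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(gt)))
  stopifnot(length(sample_ids) == nrow(gt))
  variants <- normalize_variants(variants, ncol(gt))
  if (is.null(chrom_order)) chrom_order <- unique(as.character(variants$chrom))

  bad <- !(gt %in% c(0L, 1L, 2L) | is.na(gt))
  if (any(bad)) {
    stop("genotype values outside {0, 1, 2, NA}: e.g. ", gt[which(bad)[1]])
  }
  storage.mode(gt) <- "integer"

  if (phased) {
    if (is.null(haplotypes)) stop("phased = TRUE requires a haplotype matrix")
    haplotypes <- as.matrix(haplotypes)
    storage.mode(haplotypes) <- "integer"
    if (nrow(haplotypes) != 2L * nrow(gt) || ncol(haplotypes) != ncol(gt)) {
      stop("haplotypes must be a (2 * samples) x variants matrix")
    }
    hs <- haplotypes[seq(1L, nrow(haplotypes), 2L), , drop = FALSE] +
      haplotypes[seq(2L, nrow(haplotypes), 2L), , drop = FALSE]
    mism <- which(!is.na(gt) & (is.na(hs) | hs != gt))
    if (length(mism)) stop("haplotype rows do not sum to gt at ", length(mism), " entries")
  } else {
    haplotypes <- NULL
  }

  ord <- order(match(as.character(variants$chrom), chrom_order), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  gt <- gt[, ord, drop = FALSE]
  if (!is.null(haplotypes)) haplotypes <- haplotypes[, ord, drop = FALSE]

  rownames(gt) <- sample_ids
  structure(
    list(sample_ids = as.character(sample_ids), variants = variants, gt = gt,
         phased = isTRUE(phased), haplotypes = haplotypes,
         chrom_order = chrom_order),
    class = "genotype_matrix")
}

normalize_variants <- function(variants, n) {
  variants <- as.data.frame(variants)
  stopifnot(all(c("chrom", "pos") %in% names(variants)), nrow(variants) == n)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (any(variants$pos < 1L)) stop("positions must be >= 1 (1-based)")
  if (is.null(variants$id)) variants$id <- rep(NA_character_, n)
  if (is.null(variants$ref)) variants$ref <- rep("A", n)
  if (is.null(variants$alt)) variants$alt <- rep("C", n)
  if (is.null(variants$multiallelic)) {
    variants$multiallelic <- grepl(",", variants$alt, fixed = TRUE)
  }
  if (is.null(variants$impact)) variants$impact <- rep(NA_character_, n)
  if (is.null(variants$dr2)) variants$dr2 <- rep(NA_real_, n)
  variants
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants",
      if (x$phased) "(phased)" else "(unphased)", "\n")
  cat("  chromosomes:", paste(x$chrom_order, collapse = ", "), "\n")
  cat("  missing genotypes:", sum(is.na(x$gt)), "\n")
  invisible(x)
}

#' Number of samples / variants in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(gm) length(gm$sample_ids)

#' @rdname n_samples
#' @export
n_variants <- function(gm) nrow(gm$variants)

variant_keys <- function(x) {
  if (inherits(x, "genotype_matrix")) x <- x$variants
  if (inherits(x, "marker_panel")) x <- x$sites
  paste(x$chrom, x$pos, sep = ":")
}

#' Subset a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @param samples sample ids or indices to keep (default all).
#' @param sites logical or integer index over variants (default all).
#' @return a `genotype_matrix` restricted to the selection.
#' @export
subset_gm <- function(gm, samples = NULL, sites = NULL) {
  si <- if (is.null(samples)) seq_along(gm$sample_ids) else {
    if (is.character(samples)) {
      idx <- match(samples, gm$sample_ids)
      if (anyNA(idx)) stop("unknown sample id: ", samples[which(is.na(idx))[1]])
      idx
    } else samples
  }
  vi <- if (is.null(sites)) seq_len(n_variants(gm)) else {
    if (is.logical(sites)) which(sites) else sites
  }
  hap <- NULL
  if (gm$phased) {
    hrows <- as.vector(rbind(2L * si - 1L, 2L * si))
    hap <- gm$haplotypes[hrows, vi, drop = FALSE]
  }
  genotype_matrix(gm$gt[si, vi, drop = FALSE], gm$variants[vi, , drop = FALSE],
                  sample_ids = gm$sample_ids[si], phased = gm$phased,
                  haplotypes = hap, chrom_order = gm$chrom_order)
}

#' Construct a marker panel
#'
#' An ordered, deduplicated set of `(chrom, pos)` sites describing the
#' markers of a genotyping array (e.g. a medium-density 60K or a
#' high-density 670K chip) as a subset of the sequence-level variants.
#'
#' @param chrom,pos vectors of chromosome labels and 1-based positions.
#' @param name panel label, e.g. `"medium"` or `"high"`.
#' @param chrom_order chromosome sort order; defaults to order of first
#'   appearance.
#' @return An object of class `marker_panel`.
#' @export
marker_panel <- function(chrom, pos, name = "panel", chrom_order = NULL) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  stopifnot(length(chrom) == length(pos))
  if (is.null(chrom_order)) chrom_order <- unique(chrom)
  keep <- !duplicated(paste(chrom, pos, sep = ":"))
  chrom <- chrom[keep]; pos <- pos[keep]
  ord <- order(match(chrom, chrom_order), pos)
  structure(list(name = name,
                 sites = data.frame(chrom = chrom[ord], pos = pos[ord]),
                 chrom_order = chrom_order),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker_panel '", x$name, "': ", nrow(x$sites), " sites on ",
      length(unique(x$sites$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file (plain or gzipped) with GT fields. Phase is taken
#' from the `|` separator: the matrix is flagged phased only when every
#' non-missing genotype is phased. Multiallelic records are retained and
#' flagged; their `gt` entry counts non-reference alleles. `INFO/IMPACT`
#' and `INFO/DR2` are parsed into the variant table when present.
#'
#' @param path path to a VCF file.
#' @param region optional region string `"chrom"` or `"chrom:start-end"`
#'   (1-based, inclusive) to subset records after parsing.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, region = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  chrom_order <- header_contigs(vcf)
  if (nrow(fix) == 0L) {
    smp <- colnames(vcf@gt)[-1]
    return(genotype_matrix(
      matrix(integer(0), nrow = length(smp), ncol = 0),
      data.frame(chrom = character(0), pos = integer(0)),
      sample_ids = smp, chrom_order = chrom_order))
  }
  if (length(chrom_order) == 0L) chrom_order <- unique(fix$CHROM)

  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    parts <- strsplit(region, "[:-]")[[1]]
    keep <- fix$CHROM == parts[1]
    if (length(parts) == 3L) {
      p <- as.numeric(fix$POS)
      keep <- keep & p >= as.numeric(parts[2]) & p <= as.numeric(parts[3])
    }
  }

  gt_str <- vcf@gt[keep, -1, drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  fmt <- vcf@gt[keep, 1]
  gt_field <- vapply(strsplit(fmt, ":"), function(f) match("GT", f), integer(1))
  if (anyNA(gt_field)) stop("malformed VCF: record without GT at line ",
                            which(is.na(gt_field))[1])
  smp <- colnames(gt_str)

  calls <- matrix(vapply(seq_len(nrow(fix)), function(i) {
    vapply(strsplit(gt_str[i, ], ":"), `[`, character(1), gt_field[i])
  }, character(length(smp))), nrow = length(smp))

  phased_call <- grepl("|", calls, fixed = TRUE)
  alleles <- strsplit(calls, "[/|]")
  counts <- vapply(alleles, function(a) {
    if (length(a) == 0 || anyNA(a) || any(a == "." | a == "")) {
      return(NA_integer_)  # vcfR reports fully missing calls as NA
    }
    sum(a != "0")
  }, integer(1))
  gt <- matrix(counts, nrow = length(smp))
  missing_call <- is.na(gt)
  phased <- all(phased_call | missing_call)

  hap <- NULL
  if (phased && nrow(fix) > 0L) {
    hap <- matrix(NA_integer_, nrow = 2L * length(smp), ncol = nrow(fix))
    a1 <- vapply(alleles, function(a) {
      if (length(a) < 1L || is.na(a[1]) || a[1] %in% c(".", "")) NA_integer_
      else as.integer(a[1] != "0")
    }, integer(1))
    a2 <- vapply(alleles, function(a) {
      if (length(a) < 2L || is.na(a[2]) || a[2] %in% c(".", "")) NA_integer_
      else as.integer(a[2] != "0")
    }, integer(1))
    hap[seq(1L, nrow(hap), 2L), ] <- matrix(a1, nrow = length(smp))
    hap[seq(2L, nrow(hap), 2L), ] <- matrix(a2, nrow = length(smp))
    # haplotype alleles may be NA only where the genotype itself is missing
    if (any(is.na(hap[seq(1L, nrow(hap), 2L), ] + hap[seq(2L, nrow(hap), 2L), ]) & !missing_call)) {
      phased <- FALSE; hap <- NULL
    }
  }

  info_get <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0("(^|;)", key, "=[^;]*"), fix$INFO))
    out <- rep(NA_character_, nrow(fix))
    hit <- grepl(paste0(key, "="), fix$INFO)
    out[hit] <- sub(paste0(".*", key, "="), "",
                    regmatches(fix$INFO, regexpr(paste0(key, "=[^;]*"), fix$INFO)))
    out
  }
  impact <- if (any(grepl("IMPACT=", fix$INFO))) info_get("IMPACT") else NA_character_
  dr2 <- if (any(grepl("DR2=", fix$INFO))) suppressWarnings(as.numeric(info_get("DR2"))) else NA_real_

  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    id = ifelse(fix$ID == ".", NA_character_, fix$ID),
    ref = fix$REF, alt = fix$ALT,
    multiallelic = grepl(",", fix$ALT, fixed = TRUE),
    impact = impact, dr2 = dr2)

  genotype_matrix(gt, variants, sample_ids = smp, phased = phased,
                  haplotypes = hap, chrom_order = chrom_order)
}

header_contigs <- function(vcf) {
  meta <- vcf@meta
  cl <- meta[grepl("^##contig=", meta)]
  sub(".*ID=([^,>]+).*", "\\1", cl)
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a VCF 4.2 text file. Phased matrices are written with `|`
#' separators, unphased with `/`; missing genotypes become `./.`. When
#' `dosages` is supplied, expected alt-allele dosages are written as a
#' `DS` FORMAT field and per-variant dosage R-squared as `INFO/DR2`.
#' Reading the file back with [read_vcf()] reproduces `gt`, phase,
#' sample order and site order exactly.
#'
#' @param gm a `genotype_matrix`.
#' @param path output file path.
#' @param dosages optional `imputed_dosages` object aligned to `gm`'s
#'   samples (dosages at any subset of `gm`'s sites).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, dosages = NULL) {
  v <- gm$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##source=impanel",
           paste0("##contig=<ID=", gm$chrom_order, ">"),
           '##INFO=<ID=IMPACT,Number=1,Type=String,Description="Predicted impact class">',
           '##INFO=<ID=DR2,Number=1,Type=Float,Description="Dosage r-squared">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  fmt <- "GT"
  ds_mat <- NULL
  ds_dr2 <- rep(NA_real_, nrow(v))
  if (!is.null(dosages)) {
    hdr <- c(hdr, '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Estimated alt allele dosage">')
    fmt <- "GT:DS"
    idx <- match(variant_keys(gm), variant_keys(dosages$variants))
    ds_mat <- matrix(NA_real_, nrow = n_samples(gm), ncol = nrow(v))
    ok <- !is.na(idx)
    ds_mat[, ok] <- dosages$ds[match(gm$sample_ids, dosages$sample_ids), idx[ok], drop = FALSE]
    ds_dr2[ok] <- dosages$dr2[idx[ok]]
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", gm$sample_ids), collapse = "\t"))

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(v) > 0L) {
    info <- rep(".", nrow(v))
    has_imp <- !is.na(v$impact)
    info[has_imp] <- paste0("IMPACT=", v$impact[has_imp])
    dr2v <- ifelse(is.na(ds_dr2), v$dr2, ds_dr2)
    has_dr2 <- !is.na(dr2v)
    info[has_dr2] <- ifelse(info[has_dr2] == ".",
                            paste0("DR2=", signif(dr2v[has_dr2], 5)),
                            paste0(info[has_dr2], ";DR2=", signif(dr2v[has_dr2], 5)))
    sep <- if (gm$phased) "|" else "/"
    n <- n_samples(gm)
    gcalls <- matrix("", nrow = n, ncol = nrow(v))
    if (gm$phased) {
      h1 <- gm$haplotypes[seq(1L, 2L * n, 2L), , drop = FALSE]
      h2 <- gm$haplotypes[seq(2L, 2L * n, 2L), , drop = FALSE]
      gcalls[] <- paste0(h1, sep, h2)
    } else {
      gcalls[] <- c("0/0", "0/1", "1/1")[gm$gt + 1L]
    }
    gcalls[is.na(gm$gt)] <- paste0(".", sep, ".")
    if (!is.null(ds_mat)) {
      dss <- ifelse(is.na(ds_mat), ".", formatC(ds_mat, format = "f", digits = 3))
      gcalls[] <- paste0(gcalls, ":", dss)
    }
    lines <- vapply(seq_len(nrow(v)), function(j) {
      paste(c(v$chrom[j], v$pos[j], ifelse(is.na(v$id[j]), ".", v$id[j]),
              v$ref[j], v$alt[j], ".", "PASS", info[j], fmt, gcalls[, j]),
            collapse = "\t")
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read imputed dosages from a VCF with DS fields
#'
#' Ingests the output of [write_vcf()] with dosages (or any external
#' imputer's VCF carrying a `DS` FORMAT field and optional `INFO/DR2`)
#' as an `imputed_dosages` object, for evaluation-only workflows.
#' Posterior variances are not recoverable from a dosage VCF and are
#' set to `NA`.
#'
#' @param path path to a VCF with a DS FORMAT field.
#' @return an `imputed_dosages` object (`post_var` all `NA`; `dr2`
#'   taken from `INFO/DR2` where present).
#' @export
read_dosage_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gm <- read_vcf(path)
  ds_str <- vcfR::extract.gt(vcf, element = "DS")
  if (is.null(ds_str) || all(is.na(ds_str))) stop("no DS field in ", path)
  ds <- t(matrix(suppressWarnings(as.numeric(ds_str)), nrow = nrow(ds_str),
                 dimnames = dimnames(ds_str)))
  # align file record order with the sorted variant table
  file_keys <- paste(vcf@fix[, "CHROM"], vcf@fix[, "POS"], sep = ":")
  ds <- ds[, match(variant_keys(gm), file_keys), drop = FALSE]
  structure(list(sample_ids = gm$sample_ids, variants = gm$variants,
                 ds = ds, post_var = matrix(NA_real_, nrow(ds), ncol(ds)),
                 dr2 = gm$variants$dr2),
            class = "imputed_dosages")
}

#' Basic variant statistics
#'
#' Counts sites, SNPs, indels and multiallelic records and computes the
#' transition/transversion (Ti/Tv) ratio of the biallelic SNPs.
#' Transitions are the purine-purine and pyrimidine-pyrimidine changes
#' (A<->G, C<->T); all other single-nucleotide changes are transversions.
#' Multiallelic and mixed-type records are excluded from the SNP/indel
#' counts and from Ti/Tv.
#'
#' @param gm a `genotype_matrix`.
#' @return a list of class `variant_stats` with fields `n_sites`,
#'   `n_snps`, `n_indels`, `n_multiallelic`, `ti`, `tv`, `titv`
#'   (`NaN` when no transversions).
#' @export
compute_variant_stats <- function(gm) {
  v <- gm$variants
  multi <- v$multiallelic
  ref <- toupper(v$ref); alt <- toupper(v$alt)
  bi <- !multi
  is_snp <- bi & nchar(ref) == 1L & nchar(alt) == 1L
  is_indel <- bi & nchar(ref) != nchar(alt)
  pair <- paste0(ref[is_snp], alt[is_snp])
  ti <- sum(pair %in% c("AG", "GA", "CT", "TC"))
  tv <- sum(is_snp) - ti
  structure(list(n_sites = nrow(v), n_snps = sum(is_snp),
                 n_indels = sum(is_indel), n_multiallelic = sum(multi),
                 ti = ti, tv = tv,
                 titv = if (tv > 0) ti / tv else NaN),
            class = "variant_stats")
}

#' @export
print.variant_stats <- function(x, ...) {
  cat(sprintf("sites: %d  snps: %d  indels: %d  multiallelic: %d  Ti/Tv: %s\n",
              x$n_sites, x$n_snps, x$n_indels, x$n_multiallelic,
              format(x$titv, digits = 4)))
  invisible(x)
}

#' Load a marker panel from a positions file
#'
#' Accepts either a two-column `chrom pos` table (1-based positions,
#' whitespace- or tab-separated, optional header) or a three-column BED
#' file (0-based half-open intervals, expanded to the 1-based positions
#' they cover). Sites are deduplicated and sorted.
#'
#' @param path path to the positions file.
#' @param name panel label.
#' @return a [marker_panel()].
#' @export
load_marker_panel <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) > 0 && suppressWarnings(is.na(as.numeric(tab[1, 2])))) {
    tab <- tab[-1, , drop = FALSE]  # header row
  }
  if (ncol(tab) < 2L) stop("need at least chrom and position columns")
  if (anyNA(suppressWarnings(as.numeric(tab[[2]])))) {
    stop("non-numeric position in ", path)
  }
  if (ncol(tab) >= 3L &&
      !anyNA(suppressWarnings(as.numeric(tab[[3]])))) {
    # BED: 0-based half-open [start, end) -> 1-based positions start+1 .. end
    start <- as.integer(tab[[2]]); end <- as.integer(tab[[3]])
    if (any(end <= start)) stop("empty BED interval in ", path)
    chrom <- rep(tab[[1]], end - start)
    pos <- unlist(mapply(function(s, e) (s + 1L):e, start, end,
                         SIMPLIFY = FALSE))
  } else {
    chrom <- tab[[1]]
    pos <- as.integer(tab[[2]])
  }
  marker_panel(chrom, pos, name = name)
}

#' Write a marker panel as a two-column TSV
#' @param panel a `marker_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_panel <- function(panel, path) {
  utils::write.table(panel$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
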