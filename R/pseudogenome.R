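# Depth filtering of breed-diagnostic SNPs and reference substitution.

#' Read-depth retention thresholds for SNP filtering
#'
#' SNPs are retained only when supported by strictly more reads than the
#' threshold in *each* parental breed. The autosomal default is >10 reads;
#' on the Z chromosome — present in one copy in females, so coverage is
#' systematically lower — the threshold drops to >4 reads.
#'
#' @param autosome_min_exclusive,z_min_exclusive Exclusive lower depth
#'   bounds.
#' @return A named list of class `depth_thresholds`.
#' @export
depth_thresholds <- function(autosome_min_exclusive = 10L, z_min_exclusive = 4L) {
  if (autosome_min_exclusive < 0 || z_min_exclusive < 0) {
    stop("Depth thresholds must be non-negative.", call. = FALSE)
  }
  structure(list(autosome_min_exclusive = as.integer(autosome_min_exclusive),
                 z_min_exclusive = as.integer(z_min_exclusive)),
            class = "depth_thresholds")
}

#' Filter SNPs by per-breed supporting read depth
#'
#' Keeps a SNP only if both breeds' supporting depths strictly exceed the
#' threshold for the SNP's chromosome class (boundary depths are rejected:
#' the rule is "more than", not "at least"). Input order is preserved.
#'
#' @param snps Tibble with `depth_cor`, `depth_wl` and `chromosome_class`
#'   (`"autosome"` or `"Z"`) columns.
#' @param thresholds A [depth_thresholds()].
#' @return The retained subset of `snps`.
#' @export
filter_snps <- function(snps, thresholds = depth_thresholds()) {
  stopifnot(inherits(thresholds, "depth_thresholds"))
  cut <- ifelse(snps$chromosome_class == "Z",
                thresholds$z_min_exclusive, thresholds$autosome_min_exclusive)
  snps[snps$depth_cor > cut & snps$depth_wl > cut, , drop = FALSE]
}

#' Substitute SNP alleles into a reference sequence
#'
#' Builds a parental pseudo-genome by replacing the reference base at each
#' SNP position with the alternate allele. Only biallelic single-nucleotide
#' records are substituted; indels or multi-allelic records are skipped
#' with a warning. By default the reference base at each position must
#' equal the record's `ref_allele`, otherwise the function stops naming the
#' offending `chrom:pos`.
#'
#' @param reference A [Biostrings::DNAStringSet] (names are chromosome ids).
#' @param snps Tibble with `chrom`, `pos` (1-based), `ref_allele`,
#'   `alt_allele`.
#' @param check_ref Verify the reference base before substituting.
#' @return A [Biostrings::DNAStringSet] of equal lengths with alternate
#'   alleles substituted.
#' @export
substitute_variants <- function(reference, snps, check_ref = TRUE) {
  stopifnot(methods::is(reference, "DNAStringSet"))
  snv <- nchar(snps$ref_allele) == 1 & nchar(snps$alt_allele) == 1 &
    snps$ref_allele %in% c("A", "C", "G", "T") &
    snps$alt_allele %in% c("A", "C", "G", "T")
  if (any(!snv)) {
    warning("Skipping ", sum(!snv), " non-SNV (indel or non-ACGT) record(s).",
            call. = FALSE)
    snps <- snps[snv, , drop = FALSE]
  }
  missing_chrom <- setdiff(unique(snps$chrom), names(reference))
  if (length(missing_chrom) > 0) {
    stop("SNP chromosome(s) absent from reference: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  out <- reference
  for (ch in unique(snps$chrom)) {
    s <- snps[snps$chrom == ch, , drop = FALSE]
    if (any(s$pos < 1 | s$pos > length(out[[ch]]))) {
      bad <- s[s$pos < 1 | s$pos > length(out[[ch]]), ][1, ]
      stop("Position out of range: ", ch, ":", bad$pos, call. = FALSE)
    }
    if (check_ref) {
      have <- strsplit(as.character(out[[ch]]), "")[[1]][s$pos]
      if (any(have != s$ref_allele)) {
        bad <- which(have != s$ref_allele)[1]
        stop("Reference mismatch at ", ch, ":", s$pos[bad],
             " (expected ", s$ref_allele[bad], ", found ", have[bad], ")",
             call. = FALSE)
      }
    }
    out[[ch]] <- Biostrings::replaceLetterAt(
      out[[ch]], s$pos, paste(s$alt_allele, collapse = ""))
  }
  out
}

#' Read a SNP table from VCF
#'
#' Parses a VCF 4.2 file carrying per-breed supporting depths in the INFO
#' fields `DPC` (Cornish) and `DPW` (White Leghorn), as written by
#' [write_snp_vcf()]. Chromosomes whose name matches `z_pattern` are
#' classed as Z-linked.
#'
#' @param path VCF file path.
#' @param z_pattern Regular expression identifying Z-chromosome names.
#' @return SNP tibble (`chrom`, `pos`, `ref_allele`, `alt_allele`,
#'   `depth_cor`, `depth_wl`, `chromosome_class`).
#' @export
read_snp_vcf <- function(path, z_pattern = "Z") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref_allele = fix$REF,
    alt_allele = fix$ALT,
    depth_cor = as.integer(vcfR::extract.info(v, "DPC")),
    depth_wl = as.integer(vcfR::extract.info(v, "DPW")),
    chromosome_class = ifelse(grepl(z_pattern, fix$CHROM), "Z", "autosome")
  )
}

#' Write a SNP table as VCF 4.2
#'
#' Per-breed depths go into the INFO fields `DPC` and `DPW`.
#'
#' @param snps SNP tibble as produced by [simulate_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DPC,Number=1,Type=Integer,Description=\"Supporting read depth, Cornish\">",
    "##INFO=<ID=DPW,Number=1,Type=Integer,Description=\"Supporting read depth, White Leghorn\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDPC=%d;DPW=%d",
                  snps$chrom, snps$pos, snps$ref_allele, snps$alt_allele,
                  snps$depth_cor, snps$depth_wl)
  readr::write_lines(c(header, body), path)
  invisible(path)
}
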